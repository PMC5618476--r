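#' Parameters for the synthetic two-state LBD model
#'
#' The generator emulates, at C-alpha resolution, the features of a
#' ligand-binding-domain trajectory that the analysis stages consume: a
#' rigid core (pseudo-residues 698-844), a mobile helix-11/loop/helix-12
#' lid (residues 873-908) switching between a closed, agonist-like state
#' and an open, antagonist-like state with isotropic Gaussian positional
#' noise, a ligand whose hydroxyl donor alternates between two acceptor
#' sites (an N705-like OD1 and a T877-like OG1) with a set probability,
#' and per-frame MM-GBSA components drawn around known means. The default
#' state geometry (12 vs 20 Angstrom lid radius against 0.5 Angstrom
#' noise) keeps the two states unambiguous, so downstream recovery tests
#' score against exact ground truth; the default energy means are those of
#' a typical hydroxyflutamide/receptor complex with per-frame SDs of a few
#' kcal/mol.
#'
#' @param n_frames number of frames.
#' @param open_fraction per-frame probability of the open (antagonist-like)
#'   lid state.
#' @param lid_closed_distance,lid_open_distance mean lid-C-alpha-to-core-
#'   center radii, Angstrom.
#' @param noise_sd per-coordinate Gaussian noise SD of lid atoms, Angstrom.
#' @param core_noise_sd noise SD of core atoms (kept small: the core is
#'   rigid), Angstrom.
#' @param p_site_a probability the ligand hydroxyl donor hydrogen-bonds the
#'   N705-like site (vs the T877-like site) in a frame.
#' @param energy_means,energy_sds named numeric vectors over `e_ele`,
#'   `e_vdw`, `g_polar`, `g_nonpolar`, kcal/mol.
#' @param seed RNG seed (single stream for the whole run).
#' @return object of class `"synthetic_params"`.
#' @export
synthetic_params <- function(n_frames = 1000L,
                             open_fraction = 0.0,
                             lid_closed_distance = 12,
                             lid_open_distance = 20,
                             noise_sd = 0.5,
                             core_noise_sd = 0.1,
                             p_site_a = 0.9,
                             energy_means = c(e_ele = -28.21, e_vdw = -40.24,
                                              g_polar = 44.92, g_nonpolar = -5.66),
                             energy_sds = c(e_ele = 3, e_vdw = 2.5,
                                            g_polar = 3, g_nonpolar = 0.3),
                             seed = 1L) {
  stopifnot(n_frames >= 1L,
            open_fraction >= 0, open_fraction <= 1,
            lid_open_distance > lid_closed_distance,
            noise_sd >= 0, core_noise_sd >= 0,
            p_site_a >= 0, p_site_a <= 1)
  need <- c("e_ele", "e_vdw", "g_polar", "g_nonpolar")
  stopifnot(all(need %in% names(energy_means)),
            all(need %in% names(energy_sds)))
  if (any(energy_sds < 0)) stop("energy SDs must be non-negative")
  structure(list(n_frames = as.integer(n_frames),
                 open_fraction = open_fraction,
                 lid_closed_distance = lid_closed_distance,
                 lid_open_distance = lid_open_distance,
                 noise_sd = noise_sd, core_noise_sd = core_noise_sd,
                 p_site_a = p_site_a,
                 energy_means = energy_means[need],
                 energy_sds = energy_sds[need],
                 seed = as.integer(seed)),
            class = "synthetic_params")
}

# Fixed scaffold geometry shared by topology and trajectory generation.
.synthetic_geometry <- function() {
  core_res <- 698:844
  lid_res <- 873:908
  n_core <- length(core_res)
  # core C-alphas on a spherical spiral of radius 10 around the origin
  core_xyz <- fibonacci_sphere(n_core) * 10
  # lid directions: a cap of the unit sphere (z in [0.3, 0.9]), golden-angle
  # spread in azimuth, one fixed direction per lid residue
  i <- seq_along(lid_res)
  zc <- 0.3 + 0.6 * (i - 1) / (length(i) - 1)
  phi <- i * pi * (3 - sqrt(5))
  rr <- sqrt(1 - zc^2)
  lid_dir <- cbind(rr * cos(phi), rr * sin(phi), zc)
  list(core_res = core_res, lid_res = lid_res,
       core_xyz = core_xyz, lid_dir = lid_dir,
       site_a = c(4, 0, 0),     # N705-like acceptor (OD1)
       site_b = c(-4, 0, 0),    # T877-like acceptor (OG1)
       ligand_res = 999L)
}

#' Generate the synthetic LBD-like topology
#'
#' Core pseudo-residues 698-844 (C-alpha only, on a compact spherical
#' scaffold), lid residues 873-908 (C-alpha), acceptor-site atoms OD1 on
#' residue 705 and OG1 on residue 877, and a ligand residue `HF` (id 999)
#' with atoms O4 (hydroxyl oxygen), H11 (hydroxyl hydrogen) and C11.
#' Deterministic: the topology and its attached base coordinates depend
#' only on the fixed scaffold, not on the seed.
#'
#' @param params a [synthetic_params()] (unused fields tolerated; present
#'   for interface symmetry).
#' @return a [topology()] with base coordinates attached as attribute
#'   `"coords"` (the closed-state, noise-free, site-A structure).
#' @export
generate_topology <- function(params = synthetic_params()) {
  g <- .synthetic_geometry()
  atom_name <- character(0); residue_name <- character(0)
  residue_id <- integer(0); record <- character(0)
  xyz <- NULL
  add <- function(an, rn, ri, rec, co) {
    atom_name <<- c(atom_name, an)
    residue_name <<- c(residue_name, rn)
    residue_id <<- c(residue_id, ri)
    record <<- c(record, rec)
    xyz <<- rbind(xyz, matrix(co, ncol = 3L))
  }
  for (j in seq_along(g$core_res)) {
    res <- g$core_res[j]
    rn <- if (res == 705L) "ASN" else "ALA"
    add("CA", rn, res, "ATOM", g$core_xyz[j, ])
    if (res == 705L) add("OD1", "ASN", res, "ATOM", g$site_a)
  }
  lid_xyz_closed <- g$lid_dir * 12
  for (j in seq_along(g$lid_res)) {
    res <- g$lid_res[j]
    rn <- if (res == 877L) "THR" else if (res == 895L) "MET" else "ALA"
    add("CA", rn, res, "ATOM", lid_xyz_closed[j, ])
    if (res == 877L) add("OG1", "THR", res, "ATOM", g$site_b)
  }
  lig <- .ligand_coords(g, site = "A", d = 2.8, tilt = 0, tilt_dir = c(0, 0, 1))
  add("O4", "HF", g$ligand_res, "HETATM", lig["O4", ])
  add("H11", "HF", g$ligand_res, "HETATM", lig["H11", ])
  add("C11", "HF", g$ligand_res, "HETATM", lig["C11", ])
  top <- topology(atom_name, residue_name, residue_id, chain_id = "A",
                  record = record)
  attr(top, "coords") <- xyz
  top
}

# Ligand coordinates bonded to the chosen acceptor site. `d` is the
# donor-acceptor distance; `tilt` bends the acceptor-H-donor angle away
# from linearity in the plane spanned by the bond axis and `tilt_dir`.
.ligand_coords <- function(g, site, d, tilt, tilt_dir) {
  acc <- if (site == "A") g$site_a else g$site_b
  u <- if (site == "A") c(-1, 0, 0) else c(1, 0, 0)   # acceptor -> ligand
  o4 <- acc + d * u
  v <- tilt_dir - sum(tilt_dir * u) * u
  v <- v / sqrt(sum(v^2))
  h_dir <- cos(tilt) * (-u) + sin(tilt) * v            # toward acceptor
  h11 <- o4 + 0.96 * h_dir
  c11 <- o4 + c(0, 1.5, 0)
  rbind(O4 = o4, H11 = h11, C11 = c11)
}

# Uniform rotation matrix from four standard normals (quaternion).
.quaternion_rotation <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3L, 3L, byrow = TRUE)
}

#' Generate a synthetic two-state trajectory
#'
#' Per frame: the lid state is drawn Bernoulli(`open_fraction`); lid
#' C-alphas are placed at their fixed directions times the state's radius
#' plus isotropic Gaussian noise; core atoms jitter with `core_noise_sd`;
#' the ligand hydroxyl is bonded (geometry satisfying the default
#' hydrogen-bond criterion, with realistic distance/angle scatter) to the
#' N705-like site with probability `p_site_a`, else to the T877-like site,
#' the unchosen site being too far for a bond; finally a random global
#' rigid motion is applied to the whole frame, so only superposition- and
#' internal-coordinate-correct analyses recover the ground truth. The true
#' per-frame state and site sequences are attached as attributes
#' `"states"` (`"closed"`/`"open"`) and `"sites"` (`"A"`/`"B"`).
#'
#' @param top topology from [generate_topology()].
#' @param params a [synthetic_params()].
#' @return a [trajectory()] with ground-truth attributes.
#' @export
generate_trajectory <- function(top, params = synthetic_params()) {
  stopifnot(inherits(top, "topology"), inherits(params, "synthetic_params"))
  g <- .synthetic_geometry()
  set.seed(params$seed)
  nf <- params$n_frames
  a <- top$atoms
  core_ca <- which(a$residue_id %in% g$core_res & a$atom_name == "CA")
  od1 <- which(a$atom_name == "OD1")
  og1 <- which(a$atom_name == "OG1")
  lid_ca <- which(a$residue_id %in% g$lid_res & a$atom_name == "CA")
  lig <- match(c("O4", "H11", "C11"), a$atom_name)
  n <- top$n_atoms

  # all stochastic draws happen upfront in a fixed, documented order, so the
  # frame loop below is pure assembly (keeps large runs fast and the stream
  # layout stable)
  states <- ifelse(stats::runif(nf) < params$open_fraction, "open", "closed")
  sites <- ifelse(stats::runif(nf) < params$p_site_a, "A", "B")
  n_core <- length(core_ca)
  n_lid <- length(lid_ca)
  core_noise <- array(stats::rnorm(n_core * 3L * nf, sd = params$core_noise_sd),
                      c(n_core, 3L, nf))
  site_noise <- array(stats::rnorm(2L * 3L * nf, sd = params$core_noise_sd),
                      c(2L, 3L, nf))
  lid_noise <- array(stats::rnorm(n_lid * 3L * nf, sd = params$noise_sd),
                     c(n_lid, 3L, nf))
  dvec <- pmin(3.3, pmax(2.5, 2.8 + 0.15 * stats::rnorm(nf)))
  tiltvec <- pmin(25, abs(stats::rnorm(nf, sd = 8))) * pi / 180
  azvec <- stats::runif(nf, 0, 2 * pi)
  quat <- matrix(stats::rnorm(4L * nf), nf)
  shifts <- matrix(stats::runif(3L * nf, -20, 20), nf)

  radius <- ifelse(states == "open", params$lid_open_distance,
                   params$lid_closed_distance)
  # assemble all unrotated frames at once
  coords <- array(NA_real_, c(n, 3L, nf))
  coords[core_ca, , ] <- array(g$core_xyz, c(n_core, 3L, nf)) + core_noise
  coords[od1, , ] <- g$site_a + site_noise[1L, , ]
  coords[og1, , ] <- g$site_b + site_noise[2L, , ]
  coords[lid_ca, , ] <- array(g$lid_dir, c(n_lid, 3L, nf)) *
    rep(radius, each = n_lid * 3L) + lid_noise
  # ligand geometry, vectorised over frames: the hydroxyl bonds the chosen
  # acceptor along +-x with distance dvec and an off-axis H tilt of tiltvec
  ux <- ifelse(sites == "A", -1, 1)               # acceptor -> ligand
  accx <- ifelse(sites == "A", g$site_a[1L], g$site_b[1L])
  o4 <- rbind(accx + dvec * ux, 0, 0)             # 3 x nf
  hdir <- rbind(cos(tiltvec) * (-ux),
                sin(tiltvec) * cos(azvec),
                sin(tiltvec) * sin(azvec))
  coords[lig[1L], , ] <- o4
  coords[lig[2L], , ] <- o4 + 0.96 * hdir
  coords[lig[3L], , ] <- o4 + c(0, 1.5, 0)
  # per-frame global rigid motion
  for (k in seq_len(nf)) {
    y <- coords[, , k] %*% .quaternion_rotation(quat[k, ])
    y[, 1L] <- y[, 1L] + shifts[k, 1L]
    y[, 2L] <- y[, 2L] + shifts[k, 2L]
    y[, 3L] <- y[, 3L] + shifts[k, 3L]
    coords[, , k] <- y
  }
  traj <- trajectory(top, coords, times = 2 * seq_len(nf))  # 2 ps stride
  attr(traj, "states") <- states
  attr(traj, "sites") <- sites
  attr(traj, "params") <- params
  traj
}

#' Generate a per-frame MM-GBSA component table with known truth
#'
#' Seeded Gaussian draws around `params$energy_means` with
#' `params$energy_sds`, one row per frame. The true means are attached as
#' attribute `"truth"`.
#'
#' @param params a [synthetic_params()].
#' @return data frame `frame`, `e_ele`, `e_vdw`, `g_polar`, `g_nonpolar`.
#' @export
generate_energy_components <- function(params = synthetic_params()) {
  stopifnot(inherits(params, "synthetic_params"))
  set.seed(params$seed + 1L)
  nf <- params$n_frames
  df <- data.frame(frame = seq_len(nf))
  for (comp in names(params$energy_means)) {
    df[[comp]] <- stats::rnorm(nf, params$energy_means[[comp]],
                               params$energy_sds[[comp]])
  }
  attr(df, "truth") <- params$energy_means
  df
}

#' Write the generator's ground truth as a JSON sidecar
#'
#' @param traj a trajectory from [generate_trajectory()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(traj, path) {
  p <- attr(traj, "params")
  jsonlite::write_json(list(
    states = attr(traj, "states"),
    sites = attr(traj, "sites"),
    open_fraction = p$open_fraction,
    p_site_a = p$p_site_a,
    lid_closed_distance = p$lid_closed_distance,
    lid_open_distance = p$lid_open_distance,
    noise_sd = p$noise_sd,
    seed = p$seed
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
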