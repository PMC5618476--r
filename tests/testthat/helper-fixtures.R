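# Shared fixtures and independent oracles, all built in code at test time.

# A minimal 3-residue PDB text block (author numbering with gaps).
tiny_pdb_lines <- function() {
  c(
    "ATOM      1  N   ALA A 698       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A 698       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  OD1 ASN A 705       3.000   4.000   0.000  1.00  0.00           O",
    "ATOM      4  CA  MET A 908      -2.500   1.250   9.875  1.00  0.00           C",
    "END"
  )
}

write_tiny_pdb <- function(lines = tiny_pdb_lines()) {
  path <- withr::local_tempfile(fileext = ".pdb",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# Small in-code topology: n residues, one CA each, residue ids given.
make_ca_topology <- function(residue_ids, coords,
                             atom_names = rep("CA", length(residue_ids))) {
  top <- topology(atom_name = atom_names,
                  residue_name = rep("ALA", length(residue_ids)),
                  residue_id = residue_ids)
  attr(top, "coords") <- coords
  top
}

random_rotation_matrix <- function() {
  q <- rnorm(4L); q <- q / sqrt(sum(q^2))
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3L, 3L, byrow = TRUE)
}

rigid_move <- function(coords, rot = random_rotation_matrix(),
                       shift = runif(3L, -10, 10)) {
  sweep(coords %*% rot, 2L, shift, `+`)
}

euler_rotation <- function(a, b, g) {
  rz <- function(t) matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0, 0, 0, 1),
                           3L, 3L, byrow = TRUE)
  ry <- function(t) matrix(c(cos(t), 0, sin(t), 0, 1, 0, -sin(t), 0, cos(t)),
                           3L, 3L, byrow = TRUE)
  rz(a) %*% ry(b) %*% rz(g)
}

# Brute-force superposition oracle: multi-start nested grid search over ZYZ
# Euler angles (centering removes the translation), refined until the grid
# spacing is far below the rotational scale that moves the RMSD by 1e-4.
# Independent of the SVD route used by superpose(). The per-rotation cost is
# reduced through the algebraic identity
#   sum((mc R^T - rc)^2) = sum(mc^2) + sum(rc^2) - 2 trace(R H),  H = mc^T rc,
# verified against the direct formula below.
oracle_superpose_rmsd <- function(mobile, reference) {
  mc <- sweep(mobile, 2L, colMeans(mobile))
  rc <- sweep(reference, 2L, colMeans(reference))
  n <- nrow(mc)
  s0 <- sum(mc^2) + sum(rc^2)
  ht <- t(crossprod(mc, rc))   # t(H), so trace(R H) = sum(R * t(H))
  rmsd_of <- function(a, b, g) {
    rot <- euler_rotation(a, b, g)
    sqrt(max(0, (s0 - 2 * sum(rot * ht)) / n))
  }
  # sanity-check the identity against the direct computation once
  fitted <- mc %*% t(euler_rotation(0.3, 0.7, 1.1))
  stopifnot(abs(rmsd_of(0.3, 0.7, 1.1) -
                  sqrt(mean(rowSums((fitted - rc)^2)))) < 1e-9)

  grid <- expand.grid(a = seq(0, 2 * pi, length.out = 13L)[-13L],
                      b = seq(0, pi, length.out = 9L),
                      g = seq(0, 2 * pi, length.out = 13L)[-13L])
  vals <- mapply(rmsd_of, grid$a, grid$b, grid$g)
  starts <- grid[order(vals)[1:8], ]
  best_val <- Inf
  for (s in seq_len(nrow(starts))) {
    best <- as.numeric(starts[s, ])
    span <- 0.45
    for (lev in 1:22) {
      cand <- expand.grid(a = best[1L] + seq(-span, span, length.out = 5L),
                          b = best[2L] + seq(-span, span, length.out = 5L),
                          g = best[3L] + seq(-span, span, length.out = 5L))
      v <- mapply(rmsd_of, cand$a, cand$b, cand$g)
      best <- as.numeric(cand[which.min(v), ])
      span <- span * 0.6
    }
    best_val <- min(best_val, rmsd_of(best[1L], best[2L], best[3L]))
  }
  best_val
}

# Coordinates of a donor/H/acceptor triple realising a prescribed
# donor-acceptor distance (Angstrom) and acceptor-H-donor angle (degrees),
# with a 0.96 Angstrom donor-H bond.
hbond_triple_coords <- function(distance, angle_deg) {
  d <- c(0, 0, 0)
  h <- c(0.96, 0, 0)
  theta <- (180 - angle_deg) * pi / 180   # direction of H->A from +x
  dir <- c(cos(theta), sin(theta), 0)
  # solve |h + r*dir| = distance for r > 0
  bq <- 2 * sum(h * dir)
  cq <- sum(h^2) - distance^2
  r <- (-bq + sqrt(bq^2 - 4 * cq)) / 2
  list(donor = d, hydrogen = h, acceptor = h + r * dir)
}

# The published six-system binding free-energy table (kcal/mol), used as a
# validation fixture: components, enthalpy-like sum, entropy term, total.
published_energy_table <- function() {
  data.frame(
    system = c("WT", "T877A", "W741C", "F876L", "W741C_T877A", "F876L_T877A"),
    e_ele = c(-28.21, -32.34, -23.22, -23.38, -36.67, -24.34),
    e_vdw = c(-40.24, -40.16, -38.36, -39.45, -39.89, -35.36),
    g_polar = c(44.92, 47.45, 41.52, 39.42, 53.16, 39.47),
    g_nonpolar = c(-5.66, -5.63, -5.53, -5.63, -5.67, -5.19),
    e_bind = c(-29.19, -30.67, -25.60, -29.04, -29.08, -25.31),
    minus_t_ds = c(23.12, 22.25, 23.10, 20.82, 23.12, 20.79),
    g_bind = c(-6.07, -8.42, -2.50, -8.22, -5.77, -4.52)
  )
}

# The published hydrogen-bond geometry entries (distance Angstrom, angle deg).
published_hbond_geometries <- function() {
  data.frame(
    distance = c(2.71, 2.87, 2.87, 2.68, 2.68, 2.89, 2.86, 2.75, 2.77,
                 2.67, 2.67, 2.70, 2.71),
    angle = c(159.15, 161.89, 162.05, 160.73, 160.34, 163.49, 163.88,
              162.15, 162.13, 161.27, 161.54, 160.91, 160.44)
  )
}
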