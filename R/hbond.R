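#' Geometric hydrogen-bond criterion
#'
#' The standard two-condition geometric definition used in trajectory
#' analysis: donor-to-acceptor heavy-atom distance strictly below a cutoff
#' (default 3.5 Angstrom, i.e. 0.35 nm) and the acceptor-hydrogen-donor
#' angle (vertex at the hydrogen) strictly above a minimum (default 120
#' degrees; near-linear bonds approach 180).
#'
#' @param max_distance donor-acceptor heavy-atom cutoff, Angstrom.
#' @param min_angle acceptor-H-donor angle minimum, degrees.
#' @return object of class `"hbond_criterion"`.
#' @export
hbond_criterion <- function(max_distance = 3.5, min_angle = 120) {
  stopifnot(max_distance > 0, min_angle > 0, min_angle <= 180)
  structure(list(max_distance = max_distance, min_angle = min_angle),
            class = "hbond_criterion")
}

#' Evaluate the hydrogen-bond criterion on one donor/H/acceptor triple
#'
#' @param donor_xyz,hydrogen_xyz,acceptor_xyz length-3 coordinates (Angstrom).
#' @param criterion an [hbond_criterion()].
#' @return list with `bond` (logical), `distance` (donor-acceptor heavy-atom
#'   distance, Angstrom) and `angle` (acceptor-H-donor angle, degrees).
#' @export
is_hbond <- function(donor_xyz, hydrogen_xyz, acceptor_xyz,
                     criterion = hbond_criterion()) {
  d <- as.numeric(donor_xyz); h <- as.numeric(hydrogen_xyz)
  a <- as.numeric(acceptor_xyz)
  dh <- sqrt(sum((h - d)^2))
  if (dh > 1.5) {
    stop("hydrogen is ", format(round(dh, 2)), " Angstrom from the donor ",
         "(> 1.5); mislabeled donor/H/acceptor triple?")
  }
  dist <- sqrt(sum((a - d)^2))
  v1 <- a - h
  v2 <- d - h
  cosang <- sum(v1 * v2) / (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))
  angle <- acos(max(-1, min(1, cosang))) * 180 / pi
  list(bond = (dist < criterion$max_distance) && (angle > criterion$min_angle),
       distance = dist, angle = angle)
}

#' Hydrogen-bond occupancy over a trajectory
#'
#' Evaluates the geometric criterion for one declared donor/H/acceptor
#' triple in every frame and reports occupancy (percentage of frames
#' satisfying the bond, to two decimals) over the full trajectory and over
#' the final `window_last_frames` frames — the convention of reporting a
#' whole run alongside its equilibrated tail. Mean distance and angle are
#' averaged over the satisfying frames of each window; when a window has no
#' satisfying frame those means are `NA` (flagged absent).
#'
#' @param traj a [trajectory()].
#' @param donor,hydrogen,acceptor length-2 `(residue_id, atom_name)` specs.
#' @param criterion an [hbond_criterion()].
#' @param window_last_frames size of the tail window; default the last sixth
#'   of the trajectory (the "last 10 ns of a 60 ns run" convention).
#' @param means_over `"satisfying"` (default) averages distance/angle over
#'   frames meeting the criterion; `"all"` averages over every frame of the
#'   window.
#' @return object of class `"hbond_series"`: list with the triple, logical
#'   `per_frame`, `occupancy_full`, `occupancy_window` (percent),
#'   `mean_distance_full/window` (Angstrom), `mean_angle_full/window`
#'   (degrees) and `window_last_frames`.
#' @export
hbond_occupancy <- function(traj, donor, hydrogen, acceptor,
                            criterion = hbond_criterion(),
                            window_last_frames = NULL,
                            means_over = c("satisfying", "all")) {
  means_over <- match.arg(means_over)
  nf <- n_frames(traj)
  if (is.null(window_last_frames)) {
    window_last_frames <- max(1L, nf %/% 6L)
  }
  window_last_frames <- as.integer(window_last_frames)
  if (window_last_frames < 1L) stop("window must contain at least 1 frame")
  if (window_last_frames > nf) {
    stop("window (", window_last_frames, ") exceeds frame count (", nf, ")")
  }
  top <- traj$topology
  id <- .atom_index(top, as.integer(donor[[1L]]), as.character(donor[[2L]]))
  ih <- .atom_index(top, as.integer(hydrogen[[1L]]), as.character(hydrogen[[2L]]))
  ia <- .atom_index(top, as.integer(acceptor[[1L]]), as.character(acceptor[[2L]]))
  bond <- logical(nf); dist <- numeric(nf); ang <- numeric(nf)
  for (k in seq_len(nf)) {
    x <- frame_coords(traj, k)
    r <- is_hbond(x[id, ], x[ih, ], x[ia, ], criterion)
    bond[k] <- r$bond; dist[k] <- r$distance; ang[k] <- r$angle
  }
  win <- seq.int(nf - window_last_frames + 1L, nf)
  stat <- function(v, frames) {
    use <- if (means_over == "satisfying") frames[bond[frames]] else frames
    if (length(use) == 0L) NA_real_ else mean(v[use])
  }
  structure(list(
    donor = donor, hydrogen = hydrogen, acceptor = acceptor,
    per_frame = bond,
    occupancy_full = round(100 * mean(bond), 2L),
    occupancy_window = round(100 * mean(bond[win]), 2L),
    mean_distance_full = stat(dist, seq_len(nf)),
    mean_distance_window = stat(dist, win),
    mean_angle_full = stat(ang, seq_len(nf)),
    mean_angle_window = stat(ang, win),
    window_last_frames = window_last_frames
  ), class = "hbond_series")
}

#' @export
print.hbond_series <- function(x, ...) {
  cat(sprintf("H-bond %s@%s-%s...%s@%s: occupancy %.2f%% (full), %.2f%% (last %d frames)\n",
              x$donor[[1L]], x$donor[[2L]], x$hydrogen[[2L]],
              x$acceptor[[1L]], x$acceptor[[2L]],
              x$occupancy_full, x$occupancy_window, x$window_last_frames))
  invisible(x)
}

#' Write a hydrogen-bond report table
#'
#' One row per analysed triple: interaction pair, mean distance and angle,
#' and occupancy, each for the full trajectory and the tail window —
#' mirroring the two-window layout conventional in MD hydrogen-bond tables.
#'
#' @param series list of [hbond_occupancy()] results.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hbond_report <- function(series, path) {
  fmt <- function(v) ifelse(is.na(v), "-", sprintf("%.2f", v))
  rows <- vapply(series, function(s) {
    pair <- sprintf("%s@%s-%s...%s (%s)", s$donor[[1L]], s$donor[[2L]],
                    s$hydrogen[[2L]], s$acceptor[[1L]], s$acceptor[[2L]])
    paste(pair,
          fmt(s$mean_distance_full), fmt(s$mean_distance_window),
          fmt(s$mean_angle_full), fmt(s$mean_angle_window),
          sprintf("%.2f", s$occupancy_full),
          sprintf("%.2f", s$occupancy_window), sep = "\t")
  }, character(1L))
  writeLines(c(paste("interaction_pair", "distance_full", "distance_window",
                     "angle_full", "angle_window",
                     "occupancy_full_pct", "occupancy_window_pct", sep = "\t"),
               rows), path)
  invisible(path)
}
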