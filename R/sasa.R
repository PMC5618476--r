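#' Deterministic unit-sphere point set (Fibonacci lattice)
#'
#' @param n number of points.
#' @return n x 3 matrix of unit vectors.
#' @keywords internal
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- pi * (1 + sqrt(5)) * i
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Numerical SASA: each atom's sphere of radius `r_i + probe` is sampled on
#' a deterministic Fibonacci lattice; a sample point is exposed iff it lies
#' outside every other atom's expanded sphere. The per-atom area is
#' `4*pi*(r_i + probe)^2` times the exposed fraction. Deterministic for a
#' given `n_sphere_points` (no random sampling).
#'
#' @param frame n_atoms x 3 coordinates (Angstrom).
#' @param radii per-atom radii (Angstrom).
#' @param probe probe radius (Angstrom), default 1.4 (water).
#' @param n_sphere_points lattice size per atom, default 960.
#' @return numeric vector of per-atom SASA (Angstrom^2).
#' @export
sasa <- function(frame, radii, probe = 1.4, n_sphere_points = 960L) {
  stopifnot(is.matrix(frame), ncol(frame) == 3L)
  n <- nrow(frame)
  if (length(radii) != n) stop("one radius per atom required")
  if (any(!is.finite(radii)) || any(radii <= 0)) stop("radii must be positive")
  if (n_sphere_points < 100L) stop("n_sphere_points must be at least 100")
  if (n > 1L) {
    d2 <- .cross_dist2(frame, frame)
    diag(d2) <- Inf
    if (any(d2 < 1e-12)) stop("two atoms share identical coordinates")
  }
  pts <- fibonacci_sphere(n_sphere_points)
  rx <- radii + probe
  out <- numeric(n)
  for (i in seq_len(n)) {
    sphere <- sweep(pts * rx[i], 2L, frame[i, ], `+`)
    exposed <- rep(TRUE, n_sphere_points)
    if (n > 1L) {
      # only neighbours close enough to occlude matter
      dij2 <- colSums((t(frame) - frame[i, ])^2)
      nb <- which(dij2 < (rx[i] + rx)^2 & seq_len(n) != i)
      for (j in nb) {
        if (!any(exposed)) break
        dj2 <- colSums((t(sphere[exposed, , drop = FALSE]) - frame[j, ])^2)
        exposed[exposed] <- dj2 >= rx[j]^2
      }
    }
    out[i] <- 4 * pi * rx[i]^2 * mean(exposed)
  }
  out
}
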