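#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation that minimise the RMSD between
#' the fit atoms of a mobile structure and a reference, by singular value
#' decomposition of the cross-covariance matrix with reflection correction
#' (the sign of the smallest singular value's contribution is flipped when
#' the optimal orthogonal matrix would be a reflection).
#'
#' @param mobile,reference n_atoms x 3 coordinate matrices (Angstrom).
#' @param fit_selection optional [select()] result (or integer indices)
#'   naming the atoms used for the fit; default all atoms.
#' @return object of class `"superposition"`: list with `rotation` (3 x 3,
#'   det = +1), `translation` (length-3, Angstrom), `rmsd` (Angstrom, over
#'   the fit atoms after transform). The transform maps mobile coordinates
#'   `x` to `x %*% rotation + translation` (rows are atoms).
#' @export
superpose <- function(mobile, reference, fit_selection = NULL) {
  idx <- .sel_indices(fit_selection, nrow(mobile))
  stopifnot(nrow(mobile) == nrow(reference))
  m <- mobile[idx, , drop = FALSE]
  r <- reference[idx, , drop = FALSE]
  if (nrow(m) < 3L) stop("superposition needs at least 3 fit atoms")
  cm <- colMeans(m)
  cr <- colMeans(r)
  mc <- sweep(m, 2L, cm)
  rc <- sweep(r, 2L, cr)
  sv_m <- svd(mc)$d
  if (sv_m[2L] < 1e-8 * max(sv_m[1L], 1e-12)) {
    stop("fit atoms are collinear; superposition is degenerate")
  }
  h <- crossprod(mc, rc)           # 3x3 cross-covariance
  s <- svd(h)
  d <- sign(det(s$u %*% t(s$v)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  trans <- cr - drop(cm %*% rot)
  fitted <- sweep(m %*% rot, 2L, trans, `+`)
  rmsd <- sqrt(mean(rowSums((fitted - r)^2)))
  structure(list(rotation = rot, translation = trans, rmsd = rmsd),
            class = "superposition")
}

#' Apply a superposition transform to coordinates
#' @param sp a `"superposition"` from [superpose()].
#' @param coords n x 3 matrix.
#' @return transformed n x 3 matrix.
#' @export
apply_superposition <- function(sp, coords) {
  sweep(coords %*% sp$rotation, 2L, sp$translation, `+`)
}

.sel_indices <- function(sel, n_atoms) {
  if (is.null(sel)) return(seq_len(n_atoms))
  idx <- if (inherits(sel, "selection")) sel$indices else as.integer(sel)
  if (length(idx) == 0L) stop("empty selection")
  if (any(idx < 1L | idx > n_atoms)) stop("selection indices out of range")
  idx
}

.rmsd_between <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

#' Per-frame RMSD time series
#'
#' Each frame is superposed onto the reference over `fit_selection`, then the
#' RMSD is measured over `measure_selection` (the two may differ: e.g. fit on
#' protein backbone, measure the ligand heavy atoms — the convention used
#' when monitoring trajectory convergence relative to the initial structure).
#'
#' @param traj a [trajectory()].
#' @param reference n_atoms x 3 reference coordinates; default frame 1.
#' @param fit_selection,measure_selection [select()] results or index
#'   vectors; `measure_selection` defaults to `fit_selection`.
#' @return data frame with columns `frame` and `rmsd` (Angstrom).
#' @export
rmsd_series <- function(traj, reference = NULL, fit_selection = NULL,
                        measure_selection = fit_selection) {
  if (is.null(reference)) reference <- frame_coords(traj, 1L)
  n <- traj$topology$n_atoms
  fit <- .sel_indices(fit_selection, n)
  meas <- .sel_indices(measure_selection, n)
  nf <- n_frames(traj)
  out <- numeric(nf)
  ref_meas <- reference[meas, , drop = FALSE]
  for (k in seq_len(nf)) {
    x <- frame_coords(traj, k)
    sp <- superpose(x, reference, fit)
    out[k] <- .rmsd_between(apply_superposition(sp, x[meas, , drop = FALSE]),
                            ref_meas)
  }
  data.frame(frame = seq_len(nf), rmsd = out)
}

#' Per-residue root mean square fluctuation
#'
#' Frames are first superposed onto a reference frame over `fit_selection`
#' (removing global rigid motion), then for each selected atom
#' `RMSF = sqrt(mean |r - <r>|^2)` about its mean position over all frames.
#' Intended for one C-alpha per residue; results are reported per residue.
#'
#' @param traj a [trajectory()].
#' @param selection atoms to report (one per residue, e.g. `name CA`).
#' @param fit_selection atoms used for the superposition; defaults to
#'   `selection`.
#' @param reference `"first"` (default) fits to frame 1; `"mean"` fits to
#'   frame 1 first and then refits to the resulting mean structure.
#' @param align set `FALSE` to skip the superposition step entirely (for
#'   trajectories already free of global rigid motion).
#' @return data frame with columns `residue_id` and `rmsf` (Angstrom).
#' @export
rmsf <- function(traj, selection, fit_selection = selection,
                 reference = c("first", "mean"), align = TRUE) {
  reference <- match.arg(reference)
  nf <- n_frames(traj)
  if (nf < 2L) stop("RMSF needs at least 2 frames")
  n <- traj$topology$n_atoms
  sel <- .sel_indices(selection, n)
  fit <- .sel_indices(fit_selection, n)
  align_to <- function(ref) {
    arr <- array(NA_real_, c(length(sel), 3L, nf))
    for (k in seq_len(nf)) {
      x <- frame_coords(traj, k)
      if (align) {
        sp <- superpose(x, ref, fit)
        arr[, , k] <- apply_superposition(sp, x[sel, , drop = FALSE])
      } else {
        arr[, , k] <- x[sel, , drop = FALSE]
      }
    }
    arr
  }
  ref <- frame_coords(traj, 1L)
  arr <- align_to(ref)
  if (reference == "mean") {
    mean_full <- ref
    mean_full[sel, ] <- apply(arr, c(1L, 2L), mean)
    # refit against the mean structure (fit atoms must be within selection
    # for the mean to be defined; otherwise keep first-frame fit)
    if (all(fit %in% sel)) {
      ref2 <- frame_coords(traj, 1L)
      ref2[sel, ] <- mean_full[sel, ]
      arr <- align_to(ref2)
    }
  }
  mean_pos <- apply(arr, c(1L, 2L), mean)
  dev2 <- vapply(seq_len(nf), function(k) {
    rowSums((matrix(arr[, , k], ncol = 3L) - mean_pos)^2)
  }, numeric(length(sel)))
  dev2 <- matrix(dev2, nrow = length(sel))
  vals <- sqrt(rowMeans(dev2))
  data.frame(residue_id = traj$topology$atoms$residue_id[sel], rmsf = vals)
}

#' Weighted center of a group of atoms
#'
#' @param frame n_atoms x 3 coordinates.
#' @param top the [topology()] (needed for masses).
#' @param selection [select()] result or indices.
#' @param weighting `"mass"` (default) or `"geometric"`.
#' @return length-3 vector (Angstrom).
#' @export
mass_center <- function(frame, top, selection = NULL,
                        weighting = c("mass", "geometric")) {
  weighting <- match.arg(weighting)
  idx <- .sel_indices(selection, nrow(frame))
  w <- if (weighting == "mass") top$atoms$mass[idx] else rep(1, length(idx))
  tw <- sum(w)
  if (tw <= 0) stop("zero total weight in mass_center")
  drop(w %*% frame[idx, , drop = FALSE]) / tw
}

.atom_index <- function(top, residue_id, atom_name) {
  i <- which(top$atoms$residue_id == residue_id &
               top$atoms$atom_name == atom_name)
  if (length(i) != 1L) {
    stop("atom (", residue_id, ", ", atom_name, ") ",
         if (length(i) == 0L) "not found" else "is not unique")
  }
  i
}

#' Distance time series between two named atoms
#'
#' Plain per-frame Euclidean distance; no superposition is applied because
#' an intramolecular distance is frame-internal (rigid-motion invariant).
#' Atoms are addressed as `(residue_id, atom_name)` pairs in author
#' numbering, e.g. `c(895, "CE")` vs the ligand's `c(999, "C11")`.
#'
#' @param traj a [trajectory()].
#' @param atom_a,atom_b length-2 vectors `(residue_id, atom_name)`.
#' @return data frame with columns `frame` and `distance` (Angstrom).
#' @export
distance_series <- function(traj, atom_a, atom_b) {
  ia <- .atom_index(traj$topology, as.integer(atom_a[[1L]]), as.character(atom_a[[2L]]))
  ib <- .atom_index(traj$topology, as.integer(atom_b[[1L]]), as.character(atom_b[[2L]]))
  d <- sqrt(colSums((traj$coords[ia, , ] - traj$coords[ib, , ])^2))
  data.frame(frame = seq_len(n_frames(traj)), distance = d)
}

#' Write a numeric series as tab-separated text
#'
#' Writes `# `-prefixed header comment lines followed by tab-separated
#' columns — the plottable format emitted by the pipeline for RMSD, RMSF
#' and distance series.
#'
#' @param df data frame.
#' @param path output path.
#' @param comments character vector of header comments (without `#`).
#' @return `path`, invisibly.
#' @export
write_series <- function(df, path, comments = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments)) writeLines(paste("#", comments), con)
  writeLines(paste(colnames(df), collapse = "\t"), con)
  lines <- do.call(paste, c(lapply(df, function(col) {
    if (is.numeric(col) && !is.integer(col)) sprintf("%.6f", col) else as.character(col)
  }), sep = "\t"))
  writeLines(lines, con)
  invisible(path)
}
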