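#' Construct a trajectory
#'
#' A trajectory couples a [topology()] with an ordered set of coordinate
#' frames. Coordinates are Angstrom; optional frame times are picoseconds.
#'
#' @param top a [topology()].
#' @param coords n_atoms x 3 x n_frames numeric array, or a list of
#'   n_atoms x 3 matrices.
#' @param times optional numeric vector of frame times (ps).
#' @return an object of class `"trajectory"`: list with `topology`, `coords`
#'   (n_atoms x 3 x n_frames array) and `times`.
#' @export
trajectory <- function(top, coords, times = NULL) {
  stopifnot(inherits(top, "topology"))
  if (is.list(coords)) {
    coords <- array(unlist(lapply(coords, t), use.names = FALSE),
                    dim = c(3L, top$n_atoms, length(coords)))
    coords <- aperm(coords, c(2L, 1L, 3L))
  }
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2L] == 3L)
  if (dim(coords)[1L] != top$n_atoms) {
    stop("coordinate frames have ", dim(coords)[1L],
         " atoms but topology has ", top$n_atoms)
  }
  if (any(!is.finite(coords))) stop("non-finite coordinates")
  if (!is.null(times)) stopifnot(length(times) == dim(coords)[3L])
  structure(list(topology = top, coords = coords, times = times),
            class = "trajectory")
}

#' Number of frames in a trajectory
#' @param traj a [trajectory()].
#' @return integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[3L]

#' Extract one frame's coordinates
#' @param traj a [trajectory()].
#' @param i frame index (1-based).
#' @return n_atoms x 3 matrix (Angstrom).
#' @export
frame_coords <- function(traj, i) {
  m <- traj$coords[, , i, drop = FALSE]
  dim(m) <- dim(m)[1:2]
  m
}

#' @export
print.trajectory <- function(x, ...) {
  cat("trajectory:", n_frames(x), "frames x", x$topology$n_atoms, "atoms\n")
  invisible(x)
}

#' Read a trajectory
#'
#' Two plain-text formats are supported:
#' \describe{
#'   \item{`pdb-multimodel`}{standard MODEL/ENDMDL multi-model PDB; atom
#'     order must match the topology.}
#'   \item{`xyz-frames`}{per frame, one header line `n_atoms [time_ps]`
#'     followed by `n_atoms` lines of `x y z` in Angstrom.}
#' }
#' Frames are returned in file order. An atom-count mismatch or a truncated
#' final frame is rejected with the offending frame number.
#'
#' @param path input file.
#' @param top the [topology()] the frames belong to.
#' @param format `"pdb-multimodel"` or `"xyz-frames"` (default guessed from
#'   the extension: `.pdb` vs anything else).
#' @return a [trajectory()].
#' @export
read_trajectory <- function(path, top,
                            format = c("auto", "pdb-multimodel", "xyz-frames")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE))
      "pdb-multimodel" else "xyz-frames"
  }
  if (format == "pdb-multimodel") .read_traj_pdb(path, top)
  else .read_traj_xyz(path, top)
}

.read_traj_pdb <- function(path, top) {
  lines <- readLines(path, warn = FALSE)
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  starts <- grep("^MODEL", lines)
  ends <- grep("^ENDMDL", lines)
  if (length(starts) == 0L) {  # single implicit model
    starts <- 1L; ends <- length(lines)
  }
  if (length(starts) != length(ends)) {
    stop("unbalanced MODEL/ENDMDL records (truncated final frame?) in ", path)
  }
  n <- top$n_atoms
  frames <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    sel <- which(is_atom & seq_along(lines) >= starts[k] &
                   seq_along(lines) <= ends[k])
    if (length(sel) != n) {
      stop("frame ", k, " has ", length(sel), " atoms; expected ", n)
    }
    xyz <- matrix(NA_real_, n, 3L)
    for (j in seq_along(sel)) {
      f <- .parse_pdb_atom_line(lines[sel[j]])
      xyz[j, ] <- c(f$x, f$y, f$z)
    }
    if (anyNA(xyz)) stop("unparseable coordinates in frame ", k, " of ", path)
    frames[[k]] <- xyz
  }
  trajectory(top, frames)
}

.read_traj_xyz <- function(path, top) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  n <- top$n_atoms
  frames <- list()
  times <- numeric(0)
  has_time <- TRUE
  pos <- 1L
  k <- 0L
  while (pos <= length(lines)) {
    k <- k + 1L
    hdr <- strsplit(trimws(lines[pos]), "\\s+")[[1L]]
    n_decl <- suppressWarnings(as.integer(hdr[1L]))
    if (is.na(n_decl)) stop("malformed frame header at frame ", k)
    if (n_decl != n) {
      stop("frame ", k, " declares ", n_decl, " atoms; topology has ", n)
    }
    if (length(hdr) >= 2L) times[k] <- as.numeric(hdr[2L]) else has_time <- FALSE
    if (pos + n > length(lines)) stop("truncated final frame ", k, " in ", path)
    block <- lines[(pos + 1L):(pos + n)]
    xyz <- matrix(suppressWarnings(as.numeric(
      unlist(strsplit(trimws(block), "\\s+"), use.names = FALSE))),
      ncol = 3L, byrow = TRUE)
    if (nrow(xyz) != n || anyNA(xyz)) {
      stop("frame ", k, " has malformed coordinate lines (expected ", n,
           " rows of 'x y z')")
    }
    frames[[k]] <- xyz
    pos <- pos + n + 1L
  }
  if (length(frames) == 0L) stop("no frames in ", path)
  trajectory(top, frames, times = if (has_time) times else NULL)
}

#' Write a trajectory
#'
#' @param traj a [trajectory()].
#' @param path output file.
#' @param format `"pdb-multimodel"` or `"xyz-frames"`. PDB coordinates carry
#'   three decimals (1e-3 Angstrom round-trip precision); xyz-frames are
#'   written with six decimals.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path,
                             format = c("pdb-multimodel", "xyz-frames")) {
  format <- match.arg(format)
  con <- file(path, "w")
  on.exit(close(con))
  nf <- n_frames(traj)
  if (format == "pdb-multimodel") {
    for (k in seq_len(nf)) {
      writeLines(sprintf("MODEL %8d", k), con)
      .write_model_atoms(con, traj$topology, frame_coords(traj, k))
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
  } else {
    n <- traj$topology$n_atoms
    for (k in seq_len(nf)) {
      hdr <- if (!is.null(traj$times)) {
        sprintf("%d %.6g", n, traj$times[k])
      } else sprintf("%d", n)
      writeLines(hdr, con)
      xyz <- frame_coords(traj, k)
      writeLines(sprintf("%.6f %.6f %.6f", xyz[, 1L], xyz[, 2L], xyz[, 3L]), con)
    }
  }
  invisible(path)
}
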