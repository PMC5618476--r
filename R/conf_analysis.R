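#' Lid distance-feature matrix
#'
#' The internal-coordinate description of the helix-11/loop/helix-12 "lid":
#' per frame, the Euclidean distances from each lid C-alpha (residues
#' 873-908 in androgen-receptor numbering, 36 features) to the mass center
#' of the rigid core (residues 698-844). Because every feature is an
#' intramolecular distance, the matrix is invariant under global rigid
#' motion — no superposition is needed or applied.
#'
#' @param traj a [trajectory()].
#' @param lid [select()] result resolving one C-alpha per lid residue.
#' @param core [select()] result for the core region.
#' @param weighting center weighting, `"mass"` (default) or `"geometric"`.
#' @return object of class `"lid_features"`: list with `features` (frames x
#'   n_lid matrix, Angstrom, columns named by residue id), `lid_residues`,
#'   `core_residues`.
#' @export
lid_distance_features <- function(traj, lid, core,
                                  weighting = c("mass", "geometric")) {
  weighting <- match.arg(weighting)
  top <- traj$topology
  lid_idx <- .sel_indices(lid, top$n_atoms)
  lid_res <- top$atoms$residue_id[lid_idx]
  if (anyDuplicated(lid_res)) {
    stop("lid selection must resolve one atom (C-alpha) per residue")
  }
  if (!all(top$atoms$atom_name[lid_idx] == "CA")) {
    stop("lid residue(s) without a C-alpha in the selection: ",
         paste(lid_res[top$atoms$atom_name[lid_idx] != "CA"], collapse = ", "))
  }
  core_idx <- .sel_indices(core, top$n_atoms)
  nf <- n_frames(traj)
  feats <- matrix(NA_real_, nf, length(lid_idx),
                  dimnames = list(NULL, lid_res))
  for (k in seq_len(nf)) {
    x <- frame_coords(traj, k)
    cc <- mass_center(x, top, core_idx, weighting)
    feats[k, ] <- sqrt(colSums((t(x[lid_idx, , drop = FALSE]) - cc)^2))
  }
  structure(list(features = feats, lid_residues = lid_res,
                 core_residues = sort(unique(top$atoms$residue_id[core_idx]))),
            class = "lid_features")
}

#' Principal component analysis of a distance-feature ensemble
#'
#' Builds the covariance of the feature columns with ensemble-average (1/N)
#' normalisation — `sigma_ij = <(d_i - <d_i>)(d_j - <d_j>)>`, the angle
#' brackets averaging over sampled conformations — and diagonalises it.
#' Eigenvalues are sorted descending; each eigenvector's sign is fixed so
#' that its largest-magnitude coefficient is positive, making the output
#' reproducible across linear-algebra backends.
#'
#' @param features a `"lid_features"` object or a plain frames x p matrix.
#' @param normalization `"population"` (1/N, default, matching the
#'   ensemble-average definition) or `"sample"` (1/(N-1)).
#' @return object of class `"distance_pca"`: list with `feature_means`,
#'   `covariance`, `eigenvalues`, `pc_vectors` (orthonormal columns, PC1
#'   first) and `scores` (training projections onto all PCs).
#' @export
lid_pca <- function(features, normalization = c("population", "sample")) {
  normalization <- match.arg(normalization)
  x <- if (inherits(features, "lid_features")) features$features else features
  stopifnot(is.matrix(x))
  if (nrow(x) < 2L) stop("PCA needs at least 2 frames")
  if (any(!is.finite(x))) stop("non-finite feature value")
  n <- nrow(x)
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu)
  denom <- if (normalization == "population") n else n - 1L
  covm <- crossprod(xc) / denom
  eg <- eigen(covm, symmetric = TRUE)
  vals <- pmax(eg$values, 0)        # clip tiny negative round-off
  vecs <- eg$vectors
  for (j in seq_len(ncol(vecs))) {
    i_max <- which.max(abs(vecs[, j]))
    if (vecs[i_max, j] < 0) vecs[, j] <- -vecs[, j]
  }
  structure(list(feature_means = mu, covariance = covm,
                 eigenvalues = vals, pc_vectors = vecs,
                 scores = xc %*% vecs),
            class = "distance_pca")
}

#' Project feature rows onto the leading principal components
#'
#' @param model a `"distance_pca"` from [lid_pca()].
#' @param features a `"lid_features"`, matrix, or single feature row.
#' @param n_components number of components (default 2: the conformational
#'   map plane).
#' @return matrix of scores (rows = frames, columns = PCs).
#' @export
project_features <- function(model, features, n_components = 2L) {
  x <- if (inherits(features, "lid_features")) features$features else features
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != length(model$feature_means)) {
    stop("feature dimension (", ncol(x), ") does not match model (",
         length(model$feature_means), ")")
  }
  sweep(x, 2L, model$feature_means) %*%
    model$pc_vectors[, seq_len(n_components), drop = FALSE]
}

# Boundary-inclusive point-in-convex-polygon test. `hull` is the polygon
# vertex matrix in counterclockwise (chull) order.
.inside_convex_hull <- function(hull, p, tol = 1e-9) {
  nv <- nrow(hull)
  sgn <- numeric(nv)
  for (i in seq_len(nv)) {
    a <- hull[i, ]
    b <- hull[if (i == nv) 1L else i + 1L, ]
    sgn[i] <- (b[1L] - a[1L]) * (p[2L] - a[2L]) -
              (b[2L] - a[2L]) * (p[1L] - a[1L])
  }
  scale <- max(abs(hull))^2 + 1
  all(sgn >= -tol * scale) || all(sgn <= tol * scale)
}

#' Classify a reference conformation against a projected ensemble
#'
#' Operationalises the "is the reference structure inside the sampled
#' cloud?" reading of a 2-D conformational map: the reference's (PC1, PC2)
#' score is tested for membership in the convex hull of the ensemble's
#' scores (boundary counts as inside), and the Mahalanobis distance from
#' the cloud's 2-D mean/covariance is reported as a graded score. A
#' reference inside the cloud means the ensemble still visits the
#' reference's (antagonist-like) lid conformation; outside means the
#' ensemble has shifted away from it (agonist-like).
#'
#' @param cloud n x 2 matrix of ensemble (PC1, PC2) scores.
#' @param reference length-2 reference score.
#' @return object of class `"cloud_classification"`: list with
#'   `cloud_points`, `reference_point`, `inside_hull`, `mahalanobis`, and
#'   `label` (`"antagonist-consistent"` if inside, `"agonist-shifted"` if
#'   outside).
#' @export
classify_reference <- function(cloud, reference) {
  cloud <- as.matrix(cloud)
  stopifnot(ncol(cloud) == 2L, length(reference) == 2L)
  if (nrow(cloud) < 3L) stop("need at least 3 cloud points")
  hull_idx <- grDevices::chull(cloud)
  if (length(hull_idx) < 3L) {
    stop("cloud points are collinear; the 2-D map is degenerate ",
         "(sample more frames)")
  }
  covm <- stats::cov(cloud)
  if (det(covm) <= 0 || !is.finite(det(covm))) {
    stop("degenerate cloud covariance; sample more frames")
  }
  inside <- .inside_convex_hull(cloud[hull_idx, , drop = FALSE],
                                as.numeric(reference))
  maha <- sqrt(stats::mahalanobis(matrix(reference, 1L), colMeans(cloud), covm))
  structure(list(
    cloud_points = cloud,
    reference_point = as.numeric(reference),
    inside_hull = inside,
    mahalanobis = as.numeric(maha),
    label = if (inside) "antagonist-consistent" else "agonist-shifted"
  ), class = "cloud_classification")
}

#' @export
print.cloud_classification <- function(x, ...) {
  cat(sprintf("reference %s the sampled cloud (Mahalanobis %.2f): %s\n",
              if (x$inside_hull) "inside" else "outside",
              x$mahalanobis, x$label))
  invisible(x)
}

#' RMSD-radius trajectory clustering
#'
#' A deterministic leader-then-refine radius clustering of trajectory
#' frames: scanning frames in order, a frame joins the first existing
#' cluster whose centroid structure lies within `cutoff` (RMSD after
#' superposition over `selection`), else founds a new cluster. After the
#' scan, centroids are recomputed as the coordinate mean of the superposed
#' members and frames are reassigned to the nearest centroid, iterating to
#' a fixed point (at most `max_iter` rounds). Fractions are member counts
#' over the total, in percent.
#'
#' @param traj a [trajectory()].
#' @param selection atoms used for superposition and RMSD.
#' @param cutoff cluster radius, Angstrom (1.2 is a common choice for
#'   C-alpha clustering of a stable domain).
#' @param max_iter refinement cap, default 100.
#' @return object of class `"cluster_result"`: list with `assignments`
#'   (cluster id per frame), `cluster_fractions` (percent, by cluster id),
#'   `representatives` (frame index per cluster), `centroids` (list of
#'   member-mean coordinate matrices over the selection), `cutoff`.
#' @export
kclust <- function(traj, selection, cutoff, max_iter = 100L) {
  if (cutoff <= 0) stop("cutoff must be positive")
  nf <- n_frames(traj)
  sel <- .sel_indices(selection, traj$topology$n_atoms)
  get_sel <- function(k) frame_coords(traj, k)[sel, , drop = FALSE]
  # RMSD of frame coords x to centroid c after optimal fit
  fit_rmsd <- function(x, cen) superpose(x, cen)$rmsd

  centroids <- list(get_sel(1L))
  assign_vec <- integer(nf)
  assign_vec[1L] <- 1L
  if (nf > 1L) for (k in 2:nf) {
    x <- get_sel(k)
    placed <- FALSE
    for (ci in seq_along(centroids)) {
      if (fit_rmsd(x, centroids[[ci]]) < cutoff) {
        assign_vec[k] <- ci; placed <- TRUE; break
      }
    }
    if (!placed) {
      centroids[[length(centroids) + 1L]] <- x
      assign_vec[k] <- length(centroids)
    }
  }
  recompute <- function(assign_vec, centroids) {
    lapply(seq_along(centroids), function(ci) {
      members <- which(assign_vec == ci)
      acc <- matrix(0, length(sel), 3L)
      for (k in members) {
        x <- get_sel(k)
        sp <- superpose(x, centroids[[ci]])
        acc <- acc + apply_superposition(sp, x)
      }
      acc / length(members)
    })
  }
  for (it in seq_len(max_iter)) {
    centroids <- recompute(assign_vec, centroids)
    new_assign <- vapply(seq_len(nf), function(k) {
      x <- get_sel(k)
      which.min(vapply(centroids, function(cen) fit_rmsd(x, cen), numeric(1L)))
    }, integer(1L))
    # drop emptied clusters, renumbering by first appearance
    keep <- sort(unique(new_assign))
    centroids <- centroids[keep]
    new_assign <- match(new_assign, keep)
    if (identical(new_assign, assign_vec)) break
    assign_vec <- new_assign
  }
  counts <- tabulate(assign_vec, nbins = length(centroids))
  fractions <- 100 * counts / nf
  res <- structure(list(assignments = assign_vec,
                        cluster_fractions = fractions,
                        centroids = centroids,
                        cutoff = cutoff,
                        selection_indices = sel),
                   class = "cluster_result")
  res$representatives <- vapply(seq_along(centroids), function(ci) {
    representative(res, traj, ci)
  }, integer(1L))
  res
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("kclust:", length(x$centroids), "cluster(s) at cutoff", x$cutoff, "Angstrom\n")
  for (i in seq_along(x$centroids)) {
    cat(sprintf("  cluster %d: %.2f%% (representative frame %d)\n",
                i, x$cluster_fractions[i], x$representatives[i]))
  }
  invisible(x)
}

#' Representative frame of a cluster
#'
#' The member frame with the lowest RMSD (after superposition over the
#' clustering selection) to the cluster's final centroid; ties break to the
#' lowest frame index.
#'
#' @param result a [kclust()] result.
#' @param traj the clustered [trajectory()].
#' @param cluster_id cluster number.
#' @return frame index (integer).
#' @export
representative <- function(result, traj, cluster_id) {
  if (!cluster_id %in% seq_along(result$centroids)) {
    stop("unknown cluster id ", cluster_id)
  }
  members <- which(result$assignments == cluster_id)
  sel <- result$selection_indices
  cen <- result$centroids[[cluster_id]]
  d <- vapply(members, function(k) {
    superpose(frame_coords(traj, k)[sel, , drop = FALSE], cen)$rmsd
  }, numeric(1L))
  members[which.min(d)]  # which.min takes the first minimum: lowest index
}

#' Write PCA scores / cluster summary / classification report
#'
#' Small delimited-text writers for the conformational-analysis outputs.
#'
#' @param scores frames x >=2 score matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pca_scores <- function(scores, path) {
  df <- data.frame(frame = seq_len(nrow(scores)),
                   PC1 = scores[, 1L], PC2 = scores[, 2L])
  write_series(df, path)
}

#' @rdname write_pca_scores
#' @param result a [kclust()] result.
#' @export
write_cluster_summary <- function(result, path) {
  writeLines(c("cluster\tfraction_pct\trepresentative_frame",
               sprintf("%d\t%.2f\t%d", seq_along(result$centroids),
                       result$cluster_fractions, result$representatives)),
             path)
  invisible(path)
}

#' @rdname write_pca_scores
#' @param cls a [classify_reference()] result.
#' @export
write_classification <- function(cls, path) {
  writeLines(c(
    sprintf("reference_pc1\t%.6f", cls$reference_point[1L]),
    sprintf("reference_pc2\t%.6f", cls$reference_point[2L]),
    sprintf("inside_hull\t%s", tolower(cls$inside_hull)),
    sprintf("mahalanobis\t%.6f", cls$mahalanobis),
    sprintf("label\t%s", cls$label)
  ), path)
  invisible(path)
}
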