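test_that("lid distance features are plain center-to-CA distances", {
  # two core atoms symmetric about the origin, one lid CA at (3,4,0)
  top <- topology(atom_name = c("CA", "CA", "CA"),
                  residue_name = c("ALA", "ALA", "ALA"),
                  residue_id = c(1L, 2L, 10L))
  frame <- rbind(c(-1, 0, 0), c(1, 0, 0), c(3, 4, 0))
  traj <- trajectory(top, list(frame))
  f <- lid_distance_features(traj, select(top, "resid 10"),
                             select(top, "resid 1,2"))
  expect_equal(unname(f$features[1L, ]), 5)
  expect_equal(colnames(f$features), "10")
})

test_that("features are invariant under global rigid motion", {
  sp <- synthetic_params(n_frames = 5L, seed = 61L)
  top <- generate_topology(sp)
  traj <- generate_trajectory(top, sp)
  lid <- select(top, "resid 873-908 and name CA")
  core <- select(top, "resid 698-844")
  f1 <- lid_distance_features(traj, lid, core)
  set.seed(62)
  moved <- trajectory(top, lapply(seq_len(n_frames(traj)), function(k) {
    rigid_move(frame_coords(traj, k))
  }))
  f2 <- lid_distance_features(moved, lid, core)
  expect_equal(f2$features, f1$features, tolerance = 1e-9)
})

test_that("features match a direct hand loop", {
  sp <- synthetic_params(n_frames = 1L, seed = 63L)
  top <- generate_topology(sp)
  traj <- generate_trajectory(top, sp)
  lid <- select(top, "resid 873-908 and name CA")
  core <- select(top, "resid 698-844")
  f <- lid_distance_features(traj, lid, core)
  x <- frame_coords(traj, 1L)
  w <- top$atoms$mass[core$indices]
  cc <- colSums(x[core$indices, ] * w) / sum(w)
  hand <- vapply(lid$indices, function(i) sqrt(sum((x[i, ] - cc)^2)),
                 numeric(1L))
  expect_equal(unname(f$features[1L, ]), hand, tolerance = 1e-9)
})

test_that("lid selection must be one C-alpha per residue", {
  top <- generate_topology()
  traj <- trajectory(top, list(attr(top, "coords")))
  expect_error(lid_distance_features(traj, select(top, "resid 877"),
                                     select(top, "resid 698-844")),
               "one atom")
  expect_error(lid_distance_features(traj, select(top, "resid 877 and name OG1"),
                                     select(top, "resid 698-844")),
               "C-alpha")
})

test_that("PCA of constant features has a null spectrum", {
  x <- matrix(5, 10L, 4L)
  m <- lid_pca(x)
  expect_equal(m$eigenvalues, rep(0, 4L))
  expect_equal(unname(m$feature_means), rep(5, 4L))
})

test_that("PCA recovers the hand-worked 2x2 eigenproblem", {
  x <- rbind(c(1, 0), c(-1, 0))
  m <- lid_pca(x)   # population covariance: diag(1, 0)
  expect_equal(m$eigenvalues, c(1, 0))
  expect_equal(m$pc_vectors[, 1L], c(1, 0))  # sign rule: largest coef positive
  expect_equal(unname(m$covariance), rbind(c(1, 0), c(0, 0)))
})

test_that("PCA satisfies the spectral identities on random ensembles", {
  set.seed(64)
  x <- matrix(rnorm(200 * 36), 200L) %*% diag(runif(36, 0.5, 3))
  m <- lid_pca(x)
  expect_equal(sum(m$eigenvalues), sum(diag(m$covariance)), tolerance = 1e-9)
  expect_equal(crossprod(m$pc_vectors), diag(36), tolerance = 1e-9)
  expect_true(all(diff(m$eigenvalues) <= 1e-12))
  # scores are decorrelated with variances = eigenvalues (1/N convention)
  sc <- m$scores
  cv <- crossprod(sc) / nrow(sc)
  expect_equal(diag(cv), m$eigenvalues, tolerance = 1e-9)
  expect_lt(max(abs(cv - diag(diag(cv)))), 1e-9)
  # sample normalization differs by n/(n-1)
  m2 <- lid_pca(x, normalization = "sample")
  expect_equal(m2$eigenvalues, m$eigenvalues * 200 / 199, tolerance = 1e-9)
})

test_that("projection is consistent with training scores", {
  set.seed(65)
  x <- matrix(rnorm(50 * 6), 50L)
  m <- lid_pca(x)
  expect_equal(unname(project_features(m, colMeans(x))), matrix(0, 1L, 2L),
               tolerance = 1e-9)
  expect_equal(project_features(m, x), m$scores[, 1:2], tolerance = 1e-9)
  expect_equal(mean(project_features(m, x)[, 1L]^2), m$eigenvalues[1L],
               tolerance = 1e-9)
  expect_error(project_features(m, matrix(0, 1L, 5L)), "dimension")
})

test_that("reference classification distinguishes inside from outside", {
  set.seed(66)
  cloud <- matrix(rnorm(400), 200L)
  ctr <- classify_reference(cloud, colMeans(cloud))
  expect_true(ctr$inside_hull)
  expect_equal(ctr$label, "antagonist-consistent")
  far <- classify_reference(cloud, c(100, 100))
  expect_false(far$inside_hull)
  expect_equal(far$label, "agonist-shifted")
  expect_gt(far$mahalanobis, ctr$mahalanobis)
  # a hull vertex counts as inside (boundary inclusive)
  v <- cloud[grDevices::chull(cloud)[1L], ]
  expect_true(classify_reference(cloud, v)$inside_hull)
})

test_that("classification is invariant under joint affine rescaling", {
  set.seed(67)
  cloud <- matrix(rnorm(300), 150L)
  refs <- rbind(c(0.1, -0.2), c(3, 3), colMeans(cloud))
  s <- diag(c(4, 0.25))
  for (i in seq_len(nrow(refs))) {
    a <- classify_reference(cloud, refs[i, ])
    b <- classify_reference(cloud %*% s, drop(refs[i, ] %*% s))
    expect_identical(a$inside_hull, b$inside_hull)
  }
})

test_that("degenerate clouds are rejected", {
  line <- cbind(1:10, 2 * (1:10))
  expect_error(classify_reference(line, c(0, 0)), "collinear|degenerate")
  expect_error(classify_reference(matrix(0, 2L, 2L), c(0, 0)), "at least 3")
})

test_that("kclust collapses indistinguishable frames into one cluster", {
  set.seed(68)
  base <- matrix(rnorm(30, sd = 5), 10L)
  top <- make_ca_topology(1:10, base)
  static <- trajectory(top, replicate(6, base, simplify = FALSE))
  cl <- kclust(static, 1:10, cutoff = 1.2)
  expect_length(cl$centroids, 1L)
  expect_equal(cl$cluster_fractions, 100)
  expect_equal(cl$representatives, 1L)  # tie broken to the lowest frame

  # cutoff above the maximal pairwise RMSD also gives one cluster
  frames <- lapply(1:6, function(i) base + matrix(rnorm(30, sd = 0.5), 10L))
  spread <- trajectory(top, frames)
  cl2 <- kclust(spread, 1:10, cutoff = 1e3)
  expect_length(cl2$centroids, 1L)
  expect_equal(sum(cl2$cluster_fractions), 100, tolerance = 1e-9)
})

test_that("a vanishing cutoff isolates each distinct structure", {
  set.seed(69)
  a <- matrix(rnorm(30, sd = 5), 10L)
  b <- a + 3
  b[1L, ] <- b[1L, ] + 5   # not a rigid image of a
  top <- make_ca_topology(1:10, a)
  traj <- trajectory(top, list(a, b, a, b))
  cl <- kclust(traj, 1:10, cutoff = 1e-6)
  expect_length(cl$centroids, 2L)
  expect_equal(cl$assignments, c(1L, 2L, 1L, 2L))
  expect_equal(cl$cluster_fractions, c(50, 50))
})

test_that("the representative is the planted medoid", {
  set.seed(70)
  base <- matrix(rnorm(36, sd = 5), 12L)
  # symmetric perturbation pairs keep the member mean at `base`; the planted
  # medoid (frame 5) sits exactly on it
  deltas <- lapply(1:4, function(i) matrix(rnorm(36, sd = 0.4), 12L))
  frames <- c(lapply(deltas, function(d) base + d),
              list(base),
              lapply(deltas, function(d) base - d))
  top <- make_ca_topology(1:12, base)
  traj <- trajectory(top, frames)
  cl <- kclust(traj, 1:12, cutoff = 5)
  expect_length(cl$centroids, 1L)
  expect_equal(representative(cl, traj, 1L), 5L)
  expect_error(representative(cl, traj, 9L), "unknown cluster")
})

test_that("two-state trajectories cluster to the designed occupancies", {
  sp <- synthetic_params(n_frames = 400L, open_fraction = 0.3, seed = 71L)
  top <- generate_topology(sp)
  traj <- generate_trajectory(top, sp)
  cl <- kclust(traj, select(top, "name CA"), cutoff = 1.2)
  expect_length(cl$centroids, 2L)
  states <- attr(traj, "states")
  # cluster labels must reproduce the true state partition exactly: the
  # inter-state RMSD dwarfs the cutoff
  split1 <- states[cl$assignments == 1L]
  expect_length(unique(split1), 1L)
  expect_equal(sort(cl$cluster_fractions),
               sort(100 * as.numeric(table(states)) / 400))
})
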