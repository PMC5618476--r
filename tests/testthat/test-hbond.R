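test_that("published hydrogen-bond geometries all pass the criterion", {
  geo <- published_hbond_geometries()
  for (i in seq_len(nrow(geo))) {
    tri <- hbond_triple_coords(geo$distance[i], geo$angle[i])
    r <- is_hbond(tri$donor, tri$hydrogen, tri$acceptor)
    expect_true(r$bond, info = paste(geo$distance[i], geo$angle[i]))
    expect_equal(r$distance, geo$distance[i], tolerance = 1e-9)
    expect_equal(r$angle, geo$angle[i], tolerance = 1e-9)
  }
})

test_that("criterion boundaries are strict", {
  # collinear triple: donor-acceptor distance exactly 3.50, angle 180
  at_dist <- is_hbond(c(0, 0, 0), c(0.96, 0, 0), c(3.5, 0, 0))
  expect_equal(at_dist$distance, 3.5)
  expect_false(at_dist$bond)

  # a triple sitting exactly on either threshold must fail (strict < and >)
  tri <- hbond_triple_coords(2.8, 160)
  r <- is_hbond(tri$donor, tri$hydrogen, tri$acceptor)
  expect_false(is_hbond(tri$donor, tri$hydrogen, tri$acceptor,
                        hbond_criterion(max_distance = r$distance))$bond)
  expect_false(is_hbond(tri$donor, tri$hydrogen, tri$acceptor,
                        hbond_criterion(min_angle = r$angle))$bond)

  just_in <- hbond_triple_coords(3.49, 120.5)
  expect_true(is_hbond(just_in$donor, just_in$hydrogen, just_in$acceptor)$bond)
})

test_that("a hydrogen far from its donor flags a mislabeled triple", {
  expect_error(is_hbond(c(0, 0, 0), c(2, 0, 0), c(3, 0, 0)), "mislabeled")
})

test_that("is_hbond agrees with a brute-force recomputation", {
  set.seed(41)
  crit <- hbond_criterion()
  for (i in 1:1000) {
    d <- rnorm(3)
    h <- d + 0.96 * { u <- rnorm(3); u / sqrt(sum(u^2)) }
    a <- d + runif(1, 0.5, 5) * { u <- rnorm(3); u / sqrt(sum(u^2)) }
    got <- is_hbond(d, h, a, crit)
    dist <- sqrt(sum((a - d)^2))
    ang <- acos(sum((a - h) * (d - h)) /
                  (sqrt(sum((a - h)^2)) * sqrt(sum((d - h)^2)))) * 180 / pi
    expect_equal(got$distance, dist)
    expect_equal(got$angle, ang)
    expect_identical(got$bond, dist < 3.5 && ang > 120)
  }
})

# trajectory with the triple satisfying in a prescribed set of frames
make_switch_traj <- function(on) {
  top <- topology(atom_name = c("O4", "H11", "OD1"),
                  residue_name = c("HF", "HF", "ASN"),
                  residue_id = c(999L, 999L, 705L))
  near <- hbond_triple_coords(2.8, 160)
  far <- hbond_triple_coords(6.0, 160)
  frames <- lapply(on, function(b) {
    tri <- if (b) near else far
    rbind(tri$donor, tri$hydrogen, tri$acceptor)
  })
  trajectory(top, frames)
}

test_that("occupancy counts satisfying frames over each window", {
  on <- rep(c(TRUE, FALSE), c(600L, 400L))
  traj <- make_switch_traj(on)
  hb <- hbond_occupancy(traj, c(999, "O4"), c(999, "H11"), c(705, "OD1"),
                        window_last_frames = 400L)
  expect_equal(hb$occupancy_full, 60.00)
  expect_equal(hb$occupancy_window, 0.00)
  expect_true(is.na(hb$mean_distance_window))
  expect_equal(hb$mean_distance_full, 2.8, tolerance = 1e-9)
  expect_equal(hb$mean_angle_full, 160, tolerance = 1e-9)

  none <- hbond_occupancy(make_switch_traj(rep(FALSE, 50L)),
                          c(999, "O4"), c(999, "H11"), c(705, "OD1"))
  expect_equal(none$occupancy_full, 0.00)
  expect_true(is.na(none$mean_distance_full))
  expect_true(is.na(none$mean_angle_full))
})

test_that("occupancy of a concatenation is the frame-weighted mean", {
  set.seed(42)
  on1 <- runif(300) < 0.8
  on2 <- runif(200) < 0.2
  o1 <- hbond_occupancy(make_switch_traj(on1), c(999, "O4"), c(999, "H11"),
                        c(705, "OD1"), window_last_frames = 300L)
  o2 <- hbond_occupancy(make_switch_traj(on2), c(999, "O4"), c(999, "H11"),
                        c(705, "OD1"), window_last_frames = 200L)
  oc <- hbond_occupancy(make_switch_traj(c(on1, on2)), c(999, "O4"),
                        c(999, "H11"), c(705, "OD1"),
                        window_last_frames = 500L)
  # parts' occupancies are rounded to 2 decimals, so allow that rounding
  expect_lt(abs(oc$occupancy_full -
                  (300 * o1$occupancy_full + 200 * o2$occupancy_full) / 500),
            0.011)
})

test_that("tightening either cutoff never increases occupancy", {
  set.seed(43)
  sp <- synthetic_params(n_frames = 300L, p_site_a = 0.7, seed = 43L)
  top <- generate_topology(sp)
  traj <- generate_trajectory(top, sp)
  occ <- function(dmax, amin) {
    hbond_occupancy(traj, c(999, "O4"), c(999, "H11"), c(705, "OD1"),
                    criterion = hbond_criterion(dmax, amin))$occupancy_full
  }
  base <- occ(3.5, 120)
  expect_lte(occ(3.0, 120), base)
  expect_lte(occ(2.8, 120), occ(3.0, 120))
  expect_lte(occ(3.5, 150), base)
  expect_lte(occ(3.5, 170), occ(3.5, 150))
})

test_that("window validation", {
  traj <- make_switch_traj(rep(TRUE, 10L))
  expect_error(hbond_occupancy(traj, c(999, "O4"), c(999, "H11"),
                               c(705, "OD1"), window_last_frames = 0L),
               "at least 1 frame")
  expect_error(hbond_occupancy(traj, c(999, "O4"), c(999, "H11"),
                               c(705, "OD1"), window_last_frames = 11L),
               "exceeds")
  expect_error(hbond_occupancy(traj, c(999, "O4"), c(999, "H11"),
                               c(1, "OX")), "not found")
})

test_that("donor-switching occupancy is recovered from the generator", {
  sp <- synthetic_params(n_frames = 1500L, p_site_a = 0.85, seed = 44L)
  top <- generate_topology(sp)
  traj <- generate_trajectory(top, sp)
  hb_a <- hbond_occupancy(traj, c(999, "O4"), c(999, "H11"), c(705, "OD1"))
  hb_b <- hbond_occupancy(traj, c(999, "O4"), c(999, "H11"), c(877, "OG1"))
  # the measured occupancies equal the true per-frame site assignments
  expect_equal(hb_a$occupancy_full,
               round(100 * mean(attr(traj, "sites") == "A"), 2L))
  expect_equal(hb_a$occupancy_full + hb_b$occupancy_full, 100)
  se3 <- 3 * sqrt(0.85 * 0.15 / 1500) * 100
  expect_lt(abs(hb_a$occupancy_full - 85), se3)
})

test_that("the report writer emits the two-window table", {
  traj <- make_switch_traj(rep(c(TRUE, FALSE), 5L))
  hb <- hbond_occupancy(traj, c(999, "O4"), c(999, "H11"), c(705, "OD1"),
                        window_last_frames = 2L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_hbond_report(list(hb), path)
  tab <- read.delim(path)
  expect_named(tab, c("interaction_pair", "distance_full", "distance_window",
                      "angle_full", "angle_window", "occupancy_full_pct",
                      "occupancy_window_pct"))
  expect_equal(tab$occupancy_full_pct, 50)
})
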