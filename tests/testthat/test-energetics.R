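test_that("the component ledger identities hold by construction", {
  ec <- energy_components(e_ele = -28.21, e_vdw = -40.24, g_polar = 44.92,
                          g_nonpolar = -5.66, minus_t_ds = 23.12)
  expect_equal(ec$e_mm, ec$e_int + ec$e_ele + ec$e_vdw, tolerance = 1e-12)
  expect_equal(ec$g_sol, ec$g_polar + ec$g_nonpolar, tolerance = 1e-12)
  expect_equal(ec$e_bind, ec$e_mm + ec$g_sol, tolerance = 1e-12)
  expect_equal(ec$g_bind, ec$e_bind + ec$minus_t_ds, tolerance = 1e-12)
  expect_error(energy_components(NA, 1, 1, 1), "non-finite")
})

test_that("aggregation reproduces the published wild-type and F876L rows", {
  wt <- aggregate_binding(
    data.frame(e_ele = -28.21, e_vdw = -40.24, g_polar = 44.92,
               g_nonpolar = -5.66),
    minus_t_ds = 23.12)
  expect_equal(wt$e_bind, -29.19, tolerance = 1e-9)
  expect_equal(wt$g_bind, -6.07, tolerance = 1e-9)

  f876l <- aggregate_binding(
    data.frame(e_ele = -23.38, e_vdw = -39.45, g_polar = 39.42,
               g_nonpolar = -5.63),
    minus_t_ds = 20.82)
  expect_equal(f876l$e_bind, -29.04, tolerance = 1e-9)
  expect_equal(f876l$g_bind, -8.22, tolerance = 1e-9)

  zero <- aggregate_binding(
    data.frame(e_ele = 0, e_vdw = 0, g_polar = 0, g_nonpolar = 0),
    minus_t_ds = 0)
  expect_equal(zero$g_bind, 0)
})

test_that("aggregation is linear over concatenated frame sets", {
  set.seed(51)
  mk <- function(n) data.frame(e_ele = rnorm(n, -28, 3), e_vdw = rnorm(n, -40, 2),
                               g_polar = rnorm(n, 45, 3), g_nonpolar = rnorm(n, -5.6, 0.3))
  a <- mk(40L); b <- mk(60L)
  agg_a <- aggregate_binding(a, 0); agg_b <- aggregate_binding(b, 0)
  agg_all <- aggregate_binding(rbind(a, b), 0)
  expect_equal(agg_all$e_bind, (40 * agg_a$e_bind + 60 * agg_b$e_bind) / 100,
               tolerance = 1e-12)
  expect_error(aggregate_binding(a[0, ], 0), "no frame")
  expect_error(aggregate_binding(data.frame(e_ele = 1), 0), "missing component")
})

test_that("the nonpolar solvation model is linear in the surface area", {
  expect_equal(nonpolar_solvation(0), 0)
  expect_equal(nonpolar_solvation(1000), 7.2, tolerance = 1e-12)
  # the published wild-type nonpolar term corresponds to -786.11 A^2
  expect_equal(nonpolar_solvation(-786.11), -5.66, tolerance = 1e-3)
  m <- nonpolar_model(gamma = 0.005, beta = 1)
  expect_equal(nonpolar_solvation(200, m), 2)
  expect_error(nonpolar_solvation(NaN), "non-finite")
})

test_that("pair energies match the force-field functional form", {
  frame <- rbind(c(0, 0, 0), c(1, 0, 0))
  q <- c(1, -1)
  eps0 <- c(0, 0); rmh <- c(1, 1)
  pe <- pair_energy(frame, 1L, 2L, q, eps0, rmh)
  expect_equal(pe$e_ele, -332.0636, tolerance = 1e-9)
  expect_equal(pe$e_vdw, 0)

  # at r = rmin_ij the LJ term sits at its minimum, -eps_ij
  eps <- c(0.2, 0.45)
  frame2 <- rbind(c(0, 0, 0), c(2.5, 0, 0))   # rmin_ij = 1.2 + 1.3 = 2.5
  pe2 <- pair_energy(frame2, 1L, 2L, c(0, 0), eps, c(1.2, 1.3))
  expect_equal(pe2$e_vdw, -sqrt(0.2 * 0.45), tolerance = 1e-12)

  expect_error(pair_energy(frame, 1L, 1L, q, eps0, rmh), "disjoint")
  expect_error(pair_energy(rbind(c(0, 0, 0), c(0, 0, 0)), 1L, 2L, q, eps0, rmh),
               "zero interatomic")
  expect_error(pair_energy(frame, 1L, 2L, c(1, NA), eps0, rmh),
               "parameter for atom 2")
})

test_that("pair energies match an independent double-loop recomputation", {
  set.seed(52)
  n <- 10L
  frame <- matrix(rnorm(3 * n, sd = 4), n)
  q <- rnorm(n, sd = 0.5)
  eps <- runif(n, 0.05, 0.3)
  rmh <- runif(n, 1, 2)
  ia <- 1:5; ib <- 6:10
  got <- pair_energy(frame, ia, ib, q, eps, rmh)
  ele <- 0; vdw <- 0
  for (i in ia) for (j in ib) {
    r <- sqrt(sum((frame[i, ] - frame[j, ])^2))
    ele <- ele + 332.0636 * q[i] * q[j] / r
    rmin <- rmh[i] + rmh[j]
    vdw <- vdw + sqrt(eps[i] * eps[j]) * ((rmin / r)^12 - 2 * (rmin / r)^6)
  }
  expect_equal(got$e_ele, ele, tolerance = 1e-9)
  expect_equal(got$e_vdw, vdw, tolerance = 1e-9)
})

make_decomp_fixture <- function() {
  # two protein residues (2 atoms each) + a 2-atom ligand, 2 frames
  top <- topology(atom_name = c("CA", "CB", "CA", "CB", "C1", "C2"),
                  residue_name = c("ALA", "ALA", "VAL", "VAL", "HF", "HF"),
                  residue_id = c(10L, 10L, 11L, 11L, 99L, 99L),
                  record = c(rep("ATOM", 4L), "HETATM", "HETATM"))
  set.seed(53)
  frames <- lapply(1:2, function(i) matrix(rnorm(18, sd = 3), 6L))
  list(top = top, traj = trajectory(top, frames),
       q = c(0.1, -0.2, 0.3, -0.1, 0.25, -0.15),
       eps = rep(0.15, 6L), rmh = rep(1.7, 6L))
}

test_that("per-residue decomposition conserves the group-group totals", {
  fx <- make_decomp_fixture()
  lig <- select(fx$top, "resname HF")
  dec <- per_residue_decomposition(fx$traj, lig, fx$q, fx$eps, fx$rmh)
  tot_ele <- tot_vdw <- 0
  for (k in 1:2) {
    pe <- pair_energy(frame_coords(fx$traj, k), 1:4, lig, fx$q, fx$eps, fx$rmh)
    tot_ele <- tot_ele + pe$e_ele / 2
    tot_vdw <- tot_vdw + pe$e_vdw / 2
  }
  expect_equal(sum(dec$e_ele), tot_ele, tolerance = 1e-9)
  expect_equal(sum(dec$e_vdw), tot_vdw, tolerance = 1e-9)
  expect_equal(dec$total, dec$e_ele + dec$e_vdw + dec$g_polar + dec$g_nonpolar,
               tolerance = 1e-12)
})

test_that("per-residue decomposition matches hand-computed pair sums", {
  fx <- make_decomp_fixture()
  lig <- select(fx$top, "resname HF")
  dec <- per_residue_decomposition(fx$traj, lig, fx$q, fx$eps, fx$rmh)
  for (res in c(10L, 11L)) {
    idx <- which(fx$top$atoms$residue_id == res)
    ele <- mean(vapply(1:2, function(k) {
      pair_energy(frame_coords(fx$traj, k), idx, lig,
                  fx$q, fx$eps, fx$rmh)$e_ele
    }, numeric(1L)))
    expect_equal(dec$e_ele[dec$residue_id == res], ele, tolerance = 1e-9)
  }
})

test_that("a chargeless, epsilon-free ligand contributes nothing", {
  fx <- make_decomp_fixture()
  q <- fx$q; q[5:6] <- 0
  eps <- fx$eps; eps[5:6] <- 0
  dec <- per_residue_decomposition(fx$traj, select(fx$top, "resname HF"),
                                   q, eps, fx$rmh)
  expect_equal(dec$e_ele, c(0, 0))
  expect_equal(dec$e_vdw, c(0, 0))
  expect_equal(dec$total, c(0, 0))
})

test_that("external polar and surface-area tables enter per residue", {
  fx <- make_decomp_fixture()
  lig <- select(fx$top, "resname HF")
  dec <- per_residue_decomposition(
    fx$traj, lig, fx$q, fx$eps, fx$rmh,
    g_polar_table = data.frame(residue_id = c(10L, 11L), g_polar = c(1.5, -0.5)),
    delta_sasa_table = data.frame(residue_id = 10L, delta_sasa = -100))
  expect_equal(dec$g_polar, c(1.5, -0.5))
  expect_equal(dec$g_nonpolar, c(-0.72, 0), tolerance = 1e-12)
  expect_error(per_residue_decomposition(
    fx$traj, lig, fx$q, fx$eps, fx$rmh,
    g_polar_table = data.frame(residue_id = 55L, g_polar = 1)),
    "absent from the trajectory")
})

test_that("energy tables round-trip through the delimited format", {
  sp <- synthetic_params(n_frames = 20L, seed = 54L)
  df <- generate_energy_components(sp)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_energy_table(df, path)
  back <- read_energy_table(path)
  expect_equal(back$e_ele, df$e_ele, tolerance = 1e-6)
  expect_error(read_energy_table(tempfile()), "not found")
})
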