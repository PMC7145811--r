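# Forward Monte Carlo kernel: limiting cases with exact answers, energy
# bookkeeping, and agreement with diffusion theory.

test_that("transparent matched-index slab transmits all photons with flat fluence", {
  slab <- layered_slab(material(0, 0, 0, 1), thickness = 1)
  res <- mc_simulate(slab, n_photons = 2000, seed = 1)
  expect_identical(res$T_total, 1)
  expect_identical(res$R_total + res$A_total, 0)
  prof <- fluence_depth_profile(res)
  expect_equal(prof$E0_percent, rep(100, nrow(prof)), tolerance = 1e-12)
})

test_that("non-scattering absorbing slab follows Beer-Lambert", {
  slab <- layered_slab(material(mu_a = 1, mu_s = 0), thickness = 1)
  res <- mc_simulate(slab, n_photons = 5e4, seed = 2)
  se <- sqrt(exp(-1) * (1 - exp(-1)) / 5e4)
  expect_lt(abs(res$T_total - exp(-1)), 3 * se)
  # fluence decays exponentially with depth
  prof <- fluence_depth_profile(res)
  i1 <- which.min(abs(prof$depth_um - 250))
  i2 <- which.min(abs(prof$depth_um - 750))
  expect_equal(log(prof$E0_percent[i1] / prof$E0_percent[i2]),
               (prof$depth_um[i2] - prof$depth_um[i1]) / 1000,
               tolerance = 0.05)
  # ballistic transmission exits in the zero-degree bin only
  scan <- angular_transmittance(res)
  expect_true(all(scan$intensity[abs(scan$theta_deg) > 1] == 0))
})

test_that("Fresnel reflectance and Henyey-Greenstein sampler match theory", {
  expect_equal(fresnel_unpolarized(1, 1.5, 1), 0.04, tolerance = 1e-12)
  # total internal reflection beyond the critical angle
  expect_identical(fresnel_unpolarized(1.5, 1, cos(80 * pi / 180)), 1)
  set.seed(7)
  for (g in c(0, 0.5, 0.9, -0.5)) {
    x <- hg_sample(g, 2e5)
    se <- sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x) - g), 3 * se)
  }
})

test_that("energy is conserved (T + R + A + side = 1) across geometries", {
  geoms <- list(
    layered_slab(material(1, 5, 0.8, 1.4), 1),
    layered_slab(list(material(0.5, 2, 0.5, 1.4), material(0.02, 1 / 3, 0, 1.4)),
                 c(1, 1), n_below = 1.33),
    layered_slab(material(1e-9, 1, 0, 1.5), 5))
  for (i in seq_along(geoms)) {
    for (s in 1:4) {
      res <- mc_simulate(geoms[[i]], n_photons = 3000, seed = 100 * i + s)
      closure <- res$T_total + res$R_total + res$A_total + res$S_total
      expect_lt(abs(closure - 1), 3 * res$closure_se + 1e-9)
    }
  }
  labs <- array(1L, dim = c(30, 30, 30)); labs[, , 16:30] <- 2L
  vg <- voxel_grid(labs, 0.05,
                   list(material(0.5, 2, 0.5, 1.4), material(0.1, 1, 0, 1.45)))
  rv <- mc_simulate(vg, plane_source(), n_photons = 5000, seed = 42)
  expect_lt(abs(rv$T_total + rv$R_total + rv$A_total + rv$S_total - 1),
            3 * rv$closure_se + 1e-9)
})

test_that("absorbed fraction equals mu_a-weighted fluence integral", {
  slab <- layered_slab(list(material(0.5, 2, 0.5, 1.4),
                            material(0.1, 1, 0, 1.45)), c(1, 1))
  res <- mc_simulate(slab, n_photons = 2e4, seed = 10)
  mua_z <- ifelse(res$depth_mm <= 1, 0.5, 0.1)
  A_from_fluence <- sum(mua_z * res$fluence_steady * res$dz)
  expect_equal(A_from_fluence, res$A_total, tolerance = 0.02)
})

test_that("matched-index diffusive slab transmission follows diffusion scaling", {
  for (LL in c(5, 10, 20)) {
    slab <- layered_slab(material(1e-9, 1, 0, 1), thickness = LL)
    res <- mc_simulate(slab, n_photons = 3e4, seed = 20 + LL)
    Tth <- diffusion_T_absfree(LL, 1, 0.7104)
    expect_lt(abs(res$T_total - Tth) / Tth, 0.1)
  }
})

test_that("two-layer slab transmission is reciprocal under flipping", {
  a <- layered_slab(list(material(0.2, 1, 0.7, 1.4),
                         material(0.05, 0.5, 0, 1.33)), c(0.5, 1.5))
  b <- layered_slab(list(material(0.05, 0.5, 0, 1.33),
                         material(0.2, 1, 0.7, 1.4)), c(1.5, 0.5))
  ra <- mc_simulate(a, n_photons = 5e4, seed = 11)
  rb <- mc_simulate(b, n_photons = 5e4, seed = 12)
  expect_lt(abs(ra$T_total - rb$T_total),
            3 * sqrt(ra$T_se^2 + rb$T_se^2))
})

test_that("TPSF snapshots partition the steady-state fluence and spread with time", {
  slab <- layered_slab(material(0.01, 2, 0, 1.4), thickness = 10)
  res <- mc_simulate(slab, n_photons = 2e4, seed = 13,
                     time_edges = c(0, 0.01, seq(0.05, 5, by = 0.05)))
  # partition is exact by construction of the joint depth-time tally
  expect_equal(rowSums(res$fluence), res$fluence_steady, tolerance = 1e-12)
  # causality: no fluence deeper than c/n * t in the first gate
  s1 <- tpsf_snapshot(res, 0.005)
  reachable <- 0.01 * 299.792458 / 1.4
  expect_true(all(s1$fluence[res$depth_mm > reachable] == 0))
  expect_gt(sum(s1$fluence[res$depth_mm <= reachable]), 0)
  # the fluence centroid moves deeper at later snapshots
  s2 <- tpsf_snapshot(res, 0.2)
  s3 <- tpsf_snapshot(res, 1.0)
  cen <- function(s) sum(s$fluence * res$depth_mm) / sum(s$fluence)
  expect_gt(cen(s3), cen(s2))
  expect_error(tpsf_snapshot(res, 99), "time gate")
})

test_that("degenerate inputs are rejected", {
  expect_error(material(NaN, 1), "finite")
  expect_error(mc_simulate(layered_slab(material(1, 1), 1), n_photons = 10),
               ">= 1000")
  thick <- layered_slab(material(5, 0), thickness = 5)
  res <- mc_simulate(thick, n_photons = 2000, seed = 3)
  expect_error(angular_transmittance(res), "transmitted")
})
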