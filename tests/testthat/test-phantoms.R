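# Synthetic-data generators: determinism, noiseless exactness, ground-truth
# round trips through the matching fitters.

test_that("generators are deterministic under a fixed seed", {
  cfg <- phantom_config(seed = 11, noise_rel = 0.03, grid_spacing = 25)
  expect_identical(make_corallite_volume(cfg)$data,
                   make_corallite_volume(cfg)$data)
  expect_identical(make_transmission_series(config = cfg)$T,
                   make_transmission_series(config = cfg)$T)
  expect_identical(make_growth_series(config = cfg)$cells_per_mL,
                   make_growth_series(config = cfg)$cells_per_mL)
  # generators do not disturb the caller's RNG stream
  set.seed(99); before <- .Random.seed
  invisible(make_angular_scan(config = cfg))
  expect_identical(.Random.seed, before)
})

test_that("corallite phantom has the printed dimensions and two-level noiseless histogram", {
  v <- make_corallite_volume(phantom_config(seed = 1, noise_rel = 0,
                                            grid_spacing = 10))
  expect_identical(sort(unique(as.integer(v$data))), c(1000L, 10000L))
  fg <- v$data == 10000
  idx <- which(fg, arr.ind = TRUE)
  # 1 mm cup diameter at 10 um spacing: about 100 voxels across in x and y
  expect_equal(diff(range(idx[, 1])) + 1, 100, tolerance = 0.03)
  expect_equal(diff(range(idx[, 2])) + 1, 100, tolerance = 0.03)
  # tentacles (1 mm) above the cup (1 mm depth): 2 mm of structure in z
  expect_equal((diff(range(idx[, 3])) + 1) * 10, 2000, tolerance = 0.01)
  expect_error(make_corallite_volume(phantom_config(grid_spacing = 30)),
               "25 um")
  expect_error(make_corallite_volume(phantom_config(noise_rel = 0.5)),
               "separation")
})

test_that("transmission phantom follows the diffusion model and warns outside its regime", {
  ser <- make_transmission_series(l_a = 1e9, l_t = 1, z_e = 2 / 3,
                                  thicknesses = c(8, 10, 15, 20),
                                  config = phantom_config(seed = 1, noise_rel = 0))
  expect_true(all(diff(ser$T) < 0))
  expect_equal(ser$T[2], (5 / 3) / (10 + 4 / 3), tolerance = 1e-4)
  expect_warning(
    make_transmission_series(l_t = 5, thicknesses = c(4, 8, 12, 16),
                             config = phantom_config(noise_rel = 0)),
    "diffusion-regime")
})

test_that("angular phantom matches the diffusion angular law with unit peak", {
  sc <- make_angular_scan(z_e = 1.32, config = phantom_config(seed = 2, noise_rel = 0))
  expect_equal(max(sc$intensity), 1)
  expect_equal(sc$intensity[sc$theta_deg == 60],
               p_mu(cos(pi / 3), 1.32) / p_mu(1, 1.32), tolerance = 1e-10)
  expect_equal(sc$intensity[abs(sc$theta_deg) == 90], c(0, 0))
})

test_that("Brewster phantom has its reflectance minimum at arctan(n)", {
  bs <- make_brewster_scan(1.37, phantom_config(seed = 1, noise_rel = 0))
  expect_equal(bs$theta_deg[which.min(bs$intensity)], 54,
               tolerance = 0.5 / 54) # 0.5 degree grid
  flat <- make_brewster_scan(1.0, phantom_config(noise_rel = 0))
  expect_true(all(flat$intensity == 0))
  # the printed 1.37-1.40 index family: minima at arctan(n), 53.9-54.5 deg
  for (n in c(1.37, 1.40)) {
    tb <- find_brewster(make_brewster_scan(n, phantom_config(seed = 3,
                                                             noise_rel = 0)))$theta_B
    expect_equal(tb, atan(n) * 180 / pi, tolerance = 0.1 / 54)
  }
})

test_that("O2 profile phantom is flat without flux and linear in the boundary layer", {
  flat <- make_o2_profile(J = 0, config = phantom_config(seed = 1, noise_rel = 0))
  expect_equal(diff(range(flat$conc_umolL)), 0)
  pr <- make_o2_profile(J = 0.25, config = phantom_config(seed = 1, noise_rel = 0))
  dbl <- pr[pr$depth_um >= -300, ]
  slopes <- diff(dbl$conc_umolL) / diff(dbl$depth_um)
  expect_equal(unique(round(slopes, 9)), 0.25 / (2.255e-5 * 1e4),
               tolerance = 1e-6)
})

test_that("PI phantom passes through the origin and uses the measured irradiance levels", {
  d <- make_pi_data(config = phantom_config(seed = 1, noise_rel = 0))
  expect_identical(sort(unique(d$E)), c(0, 110, 220, 1200))
  expect_true(all(d$P[d$E == 0] == 0))
  # rate at E = Ek is (1 - 1/e) of Pmax
  d2 <- make_pi_data(Pmax = 2, Ek = 150, irradiances = c(0, 150, 1200),
                     config = phantom_config(noise_rel = 0))
  expect_equal(unique(d2$P[d2$E == 150]), 2 * (1 - exp(-1)), tolerance = 1e-12)
})

test_that("growth phantom is constant without growth and exceeds 8e8 cells/mL by day 12", {
  g0 <- make_growth_series(r = 0, config = phantom_config(seed = 1, noise_rel = 0))
  expect_equal(diff(range(g0$cells_per_mL)), 0)
  expect_equal(g0$cells_per_mL[1], 1e6)
  g <- make_growth_series(config = phantom_config(seed = 1, noise_rel = 0))
  expect_gt(min(g$cells_per_mL[g$day == 12]), 8e8)
})

test_that("aggregate phantom packs the requested particles or fails loudly", {
  v <- make_aggregate_stack(n_particles = 5,
                            config = phantom_config(seed = 2, noise_rel = 0,
                                                    grid_spacing = 2),
                            sphericity_mean = 1, sphericity_sd = 0)
  gt <- attr(v, "ground_truth")
  expect_identical(gt$n_particles, 5)
  expect_true(all(v$data <= 4095))
  expect_identical(v$bit_depth, 12)
  expect_error(
    make_aggregate_stack(n_particles = 30, box_um = c(100, 100, 100),
                         config = phantom_config(seed = 1, grid_spacing = 2),
                         max_retries = 50),
    "packing")
  expect_error(make_aggregate_stack(config = phantom_config(grid_spacing = 10)),
               "coarse")
})

test_that("analytic ground truth round-trips through the matching fitters over 20 seeds", {
  ze_err <- sapply(1:20, function(s) {
    sc <- make_angular_scan(z_e = 1.32, config = phantom_config(seed = s, noise_rel = 0.02))
    abs(fit_extrapolation_length(sc)$z_e - 1.32) / 1.32
  })
  expect_lt(median(ze_err), 0.05)

  J_err <- sapply(1:20, function(s) {
    pr <- make_o2_profile(J = 0.25, config = phantom_config(seed = s, noise_rel = 0.01))
    abs(diffusive_flux(pr)$J - 0.25) / 0.25
  })
  expect_lt(median(J_err), 0.05)

  pi_err <- sapply(1:20, function(s) {
    d <- make_pi_data(Pmax = 2, Ek = 150, config = phantom_config(seed = s, noise_rel = 0.05))
    f <- fit_pi_curve(d$P, d$E)
    max(abs(f$Pmax - 2) / 2, abs(f$Ek - 150) / 150)
  })
  expect_lt(median(pi_err), 0.10)

  gr_err <- sapply(1:20, function(s) {
    g <- make_growth_series(config = phantom_config(seed = s, noise_rel = 0.05))
    f <- fit_growth(g)
    max(abs(f$r - 0.8) / 0.8, abs(f$K - 9e8) / 9e8)
  })
  expect_lt(median(gr_err), 0.15)
})
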