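# Image-stack -> surface -> print-mask chain and confocal particle
# quantification.

test_that("3D median filtering removes impulses and preserves constants", {
  arr <- array(500L, dim = c(9, 9, 9))
  v <- image_volume(arr, 10)
  expect_identical(denoise_median3d(v, 1)$data, arr)
  arr2 <- arr; arr2[5, 5, 5] <- 60000L
  v2 <- denoise_median3d(image_volume(arr2, 10), 1)
  expect_identical(v2$data, arr)
  expect_error(denoise_median3d(v, 9), "smaller")
})

test_that("per-slice Otsu threshold separates bimodal intensities", {
  set.seed(4)
  vals <- c(rnorm(4000, 1000, 60), rnorm(4000, 3000, 60))
  thr <- as.numeric(coraloptics:::otsu_thresholds(vals, n_classes = 2))
  expect_gt(thr, 1300)
  expect_lt(thr, 2700)
  # independent oracle: exhaustive scan of the between-class objective
  cand <- seq(min(vals), max(vals), length.out = 400)
  obj <- sapply(cand, function(t) {
    lo <- vals[vals <= t]; hi <- vals[vals > t]
    if (!length(lo) || !length(hi)) return(-Inf)
    length(lo) * mean(lo)^2 + length(hi) * mean(hi)^2
  })
  expect_equal(thr, cand[which.max(obj)], tolerance = 0.05 * diff(range(vals)))
  # cross-check against an established implementation
  img <- EBImage::Image(matrix(vals / 65535, 80, 100))
  expect_equal(thr / 65535, EBImage::otsu(img, range = range(vals / 65535)),
               tolerance = 0.02)
})

test_that("surface segmentation is exact on the noiseless phantom and robust to speckle", {
  v0 <- make_corallite_volume(phantom_config(seed = 5, noise_rel = 0,
                                             grid_spacing = 20))
  truth <- v0$data == 10000
  seg0 <- segment_surface(v0, n_classes = 2)
  expect_identical(sum((seg0$data > 0) != truth), 0L)
  # 5% speckle after median filtering: < 2% misclassified voxels
  vn <- make_corallite_volume(phantom_config(seed = 6, noise_rel = 0.05,
                                             grid_spacing = 20))
  segn <- segment_surface(denoise_median3d(vn, 1), n_classes = 2)
  err_filtered <- mean((segn$data > 0) != truth)
  expect_lt(err_filtered, 0.02)
  # impulse (hot/dead pixel) noise: median prefiltering reduces the
  # downstream misclassification rate
  vi <- v0
  bad <- withr::with_seed(8, sample(length(vi$data), length(vi$data) * 0.02))
  vi$data[bad] <- withr::with_seed(9, sample(c(0L, 60000L), length(bad),
                                             replace = TRUE))
  err_raw <- mean((segment_surface(vi, n_classes = 2)$data > 0) != truth)
  err_med <- mean((segment_surface(denoise_median3d(vi, 1),
                                   n_classes = 2)$data > 0) != truth)
  expect_lt(err_med, err_raw)
  # constant or background-only slices inherit a neighbor's threshold,
  # and the provenance log records which
  arr <- array(1000L, dim = c(12, 12, 3))
  arr[3:8, 3:8, c(1, 3)] <- 9000L
  segc <- segment_surface(image_volume(arr, 10), n_classes = 2)
  prov <- attr(segc, "provenance")
  expect_identical(prov$inherited, c(FALSE, TRUE, FALSE))
  expect_identical(sum(segc$data > 0), 2L * 36L)
})

test_that("isosurface of a digital ball reproduces sphere area, volume and slices", {
  r <- 20
  mesh <- extract_surface(digital_ball(r), spacing_um = 1)
  expect_true(mesh_is_watertight(mesh))
  expect_equal(mesh_area(mesh), 4 * pi * r^2, tolerance = 0.03)
  expect_equal(mesh_volume(mesh), 4 / 3 * pi * r^3, tolerance = 0.03)
  # physical scaling: the same ball at 5 um spacing has 125x the volume
  mesh5 <- extract_surface(digital_ball(r), spacing_um = 5)
  expect_equal(mesh_volume(mesh5) / mesh_volume(mesh), 125, tolerance = 0.001)
  # single voxel still gives a closed surface
  single <- array(FALSE, dim = c(7, 7, 7)); single[4, 4, 4] <- TRUE
  ms <- extract_surface(single, spacing_um = 2)
  expect_true(mesh_is_watertight(ms))
  expect_error(extract_surface(array(FALSE, dim = c(4, 4, 4)), 1), "empty")
})

test_that("hole filling repairs small punctures and reports large ones", {
  mesh <- extract_surface(digital_ball(8), spacing_um = 1)
  expect_identical(length(attr(fill_holes(mesh), "hole_report")$filled), 0L)
  punctured <- mesh; punctured$faces <- mesh$faces[-1, ]
  expect_false(mesh_is_watertight(punctured))
  fixed <- fill_holes(punctured)
  expect_true(mesh_is_watertight(fixed))
  expect_identical(attr(fixed, "hole_report")$filled, 3L)
  # a hole above the cap size is reported, not filled
  skipped <- fill_holes(punctured, max_hole_edges = 2)
  expect_identical(attr(skipped, "hole_report")$skipped, 3L)
  expect_false(mesh_is_watertight(skipped))
  expect_error(slice_masks(skipped, 2), "fill_holes")
})

test_that("mask slicing reproduces cross-sections and conserves volume", {
  r <- 15
  mesh <- extract_surface(digital_ball(r), spacing_um = 2)
  st <- slice_masks(mesh, layer_um = 2, pixel_um = 2)
  expect_identical(length(st$masks),
                   as.integer(ceiling(diff(range(mesh$vertices[, 3])) / 2)))
  mid <- st$masks[[round(length(st$masks) / 2)]]
  expect_equal(sqrt(sum(mid) * 4 / pi), 2 * r, tolerance = 2 / (2 * r))
  expect_equal(mask_stack_volume(st), mesh_volume(mesh), tolerance = 0.03)
})

test_that("corallite chain conserves volume and is idempotent within 5%", {
  v <- make_corallite_volume(phantom_config(seed = 5, noise_rel = 0,
                                            grid_spacing = 20))
  mesh <- extract_surface(segment_surface(v, n_classes = 2))
  # mesh volume agrees with the voxel-count volume of the phantom
  vox_vol <- attr(v, "ground_truth")$n_foreground * 20^3
  expect_equal(mesh_volume(mesh), vox_vol, tolerance = 0.05)
  st <- slice_masks(mesh, layer_um = 20)
  expect_equal(mask_stack_volume(st), mesh_volume(mesh), tolerance = 0.03)
  # rasterize -> re-extract: volume changes by < 5%
  arr2 <- simplify2array(st$masks)
  m2 <- extract_surface(arr2, spacing_um = c(st$pixel_um, st$pixel_um,
                                             st$layer_um))
  expect_equal(mesh_volume(m2), mesh_volume(mesh), tolerance = 0.05)
  # voxel-spacing invariance: physical volume at 10 um within 3% of 20 um
  v10 <- make_corallite_volume(phantom_config(seed = 5, noise_rel = 0,
                                              grid_spacing = 10))
  m10 <- extract_surface(segment_surface(v10, n_classes = 2))
  expect_equal(mesh_volume(m10), mesh_volume(mesh), tolerance = 0.03)
})

test_that("cup-only phantom mesh spans the printed 1 mm depth", {
  v <- make_corallite_volume(phantom_config(seed = 1, noise_rel = 0,
                                            grid_spacing = 20),
                             tentacle_length_mm = 0)
  mesh <- extract_surface(segment_surface(v, n_classes = 2))
  expect_equal(diff(range(mesh$vertices[, 3])), 1000, tolerance = 20 / 1000)
})

test_that("particle segmentation recovers counts, diameters and sphericity", {
  v <- make_aggregate_stack(n_particles = 44,
                            config = phantom_config(seed = 3, noise_rel = 0,
                                                    grid_spacing = 2),
                            sphericity_mean = 1, sphericity_sd = 0)
  ps <- segment_particles(v)
  expect_identical(ps$n_particles, 44L)
  expect_true(all(ps$stats$sphericity > 0.97)) # spheres within 3%
  gt <- attr(v, "ground_truth")
  expect_equal(sort(ps$stats$equiv_diameter_um), sort(gt$d_eq_um),
               tolerance = 0.05)
  expect_equal(ps$density_per_mm3,
               44 / (prod(dim(v$data)) * 8 / 1e9), tolerance = 1e-6)
})

test_that("ellipsoid aggregates reproduce the target sphericity distribution", {
  v <- make_aggregate_stack(n_particles = 12,
                            config = phantom_config(seed = 4, noise_rel = 0,
                                                    grid_spacing = 2))
  gt <- attr(v, "ground_truth")
  ps <- segment_particles(v)
  expect_identical(ps$n_particles, 12L)
  # measured sphericity tracks the analytic ground truth per phantom
  expect_equal(mean(ps$stats$sphericity), mean(gt$sphericity),
               tolerance = 0.03)
  # and the generator is calibrated to the 0.75 target on average
  expect_equal(mean(gt$sphericity), 0.75, tolerance = 0.07)
})

test_that("touching particles below the smoothing scale merge (documented behavior)", {
  arr <- array(100L, dim = c(40, 40, 24))
  g <- expand.grid(x = 1:40, y = 1:40, z = 1:24)
  b1 <- (g$x - 14)^2 + (g$y - 20)^2 + (g$z - 12)^2 <= 36
  b2 <- (g$x - 28)^2 + (g$y - 20)^2 + (g$z - 12)^2 <= 36 # 2-voxel gap
  arr[as.matrix(g[b1 | b2, ])] <- 3000L
  ps <- segment_particles(image_volume(arr, 2, bit_depth = 12),
                          clean_factor = 1, smooth_factor = 2)
  expect_identical(ps$n_particles, 1L)
})

test_that("16-bit volumes round-trip through multi-page TIFF", {
  v <- make_corallite_volume(phantom_config(seed = 9, noise_rel = 0.02,
                                            grid_spacing = 25))
  path <- withr::local_tempfile(fileext = ".tif")
  write_volume_tiff(v, path)
  back <- read_volume_tiff(path, spacing_um = v$spacing_um)
  expect_identical(back$data, v$data)
})
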