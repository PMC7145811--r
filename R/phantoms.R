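#' Phantom generator configuration
#'
#' Shared configuration for all synthetic-data generators. Every generator
#' runs under `withr::with_seed(config$seed, ...)`, so a fixed seed gives
#' byte-identical output, and attaches its ground-truth parameters as the
#' `ground_truth` attribute of the result (fitting code never reads it).
#'
#' @param seed Integer RNG seed.
#' @param noise_rel Relative noise amplitude (>= 0). Interpreted as
#'   multiplicative Gaussian noise on intensities/transmittances and
#'   additive Gaussian noise (relative to a reference level) on
#'   concentrations and rates.
#' @param grid_spacing Voxel spacing in micrometers for volume phantoms;
#'   scalar or length 3 `(x, y, z)`.
#' @param wavelength Nominal wavelength, nm.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(seed = 1L, noise_rel = 0.02, grid_spacing = 10,
                           wavelength = 550) {
  if (noise_rel < 0) stop("noise_rel must be >= 0")
  if (any(grid_spacing <= 0)) stop("grid_spacing must be > 0")
  structure(list(seed = as.integer(seed), noise_rel = noise_rel,
                 grid_spacing = grid_spacing, wavelength = wavelength),
            class = "phantom_config")
}

spacing3 <- function(config) {
  s <- config$grid_spacing
  if (length(s) == 1) rep(s, 3) else s
}

mult_noise <- function(x, noise_rel) {
  if (noise_rel == 0) return(x)
  x * (1 + noise_rel * stats::rnorm(length(x)))
}

#' Synthetic corallite volume
#'
#' Generates a 16-bit tomography-style volume of the bionic corallite
#' geometry: a cup 1 mm in diameter and depth (100 um wall and floor) with
#' vertical 200 um x 1 mm tentacle cylinders arranged radially around the
#' rim, all inside the cup's lateral footprint. Foreground and background
#' are two intensity levels separated by at least 4x the speckle standard
#' deviation; multiplicative Gaussian speckle is applied.
#'
#' @param config A [phantom_config()]; `grid_spacing` must be <= 25 um to
#'   resolve the tentacles.
#' @param cup_diameter_mm,cup_depth_mm Cup diameter and depth, mm.
#' @param wall_um Wall/floor thickness, um.
#' @param tentacle_diameter_um,tentacle_length_mm Tentacle size.
#' @param n_tentacles Number of tentacles around the rim.
#' @param fg,bg Foreground/background intensity levels (16-bit).
#' @return An [image_volume()] with `ground_truth` attribute.
#' @export
make_corallite_volume <- function(config = phantom_config(),
                                  cup_diameter_mm = 1, cup_depth_mm = 1,
                                  wall_um = 100,
                                  tentacle_diameter_um = 200,
                                  tentacle_length_mm = 1,
                                  n_tentacles = 8,
                                  fg = 10000, bg = 1000) {
  sp <- spacing3(config)
  if (max(sp) > 25)
    stop("grid spacing must be <= 25 um to resolve the ",
         tentacle_diameter_um, " um tentacles (got ", max(sp), " um)")
  if (config$noise_rel > 0 &&
      (fg - bg) < 4 * fg * config$noise_rel)
    stop("noise_rel too large for 4x foreground/background separation; ",
         "need noise_rel <= ", signif((fg - bg) / (4 * fg), 3))

  R_out <- cup_diameter_mm * 500          # outer radius, um
  depth <- cup_depth_mm * 1000
  t_len <- tentacle_length_mm * 1000
  t_rad <- tentacle_diameter_um / 2
  ring_r <- R_out - t_rad                  # tentacle centers inside footprint
  margin <- 3                              # voxels of background padding

  nx <- ceiling(2 * R_out / sp[1]) + 2 * margin
  ny <- ceiling(2 * R_out / sp[2]) + 2 * margin
  nz <- ceiling((t_len + depth) / sp[3]) + 2 * margin
  x <- (seq_len(nx) - 0.5) * sp[1] - nx * sp[1] / 2
  y <- (seq_len(ny) - 0.5) * sp[2] - ny * sp[2] / 2
  z <- (seq_len(nz) - 0.5) * sp[3] - margin * sp[3]  # 0 at top of tentacles

  r2 <- outer(x^2, y^2, `+`)
  ang <- 2 * pi * (seq_len(n_tentacles) - 1) / n_tentacles
  tcx <- ring_r * cos(ang); tcy <- ring_r * sin(ang)
  tent_xy <- matrix(FALSE, nx, ny)
  for (k in seq_len(n_tentacles)) {
    tent_xy <- tent_xy |
      (outer((x - tcx[k])^2, (y - tcy[k])^2, `+`) <= t_rad^2)
  }

  arr <- array(FALSE, dim = c(nx, ny, nz))
  for (iz in seq_len(nz)) {
    zc <- z[iz]
    if (zc >= 0 && zc < t_len) {
      arr[, , iz] <- tent_xy
    } else if (zc >= t_len && zc <= t_len + depth) {
      zcup <- zc - t_len
      cup <- (r2 <= R_out^2) &
        !((r2 <= (R_out - wall_um)^2) & (zcup <= depth - wall_um))
      arr[, , iz] <- cup
    }
  }

  vol <- withr::with_seed(config$seed, {
    v <- ifelse(arr, fg, bg)
    v <- mult_noise(v, config$noise_rel)
    array(as.integer(pmin(65535, pmax(0, round(v)))), dim = dim(arr))
  })
  out <- image_volume(vol, spacing_um = sp, bit_depth = 16)
  attr(out, "ground_truth") <- list(
    cup_diameter_mm = cup_diameter_mm, cup_depth_mm = cup_depth_mm,
    wall_um = wall_um, tentacle_diameter_um = tentacle_diameter_um,
    tentacle_length_mm = tentacle_length_mm, n_tentacles = n_tentacles,
    fg = fg, bg = bg, foreground = which(arr),
    n_foreground = sum(arr))
  attr(out, "config") <- config
  out
}

#' Synthetic transmission-versus-thickness series
#'
#' Total transmittance of diffusive slabs generated from the
#' diffusion-slab model ([diffusion_transmission()]) with multiplicative
#' Gaussian noise.
#'
#' @param l_a Absorption length, mm.
#' @param l_t Transport mean free path, mm.
#' @param z_e Extrapolation length (dimensionless).
#' @param thicknesses Sample thicknesses, mm (>= 4 values); default
#'   `l_t * seq(5, 20, by = 2.5)`, spanning the diffusive regime.
#' @param config A [phantom_config()].
#' @return A [transmission_series()] with `ground_truth` attribute.
#' @export
make_transmission_series <- function(l_a = 100, l_t = 3, z_e = 1.32,
                                     thicknesses = NULL,
                                     config = phantom_config()) {
  if (l_a <= 0 || l_t <= 0 || z_e <= 0) stop("l_a, l_t, z_e must be > 0")
  if (is.null(thicknesses)) thicknesses <- l_t * seq(5, 20, by = 2.5)
  if (length(thicknesses) < 4 || any(thicknesses <= 0))
    stop("need >= 4 strictly positive thicknesses")
  if (l_t >= min(thicknesses))
    warning("l_t >= thinnest sample: diffusion-regime assumption violated")
  Tt <- suppressWarnings(diffusion_transmission(thicknesses, l_a, l_t, z_e))
  Tn <- withr::with_seed(config$seed, mult_noise(Tt, config$noise_rel))
  Tn <- pmin(1, pmax(1e-12, Tn))
  out <- transmission_series(thicknesses, Tn, wavelength = config$wavelength)
  attr(out, "ground_truth") <- list(l_a = l_a, l_t = l_t, z_e = z_e)
  attr(out, "config") <- config
  out
}

#' Synthetic angular transmittance scan
#'
#' Intensities proportional to the diffusion angular law [p_mu()] over the
#' forward hemisphere at 1-degree steps, with multiplicative noise,
#' normalized to maximum 1.
#'
#' @param z_e Extrapolation length (> 0).
#' @param config A [phantom_config()].
#' @param theta_deg Signed detection angles (default -90..90 by 1).
#' @return An [angular_scan()] with `ground_truth` attribute.
#' @export
make_angular_scan <- function(z_e = 1.32, config = phantom_config(),
                              theta_deg = seq(-90, 90, by = 1)) {
  if (z_e <= 0) stop("z_e must be > 0")
  mu <- cos(abs(theta_deg) * pi / 180)
  intens <- ifelse(mu > 0, mu * (z_e + mu) / (z_e / 2 + 1 / 3), 0)
  intens <- withr::with_seed(config$seed,
                             pmax(0, mult_noise(intens, config$noise_rel)))
  out <- angular_scan(theta_deg, intens)
  attr(out, "ground_truth") <- list(z_e = z_e)
  attr(out, "config") <- config
  out
}

#' Synthetic Brewster-angle reflectance scan
#'
#' p-polarized Fresnel reflectance of a flat sample of index `n` in
#' ambient index 1 versus incidence angle, with multiplicative noise. The
#' reflectance minimum sits at `arctan(n)`.
#'
#' @param n Sample refractive index (> 1; `n = 1` gives the degenerate
#'   all-zero scan).
#' @param config A [phantom_config()].
#' @param theta_deg Incidence angles, degrees (default 0..89 by 0.5).
#' @return An [angular_scan()] (reflectance in the `intensity` column).
#' @export
make_brewster_scan <- function(n = 1.40, config = phantom_config(),
                               theta_deg = seq(0, 89, by = 0.5)) {
  if (n < 1) stop("n must be >= 1")
  ti <- theta_deg * pi / 180
  ci <- cos(ti); si <- sin(ti)
  st <- si / n
  ct <- sqrt(pmax(0, 1 - st^2))
  rp <- (n * ci - ct) / (n * ci + ct)
  Rp <- rp^2
  Rp[Rp < 1e-20] <- 0 # snap float dust so n = 1 gives exact zeros
  Rp <- withr::with_seed(config$seed, pmax(0, mult_noise(Rp, config$noise_rel)))
  if (max(Rp) == 0) {
    out <- structure(data.frame(theta_deg = theta_deg,
                                mu = cos(ti), intensity = Rp),
                     class = c("angular_scan", "data.frame"))
  } else {
    out <- angular_scan(theta_deg, Rp)
  }
  attr(out, "ground_truth") <- list(n = n, theta_B = atan(n) * 180 / pi)
  attr(out, "config") <- config
  out
}

#' Synthetic O2 microprofile
#'
#' Oxygen concentration versus depth for a surface with diffusive flux `J`
#' out of it: linear within the diffusive boundary layer (DBL) with
#' gradient `J / (D * 1e4)` micromol/L per um (so the surface is enriched
#' for positive `J`), constant at the bulk value above the DBL. Additive
#' Gaussian noise of `noise_rel * bulk` is applied.
#'
#' @param J Flux out of the surface, nmol O2 cm^-2 s^-1 (positive = net
#'   production).
#' @param D Molecular diffusion coefficient, cm^2 s^-1 (default the O2
#'   value at 25 degC, salinity 30: 2.255e-5).
#' @param dbl_thickness_um Diffusive-boundary-layer thickness, um.
#' @param config A [phantom_config()].
#' @param bulk Bulk O2 concentration, micromol/L.
#' @param depths_um Measurement depths (um, negative above the surface,
#'   0 at the surface).
#' @return An `o2_profile` with `ground_truth` attribute.
#' @export
make_o2_profile <- function(J = 0.25, D = 2.255e-5, dbl_thickness_um = 300,
                            config = phantom_config(), bulk = 206,
                            depths_um = seq(-600, 0, by = 25)) {
  if (D <= 0 || dbl_thickness_um <= 0) stop("D and dbl_thickness must be > 0")
  slope <- J / (D * 1e4)   # micromol/L per um
  conc <- ifelse(depths_um >= -dbl_thickness_um,
                 bulk + slope * (depths_um + dbl_thickness_um),
                 bulk)
  conc <- withr::with_seed(config$seed, {
    if (config$noise_rel > 0)
      conc + config$noise_rel * bulk * stats::rnorm(length(conc))
    else conc
  })
  out <- o2_profile(depths_um, conc)
  attr(out, "ground_truth") <- list(J = J, D = D,
                                    dbl_thickness_um = dbl_thickness_um,
                                    bulk = bulk)
  attr(out, "config") <- config
  out
}

#' Synthetic photosynthesis-irradiance data
#'
#' Rates from the saturating-exponential (Webb-type) model
#' `P = Pmax * (1 - exp(-E / Ek))` at the given irradiances, with additive
#' Gaussian noise of `noise_rel * Pmax` per replicate.
#'
#' @param Pmax Maximum photosynthetic rate.
#' @param Ek Saturation irradiance, micromol photons m^-2 s^-1.
#' @param irradiances Irradiance levels (must include 0); default the
#'   measurement levels 0, 110, 220, 1200 micromol photons m^-2 s^-1.
#' @param config A [phantom_config()].
#' @param replicates Replicates per irradiance.
#' @return Data frame `(E, P, replicate)` with `ground_truth` attribute.
#' @export
make_pi_data <- function(Pmax = 2, Ek = 150,
                         irradiances = c(0, 110, 220, 1200),
                         config = phantom_config(), replicates = 3) {
  if (!any(irradiances == 0)) stop("irradiances must include 0")
  E <- rep(irradiances, each = replicates)
  P0 <- Pmax * (1 - exp(-E / Ek))
  P <- withr::with_seed(config$seed, {
    if (config$noise_rel > 0)
      P0 + config$noise_rel * Pmax * stats::rnorm(length(P0))
    else P0
  })
  out <- data.frame(E = E, P = P,
                    replicate = rep(seq_len(replicates), length(irradiances)))
  attr(out, "ground_truth") <- list(Pmax = Pmax, Ek = Ek)
  attr(out, "config") <- config
  out
}

#' Synthetic algal growth series
#'
#' Logistic growth `N(t) = K / (1 + ((K - N0)/N0) exp(-r t))` sampled at
#' the given days with multiplicative Gaussian replicate noise. The default
#' calibration (`N0 = 1e6` cells/mL inoculum, `K = 9e8`, `r = 0.8` per
#' day) exceeds 8e8 cells/mL by day 12.
#'
#' @param r Intrinsic growth rate, day^-1.
#' @param K Carrying capacity, cells/mL.
#' @param config A [phantom_config()].
#' @param days Sampling days.
#' @param n_replicates Replicates per day.
#' @param N0 Inoculum density, cells/mL.
#' @return Data frame of class `growth_series` `(day, replicate,
#'   cells_per_mL)` with `ground_truth` attribute.
#' @export
make_growth_series <- function(r = 0.8, K = 9e8,
                               config = phantom_config(),
                               days = c(0, 3, 6, 10, 12),
                               n_replicates = 4, N0 = 1e6) {
  if (K <= N0 || N0 <= 0) stop("need K > N0 > 0")
  day <- rep(days, each = n_replicates)
  N <- K / (1 + (K - N0) / N0 * exp(-r * day))
  cells <- withr::with_seed(config$seed, pmax(1, mult_noise(N, config$noise_rel)))
  out <- structure(data.frame(day = day,
                              replicate = rep(seq_len(n_replicates),
                                              length(days)),
                              cells_per_mL = cells),
                   class = c("growth_series", "data.frame"))
  attr(out, "ground_truth") <- list(r = r, K = K, N0 = N0)
  attr(out, "config") <- config
  out
}

# analytic sphericity of a spheroid with equal semi-axes a = b and c = q*a
spheroid_sphericity <- function(q) {
  if (abs(q - 1) < 1e-9) return(1)
  if (q > 1) { # prolate
    e <- sqrt(1 - 1 / q^2)
    A <- 2 * pi * (1 + q / e * asin(e))
  } else {     # oblate
    e <- sqrt(1 - q^2)
    A <- 2 * pi * (1 + (1 - e^2) / e * atanh(e))
  }
  V <- 4 / 3 * pi * q
  pi^(1 / 3) * (6 * V)^(2 / 3) / A
}

# prolate axis ratio hitting a target sphericity
axis_ratio_for_sphericity <- function(psi) {
  if (psi >= 1) return(1)
  stats::uniroot(function(q) spheroid_sphericity(q) - psi,
                 interval = c(1 + 1e-6, 60), tol = 1e-8)$root
}

#' Synthetic confocal aggregate stack
#'
#' A 12-bit-in-16 confocal-style volume of non-overlapping ellipsoidal
#' algal aggregates with known equivalent diameters and axis ratios chosen
#' to hit a target sphericity distribution (prolate spheroids with random
#' orientation; `sphericity_sd = 0` and `sphericity_mean = 1` gives
#' spheres).
#'
#' @param n_particles Number of aggregates.
#' @param diameter_range Equivalent-sphere diameter range, um (default
#'   30-50 um).
#' @param config A [phantom_config()] (default spacing 2 um, fine enough
#'   that the smallest aggregate spans > 10 voxels).
#' @param sphericity_mean,sphericity_sd Target sphericity distribution,
#'   defaults matching the measured aggregates (0.75 +/- 0.09 SD, truncated
#'   to [0.6, 0.98]; set mean 1, sd 0 for exact spheres).
#' @param box_um Volume extent `(x, y, z)`, um; default sized to hold the
#'   particles at moderate packing.
#' @param fg,bg Foreground/background intensities (12-bit scale).
#' @param clearance_um Minimum surface-to-surface spacing between
#'   particles, um; must exceed the bridging scale of the downstream
#'   morphological closing (2x its radius) or nearby particles merge.
#' @param max_retries Placement retries per particle before a packing
#'   error is raised.
#' @return An [image_volume()] (bit_depth 12) with per-particle ground
#'   truth.
#' @export
make_aggregate_stack <- function(n_particles = 44,
                                 diameter_range = c(30, 50),
                                 config = phantom_config(grid_spacing = 2),
                                 sphericity_mean = 0.75,
                                 sphericity_sd = 0.09,
                                 box_um = NULL,
                                 fg = 3000, bg = 100,
                                 clearance_um = 12,
                                 max_retries = 5000) {
  sp <- spacing3(config)
  if (max(sp) > diameter_range[1] / 10)
    stop("grid spacing too coarse to resolve ", diameter_range[1],
         " um aggregates; need <= ", diameter_range[1] / 10, " um")
  withr::with_seed(config$seed, {
    d_eq <- stats::runif(n_particles, diameter_range[1], diameter_range[2])
    psi <- if (sphericity_sd == 0) rep(sphericity_mean, n_particles) else
      pmin(0.98, pmax(0.6, sphericity_mean +
                             sphericity_sd * stats::rnorm(n_particles)))
    q <- vapply(psi, axis_ratio_for_sphericity, 0)
    # semi-axes: a = b, c = q a with (4/3) pi a^2 c = (pi/6) d_eq^3
    a <- d_eq / 2 / q^(1 / 3)
    cax <- q * a
    rbound <- cax + max(sp)          # bounding radius, um

    if (is.null(box_um)) {
      reff <- rbound + clearance_um / 2
      side <- max(2.2 * max(reff),
                  (sum(4 / 3 * pi * reff^3) / 0.15)^(1 / 3))
      box_um <- rep(ceiling(side / 10) * 10, 3)
    }
    if (any(2 * rbound >= min(box_um)))
      stop("aggregate packing failed: box_um is smaller than a particle")
    centers <- matrix(NA_real_, n_particles, 3)
    axes <- vector("list", n_particles)
    for (i in seq_len(n_particles)) {
      placed <- FALSE
      for (try in seq_len(max_retries)) {
        cen <- stats::runif(3, rbound[i], box_um - rbound[i])
        ok <- TRUE
        if (i > 1) {
          dd <- sqrt(colSums((t(centers[seq_len(i - 1), , drop = FALSE]) -
                                cen)^2))
          ok <- all(dd >= rbound[i] + rbound[seq_len(i - 1)] + clearance_um)
        }
        if (ok) { centers[i, ] <- cen; placed <- TRUE; break }
      }
      if (!placed)
        stop("aggregate packing failed after ", max_retries,
             " retries for particle ", i, "; enlarge box_um")
      # random orientation: principal axis uniform on the sphere
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
      axes[[i]] <- u
    }

    dims <- ceiling(box_um / sp)
    arr <- array(FALSE, dim = dims)
    gx <- (seq_len(dims[1]) - 0.5) * sp[1]
    gy <- (seq_len(dims[2]) - 0.5) * sp[2]
    gz <- (seq_len(dims[3]) - 0.5) * sp[3]
    for (i in seq_len(n_particles)) {
      cen <- centers[i, ]; u <- axes[[i]]
      ix <- which(abs(gx - cen[1]) <= rbound[i])
      iy <- which(abs(gy - cen[2]) <= rbound[i])
      iz <- which(abs(gz - cen[3]) <= rbound[i])
      dxv <- gx[ix] - cen[1]; dyv <- gy[iy] - cen[2]; dzv <- gz[iz] - cen[3]
      G <- expand.grid(dx = dxv, dy = dyv, dz = dzv)
      proj <- G$dx * u[1] + G$dy * u[2] + G$dz * u[3]  # along principal axis
      r2perp <- G$dx^2 + G$dy^2 + G$dz^2 - proj^2
      inside <- (proj / cax[i])^2 + r2perp / a[i]^2 <= 1
      sub <- array(inside, dim = c(length(ix), length(iy), length(iz)))
      arr[ix, iy, iz] <- arr[ix, iy, iz] | sub
    }
    v <- ifelse(arr, fg, bg)
    v <- mult_noise(v, config$noise_rel)
    vol <- array(as.integer(pmin(4095, pmax(0, round(v)))), dim = dims)
    out <- image_volume(vol, spacing_um = sp, bit_depth = 12)
    attr(out, "ground_truth") <- list(
      n_particles = n_particles, d_eq_um = d_eq, sphericity = psi,
      axis_ratio = q, centers_um = centers, box_um = box_um)
    attr(out, "config") <- config
    out
  })
}
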