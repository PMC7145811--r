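#' O2 depth microprofile
#'
#' Oxygen concentration versus depth measured with a Clark-type
#' microsensor. Depths are in micrometers with 0 at the sample surface and
#' negative values above it (in the diffusive boundary layer and bulk);
#' concentrations in micromol per liter.
#'
#' @param depth_um Strictly monotone depths, um.
#' @param conc_umolL O2 concentrations, micromol/L.
#' @param temperature_C,salinity Measurement conditions (metadata).
#' @return A data frame of class `o2_profile`.
#' @export
o2_profile <- function(depth_um, conc_umolL, temperature_C = 25,
                       salinity = 30) {
  stopifnot(length(depth_um) == length(conc_umolL))
  if (any(diff(depth_um) <= 0) && any(diff(depth_um) >= 0)) {
    if (!(all(diff(depth_um) > 0) || all(diff(depth_um) < 0)))
      stop("depths must be strictly monotone")
  }
  o <- order(depth_um)
  structure(data.frame(depth_um = depth_um[o], conc_umolL = conc_umolL[o]),
            temperature_C = temperature_C, salinity = salinity,
            class = c("o2_profile", "data.frame"))
}

# R^2 that treats an (almost) exact linear fit as 1 even when the
# response is constant (flat profiles are perfectly linear)
lin_r2 <- function(x, y) {
  if (stats::sd(y) < 1e-12 * (abs(mean(y)) + 1)) return(1)
  suppressWarnings(summary(stats::lm(y ~ x))$r.squared)
}

#' Diffusive O2 flux from a microprofile (Fick's first law)
#'
#' Estimates the flux of O2 leaving the sample surface from the linear
#' concentration gradient in the diffusive boundary layer:
#' `J = D * dC/dz * 1e4` in nmol cm^-2 s^-1, with `dC/dz` in micromol/L
#' per um along the depth axis (which points into the sample, so a
#' surface-enriched profile — concentration falling away from the surface
#' — gives positive J = net production, and a consumption profile gives
#' negative J). The linear region is selected automatically as the
#' maximal-R^2 window anchored at the surface (windows of >= `min_points`
#' points ending at the shallowest depth <= 0: within the linear boundary
#' layer R^2 grows as the window extends, and drops once the window
#' crosses into the well-mixed bulk), or supplied by the user.
#'
#' @param profile An [o2_profile()].
#' @param D Molecular diffusion coefficient, cm^2 s^-1 (default 2.255e-5,
#'   O2 in seawater at 25 degC, salinity 30).
#' @param window Optional `c(depth_min, depth_max)` (um) overriding the
#'   automatic linear-region selection.
#' @param r2_threshold Linearity requirement for the automatic window.
#' @param min_points Minimum points in the window (>= 3).
#' @return A list of class `flux_estimate`: `J`, `J_se` (nmol cm^-2 s^-1),
#'   `slope`, `slope_se` (micromol/L per um), `D`, `window_um`,
#'   `r_squared`.
#' @export
diffusive_flux <- function(profile, D = 2.255e-5, window = NULL,
                           r2_threshold = 0.95, min_points = 3) {
  stopifnot(inherits(profile, "o2_profile"))
  if (D <= 0) stop("D must be > 0")
  d <- profile[profile$depth_um <= 0, , drop = FALSE]
  if (nrow(d) < min_points) stop("need >= ", min_points,
                                 " points at or above the surface")
  if (!is.null(window)) {
    sel <- d$depth_um >= window[1] & d$depth_um <= window[2]
    if (sum(sel) < min_points) stop("user window holds < ", min_points, " points")
    use <- d[sel, , drop = FALSE]
    r2 <- lin_r2(use$depth_um, use$conc_umolL)
  } else {
    n <- nrow(d) # sorted ascending; row n is the shallowest point
    starts <- seq_len(n - min_points + 1)
    r2s <- vapply(starts, function(i) lin_r2(d$depth_um[i:n],
                                             d$conc_umolL[i:n]), 0)
    best_i <- starts[which.max(r2s)]
    best_r2 <- max(r2s)
    if (best_r2 < r2_threshold)
      stop(sprintf(
        "no surface-anchored window reaches R^2 >= %.2f; best window [%g, %g] um has R^2 = %.3f",
        r2_threshold, d$depth_um[best_i], d$depth_um[n], best_r2))
    use <- d[best_i:n, , drop = FALSE]
    r2 <- best_r2
  }
  fit <- stats::lm(conc_umolL ~ depth_um, data = use)
  cf <- suppressWarnings(summary(fit)$coefficients)
  slope <- unname(cf["depth_um", "Estimate"])
  slope_se <- unname(cf["depth_um", "Std. Error"])
  # micromol/L per um = 1e4 nmol cm^-4; J [nmol cm^-2 s^-1] = D * 1e4 * slope
  structure(list(J = D * 1e4 * slope, J_se = D * 1e4 * slope_se,
                 slope = slope, slope_se = slope_se, D = D,
                 window_um = range(use$depth_um), r_squared = r2),
            class = "flux_estimate")
}

#' Gross photosynthesis by the light-dark shift method
#'
#' The initial rate of O2 decline immediately after darkening equals the
#' gross photosynthesis rate at that point. Fits a line over a short
#' window (default 1 s, matching a sub-0.2 s sensor response) starting at
#' the darkening time and returns the negated slope.
#'
#' @param time_s Time stamps, s (sampling interval <= 0.1 s around the
#'   shift).
#' @param conc O2 readings (any concentration unit).
#' @param darkening_time Time of darkening, s.
#' @param window_s Fit window length, s (default 1).
#' @return A list: `rate` (concentration units per s), `se`, `n_points`.
#' @export
gross_photosynthesis <- function(time_s, conc, darkening_time,
                                 window_s = 1) {
  stopifnot(length(time_s) == length(conc))
  if (darkening_time + window_s > max(time_s) || darkening_time < min(time_s))
    stop("fit window extends beyond the trace")
  sel <- time_s >= darkening_time & time_s <= darkening_time + window_s
  if (sum(sel) < 3) stop("fewer than 3 samples in the fit window")
  dt <- stats::median(diff(time_s[sel]))
  if (dt > 0.1)
    stop("trace must be sampled at >= 10 Hz around darkening (got ",
         signif(1 / dt, 3), " Hz)")
  fit <- stats::lm(conc[sel] ~ time_s[sel])
  cf <- suppressWarnings(summary(fit)$coefficients)
  list(rate = -unname(cf[2, "Estimate"]), se = unname(cf[2, "Std. Error"]),
       n_points = sum(sel))
}

#' Fit a photosynthesis-irradiance (PI) curve
#'
#' Nonlinear least squares of the saturating exponential (Webb-type)
#' model `P = Pmax * (1 - exp(-E / Ek))` — photosynthesis rises linearly
#' at low irradiance with slope `Pmax / Ek` and saturates at `Pmax`; at
#' `E = Ek` the rate is `(1 - 1/e) * Pmax`.
#'
#' @param rates Measured photosynthesis rates.
#' @param irradiances Irradiances, micromol photons m^-2 s^-1; at least 3
#'   distinct values including (near-)zero.
#' @return A list of class `pi_fit`: `Pmax`, `Ek`, standard errors,
#'   `covariance`, `residuals`, `fit`.
#' @export
fit_pi_curve <- function(rates, irradiances) {
  stopifnot(length(rates) == length(irradiances))
  Ev <- unique(irradiances)
  if (length(Ev) < 3) stop("need >= 3 distinct irradiances")
  if (min(irradiances) > 0.02 * max(irradiances))
    stop("irradiances must include a near-zero level")
  d <- data.frame(E = irradiances, P = rates)
  start <- list(Pmax = max(rates), Ek = max(stats::median(Ev), 1) / 2)
  fit <- tryCatch(
    minpack.lm::nlsLM(P ~ Pmax * (1 - exp(-E / Ek)), data = d, start = start,
                      lower = c(Pmax = 1e-12, Ek = 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop("PI fit failed to converge (start Pmax = ",
                             signif(start$Pmax, 3), ", Ek = ",
                             signif(start$Ek, 3), "): ", conditionMessage(e)))
  cf <- summary(fit)$coefficients
  structure(list(Pmax = unname(cf["Pmax", "Estimate"]),
                 Ek = unname(cf["Ek", "Estimate"]),
                 Pmax_se = unname(cf["Pmax", "Std. Error"]),
                 Ek_se = unname(cf["Ek", "Std. Error"]),
                 covariance = stats::vcov(fit),
                 residuals = stats::residuals(fit), fit = fit),
            class = "pi_fit")
}

#' Normalize a fluence-rate profile to incident irradiance
#'
#' Expresses scalar-irradiance (fluence-rate) readings as a percentage of
#' the incident downwelling irradiance reference.
#'
#' @param raw_profile Data frame with columns `depth_um` and a raw reading
#'   column (second column used), or a `fluence_profile`.
#' @param E_d_reference Incident downwelling irradiance in the same raw
#'   units (> 0).
#' @return A `fluence_profile` data frame (`depth_um`, `E0_percent`).
#' @export
normalize_fluence <- function(raw_profile, E_d_reference) {
  if (E_d_reference <= 0) stop("E_d reference must be > 0")
  depth <- raw_profile$depth_um
  raw <- raw_profile[[setdiff(names(raw_profile), "depth_um")[1]]]
  structure(data.frame(depth_um = depth,
                       E0_percent = 100 * raw / E_d_reference),
            class = c("fluence_profile", "data.frame"))
}

#' Interpolate a fluence profile, and compare two profiles at depth
#'
#' `fluence_at_depth` linearly interpolates `E0_percent` at a depth;
#' `fluence_fold_change` is the ratio of two profiles at a depth (e.g.
#' scattering versus non-scattering geometry).
#'
#' @param profile,profile_num,profile_den `fluence_profile` data frames.
#' @param depth_um Depth, um.
#' @return A number.
#' @export
fluence_at_depth <- function(profile, depth_um) {
  stats::approx(profile$depth_um, profile$E0_percent, xout = depth_um,
                rule = 2)$y
}

#' @rdname fluence_at_depth
#' @export
fluence_fold_change <- function(profile_num, profile_den, depth_um) {
  fluence_at_depth(profile_num, depth_um) /
    fluence_at_depth(profile_den, depth_um)
}

#' Fit a logistic growth curve with confidence and prediction bands
#'
#' Nonlinear least squares of the logistic model
#' `N(t) = K / (1 + ((K - N0) / N0) * exp(-r t))` to replicated cell
#' densities. Replicate scatter of cell counts grows with the mean, so the
#' fit uses relative-error weighting (weights 1/N^2) and the residual
#' standard deviation is a relative one. 95% confidence bands come from
#' delta-method propagation of the parameter covariance; prediction bands
#' add the (proportional) residual variance `sigma^2 * N(t)^2`, so the
#' prediction band always contains the confidence band.
#'
#' @param series A data frame with columns `day` and `cells_per_mL`
#'   (e.g. a `growth_series` from [make_growth_series()]); >= 4 distinct
#'   days.
#' @param conf_level Band level (default 0.95).
#' @param band_days Days at which bands are evaluated (default the
#'   observed days).
#' @return A list of class `growth_fit`: `r`, `K`, `N0`, standard errors,
#'   `sigma`, `converged`, `bands` (data frame with `day`, `fit`,
#'   `conf_lo`, `conf_hi`, `pred_lo`, `pred_hi`) and the `nls` fit.
#'   Degenerate no-growth data yields `converged = FALSE` rather than an
#'   error.
#' @export
fit_growth <- function(series, conf_level = 0.95, band_days = NULL) {
  d <- data.frame(day = series$day, N = series$cells_per_mL)
  if (length(unique(d$day)) < 4) stop("need >= 4 distinct days")
  if (is.null(band_days)) band_days <- sort(unique(d$day))
  N0s <- max(mean(d$N[d$day == min(d$day)]), 1)
  Ks <- max(d$N) * 1.05
  rs <- 0.5
  fit <- tryCatch(
    minpack.lm::nlsLM(N ~ K / (1 + (K - N0) / N0 * exp(-r * day)), data = d,
                      start = list(K = Ks, N0 = N0s, r = rs),
                      weights = 1 / pmax(d$N, 1)^2,
                      lower = c(K = 1e-6, N0 = 1e-6, r = 0),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(r = NA_real_, K = NA_real_, N0 = NA_real_,
                          converged = FALSE, bands = NULL, fit = NULL),
                     class = "growth_fit"))
  }
  cf <- stats::coef(fit)
  K <- cf[["K"]]; N0 <- cf[["N0"]]; r <- cf[["r"]]
  vc <- stats::vcov(fit)
  sigma <- summary(fit)$sigma
  dfree <- nrow(d) - 3
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, dfree)

  logistic <- function(t, K, N0, r) K / (1 + (K - N0) / N0 * exp(-r * t))
  grad <- function(t) {
    h <- 1e-6
    vapply(seq_along(cf), function(k) {
      p1 <- cf; p2 <- cf
      p1[k] <- p1[k] * (1 + h) + 1e-12
      p2[k] <- p2[k] * (1 - h) - 1e-12
      (logistic(t, p1[["K"]], p1[["N0"]], p1[["r"]]) -
         logistic(t, p2[["K"]], p2[["N0"]], p2[["r"]])) / (p1[k] - p2[k])
    }, 0)
  }
  fitv <- logistic(band_days, K, N0, r)
  se_conf <- vapply(band_days, function(t) {
    g <- grad(t); sqrt(max(0, t(g) %*% vc %*% g))
  }, 0)
  se_pred <- sqrt(se_conf^2 + sigma^2 * fitv^2)
  bands <- data.frame(day = band_days, fit = fitv,
                      conf_lo = fitv - tcrit * se_conf,
                      conf_hi = fitv + tcrit * se_conf,
                      pred_lo = fitv - tcrit * se_pred,
                      pred_hi = fitv + tcrit * se_pred)
  # no-growth degeneracy: rate indistinguishable from zero
  se_r <- summary(fit)$coefficients["r", "Std. Error"]
  degenerate <- !is.finite(se_r) || r < 1e-8 || r <= 2 * se_r
  structure(list(r = r, K = K, N0 = N0,
                 r_se = se_r,
                 K_se = summary(fit)$coefficients["K", "Std. Error"],
                 sigma = sigma, converged = !degenerate, bands = bands,
                 fit = fit), class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  if (!isTRUE(x$converged) && is.null(x$fit)) {
    cat("<growth_fit> fit failed (degenerate data)\n")
    return(invisible(x))
  }
  cat(sprintf("<growth_fit> r = %.3g /day, K = %.3g cells/mL, N0 = %.3g%s\n",
              x$r, x$K, x$N0,
              if (x$converged) "" else " (flagged: no growth signal)"))
  invisible(x)
}
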