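#' Angular scan container
#'
#' Goniometer-style angular scan: normalized transmitted (or reflected)
#' intensity versus detection angle. Intensities are rescaled to a maximum
#' of 1; `mu` is the cosine of the (absolute) detection angle with respect
#' to the incident ballistic beam.
#'
#' @param theta_deg Signed detection angles, degrees.
#' @param intensity Non-negative intensities (any positive scale).
#' @return A data frame of class `angular_scan` with columns `theta_deg`,
#'   `mu`, `intensity`.
#' @export
angular_scan <- function(theta_deg, intensity) {
  stopifnot(length(theta_deg) == length(intensity))
  if (any(intensity < 0)) stop("intensities must be >= 0")
  m <- max(intensity)
  if (m <= 0) stop("scan has no signal")
  structure(data.frame(theta_deg = theta_deg,
                       mu = cos(abs(theta_deg) * pi / 180),
                       intensity = intensity / m),
            class = c("angular_scan", "data.frame"))
}

#' Transmission-versus-thickness series
#'
#' Integrating-sphere total transmittance measured on samples of several
#' thicknesses at one wavelength.
#'
#' @param L Sample thicknesses, mm (> 0); sorted ascending on creation.
#' @param T Total transmittance in (0, 1].
#' @param wavelength Wavelength, nm.
#' @param sigma Optional per-point uncertainties (same length as `T`).
#' @return A data frame of class `transmission_series`.
#' @export
transmission_series <- function(L, T, wavelength = NA_real_, sigma = NULL) {
  stopifnot(length(L) == length(T))
  if (any(L <= 0)) stop("thicknesses must be > 0")
  if (any(T <= 0) || any(T > 1)) stop("transmittance must lie in (0, 1]")
  o <- order(L)
  df <- data.frame(L = L[o], T = T[o])
  if (!is.null(sigma)) df$sigma <- sigma[o]
  attr(df, "wavelength") <- wavelength
  class(df) <- c("transmission_series", "data.frame")
  df
}

#' Diffusion-theory angular transmittance shape
#'
#' The angular distribution of light transmitted through a diffusive slab,
#' `P(mu) = mu * (z_e + mu) / (z_e/2 + 1/3)`, where `mu` is the cosine of
#' the transmission angle and `z_e` the extrapolation length in units of
#' the transport mean free path. The normalization makes `P` a density in
#' `mu` on (0, 1].
#'
#' @param mu Cosine(s) of the transmission angle, in (0, 1].
#' @param z_e Extrapolation length (> 0), dimensionless.
#' @return `P(mu)`.
#' @examples
#' p_mu(1, 2 / 3) # 2.5
#' @export
p_mu <- function(mu, z_e) {
  if (any(mu <= 0) || any(mu > 1)) stop("mu must lie in (0, 1]")
  if (z_e <= 0) stop("z_e must be > 0")
  mu * (z_e + mu) / (z_e / 2 + 1 / 3)
}

#' Estimate the extrapolation length from an angular scan
#'
#' Least-squares fit of `a * P(mu; z_e)` (free positive scale `a`) to the
#' forward-hemisphere intensities of an angular scan. The scale freedom
#' makes the estimate invariant under any positive rescaling of the
#' intensities. The fit is unweighted. For scans carrying per-bin photon
#' `counts` (Monte Carlo histograms from [angular_transmittance()]) the
#' residuals are formed on the per-bin *flux* scale (intensity times the
#' bin's solid-angle measure) rather than the per-solid-angle intensity:
#' near-normal 1-degree bins subtend tiny solid angles and hold a handful
#' of photons, so their intensities are pure counting noise and would
#' otherwise destabilize the fit, while their fluxes are small and
#' harmless. Measured or analytic scans (no counts) are fitted on the
#' intensity scale directly.
#'
#' @param scan An [angular_scan()]; needs >= 10 points with `mu > 0`
#'   spanning at least 60 degrees of the forward hemisphere.
#' @param weights Optional fit weights (default unweighted).
#' @return A list of class `ze_fit`: `z_e`, `se` (standard error), `scale`,
#'   `fit` (the `nls` object).
#' @export
fit_extrapolation_length <- function(scan, weights = NULL) {
  stopifnot(inherits(scan, "angular_scan"))
  d <- scan[scan$mu > 0 & is.finite(scan$intensity), , drop = FALSE]
  if (nrow(d) < 10) stop("need >= 10 angular points with mu > 0")
  span <- diff(range(abs(d$theta_deg)))
  if (span < 60) stop("scan must span >= 60 degrees of the forward hemisphere")
  if (is.null(weights)) weights <- rep(1, nrow(d))
  if (!is.null(d$counts)) {
    # MC histogram: fit per-bin flux = intensity * solid-angle measure
    lo <- floor(abs(d$theta_deg))
    d$dmu <- cos(lo * pi / 180) - cos((lo + 1) * pi / 180)
    d$y <- d$intensity * d$dmu
  } else {
    d$dmu <- 1
    d$y <- d$intensity
  }
  start <- list(a = max(d$y / d$dmu) / 2.5, z_e = 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * mu * (z_e + mu) / (z_e / 2 + 1 / 3) * dmu,
                      data = d, start = start, weights = weights,
                      lower = c(a = 1e-12, z_e = 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("extrapolation-length fit failed to converge: ",
                             conditionMessage(e)))
  cf <- summary(fit)$coefficients
  structure(list(z_e = unname(cf["z_e", "Estimate"]),
                 se = unname(cf["z_e", "Std. Error"]),
                 scale = unname(cf["a", "Estimate"]),
                 fit = fit), class = "ze_fit")
}

#' Total transmission of a diffusive slab
#'
#' Diffusion-approximation transmittance of a slab of thickness `L` with
#' absorption length `l_a`, transport mean free path `l_t` and
#' extrapolation length `z_e` (in units of `l_t`). The default mode is the
#' diffusive-slab solution with extrapolated boundary conditions
#' (extrapolation distance `z_e * l_t`, isotropized source at depth `l_t`,
#' diffusive absorption length `L_alpha = sqrt(l_a * l_t / 3)`):
#'
#' `T = sinh(l_t (1 + z_e) / L_alpha) / sinh((L + 2 z_e l_t) / L_alpha)`
#'
#' which reduces to `(l_t + z_e l_t) / (L + 2 z_e l_t)` as `l_a -> Inf`.
#' `mode = "as_printed"` evaluates instead the literal textbook-style
#' variant `T = (1/l_a) sinh(z_e l_t / l_a)^2 / sinh((L + z_e l_t)/l_a)`,
#' retained for transparency; it is dimensionally inconsistent and not
#' used by the fitters (see the methods vignette).
#'
#' @param L Slab thickness, mm.
#' @param l_a Absorption length, mm.
#' @param l_t Transport mean free path, mm.
#' @param z_e Extrapolation length, dimensionless.
#' @param mode `"physical"` (default) or `"as_printed"`.
#' @return Transmittance.
#' @examples
#' diffusion_transmission(10, 1e12, 1, 2 / 3) # (5/3)/(10 + 4/3)
#' @export
diffusion_transmission <- function(L, l_a, l_t, z_e,
                                   mode = c("physical", "as_printed")) {
  mode <- match.arg(mode)
  if (any(L <= 0) || l_a <= 0 || l_t <= 0 || z_e <= 0)
    stop("L, l_a, l_t and z_e must all be > 0")
  if (any(L < 5 * l_t))
    warning("diffusion approximation is questionable for L < 5 * l_t")
  if (mode == "as_printed") {
    return(1 / l_a * sinh(z_e * l_t / l_a)^2 / sinh((L + z_e * l_t) / l_a))
  }
  La <- sqrt(l_a * l_t / 3)
  num <- l_t * (1 + z_e) / La
  den <- (L + 2 * z_e * l_t) / La
  # guard against overflow for strongly absorbing, thick slabs
  ifelse(den > 700, exp(num - den) * (1 - exp(-2 * num)) / (1 - exp(-2 * den)),
         sinh(num) / sinh(den))
}

#' Fit absorption length and transport mean free path
#'
#' Implements the two-step iterative estimation of optical properties from
#' an integrating-sphere transmission series plus a goniometer angular
#' scan: (1) estimate the extrapolation length `z_e` from the angular scan;
#' (2) nonlinear least squares of [diffusion_transmission()] over
#' `(l_a, l_t)` at fixed `z_e` (fitted on log-transmittance so thin and
#' thick samples weigh comparably); (3) iterate refits from the updated
#' estimates until successive `(l_a, l_t)` change by less than `tol`
#' (relative) or `max_iter` is reached.
#'
#' @param series A [transmission_series()] with >= 4 thicknesses.
#' @param scan An [angular_scan()] (or a fitted `ze_fit`).
#' @param tol Relative convergence tolerance on `(l_a, l_t)` (default 1%).
#' @param max_iter Iteration cap (default 50).
#' @param start Optional named list with starting `l_a`, `l_t`.
#' @return A list of class `diffusion_fit`: `l_a`, `l_t`, `z_e`, standard
#'   errors, `n_iterations`, `converged`, and the final `nls` fit. A
#'   non-converged fit is returned flagged, not raised as an error.
#' @export
fit_diffusion <- function(series, scan, tol = 0.01, max_iter = 50,
                          start = NULL) {
  stopifnot(inherits(series, "transmission_series"))
  if (nrow(series) < 4) stop("need >= 4 thicknesses for the diffusion fit")
  zf <- if (inherits(scan, "ze_fit")) scan else fit_extrapolation_length(scan)
  z_e <- zf$z_e

  L <- series$L; Tt <- series$T
  w <- if (!is.null(series$sigma)) 1 / (series$sigma / Tt)^2 else rep(1, length(L))

  if (is.null(start)) {
    # crude initialization: thin-limit for l_t, tail slope for L_alpha
    lt0 <- max(min(L) / 5, L[1] * Tt[1] / (1 + z_e - 2 * z_e * Tt[1]))
    lt0 <- min(max(lt0, 1e-3), min(L))
    sl <- stats::coef(stats::lm(log(Tt) ~ L))[2]
    la0 <- if (is.finite(sl) && sl < 0) 3 / (lt0 * sl^2) else 100 * lt0
    start <- list(l_a = max(la0, lt0), l_t = lt0)
  }

  est <- c(start$l_a, start$l_t)
  converged <- FALSE
  fit <- NULL
  iter <- 0
  # warning-free model for the optimizer, which may probe l_t ~ L
  dt_quiet <- function(L, l_a, l_t)
    suppressWarnings(diffusion_transmission(L, l_a, l_t, z_e))
  d <- data.frame(L = L, logT = log(Tt))
  for (iter in seq_len(max_iter)) {
    prev <- est
    fit <- tryCatch(
      minpack.lm::nlsLM(
        logT ~ log(dt_quiet(L, l_a, l_t)),
        data = d, start = list(l_a = est[1], l_t = est[2]), weights = w,
        lower = c(l_a = 1e-6, l_t = 1e-6),
        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (is.null(fit)) break
    est <- unname(stats::coef(fit)[c("l_a", "l_t")])
    if (all(abs(est - prev) / prev < tol)) { converged <- TRUE; break }
  }

  se <- c(NA_real_, NA_real_)
  if (!is.null(fit)) {
    cf <- summary(fit)$coefficients
    se <- unname(cf[c("l_a", "l_t"), "Std. Error"])
  }
  structure(list(l_a = est[1], l_t = est[2], z_e = z_e,
                 l_a_se = se[1], l_t_se = se[2], z_e_se = zf$se,
                 n_iterations = iter, converged = converged, fit = fit),
            class = "diffusion_fit")
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf(
    "<diffusion_fit> l_a = %.3g mm, l_t = %.3g mm, z_e = %.3g (%s, %d iter)\n",
    x$l_a, x$l_t, x$z_e, if (x$converged) "converged" else "NOT converged",
    x$n_iterations))
  invisible(x)
}

#' Beer-Lambert extinction fit
#'
#' For weakly scattering samples where the diffusion approximation does
#' not apply, the extinction coefficient is the slope of `-log(T)` against
#' thickness `L`.
#'
#' @param series A [transmission_series()] with >= 3 thicknesses.
#' @return A list of class `extinction_fit`: `mu_ext` (mm^-1), `mu_ext_se`,
#'   `intercept`, `r_squared`, and the `lm` fit.
#' @export
fit_beer_lambert <- function(series) {
  stopifnot(inherits(series, "transmission_series"))
  if (nrow(series) < 3) stop("need >= 3 thicknesses")
  if (any(series$T <= 0)) stop("transmittance must be > 0")
  fit <- stats::lm(I(-log(T)) ~ L, data = series)
  sm <- suppressWarnings(summary(fit)) # exact data trips the perfect-fit warning
  cf <- sm$coefficients
  structure(list(mu_ext = unname(cf["L", "Estimate"]),
                 mu_ext_se = unname(cf["L", "Std. Error"]),
                 intercept = unname(cf["(Intercept)", "Estimate"]),
                 r_squared = sm$r.squared, fit = fit),
            class = "extinction_fit")
}

#' Refractive index from the Brewster angle
#'
#' At the Brewster angle the p-polarized reflectance vanishes and
#' `theta_B = arctan(n2 / n1)`, so for a sample in ambient index `n1` the
#' sample index is `n2 = n1 * tan(theta_B)`.
#'
#' @param theta_B Brewster angle, degrees, in (0, 90).
#' @param n_ambient Ambient refractive index `n1` (default 1, air).
#' @return A list of class `refractive_index_estimate`: `theta_B`, `n`,
#'   `n_ambient`.
#' @examples
#' brewster_index(54.0)$n # 1.376
#' @export
brewster_index <- function(theta_B, n_ambient = 1) {
  if (theta_B <= 0 || theta_B >= 90)
    stop("theta_B must lie strictly between 0 and 90 degrees")
  structure(list(theta_B = theta_B,
                 n = n_ambient * tan(theta_B * pi / 180),
                 n_ambient = n_ambient),
            class = "refractive_index_estimate")
}

#' Locate the Brewster angle in a reflectance scan
#'
#' Finds the p-polarized reflectance minimum by parabolic interpolation
#' through the minimum sample and its neighbors (fitting a quadratic over
#' a small window around the discrete minimum).
#'
#' @param scan An [angular_scan()] of p-polarized reflectance versus
#'   incidence angle; the minimum must be bracketed (not at the scan edge).
#' @param window Half-width (number of points each side) of the parabolic
#'   fit window; the default 1 (three-point parabola) has negligible bias
#'   because the reflectance is asymmetric around its quadratic minimum.
#' @return A list: `theta_B` (degrees) and `halfwidth` (degrees, where the
#'   fitted parabola doubles its minimum depth relative to the window rim).
#' @export
find_brewster <- function(scan, window = 1) {
  stopifnot(inherits(scan, "angular_scan"))
  th <- scan$theta_deg; y <- scan$intensity
  i <- which.min(y)
  if (i <= 1 || i >= length(y))
    stop("reflectance minimum lies at the scan edge; bracket is not contained")
  lo <- max(1, i - window); hi <- min(length(y), i + window)
  xs <- th[lo:hi]; ys <- y[lo:hi]
  q <- stats::lm(ys ~ xs + I(xs^2))
  a <- stats::coef(q)[["I(xs^2)"]]; b <- stats::coef(q)[["xs"]]
  if (!is.finite(a) || a <= 0) return(list(theta_B = th[i], halfwidth = NA_real_))
  vertex <- -b / (2 * a)
  if (vertex < th[lo] || vertex > th[hi]) vertex <- th[i]
  rim <- max(ys) - min(ys)
  halfwidth <- if (rim > 0) sqrt(rim / (2 * a)) else NA_real_
  list(theta_B = unname(vertex), halfwidth = unname(halfwidth))
}
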