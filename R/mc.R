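#' Monte Carlo photon transport simulation
#'
#' Simulates photon migration through a [layered_slab()] or [voxel_grid()]
#' geometry. Photons perform an exponential random walk (step length
#' `-log(U)/(mu_a + mu_s)`), scatter into deflection angles drawn from the
#' Henyey-Greenstein distribution with anisotropy `g` (isotropic for
#' `g = 0`, uniform azimuth), lose weight to absorption by the albedo
#' method with Russian-roulette termination below weight 1e-4, and undergo
#' unpolarized Fresnel reflection/refraction (Snell's law) at every
#' refractive-index mismatch. Time of flight accumulates `n * s / c` per
#' step with `c = 299.792458` mm/ns.
#'
#' Fluence is tallied by the track-length estimator into depth bins (and
#' per voxel for voxel grids), jointly binned in time so that the sum over
#' time bins equals the steady-state fluence exactly.
#'
#' @param geometry A [layered_slab()] or [voxel_grid()].
#' @param source A [pencil_source()] or [plane_source()].
#' @param n_photons Number of photons (>= 1000).
#' @param seed Optional integer; when given, `set.seed(seed)` is called so
#'   the run is reproducible.
#' @param nz Number of depth bins for the fluence profile (layered slabs).
#' @param time_edges Increasing time-bin edges in ns starting at 0. Photons
#'   older than the last edge fall into an overflow bin, so energy is never
#'   lost from the time partition.
#' @return An object of class `sim_result` with elements `T_total`,
#'   `R_total`, `A_total` (fractions of launched energy; `S_total` holds
#'   lateral escape for voxel grids), their Monte Carlo standard errors,
#'   `fluence` (depth x time matrix, per unit incident power, normalized so
#'   a collimated beam in transparent medium gives 1 at all depths),
#'   `fluence_steady`, `depth_mm`, the transmitted-angle histogram, and for
#'   voxel grids `fluence_voxel` (per-voxel fluence, 1/mm^2 per photon
#'   packet path density, normalized by voxel volume).
#' @examples
#' slab <- layered_slab(material(mu_a = 1, mu_s = 0), thickness = 1)
#' res <- mc_simulate(slab, n_photons = 2000, seed = 1)
#' res$T_total # ~ exp(-1)
#' @export
mc_simulate <- function(geometry, source = pencil_source(),
                        n_photons = 1e5, seed = NULL, nz = 200,
                        time_edges = seq(0, 5, by = 0.25)) {
  stopifnot(inherits(geometry, "mc_geometry"), inherits(source, "mc_source"))
  if (n_photons < 1e3) stop("n_photons must be >= 1000")
  if (is.unsorted(time_edges, strictly = TRUE) || time_edges[1] != 0)
    stop("time_edges must be strictly increasing and start at 0")
  if (!is.null(seed)) set.seed(seed)
  n_photons <- as.integer(n_photons)

  if (inherits(geometry, "layered_slab")) {
    mats <- geometry$materials
    raw <- cpp_mc_layered(
      mua = vapply(mats, `[[`, 0, "mu_a"),
      mus = vapply(mats, `[[`, 0, "mu_s"),
      g = vapply(mats, `[[`, 0, "g"),
      n = vapply(mats, `[[`, 0, "n"),
      thickness = geometry$thickness,
      n_top = geometry$n_above, n_bot = geometry$n_below,
      n_photons = n_photons, nz = as.integer(nz),
      time_edges = as.numeric(time_edges))
    dz <- raw$dz
    fl <- raw$fluence / (n_photons * dz)
    fluence_voxel <- NULL
  } else {
    dims <- dim(geometry$labels)
    sp <- geometry$spacing
    raw <- cpp_mc_voxel(
      labels = as.integer(geometry$labels),
      nx = dims[1], ny = dims[2], nz = dims[3],
      dx = sp[1], dy = sp[2], dzv = sp[3],
      mua = vapply(geometry$materials, `[[`, 0, "mu_a"),
      mus = vapply(geometry$materials, `[[`, 0, "mu_s"),
      g = vapply(geometry$materials, `[[`, 0, "g"),
      n = vapply(geometry$materials, `[[`, 0, "n"),
      n_amb = geometry$n_ambient,
      n_photons = n_photons, time_edges = as.numeric(time_edges),
      plane = source$type == "plane",
      x0 = source$position[1], y0 = source$position[2])
    dz <- raw$dz
    # depth-time track length, laterally averaged over the illuminated face
    fl <- raw$depth_time / (n_photons * dz)
    fluence_voxel <- raw$fluence / (n_photons * prod(sp))
  }

  N <- n_photons
  Tt <- raw$T_sum / N; Rt <- raw$R_sum / N
  At <- raw$A_sum / N; St <- raw$S_sum / N
  cl_mean <- Tt + Rt + At + St
  cl_var <- max(0, raw$closure_sumsq / N - cl_mean^2)
  T_var <- max(0, raw$T_sumsq / N - Tt^2)

  nt <- length(time_edges) # includes overflow column
  theta <- seq(-89.5, 89.5, by = 1)
  structure(list(
    T_total = Tt, R_total = Rt, A_total = At, S_total = St,
    T_se = sqrt(T_var / N), closure_se = sqrt(cl_var / N),
    fluence = fl, fluence_steady = rowSums(fl),
    fluence_voxel = fluence_voxel,
    depth_mm = (seq_len(nrow(fl)) - 0.5) * dz, dz = dz, L = raw$L,
    time_edges = as.numeric(time_edges),
    transmitted_angles = data.frame(theta_deg = theta,
                                    weight = as.numeric(raw$ang_w),
                                    count = as.integer(raw$ang_n)),
    n_transmitted = raw$n_transmitted,
    n_photons = N, seed = seed), class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf(
    "<sim_result> %g photons: T = %.4f, R = %.4f, A = %.4f%s (closure se %.2g)\n",
    x$n_photons, x$T_total, x$R_total, x$A_total,
    if (x$S_total > 0) sprintf(", side = %.4f", x$S_total) else "",
    x$closure_se))
  invisible(x)
}

#' Angular distribution of transmitted light
#'
#' Converts the transmitted-exit-angle histogram of a simulation into a
#' goniometer-style angular scan: intensity per unit solid angle (counts
#' per 1-degree bin divided by the solid angle of the bin's annulus),
#' normalized to a maximum of 1, at signed exit angles. This is directly
#' comparable to measured scans and fittable with
#' [fit_extrapolation_length()].
#'
#' @param result A `sim_result` from [mc_simulate()].
#' @return An [angular_scan()] data frame with columns `theta_deg`, `mu`,
#'   `intensity`.
#' @export
angular_transmittance <- function(result) {
  stopifnot(inherits(result, "sim_result"))
  if (result$n_transmitted == 0) stop("no transmitted photons")
  if (result$n_transmitted < 100)
    stop("need >= 100 transmitted photons for an angular histogram (have ",
         result$n_transmitted, ")")
  h <- result$transmitted_angles
  lo <- floor(abs(h$theta_deg)) # 0..89 for |theta| band
  dmu <- cos(lo * pi / 180) - cos((lo + 1) * pi / 180)
  intensity <- h$weight / dmu
  scan <- angular_scan(h$theta_deg, intensity)
  scan$counts <- h$count # per-bin photon counts, used as fit weights
  scan
}

#' Laterally averaged fluence-rate depth profile
#'
#' Expresses the simulated fluence rate (scalar irradiance, E0) as a
#' percentage of incident irradiance: 100% equals the unscattered
#' collimated level just below the surface of a transparent medium.
#'
#' @param result A `sim_result`.
#' @return A data frame of class `fluence_profile` with columns `depth_um`
#'   and `E0_percent`.
#' @export
fluence_depth_profile <- function(result) {
  stopifnot(inherits(result, "sim_result"))
  structure(data.frame(depth_um = result$depth_mm * 1000,
                       E0_percent = 100 * result$fluence_steady),
            class = c("fluence_profile", "data.frame"))
}

#' Time-gated fluence snapshot (TPSF)
#'
#' Returns the spatial fluence distribution restricted to the time bin that
#' contains `t`, i.e. one frame of the temporal point spread function.
#' For layered slabs this is a depth profile (laterally integrated); for
#' voxel grids the depth profile of the grid. Summing snapshots over all
#' time bins reproduces the steady-state fluence exactly.
#'
#' @param result A `sim_result`.
#' @param t Time in ns; must not exceed the last time-bin edge.
#' @return A list with `t_lo`, `t_hi` (bin edges, ns), `depth_mm` and
#'   `fluence` (per unit incident power per mm depth).
#' @export
tpsf_snapshot <- function(result, t) {
  stopifnot(inherits(result, "sim_result"))
  edges <- result$time_edges
  if (t < 0 || t > edges[length(edges)])
    stop("t = ", t, " ns is beyond the simulated time gate (max ",
         edges[length(edges)], " ns)")
  bin <- findInterval(t, edges, rightmost.closed = TRUE)
  list(t_lo = edges[bin], t_hi = edges[bin + 1],
       depth_mm = result$depth_mm, fluence = result$fluence[, bin])
}

#' Unpolarized Fresnel reflectance
#'
#' Average of s- and p-polarized Fresnel power reflectance for light
#' hitting an interface from medium `n1` into `n2` with incidence cosine
#' `cos_i`. Returns 1 under total internal reflection.
#'
#' @param n1,n2 Refractive indices of the incidence / transmission media.
#' @param cos_i Cosine of the incidence angle (0, 1].
#' @return Reflectance in [0, 1].
#' @examples
#' fresnel_unpolarized(1, 1.5, 1) # 0.04
#' @export
fresnel_unpolarized <- function(n1, n2, cos_i) {
  stopifnot(n1 >= 1, n2 >= 1, cos_i > 0, cos_i <= 1)
  cpp_fresnel_unpolarized(n1, n2, cos_i)
}

#' Sample Henyey-Greenstein deflection cosines
#'
#' Draws `n` deflection-angle cosines from the Henyey-Greenstein phase
#' function with anisotropy `g`; the expectation of the sample is `g`.
#' Exposed mainly for verification of the scattering kernel.
#'
#' @param g Anisotropy in (-1, 1).
#' @param n Number of draws.
#' @return Numeric vector of cosines in [-1, 1].
#' @export
hg_sample <- function(g, n) {
  stopifnot(g > -1, g < 1, n >= 1)
  cpp_hg_sample(g, as.integer(n))
}
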