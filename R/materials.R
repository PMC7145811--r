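#' Optical material
#'
#' Bundle of inherent optical properties used by the photon-transport
#' simulator: absorption coefficient `mu_a` (mm^-1), scattering coefficient
#' `mu_s` (mm^-1), scattering anisotropy `g` (mean cosine of the
#' single-scattering deflection, dimensionless, in (-1, 1)), and refractive
#' index `n` (dimensionless, >= 1).
#'
#' @param mu_a Absorption coefficient, mm^-1 (>= 0).
#' @param mu_s Scattering coefficient, mm^-1 (>= 0).
#' @param g Scattering anisotropy in (-1, 1); 0 means isotropic scattering.
#' @param n Refractive index (>= 1).
#' @return An object of class `material`.
#' @examples
#' material(mu_a = 1, mu_s = 10, g = 0.9, n = 1.4)
#' @export
material <- function(mu_a, mu_s, g = 0, n = 1) {
  vals <- c(mu_a = mu_a, mu_s = mu_s, g = g, n = n)
  if (any(!is.finite(vals))) {
    stop("material properties must be finite (no NaN/NA): ",
         paste(names(vals)[!is.finite(vals)], collapse = ", "))
  }
  if (mu_a < 0 || mu_s < 0) stop("mu_a and mu_s must be >= 0")
  if (g <= -1 || g >= 1) stop("g must lie in (-1, 1)")
  if (n < 1) stop("refractive index n must be >= 1")
  structure(list(mu_a = mu_a, mu_s = mu_s, g = g, n = n),
            class = "material")
}

#' @export
print.material <- function(x, ...) {
  cat(sprintf("<material> mu_a = %g mm^-1, mu_s = %g mm^-1, g = %g, n = %g\n",
              x$mu_a, x$mu_s, x$g, x$n))
  invisible(x)
}

#' Named material presets
#'
#' Presets for the printed biomaterials studied with this package:
#'
#' * `"skeleton"`: the diffusely backscattering skeletal material.
#'   Transport mean free path 3 mm with near-isotropic scattering, so
#'   `mu_s = 1/3` mm^-1 and `g = 0` (scattering and transport mean free
#'   paths coincide); weak residual absorption.
#' * `"tissue"`: algal-laden tissue at the dense simulation regime
#'   (`mu_a = 15` mm^-1) with a forward-scattering cone (`g = 0.9`).
#' * `"tissue_culture"`: the same tissue at early-culture algal density
#'   (about 5e6 cells/mL), where absorption is roughly thirty-fold lower.
#' * `"gelma"`: plain (cell-free) GelMA hydrogel, essentially
#'   non-scattering and weakly absorbing.
#'
#' All presets use n = 1.40, within the Brewster-angle-measured 1.37-1.40
#' window for the printed tissue.
#'
#' @param name One of `"skeleton"`, `"tissue"`, `"tissue_culture"`,
#'   `"gelma"`.
#' @return A [material()].
#' @export
material_preset <- function(name = c("skeleton", "tissue", "tissue_culture",
                                     "gelma")) {
  name <- match.arg(name)
  switch(name,
    skeleton       = material(mu_a = 0.02, mu_s = 1 / 3, g = 0, n = 1.40),
    tissue         = material(mu_a = 15,   mu_s = 10,    g = 0.9, n = 1.40),
    tissue_culture = material(mu_a = 0.5,  mu_s = 10,    g = 0.9, n = 1.40),
    gelma          = material(mu_a = 0.01, mu_s = 0,     g = 0, n = 1.40)
  )
}

#' Layered slab geometry
#'
#' Laterally infinite stack of homogeneous layers, illuminated from above.
#' The ambient media above and below are non-scattering and non-absorbing
#' with the given refractive indices.
#'
#' @param materials A list of [material()] objects, ordered from the
#'   illuminated side downwards.
#' @param thickness Numeric vector of layer thicknesses, mm (> 0).
#' @param n_above,n_below Ambient refractive indices above / below.
#' @return An object of class `layered_slab`.
#' @examples
#' layered_slab(list(material(0.01, 1)), thickness = 10)
#' @export
layered_slab <- function(materials, thickness, n_above = 1, n_below = 1) {
  if (inherits(materials, "material")) materials <- list(materials)
  if (!all(vapply(materials, inherits, TRUE, "material")))
    stop("`materials` must be a list of material() objects")
  if (length(thickness) != length(materials))
    stop("one thickness per layer required")
  if (any(!is.finite(thickness)) || any(thickness <= 0))
    stop("layer thicknesses must be finite and > 0")
  if (n_above < 1 || n_below < 1) stop("ambient indices must be >= 1")
  structure(list(materials = materials, thickness = as.numeric(thickness),
                 n_above = n_above, n_below = n_below),
            class = c("layered_slab", "mc_geometry"))
}

#' Voxel grid geometry
#'
#' Cuboidal voxel domain defined by an integer label array and a label ->
#' material map. The grid is surrounded by non-scattering ambient medium of
#' index `n_ambient`; illumination enters through the top face (z = 0).
#'
#' @param labels 3D integer array (dims nx, ny, nz; x fastest) of material
#'   labels 1..K. Every label occurring in the array must be mapped.
#' @param spacing Voxel spacing in mm, length 3 `(dx, dy, dz)` or scalar.
#' @param materials List of [material()]s; `materials[[k]]` is label k.
#' @param n_ambient Ambient refractive index.
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(labels, spacing, materials, n_ambient = 1) {
  if (length(dim(labels)) != 3) stop("`labels` must be a 3D array")
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  if (any(spacing <= 0)) stop("voxel spacing must be > 0")
  if (inherits(materials, "material")) materials <- list(materials)
  labs <- sort(unique(as.integer(labels)))
  if (any(labs < 1) || max(labs) > length(materials))
    stop("every voxel label must map to an entry of `materials`")
  if (!all(vapply(materials, inherits, TRUE, "material")))
    stop("`materials` must be a list of material() objects")
  structure(list(labels = labels, spacing = as.numeric(spacing),
                 materials = materials, n_ambient = n_ambient),
            class = c("voxel_grid", "mc_geometry"))
}

#' Photon sources
#'
#' `pencil_source()` is a collimated pencil beam entering the top surface
#' at normal incidence (at the given lateral position for voxel grids).
#' `plane_source()` is a collimated plane wave of uniform irradiance over
#' the whole top face (equivalent to the pencil beam for laterally
#' infinite layered slabs).
#'
#' @param position Lateral entry point `(x, y)` in mm (voxel grids only).
#' @return An object of class `mc_source`.
#' @export
pencil_source <- function(position = c(0, 0)) {
  structure(list(type = "pencil", position = position), class = "mc_source")
}

#' @rdname pencil_source
#' @export
plane_source <- function() {
  structure(list(type = "plane", position = c(0, 0)), class = "mc_source")
}
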