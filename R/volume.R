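#' Image volume container
#'
#' A 3D intensity volume with physical voxel spacing. The array is indexed
#' `[x, y, z]` (x fastest, matching column-major storage); index (1, 1, 1)
#' is the top corner of the stack with z increasing into the sample.
#' Intensities are integers on a 16-bit (tomography) or 12-bit-in-16
#' (confocal) scale.
#'
#' @param data 3D numeric/integer array.
#' @param spacing_um Voxel spacing in micrometers: scalar or length 3
#'   `(x, y, z)`.
#' @param bit_depth 16 (default) or 12.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, spacing_um, bit_depth = 16) {
  if (length(dim(data)) != 3) stop("`data` must be a 3D array")
  if (length(spacing_um) == 1) spacing_um <- rep(spacing_um, 3)
  if (length(spacing_um) != 3 || any(spacing_um <= 0))
    stop("spacing_um must be positive, length 1 or 3 (x, y, z)")
  if (!bit_depth %in% c(12, 16)) stop("bit_depth must be 12 or 16")
  maxv <- if (bit_depth == 12) 4095 else 65535
  if (max(data) > maxv || min(data) < 0)
    stop("intensities must lie in [0, ", maxv, "] for ", bit_depth, "-bit data")
  structure(list(data = data, spacing_um = as.numeric(spacing_um),
                 bit_depth = bit_depth),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_volume> %d x %d x %d voxels, %g x %g x %g um, %d-bit\n",
              d[1], d[2], d[3], x$spacing_um[1], x$spacing_um[2],
              x$spacing_um[3], x$bit_depth))
  invisible(x)
}

#' Read / write image volumes as multi-page TIFF
#'
#' Volumes are written one z-slice per page as 16-bit grayscale TIFF
#' (12-bit data is stored in the 16-bit container, as confocal software
#' does). Spacing is not stored in the TIFF and must be supplied on read.
#'
#' @param vol An [image_volume()].
#' @param path File path.
#' @param spacing_um Voxel spacing for the volume read back.
#' @param bit_depth Bit depth of the volume read back.
#' @return `read_volume_tiff` returns an [image_volume()];
#'   `write_volume_tiff` returns `path` invisibly.
#' @export
write_volume_tiff <- function(vol, path) {
  stopifnot(inherits(vol, "image_volume"))
  pages <- lapply(seq_len(dim(vol$data)[3]), function(z) {
    # page as y-rows by x-cols
    t(vol$data[, , z]) / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' @rdname write_volume_tiff
#' @export
read_volume_tiff <- function(path, spacing_um, bit_depth = 16) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  arr <- array(0L, dim = c(ncol(pages[[1]]), nrow(pages[[1]]), length(pages)))
  for (z in seq_along(pages)) arr[, , z] <- as.integer(round(t(pages[[z]]) * 65535))
  image_volume(arr, spacing_um = spacing_um, bit_depth = bit_depth)
}

#' Write a measurement table with a ground-truth sidecar
#'
#' Writes a data frame as a plain CSV with header row; any `ground_truth`
#' and `config` attributes (attached by the phantom generators) go into a
#' JSON sidecar `<path>.json`.
#'
#' @param df Data frame (possibly with `ground_truth`/`config` attributes).
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(df, path) {
  utils::write.csv(as.data.frame(df), path, row.names = FALSE)
  gt <- attr(df, "ground_truth"); cfg <- attr(df, "config")
  if (!is.null(gt) || !is.null(cfg)) {
    jsonlite::write_json(list(ground_truth = gt, config = unclass(cfg)),
                         paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read measurement tables from CSV
#'
#' Column conventions: transmission series `(L_mm, T[, sigma])`, angular
#' scans `(theta_deg, intensity)`, O2 profiles `(depth_um, conc_umolL)`.
#'
#' @param path CSV path.
#' @param wavelength Optional wavelength (nm) for transmission series.
#' @return The corresponding container object.
#' @export
read_transmission_csv <- function(path, wavelength = NA_real_) {
  d <- utils::read.csv(path)
  transmission_series(d$L_mm, d$T, wavelength = wavelength, sigma = d$sigma)
}

#' @rdname read_transmission_csv
#' @export
read_angular_csv <- function(path) {
  d <- utils::read.csv(path)
  angular_scan(d$theta_deg, d$intensity)
}

#' @rdname read_transmission_csv
#' @export
read_o2_profile_csv <- function(path) {
  d <- utils::read.csv(path)
  o2_profile(d$depth_um, d$conc_umolL)
}
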