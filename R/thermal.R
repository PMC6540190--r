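# Radiometry and canopy-temperature extraction.
#
# Thermal images carry apparent temperature (deg C). Under the greybody
# assumption (emissivity constant across the sensed waveband) the apparent
# radiance mixes the emitted and reflected components,
#   W_app = eps * W_obj + (1 - eps) * W_refl,
# with W = sigma * T^4 on absolute temperature; atmospheric transmission is
# treated as 1 (short range). Canopy emissivity defaults to 0.98.

#' Construct a thermal image
#'
#' @param temps_c numeric matrix of apparent temperature in deg C.
#' @param emissivity_setting emissivity the camera (or generator) assumed.
#' @param reflected_temp_c reflected apparent temperature (deg C), e.g. from
#'   the aluminium-foil method.
#' @param height_m acquisition height above the canopy (m), if known.
#' @param timestamp acquisition time, if known.
#' @param plausible_range warn when temperatures fall outside this range
#'   (deg C); default -20..80.
#' @return an object of class `"thermal_image"`.
#' @export
thermal_image <- function(temps_c, emissivity_setting = 0.98, reflected_temp_c = 20,
                          height_m = NA_real_, timestamp = NA_character_,
                          plausible_range = c(-20, 80)) {
  if (!is.matrix(temps_c) || !is.numeric(temps_c)) stopf("temps_c must be a numeric matrix")
  if (!all(is.finite(temps_c))) stopf("thermal image contains non-finite temperatures")
  if (any(temps_c < plausible_range[1] | temps_c > plausible_range[2])) {
    warnf("thermal image has pixels outside the plausible range [%g, %g] degC",
          plausible_range[1], plausible_range[2])
  }
  structure(list(
    temps_c = temps_c,
    meta = list(emissivity_setting = emissivity_setting,
                reflected_temp_c = reflected_temp_c,
                height_m = height_m, timestamp = timestamp)
  ), class = "thermal_image")
}

#' @export
print.thermal_image <- function(x, ...) {
  r <- range(x$temps_c)
  cat(sprintf("thermal image %d x %d px, %.2f..%.2f degC (eps=%.3g, Trefl=%.3g degC)\n",
              nrow(x$temps_c), ncol(x$temps_c), r[1], r[2],
              x$meta$emissivity_setting, x$meta$reflected_temp_c))
  invisible(x)
}

as_temp_matrix <- function(img) {
  if (inherits(img, "thermal_image")) img$temps_c else img
}

#' Greybody correction: apparent to object temperature
#'
#' Solves the two-term greybody decomposition for the object temperature:
#' `T_obj = ((T_app^4 - (1 - eps) T_refl^4) / eps)^(1/4)` on Kelvin.
#' At `emissivity = 1` the correction is the identity; imagery already
#' corrected in-camera should be passed through with `emissivity = 1`.
#'
#' @param apparent a [thermal_image()] or numeric matrix of apparent deg C.
#' @param emissivity object emissivity in (0, 1].
#' @param reflected_temp_c reflected apparent temperature (deg C).
#' @return object of the same type as `apparent`, in object temperature deg C.
#' @seealso [apparent_from_object()] for the forward model.
#' @export
greybody_correct <- function(apparent, emissivity, reflected_temp_c) {
  if (!is_number(emissivity) || emissivity <= 0 || emissivity > 1) {
    stopf("emissivity must be in (0, 1], got %s", format(emissivity))
  }
  t_app <- as_temp_matrix(apparent)
  K <- t_app + 273.15
  Kr <- reflected_temp_c + 273.15
  rad <- (K^4 - (1 - emissivity) * Kr^4) / emissivity
  if (any(rad <= 0)) stopf("greybody correction yields non-positive absolute temperature; check emissivity/reflected temperature")
  obj <- rad^0.25 - 273.15
  if (inherits(apparent, "thermal_image")) {
    out <- apparent
    out$temps_c <- obj
    out$meta$emissivity_setting <- emissivity
    out$meta$reflected_temp_c <- reflected_temp_c
    out
  } else obj
}

#' Forward greybody model: object to apparent temperature
#'
#' Inverse of [greybody_correct()]; used by the scene generator to render
#' apparent-temperature imagery from known object temperatures.
#'
#' @inheritParams greybody_correct
#' @param object_c numeric object temperature(s) in deg C.
#' @return apparent temperature(s), deg C, same shape as `object_c`.
#' @export
apparent_from_object <- function(object_c, emissivity, reflected_temp_c) {
  if (!is_number(emissivity) || emissivity <= 0 || emissivity > 1) {
    stopf("emissivity must be in (0, 1], got %s", format(emissivity))
  }
  K <- object_c + 273.15
  Kr <- reflected_temp_c + 273.15
  (emissivity * K^4 + (1 - emissivity) * Kr^4)^0.25 - 273.15
}

#' Extract canopy pixel temperatures under a mask
#'
#' @param img [thermal_image()] or numeric temperature matrix.
#' @param mask logical matrix of the same shape (canopy mask in thermal
#'   coordinates).
#' @return numeric vector of temperatures at `TRUE` positions, in row-major
#'   (raster) order.
#' @export
extract_canopy_pixels <- function(img, mask) {
  m <- as_temp_matrix(img)
  if (!is.matrix(mask) || !is.logical(mask)) stopf("mask must be a logical matrix")
  if (!all(dim(mask) == dim(m))) {
    stopf("mask shape (%d x %d) does not match image shape (%d x %d)",
          nrow(mask), ncol(mask), nrow(m), ncol(m))
  }
  if (!any(mask)) stopf("no canopy pixels: mask is empty")
  t(m)[t(mask)]
}

#' Frequency histogram of canopy pixel temperatures
#'
#' Uniform bins of width `bin_width_c` covering `[floor(min), ceiling(max)]`;
#' bins are left-closed/right-open with the last bin closed, so counts always
#' conserve the number of pixels.
#'
#' @param pixels numeric vector of pixel temperatures (deg C).
#' @param bin_width_c bin width in deg C (default 0.5).
#' @return object of class `"thermal_histogram"` with `bin_edges_c`, `counts`,
#'   `bin_width_c`, `n_pixels`.
#' @export
thermal_histogram <- function(pixels, bin_width_c = 0.5) {
  if (length(pixels) == 0) stopf("empty pixel vector")
  if (!is_number(bin_width_c) || bin_width_c <= 0) stopf("bin_width_c must be > 0")
  lo <- floor(min(pixels))
  hi <- ceiling(max(pixels))
  k <- max(1, ceiling((hi - lo) / bin_width_c))
  edges <- lo + bin_width_c * (0:k)
  idx <- findInterval(pixels, edges, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = k)
  structure(list(bin_edges_c = edges, counts = counts,
                 bin_width_c = bin_width_c, n_pixels = length(pixels)),
            class = "thermal_histogram")
}

#' Canopy temperature summary
#'
#' The arithmetic mean of the masked pixels is the canopy temperature (CT)
#' statistic used downstream; the median and 5th/95th percentiles (linear
#' interpolation) are always reported so outlying pixels can be audited.
#'
#' @param pixels numeric vector of canopy pixel temperatures (deg C).
#' @return list with `mean`, `median`, `p5`, `p95` (deg C) and `n`.
#' @export
canopy_temperature <- function(pixels) {
  if (length(pixels) == 0) stopf("empty pixel vector")
  q <- stats::quantile(pixels, c(0.05, 0.95), names = FALSE, type = 7)
  list(mean = mean(pixels), median = stats::median(pixels),
       p5 = q[1], p95 = q[2], n = length(pixels))
}

#' Drought-induced canopy temperature increase (delta-CT)
#'
#' `delta_ct = mean(CT_drought) - mean(CT_control)`, with a replicate-level
#' table (each drought CT minus the control mean) for variance estimation.
#'
#' @param ct_drought,ct_control numeric vectors of per-replicate canopy
#'   temperatures (deg C) under drought and control.
#' @return list with `delta_ct_c`, `se` (standard error of the difference of
#'   means) and `table` (replicate-level drought CT minus control mean).
#' @export
delta_ct <- function(ct_drought, ct_control) {
  if (length(ct_drought) == 0 || length(ct_control) == 0) {
    stopf("both drought and control CT vectors must be nonempty")
  }
  mc <- mean(ct_control)
  d <- mean(ct_drought) - mc
  se <- sqrt(stats::var(ct_drought) / length(ct_drought) +
               stats::var(ct_control) / length(ct_control))
  list(delta_ct_c = d,
       se = if (is.finite(se)) se else NA_real_,
       table = data.frame(replicate = seq_along(ct_drought),
                          ct_drought_c = ct_drought,
                          delta_c = ct_drought - mc))
}

#' Ground sampling distance
#'
#' Ground extent covered by one pixel for a lens of the given field of view at
#' the given height: `GSD = 2 * height * tan(fov/2) / n_pixels_across`.
#'
#' @param fov_deg lens field of view across the sensor dimension, degrees.
#' @param n_pixels_across pixel count across that dimension.
#' @param height_m acquisition height above the canopy, metres.
#' @return metres per pixel.
#' @export
ground_sampling_distance <- function(fov_deg, n_pixels_across, height_m) {
  if (!is_number(fov_deg) || fov_deg <= 0 || fov_deg >= 180) stopf("fov_deg must be in (0, 180)")
  if (!is_count(n_pixels_across)) stopf("n_pixels_across must be a positive integer")
  if (!is_number(height_m) || height_m <= 0) stopf("height_m must be > 0")
  2 * height_m * tan(fov_deg * pi / 360) / n_pixels_across
}
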