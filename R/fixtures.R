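# Fixture sets on disk: PNG for visible frames and masks, 32-bit float TIFF
# for thermal frames, CSV for correspondences and plant records, and a YAML
# manifest tying everything together.
#
# TIFF samples are stored normalized: value = (T_c - offset) / scale with
# offset = -50 degC and scale = 150 degC (covering -50..100 degC), both
# recorded in the manifest; the reader inverts the encoding. Round trips are
# exact to 32-bit float resolution (~1e-5 degC).

THERMAL_TIFF_OFFSET_C <- -50
THERMAL_TIFF_SCALE_C <- 150

write_thermal_tiff <- function(temps_c, path) {
  enc <- (temps_c - THERMAL_TIFF_OFFSET_C) / THERMAL_TIFF_SCALE_C
  if (any(enc < 0 | enc > 1)) {
    stopf("temperatures outside the encodable range [%g, %g] degC",
          THERMAL_TIFF_OFFSET_C, THERMAL_TIFF_OFFSET_C + THERMAL_TIFF_SCALE_C)
  }
  tiff::writeTIFF(enc, path, bits.per.sample = 32L)
  invisible(path)
}

read_thermal_tiff <- function(path, offset = THERMAL_TIFF_OFFSET_C,
                              scale = THERMAL_TIFF_SCALE_C) {
  enc <- tiff::readTIFF(path)
  if (length(dim(enc)) == 3) enc <- enc[, , 1]
  enc * scale + offset
}

write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

read_mask_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  m > 0.5
}

write_rgb_png <- function(rgb, path) {
  png::writePNG(rgb / 255, path)
  invisible(path)
}

read_rgb_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) != 3) stopf("%s is not an RGB PNG", path)
  round(a[, , 1:3] * 255)
}

#' Write a synthetic fixture set to disk
#'
#' One PNG (visible) + float TIFF (thermal, deg C) + truth-mask PNGs +
#' correspondence CSV per scene, the plant-record table as CSV, and a YAML
#' manifest listing every file together with the seeds, parameters and the
#' thermal encoding used.
#'
#' @param dir_path output directory (created if missing).
#' @param experiment a `"synthetic_experiment"` from [generate_experiment()]
#'   (with scenes), or a list with `scenes` and `records`.
#' @param correspondence_noise_sd annotation noise on the stored corresponding
#'   points (px).
#' @param n_points corresponding points per scene.
#' @return the manifest (also written to `manifest.yaml`), invisibly.
#' @export
write_fixture_set <- function(dir_path, experiment, correspondence_noise_sd = 0,
                              n_points = 9) {
  scenes <- experiment$scenes
  records <- experiment$records
  if (length(scenes) == 0) stopf("experiment has no scenes to write")
  if (!dir.exists(dir_path) && !dir.create(dir_path, recursive = TRUE)) {
    stopf("cannot create directory %s", dir_path)
  }
  entries <- vector("list", length(scenes))
  for (i in seq_along(scenes)) {
    sc <- scenes[[i]]
    id <- sprintf("scene_%03d", i)
    files <- list(rgb = paste0(id, "_rgb.png"),
                  thermal = paste0(id, "_thermal.tif"),
                  mask = paste0(id, "_truemask.png"),
                  mask_thermal = paste0(id, "_truemask_thermal.png"),
                  points = paste0(id, "_points.csv"))
    write_rgb_png(sc$rgb, file.path(dir_path, files$rgb))
    write_thermal_tiff(sc$thermal$temps_c, file.path(dir_path, files$thermal))
    write_mask_png(sc$truth$true_mask, file.path(dir_path, files$mask))
    write_mask_png(sc$truth$true_mask_thermal, file.path(dir_path, files$mask_thermal))
    pts <- annotate_correspondences(sc, n_points = n_points,
                                    noise_sd = correspondence_noise_sd,
                                    seed = sc$params$rng_seed)
    write_correspondences(pts, file.path(dir_path, files$points))
    entries[[i]] <- c(list(id = id, seed = sc$params$rng_seed,
                           true_homography = as.vector(t(unclass(sc$truth$true_homography))),
                           true_canopy_temp_c = sc$truth$true_canopy_temp_c,
                           unit = sc$unit), files)
  }
  utils::write.csv(records, file.path(dir_path, "records.csv"), row.names = FALSE)
  manifest <- list(
    n_scenes = length(scenes),
    thermal_encoding = list(offset_c = THERMAL_TIFF_OFFSET_C,
                            scale_c = THERMAL_TIFF_SCALE_C),
    records = "records.csv",
    scenes = entries)
  yaml::write_yaml(manifest, file.path(dir_path, "manifest.yaml"))
  invisible(manifest)
}

#' Read a fixture set written by [write_fixture_set()]
#'
#' @param dir_path fixture directory containing `manifest.yaml`.
#' @return list with `scenes` (each with `rgb`, `thermal`, `points`,
#'   `true_mask`, `true_mask_thermal`, `unit`, `id`), `records` and `manifest`.
#' @export
read_fixture_set <- function(dir_path) {
  mf <- file.path(dir_path, "manifest.yaml")
  if (!file.exists(mf)) stopf("no manifest.yaml in %s", dir_path)
  manifest <- yaml::read_yaml(mf)
  enc <- manifest$thermal_encoding
  scenes <- lapply(manifest$scenes, function(e) {
    list(id = e$id,
         rgb = read_rgb_png(file.path(dir_path, e$rgb)),
         thermal = thermal_image(read_thermal_tiff(file.path(dir_path, e$thermal),
                                                   enc$offset_c, enc$scale_c)),
         points = read_correspondences(file.path(dir_path, e$points)),
         true_mask = read_mask_png(file.path(dir_path, e$mask)),
         true_mask_thermal = read_mask_png(file.path(dir_path, e$mask_thermal)),
         true_homography = homography(matrix(unlist(e$true_homography), 3, 3, byrow = TRUE)),
         true_canopy_temp_c = unlist(e$true_canopy_temp_c),
         unit = e$unit)
  })
  records <- utils::read.csv(file.path(dir_path, manifest$records))
  list(scenes = scenes, records = records, manifest = manifest)
}
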