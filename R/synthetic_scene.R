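# Synthetic paired visible/thermal canopy scenes with full ground truth.
#
# Scenes emulate potted canopies imaged by a dual-sensor camera: green
# disk-shaped canopies over a warm soil background in the visible frame, the
# same layout at canopy/background temperature in a smaller thermal frame
# related to the visible one by a projective transform (the two sensors share
# neither resolution nor alignment). Canopy geometry is analytic (disk
# centers/radii), so the truth masks in both coordinate frames are exact, not
# resampled. Gaussian i.i.d. noise is added per pixel; one top-level seed feeds
# explicit per-scene substreams.

#' Parameters of a synthetic scene
#'
#' @param image_width_px,image_height_px visible-frame size (default 640 x 480).
#' @param thermal_width_px,thermal_height_px thermal-frame size (default
#'   320 x 240; must not exceed the visible size, emulating the dual-sensor
#'   resolution mismatch).
#' @param n_plants number of potted canopies, laid out on a grid.
#' @param canopy_radius_px canopy disk radius in visible pixels.
#' @param canopy_color_mean,background_color_mean sRGB triples in 0..255; they
#'   must differ along the green-red (a*) axis so chromaticity separates them.
#' @param color_noise_sd per-channel Gaussian noise SD (sRGB units).
#' @param canopy_temp_c canopy object temperature(s), deg C — a scalar or one
#'   value per plant.
#' @param background_temp_c soil background temperature, deg C.
#' @param temp_noise_sd per-pixel Gaussian temperature noise SD, deg C.
#' @param emissivity scene emissivity: 1 (default) renders object temperature
#'   directly; values < 1 render apparent temperature through the forward
#'   greybody model with `reflected_temp_c`.
#' @param reflected_temp_c reflected temperature used when `emissivity < 1`.
#' @param height_m nominal acquisition height recorded in the metadata.
#' @param true_homography 3 x 3 projective map from visible (col, row) to
#'   thermal (col, row); default: a scale + shear + translation + mild
#'   perspective map fitted to the two frame sizes (see
#'   [default_scene_homography()]).
#' @param rng_seed integer seed for this scene's noise.
#' @return validated list of class `"scene_params"`.
#' @export
scene_params <- function(image_width_px = 640, image_height_px = 480,
                         thermal_width_px = 320, thermal_height_px = 240,
                         n_plants = 4, canopy_radius_px = 60,
                         canopy_color_mean = c(58, 118, 48),
                         background_color_mean = c(150, 112, 80),
                         color_noise_sd = 8,
                         canopy_temp_c = 28, background_temp_c = 40,
                         temp_noise_sd = 0.5,
                         emissivity = 1, reflected_temp_c = 20,
                         height_m = 20,
                         true_homography = NULL,
                         rng_seed = 1L) {
  p <- list(image_width_px = image_width_px, image_height_px = image_height_px,
            thermal_width_px = thermal_width_px, thermal_height_px = thermal_height_px,
            n_plants = n_plants, canopy_radius_px = canopy_radius_px,
            canopy_color_mean = canopy_color_mean,
            background_color_mean = background_color_mean,
            color_noise_sd = color_noise_sd,
            canopy_temp_c = canopy_temp_c, background_temp_c = background_temp_c,
            temp_noise_sd = temp_noise_sd,
            emissivity = emissivity, reflected_temp_c = reflected_temp_c,
            height_m = height_m,
            true_homography = true_homography, rng_seed = as.integer(rng_seed))
  if (!is_count(p$image_width_px) || !is_count(p$image_height_px) ||
      !is_count(p$thermal_width_px) || !is_count(p$thermal_height_px)) {
    stopf("image dimensions must be positive integers")
  }
  if (p$thermal_width_px > p$image_width_px || p$thermal_height_px > p$image_height_px) {
    stopf("thermal dimensions must not exceed visible dimensions")
  }
  if (!is_count(p$n_plants)) stopf("n_plants must be a positive integer")
  if (!is_number(p$canopy_radius_px) || p$canopy_radius_px <= 1) stopf("canopy_radius_px must exceed 1")
  if (p$color_noise_sd < 0 || p$temp_noise_sd < 0) stopf("noise SDs must be >= 0")
  for (nm in c("canopy_color_mean", "background_color_mean")) {
    v <- p[[nm]]
    if (length(v) != 3 || any(v < 0) || any(v > 255)) stopf("%s must be an RGB triple in 0..255", nm)
  }
  ab <- rgb_to_lab(array(rbind(p$canopy_color_mean, p$background_color_mean) / 1,
                         dim = c(2, 1, 3)))
  p$canopy_ab <- c(ab[1, 1, 2], ab[1, 1, 3])
  p$background_ab <- c(ab[2, 1, 2], ab[2, 1, 3])
  if (abs(p$canopy_ab[1] - p$background_ab[1]) < 1) {
    stopf("canopy and background colors must differ along the green-red (a*) axis")
  }
  if (length(p$canopy_temp_c) == 1) p$canopy_temp_c <- rep(p$canopy_temp_c, p$n_plants)
  if (length(p$canopy_temp_c) != p$n_plants) {
    stopf("canopy_temp_c must be a scalar or one value per plant")
  }
  if (is.null(p$true_homography)) {
    p$true_homography <- default_scene_homography(p$image_width_px, p$image_height_px,
                                                  p$thermal_width_px, p$thermal_height_px)
  }
  H <- unclass(p$true_homography)
  if (!all(dim(H) == c(3, 3))) stopf("true_homography must be 3 x 3")
  if (abs(det(H[1:2, 1:2])) < 1e-8) {
    stopf("degenerate homography: the upper-left 2 x 2 block is singular, the map collapses the image plane")
  }
  p$true_homography <- homography(H)
  structure(p, class = "scene_params")
}

#' Default dual-sensor homography for a scene
#'
#' A plausible visible-to-thermal map: the downscale implied by the two frame
#' sizes plus a small shear, translation and perspective component, so the
#' alignment path is always genuinely exercised (the identity would hide
#' registration bugs).
#'
#' @param vw,vh visible width/height (px); `tw,th` thermal width/height (px).
#' @return a [homography()].
#' @export
default_scene_homography <- function(vw, vh, tw, th) {
  sx <- tw / vw * 0.96
  sy <- th / vh * 0.96
  homography(matrix(c(sx, 0.015 * sx, 3,
                      -0.012 * sy, sy, 2,
                      2e-6, -1e-6, 1), 3, 3, byrow = TRUE))
}

# grid layout of plant centers (0-based (col, row)), disjoint by construction
plant_centers <- function(p) {
  n <- p$n_plants
  ncols <- ceiling(sqrt(n))
  nrows <- ceiling(n / ncols)
  cx <- (seq_len(ncols) - 0.5) / ncols * p$image_width_px
  cy <- (seq_len(nrows) - 0.5) / nrows * p$image_height_px
  centers <- cbind(col = rep(cx, times = nrows)[seq_len(n)],
                   row = rep(cy, each = ncols)[seq_len(n)])
  gap <- min(diff(sort(unique(cx))), diff(sort(unique(cy))),
             2 * min(cx, cy, p$image_width_px - cx, p$image_height_px - cy))
  if (is.finite(gap) && gap < 2 * p$canopy_radius_px) {
    stopf("canopy_radius_px %.1f too large for %d plants in a %d x %d frame (disks would overlap)",
          p$canopy_radius_px, n, p$image_width_px, p$image_height_px)
  }
  centers
}

# 0-based per-pixel plant label (0 = background) for an h x w grid whose pixel
# (row, col) maps to visible coordinates via `map` (NULL = identity)
plant_label_grid <- function(h, w, centers, radius, Hinv = NULL) {
  cc <- rep(0:(w - 1), each = h)
  rr <- rep(0:(h - 1), times = w)
  if (!is.null(Hinv)) {
    q <- Hinv %*% rbind(cc, rr, 1)
    cc <- q[1, ] / q[3, ]
    rr <- q[2, ] / q[3, ]
  }
  lab <- integer(h * w)
  for (k in seq_len(nrow(centers))) {
    inside <- (cc - centers[k, 1])^2 + (rr - centers[k, 2])^2 <= radius^2
    lab[inside] <- k
  }
  matrix(lab, h, w)
}

#' Generate one paired visible/thermal scene with ground truth
#'
#' @param params a [scene_params()] object.
#' @return list with `rgb` (H x W x 3, 0..255), `thermal` (a [thermal_image()])
#'   and `truth` (class `"scene_truth"`): `true_mask` / `true_mask_thermal`
#'   (logical), `plant_labels` / `plant_labels_thermal` (integer, 0 =
#'   background), `true_canopy_temp_c` (per plant), `true_background_temp_c`
#'   and `true_homography`. Identical params (including seed) give identical
#'   output.
#' @export
generate_scene <- function(params) {
  if (!inherits(params, "scene_params")) params <- do.call(scene_params, params)
  p <- params
  centers <- plant_centers(p)
  vh <- p$image_height_px; vw <- p$image_width_px
  th <- p$thermal_height_px; tw <- p$thermal_width_px

  lab_vis <- plant_label_grid(vh, vw, centers, p$canopy_radius_px)
  Hinv <- solve(unclass(p$true_homography))
  lab_th <- plant_label_grid(th, tw, centers, p$canopy_radius_px, Hinv = Hinv)
  mask_vis <- lab_vis > 0
  mask_th <- lab_th > 0

  # visible frame
  set.seed(child_seed(p$rng_seed, 1L))
  rgb <- array(0, dim = c(vh, vw, 3))
  for (ch in 1:3) {
    base <- ifelse(mask_vis, p$canopy_color_mean[ch], p$background_color_mean[ch])
    if (p$color_noise_sd > 0) base <- base + stats::rnorm(vh * vw, 0, p$color_noise_sd)
    rgb[, , ch] <- pmin(255, pmax(0, round(base)))
  }

  # thermal frame: object temperatures, then (optionally) the forward greybody
  # model, then sensor noise
  set.seed(child_seed(p$rng_seed, 2L))
  tt <- matrix(p$background_temp_c, th, tw)
  for (k in seq_len(p$n_plants)) tt[lab_th == k] <- p$canopy_temp_c[k]
  if (p$emissivity < 1) {
    tt <- apparent_from_object(tt, p$emissivity, p$reflected_temp_c)
  }
  if (p$temp_noise_sd > 0) tt <- tt + matrix(stats::rnorm(th * tw, 0, p$temp_noise_sd), th, tw)
  thermal <- thermal_image(tt, emissivity_setting = p$emissivity,
                           reflected_temp_c = p$reflected_temp_c,
                           height_m = p$height_m)

  truth <- structure(list(
    true_mask = mask_vis, true_mask_thermal = mask_th,
    plant_labels = lab_vis, plant_labels_thermal = lab_th,
    true_canopy_temp_c = p$canopy_temp_c,
    true_background_temp_c = p$background_temp_c,
    true_homography = p$true_homography,
    plant_centers = centers, canopy_radius_px = p$canopy_radius_px
  ), class = "scene_truth")
  list(rgb = rgb, thermal = thermal, truth = truth, params = p)
}

#' Emulate an annotator: corresponding points from the true homography
#'
#' Points are drawn from a jittered grid over the visible frame interior (so no
#' three are collinear) and mapped through the scene's true homography;
#' optional Gaussian noise on the thermal-side points emulates annotation
#' error.
#'
#' @param scene a scene from [generate_scene()], or a `"scene_truth"`.
#' @param n_points number of correspondences (>= 4).
#' @param noise_sd annotation noise SD on the destination points, px.
#' @param seed integer seed.
#' @return list with `src` and `dst` N x 2 (col, row) matrices.
#' @export
annotate_correspondences <- function(scene, n_points = 9, noise_sd = 0, seed = 1L) {
  truth <- if (inherits(scene, "scene_truth")) scene else scene$truth
  p <- scene$params
  vw <- if (!is.null(p)) p$image_width_px else 2 * max(truth$plant_centers[, 1])
  vh <- if (!is.null(p)) p$image_height_px else 2 * max(truth$plant_centers[, 2])
  if (!is_count(n_points, min = 4)) stopf("n_points must be an integer >= 4")
  g <- ceiling(sqrt(n_points))
  gx <- (seq_len(g) - 0.5) / g * (vw * 0.9) + vw * 0.05
  gy <- (seq_len(g) - 0.5) / g * (vh * 0.9) + vh * 0.05
  grid <- cbind(rep(gx, times = g), rep(gy, each = g))[seq_len(n_points), , drop = FALSE]
  set.seed(child_seed(seed, 7L))
  src <- grid + matrix(stats::runif(2 * n_points, -0.15, 0.15) *
                         c(vw / g, vh / g), ncol = 2)
  dst <- apply_homography(truth$true_homography, src)
  if (noise_sd > 0) dst <- dst + matrix(stats::rnorm(2 * n_points, 0, noise_sd), ncol = 2)
  list(src = src, dst = dst)
}
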