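# Canopy segmentation in the visible image.
#
# RGB frames are converted to CIELAB and clustered by mean-shift using only the
# chromaticity channels a* and b*; discarding L* makes the segmentation robust
# to lightness differences. Plant clusters are then selected (by default the
# green-dominant modes, a* < 0) and the mask borders are eroded so that mixed
# plant/background pixels never enter the temperature readings.

#' Convert an sRGB image to CIELAB
#'
#' Standard transform: sRGB gamma decoding -> linear RGB -> XYZ (D65) -> CIELAB.
#'
#' @param img numeric H x W x 3 array, sRGB values in 0..255.
#' @return numeric H x W x 3 array; channel 1 is L* (0..100), channels 2-3 are
#'   a* and b*.
#' @export
rgb_to_lab <- function(img) {
  if (!is.array(img) || length(dim(img)) != 3 || dim(img)[3] != 3) {
    stopf("img must be an H x W x 3 array")
  }
  if (min(img) < 0 || max(img) > 255) stopf("sRGB values must lie in [0, 255]")
  d <- dim(img)
  m <- matrix(as.numeric(img), ncol = 3) / 255
  lab <- grDevices::convertColor(m, from = "sRGB", to = "Lab")
  array(lab, dim = d)
}

#' Mean-shift clustering of the a*/b* chromaticity plane
#'
#' Flat-kernel mean-shift in the 2-D (a*, b*) feature space; L* is ignored.
#' Seeds are a random pixel subsample (for speed); each seed ascends the local
#' density until convergence, converged modes closer than the bandwidth are
#' merged, and every image pixel is finally assigned to its nearest mode.
#'
#' @param lab H x W x 3 CIELAB array from [rgb_to_lab()].
#' @param bandwidth positive kernel radius in a*b* units, or `"auto"`: the
#'   0.2 quantile (`auto_quantile`) of pairwise a*b* distances over a seeded
#'   random subsample.
#' @param subsample number of pixels used for seeding and density evaluation.
#' @param seed integer seed for the pixel subsample (keeps runs reproducible).
#' @param auto_quantile quantile used by the automatic bandwidth.
#' @param max_iter,tol iteration cap and relative convergence tolerance.
#' @param min_support minimum fraction of the subsample that must fall within
#'   one bandwidth of a merged cluster (modes within one bandwidth of each
#'   other merge transitively, pooling their support) for it to be kept;
#'   weaker clusters — seeds stranded on isolated noise-outlier pixels — are
#'   dropped and their pixels assigned to the nearest surviving mode. The
#'   best-supported cluster is always kept.
#' @return object of class `"label_image"`: `labels` (H x W integer matrix,
#'   0-based, label 0 = largest cluster), `mode_centers` (K x 2 matrix of
#'   (a*, b*) mode positions, row k+1 for label k) and `bandwidth`.
#' @export
mean_shift_ab <- function(lab, bandwidth = "auto", subsample = 1000, seed = 1L,
                          auto_quantile = 0.2, max_iter = 200, tol = 1e-4,
                          min_support = 0.02) {
  if (!is.array(lab) || length(dim(lab)) != 3 || dim(lab)[3] != 3) {
    stopf("lab must be an H x W x 3 array")
  }
  h <- dim(lab)[1]; w <- dim(lab)[2]
  ab <- cbind(as.vector(lab[, , 2]), as.vector(lab[, , 3]))
  n <- nrow(ab)
  set.seed(seed)
  idx <- if (n > subsample) sample.int(n, subsample) else seq_len(n)
  X <- ab[idx, , drop = FALSE]
  if (identical(bandwidth, "auto")) {
    bidx <- if (nrow(X) > 1000) sample.int(nrow(X), 1000) else seq_len(nrow(X))
    bw <- as.numeric(stats::quantile(stats::dist(X[bidx, , drop = FALSE]), auto_quantile))
    if (!is.finite(bw) || bw <= 1e-8) bw <- 1  # constant image: any small radius
  } else {
    if (!is_number(bandwidth) || bandwidth <= 0) stopf("bandwidth must be > 0")
    bw <- bandwidth
  }
  modes <- unique(X)
  for (it in seq_len(max_iter)) {
    W <- dist2(modes, X) <= bw^2
    cnt <- rowSums(W)
    new_modes <- (W %*% X) / pmax(cnt, 1)
    iso <- cnt == 0
    if (any(iso)) new_modes[iso, ] <- modes[iso, ]  # isolated seed stays put
    shift <- sqrt(max(rowSums((new_modes - modes)^2)))
    # coincident seeds collapse to one row, so later iterations only shift the
    # distinct modes (the convergence path is unchanged)
    modes <- unique(round(new_modes, 8))
    if (shift < tol * bw) break
  }
  # merge modes transitively within one bandwidth (fragments of a sparsely
  # sampled class pool into one cluster), then drop merged clusters whose
  # union support is too small (seeds stranded on isolated outlier pixels)
  Wm <- dist2(modes, X) <= bw^2
  adj <- dist2(modes, modes) <= bw^2
  comp <- seq_len(nrow(modes))
  repeat {
    new_comp <- apply(adj, 1, function(a) min(comp[a]))
    if (identical(new_comp, comp)) break
    comp <- new_comp
  }
  support_mode <- rowSums(Wm)
  centers <- NULL; support <- numeric(0)
  for (cmp in unique(comp)) {
    members <- which(comp == cmp)
    union_support <- sum(colSums(Wm[members, , drop = FALSE]) > 0)
    best <- members[which.max(support_mode[members])]
    centers <- rbind(centers, modes[best, ])
    support <- c(support, union_support)
  }
  keep <- support >= min(max(support), min_support * nrow(X))
  centers <- centers[keep, , drop = FALSE]
  # full-image assignment to the nearest mode
  assign_idx <- max.col(-dist2(ab, centers), ties.method = "first")
  # relabel by decreasing pixel count, labels 0-based
  sizes <- tabulate(assign_idx, nbins = nrow(centers))
  rank <- order(order(sizes, decreasing = TRUE))  # old index -> new rank
  labels0 <- rank[assign_idx] - 1L
  centers <- centers[order(sizes, decreasing = TRUE), , drop = FALSE]
  colnames(centers) <- c("a", "b")
  if (nrow(centers) == 1) {
    message("mean-shift produced a single cluster (bandwidth ", format(bw),
            " covers the whole a*b* spread)")
  }
  structure(list(labels = matrix(labels0, h, w),
                 mode_centers = centers, bandwidth = bw),
            class = "label_image")
}

#' @export
print.label_image <- function(x, ...) {
  cat(sprintf("label image %d x %d px, %d cluster(s), bandwidth %.3g\n",
              nrow(x$labels), ncol(x$labels), nrow(x$mode_centers), x$bandwidth))
  print(cbind(x$mode_centers, n_pixels = tabulate(as.vector(x$labels) + 1L,
                                                  nbins = nrow(x$mode_centers))))
  invisible(x)
}

#' Select plant clusters from a label image
#'
#' Default rule: the plant mask is the union of clusters whose mode a* falls
#' below `a_threshold` (0 = green-dominant modes). The rule can be overridden
#' with an explicit label list, e.g. after visual inspection of the clusters.
#'
#' @param labels a `"label_image"` from [mean_shift_ab()].
#' @param a_threshold clusters with mode a* strictly below this are plant.
#' @param override_labels optional integer vector of 0-based labels to use as
#'   the plant mask instead of the greenness rule.
#' @return logical H x W mask; empty (with a warning) when no cluster matches.
#' @export
select_plant_mask <- function(labels, a_threshold = 0, override_labels = NULL) {
  if (!inherits(labels, "label_image")) stopf("labels must be a label_image")
  if (!is.null(override_labels)) {
    keep <- override_labels
  } else {
    keep <- which(labels$mode_centers[, "a"] < a_threshold) - 1L
  }
  mask <- matrix(labels$labels %in% keep,
                 nrow(labels$labels), ncol(labels$labels))
  if (!any(mask)) warnf("no cluster satisfies the plant rule; returning an empty mask")
  mask
}

#' Morphological erosion of a binary mask
#'
#' Binary erosion with a square structuring element of side
#' `2 * selem_radius + 1`, repeated `iterations` times. Pixels outside the
#' image are background, so mask regions touching the border erode too. Used
#' to remove plant-border pixels whose temperature mixes plant and background.
#'
#' @param mask logical matrix.
#' @param selem_radius structuring-element radius (>= 1); 1 gives 3 x 3.
#' @param iterations number of erosion passes (>= 1).
#' @return logical matrix, always a subset of the input mask.
#' @export
erode_mask <- function(mask, selem_radius = 1, iterations = 1) {
  if (!is.matrix(mask) || !is.logical(mask)) stopf("mask must be a logical matrix")
  if (!is_count(selem_radius)) stopf("selem_radius must be a positive integer")
  if (!is_count(iterations)) stopf("iterations must be a positive integer")
  r <- as.integer(selem_radius)
  out <- mask
  for (i in seq_len(iterations)) out <- erode_once(out, r)
  out
}

erode_once <- function(m, r) {
  h <- nrow(m); w <- ncol(m)
  side <- 2L * r + 1L
  # summed-area table over the zero-padded mask
  P <- matrix(0, h + side, w + side)
  P[(r + 2):(r + 1 + h), (r + 2):(r + 1 + w)] <- m
  S <- apply(P, 2, cumsum)
  S <- t(apply(S, 1, cumsum))
  win <- S[(side + 1):(side + h), (side + 1):(side + w)] -
    S[1:h, (side + 1):(side + w)] -
    S[(side + 1):(side + h), 1:w] +
    S[1:h, 1:w]
  win >= side^2 - 0.5
}

#' Pixel-level precision and recall of a mask against ground truth
#'
#' @param mask,truth logical matrices of equal shape.
#' @return list with `precision`, `recall`, `jaccard`.
#' @export
mask_scores <- function(mask, truth) {
  if (!all(dim(mask) == dim(truth))) stopf("mask and truth shapes differ")
  tp <- sum(mask & truth)
  list(precision = if (sum(mask) > 0) tp / sum(mask) else NA_real_,
       recall = if (sum(truth) > 0) tp / sum(truth) else NA_real_,
       jaccard = if (sum(mask | truth) > 0) tp / sum(mask | truth) else NA_real_)
}
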