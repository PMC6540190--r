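# Independent oracles used to freeze expected values. Each one re-derives the
# quantity from its defining equations by a route different from the package
# implementation (closed forms, brute force, scalar root finding, enumeration).

# sRGB (0..255) -> CIELAB via the published closed forms: gamma decoding,
# the sRGB->XYZ (D65) matrix, and the Lab f() compression.
oracle_rgb_to_lab <- function(rgb255) {
  v <- rgb255 / 255
  lin <- ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
  M <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                0.2126729, 0.7151522, 0.0721750,
                0.0193339, 0.1191920, 0.9503041), 3, 3, byrow = TRUE)
  xyz <- as.vector(M %*% lin)
  wp <- c(0.95047, 1.0, 1.08883)  # D65
  f <- function(t) ifelse(t > (6 / 29)^3, t^(1 / 3), t / (3 * (6 / 29)^2) + 4 / 29)
  fx <- f(xyz / wp)
  c(L = 116 * fx[2] - 16, a = 500 * (fx[1] - fx[2]), b = 200 * (fx[2] - fx[3]))
}

# binary erosion by its definition: a pixel survives iff every pixel of the
# square window of side 2r+1 centered on it lies inside the mask
oracle_erode <- function(mask, r) {
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(FALSE, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    ri <- (i - r):(i + r); cj <- (j - r):(j + r)
    if (any(ri < 1 | ri > h | cj < 1 | cj > w)) next
    out[i, j] <- all(mask[ri, cj])
  }
  out
}

# object temperature from the greybody fourth-power balance, found by a scalar
# root solve instead of the closed form
oracle_greybody <- function(apparent_c, emissivity, reflected_c) {
  f <- function(tobj_c) {
    emissivity * (tobj_c + 273.15)^4 +
      (1 - emissivity) * (reflected_c + 273.15)^4 - (apparent_c + 273.15)^4
  }
  stats::uniroot(f, c(-150, 400), tol = 1e-10)$root
}

# a random, well-conditioned homography: similarity (scale, rotation,
# translation) plus a small perspective component; all entries nonzero
random_homography <- function(seed) {
  set.seed(seed)
  s <- stats::runif(1, 0.4, 1.6)
  th <- stats::runif(1, -0.4, 0.4)
  tx <- stats::runif(1, -30, 30); ty <- stats::runif(1, -30, 30)
  H <- matrix(c(s * cos(th), -s * sin(th), tx,
                s * sin(th), s * cos(th), ty,
                stats::runif(1, -1, 1) * 1e-4, stats::runif(1, -1, 1) * 1e-4, 1),
              3, 3, byrow = TRUE)
  canopytherm::homography(H)
}

rel_err_homography <- function(H_est, H_true) {
  A <- unclass(H_est); B <- unclass(H_true)
  # element-wise relative error; (near-)zero entries are judged relative to
  # the matrix scale instead of blowing up the denominator
  max(abs(A - B) / pmax(abs(B), 1e-3 * max(abs(B))))
}

# letter-display validity: groups share a letter iff their pair is
# non-significant (checked exhaustively over all pairs)
cld_valid <- function(letters_vec, p, alpha) {
  g <- length(letters_vec)
  sets <- strsplit(letters_vec, "")
  for (i in seq_len(g - 1)) for (j in (i + 1):g) {
    share <- length(intersect(sets[[i]], sets[[j]])) > 0
    ns <- is.na(p[i, j]) || p[i, j] > alpha
    if (share != ns) return(FALSE)
  }
  TRUE
}

# minimal number of letters by brute force: letters must be cliques of the
# non-significance graph, jointly covering every ns-edge and every group
cld_min_letters <- function(p, alpha) {
  g <- nrow(p)
  ns <- function(i, j) is.na(p[i, j]) || p[i, j] > alpha
  subsets <- lapply(seq_len(2^g - 1), function(m) which(bitwAnd(m, 2^(seq_len(g) - 1)) > 0))
  cliques <- Filter(function(s) {
    if (length(s) < 2) return(TRUE)
    all(apply(utils::combn(s, 2), 2, function(pr) ns(pr[1], pr[2])))
  }, subsets)
  edges <- list()
  for (i in seq_len(g - 1)) for (j in (i + 1):g) if (ns(i, j)) edges[[length(edges) + 1]] <- c(i, j)
  covers <- function(sel) {
    covered_v <- sort(unique(unlist(cliques[sel])))
    if (!identical(covered_v, seq_len(g))) return(FALSE)
    all(vapply(edges, function(e) {
      any(vapply(cliques[sel], function(cl) all(e %in% cl), TRUE))
    }, TRUE))
  }
  for (k in seq_along(cliques)) {
    sel_all <- utils::combn(length(cliques), k)
    for (c2 in seq_len(ncol(sel_all))) {
      if (covers(sel_all[, c2])) return(k)
    }
  }
  stop("no valid letter assignment found")  # unreachable
}

# a random symmetric p-value matrix with a mix of clear and borderline pairs
random_p_matrix <- function(g, seed) {
  set.seed(seed)
  p <- matrix(0, g, g)
  m <- g * (g - 1) / 2
  v <- stats::runif(m)
  make_sig <- stats::runif(m) < 0.4
  v[make_sig] <- stats::runif(sum(make_sig), 0, 0.05)
  p[upper.tri(p)] <- v
  p <- p + t(p); diag(p) <- 1
  p
}

# compact scenes used throughout the tests (fast but fully representative)
test_scene_params <- function(seed, ...) {
  canopytherm::scene_params(image_width_px = 192, image_height_px = 144,
                            thermal_width_px = 96, thermal_height_px = 72,
                            n_plants = 2, canopy_radius_px = 28,
                            rng_seed = seed, ...)
}
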