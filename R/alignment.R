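# Visible-to-thermal image registration.
#
# The two sensors of a combined visible/thermal camera share neither resolution
# nor alignment, so canopy masks segmented in the visible image must be carried
# into thermal coordinates through a projective transform (homography) estimated
# by least squares from manually annotated corresponding points.
#
# Coordinate convention (binding package-wide): pixels are addressed 0-based as
# (row, col) with the origin at the top-left; homographies act on homogeneous
# (col, row, 1) triples.

#' Construct a homography
#'
#' A 3x3 projective map between image planes, normalized so that `H[3, 3] = 1`.
#' By package convention homographies map visible-image (col, row) coordinates
#' to thermal-image (col, row) coordinates.
#'
#' @param H numeric 3x3 matrix with nonzero `H[3, 3]` and nonzero determinant.
#' @return the normalized matrix with class `"homography"`.
#' @export
homography <- function(H) {
  if (!is.matrix(H) || !all(dim(H) == c(3, 3)) || !all(is.finite(H))) {
    stopf("a homography must be a finite 3x3 matrix")
  }
  if (abs(H[3, 3]) < 1e-12) stopf("H[3,3] is (near) zero; cannot normalize")
  H <- H / H[3, 3]
  if (abs(det(H)) < 1e-12) stopf("homography is singular (det ~ 0)")
  structure(H, class = c("homography", "matrix"))
}

#' @export
print.homography <- function(x, ...) {
  cat("projective transform (visible -> thermal), H[3,3] = 1:\n")
  print(unclass(x), ...)
  invisible(x)
}

#' Validate a set of point correspondences
#'
#' Correspondences come from a human annotator: N >= 4 pairs of (col, row)
#' positions, the source points not all collinear. Exactly collinear triples
#' (common in grid-like annotations) are only warned about for small N; full
#' degeneracy is caught here and again inside the DLT.
#'
#' @param src,dst numeric N x 2 matrices of (col, row) positions in the visible
#'   and thermal image respectively.
#' @param tol relative tolerance for the collinearity checks.
#' @return invisibly, a list with the validated `src` and `dst`.
#' @export
validate_correspondences <- function(src, dst, tol = 1e-8) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  if (ncol(src) != 2 || ncol(dst) != 2) stopf("correspondences must be N x 2 (col, row)")
  if (nrow(src) != nrow(dst)) stopf("src and dst must have the same number of points")
  if (nrow(src) < 4) stopf("at least 4 point correspondences are required (got %d)", nrow(src))
  if (!all(is.finite(src)) || !all(is.finite(dst))) stopf("correspondences must be finite")
  ctr <- sweep(src, 2, colMeans(src))
  sv <- svd(ctr)$d
  if (sv[2] <= tol * max(sv[1], 1)) {
    stopf("degenerate correspondences: source points are (near) collinear")
  }
  if (nrow(src) <= 12) {
    idx <- utils::combn(nrow(src), 3)
    scale2 <- max(sv[1]^2, 1)
    for (k in seq_len(ncol(idx))) {
      p <- src[idx[, k], , drop = FALSE]
      area2 <- abs((p[2, 1] - p[1, 1]) * (p[3, 2] - p[1, 2]) -
                     (p[3, 1] - p[1, 1]) * (p[2, 2] - p[1, 2]))
      if (area2 <= tol * scale2) {
        warnf("three source points (%s) are collinear; estimation proceeds",
              paste(idx[, k], collapse = ", "))
        break
      }
    }
  }
  invisible(list(src = src, dst = dst))
}

#' Read annotated corresponding points from CSV
#'
#' @param path CSV file with header `src_col,src_row,dst_col,dst_row`.
#' @return list with `src` and `dst` N x 2 matrices (col, row).
#' @export
read_correspondences <- function(path) {
  df <- utils::read.csv(path)
  need <- c("src_col", "src_row", "dst_col", "dst_row")
  if (!all(need %in% names(df))) {
    stopf("correspondence file %s lacks columns %s", path,
          paste(setdiff(need, names(df)), collapse = ", "))
  }
  list(src = cbind(df$src_col, df$src_row), dst = cbind(df$dst_col, df$dst_row))
}

#' Write corresponding points to CSV
#' @param pts list with `src` and `dst` N x 2 matrices.
#' @param path output CSV path.
#' @export
write_correspondences <- function(pts, path) {
  df <- data.frame(src_col = pts$src[, 1], src_row = pts$src[, 2],
                   dst_col = pts$dst[, 1], dst_row = pts$dst[, 2])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

hartley_normalization <- function(P) {
  ctr <- colMeans(P)
  d <- sqrt(rowSums(sweep(P, 2, ctr)^2))
  md <- mean(d)
  s <- if (md > 0) sqrt(2) / md else 1
  T <- matrix(c(s, 0, -s * ctr[1],
                0, s, -s * ctr[2],
                0, 0, 1), 3, 3, byrow = TRUE)
  Pn <- t(T %*% rbind(t(P), 1))[, 1:2, drop = FALSE]
  list(T = T, P = Pn)
}

#' Estimate a projective transform from corresponding points
#'
#' Least-squares estimation by the normalized direct linear transform (DLT):
#' both point sets are centered and scaled to mean distance sqrt(2) from the
#' origin, the 2N x 9 design matrix is assembled, the solution is the right
#' singular vector of the smallest singular value, and the result is
#' denormalized and scaled to `H[3,3] = 1`. No robust loop is used: the points
#' are curated human annotations, and the per-point residuals let the user
#' audit bad annotations instead.
#'
#' @inheritParams validate_correspondences
#' @return list with `H` (a [homography()]) and `residuals`, the per-point
#'   Euclidean reprojection errors (in destination pixels).
#' @export
estimate_homography <- function(src, dst) {
  v <- validate_correspondences(src, dst)
  src <- v$src; dst <- v$dst
  ns <- hartley_normalization(src)
  nd <- hartley_normalization(dst)
  x <- ns$P[, 1]; y <- ns$P[, 2]
  u <- nd$P[, 1]; w <- nd$P[, 2]
  n <- nrow(src)
  A <- matrix(0, 2 * n, 9)
  A[seq(1, 2 * n, 2), ] <- cbind(-x, -y, -1, 0, 0, 0, u * x, u * y, u)
  A[seq(2, 2 * n, 2), ] <- cbind(0, 0, 0, -x, -y, -1, w * x, w * y, w)
  sv <- svd(A, nu = 0, nv = 9)
  d <- sv$d
  # with >= 4 non-degenerate points only the smallest singular value may
  # approach zero; a (near) zero eighth value means the solution is not unique
  if (d[8] <= 1e-10 * d[1]) {
    stopf("degenerate point configuration: homography not uniquely determined (two vanishing singular values)")
  }
  Hn <- matrix(sv$v[, 9], 3, 3, byrow = TRUE)
  H <- solve(nd$T) %*% Hn %*% ns$T
  H <- homography(H)
  proj <- apply_homography(H, src)
  res <- sqrt(rowSums((proj - dst)^2))
  list(H = H, residuals = res)
}

#' Apply a homography to points
#'
#' Homogeneous multiplication followed by perspective division.
#'
#' @param H a [homography()] (or plain 3x3 matrix).
#' @param points numeric N x 2 matrix of (col, row) positions.
#' @param w_tol points whose homogeneous w falls below this tolerance map to
#'   the plane at infinity and raise an error.
#' @return N x 2 matrix of mapped (col, row) positions.
#' @export
apply_homography <- function(H, points, w_tol = 1e-12) {
  points <- if (is.matrix(points)) points else matrix(points, ncol = 2)
  if (!all(is.finite(points))) stopf("points must be finite")
  q <- unclass(H) %*% rbind(points[, 1], points[, 2], 1)
  w <- q[3, ]
  bad <- abs(w) < w_tol
  if (any(bad)) {
    stopf("point(s) %s map to the plane at infinity (|w| < %g)",
          paste(which(bad), collapse = ", "), w_tol)
  }
  cbind(q[1, ] / w, q[2, ] / w)
}

#' Warp a binary mask into another image grid
#'
#' Inverse mapping with nearest-neighbour sampling: every output pixel is
#' pulled back through `H^-1` and takes the value of the nearest source pixel
#' (binary data must stay binary; interpolation would blur mask borders).
#' Output pixels falling outside the source domain are `FALSE`.
#'
#' @param mask logical matrix (visible-image mask).
#' @param H [homography()] mapping mask (source) coordinates to output
#'   coordinates, typically visible -> thermal.
#' @param out_shape integer `c(rows, cols)` of the output grid (thermal shape).
#' @return logical matrix of dimension `out_shape`.
#' @export
warp_mask <- function(mask, H, out_shape) {
  if (!is.matrix(mask) || !is.logical(mask)) stopf("mask must be a logical matrix")
  if (length(out_shape) != 2 || !all(out_shape >= 1)) stopf("out_shape must be c(rows, cols)")
  Hi <- tryCatch(solve(unclass(H)), error = function(e) stopf("homography is not invertible"))
  oh <- out_shape[1]; ow <- out_shape[2]
  # 0-based output pixel centers
  cc <- rep(0:(ow - 1), each = oh)
  rr <- rep(0:(oh - 1), times = ow)
  q <- Hi %*% rbind(cc, rr, 1)
  w <- q[3, ]
  ok <- abs(w) > 1e-12
  sc <- round(q[1, ] / w)  # source col, 0-based
  sr <- round(q[2, ] / w)
  inside <- ok & sr >= 0 & sr < nrow(mask) & sc >= 0 & sc < ncol(mask)
  out <- matrix(FALSE, oh, ow)
  out[inside] <- mask[cbind(sr[inside] + 1, sc[inside] + 1)]
  out
}
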