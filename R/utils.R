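#' @keywords internal
"_PACKAGE"

#' Derive a reproducible child seed from a top-level seed
#'
#' All randomness in the package flows from one top-level seed through named
#' substreams so that individual scenes and Monte-Carlo replicates are
#' independently reproducible. Child seeds stay below 2^31 - 1.
#'
#' @param seed integer top-level seed.
#' @param index integer substream index (>= 0).
#' @param salt optional integer separating different kinds of substreams.
#' @return an integer seed usable with [set.seed()].
#' @export
child_seed <- function(seed, index, salt = 0L) {
  m <- 2147483629
  s <- (as.numeric(seed) %% m)
  v <- (s * 48271 + as.numeric(index) * 104729 + as.numeric(salt) * 7919 + 1) %% m
  as.integer(v)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Flatten a matrix in row-major order
#'
#' Pixel vectors in this package follow the raster convention (row-major,
#' origin top-left); R matrices are column-major, hence this helper.
#'
#' @param m a matrix.
#' @return a vector of the elements of `m` in row-major order.
#' @keywords internal
row_major <- function(m) as.vector(t(m))

# squared Euclidean distances between rows of A (n x d) and rows of B (m x d)
dist2 <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}

is_count <- function(x, min = 1) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x == round(x) && x >= min
}

is_number <- function(x) length(x) == 1 && is.numeric(x) && is.finite(x)
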