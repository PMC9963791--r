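#' Distance on the flat torus
#'
#' Euclidean distance on a square domain `[0, L)^2` with periodic boundary
#' conditions: each coordinate difference is wrapped to the shorter way
#' around, so `d(x, y)^2 = sum_i min(|x_i - y_i|, L - |x_i - y_i|)^2`.
#' The maximum attainable distance in two dimensions is `L / sqrt(2)`.
#'
#' @param x,y Points as numeric vectors, or matrices with one point per row.
#'   A single point is recycled against a matrix of points.
#' @param domain_size Side length `L` of the periodic domain (positive).
#'
#' @return A numeric vector of distances, one per row pair.
#' @examples
#' torus_distance(c(0.5, 0.5), c(9.5, 0.5), 10) # wraps: 1, not 9
#' @export
torus_distance <- function(x, y, domain_size) {
  if (!is.numeric(domain_size) || length(domain_size) != 1L ||
      !is.finite(domain_size) || domain_size <= 0) {
    stop("`domain_size` must be a single positive number.", call. = FALSE)
  }
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (is.null(dim(y))) y <- matrix(y, nrow = 1L)
  n <- max(nrow(x), nrow(y))
  if (nrow(x) == 1L && n > 1L) x <- x[rep(1L, n), , drop = FALSE]
  if (nrow(y) == 1L && n > 1L) y <- y[rep(1L, n), , drop = FALSE]
  if (!identical(dim(x), dim(y))) {
    stop("`x` and `y` must have matching dimensions.", call. = FALSE)
  }
  d <- abs(x - y)
  d <- pmin(d, domain_size - d)
  sqrt(rowSums(d * d))
}

# Squared torus distance between paired rows; internal hot-path helper
# (no validation, no sqrt).
.torus_dist2 <- function(x, y, L) {
  d <- abs(x - y)
  d <- pmin(d, L - d)
  rowSums(d * d)
}
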