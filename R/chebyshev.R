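#' Chebyshev polynomial basis matrix
#'
#' Evaluates the Chebyshev polynomials of the first kind \eqn{T_0,\dots,T_D}
#' at a set of points in \eqn{[-1,1]} by the three-term recurrence
#' \eqn{T_{j+1}(x) = 2x T_j(x) - T_{j-1}(x)}.  These are the basis functions
#' of the exponent of the maximum-entropy density: they are bounded
#' (\eqn{|T_j(x)| \le 1}) so every exponent moment exists, and they form a
#' complete orthogonal system on \eqn{[-1,1]}.
#'
#' @param x numeric vector of evaluation points in \eqn{[-1,1]}.
#' @param degree integer \eqn{D \ge 0}, highest polynomial order.
#' @return numeric matrix with `length(x)` rows and `degree + 1` columns;
#'   column `j + 1` holds \eqn{T_j(x)}.
#' @examples
#' x <- seq(-1, 1, length.out = 5)
#' B <- cheb_basis(x, 3)
#' all.equal(B[, 4], cos(3 * acos(x)))
#' @export
cheb_basis <- function(x, degree) {
  stopifnot(is.numeric(x), degree >= 0, degree == as.integer(degree))
  n <- length(x)
  B <- matrix(0, n, degree + 1L)
  B[, 1L] <- 1
  if (degree >= 1L) B[, 2L] <- x
  if (degree >= 2L) {
    for (j in 2L:degree) {
      B[, j + 1L] <- 2 * x * B[, j] - B[, j - 1L]
    }
  }
  B
}
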