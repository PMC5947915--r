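#' Data-driven censor window
#'
#' Determines a finite support \eqn{[a,b]} for a sample, combining an
#' empirical-gap padding rule with an IQR-multiple outlier rule:
#' \deqn{a_1 = V^{(1)} - (V^{(5)} - V^{(1)}), \quad
#'       b_1 = V^{(N)} + (V^{(N)} - V^{(N-5)}),}
#' \deqn{a_2 = Q_{25} - c (Q_{75} - Q_{25}), \quad
#'       b_2 = Q_{75} + c (Q_{75} - Q_{25}),}
#' with \eqn{a = \max(a_1, a_2)} and \eqn{b = \min(b_1, b_2)}.  The gap rule
#' pads the observed range so all data is kept; the quantile rule trims very
#' extreme values of heavy-tailed samples (at the default `c = 7` only "very
#' extreme" points are cut) so numerical integration of the CDF stays
#' tractable.  The fraction of observations retained inside \eqn{[a,b]} is
#' reported as `kept_fraction`: the fitted density is the conditional density
#' on the window, and callers may multiply by `kept_fraction` to recover the
#' unconditional scale.
#'
#' Quantiles use linear interpolation between order statistics
#' (`stats::quantile` type 7).  For `N < 6` the gap rule degrades gracefully
#' to padding by the full observed range.  If bounds are known they should be
#' passed instead (see `bounds`), which bypasses both heuristics.
#'
#' @param x numeric sample (need not be sorted; non-finite values are an
#'   error).
#' @param c positive outlier multiplier (default 7).
#' @param bounds optional numeric `c(a, b)` of known support bounds;
#'   overrides the data-driven rules.
#' @return an object of class `"censor_window"`: list with `a`, `b`, `a1`,
#'   `b1`, `a2`, `b2`, `c`, `n`, `n_kept`, `kept_fraction`.
#' @examples
#' w <- censor_window(1:10, c = Inf)
#' c(w$a1, w$b1)   # -3, 15
#' @export
censor_window <- function(x, c = 7, bounds = NULL) {
  if (any(!is.finite(x))) stop("'x' must contain only finite values")
  n <- length(x)
  if (n < 2L) stop("need at least 2 observations")
  v <- sort(x)
  if (!is.null(bounds)) {
    stopifnot(length(bounds) == 2L, bounds[1] < bounds[2])
    a <- bounds[1]; b <- bounds[2]
    a1 <- b1 <- a2 <- b2 <- NA_real_
  } else {
    stopifnot(is.numeric(c), c > 0)
    if (n >= 6L) {
      a1 <- v[1] - (v[5] - v[1])          # V^(5): the 5th order statistic
      b1 <- v[n] + (v[n] - v[n - 5L])
    } else {
      a1 <- v[1] - (v[n] - v[1])
      b1 <- v[n] + (v[n] - v[1])
    }
    q <- stats::quantile(v, c(0.25, 0.75), names = FALSE, type = 7)
    iqr <- q[2] - q[1]
    if (iqr <= 0 && a1 >= b1)
      stop("degenerate window: data has zero spread; supply known bounds via 'bounds'")
    a2 <- q[1] - c * iqr
    b2 <- q[2] + c * iqr
    a <- max(a1, a2)
    b <- min(b1, b2)
    if (!(a < b))
      stop("degenerate window: computed a >= b; supply known bounds via 'bounds'")
  }
  n_kept <- sum(x >= a & x <= b)
  structure(list(a = a, b = b, a1 = a1, b1 = b1, a2 = a2, b2 = b2,
                 c = if (is.null(bounds)) c else NA_real_,
                 n = n, n_kept = n_kept, kept_fraction = n_kept / n),
            class = "censor_window")
}

#' @export
print.censor_window <- function(x, ...) {
  cat(sprintf("Censor window [%g, %g]  (kept %d of %d observations, %.1f%%)\n",
              x$a, x$b, x$n_kept, x$n, 100 * x$kept_fraction))
  invisible(x)
}

#' Linear map between a censor window and the canonical domain
#'
#' Maps data values \eqn{V} in \eqn{[a,b]} onto \eqn{X = (2V - b - a)/(b-a)}
#' in \eqn{[-1,1]}, the natural range of the Chebyshev basis.  Values outside
#' the window are dropped (with attribute `n_dropped`).  `linear_unmap` is
#' the exact inverse.
#'
#' @param window a `"censor_window"` (or any list with elements `a`, `b`).
#' @param v,x numeric vectors in data units / canonical units.
#' @return numeric vector; `linear_map` carries an integer attribute
#'   `n_dropped`.
#' @export
linear_map <- function(window, v) {
  a <- window$a; b <- window$b
  keep <- v >= a & v <= b
  out <- (2 * v[keep] - b - a) / (b - a)
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' @rdname linear_map
#' @export
linear_unmap <- function(window, x) {
  a <- window$a; b <- window$b
  (x * (b - a) + b + a) / 2
}
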