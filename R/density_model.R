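#' Maximum-entropy density model
#'
#' Constructs the exponential-of-Chebyshev-series probability density
#' \deqn{p(v) = \exp\left[(\lambda_0 - 1) + \sum_{j=1}^{D} \lambda_j
#'   T_j(x)\right] \cdot \frac{2}{b-a},}
#' where \eqn{x = (2v - b - a)/(b - a)} maps the support \eqn{[a,b]} onto
#' \eqn{[-1,1]} and \eqn{T_j} are Chebyshev polynomials of the first kind.
#' The constant \eqn{\lambda_0} is not free: it carries the log-partition
#' value and is recomputed here so that the density integrates to one over
#' \eqn{[a,b]}.  Only the coefficients \eqn{\lambda_1,\dots,\lambda_D} shape
#' the density.
#'
#' The normalization integral and the tabulated CDF are computed on a dense
#' equispaced grid: composite Simpson weights for the partition function and
#' a cumulative trapezoid for the CDF, with the grid doubled until the
#' partition function is stable to `tol`.  The exponent is evaluated with its
#' maximum subtracted before exponentiation so wild coefficient vectors
#' cannot overflow.
#'
#' @param lambda numeric vector `c(lambda0, lambda1, ..., lambdaD)` of finite
#'   coefficients.  `lambda[1]` is overwritten by the normalization constant;
#'   a vector of length 1 gives the uniform density on `domain`.
#' @param domain numeric length-2 vector `c(a, b)` with `a < b`, the support
#'   in data units.
#' @param n_grid odd integer, number of quadrature nodes (default 4097).
#' @param tol absolute tolerance on the normalization integral (default 1e-8).
#' @return an object of class `"maxent_model"` with elements `lambda`,
#'   `domain`, `basis_order`, `log_norm` (log partition function on the
#'   canonical domain), and tabulated `grid` (canonical nodes), `pdf_grid`
#'   (density in data units) and `cdf_grid`.
#' @seealso [dmaxent()], [pmaxent()], [qmaxent()], [rmaxent()]
#' @examples
#' m <- maxent_model(c(0, 0.5), c(-1, 1))
#' dmaxent(0, m)                  # 0.5 / (2 sinh 0.5)
#' pmaxent(0, m)                  # (1 - exp(-0.5)) / (2 sinh 0.5)
#' @export
maxent_model <- function(lambda, domain, n_grid = 4097L, tol = 1e-8) {
  if (!is.numeric(lambda) || length(lambda) < 1L || any(!is.finite(lambda)))
    stop("invalid model: 'lambda' must be a numeric vector of finite coefficients")
  if (!is.numeric(domain) || length(domain) != 2L || !all(is.finite(domain)) ||
      domain[1] >= domain[2])
    stop("invalid model: 'domain' must be c(a, b) with a < b")
  n_grid <- as.integer(n_grid)
  if (n_grid %% 2L == 0L) n_grid <- n_grid + 1L
  D <- length(lambda) - 1L

  theta <- lambda[-1L]
  g <- NULL
  repeat {
    g <- .me_tabulate(theta, n_grid)
    if (is.null(g$err) || g$err <= tol || n_grid >= 32769L) break
    n_grid <- 2L * n_grid - 1L
  }
  if (!is.finite(g$log_norm))
    stop("integration error: partition function is not finite at tolerance ", tol)

  jac <- 2 / (domain[2] - domain[1])
  lambda[1L] <- 1 - g$log_norm
  structure(list(
    lambda      = lambda,
    domain      = domain,
    basis_order = D,
    log_norm    = g$log_norm,
    grid        = g$x,
    pdf_grid    = g$pdf * jac,
    cdf_grid    = g$cdf
  ), class = "maxent_model")
}

# Tabulate exp(sum_j theta_j T_j(x)) on n equispaced canonical nodes.
# Returns the canonically normalized pdf, trapezoid CDF (endpoints 0/1),
# log partition value and a grid-halving error estimate.
.me_tabulate <- function(theta, n) {
  x <- seq(-1, 1, length.out = n)
  S <- if (length(theta)) drop(cheb_basis(x, length(theta))[, -1L, drop = FALSE] %*% theta)
       else numeric(n)
  m <- max(S)
  e <- exp(pmax(S - m, -745))
  h <- 2 / (n - 1)
  w <- rep(c(2, 4), length.out = n); w[c(1L, n)] <- 1          # Simpson
  Z <- sum(w * e) * h / 3
  half <- seq(1L, n, by = 2L)
  wh <- rep(c(2, 4), length.out = length(half)); wh[c(1L, length(half))] <- 1
  Zh <- sum(wh * e[half]) * 2 * h / 3
  ct <- c(0, cumsum((e[-1L] + e[-n]) * h / 2))
  list(x = x, pdf = e / Z, cdf = ct / ct[n],
       log_norm = m + log(Z), err = abs(Z - Zh) / Z)
}

#' Density, distribution, quantile and random generation for a fitted
#' maximum-entropy model
#'
#' `dmaxent` evaluates the density in data units (exactly positive on the
#' support, zero outside); `pmaxent` evaluates the CDF by piecewise monotone
#' cubic interpolation of the tabulated cumulative integral, so it is
#' strictly increasing with `pmaxent(a) = 0` and `pmaxent(b) = 1`;
#' `qmaxent` inverts it by monotone interpolation; `rmaxent` draws samples
#' by the inverse-CDF transform.
#'
#' @param x,q numeric vector of values in data units.
#' @param p numeric vector of probabilities in \eqn{[0,1]}.
#' @param n integer number of draws.
#' @param model a `"maxent_model"` object.
#' @param log logical; return the log density?
#' @return numeric vector.
#' @export
dmaxent <- function(x, model, log = FALSE) {
  stopifnot(inherits(model, "maxent_model"))
  a <- model$domain[1]; b <- model$domain[2]
  u <- (2 * x - b - a) / (b - a)
  theta <- model$lambda[-1L]
  S <- if (length(theta)) drop(cheb_basis(pmin(pmax(u, -1), 1), length(theta))[, -1L, drop = FALSE] %*% theta)
       else numeric(length(u))
  lg <- S - model$log_norm + base::log(2 / (b - a))
  lg[x < a | x > b] <- -Inf
  if (log) lg else exp(lg)
}

#' @rdname dmaxent
#' @export
pmaxent <- function(q, model) {
  stopifnot(inherits(model, "maxent_model"))
  a <- model$domain[1]; b <- model$domain[2]
  u <- (2 * q - b - a) / (b - a)
  f <- stats::splinefun(model$grid, model$cdf_grid, method = "hyman")
  out <- pmin(pmax(f(pmin(pmax(u, -1), 1)), 0), 1)
  out[q <= a] <- 0
  out[q >= b] <- 1
  out
}

#' @rdname dmaxent
#' @export
qmaxent <- function(p, model) {
  stopifnot(inherits(model, "maxent_model"))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("'p' must lie in [0, 1]")
  a <- model$domain[1]; b <- model$domain[2]
  keep <- c(TRUE, diff(model$cdf_grid) > 0)      # strictly increasing knots
  f <- stats::splinefun(model$cdf_grid[keep], model$grid[keep], method = "hyman")
  u <- pmin(pmax(f(p), -1), 1)
  u[p == 0] <- -1
  u[p == 1] <- 1
  (u * (b - a) + b + a) / 2
}

#' @rdname dmaxent
#' @export
rmaxent <- function(n, model) {
  qmaxent(stats::runif(n), model)
}

#' @export
print.maxent_model <- function(x, ...) {
  cat("Maximum-entropy density model\n")
  cat(sprintf("  support       : [%g, %g]\n", x$domain[1], x$domain[2]))
  cat(sprintf("  basis order D : %d (%d Lagrange multipliers incl. normalization)\n",
              x$basis_order, x$basis_order + 1L))
  cat(sprintf("  lambda0       : %.6g\n", x$lambda[1]))
  if (x$basis_order > 0)
    cat("  lambda[1..D]  :", paste(signif(x$lambda[-1L], 4), collapse = " "), "\n")
  invisible(x)
}

#' Write or read a maximum-entropy model as TSV
#'
#' The file stores the support and one coefficient per line at 17 significant
#' digits, which round-trips IEEE doubles bit-exactly.  Reading rebuilds the
#' model (and recomputes the normalization constant from the coefficients).
#'
#' @param model a `"maxent_model"`.
#' @param path file path.
#' @return `read_maxent` returns a `"maxent_model"`; `write_maxent` returns
#'   `path` invisibly.
#' @export
write_maxent <- function(model, path) {
  stopifnot(inherits(model, "maxent_model"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# memde maxent_model",
    sprintf("# domain\t%.17g\t%.17g", model$domain[1], model$domain[2]),
    sprintf("# basis_order\t%d", model$basis_order),
    "lambda",
    sprintf("%.17g", model$lambda)), con)
  invisible(path)
}

#' @rdname write_maxent
#' @export
read_maxent <- function(path) {
  lines <- readLines(path)
  dom <- as.numeric(strsplit(grep("^# domain", lines, value = TRUE), "\t")[[1]][2:3])
  lam <- as.numeric(lines[-c(grep("^#", lines), grep("^lambda$", lines))])
  maxent_model(lam, dom)
}
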