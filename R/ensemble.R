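#' Fit an ensemble of maximum-entropy density models
#'
#' The main fitting function.  Runs `models` independent single fits
#' (see [memde_one()]) with seeds derived deterministically from `seed`,
#' then selects the most central model: pairwise total squared error
#' between every pair of model densities is evaluated on a shared
#' 1001-point grid over the common window, and the model with the least
#' row-sum is the estimate.  The remaining models quantify the
#' fit-to-fit variability due to the stochastic search and to finite
#' sample fluctuations; the per-grid-point standard deviation across
#' models is returned as a spread band.  Failed members are excluded from
#' selection but kept for inspection.
#'
#' @param x numeric sample, or a file path accepted by [read_sample()].
#' @param bounds optional known support bounds `c(a, b)`.
#' @param outlier_c censor-window outlier multiplier; default 7.
#' @param models ensemble size M; default 5.
#' @param control a [memde_control()] list.
#' @param score_table a `"surd_score_table"`; defaults to the packaged one.
#' @param seed optional integer seed making the whole ensemble reproducible.
#' @return an object of class `"memde"`: list with `fits` (list of
#'   `"memde_fit"`), `central` (index of the selected model), `pairwise`
#'   (symmetric squared-error matrix, failures as `NA`), `grid`,
#'   `spread` (per-grid-point sd across successful models), `window`,
#'   `data`, `seed`, `call`.
#' @examples
#' \donttest{
#' set.seed(7)
#' fit <- memde(rnorm(512), models = 3, seed = 7)
#' print(fit)
#' }
#' @export
memde <- function(x, bounds = NULL, outlier_c = 7, models = 5L,
                  control = memde_control(),
                  score_table = default_score_table(), seed = NULL) {
  cl <- match.call()
  if (is.character(x)) x <- read_sample(x)
  stopifnot(models >= 1L)
  seeds <- if (is.null(seed)) rep(list(NULL), models)
           else as.list(.with_seed(seed, sample.int(2147483646L, models)))
  fits <- vector("list", models)
  for (i in seq_len(models)) {
    fits[[i]] <- tryCatch(
      memde_one(x, bounds = bounds, outlier_c = outlier_c, control = control,
                score_table = score_table, seed = seeds[[i]]),
      error = function(e) e)
  }
  errs <- vapply(fits, inherits, TRUE, "error")
  ok <- !errs & vapply(fits, function(f) isTRUE(f$success), TRUE)
  if (!any(!errs)) stop("all ensemble members failed: ",
                        conditionMessage(fits[[1]]))
  usable <- if (any(ok)) ok else !errs

  window <- fits[[which(usable)[1]]]$window
  grid <- seq(window$a, window$b, length.out = 1001L)
  dens <- matrix(NA_real_, 1001L, models)
  for (i in which(!errs)) dens[, i] <- dmaxent(grid, fits[[i]]$model)

  pw <- matrix(NA_real_, models, models)
  iu <- which(usable)
  for (i in iu) for (j in iu)
    pw[i, j] <- if (i == j) 0 else sum((dens[, i] - dens[, j])^2)
  central <- iu[which.min(rowSums(pw[iu, iu, drop = FALSE]))]
  spread <- if (length(iu) > 1L)
    apply(dens[, iu, drop = FALSE], 1L, stats::sd) else rep(0, 1001L)

  structure(list(fits = fits, central = central, pairwise = pw,
                 grid = grid, density_grid = dens, spread = spread,
                 window = window, data = x, seed = seed, call = cl),
            class = "memde")
}

#' @export
print.memde <- function(x, ...) {
  f <- x$fits[[x$central]]
  cat("Maximum-entropy density estimate (memde)\n")
  cat("  call   :", deparse(x$call), "\n")
  cat(sprintf("  data   : %d observations, window [%g, %g] (kept %.1f%%)\n",
              x$window$n, x$window$a, x$window$b,
              100 * x$window$kept_fraction))
  cat(sprintf("  central model %d of %d: L = %.4f, SURD coverage = %.1f%%, %d Lagrange multipliers\n",
              x$central, length(x$fits), f$L, 100 * f$coverage, f$n_lagrange))
  invisible(x)
}

#' @export
summary.memde <- function(object, ...) {
  rows <- lapply(seq_along(object$fits), function(i) {
    f <- object$fits[[i]]
    if (inherits(f, "error"))
      return(data.frame(model = i, L = NA, coverage = NA, n_lagrange = NA,
                        success = FALSE, sq_error = NA, central = FALSE))
    data.frame(model = i, L = f$L, coverage = f$coverage,
               n_lagrange = f$n_lagrange, success = f$success,
               sq_error = sum(object$pairwise[i, ], na.rm = TRUE),
               central = i == object$central)
  })
  out <- list(table = do.call(rbind, rows), window = object$window,
              central = object$central)
  class(out) <- "summary.memde"
  out
}

#' @export
print.summary.memde <- function(x, ...) {
  cat("Ensemble of maximum-entropy density fits\n")
  print(x$window)
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.memde <- function(object, ...) object$fits[[object$central]]$model$lambda

#' Predict density, CDF or quantiles from a fitted ensemble
#'
#' Evaluates the central model of a [memde()] fit.
#'
#' @param object a `"memde"` object.
#' @param newdata numeric vector of evaluation points (values for
#'   `type = "pdf"`/`"cdf"`, probabilities for `type = "quantile"`);
#'   defaults to the fit's evaluation grid.
#' @param type one of `"pdf"`, `"cdf"`, `"quantile"`.
#' @param ... unused.
#' @return numeric vector.
#' @export
predict.memde <- function(object, newdata = NULL,
                          type = c("pdf", "cdf", "quantile"), ...) {
  type <- match.arg(type)
  m <- object$fits[[object$central]]$model
  if (is.null(newdata))
    newdata <- if (type == "quantile") seq(0, 1, length.out = 101L)
               else object$grid
  switch(type,
         pdf = dmaxent(newdata, m),
         cdf = pmaxent(newdata, m),
         quantile = qmaxent(newdata, m))
}

#' @export
simulate.memde <- function(object, nsim = 1, seed = NULL, ...) {
  m <- object$fits[[object$central]]$model
  .with_seed(seed, rmaxent(nsim, m))
}

#' Scaled quantile residuals of a fit
#'
#' Returns the SQR diagnostic (see [sqr()]) of the central model: the data
#' is pushed through the fitted CDF and its sorted positions are compared
#' with the expected positions of uniform order statistics.
#'
#' @param object a `"memde"` object.
#' @param ... unused.
#' @return a `"memde_sqr"` data frame.
#' @export
residuals.memde <- function(object, ...) {
  sqr(object$fits[[object$central]]$u)
}

#' Plot a fitted density ensemble
#'
#' Two base-graphics panels: the estimated density (central model, with the
#' ensemble spread as a band and a data histogram underneath) and the SQR
#' diagnostic of the central model with its typicality envelope.
#'
#' @param x a `"memde"` object.
#' @param which subset of `1:2` selecting the panels.
#' @param ... passed to `plot.default` for the density panel.
#' @export
plot.memde <- function(x, which = 1:2, ...) {
  if (length(which) > 1L) {
    op <- graphics::par(mfrow = c(1, length(which)))
    on.exit(graphics::par(op))
  }
  if (1L %in% which) {
    d <- x$density_grid[, x$central]
    graphics::hist(x$data[x$data >= x$window$a & x$data <= x$window$b],
                   breaks = "FD", freq = FALSE, col = "grey90",
                   border = "grey80", main = "Density estimate",
                   xlab = "value", ylim = c(0, max(d) * 1.1))
    graphics::polygon(c(x$grid, rev(x$grid)),
                      c(d - x$spread, rev(d + x$spread)),
                      col = grDevices::adjustcolor("steelblue", 0.3),
                      border = NA)
    graphics::lines(x$grid, d, col = "steelblue4", lwd = 2, ...)
  }
  if (2L %in% which) plot(residuals(x))
  invisible(x)
}
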