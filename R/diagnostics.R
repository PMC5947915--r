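#' Scaled quantile residuals
#'
#' For sorted positions \eqn{U^{(s)}} on \eqn{[0,1]} (typically the data
#' pushed through a fitted CDF), the scaled quantile residual is
#' \deqn{\Delta_s = \sqrt{N+2}\,\big(U^{(s)} - s/(N+1)\big),}
#' plotted against the expected mean position \eqn{\mu = s/(N+1)}.  The
#' \eqn{\sqrt{N+2}} factor makes the residuals sample-size invariant, so
#' plots for different N are directly comparable.  Typical fluctuations lie
#' inside the envelope \eqn{\pm 3.4\sqrt{\mu(1-\mu)}} (over 3 standard
#' deviations, confidence above 99%); residuals outside are flagged as
#' outliers.  For a good fit the residuals fill a comfortable fraction of
#' the envelope at random: a strongly shrunken band signals overfitting, a
#' band pressing on or beyond the envelope signals underfitting, and a
#' regular pattern signals systematic error of the truncated expansion.
#'
#' @param u sorted ascending numeric vector in \eqn{[0,1]}.
#' @return a data frame of class `"memde_sqr"` with columns `s`, `mu`,
#'   `residual` (\eqn{\delta_s}), `scaled` (\eqn{\Delta_s}), `envelope`
#'   (half-width) and `outlier`.
#' @export
sqr <- function(u) {
  if (is.unsorted(u)) stop("'u' must be sorted ascending")
  n <- length(u)
  s <- seq_len(n)
  mu <- s / (n + 1)
  delta <- u - mu
  scaled <- sqrt(n + 2) * delta
  env <- 3.4 * sqrt(mu * (1 - mu))
  structure(data.frame(s = s, mu = mu, residual = delta, scaled = scaled,
                       envelope = env, outlier = abs(scaled) > env),
            class = c("memde_sqr", "data.frame"))
}

#' @export
plot.memde_sqr <- function(x, ...) {
  graphics::plot(x$mu, x$scaled, type = "n", ylim = range(-1.8, 1.8, x$scaled),
                 xlab = expression(mu(s)), ylab = expression(Delta[s]),
                 main = "Scaled quantile residuals", ...)
  graphics::polygon(c(x$mu, rev(x$mu)), c(x$envelope, rev(-x$envelope)),
                    col = "grey90", border = NA)
  graphics::abline(h = 0, col = "grey60")
  graphics::points(x$mu, x$scaled, pch = 16, cex = 0.4,
                   col = ifelse(x$outlier, "red", "black"))
  invisible(x)
}

#' Figure of merit of a fitted model against its input sample
#'
#' A single typicality number on \eqn{(-\infty, 1]} comparing the input
#' sample with samples the fitted model generates.  Ten sorted "reference"
#' samples and 100 sorted "test" samples of the input size are drawn from
#' the model CDF.  Per rank position s:
#' `delta_sample(s)` is the mean absolute difference between the input
#' sample and the test samples, `delta_test(s)` the mean absolute
#' difference between reference and test samples, and per reference r the
#' moments `delta(s, r)` and `sigma(s, r)` of its absolute differences to
#' the test samples.  Each is turned into a per-position score
#' \eqn{1 - |\delta(s,r) - \delta_\cdot(s)| / (2\sigma(s,r))}, averaged
#' over all positions and references to give `FOM_test` (with spread
#' `FOM_sigma`) and `FOM_sample`, and finally
#' \deqn{FOM = 1 - |FOM_{test} - FOM_{sample}| / (2\,FOM_\sigma).}
#' A positive FOM says the input sample looks like a typical draw from the
#' model; above 1/2 indicates an excellent model; a negative value flags a
#' mismatch.
#'
#' @param model a `"maxent_model"` (or a `"memde"` fit, whose central model
#'   and windowed data are used).
#' @param data numeric sample in data units; values outside the model
#'   support are dropped.  Not needed when `model` is a `"memde"` fit.
#' @param seed optional integer seed for the generated samples.
#' @param n_reference,n_test number of reference / test samples (10 / 100).
#' @return an object of class `"memde_fom"`: list with `fom`, `fom_test`,
#'   `fom_sigma`, `fom_sample`, `n`, `n_reference`, `n_test`.
#' @export
fom <- function(model, data = NULL, seed = NULL, n_reference = 10L,
                n_test = 100L) {
  if (inherits(model, "memde")) {
    data <- model$fits[[model$central]]$data_kept
    model <- model$fits[[model$central]]$model
  }
  stopifnot(inherits(model, "maxent_model"), !is.null(data))
  v <- sort(data[data >= model$domain[1] & data <= model$domain[2]])
  n <- length(v)
  .with_seed(seed, {
    refs <- matrix(qmaxent(stats::runif(n * n_reference), model), n)
    refs <- apply(refs, 2L, sort)
    tests <- matrix(qmaxent(stats::runif(n * n_test), model), n)
    tests <- apply(tests, 2L, sort)

    d_sample <- rowMeans(abs(tests - v))
    # per-reference moments over the test samples
    fom_test_sr <- matrix(0, n, n_reference)
    fom_sample_sr <- matrix(0, n, n_reference)
    d_test_acc <- numeric(n)
    dsr <- vector("list", n_reference)
    ssr <- vector("list", n_reference)
    for (r in seq_len(n_reference)) {
      diffs <- abs(tests - refs[, r])
      dsr[[r]] <- rowMeans(diffs)
      ssr[[r]] <- sqrt(rowMeans(diffs^2) - dsr[[r]]^2) *
        sqrt(n_test / (n_test - 1))
      d_test_acc <- d_test_acc + dsr[[r]]
    }
    d_test <- d_test_acc / n_reference
    for (r in seq_len(n_reference)) {
      s0 <- ssr[[r]]
      if (any(s0 <= 0)) return(structure(list(
        fom = NA_real_, fom_test = NA_real_, fom_sigma = 0,
        fom_sample = NA_real_, n = n, n_reference = n_reference,
        n_test = n_test,
        note = "undefined: degenerate per-position spread"),
        class = "memde_fom"))
      fom_test_sr[, r] <- 1 - abs(dsr[[r]] - d_test) / (2 * s0)
      fom_sample_sr[, r] <- 1 - abs(dsr[[r]] - d_sample) / (2 * s0)
    }
    fom_test <- mean(fom_test_sr)
    fom_sigma <- stats::sd(as.vector(fom_test_sr))
    fom_sample <- mean(fom_sample_sr)
    structure(list(fom = 1 - abs(fom_test - fom_sample) / (2 * fom_sigma),
                   fom_test = fom_test, fom_sigma = fom_sigma,
                   fom_sample = fom_sample, n = n,
                   n_reference = n_reference, n_test = n_test),
              class = "memde_fom")
  })
}

#' @export
print.memde_fom <- function(x, ...) {
  cat(sprintf("Figure of merit: %.3f  (test %.3f, sample %.3f, sigma %.3f)\n",
              x$fom, x$fom_test, x$fom_sample, x$fom_sigma))
  if (!is.null(x$note)) cat(" ", x$note, "\n")
  invisible(x)
}

#' Two-sample Kolmogorov-Smirnov p-value
#'
#' Thin wrapper around `stats::ks.test` returning the asymptotic p-value of
#' the two-sample statistic; used by the benchmark harness to compare an
#' input sample with a sample generated from the fitted model.
#'
#' @param a,b numeric samples.
#' @return list with `statistic` and `p_value`.
#' @export
ks_two_sample <- function(a, b) {
  stopifnot(length(a) > 0, length(b) > 0)
  k <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  list(statistic = unname(k$statistic), p_value = unname(k$p.value))
}

#' Kullback-Leibler distance between two densities on a window
#'
#' Computes \eqn{\int_a^b p(v) \ln[p(v)/q(v)]\, dv} by composite Simpson
#' quadrature, with the reference density `p` renormalized on the window
#' (as needed when the window censors part of its support).  A nonpositive
#' `q` anywhere on the grid where `p > 0` yields `Inf`.
#'
#' @param p_true,p_est vectorized density functions (reference, estimate).
#' @param window numeric `c(a, b)` or a `"censor_window"`.
#' @param n_grid odd quadrature grid size; default 8193.
#' @return nonnegative scalar (nats).
#' @export
kl_divergence <- function(p_true, p_est, window, n_grid = 8193L) {
  if (inherits(window, "censor_window")) window <- c(window$a, window$b)
  n <- as.integer(n_grid); if (n %% 2L == 0L) n <- n + 1L
  v <- seq(window[1], window[2], length.out = n)
  h <- (window[2] - window[1]) / (n - 1)
  w <- rep(c(2, 4), length.out = n); w[c(1L, n)] <- 1
  p <- p_true(v); q <- p_est(v)
  if (any(p < 0) || any(!is.finite(p))) stop("'p_true' must be finite and nonnegative")
  zp <- sum(w * p) * h / 3
  p <- p / zp
  if (any(q <= 0 & p > 0)) return(Inf)
  integrand <- ifelse(p > 0, p * log(p / q), 0)
  sum(w * integrand) * h / 3
}
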