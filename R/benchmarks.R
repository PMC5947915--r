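#' Benchmark test distributions
#'
#' Closed-form test densities covering qualitatively difficult features,
#' each with its quantile function for inverse-transform sampling:
#' \describe{
#'   \item{`gamma_half`}{\eqn{p(v) = e^{-v}/\sqrt{\pi v}} on \eqn{(0,\infty)}
#'     — a Gamma(1/2, 1) density with a square-root singularity at the
#'     origin.  Its CDF is \eqn{\mathrm{erf}(\sqrt v)}, so the quantile uses
#'     the exact inverse (via `qgamma`) rather than root-finding.}
#'   \item{`two_gaussian`}{\eqn{0.7\,N(5, \sigma^2{=}3) + 0.3\,N(0,
#'     \sigma^2{=}1/2)} — a broad mode with a small sharp shoulder
#'     protruding from its side; two resolution scales.  (The second
#'     parameters are variances: with standard deviations 3 and 0.5 the
#'     "shoulder" would be a spike three times taller than the main mode.)}
#'   \item{`five_fingers`}{\eqn{w \sum_{k=1}^5 \frac15 N((2k-1)/10, 0.01) +
#'     (1-w)} on \eqn{[0,1]} with `w = 0.5` — five very sharp peaks on a
#'     uniform background.  The Gaussians are so narrow that treating the
#'     support as exactly \eqn{[0,1]} needs no renormalization.}
#'   \item{`cauchy`}{scale \eqn{b = 1/2} — a heavy-tailed distribution with
#'     no finite moments, exercising the censor window.}
#'   \item{`discontinuous`}{piecewise-constant on \eqn{[0,1]}: 4/5 for
#'     \eqn{v < 0.3} or \eqn{v > 0.8}, 1 for \eqn{0.4 < v < 0.5}, and 5/4
#'     otherwise.}
#' }
#'
#' @param name one of `"gamma_half"`, `"two_gaussian"`, `"five_fingers"`,
#'   `"cauchy"`, `"discontinuous"`.
#' @param w mixture weight of the finger component (five_fingers only).
#' @return an object of class `"memde_benchmark"`: list with `name`, `pdf`,
#'   `cdf`, `quantile` (all vectorized), `support`, and `bounded` (whether
#'   the support is finite and should be passed as known bounds).
#' @examples
#' d <- benchmark_distribution("cauchy")
#' d$quantile(0.5)   # 0
#' @export
benchmark_distribution <- function(name = c("gamma_half", "two_gaussian",
                                            "five_fingers", "cauchy",
                                            "discontinuous"), w = 0.5) {
  name <- match.arg(name)
  out <- switch(name,
    gamma_half = list(
      pdf = function(v) ifelse(v > 0, exp(-v) / sqrt(pi * pmax(v, 1e-300)), 0),
      cdf = function(v) stats::pgamma(v, 0.5, 1),
      quantile = function(u) stats::qgamma(u, 0.5, 1),
      support = c(0, Inf), bounded = FALSE),
    two_gaussian = {
      s1 <- sqrt(3); s2 <- sqrt(0.5)
      cdf <- function(v) 0.7 * stats::pnorm(v, 5, s1) + 0.3 * stats::pnorm(v, 0, s2)
      list(
        pdf = function(v) 0.7 * stats::dnorm(v, 5, s1) + 0.3 * stats::dnorm(v, 0, s2),
        cdf = cdf,
        quantile = .invert_cdf(cdf, c(-20, 30)),
        support = c(-Inf, Inf), bounded = FALSE)
    },
    five_fingers = {
      mu <- (2 * (1:5) - 1) / 10
      pdf <- function(v) {
        peaks <- Reduce(`+`, lapply(mu, function(m) stats::dnorm(v, m, 0.01))) / 5
        ifelse(v >= 0 & v <= 1, w * peaks + (1 - w), 0)
      }
      cdf <- function(v) {
        peaks <- Reduce(`+`, lapply(mu, function(m) stats::pnorm(v, m, 0.01))) / 5
        pmin(pmax(w * peaks + (1 - w) * v, 0), 1)
      }
      list(pdf = pdf, cdf = cdf, quantile = .invert_cdf(cdf, c(0, 1)),
           support = c(0, 1), bounded = TRUE)
    },
    cauchy = list(
      pdf = function(v) stats::dcauchy(v, 0, 0.5),
      cdf = function(v) stats::pcauchy(v, 0, 0.5),
      quantile = function(u) stats::qcauchy(u, 0, 0.5),
      support = c(-Inf, Inf), bounded = FALSE),
    discontinuous = {
      pdf <- function(v) ifelse(v < 0 | v > 1, 0,
               ifelse(v < 0.3 | v > 0.8, 0.8, ifelse(v > 0.4 & v < 0.5, 1, 1.25)))
      brk <- c(0, 0.3, 0.4, 0.5, 0.8, 1)
      lev <- c(0.8, 1.25, 1, 1.25, 0.8)
      cum <- c(0, cumsum(lev * diff(brk)))
      cdf <- function(v) {
        i <- pmin(pmax(findInterval(v, brk), 1), 5)
        pmin(pmax(cum[i] + lev[i] * (v - brk[i]), 0), 1)
      }
      quantile <- function(u) {
        i <- pmin(pmax(findInterval(u, cum), 1), 5)
        brk[i] + (u - cum[i]) / lev[i]
      }
      list(pdf = pdf, cdf = cdf, quantile = quantile,
           support = c(0, 1), bounded = TRUE)
    })
  structure(c(list(name = name), out), class = "memde_benchmark")
}

# Vectorized numerical inverse of a strictly increasing CDF on a bracket:
# dense monotone interpolation refined by a few Newton-bisection steps.
.invert_cdf <- function(cdf, bracket, n_grid = 4097L) {
  v <- seq(bracket[1], bracket[2], length.out = n_grid)
  p <- cdf(v)
  keep <- c(TRUE, diff(p) > 0)
  v <- v[keep]; p <- p[keep]
  function(u) {
    stopifnot(all(u >= 0 & u <= 1))
    x <- stats::approx(p, v, xout = pmin(pmax(u, p[1]), p[length(p)]),
                       rule = 2)$y
    lo <- rep(bracket[1], length(u)); hi <- rep(bracket[2], length(u))
    for (it in 1:60) {
      f <- cdf(x) - u
      lo[f <= 0] <- x[f <= 0]
      hi[f > 0] <- x[f > 0]
      x2 <- (lo + hi) / 2
      if (max(abs(x2 - x)) < 1e-12 * diff(bracket)) { x <- x2; break }
      x <- x2
    }
    x
  }
}

#' Sample a benchmark distribution by the quantile transform
#'
#' Draws `n` seeded uniform variates and pushes them through the
#' distribution's quantile function, the same mechanism used by the
#' published benchmarks.
#'
#' @param dist a `"memde_benchmark"`.
#' @param n sample size.
#' @param seed optional integer seed.
#' @return numeric vector of length `n`.
#' @export
sample_benchmark <- function(dist, n, seed = NULL) {
  stopifnot(inherits(dist, "memde_benchmark"), n >= 1)
  .with_seed(seed, dist$quantile(stats::runif(n)))
}

#' Benchmark harness
#'
#' Reproduces the structure of the published benchmark tables: for each
#' sample size, `samples_per_size` independent samples are drawn, each is
#' fit with a `models_per_sample` ensemble, and five quality metrics of the
#' central model are recorded — the two-sample KS p-value between the input
#' sample and a model-generated sample, the KL distance to the true density
#' (renormalized on the fit window), the figure of merit, the SURD
#' coverage, and the number of Lagrange multipliers.
#'
#' @param dist a `"memde_benchmark"`.
#' @param sizes integer vector of sample sizes.
#' @param samples_per_size independent samples per size (default 4).
#' @param models_per_sample ensemble size per sample (default 5).
#' @param control a [memde_control()] list.
#' @param score_table a `"surd_score_table"`.
#' @param seed integer seed; sample and fit seeds are derived from it.
#' @return data frame with columns `size`, `sample`, `ks_p`, `kl`, `fom`,
#'   `coverage`, `n_lagrange`, `success` (per-sample rows, unsorted).
#' @export
run_benchmark <- function(dist, sizes, samples_per_size = 4L,
                          models_per_sample = 5L,
                          control = memde_control(),
                          score_table = default_score_table(), seed = 1L) {
  seeds <- .with_seed(seed, matrix(sample.int(2147483646L,
                                              2 * length(sizes) * samples_per_size),
                                   ncol = 2))
  rows <- list()
  k <- 0L
  for (n in sizes) for (j in seq_len(samples_per_size)) {
    k <- k + 1L
    v <- sample_benchmark(dist, n, seed = seeds[k, 1])
    row <- tryCatch({
      fit <- memde(v, bounds = if (dist$bounded) dist$support else NULL,
                   models = models_per_sample, control = control,
                   score_table = score_table, seed = seeds[k, 2])
      f <- fit$fits[[fit$central]]
      gen <- .with_seed(seeds[k, 2] %% 2000000000L + 1L,
                        rmaxent(n, f$model))
      data.frame(size = n, sample = j,
                 ks_p = ks_two_sample(f$data_kept, gen)$p_value,
                 kl = kl_divergence(dist$pdf,
                                    function(v) dmaxent(v, f$model),
                                    f$window),
                 fom = fom(fit, seed = seeds[k, 2])$fom,
                 coverage = f$coverage, n_lagrange = f$n_lagrange,
                 success = f$success)
    }, error = function(e)
      data.frame(size = n, sample = j, ks_p = NA, kl = NA, fom = NA,
                 coverage = NA, n_lagrange = NA, success = FALSE))
    rows[[k]] <- row
  }
  do.call(rbind, rows)
}
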