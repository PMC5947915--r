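#' Single order statistics of uniform samples
#'
#' For `n` i.i.d. uniform draws on \eqn{[0,1]}, the s-th smallest value
#' follows a Beta(s, n + 1 - s) law with density
#' \deqn{p_s(u \mid n) = \frac{n!}{(n-s)!\,(s-1)!} (1-u)^{n-s} u^{s-1}.}
#' `sos_density` evaluates it (through `stats::dbeta`, i.e. log-gamma
#' arithmetic); `sos_moments` returns the mean position
#' \eqn{\mu = s/(n+1)} and the standard deviation
#' \eqn{\sigma = \sqrt{\mu(1-\mu)/(n+2)}} characterizing typical
#' fluctuations about it.
#'
#' @param u numeric vector in \eqn{[0,1]}.
#' @param s integer rank(s), `1 <= s <= n`.
#' @param n integer sample size.
#' @param log logical; return the log density?
#' @return `sos_density`: numeric vector of density values.
#'   `sos_moments`: data frame with columns `s`, `n`, `mu`, `sigma`.
#' @examples
#' sos_density(0.5, s = 2, n = 3)   # 6 * 0.5 * 0.5 = 1.5
#' sos_moments(2, 3)                # mu = 0.5, sigma = sqrt(0.05)
#' @export
sos_density <- function(u, s, n, log = FALSE) {
  if (any(u < 0 | u > 1, na.rm = TRUE)) stop("'u' must lie in [0, 1]")
  stopifnot(all(s >= 1), all(s <= n))
  stats::dbeta(u, s, n + 1 - s, log = log)
}

#' @rdname sos_density
#' @export
sos_moments <- function(s, n) {
  stopifnot(all(s >= 1), all(s <= n))
  mu <- s / (n + 1)
  data.frame(s = s, n = n, mu = mu, sigma = sqrt(mu * (1 - mu) / (n + 2)))
}

# Per-rank coefficients of the log product measure.  'ranks' are positions
# in the FULL sorted sample of size n_full; a hierarchy subset keeps its
# full-sample ranks (the per-rank terms are self-averaging, so a uniformly
# spaced subsample of them estimates the full mean without bias).  Kept
# separate so the fit loop can precompute them once per subset.
.surd_coef <- function(ranks, n_full) {
  np <- length(ranks)
  list(a = ranks - 1, b = n_full - ranks,
       const = sum(lgamma(n_full + 1) - lgamma(n_full - ranks + 1) -
                     lgamma(ranks)) / np,
       offset = 0.5 * log(n_full))
}

.surd_L <- function(u, coef) {
  u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
  coef$const + (sum(coef$b * log1p(-u)) + sum(coef$a * log(u))) / length(u) -
    coef$offset
}

#' Quasi-log-likelihood of sorted uniform positions
#'
#' The scoring function of the estimator: for the sorted positions
#' \eqn{U^{(s)}} of a sample of size \eqn{N},
#' \deqn{L = \frac{1}{N} \sum_{s=1}^{N} \ln p_s(U^{(s)} \mid N)
#'       - \tfrac{1}{2}\ln N,}
#' where \eqn{p_s} is the single-order-statistic density.  The product
#' measure is never formed: all arithmetic is in the log domain, and
#' positions are clamped to \eqn{[10^{-12}, 1-10^{-12}]} so a saturated
#' trial CDF yields a finite (very poor) score.  For true uniform data
#' \eqn{L} is nearly independent of sample size, which makes it a universal
#' typicality scale.
#'
#' Under hierarchical data augmentation only a uniformly spaced (by sort
#' index) subset of the terms is evaluated.  Each subset point keeps its
#' *full-sample* rank: the per-rank terms all share the same expectation
#' (the sum is self-averaging), so averaging \eqn{N_p < N} of them — with
#' `ranks` giving the full-sample sort indices and `n_full = N` — estimates
#' the full score without bias.
#'
#' @param u sorted ascending numeric vector in \eqn{[0,1]} (the full sorted
#'   sample, or a sort-index subset of it).
#' @param n_full full sample size \eqn{N}; defaults to `length(u)`.
#' @param ranks integer full-sample sort indices of the entries of `u`;
#'   defaults to `seq_along(u)` (no subsetting).
#' @return scalar score `L`.
#' @examples
#' surd_loglik(c(1, 2) / 3)  # 0.5*log(16/9) - 0.5*log(2)
#' @export
surd_loglik <- function(u, n_full = length(u), ranks = seq_along(u)) {
  if (is.unsorted(u)) stop("'u' must be sorted ascending")
  if (any(u < 0 | u > 1)) stop("'u' must lie in [0, 1]")
  stopifnot(length(ranks) == length(u), all(ranks >= 1), all(ranks <= n_full),
            !is.unsorted(ranks))
  .surd_L(u, .surd_coef(as.numeric(ranks), n_full))
}

#' Boundary penalty for the search score
#'
#' A penalty subtracted from the quasi-log-likelihood during the random
#' search, based on deviations of the outermost 0.5% of sorted positions
#' from their expected means at each boundary:
#' \deqn{\ln\!\Big[1 + \frac{0.1}{p}\sum_{i=1}^{p}\big|U^{(i)} -
#'   \tfrac{i}{N+1}\big| + \frac{0.1}{p}\sum_{j=N-p}^{N}\big|U^{(j)} -
#'   \tfrac{j}{N+1}\big|\Big], \qquad p = \lfloor 0.005\,N \rfloor.}
#' The upper sum spans the `p + 1` indices `N-p, ..., N` (as defined).  It
#' guides the search strongly when the coefficients are far from converged
#' and has virtually no effect on good solutions; it returns 0 when
#' `p == 0` (N < 200).  The reported score of a fit is the unpenalized
#' likelihood.
#'
#' @param u sorted ascending numeric vector in \eqn{[0,1]}.
#' @return nonnegative scalar.
#' @export
surd_penalty <- function(u) {
  if (is.unsorted(u)) stop("'u' must be sorted ascending")
  n <- length(u)
  p <- floor(n * 0.005)
  if (p < 1) return(0)
  mu <- seq_len(n) / (n + 1)
  lo <- sum(abs(u[1:p] - mu[1:p]))
  hi <- sum(abs(u[(n - p):n] - mu[(n - p):n]))
  log1p(0.1 / p * lo + 0.1 / p * hi)
}

#' Build the universal SURD score table
#'
#' Simulates sampled uniform random data (SURD), computes the
#' quasi-log-likelihood `L` of each sorted sample, pools the scores across
#' sample sizes with equal weight, and stores the empirical CDF of `L`.
#' The percentile of a score in this distribution is its *SURD coverage*:
#' an absolute, problem-independent typicality scale (the distribution of
#' `L` is nearly sample-size invariant, which is what makes pooling across
#' sizes meaningful).
#'
#' The empirical CDF is compressed to `n_knots` quantile knots, which is
#' what gets interpolated by [surd_coverage()] and serialized by
#' [write_score_table()].  A precomputed default table (sizes
#' \eqn{2^8, 2^{10}, \dots, 2^{16}}, \eqn{10^4} replicates per size) ships
#' with the package; see [default_score_table()].
#'
#' @param sizes integer vector of SURD sample sizes.
#' @param replicates integer, simulated samples per size.
#' @param seed integer RNG seed.
#' @param n_knots number of quantile knots retained.
#' @return object of class `"surd_score_table"`: list with `L` (knot
#'   scores), `coverage` (knot probabilities), `sizes`, `replicates`,
#'   `seed`.
#' @export
build_score_table <- function(sizes = 2^c(8, 10, 12, 14, 16),
                              replicates = 1e4, seed = 1L,
                              n_knots = 2001L) {
  scores <- .with_seed(seed, {
    unlist(lapply(sizes, function(n) {
      cf <- .surd_coef(seq_len(n), n)
      vapply(seq_len(replicates), function(r)
        .surd_L(sort.int(stats::runif(n), method = "quick"), cf), 0)
    }))
  })
  p <- seq(0, 1, length.out = n_knots)
  structure(list(L = unname(stats::quantile(scores, p, type = 7)),
                 coverage = p, sizes = sizes,
                 replicates = replicates, seed = seed),
            class = "surd_score_table")
}

#' SURD coverage of a score
#'
#' Maps a quasi-log-likelihood value to its percentile within the empirical
#' SURD score distribution by monotone interpolation of the tabulated CDF;
#' scores below/above the tabulated range clamp to 0/1.
#'
#' @param table a `"surd_score_table"`.
#' @param L numeric vector of scores.
#' @return numeric vector of coverages in \eqn{[0,1]}.
#' @export
surd_coverage <- function(table, L) {
  stopifnot(inherits(table, "surd_score_table"))
  keep <- c(TRUE, diff(table$L) > 0)
  stats::approx(table$L[keep], table$coverage[keep], xout = L,
                yleft = 0, yright = 1, rule = 2)$y
}

#' @export
print.surd_score_table <- function(x, ...) {
  cat("SURD score table\n")
  cat("  sizes     :", paste(x$sizes, collapse = " "), "\n")
  cat(sprintf("  replicates: %d per size, seed %d\n", x$replicates, x$seed))
  cat(sprintf("  L range   : [%.3f, %.3f]\n", min(x$L), max(x$L)))
  invisible(x)
}

#' Read and write SURD score tables
#'
#' Two tab-separated columns (`L`, `coverage`) preceded by `#` metadata
#' lines recording the simulated sizes, replicates per size and seed.
#'
#' @param table a `"surd_score_table"`.
#' @param path file path.
#' @export
write_score_table <- function(table, path) {
  stopifnot(inherits(table, "surd_score_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# memde surd_score_table",
    paste0("# sizes\t", paste(table$sizes, collapse = "\t")),
    sprintf("# replicates\t%d", table$replicates),
    sprintf("# seed\t%d", table$seed),
    "L\tcoverage",
    sprintf("%.10g\t%.10g", table$L, table$coverage)), con)
  invisible(path)
}

#' @rdname write_score_table
#' @export
read_score_table <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  field <- function(key) {
    ln <- grep(paste0("^# ", key), meta, value = TRUE)
    as.numeric(strsplit(ln, "\t")[[1]][-1])
  }
  body <- lines[!grepl("^#", lines)][-1L]
  m <- do.call(rbind, lapply(strsplit(body, "\t"), as.numeric))
  structure(list(L = m[, 1], coverage = m[, 2], sizes = field("sizes"),
                 replicates = field("replicates"), seed = field("seed")),
            class = "surd_score_table")
}

#' The packaged default score table
#'
#' Loads the precomputed SURD score table shipped with the package
#' (sizes \eqn{2^8, 2^{10}, 2^{12}, 2^{14}, 2^{16}}, \eqn{10^4} replicates
#' per size, fixed seed; regenerable with `scripts/make_score_table.R`).
#' The result is cached for the session.
#'
#' @return a `"surd_score_table"`.
#' @export
default_score_table <- function() {
  if (is.null(.memde_cache$table)) {
    path <- system.file("extdata", "surd_score_table.tsv", package = "memde",
                        mustWork = TRUE)
    .memde_cache$table <- read_score_table(path)
  }
  .memde_cache$table
}

.memde_cache <- new.env(parent = emptyenv())

# Evaluate 'expr' under a temporary RNG seed, restoring the caller's state.
.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else suppressWarnings(rm(".Random.seed", envir = globalenv())))
    set.seed(seed)
  }
  expr
}
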