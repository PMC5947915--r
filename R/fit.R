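#' Control parameters for the density fit
#'
#' Collects the tunable parameters of the funnel-diffusion random search.
#' Defaults follow the published algorithm: the search stops as soon as the
#' trial density's score reaches `target_coverage` (40% SURD coverage), a
#' terminated search is still accepted if it reaches `min_coverage` (5%),
#' Gaussian trial steps start at standard deviation `sigma0` and the funnel
#' contracts by `sigma_decay` per stage down to `sigma_min`, with `loop_max`
#' trials per stage.  Lagrange multipliers are added two at a time until
#' `max_lagrange` or until the score has improved by less than
#' `stall_improvement` (relative) over `stall_additions` consecutive
#' additions.
#'
#' @param target_coverage target SURD coverage in (0,1); default 0.40.
#' @param min_coverage minimum acceptable coverage on termination; default 0.05.
#' @param sigma0 initial Gaussian step standard deviation; default 0.1.
#' @param sigma_min smallest step standard deviation; default 0.001.
#' @param sigma_decay multiplicative funnel contraction per stage in (0,1);
#'   default 0.5.
#' @param loop_max trials per funnel stage; default 100.
#' @param max_lagrange maximum number of Lagrange multipliers (including the
#'   normalization constant); default 300.
#' @param stall_improvement minimum relative score improvement per
#'   multiplier addition; default 0.01.
#' @param stall_additions consecutive stalled additions tolerated; default 3.
#' @param n_grid quadrature grid size used inside the search; default 1025.
#' @return a list of class `"memde_control"`.
#' @export
memde_control <- function(target_coverage = 0.40, min_coverage = 0.05,
                          sigma0 = 0.1, sigma_min = 0.001, sigma_decay = 0.5,
                          loop_max = 100L, max_lagrange = 300L,
                          stall_improvement = 0.01, stall_additions = 3L,
                          n_grid = 1025L) {
  stopifnot(0 < min_coverage, min_coverage <= target_coverage,
            target_coverage < 1, sigma_min < sigma0, sigma_min > 0,
            0 < sigma_decay, sigma_decay < 1, loop_max >= 1,
            max_lagrange >= 1, stall_improvement > 0, stall_additions >= 1)
  structure(list(target_coverage = target_coverage,
                 min_coverage = min_coverage, sigma0 = sigma0,
                 sigma_min = sigma_min, sigma_decay = sigma_decay,
                 loop_max = as.integer(loop_max),
                 max_lagrange = as.integer(max_lagrange),
                 stall_improvement = stall_improvement,
                 stall_additions = as.integer(stall_additions),
                 n_grid = as.integer(n_grid)),
            class = "memde_control")
}

#' Hierarchical data-augmentation subsets
#'
#' Index subsets used to fit large samples hierarchically.  Sorted data
#' carries global shape information in any uniformly spaced (by sort index)
#' subset, so the search starts on a base subset of 1,025 points and then
#' refines on nested subsets of \eqn{2^k + 1} points — each level inserting
#' sort-index midpoints — ending with the full sample.  Samples of at most
#' 1,025 points are used whole.
#'
#' @param n integer sample size.
#' @return list of strictly increasing integer index vectors, each nested in
#'   the next.
#' @examples
#' lengths(hierarchical_subsets(5000))  # 1025 2049 4097 5000
#' @export
hierarchical_subsets <- function(n) {
  stopifnot(n >= 1)
  if (n <= 1025L) return(list(seq_len(n)))
  ks <- 10L:floor(log2(n - 2))           # sizes 2^k + 1 < n
  subs <- lapply(ks, function(k) unique(1L + round((n - 1) * (0:(2^k)) / 2^k)))
  c(subs, list(seq_len(n)))
}

#' Gaussian perturbation of Lagrange multipliers
#'
#' One funnel-diffusion trial step: every shape coefficient
#' (`lambda[2]` onward) receives an independent Gaussian increment of
#' standard deviation `sigma`.  The normalization constant `lambda[1]` is
#' not perturbed — it is recomputed from the normalization whenever the
#' model is rebuilt.
#'
#' @param lambda numeric coefficient vector `c(lambda0, lambda1, ...)`.
#' @param sigma nonnegative step standard deviation.
#' @return perturbed coefficient vector.
#' @export
perturb_lambdas <- function(lambda, sigma) {
  stopifnot(sigma >= 0)
  if (length(lambda) > 1L)
    lambda[-1L] <- lambda[-1L] + stats::rnorm(length(lambda) - 1L, 0, sigma)
  lambda
}

#' Fit one maximum-entropy density model
#'
#' Runs the full single-model pipeline: censor windowing, linear mapping to
#' \eqn{[-1,1]}, a uniform-model check (uniform data is accepted immediately
#' with a single multiplier), and the funnel-diffusion random search with
#' hierarchical data augmentation.  Within each hierarchy subset the search
#' alternates funnel stages of shrinking Gaussian steps with additions of
#' two Lagrange multipliers (initialized to zero, funnel re-opened) until
#' the score reaches the target SURD coverage; the coefficients then warm
#' start the next, larger subset.  A trial step is accepted only if the
#' penalized score strictly improves; the reported score and coverage are
#' unpenalized.  If the search terminates without reaching the target
#' (multiplier budget exhausted or stalled score), the fit is still a
#' success if its coverage reaches `control$min_coverage`; otherwise it is
#' flagged as a failure and returned with full diagnostics.
#'
#' @param x numeric sample (at least 2 finite observations).
#' @param bounds optional known support bounds `c(a, b)`; bypasses the
#'   censor-window heuristics.
#' @param outlier_c outlier multiplier for the censor window; default 7.
#' @param control a [memde_control()] list.
#' @param score_table a `"surd_score_table"`; defaults to the packaged one.
#' @param seed optional integer seed for the search RNG.
#' @return an object of class `"memde_fit"`: list with `model`
#'   (a [maxent_model()]), `L`, `coverage`, `success`, `n_lagrange`,
#'   `trace` (accepted-step log), `subset_sizes`, `window`, `u`
#'   (final probability-integral transform of the kept data), `data_kept`.
#' @seealso [memde()] for the ensemble front end.
#' @export
memde_one <- function(x, bounds = NULL, outlier_c = 7,
                      control = memde_control(),
                      score_table = default_score_table(), seed = NULL) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) stop("need at least 2 finite observations")
  window <- censor_window(x, c = outlier_c, bounds = bounds)
  .with_seed(seed, .memde_search(x, window, control, score_table))
}

# The search proper, run under the caller's RNG state.
.memde_search <- function(x, window, ctl, tab) {
  xs <- sort(linear_map(window, x))
  n <- length(xs)
  G <- ctl$n_grid
  # Chebyshev-extrema quadrature nodes: clustered at the window edges,
  # where exponents of high-order models vary fastest
  xg <- -cos(pi * (0:(G - 1)) / (G - 1))
  dxg <- diff(xg)
  subs <- hierarchical_subsets(n)

  # per-subset precomputation: grid positions of the data, score coefs
  # (subset points keep their full-sample ranks) and boundary-penalty terms
  prep <- lapply(subs, function(idx) {
    xp <- xs[idx]
    i0 <- pmin(pmax(findInterval(xp, xg), 1L), G - 1L)
    np <- length(idx)
    p <- floor(np * 0.005)
    list(np = np, i0 = as.integer(i0), w = (xp - xg[i0]) / dxg[i0],
         coef = .surd_coef(as.numeric(idx), n),
         pen_p = p,
         mu_lo = idx[seq_len(p)] / (n + 1),
         mu_hi = idx[seq.int(np - p, np)] / (n + 1))
  })

  # trial evaluation: unnormalized exponent -> (L, penalty) on subset k
  basis <- matrix(numeric(0), G, 0)
  grow_basis <- function(d) {
    while (ncol(basis) < d) {
      j <- ncol(basis)
      col <- if (j == 0L) xg
        else if (j == 1L) 2 * xg * basis[, 1L] - 1
        else 2 * xg * basis[, j] - basis[, j - 1L]
      basis <<- cbind(basis, col, deparse.level = 0)
    }
  }
  eval_trial <- function(theta, pp) {
    S <- if (length(theta)) drop(basis[, seq_along(theta), drop = FALSE] %*% theta)
         else numeric(G)
    e <- exp(pmin(S - max(S), 700))
    ct <- c(0, cumsum((e[-1L] + e[-G]) * dxg * 0.5))
    cdf <- ct / ct[G]
    u <- cdf[pp$i0] * (1 - pp$w) + cdf[pp$i0 + 1L] * pp$w
    u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
    L <- pp$coef$const +
      (sum(pp$coef$b * log1p(-u)) + sum(pp$coef$a * log(u))) / pp$np -
      pp$coef$offset
    np <- pp$np
    p <- pp$pen_p
    pen <- if (p < 1) 0 else
      log1p(0.1 / p * sum(abs(u[seq_len(p)] - pp$mu_lo)) +
            0.1 / p * sum(abs(u[seq.int(np - p, np)] - pp$mu_hi)))
    c(L = L, pen = pen)
  }

  trace <- list()
  note <- function(stage, nlam, sigma, L, pen, cov)
    trace[[length(trace) + 1L]] <<- data.frame(
      subset = stage, n_lagrange = nlam, sigma = sigma,
      L = L, penalized = L - pen, coverage = cov)

  # uniform-model check on the full sample (identity CDF on the window)
  pfull <- prep[[length(prep)]]
  u0 <- pmin(pmax((xs + 1) / 2, 1e-12), 1 - 1e-12)
  L0 <- .surd_L(u0, pfull$coef)
  cov0 <- surd_coverage(tab, L0)
  note(0L, 1L, NA_real_, L0, surd_penalty(u0), cov0)
  if (cov0 >= ctl$target_coverage)
    return(.memde_result(numeric(0), window, ctl, tab, xs, x, trace,
                         success = TRUE, lengths(subs)))

  theta <- 0                               # first shape multiplier, zero
  stalled <- FALSE
  for (k in seq_along(subs)) {
    pp <- prep[[k]]
    grow_basis(length(theta))
    cur <- eval_trial(theta, pp)
    best_after_add <- cur[["L"]]
    n_stall <- 0L
    if (surd_coverage(tab, cur[["L"]]) >= ctl$target_coverage) next
    repeat {
      # one full funnel at the current dimension
      sigma <- ctl$sigma0
      hit <- FALSE
      while (sigma >= ctl$sigma_min && !hit) {
        # a stage ends after loop_max rejected trials; accepted steps do
        # not count against the budget, so the walker keeps diffusing at
        # this step size for as long as it improves and the funnel
        # contracts only once progress at this scale is exhausted
        fails <- 0L
        while (fails < ctl$loop_max) {
          cand <- theta + stats::rnorm(length(theta), 0, sigma)
          val <- eval_trial(cand, pp)
          if (val[["L"]] - val[["pen"]] > cur[["L"]] - cur[["pen"]]) {
            theta <- cand
            cur <- val
            cov <- surd_coverage(tab, cur[["L"]])
            note(k, length(theta) + 1L, sigma, cur[["L"]], cur[["pen"]], cov)
            if (cov >= ctl$target_coverage) { hit <- TRUE; break }
          } else fails <- fails + 1L
        }
        sigma <- sigma * ctl$sigma_decay
      }
      if (hit) break
      # funnel exhausted below target: grow or stop
      rel_gain <- (cur[["L"]] - best_after_add) /
        max(abs(best_after_add), .Machine$double.eps)
      n_stall <- if (rel_gain < ctl$stall_improvement) n_stall + 1L else 0L
      best_after_add <- max(best_after_add, cur[["L"]])
      if (n_stall >= ctl$stall_additions ||
          length(theta) + 3L > ctl$max_lagrange) {
        stalled <- TRUE
        break
      }
      theta <- c(theta, 0, 0)
      grow_basis(length(theta))
      cur <- eval_trial(theta, pp)
    }
    if (stalled) break
  }
  .memde_result(theta, window, ctl, tab, xs, x, trace,
                success = NA, lengths(subs))
}

.memde_result <- function(theta, window, ctl, tab, xs, x, trace, success,
                          subset_sizes) {
  # grid fine enough to resolve the edge lobes of the highest-order basis
  # term (width ~ (pi/D)^2 near +-1 on a uniform grid)
  ng <- 2^ceiling(log2(max(4096, 2 * length(theta)^2))) + 1
  model <- maxent_model(c(0, theta), c(window$a, window$b), n_grid = ng)
  u <- pmaxent(linear_unmap(window, xs), model)
  u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
  L <- surd_loglik(u, length(u))
  coverage <- surd_coverage(tab, L)
  if (is.na(success)) success <- coverage >= ctl$min_coverage
  structure(list(model = model, L = L, coverage = coverage,
                 success = success, n_lagrange = length(theta) + 1L,
                 trace = do.call(rbind, trace),
                 subset_sizes = subset_sizes, window = window,
                 u = u, data_kept = linear_unmap(window, xs)),
            class = "memde_fit")
}

#' @export
print.memde_fit <- function(x, ...) {
  cat(sprintf("memde single fit: %s\n",
              if (x$success) "success" else "FAILURE"))
  cat(sprintf("  L = %.4f  SURD coverage = %.1f%%  multipliers = %d\n",
              x$L, 100 * x$coverage, x$n_lagrange))
  print(x$window)
  invisible(x)
}
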