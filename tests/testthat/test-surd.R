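test_that("single-order-statistic density matches factorial arithmetic", {
  u <- seq(0, 1, 0.1)
  expect_equal(sos_density(u, 1, 1), rep(1, length(u)))
  expect_equal(sos_density(0.5, 2, 3), 1.5)      # 6 * 0.5 * 0.5
  expect_error(sos_density(1.2, 1, 1), "\\[0, 1\\]")
})

test_that("order-statistic moments have the closed form and rank symmetry", {
  m <- sos_moments(1, 1)
  expect_equal(m$mu, 0.5)
  expect_equal(m$sigma, sqrt(1 / 12))
  m2 <- sos_moments(2, 3)
  expect_equal(m2$mu, 0.5)
  expect_equal(m2$sigma, sqrt(0.25 / 5))
  for (n in c(7, 40, 100)) {
    s <- 1:n
    expect_equal(sos_moments(s, n)$mu + sos_moments(n + 1 - s, n)$mu,
                 rep(1, n))
  }
})

test_that("simulated uniform order statistics match the moment formulas", {
  n <- 50; reps <- 2e4
  set.seed(8)
  U <- matrix(runif(n * reps), n)
  U <- apply(U, 2, sort)
  ranks <- c(1, 10, 25, 40, 50)
  for (s in ranks) {
    m <- sos_moments(s, n)
    se_mean <- m$sigma / sqrt(reps)
    expect_lt(abs(mean(U[s, ]) - m$mu), 4 * se_mean)
    se_sd <- m$sigma / sqrt(2 * (reps - 1))    # gaussian approximation
    expect_lt(abs(sd(U[s, ]) - m$sigma), 6 * se_sd)
  }
})

test_that("quasi-log-likelihood matches hand-computed cases", {
  expect_equal(surd_loglik(0.5), 0)
  expect_equal(surd_loglik(c(1, 2) / 3), 0.5 * log(16 / 9) - 0.5 * log(2))
  expect_error(surd_loglik(c(0.7, 0.2)), "sorted")
  # clamping keeps saturated positions finite
  expect_true(is.finite(surd_loglik(c(0, 0.5, 1))))
})

test_that("subset scoring keeps full-sample ranks and offset", {
  # a single retained point at full rank 2048 of N = 4095
  expect_equal(surd_loglik(0.5, n_full = 4095, ranks = 2048),
               dbeta(0.5, 2048, 4095 + 1 - 2048, log = TRUE) -
                 0.5 * log(4095))
  expect_error(surd_loglik(c(0.2, 0.4), n_full = 10, ranks = c(5, 11)))
})

test_that("boundary penalty is zero at the means and below the floor size", {
  n <- 1000
  mu <- (1:n) / (n + 1)
  expect_equal(surd_penalty(mu), 0)
  expect_equal(surd_penalty((1:100) / 101 + 0.001), 0)   # p = 0 below n = 200
  # direct arithmetic: first 5 positions shifted +5e-4, the rest at their means
  u <- mu; u[1:5] <- u[1:5] + 5e-4
  expect_equal(surd_penalty(u), log(1 + (0.1 / 5) * 5 * 5e-4))
  # upper sum spans p + 1 indices N-p..N
  u2 <- mu; u2[995:1000] <- pmin(u2[995:1000] + 5e-4, 1)
  expect_equal(surd_penalty(u2), log1p((0.1 / 5) * sum(abs(u2[995:1000] - mu[995:1000]))))
})

test_that("score table coverage is a monotone CDF with clamped ends", {
  tab <- small_score_table()
  expect_true(all(diff(tab$coverage) >= 0))
  expect_equal(surd_coverage(tab, min(tab$L) - 1), 0)
  expect_equal(surd_coverage(tab, max(tab$L) + 1), 1)
  expect_true(all(diff(surd_coverage(tab, seq(-2, 0.2, 0.01))) >= 0))
  # the pooled mean sits in the central region
  expect_gt(surd_coverage(tab, -0.42), 0.3)
  expect_lt(surd_coverage(tab, -0.42), 0.6)
})

test_that("score table building is deterministic in the seed", {
  t1 <- build_score_table(sizes = 256, replicates = 200, seed = 9)
  t2 <- build_score_table(sizes = 256, replicates = 200, seed = 9)
  expect_identical(t1$L, t2$L)
})

test_that("score table serialization round-trips", {
  tab <- small_score_table()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_score_table(tab, path)
  t2 <- read_score_table(path)
  expect_equal(t2$L, tab$L, tolerance = 1e-9)
  expect_equal(t2$sizes, tab$sizes)
  expect_equal(t2$replicates, tab$replicates)
})

test_that("mean per-sample log product measure is linear in log N with slope 1/2", {
  sizes <- 2^(8:13)
  means <- vapply(seq_along(sizes), function(i)
    surd_mean_L(sizes[i], 1500, seed = 100 + i) + 0.5 * log(sizes[i]), 0)
  fit <- lm(means ~ log(sizes))
  expect_lt(abs(coef(fit)[2] - 0.5), 0.02)
})

test_that("the score distribution collapses across sample sizes", {
  d <- abs(surd_mean_L(2^8, 1e4, seed = 21) - surd_mean_L(2^14, 1e4, seed = 22))
  expect_lt(d, 0.02)
})

test_that("a uniformly spaced subset scores like the full sample in expectation", {
  set.seed(33)
  n <- 4096
  idx <- unique(1L + round((n - 1) * (0:1024) / 1024))
  d <- mean(replicate(300, {
    u <- sort(runif(n))
    surd_loglik(u[idx], n_full = n, ranks = idx) - surd_loglik(u)
  }))
  expect_lt(abs(d), 0.03)
})
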