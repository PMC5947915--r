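test_that("scaled quantile residuals vanish at the expected positions", {
  n <- 500
  mu <- (1:n) / (n + 1)
  s <- sqr(mu)
  expect_equal(s$scaled, rep(0, n))
  expect_equal(s$mu, mu)
  expect_false(any(s$outlier))
})

test_that("the typicality envelope peaks at 1.7 in the center", {
  s <- sqr((1:999) / 1000)
  expect_equal(max(s$envelope), 3.4 * sqrt(0.25), tolerance = 1e-4)
  # envelope is maximal at mu = 0.5 and symmetric
  expect_equal(which.max(s$envelope), 500L)
})

test_that("SURD residuals stay inside the envelope over 99% of the time", {
  set.seed(14)
  n <- 256
  inside <- mean(replicate(1000, {
    s <- sqr(sort(runif(n)))
    mean(!s$outlier)
  }))
  expect_gte(inside, 0.99)
})

test_that("per-rank SURD residual spread matches sqrt(mu(1-mu))", {
  set.seed(15)
  n <- 1024; reps <- 2000
  U <- matrix(runif(n * reps), n)
  U <- apply(U, 2, sort)
  mu <- (1:n) / (n + 1)
  emp_sd <- apply(sqrt(n + 2) * (U - mu), 1, sd)
  ranks <- seq(50, n - 50, by = 100)
  expect_lt(max(abs(emp_sd[ranks] / sqrt(mu[ranks] * (1 - mu[ranks])) - 1)), 0.1)
})

test_that("figure of merit is positive under the null and bounded by one", {
  m <- maxent_model(c(0, 0.3), c(-1, 1))
  set.seed(16)
  x <- rmaxent(2048, m)
  f <- fom(m, x, seed = 17)
  expect_lte(f$fom, 1)
  expect_gt(f$fom, 0)
})

test_that("figure of merit flags a gross model mismatch", {
  uniform <- maxent_model(0, c(-4, 4))
  set.seed(18)
  f <- fom(uniform, rnorm(2048), seed = 18)
  expect_lt(f$fom, 0)
})

test_that("figure of merit depends only on sorted values", {
  m <- maxent_model(c(0, 0.2), c(-1, 1))
  set.seed(19)
  x <- rmaxent(512, m)
  f1 <- fom(m, x, seed = 20)
  f2 <- fom(m, sample(x), seed = 20)
  expect_equal(f1$fom, f2$fom)
})

test_that("two-sample KS wrapper returns the standard statistic", {
  x <- c(1, 2, 3, 4, 5)
  k <- ks_two_sample(x, x)
  expect_equal(k$statistic, 0)
  expect_equal(k$p_value, 1)
  k2 <- ks_two_sample(1:100 / 101, 1:100 / 101 + 10)
  expect_equal(k2$statistic, 1)
  set.seed(21)
  k3 <- ks_two_sample(runif(500), runif(500))
  expect_gt(k3$p_value, 0.001)
})

test_that("KL distance matches the Gaussian closed form and is asymmetric", {
  p <- function(v) dnorm(v, 0, 1)
  q <- function(v) dnorm(v, 0.1, 1)
  expect_equal(kl_divergence(p, p, c(-8, 8)), 0, tolerance = 1e-10)
  expect_equal(kl_divergence(p, q, c(-10, 10)), 0.005, tolerance = 1e-4)
  q2 <- function(v) dnorm(v, 0, 2)
  expect_false(isTRUE(all.equal(kl_divergence(p, q2, c(-10, 10)),
                                kl_divergence(q2, p, c(-10, 10)))))
})

test_that("KL distance renormalizes the reference on the window", {
  # truth restricted to half its support: still a proper distance to itself
  p <- function(v) dnorm(v)
  expect_equal(kl_divergence(p, function(v) dnorm(v) / pnorm(1), c(-8, 1)),
               0, tolerance = 1e-8)
})
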