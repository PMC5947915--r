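test_that("uniform model (no shape coefficients) is the normalized constant density", {
  m <- maxent_model(0, c(-1, 1))
  x <- seq(-1, 1, length.out = 11)
  expect_equal(dmaxent(x, m), rep(0.5, 11))
  expect_equal(pmaxent(0, m), 0.5, tolerance = 1e-8)
  expect_equal(qmaxent(0.5, m), 0, tolerance = 1e-8)
  expect_equal(m$basis_order, 0)
})

test_that("single-coefficient model matches the closed-form exponential tilt", {
  # p(x) = exp(0.5 x) / Z on [-1,1], Z = integral = 2 sinh(0.5) / 0.5
  m <- maxent_model(c(0, 0.5), c(-1, 1))
  expect_equal(dmaxent(0, m), 0.5 / (2 * sinh(0.5)), tolerance = 1e-9)
  expect_equal(pmaxent(0, m), (1 - exp(-0.5)) / (exp(0.5) - exp(-0.5)),
               tolerance = 1e-8)
  expect_equal(qmaxent((1 - exp(-0.5)) / (exp(0.5) - exp(-0.5)), m), 0,
               tolerance = 1e-6)
})

test_that("density is strictly positive and integrates to one for arbitrary coefficients", {
  set.seed(3)
  for (rep in 1:5) {
    d <- sample(1:12, 1)
    m <- maxent_model(c(0, rnorm(d, 0, 0.8)), sort(runif(2, -5, 5)))
    g <- seq(m$domain[1], m$domain[2], length.out = 1001)
    expect_gt(min(dmaxent(g, m)), 0)
    # trapezoid normalization check on a fine grid
    gg <- seq(m$domain[1], m$domain[2], length.out = 1e5)
    f <- dmaxent(gg, m)
    h <- diff(m$domain) / (1e5 - 1)
    expect_equal(sum((f[-1] + f[-1e5]) / 2) * h, 1, tolerance = 1e-6)
    # CDF endpoints and monotonicity
    cdf <- pmaxent(g, m)
    expect_equal(cdf[1], 0)
    expect_equal(cdf[1001], 1)
    expect_true(all(diff(cdf) >= 0))
  }
})

test_that("quantile function inverts the CDF across the support", {
  m <- maxent_model(c(0, 0.4, -0.3, 0.2), c(2, 7))
  x <- seq(2, 7, length.out = 101)
  expect_lt(max(abs(qmaxent(pmaxent(x, m), m) - x)), 1e-6 * 5)
  expect_equal(qmaxent(c(0, 1), m), c(2, 7))
})

test_that("Jacobian puts the density in data units", {
  # same shape on a 10x wider window must be 10x lower
  m1 <- maxent_model(c(0, 0.5), c(-1, 1))
  m2 <- maxent_model(c(0, 0.5), c(-10, 10))
  expect_equal(dmaxent(0, m2), dmaxent(0, m1) / 10, tolerance = 1e-9)
})

test_that("Chebyshev recurrence matches the cosine closed form", {
  x <- seq(-1, 1, length.out = 41)
  B <- cheb_basis(x, 300)
  direct <- outer(acos(x), 0:300, function(a, j) cos(j * a))
  expect_lt(max(abs(B - direct)), 1e-10)
})

test_that("invalid models are rejected and wild coefficients do not overflow", {
  expect_error(maxent_model(c(0, NA), c(-1, 1)), "invalid model")
  expect_error(maxent_model(0, c(2, 1)), "invalid model")
  m <- maxent_model(c(0, 400, -350), c(-1, 1))   # huge exponent range
  expect_true(all(is.finite(dmaxent(seq(-1, 1, 0.01), m))))
})

test_that("model serialization round-trips coefficients bit-exactly", {
  m <- maxent_model(c(0, pi / 7, -exp(1) / 9, 1 / 3), c(-2.5, 11))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_maxent(m, path)
  m2 <- read_maxent(path)
  expect_identical(m2$lambda, m$lambda)
  expect_identical(m2$domain, m$domain)
})
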