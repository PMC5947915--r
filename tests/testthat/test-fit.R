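test_that("hierarchical subsets follow the 2^n + 1 schedule and nest", {
  expect_equal(hierarchical_subsets(1000), list(1:1000))
  expect_equal(hierarchical_subsets(1025), list(1:1025))
  expect_equal(lengths(hierarchical_subsets(5000)), c(1025, 2049, 4097, 5000))
  expect_equal(lengths(hierarchical_subsets(1026)), c(1025, 1026))
  subs <- hierarchical_subsets(70000)
  expect_equal(lengths(subs), c(1025, 2049, 4097, 8193, 16385, 32769, 65537, 70000))
  for (k in seq_len(length(subs) - 1)) {
    expect_true(all(subs[[k]] %in% subs[[k + 1]]))
    expect_false(is.unsorted(subs[[k]], strictly = TRUE))
  }
  expect_equal(subs[[1]][1], 1L)
  expect_equal(subs[[1]][1025], 70000L)
})

test_that("coefficient perturbation is Gaussian on the shape terms only", {
  lam <- c(0.3, 0.1, -0.2)
  expect_equal(perturb_lambdas(lam, 0), lam)
  set.seed(4); a <- perturb_lambdas(lam, 0.1)
  set.seed(4); b <- perturb_lambdas(lam, 0.1)
  expect_identical(a, b)                       # seeded determinism
  expect_equal(a[1], lam[1])                   # normalization term untouched
  set.seed(6)
  steps <- replicate(1e4, perturb_lambdas(c(0, 0), 0.1)[2])
  expect_equal(var(steps), 0.01, tolerance = 0.05)
})

test_that("uniform data is usually accepted as uniform with one multiplier", {
  accepted <- vapply(1:5, function(i) {
    set.seed(400 + i)
    f <- memde_one(runif(4096), bounds = c(0, 1), seed = 400 + i)
    f$n_lagrange == 1L && f$coverage >= 0.40
  }, TRUE)
  expect_gte(sum(accepted), 3)
})

test_that("accepted-step penalized score is nondecreasing within a funnel stage", {
  set.seed(12)
  f <- memde_one(rnorm(512), seed = 12)
  tr <- f$trace[f$trace$subset > 0, ]
  if (nrow(tr) > 1) {
    stage <- interaction(tr$subset, tr$n_lagrange, tr$sigma, drop = TRUE)
    for (g in split(tr$penalized, stage))
      expect_true(all(diff(g) >= 0))
  }
  expect_s3_class(f$model, "maxent_model")
})

test_that("a Gaussian sample is fit successfully with an accurate mean", {
  set.seed(77)
  n <- 4096
  f <- memde_one(rnorm(n), seed = 77)
  expect_true(f$success)
  expect_gte(f$coverage, 0.05)
  g <- seq(f$model$domain[1], f$model$domain[2], length.out = 4001)
  h <- diff(f$model$domain) / 4000
  mean_fit <- sum(g * dmaxent(g, f$model)) * h
  expect_lt(abs(mean_fit), 4 / sqrt(n))
})

test_that("single fits are reproducible from their seed", {
  x <- sample_benchmark(benchmark_distribution("two_gaussian"), 256, seed = 5)
  f1 <- memde_one(x, seed = 99)
  f2 <- memde_one(x, seed = 99)
  expect_identical(f1$model$lambda, f2$model$lambda)
  expect_identical(f1$L, f2$L)
})

test_that("degenerate input fails with a diagnostic error", {
  expect_error(memde_one(rep(2, 50)), "degenerate window")
})

test_that("control parameters are validated", {
  expect_error(memde_control(target_coverage = 1.2))
  expect_error(memde_control(min_coverage = 0.5, target_coverage = 0.4))
  expect_error(memde_control(sigma_decay = 1.5))
  expect_error(memde_control(sigma_min = 0.2, sigma0 = 0.1))
})
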