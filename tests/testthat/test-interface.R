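test_that("plain sample files are parsed with comments and bad records handled", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("1", "2", "3"), path)
  expect_equal(as.numeric(read_sample(path)), c(1, 2, 3))

  writeLines(c("# header comment", "1.5", "2.5"), path)
  expect_equal(as.numeric(read_sample(path)), c(1.5, 2.5))

  writeLines(c("1", "NaN", "2", "Inf"), path)
  expect_warning(x <- read_sample(path), "2 non-finite")
  expect_equal(as.numeric(x), c(1, 2))
  expect_equal(attr(x, "n_dropped"), 2L)

  writeLines(character(0), path)
  expect_error(read_sample(path), "input error")
})

test_that("CSV files with a named column are supported", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,value", "a,0.1", "b,0.7"), path)
  expect_equal(as.numeric(read_sample(path, column = "value")), c(0.1, 0.7))
  expect_equal(as.numeric(read_sample(path)), c(0.1, 0.7))  # first numeric column
})

test_that("the pipeline writes the four artifacts and is seed-stable", {
  input <- system.file("extdata", "gaussian_example_synthetic.tsv",
                       package = "memde")
  out1 <- withr::local_tempdir()
  fit <- run_memde(input, out_dir = out1, models = 2, seed = 123,
                   quiet = TRUE)
  files <- c("solution.tsv", "ensemble.tsv", "sqr.tsv", "fom.tsv")
  expect_true(all(file.exists(file.path(out1, files))))
  expect_s3_class(fit, "memde")
  expect_true(fit$fits[[fit$central]]$success)

  out2 <- withr::local_tempdir()
  run_memde(input, out_dir = out2, models = 2, seed = 123, quiet = TRUE)
  for (f in files)
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))
})

test_that("solution files carry the model, score and per-observation columns", {
  set.seed(50)
  f <- memde_one(rnorm(300), seed = 50)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_solution(f, path)
  lines <- readLines(path)
  expect_true(any(grepl("^# lambda", lines)))
  expect_true(any(grepl("^# coverage", lines)))
  body <- lines[!grepl("^#", lines)]
  expect_equal(body[1], "value\tpdf\tcdf")
  expect_equal(length(body) - 1L, length(f$data_kept))
})

test_that("prediction and simulation use the central model", {
  set.seed(51)
  fit <- memde(rnorm(300), models = 2, seed = 51)
  m <- fit$fits[[fit$central]]$model
  v <- seq(m$domain[1], m$domain[2], length.out = 11)
  expect_equal(predict(fit, v, type = "pdf"), dmaxent(v, m))
  expect_equal(predict(fit, v, type = "cdf"), pmaxent(v, m))
  expect_equal(predict(fit, c(0.1, 0.9), type = "quantile"),
               qmaxent(c(0.1, 0.9), m))
  expect_identical(simulate(fit, 20, seed = 1), simulate(fit, 20, seed = 1))
  r <- residuals(fit)
  expect_s3_class(r, "memde_sqr")
  expect_equal(nrow(r), length(fit$fits[[fit$central]]$u))
})

test_that("run configurations round-trip through the key=value file format", {
  cfg <- list(target_coverage = 0.4, min_coverage = 0.05, sigma0 = 0.1,
              sigma_min = 0.001, loop_max = 100, max_lagrange = 300,
              models = 5, outlier_c = 7, bounds = c(-2.5, 11), seed = 42)
  path <- withr::local_tempfile(fileext = ".cfg")
  write_config(cfg, path)
  cfg2 <- read_config(path)
  expect_identical(names(cfg2), names(cfg))
  for (k in names(cfg)) expect_equal(cfg2[[k]], cfg[[k]])
})
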