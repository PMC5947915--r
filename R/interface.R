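#' Read a univariate sample from a text file
#'
#' Accepts one numeric value per line, or a delimited file (CSV/TSV) with a
#' named column.  Lines starting with `#` and blank lines are skipped.
#' Non-finite records (`NA`, `NaN`, `Inf`, unparseable text after the
#' header) are dropped with a warning reporting how many.
#'
#' @param path file path.
#' @param column optional column name (or index) for delimited files;
#'   by default the first numeric-looking column of a delimited file, or
#'   the whole file when each line is a single value.
#' @return numeric vector with attribute `n_dropped`.
#' @export
read_sample <- function(path, column = NULL) {
  if (!file.exists(path)) stop("input error: no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) stop("input error: ", path, " contains no data")
  delim <- grepl("[,\t;]", lines[1])
  if (delim || !is.null(column)) {
    sep <- if (grepl(",", lines[1])) "," else if (grepl("\t", lines[1])) "\t" else ";"
    df <- utils::read.table(text = lines, sep = sep, header = TRUE,
                            stringsAsFactors = FALSE)
    if (is.null(column)) {
      num <- which(vapply(df, is.numeric, TRUE))
      if (!length(num)) stop("input error: no numeric column in ", path)
      column <- num[1]
    }
    vals <- suppressWarnings(as.numeric(df[[column]]))
  } else {
    vals <- suppressWarnings(as.numeric(lines))
    if (all(is.na(vals))) {       # header line then values
      vals <- suppressWarnings(as.numeric(lines[-1]))
      if (all(is.na(vals)))
        stop("input error: could not parse numeric values (near line 1)")
    }
  }
  bad <- !is.finite(vals)
  if (any(bad))
    warning(sprintf("dropped %d non-finite record(s) from %s", sum(bad), path))
  out <- vals[!bad]
  if (!length(out)) stop("input error: no finite values in ", path)
  attr(out, "n_dropped") <- sum(bad)
  out
}

#' Write the solution artifacts of a fit
#'
#' `write_solution` writes one model's full solution as TSV: `#` header
#' lines with the coefficient vector, domain, score, coverage and success
#' flag, then per-observation rows (raw value, fitted PDF, fitted CDF) for
#' the data kept inside the window.  `write_ensemble_summary` writes the
#' per-model table of an ensemble (score, coverage, multiplier count, total
#' squared error, centrality).  `write_sqr` and `write_fom` write the
#' diagnostic tables.
#'
#' @param fit a `"memde_fit"` (for `write_solution`) or `"memde"` object.
#' @param sqr_data a `"memde_sqr"` data frame.
#' @param fom_result a `"memde_fom"` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_solution <- function(fit, path) {
  stopifnot(inherits(fit, "memde_fit"))
  m <- fit$model
  v <- fit$data_kept
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# memde solution",
    sprintf("# lambda\t%s", paste(sprintf("%.17g", m$lambda), collapse = "\t")),
    sprintf("# domain\t%.17g\t%.17g", m$domain[1], m$domain[2]),
    sprintf("# score\t%.10g", fit$L),
    sprintf("# coverage\t%.10g", fit$coverage),
    sprintf("# success\t%s", fit$success),
    sprintf("# n_lagrange\t%d", fit$n_lagrange),
    "value\tpdf\tcdf",
    sprintf("%.10g\t%.10g\t%.10g", v, dmaxent(v, m), pmaxent(v, m))), con)
  invisible(path)
}

#' @rdname write_solution
#' @export
write_ensemble_summary <- function(fit, path) {
  stopifnot(inherits(fit, "memde"))
  utils::write.table(summary(fit)$table, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_solution
#' @export
write_sqr <- function(sqr_data, path) {
  stopifnot(inherits(sqr_data, "memde_sqr"))
  utils::write.table(as.data.frame(sqr_data), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_solution
#' @export
write_fom <- function(fom_result, path) {
  stopifnot(inherits(fom_result, "memde_fom"))
  df <- data.frame(fom = fom_result$fom, fom_test = fom_result$fom_test,
                   fom_sample = fom_result$fom_sample,
                   fom_sigma = fom_result$fom_sigma, n = fom_result$n,
                   n_reference = fom_result$n_reference,
                   n_test = fom_result$n_test)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full pipeline on an input file
#'
#' The programmatic equivalent of the command-line tool: reads a sample,
#' fits the ensemble, and writes four artifacts into `out_dir` —
#' `solution.tsv` (central model with per-observation PDF/CDF),
#' `ensemble.tsv` (per-model summary), `sqr.tsv` (scaled quantile
#' residuals) and `fom.tsv` (figure of merit).  Artifacts are written even
#' for a failed fit so diagnostics are always available.
#'
#' @param input path to the sample file (see [read_sample()]).
#' @param out_dir output directory, created if needed.
#' @param ... passed to [memde()] (`bounds`, `outlier_c`, `models`,
#'   `control`, `score_table`, `seed`).
#' @param fom_seed seed for the figure-of-merit samples (defaults to the
#'   fit seed).
#' @param quiet suppress progress messages.
#' @return the `"memde"` fit, invisibly.
#' @export
run_memde <- function(input, out_dir = ".", ..., fom_seed = NULL,
                      quiet = FALSE) {
  x <- read_sample(input)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  fit <- memde(x, ...)
  f <- fit$fits[[fit$central]]
  if (is.null(fom_seed)) fom_seed <- fit$seed
  write_solution(f, file.path(out_dir, "solution.tsv"))
  write_ensemble_summary(fit, file.path(out_dir, "ensemble.tsv"))
  write_sqr(residuals(fit), file.path(out_dir, "sqr.tsv"))
  write_fom(fom(fit, seed = fom_seed), file.path(out_dir, "fom.tsv"))
  if (!quiet) {
    print(fit)
    message("artifacts written to ", normalizePath(out_dir))
  }
  invisible(fit)
}

#' Flat key=value run configuration files
#'
#' `write_config` serializes a set of run options (any of the
#' [memde_control()] fields plus `bounds`, `outlier_c`, `models`, `seed`)
#' as one `key=value` per line; `read_config` parses such a file back into
#' a named list, coercing numeric values, so that a configuration can be
#' round-tripped between flags and file losslessly.
#'
#' @param config named list of options.
#' @param path file path.
#' @return `read_config` returns a named list; `write_config` returns
#'   `path` invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(is.list(config), !is.null(names(config)))
  vals <- vapply(config, function(v)
    paste(format(v, digits = 17, scientific = FALSE, trim = TRUE),
          collapse = ","), "")
  writeLines(paste0(names(config), "=", vals), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  out <- lapply(kv, function(m) {
    parts <- strsplit(m[3], ",")[[1]]
    num <- suppressWarnings(as.numeric(parts))
    if (!anyNA(num)) num else parts
  })
  names(out) <- vapply(kv, function(m) trimws(m[2]), "")
  out
}
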