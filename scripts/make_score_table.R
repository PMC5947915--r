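#!/usr/bin/env Rscript
# Regenerates the packaged SURD score table fixture
# (inst/extdata/surd_score_table.tsv) and the packaged example sample.
# Run from the repository root; takes a few minutes.

if (requireNamespace("memde", quietly = TRUE)) {
  library(memde)
} else {
  pkgload::load_all(".", quiet = TRUE)
}

tab <- build_score_table(sizes = 2^c(8, 10, 12, 14, 16),
                         replicates = 1e4, seed = 20180511L)
write_score_table(tab, "inst/extdata/surd_score_table.tsv")
cat(sprintf("score table written: coverage(-0.15) = %.3f, coverage(-0.37) = %.3f\n",
            surd_coverage(tab, -0.15), surd_coverage(tab, -0.37)))

# synthetic packaged example: 512 standard Gaussian draws
set.seed(101)
writeLines(c("# synthetic example: 512 standard Gaussian draws (seed 101)",
             sprintf("%.8g", rnorm(512))),
           "inst/extdata/gaussian_example_synthetic.tsv")
cat("example sample written\n")
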