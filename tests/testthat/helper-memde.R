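# Shared fixtures, built in code at test time.

# a small pooled score table for tests that only need a usable coverage map
small_score_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) tab <<- build_score_table(sizes = c(256L, 1024L),
                                                replicates = 2000L,
                                                seed = 42L)
    tab
  }
})

# mean quasi-log-likelihood of simulated SURD at one sample size
surd_mean_L <- function(n, reps, seed) {
  set.seed(seed)
  mean(vapply(seq_len(reps),
              function(r) surd_loglik(sort(runif(n))), 0))
}
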