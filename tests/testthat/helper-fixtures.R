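# Small fixed trees used across tests.
tree3 <- function() read_newick(text = "((A:1,B:1):1,C:2);")
tree4 <- function() read_newick(text = "((A:1,B:1):1,(C:1,D:1):1);")
star4 <- function() read_newick(text = "(A:1,B:1,C:1,D:1);")
tree5 <- function() read_newick(text = "(((A:0.3,B:0.3):0.4,C:0.7):0.3,(D:0.5,E:0.5):0.5);")

# Mean Fritz-Purvis D_stat over simulated binary traits (one fresh
# pure-birth tree per replicate).
mean_dstat <- function(reps, ntips, mode, nsim, seed, prevalence = 0.5) {
  vapply(seq_len(reps), function(i) {
    tr <- simulate_tree(ntips, seed = seed + 2L * i)
    x <- simulate_binary_trait(tr, mode, prevalence, seed = seed + 2L * i + 1L)
    fritz_purvis_d(tr, x, n_sim = nsim, seed = seed + 100000L + i)$D_stat
  }, numeric(1))
}

# Mean ML lambda estimate over traits simulated with a given true lambda
# ("bm") or tip-shuffled Brownian traits ("shuffle").
lambda_estimates <- function(reps, ntips, mode, seed) {
  vapply(seq_len(reps), function(i) {
    tr <- simulate_tree(ntips, seed = seed + 2L * i)
    x <- simulate_continuous_trait(tr, lambda_true = 1, sigma2_true = 1,
                                   seed = seed + 2L * i + 1L)
    if (mode == "shuffle") {
      set.seed(seed + 50000L + i)
      x <- stats::setNames(sample(as.numeric(x)), names(x))
    }
    C <- phylo_covariance(tr, normalize = TRUE)
    fit_pagel_lambda(x, C)$lambda_hat
  }, numeric(1))
}

# 99% binomial band for an empirical rejection rate at nominal level alpha.
binom_band <- function(alpha, reps) {
  half <- 2.576 * sqrt(alpha * (1 - alpha) / reps)
  c(alpha - half, alpha + half)
}
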