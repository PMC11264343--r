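test_that("with an identity covariance the PGLMM collapses to OLS (ML)", {
  set.seed(51)
  n <- 40
  dat <- data.frame(species = paste0("s", 1:n),
                    x = rnorm(n), g = rbinom(n, 1, 0.5))
  dat$y <- 1 + 0.5 * dat$x - 0.3 * dat$g + rnorm(n, 0, 0.7)
  I <- diag(n); dimnames(I) <- list(dat$species, dat$species)

  ols <- lm(y ~ x + g, dat)
  s2_ml <- sum(resid(ols)^2) / n
  ll_ml <- -0.5 * n * log(2 * pi * s2_ml) - 0.5 * n

  for (ph in c(TRUE, FALSE)) {
    fit <- fit_pglmm(y ~ x + g, dat, C = I, phylo = ph)
    expect_equal(unname(fit$beta), unname(coef(ols)), tolerance = 1e-6)
    expect_equal(fit$logLik, ll_ml, tolerance = 1e-6)
    # SE uses the ML variance (n, not n - p, in the denominator)
    expect_equal(unname(fit$se),
                 unname(sqrt(diag(vcov(ols)) * s2_ml /
                               (sum(resid(ols)^2) / df.residual(ols)))),
                 tolerance = 1e-6)
  }
})

test_that("fixed-variance GLS matches the hand-inverted 3x3 oracle", {
  Cm <- matrix(c(2, 1, 0, 1, 2, 0, 0, 0, 2), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  dat <- data.frame(species = c("A", "B", "C"), y = c(1, 2, 3))
  fit <- fit_pglmm(y ~ 1, dat, C = Cm,
                   fix = c(sigma2_phylo = 1, sigma2_resid = 1))
  # V = C + I; mu = (1' V^-1 y) / (1' V^-1 1) = 1.75 / (5/6) = 2.1 by hand
  expect_equal(unname(fit$beta), 2.1, tolerance = 1e-10)
})

test_that("profiled optimum beats random variance-component probes", {
  ds <- simulate_full_dataset(sim_config(n_species = 60, seed = 61))
  C <- phylo_covariance(ds$tree, normalize = TRUE)
  fit <- fit_pglmm(D ~ height + pollination, ds$traits, C)
  set.seed(62)
  for (i in 1:20) {
    probe <- fit_pglmm(D ~ height + pollination, ds$traits, C,
                       fix = c(sigma2_phylo = runif(1, 0, 2),
                               sigma2_resid = runif(1, 0.01, 2)))
    expect_gte(fit$logLik + 1e-6, probe$logLik)
  }
})

test_that("stored z, p and AIC are internally consistent", {
  ds <- simulate_full_dataset(sim_config(n_species = 50, seed = 63))
  C <- phylo_covariance(ds$tree, normalize = TRUE)
  fit <- fit_pglmm(D ~ height + life_form, ds$traits, C)
  expect_identical(fit$z, fit$beta / fit$se)
  expect_equal(fit$AIC, -2 * fit$logLik + 2 * fit$k)
  expect_equal(fit$p, 2 * pnorm(abs(fit$z), lower.tail = FALSE))
  expect_true(fit$sigma2_phylo >= 0 && fit$sigma2_resid >= 0)
})

test_that("z statistics are invariant to affine rescaling of a predictor", {
  ds <- simulate_full_dataset(sim_config(n_species = 70, seed = 64))
  C <- phylo_covariance(ds$tree, normalize = TRUE)
  f1 <- fit_pglmm(D ~ height + pollination, ds$traits, C)
  tr2 <- ds$traits
  tr2$height <- 100 * tr2$height - 7
  f2 <- fit_pglmm(D ~ height + pollination, tr2, C)
  # slope SEs rescale conjugately with the slopes (the intercept is
  # reparameterized by the shift, so only non-intercept z are comparable)
  expect_lt(max(abs(f1$z[-1] - f2$z[-1])), 1e-6)
})

test_that("design problems are reported, not silently absorbed", {
  ds <- simulate_full_dataset(sim_config(n_species = 30, seed = 65))
  C <- phylo_covariance(ds$tree, normalize = TRUE)
  tr <- ds$traits
  tr$height2 <- 2 * tr$height
  expect_error(fit_pglmm(D ~ height + height2, tr, C), "rank-deficient")
  tr$height[1:3] <- NA
  expect_message(fit_pglmm(D ~ height, tr, C), "incomplete")
})

test_that("univariate fit recovers the sign of a known slope and guards subsets", {
  ds <- simulate_full_dataset(sim_config(n_species = 100, beta_height = 0.5,
                                         sigma2_resid_true = 0.1, seed = 66))
  C <- phylo_covariance(ds$tree, normalize = TRUE)
  fit <- univariate_pglmm("D", "height", ds$traits, C)
  expect_gt(fit$z[["height"]], 0)
  expect_error(univariate_pglmm("D", "height", ds$traits, C,
                                subset = seq_len(nrow(ds$traits)) <= 3),
               "fewer than 5")
})

test_that("stratified fits find the slope only where it exists", {
  hits_a <- hits_b <- 0L
  reps <- 30
  for (i in seq_len(reps)) {
    tr <- simulate_tree(160, seed = 700 + i)
    g <- simulate_binary_trait(tr, "shuffle", 0.5, seed = 730 + i)
    x <- simulate_continuous_trait(tr, 1, 1, seed = 760 + i)
    set.seed(790 + i)
    # slope only in group 1; noise sized for high power at n = 80
    y <- ifelse(g == 1, 0.4 * x, 0) + rnorm(160, 0, 0.4)
    dat <- data.frame(species = tr$tip.label, height = as.numeric(x),
                      D = as.numeric(y), grp = as.numeric(g))
    C <- phylo_covariance(tr, normalize = TRUE)
    fa <- univariate_pglmm("D", "height", dat, C, subset = dat$grp == 1)
    fb <- univariate_pglmm("D", "height", dat, C, subset = dat$grp == 0)
    hits_a <- hits_a + (fa$p[["height"]] < 0.05)
    hits_b <- hits_b + (fb$p[["height"]] < 0.05)
  }
  expect_gt(hits_a / reps, 0.7)
  expect_lt(hits_b / reps, 0.3)
})

test_that("phylogenetic correlation is exact in its degenerate anchors", {
  tr <- simulate_tree(40, seed = 71)
  x <- simulate_continuous_trait(tr, 1, 1, seed = 72)
  expect_equal(phylo_correlation(x, x, tr)$R, 1, tolerance = 1e-12)

  # on a star tree contrasts reduce to centered values: R == Pearson
  star <- ape::read.tree(text = paste0("(",
    paste(sprintf("t%d:1", 1:12), collapse = ","), ");"))
  set.seed(73)
  xs <- stats::setNames(rnorm(12), star$tip.label)
  ys <- stats::setNames(rnorm(12), star$tip.label)
  expect_equal(phylo_correlation(xs, ys, star)$R, cor(xs, ys),
               tolerance = 1e-10)

  expect_error(
    phylo_correlation(stats::setNames(rep(1, 40), tr$tip.label), x, tr),
    "degenerate")
})

test_that("correlation p-values are calibrated under independence", {
  reps <- 200
  rej <- 0L
  for (i in seq_len(reps)) {
    tr <- simulate_tree(40, seed = 2000 + i)
    x <- simulate_continuous_trait(tr, 1, 1, seed = 5000 + i)
    y <- simulate_continuous_trait(tr, 1, 1, seed = 8000 + i)
    rej <- rej + (phylo_correlation(x, y, tr)$p_value < 0.05)
  }
  band <- binom_band(0.05, reps)
  expect_gte(rej / reps, band[1])
  expect_lte(rej / reps, band[2])
})

test_that("contrast and GLS correlation routes agree on bifurcating trees", {
  tr <- simulate_tree(60, seed = 74)
  x <- simulate_continuous_trait(tr, 1, 1, seed = 75)
  y <- 0.5 * x + simulate_continuous_trait(tr, 1, 0.5, seed = 76)
  expect_equal(phylo_correlation(x, y, tr, method = "contrasts")$R,
               phylo_correlation(x, y, tr, method = "pgls")$R,
               tolerance = 1e-8)
})

test_that("group t test matches the hand Welch computation", {
  g <- c("a", "a", "a", "b", "b", "b")
  res <- group_t_test(c(1, 2, 3, 2, 3, 4), g, log10 = FALSE)
  expect_equal(res$t, -1.224745, tolerance = 1e-6)
  expect_equal(res$df, 4)
  expect_equal(res$p, 0.2878641, tolerance = 1e-6)
  expect_equal(sign(res$t), unname(sign(res$means[1] - res$means[2])))

  same <- group_t_test(c(1, 2, 3, 1, 2, 3), g, log10 = FALSE)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  expect_error(group_t_test(1:4, c("a", "a", "a", "b")), "at least 2")
  expect_error(group_t_test(1:4, rep("a", 4)), "2 levels")
  # log10 scale is the default; pooled variance available behind the flag
  lg <- group_t_test(c(1, 10, 100, 10, 100, 1000), g)
  expect_equal(lg$means, c(a = 1, b = 2))
  pooled <- group_t_test(c(1, 2, 3, 2, 3, 5), g, log10 = FALSE,
                         var_equal = TRUE)
  expect_equal(pooled$df, 4)
})
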