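test_that("ML lambda matches a fine grid search of the profiled likelihood", {
  tr <- tree5()
  C <- phylo_covariance(tr, normalize = TRUE)
  x <- c(A = 1.2, B = 1.0, C = 0.3, D = -0.5, E = -0.4)

  # independent oracle: direct multivariate-normal profiled log-likelihood
  # evaluated on a 0.001-step grid
  prof_ll <- function(lambda) {
    V <- lambda * C
    diag(V) <- diag(C)
    n <- nrow(V)
    Vi <- solve(V)
    one <- rep(1, n)
    mu <- drop(one %*% Vi %*% x) / drop(one %*% Vi %*% one)
    r <- x - mu
    s2 <- drop(r %*% Vi %*% r) / n
    -0.5 * n * log(2 * pi * s2) - 0.5 * determinant(V)$modulus - 0.5 * n
  }
  grid <- seq(0, 1, by = 0.001)
  lam_grid <- grid[which.max(vapply(grid, prof_ll, numeric(1)))]

  fit <- fit_pagel_lambda(x, C)
  expect_lt(abs(fit$lambda_hat - lam_grid), 0.002)
  expect_equal(fit$logLik, max(vapply(grid, prof_ll, numeric(1))),
               tolerance = 1e-6)
})

test_that("reported lambda optimum beats every coarse grid value", {
  for (i in 1:6) {
    tr <- simulate_tree(30, seed = 300 + i)
    x <- simulate_continuous_trait(tr, lambda_true = runif(1),
                                   sigma2_true = 1, seed = 400 + i)
    C <- phylo_covariance(tr, normalize = TRUE)
    fit <- fit_pagel_lambda(x, C)
    prof <- mastphylo:::lambda_profiler(C, as.numeric(x[rownames(C)]))
    gl <- vapply(seq(0, 1, length.out = 25),
                 function(l) prof$loglik(l)$logLik, numeric(1))
    expect_gte(fit$logLik + 1e-8, max(gl))
    expect_gte(fit$logLik, fit$logLik_at_zero - 1e-8)
  }
})

test_that("lambda agrees with an independent implementation", {
  tr <- simulate_tree(120, seed = 9)
  x <- simulate_continuous_trait(tr, lambda_true = 0.6, sigma2_true = 1,
                                 seed = 10)
  C <- phylo_covariance(tr, normalize = TRUE)
  fit <- fit_pagel_lambda(x, C)
  ph <- phytools::phylosig(tr, x, method = "lambda", test = TRUE)
  expect_equal(fit$lambda_hat, ph$lambda, tolerance = 1e-3)
  expect_equal(fit$logLik, ph$logL, tolerance = 1e-5)
  expect_equal(fit$logLik_at_zero, ph$logL0, tolerance = 1e-5)
})

test_that("lambda is flagged unidentifiable on a star phylogeny", {
  C <- diag(4)
  rownames(C) <- colnames(C) <- c("A", "B", "C", "D")
  fit <- fit_pagel_lambda(c(A = 1, B = 2, C = 0, D = 4), C)
  expect_true(fit$unidentifiable)
  expect_true(is.na(fit$lambda_hat))
})

test_that("lambda fit rejects degenerate input", {
  C <- phylo_covariance(simulate_tree(10, seed = 2))
  expect_error(fit_pagel_lambda(stats::setNames(rep(1, 10), rownames(C)), C),
               "constant")
  expect_error(fit_pagel_lambda(rnorm(3), phylo_covariance(tree3())),
               "at least 4")
})

test_that("lambda randomization test is seeded and demands enough permutations", {
  tr <- simulate_tree(40, seed = 21)
  x <- simulate_continuous_trait(tr, lambda_true = 1, sigma2_true = 1,
                                 seed = 22)
  C <- phylo_covariance(tr, normalize = TRUE)
  expect_error(lambda_randomization_test(x, C, n_perm = 10), "99")
  r1 <- lambda_randomization_test(x, C, n_perm = 99, seed = 7)
  r2 <- lambda_randomization_test(x, C, n_perm = 99, seed = 7)
  expect_identical(r1$perm_lambda, r2$perm_lambda)
  expect_identical(r1$p_perm, r2$p_perm)
  # strong Brownian signal on 40 tips should be detected
  expect_lte(r1$p_perm, 0.05)
})

test_that("sister-difference sum matches hand traversals", {
  tr <- tree4()
  expect_equal(sister_difference_sum(tr, c(A = 1, B = 1, C = 0, D = 0)), 1)
  expect_equal(sister_difference_sum(tr, c(A = 1, B = 0, C = 1, D = 0)), 2)
  expect_error(sister_difference_sum(tr, c(A = 1, B = 1, C = 1, D = 1)),
               "monomorphic")
  expect_error(sister_difference_sum(tr, c(A = 2, B = 0, C = 1, D = 0)),
               "0/1")
})

test_that("random-null mean matches exhaustive enumeration on a 6-tip tree", {
  tr <- read_newick(text =
    "(((A:1,B:1):1,(C:1,D:1):1):1,(E:2,F:2):1);")
  x <- c(A = 1, B = 1, C = 0, D = 0, E = 0, F = 0)
  combs <- utils::combn(6, 2)
  d_all <- apply(combs, 2, function(idx) {
    z <- stats::setNames(numeric(6), names(x))
    z[idx] <- 1
    sister_difference_sum(tr, z)
  })
  fp <- fritz_purvis_d(tr, x, n_sim = 4000, seed = 3)
  expect_equal(fp$mean_d_random, mean(d_all),
               tolerance = 3 * sd(d_all) / sqrt(4000) / mean(d_all))
})

test_that("Fritz-Purvis D is reproducible under a seed and stores its nulls", {
  tr <- simulate_tree(50, seed = 31)
  x <- simulate_binary_trait(tr, "shuffle", 0.5, seed = 32)
  a <- fritz_purvis_d(tr, x, n_sim = 200, seed = 5)
  b <- fritz_purvis_d(tr, x, n_sim = 200, seed = 5)
  expect_identical(a$null_d_random, b$null_d_random)
  expect_identical(a$null_d_brownian, b$null_d_brownian)
  expect_identical(a$D_stat, b$D_stat)
  # stored fields reproduce the standardization and p-values exactly
  expect_equal(a$D_stat, (a$d_obs - a$mean_d_brownian) /
                 (a$mean_d_random - a$mean_d_brownian))
  expect_equal(a$Pr, (1 + sum(a$null_d_random <= a$d_obs)) / 201)
  expect_equal(a$Pb, (1 + sum(a$null_d_brownian >= a$d_obs)) / 201)
  expect_true(a$Pr >= 0 && a$Pr <= 1 && a$Pb >= 0 && a$Pb <= 1)
  expect_error(fritz_purvis_d(tr, x, n_sim = 10), "100")
})

test_that("clumped traits push D below the random expectation", {
  tr <- simulate_tree(80, seed = 41)
  xb <- simulate_binary_trait(tr, "brownian_threshold", 0.5, seed = 42)
  xr <- simulate_binary_trait(tr, "shuffle", 0.5, seed = 43)
  db <- fritz_purvis_d(tr, xb, n_sim = 300, seed = 44)
  dr <- fritz_purvis_d(tr, xr, n_sim = 300, seed = 45)
  expect_lt(db$D_stat, dr$D_stat)
})
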