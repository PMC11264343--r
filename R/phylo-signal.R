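#' Pagel's lambda by maximum likelihood
#'
#' Fits the model y ~ Normal(mu * 1, sigma2 * C(lambda)), where C(lambda)
#' multiplies the off-diagonal phylogenetic covariance by lambda in [0, 1].
#' lambda = 0 means no phylogenetic signal; lambda = 1 the full Brownian
#' expectation. The mean and rate are profiled in closed form (GLS mean, ML
#' variance); lambda is maximized by bounded 1-D search seeded from a coarse
#' grid, with both boundaries checked explicitly. The reported p-value is a
#' likelihood-ratio test of lambda-hat against lambda = 0 with the boundary
#' null 0.5*chi2_0 + 0.5*chi2_1.
#'
#' When the tree is ultrametric (constant diagonal of C) the covariance
#' family C(lambda) shares one eigenbasis, so the data are rotated once and
#' each likelihood evaluation is O(n); otherwise a Cholesky factorization is
#' taken per evaluation.
#'
#' On a star phylogeny (no shared path between any tips) the likelihood is
#' flat in lambda; the fit is returned with \code{unidentifiable = TRUE} and
#' \code{lambda_hat = NA} rather than an arbitrary interior value.
#'
#' @param trait named numeric vector over tips (or ordered like \code{C}).
#' @param C phylogenetic covariance matrix with tip dimnames (see
#'   \code{\link{phylo_covariance}}).
#' @return object of class \code{"lambda_fit"}: \code{lambda_hat},
#'   \code{sigma2}, \code{mu}, \code{logLik}, \code{logLik_at_zero},
#'   \code{p_value} (boundary LRT), \code{n_tips}, \code{unidentifiable}.
#' @export
fit_pagel_lambda <- function(trait, C) {
  stopifnot(is.matrix(C), nrow(C) == ncol(C))
  n <- nrow(C)
  if (n < 4L) stop("need at least 4 tips to estimate lambda")
  if (!is.null(dimnames(C)) && !is.null(names(trait)))
    trait <- trait[rownames(C)]
  y <- as.numeric(trait)
  if (anyNA(y)) stop("trait contains NA after matching to tips")
  if (stats::var(y) == 0) stop("degenerate input: constant trait")

  prof <- lambda_profiler(C, y)

  if (prof$flat) {
    l0 <- prof$loglik(0)
    return(structure(
      list(lambda_hat = NA_real_, sigma2 = l0$sigma2, mu = l0$mu,
           logLik = l0$logLik, logLik_at_zero = l0$logLik,
           p_value = 1, n_tips = n, unidentifiable = TRUE),
      class = "lambda_fit"))
  }

  grid <- seq(0, 1, by = 0.05)
  gl <- vapply(grid, function(l) prof$loglik(l)$logLik, numeric(1))
  g <- grid[which.max(gl)]
  lo <- max(0, g - 0.05); hi <- min(1, g + 0.05)
  opt <- stats::optimize(function(l) prof$loglik(l)$logLik,
                         lower = lo, upper = hi, maximum = TRUE,
                         tol = 1e-8)
  cand <- c(opt$maximum, g, 0, 1)
  cl <- vapply(cand, function(l) prof$loglik(l)$logLik, numeric(1))
  lam <- cand[which.max(cl)]
  at <- prof$loglik(lam)
  l0 <- prof$loglik(0)
  lr <- 2 * (at$logLik - l0$logLik)
  p <- if (lr <= 0) 1 else 0.5 * stats::pchisq(lr, df = 1, lower.tail = FALSE)
  structure(
    list(lambda_hat = lam, sigma2 = at$sigma2, mu = at$mu,
         logLik = at$logLik, logLik_at_zero = l0$logLik,
         p_value = p, n_tips = n, unidentifiable = FALSE),
    class = "lambda_fit")
}

#' @export
print.lambda_fit <- function(x, ...) {
  cat("Pagel's lambda (ML)\n")
  if (x$unidentifiable) {
    cat("  lambda unidentifiable (flat likelihood, e.g. star phylogeny)\n")
  } else {
    cat(sprintf("  lambda = %.3f  logLik = %.3f  (logLik at 0 = %.3f)\n",
                x$lambda_hat, x$logLik, x$logLik_at_zero))
    cat(sprintf("  LRT p (boundary-corrected) = %.4g   n = %d\n",
                x$p_value, x$n_tips))
  }
  invisible(x)
}

# Profiled log-likelihood machinery for the lambda model. lambda_machine(C)
# does the O(n^3) preparation once and returns a factory: machine$make(y)
# yields loglik(lambda) -> list(logLik, mu, sigma2). A flatness flag marks
# star-like covariances (likelihood constant in lambda). A single
# eigendecomposition serves every lambda when diag(C) is constant
# (ultrametric tree); otherwise Cholesky per evaluation.
lambda_machine <- function(C) {
  n <- nrow(C)
  offmax <- max(abs(C[upper.tri(C)]))
  if (offmax <= 1e-12 * max(diag(C))) {
    Vd <- diag(diag(C), n)
    return(list(flat = TRUE,
                make = function(y) function(l) .gls_mean_fit(Vd, y)))
  }
  d <- diag(C)
  if (diff(range(d)) <= 1e-8 * max(d)) {
    cc <- d[1]
    eg <- eigen(C / cc, symmetric = TRUE)
    ot <- drop(crossprod(eg$vectors, rep(1, n)))
    ev <- eg$values
    make <- function(y) {
      yt <- drop(crossprod(eg$vectors, y))
      function(lambda) {
        w <- cc * (lambda * ev + (1 - lambda))
        if (any(w <= 0)) return(list(logLik = -Inf, mu = NA, sigma2 = NA))
        mu <- sum(ot * yt / w) / sum(ot^2 / w)
        r <- yt - mu * ot
        s2 <- sum(r^2 / w) / n
        ll <- -0.5 * n * log(2 * pi * s2) - 0.5 * sum(log(w)) - 0.5 * n
        list(logLik = ll, mu = mu, sigma2 = s2)
      }
    }
    return(list(flat = FALSE, make = make))
  }
  list(flat = FALSE,
       make = function(y) function(lambda)
         .gls_mean_fit(lambda_rescale(C, lambda), y))
}

lambda_profiler <- function(C, y) {
  m <- lambda_machine(C)
  list(flat = m$flat, loglik = m$make(y))
}

# ML fit of y ~ N(mu*1, sigma2*V) for fixed V by Cholesky.
.gls_mean_fit <- function(V, y) {
  n <- length(y)
  R <- tryCatch(chol(V), error = function(e)
    stop("covariance not positive definite (condition problem): ",
         conditionMessage(e)))
  ldet <- 2 * sum(log(diag(R)))
  yi <- backsolve(R, y, transpose = TRUE)
  oi <- backsolve(R, rep(1, n), transpose = TRUE)
  mu <- sum(oi * yi) / sum(oi^2)
  r <- yi - mu * oi
  s2 <- sum(r^2) / n
  ll <- -0.5 * n * log(2 * pi * s2) - 0.5 * ldet - 0.5 * n
  list(logLik = ll, mu = mu, sigma2 = s2)
}

#' Randomization test for Pagel's lambda
#'
#' Permutes trait values across tips \code{n_perm} times, refits lambda for
#' each permutation, and reports p = (1 + #\{lambda_perm >= lambda_obs\}) /
#' (n_perm + 1). Offered alongside the likelihood-ratio test; the pipeline
#' reports this randomization p as the primary significance measure.
#'
#' @inheritParams fit_pagel_lambda
#' @param n_perm number of permutations (>= 99).
#' @param seed optional integer seed.
#' @return list with \code{lambda_hat}, \code{p_perm}, \code{p_lrt},
#'   \code{n_perm}, \code{seed} and the observed \code{fit}.
#' @export
lambda_randomization_test <- function(trait, C, n_perm = 999L, seed = NULL) {
  if (n_perm < 99L) stop("n_perm must be at least 99")
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(dimnames(C)) && !is.null(names(trait)))
    trait <- trait[rownames(C)]
  fit <- fit_pagel_lambda(trait, C)
  if (fit$unidentifiable)
    stop("lambda unidentifiable on this tree; randomization test undefined")
  y <- as.numeric(trait)
  machine <- lambda_machine(C)
  perm_lambda <- vapply(seq_len(n_perm), function(i) {
    f <- fit_lambda_quick(machine$make(sample(y)))
    f$lambda
  }, numeric(1))
  p <- (1 + sum(perm_lambda >= fit$lambda_hat)) / (n_perm + 1)
  list(lambda_hat = fit$lambda_hat, p_perm = p, p_lrt = fit$p_value,
       n_perm = n_perm, seed = seed, fit = fit,
       perm_lambda = perm_lambda)
}

# Lean lambda maximization over a prepared profiled-likelihood closure,
# used inside permutation loops.
fit_lambda_quick <- function(loglik) {
  grid <- seq(0, 1, by = 0.1)
  gl <- vapply(grid, function(l) loglik(l)$logLik, numeric(1))
  g <- grid[which.max(gl)]
  opt <- stats::optimize(function(l) loglik(l)$logLik,
                         lower = max(0, g - 0.1), upper = min(1, g + 0.1),
                         maximum = TRUE, tol = 1e-6)
  cand <- c(opt$maximum, 0, 1)
  cl <- vapply(cand, function(l) loglik(l)$logLik, numeric(1))
  list(lambda = cand[which.max(cl)], logLik = max(cl))
}

# Linear operator mapping tip values to (node-averaged value differences)
# along every edge: row e of the matrix is L[child(e), ] - L[parent(e), ]
# where L assigns each internal node the mean of its children's values
# (equal weights, branch lengths ignored). The observed sister-difference
# sum for tip vector x is then sum(abs(M %*% x)), and whole null matrices
# are scored in one matrix product. Polytomies are resolved deterministically
# with zero-length branches first.
dstat_operator <- function(tree) {
  if (!ape::is.binary(tree))
    tree <- ape::multi2di(tree, random = FALSE)
  nt <- ape::Ntip(tree)
  nn <- tree$Nnode
  po <- stats::reorder(tree, "postorder")
  L <- matrix(0, nt + nn, nt)
  L[cbind(seq_len(nt), seq_len(nt))] <- 1
  parents <- unique(po$edge[, 1L])
  for (nd in parents) {
    ch <- po$edge[po$edge[, 1L] == nd, 2L]
    L[nd, ] <- colMeans(L[ch, , drop = FALSE])
  }
  M <- L[po$edge[, 2L], , drop = FALSE] - L[po$edge[, 1L], , drop = FALSE]
  colnames(M) <- tree$tip.label
  M
}

#' Sum of sister-clade differences for a binary trait
#'
#' The observed statistic underlying the Fritz-Purvis D test: each internal
#' node is assigned the mean of its children's values (tips-to-root pass,
#' equal weights), and the absolute differences between every child value
#' and its parent's value are summed.
#'
#' @param tree a \code{"phylo"} object.
#' @param binary_trait named 0/1 vector over tips; both states must occur.
#' @return the observed difference sum (a non-negative scalar).
#' @export
sister_difference_sum <- function(tree, binary_trait) {
  x <- match_to_tips(tree, binary_trait, "binary trait")
  check_binary(x)
  M <- dstat_operator(tree)
  sum(abs(M %*% x[colnames(M)]))
}

check_binary <- function(x) {
  if (!all(x %in% c(0, 1)))
    stop("trait must be coded 0/1")
  if (length(unique(x)) < 2L)
    stop("invalid input: trait is monomorphic (both states required)")
  invisible(x)
}

#' Fritz-Purvis D statistic for a binary trait
#'
#' Standardizes the observed sister-difference sum between two simulated
#' nulls: (i) a phylogenetically random null, obtained by shuffling tip
#' labels while preserving prevalence, and (ii) a Brownian-threshold null,
#' obtained by simulating a continuous Brownian trait on the tree and
#' setting the top-ranked tips to 1 so the observed prevalence is preserved
#' exactly. D near 1 indicates random structure; D near 0 indicates the
#' clumping expected under Brownian threshold evolution; D below 0 indicates
#' stronger-than-Brownian clumping.
#'
#' Pr is the permutation probability of random structure,
#' (1 + #\{d_random <= d_obs\}) / (n_sim + 1); Pb the probability of Brownian
#' structure, (1 + #\{d_brownian >= d_obs\}) / (n_sim + 1). The +1
#' pseudo-count means an extreme observation reports p < 1/(n_sim + 1)
#' rather than 0.
#'
#' @inheritParams sister_difference_sum
#' @param n_sim simulations per null (>= 100).
#' @param seed optional integer seed (stored in the result; results are
#'   bit-reproducible given the seed).
#' @return object of class \code{"dstat_result"}: \code{d_obs},
#'   \code{mean_d_random}, \code{mean_d_brownian}, \code{D_stat}, \code{Pr},
#'   \code{Pb}, \code{n_sim}, \code{seed}, plus the stored null samples.
#' @export
fritz_purvis_d <- function(tree, binary_trait, n_sim = 1000L, seed = NULL) {
  if (n_sim < 100L) stop("n_sim must be at least 100")
  if (!is.null(seed)) set.seed(seed)
  x <- match_to_tips(tree, binary_trait, "binary trait")
  check_binary(x)
  M <- dstat_operator(tree)
  x <- x[colnames(M)]
  nt <- length(x)
  d_obs <- sum(abs(M %*% x))

  # random null: prevalence-preserving tip shuffles
  XR <- vapply(seq_len(n_sim), function(i) sample(x), numeric(nt))
  d_rand <- colSums(abs(M %*% XR))

  # Brownian null: continuous BM on the tree, thresholded by rank
  C <- ape::vcv.phylo(if (ape::is.binary(tree)) tree
                      else ape::multi2di(tree, random = FALSE))
  C <- C[colnames(M), colnames(M)]
  R <- chol(C + diag(1e-10 * max(diag(C)), nt))
  Z <- crossprod(R, matrix(stats::rnorm(nt * n_sim), nt, n_sim))
  m1 <- sum(x)
  XB <- apply(Z, 2L, function(z) {
    out <- numeric(nt)
    out[order(z, decreasing = TRUE)[seq_len(m1)]] <- 1
    out
  })
  d_brow <- colSums(abs(M %*% XB))

  denom <- mean(d_rand) - mean(d_brow)
  if (abs(denom) < 1e-12)
    stop("undefined scale: random and Brownian null means coincide")
  structure(
    list(d_obs = d_obs,
         mean_d_random = mean(d_rand),
         mean_d_brownian = mean(d_brow),
         D_stat = (d_obs - mean(d_brow)) / denom,
         Pr = (1 + sum(d_rand <= d_obs)) / (n_sim + 1),
         Pb = (1 + sum(d_brow >= d_obs)) / (n_sim + 1),
         n_sim = n_sim, seed = seed,
         null_d_random = d_rand, null_d_brownian = d_brow),
    class = "dstat_result")
}

#' @export
print.dstat_result <- function(x, ...) {
  cat("Fritz-Purvis D statistic\n")
  cat(sprintf("  D = %.3f  (d_obs = %.3f; null means: random %.3f, Brownian %.3f)\n",
              x$D_stat, x$d_obs, x$mean_d_random, x$mean_d_brownian))
  cat(sprintf("  Pr (random structure) = %.4g   Pb (Brownian structure) = %.4g   n_sim = %d\n",
              x$Pr, x$Pb, x$n_sim))
  invisible(x)
}
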