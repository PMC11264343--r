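#' Gaussian phylogenetic generalized linear mixed model
#'
#' Fits y = X beta + u + e with u ~ Normal(0, sigma2_phylo * C) and
#' e ~ Normal(0, sigma2_resid * I) by maximum likelihood. The variance
#' structure is parameterized as V = sigma2 * (h*C + (1-h)*I) with the
#' phylogenetic proportion h in [0, 1]: beta is profiled by GLS and sigma2
#' in closed form, leaving a 1-D profiled likelihood in h which is maximized
#' by bounded search (boundaries h = 0 and h = 1 are admissible). Because
#' h*C + (1-h)*I shares the eigenbasis of C for every h, the data are
#' rotated once and each likelihood evaluation is O(n p^2).
#'
#' ML (not REML) is used throughout so that log-likelihood differences
#' across fixed-effect structures are valid for AIC and likelihood-based
#' partial R-squared. Standard errors come from the GLS information matrix
#' at the ML variance estimates; p-values are two-sided normal (Wald z).
#' AIC counts the regression coefficients plus two variance components (one
#' for a non-phylogenetic fit).
#'
#' @param formula model formula, e.g. \code{D ~ height + pollination}.
#'   Factor predictors are coded by treatment contrasts (alphabetically
#'   first level = 0); the coding is shown by \code{print}.
#' @param data data frame; species are taken from a \code{species} column if
#'   present, else from row names. Rows with missing values in the model
#'   variables are dropped and reported.
#' @param C phylogenetic covariance matrix with species dimnames, normally
#'   normalized to height 1 (\code{\link{phylo_covariance}}). Required when
#'   \code{phylo = TRUE}.
#' @param phylo include the phylogenetic random intercept? \code{FALSE}
#'   fits the non-phylogenetic Gaussian model (equivalently h fixed at 0).
#' @param fix optional named vector \code{c(sigma2_phylo=, sigma2_resid=)}
#'   to evaluate the model at fixed variance components (no optimization);
#'   used mainly for validation.
#' @return object of class \code{"pglmm_fit"} with elements \code{beta},
#'   \code{se}, \code{z}, \code{p}, \code{sigma2_phylo}, \code{sigma2_resid},
#'   \code{logLik}, \code{AIC}, \code{n}, \code{k} (free parameters),
#'   \code{converged}, \code{species}, \code{phylo}, \code{formula}.
#' @export
fit_pglmm <- function(formula, data, C = NULL, phylo = TRUE, fix = NULL) {
  species <- if ("species" %in% names(data)) canonical_labels(data$species)
             else canonical_labels(rownames(data))
  if (anyDuplicated(species)) stop("duplicated species in data")
  mf <- stats::model.frame(formula, data, na.action = stats::na.pass)
  ok <- stats::complete.cases(mf)
  if (!all(ok))
    message("dropping ", sum(!ok), " incomplete rows: ",
            paste(utils::head(species[!ok], 5L), collapse = ", "))
  mf <- mf[ok, , drop = FALSE]
  species <- species[ok]
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  n <- length(y)
  p <- ncol(X)
  if (is.null(fix) && n < p + 3L)
    stop("need at least ", p + 3L, " species for ", p, " coefficients")
  if (!is.null(fix) && n < p)
    stop("fewer species than coefficients")
  if (qr(X)$rank < p) {
    stop("rank-deficient design; collinear columns among: ",
         paste(colnames(X), collapse = ", "))
  }
  if (phylo || !is.null(fix)) {
    if (is.null(C)) stop("C is required for a phylogenetic fit")
    miss <- setdiff(species, canonical_labels(rownames(C)))
    if (length(miss))
      stop("species absent from covariance: ", paste(miss, collapse = ", "))
    rn <- canonical_labels(rownames(C))
    rownames(C) <- colnames(C) <- rn
    C <- C[species, species]
  }

  if (!is.null(fix)) {
    V <- fix[["sigma2_phylo"]] * C + fix[["sigma2_resid"]] * diag(n)
    fit <- .gls_fixedV(y, X, V)
    out <- list(beta = fit$beta, se = fit$se,
                sigma2_phylo = unname(fix[["sigma2_phylo"]]),
                sigma2_resid = unname(fix[["sigma2_resid"]]),
                logLik = fit$logLik, n = n, k = p + 2L, converged = TRUE,
                h = NA_real_)
  } else if (!phylo) {
    fit <- .pglmm_profile_h(y, X, ev = rep(1, n),
                            U = NULL, h = 0)
    out <- list(beta = fit$beta, se = fit$se,
                sigma2_phylo = 0, sigma2_resid = fit$sigma2,
                logLik = fit$logLik, n = n, k = p + 1L, converged = TRUE,
                h = 0)
  } else {
    eg <- eigen(C, symmetric = TRUE)
    yt <- drop(crossprod(eg$vectors, y))
    Xt <- crossprod(eg$vectors, X)
    obj <- function(h) .pglmm_profile_h(yt, Xt, eg$values, h = h)$logLik
    grid <- seq(0, 1, by = 0.05)
    gl <- vapply(grid, obj, numeric(1))
    g <- grid[which.max(gl)]
    opt <- stats::optimize(obj, lower = max(0, g - 0.05),
                           upper = min(1, g + 0.05), maximum = TRUE,
                           tol = 1e-8)
    cand <- c(opt$maximum, g, 0, 1)
    cl <- vapply(cand, obj, numeric(1))
    h <- cand[which.max(cl)]
    fit <- .pglmm_profile_h(yt, Xt, eg$values, h = h)
    out <- list(beta = fit$beta, se = fit$se,
                sigma2_phylo = h * fit$sigma2,
                sigma2_resid = (1 - h) * fit$sigma2,
                logLik = fit$logLik, n = n, k = p + 2L,
                converged = is.finite(fit$logLik), h = h)
  }
  names(out$beta) <- names(out$se) <- colnames(X)
  out$z <- out$beta / out$se
  out$p <- 2 * stats::pnorm(abs(out$z), lower.tail = FALSE)
  out$AIC <- -2 * out$logLik + 2 * out$k
  out$species <- species
  out$phylo <- phylo
  out$formula <- formula
  environment(out$formula) <- baseenv()
  out$coding <- vapply(mf, function(v)
    if (is.numeric(v)) "" else paste(levels(factor(v)), collapse = " < "),
    character(1))
  structure(out, class = "pglmm_fit")
}

# Profiled ML at a given phylogenetic proportion h, in the eigenbasis of C
# (ev = eigenvalues; pass ev = 1s for the i.i.d. model). Weights are the
# eigenvalues of h*C + (1-h)*I.
.pglmm_profile_h <- function(yt, Xt, ev, h, U = NULL) {
  n <- length(yt)
  w <- h * ev + (1 - h)
  if (any(w <= 1e-14)) return(list(logLik = -Inf))
  sw <- sqrt(w)
  Xw <- Xt / sw
  yw <- yt / sw
  XtX <- crossprod(Xw)
  beta <- drop(solve(XtX, crossprod(Xw, yw)))
  r <- yw - drop(Xw %*% beta)
  s2 <- sum(r^2) / n
  ll <- -0.5 * n * log(2 * pi * s2) - 0.5 * sum(log(w)) - 0.5 * n
  se <- sqrt(diag(solve(XtX)) * s2)
  list(beta = beta, se = se, sigma2 = s2, logLik = ll)
}

# GLS + Gaussian log-likelihood for a fully specified covariance V.
.gls_fixedV <- function(y, X, V) {
  n <- length(y)
  R <- chol(V)
  yt <- backsolve(R, y, transpose = TRUE)
  Xt <- backsolve(R, X, transpose = TRUE)
  XtX <- crossprod(Xt)
  beta <- drop(solve(XtX, crossprod(Xt, yt)))
  r <- yt - drop(Xt %*% beta)
  ll <- -0.5 * n * log(2 * pi) - sum(log(diag(R))) - 0.5 * sum(r^2)
  list(beta = beta, se = sqrt(diag(solve(XtX))), logLik = ll)
}

#' @export
print.pglmm_fit <- function(x, ...) {
  cat("Gaussian phylogenetic mixed model (ML)\n")
  cat("  ", deparse(x$formula), "\n", sep = "")
  tab <- data.frame(Estimate = x$beta, SE = x$se, z = x$z, P = x$p)
  print(round(tab, 4))
  cat(sprintf("  sigma2_phylo = %.4f  sigma2_resid = %.4f\n",
              x$sigma2_phylo, x$sigma2_resid))
  cat(sprintf("  logLik = %.3f  AIC = %.1f  n = %d  converged = %s\n",
              x$logLik, x$AIC, x$n, x$converged))
  cod <- x$coding[nzchar(x$coding)]
  if (length(cod))
    cat("  factor coding (0 < 1): ",
        paste(names(cod), "=", cod, collapse = "; "), "\n", sep = "")
  invisible(x)
}

#' Univariate phylogenetic regression of masting on one predictor
#'
#' Convenience wrapper fitting \code{response ~ predictor} with the
#' phylogenetic random intercept, optionally on a subset of species (e.g.
#' only wind-pollinated taxa), with the covariance re-restricted to the
#' subset.
#'
#' @param response,predictor column names in \code{data}.
#' @param data trait data frame (see \code{\link{fit_pglmm}}).
#' @param C phylogenetic covariance.
#' @param subset optional logical vector over rows of \code{data}.
#' @return a \code{"pglmm_fit"}.
#' @export
univariate_pglmm <- function(response, predictor, data, C, subset = NULL) {
  if (!is.null(subset)) {
    data <- data[subset, , drop = FALSE]
  }
  if (nrow(data) < 5L)
    stop("subset leaves fewer than 5 species")
  fit_pglmm(stats::reformulate(predictor, response), data, C)
}

#' Phylogenetically corrected correlation of two traits
#'
#' The default method computes independent contrasts of both traits and
#' their correlation through the origin,
#' R = sum(cx*cy) / sqrt(sum(cx^2) * sum(cy^2)), with a t test on
#' (n_contrasts - 1) degrees of freedom. A GLS alternative (Brownian
#' phylogenetic regression of y on x) is available via
#' \code{method = "pgls"}.
#'
#' @param x,y named numeric trait vectors over the tips of \code{tree}.
#' @param tree a \code{"phylo"} object.
#' @param method "contrasts" (default) or "pgls".
#' @return object of class \code{"phylo_corr"}: \code{R}, \code{p_value},
#'   \code{n_contrasts}, \code{method}.
#' @export
phylo_correlation <- function(x, y, tree, method = c("contrasts", "pgls")) {
  method <- match.arg(method)
  x <- match_to_tips(tree, x, "x")
  y <- match_to_tips(tree, y, "y")
  if (method == "contrasts") {
    cx <- independent_contrasts(tree, x)
    cy <- independent_contrasts(tree, y)
    if (sum(cx^2) == 0 || sum(cy^2) == 0)
      stop("degenerate input: zero contrast variance")
    R <- sum(cx * cy) / sqrt(sum(cx^2) * sum(cy^2))
    df <- length(cx) - 1L
    nc <- length(cx)
  } else {
    C <- phylo_covariance(tree, normalize = TRUE)
    Ci <- solve(C)
    one <- rep(1, length(x))
    wx <- x - drop(crossprod(one, Ci %*% x)) / drop(crossprod(one, Ci %*% one))
    wy <- y - drop(crossprod(one, Ci %*% y)) / drop(crossprod(one, Ci %*% one))
    sxx <- drop(crossprod(wx, Ci %*% wx))
    syy <- drop(crossprod(wy, Ci %*% wy))
    if (sxx == 0 || syy == 0)
      stop("degenerate input: zero GLS variance")
    R <- drop(crossprod(wx, Ci %*% wy)) / sqrt(sxx * syy)
    df <- length(x) - 2L
    nc <- length(x) - 1L
  }
  tstat <- R * sqrt(df / max(1 - R^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = df, lower.tail = FALSE)
  structure(list(R = R, p_value = p, n_contrasts = nc, df = df,
                 method = method),
            class = "phylo_corr")
}

#' @export
print.phylo_corr <- function(x, ...) {
  cat(sprintf("Phylogenetically corrected correlation (%s)\n  R = %.3f  p = %.4g  (n contrasts = %d)\n",
              x$method, x$R, x$p_value, x$n_contrasts))
  invisible(x)
}

#' Two-group comparison of a trait
#'
#' Welch two-sample t test (default) on the log10-transformed trait,
#' comparing e.g. angiosperms with gymnosperms. Group 1 is the
#' alphabetically first level, so sign(t) = sign(mean1 - mean2) on the
#' transformed scale. Pooled-variance and untransformed variants are
#' available behind flags.
#'
#' @param values numeric trait vector.
#' @param group two-level grouping vector aligned with \code{values}.
#' @param log10 transform before testing (default TRUE).
#' @param var_equal pooled-variance t test instead of Welch (default FALSE).
#' @return object of class \code{"group_test"}: \code{t}, \code{df},
#'   \code{p}, \code{means} (per group, transformed scale), \code{groups}.
#' @export
group_t_test <- function(values, group, log10 = TRUE, var_equal = FALSE) {
  ok <- !is.na(values) & !is.na(group)
  values <- values[ok]; group <- group[ok]
  lev <- sort(unique(as.character(group)))
  if (length(lev) != 2L)
    stop("grouping must have exactly 2 levels (got ",
         length(lev), ")")
  g <- factor(as.character(group), levels = lev)
  if (any(table(g) < 2L))
    stop("both groups need at least 2 members")
  v <- if (log10) log10_transform(values) else values
  tt <- stats::t.test(v ~ g, var.equal = var_equal)
  structure(list(t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value,
                 means = stats::setNames(as.numeric(tapply(v, g, mean)), lev),
                 groups = lev, log10 = log10, welch = !var_equal),
            class = "group_test")
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf("Two-group t test (%s%s): %s vs %s\n",
              if (x$welch) "Welch" else "pooled",
              if (x$log10) ", log10 scale" else "",
              x$groups[1], x$groups[2]))
  cat(sprintf("  t = %.3f, df = %.2f, p = %.4g  (means %.3f vs %.3f)\n",
              x$t, x$df, x$p, x$means[1], x$means[2]))
  invisible(x)
}
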