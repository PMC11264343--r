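#' Likelihood-based partial R-squared between two model fits
#'
#' Compares a full model with a reduced model from which one factor has been
#' removed and measures the consequent reduction in likelihood:
#' \deqn{R^2_{lik} = 1 - \exp\{-\tfrac{2}{n}(\ln L_{full} - \ln L_{reduced})\}}
#' with n the number of species in the fitted models. The value may be
#' negative when the reduced model attains a higher likelihood (possible
#' across model classes, e.g. dropping the phylogenetic random effect); it
#' is reported as computed, never truncated at zero.
#'
#' The p-value is a likelihood-ratio test with degrees of freedom equal to
#' the parameter difference. Removing the phylogenetic random effect while
#' keeping the fixed effects changes the covariance class rather than a
#' nested fixed effect; its p uses the 50:50 boundary mixture
#' 0.5*chi2_0 + 0.5*chi2_1 and is labeled approximate via a warning.
#'
#' @param full,reduced \code{"pglmm_fit"} objects on the identical species
#'   set, both fitted by ML.
#' @param factor_name label for the removed factor (used in reports).
#' @return object of class \code{"partial_r2"}: \code{factor},
#'   \code{r2_lik}, \code{delta_logLik}, \code{df}, \code{p_value}, \code{n}.
#' @export
r2_lik <- function(full, reduced, factor_name = "factor") {
  stopifnot(inherits(full, "pglmm_fit"), inherits(reduced, "pglmm_fit"))
  if (full$n != reduced$n || !setequal(full$species, reduced$species))
    stop("full and reduced models must be fitted on the identical species set")
  n <- full$n
  delta <- full$logLik - reduced$logLik
  r2 <- 1 - exp(-2 * delta / n)
  lr <- 2 * delta
  boundary <- full$phylo && !reduced$phylo
  df <- full$k - reduced$k
  if (boundary) {
    warning("phylogenetic vs non-phylogenetic comparison: ",
            "boundary-mixture LRT p is approximate (non-nested covariance class)")
    p <- if (lr <= 0) 1 else 0.5 * stats::pchisq(lr, 1, lower.tail = FALSE)
  } else {
    if (df <= 0L) df <- max(df, 0L)
    p <- if (df == 0L) NA_real_
         else stats::pchisq(max(lr, 0), df, lower.tail = FALSE)
  }
  structure(list(factor = factor_name, r2_lik = r2, delta_logLik = delta,
                 df = df, p_value = p, n = n),
            class = "partial_r2")
}

#' @export
print.partial_r2 <- function(x, ...) {
  cat(sprintf("Partial R2_lik [%s] = %.4f  (delta logLik = %.3f, df = %d, p = %.4g, n = %d)\n",
              x$factor, x$r2_lik, x$delta_logLik, x$df, x$p_value, x$n))
  invisible(x)
}

#' Partition variance in a response among predictors and phylogeny
#'
#' Fits the full phylogenetic model, then one reduced model per predictor
#' (that predictor removed, phylogeny kept) and one non-phylogenetic model
#' (all predictors kept, random effect removed), and converts each
#' likelihood drop into a partial R2_lik. Results are sorted by R2,
#' largest first.
#'
#' @inheritParams fit_pglmm
#' @return data frame with columns \code{factor}, \code{r2_lik},
#'   \code{delta_logLik}, \code{df}, \code{p}, \code{converged}; the full
#'   fit is attached as attribute \code{"full_fit"}.
#' @export
partition_r2 <- function(formula, data, C) {
  full <- fit_pglmm(formula, data, C, phylo = TRUE)
  if (!full$converged) stop("full model did not converge")
  data <- data[stats::complete.cases(stats::model.frame(
    formula, data, na.action = stats::na.pass)), , drop = FALSE]
  terms_all <- attr(stats::terms(formula), "term.labels")
  rows <- list()
  for (tm in terms_all) {
    red <- tryCatch(
      fit_pglmm(stats::update(formula, paste(". ~ . -", tm)),
                data, C, phylo = TRUE),
      error = function(e) NULL)
    if (is.null(red) || !red$converged) {
      rows[[tm]] <- data.frame(factor = tm, r2_lik = NA, delta_logLik = NA,
                               df = NA, p = NA, converged = FALSE)
      next
    }
    pr <- r2_lik(full, red, tm)
    if (pr$delta_logLik < -1e-6)
      warning("nested reduction for '", tm,
              "' increased the likelihood; optimizer problem suspected")
    rows[[tm]] <- data.frame(factor = tm, r2_lik = pr$r2_lik,
                             delta_logLik = pr$delta_logLik, df = pr$df,
                             p = pr$p_value, converged = TRUE)
  }
  nophy <- fit_pglmm(formula, data, C, phylo = FALSE)
  pr <- suppressWarnings(r2_lik(full, nophy, "phylogeny"))
  rows[["phylogeny"]] <- data.frame(factor = "phylogeny", r2_lik = pr$r2_lik,
                                    delta_logLik = pr$delta_logLik,
                                    df = pr$df, p = pr$p_value,
                                    converged = nophy$converged)
  out <- do.call(rbind, rows)
  out <- out[order(-out$r2_lik, na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "full_fit") <- full
  out
}
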