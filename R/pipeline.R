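#' Build or validate an analysis configuration
#'
#' The configuration drives \code{\link{run_all}}. It can be given as a
#' list or as a YAML file path. Required fields: \code{tree} (Newick path),
#' \code{traits} (CSV path with a \code{species} column). Optional:
#' \code{crops} (long CSV of seed-crop series; when present the disparity
#' index is computed and used as the response), \code{response} (default
#' "D"), \code{height_var} (default "height"), \code{binary_vars} (default
#' life_form, pollination, spermatophyte), \code{log10_vars} (columns to
#' log10-transform; default none — synthetic data are already on the
#' analysis scale), \code{stratify_by} (binary column for stratified
#' univariate fits; default pollination), \code{n_sim}, \code{n_perm},
#' \code{k}, \code{min_length}, \code{seed}, \code{out_dir}.
#'
#' @param config list or YAML file path.
#' @return validated config list of class \code{"analysis_config"}.
#' @export
analysis_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  defaults <- list(response = "D", height_var = "height",
                   binary_vars = c("life_form", "pollination", "spermatophyte"),
                   log10_vars = character(0),
                   stratify_by = "pollination",
                   n_sim = 1000L, n_perm = 999L, k = 1, min_length = 2L,
                   seed = 42L, out_dir = NULL, crops = NULL)
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  for (nm in c("tree", "traits"))
    if (is.null(config[[nm]]))
      stop("config is missing required field '", nm, "'")
  for (nm in c("tree", "traits", "crops"))
    if (!is.null(config[[nm]]) && !file.exists(config[[nm]]))
      stop("config file not found: ", nm, " = ", config[[nm]])
  traits <- utils::read.csv(config$traits, stringsAsFactors = FALSE)
  need <- c("species", config$height_var, config$binary_vars)
  if (is.null(config$crops)) need <- c(need, config$response)
  miss <- setdiff(need, names(traits))
  if (length(miss))
    stop("trait table lacks columns: ", paste(miss, collapse = ", "))
  if (!config$stratify_by %in% config$binary_vars)
    stop("stratify_by must be one of the binary variables")
  structure(config, class = "analysis_config")
}

#' Run the full comparative analysis
#'
#' Executes the complete sequence on one dataset: seed-crop screening and
#' disparity computation (when series are supplied), log transforms, tree
#' pruning and covariance construction, Pagel's lambda fits (with
#' randomization tests) for the continuous traits, Fritz-Purvis D for the
#' binary traits, two-group t tests, univariate and stratified phylogenetic
#' regressions of the response on height, the multivariate phylogenetic
#' mixed model, the phylogenetically corrected height-response correlation,
#' and the likelihood-based partial R2 partition. All hypothesis tests are
#' two-sided and no multiple-testing correction is applied. Every
#' stochastic stage is seeded from \code{config$seed}, so a rerun with the
#' same config reproduces every value exactly.
#'
#' @param config an \code{\link{analysis_config}} (list or YAML path).
#' @return list of class \code{"analysis_report"} with one element per
#'   stage plus \code{config}, \code{dropped_species} and \code{warnings};
#'   written as TSVs to \code{config$out_dir} when set.
#' @export
run_all <- function(config) {
  config <- analysis_config(config)
  seed <- as.integer(config$seed)
  report <- list(config = unclass(config))
  traits <- utils::read.csv(config$traits, stringsAsFactors = FALSE)
  traits$species <- canonical_labels(traits$species)

  # stage 1: disparity from series, if supplied
  if (!is.null(config$crops)) {
    crops <- read_crops(config$crops)
    crops$species <- canonical_labels(crops$species)
    dt <- disparity_table(crops, k = config$k,
                          min_length = config$min_length)
    report$disparity <- dt
    traits[[config$response]] <-
      dt$D[match(traits$species, dt$species)]
    traits <- traits[!is.na(traits[[config$response]]), , drop = FALSE]
  }

  # stage 2: transforms
  for (v in config$log10_vars)
    traits[[v]] <- log10_transform(traits[[v]], traits$species)

  # stage 3: tree pruning and matching
  tree <- read_newick(config$tree)
  tree$tip.label <- canonical_labels(tree$tip.label)
  in_tree <- traits$species %in% tree$tip.label
  report$dropped_species <- traits$species[!in_tree]
  traits <- traits[in_tree, , drop = FALSE]
  if (nrow(traits) < 4L)
    stop("fewer than 4 species shared between tree and traits")
  tree <- prune_to(tree, traits$species)
  C <- phylo_covariance(tree, normalize = TRUE)

  cont_vars <- unique(c(config$height_var, config$response))
  getv <- function(v) stats::setNames(traits[[v]], traits$species)

  # stage 4: lambda for continuous traits
  report$lambda <- do.call(rbind, lapply(seq_along(cont_vars), function(i) {
    v <- cont_vars[i]
    rt <- lambda_randomization_test(getv(v), C, n_perm = config$n_perm,
                                    seed = seed + i)
    data.frame(trait = v, lambda = rt$lambda_hat,
               logLik = rt$fit$logLik, p_perm = rt$p_perm,
               p_lrt = rt$p_lrt, n_perm = rt$n_perm, seed = seed + i)
  }))

  # stage 5: Fritz-Purvis D for binary traits
  report$dstat <- do.call(rbind, lapply(seq_along(config$binary_vars),
                                        function(i) {
    v <- config$binary_vars[i]
    d <- fritz_purvis_d(tree, getv(v), n_sim = config$n_sim,
                        seed = seed + 100L + i)
    data.frame(trait = v, D_stat = d$D_stat, d_obs = d$d_obs,
               mean_d_random = d$mean_d_random,
               mean_d_brownian = d$mean_d_brownian,
               Pr = d$Pr, Pb = d$Pb, n_sim = d$n_sim, seed = d$seed)
  }))

  # stage 6: two-group t tests (already-transformed scale)
  tt <- list()
  for (v in c(config$height_var, config$response))
    for (g in config$binary_vars) {
      t1 <- group_t_test(traits[[v]], traits[[g]], log10 = FALSE)
      tt[[paste(v, g)]] <- data.frame(trait = v, by = g, t = t1$t,
                                      df = t1$df, p = t1$p)
    }
  report$t_tests <- do.call(rbind, tt)
  rownames(report$t_tests) <- NULL

  # stage 7: univariate and stratified height models
  uni <- univariate_pglmm(config$response, config$height_var, traits, C)
  strat <- lapply(c(`0` = 0, `1` = 1), function(gv)
    tryCatch(univariate_pglmm(config$response, config$height_var, traits, C,
                              subset = traits[[config$stratify_by]] == gv),
             error = function(e) NULL))
  sl <- function(f, grp) if (is.null(f)) NULL else
    data.frame(group = grp, beta = f$beta[2], se = f$se[2], z = f$z[2],
               p = f$p[2], n = f$n)
  report$univariate <- rbind(sl(uni, "all"),
                             sl(strat[["0"]], paste0(config$stratify_by, "=0")),
                             sl(strat[["1"]], paste0(config$stratify_by, "=1")))
  rownames(report$univariate) <- NULL

  # stage 8: multivariate PGLMM
  form <- stats::reformulate(c(config$height_var, config$binary_vars),
                             config$response)
  fit <- fit_pglmm(form, traits, C)
  report$pglmm <- data.frame(term = names(fit$beta), estimate = fit$beta,
                             se = fit$se, z = fit$z, p = fit$p,
                             row.names = NULL)
  report$pglmm_summary <- list(logLik = fit$logLik, AIC = fit$AIC,
                               sigma2_phylo = fit$sigma2_phylo,
                               sigma2_resid = fit$sigma2_resid,
                               n = fit$n, converged = fit$converged)

  # stage 9: phylogenetically corrected correlation
  pc <- phylo_correlation(getv(config$height_var), getv(config$response),
                          tree)
  report$correlation <- data.frame(R = pc$R, p = pc$p_value,
                                   n_contrasts = pc$n_contrasts)

  # stage 10: variance partition
  report$partition <- suppressWarnings(partition_r2(form, traits, C))

  class(report) <- "analysis_report"
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tabs <- c("disparity", "lambda", "dstat", "t_tests", "univariate",
            "pglmm", "correlation", "partition")
  for (nm in tabs)
    if (!is.null(report[[nm]]))
      utils::write.table(report[[nm]], file.path(dir, paste0(nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  log <- c(paste("mastphylo", as.character(utils::packageVersion("mastphylo"))),
           paste("seed:", report$config$seed),
           paste("species dropped at tree matching:",
                 if (length(report$dropped_species))
                   paste(report$dropped_species, collapse = ", ")
                 else "none"),
           "all tests two-sided; no multiple-testing correction applied")
  writeLines(log, file.path(dir, "run_log.txt"))
  invisible(dir)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("mastphylo analysis report\n")
  cat("\nPhylogenetic signal (continuous, Pagel's lambda):\n")
  print(x$lambda, row.names = FALSE)
  cat("\nPhylogenetic signal (binary, Fritz-Purvis D):\n")
  print(x$dstat[, c("trait", "D_stat", "Pr", "Pb")], row.names = FALSE)
  cat("\nMultivariate phylogenetic mixed model:\n")
  print(x$pglmm, row.names = FALSE)
  cat(sprintf("  logLik = %.3f  AIC = %.1f  n = %d\n",
              x$pglmm_summary$logLik, x$pglmm_summary$AIC, x$pglmm_summary$n))
  cat("\nHeight-response correlation (contrasts): ")
  cat(sprintf("R = %.3f, p = %.4g\n", x$correlation$R, x$correlation$p))
  cat("\nPartial R2_lik partition:\n")
  print(x$partition, row.names = FALSE)
  invisible(x)
}
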