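#' Simulate a pure-birth (Yule) phylogeny
#'
#' Pure-birth trees are the simplest model consistent with an ultrametric
#' species tree; the result is rescaled to height 1 so variance components
#' and Brownian rates are comparable across simulated trees.
#'
#' @param n_species number of tips (>= 2).
#' @param birth_rate speciation rate (shape only; height is rescaled).
#' @param seed optional integer seed; identical seeds give identical trees.
#' @return ultrametric \code{"phylo"} of height 1.
#' @export
simulate_tree <- function(n_species, birth_rate = 1, seed = NULL) {
  if (n_species < 2L) stop("n_species must be at least 2")
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::rphylo(n_species, birth = birth_rate, death = 0)
  ht <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / ht
  tree
}

#' Simulate a continuous trait with tunable phylogenetic signal
#'
#' One multivariate-normal draw with mean \code{mean} and covariance
#' \code{sigma2 * C(lambda)}, where C is the tree's (height-normalized)
#' Brownian covariance and lambda multiplies its off-diagonal part. lambda
#' = 1 gives pure Brownian motion; lambda = 0 gives i.i.d. tip values.
#'
#' @param tree a \code{"phylo"} object.
#' @param lambda_true signal strength in [0, 1].
#' @param sigma2_true trait variance at the tips (> 0).
#' @param mean trait mean.
#' @param seed optional integer seed.
#' @return named numeric vector over tips.
#' @export
simulate_continuous_trait <- function(tree, lambda_true = 1, sigma2_true = 1,
                                      mean = 0, seed = NULL) {
  if (sigma2_true <= 0) stop("sigma2_true must be positive")
  if (!is.null(seed)) set.seed(seed)
  C <- phylo_covariance(tree, normalize = TRUE)
  Cl <- lambda_rescale(C, lambda_true)
  n <- nrow(Cl)
  R <- chol(Cl + diag(1e-10, n))
  x <- mean + sqrt(sigma2_true) * drop(crossprod(R, stats::rnorm(n)))
  stats::setNames(x, rownames(C))
}

#' Simulate a binary trait under two null regimes
#'
#' \code{"brownian_threshold"} simulates a continuous Brownian trait on the
#' tree and sets the top \code{ceiling(prevalence * n)} tips to 1 (a
#' threshold model: clumped on the phylogeny, the regime where the
#' Fritz-Purvis D statistic centers on 0). \code{"shuffle"} assigns state 1
#' to a uniformly random tip subset of the same size (phylogenetically
#' random, D centers on 1). Prevalence is preserved exactly in both modes.
#'
#' @param tree a \code{"phylo"} object.
#' @param mode "brownian_threshold" or "shuffle".
#' @param prevalence proportion of tips in state 1, strictly inside (0, 1)
#'   and yielding both states.
#' @param seed optional integer seed.
#' @return named 0/1 vector over tips.
#' @export
simulate_binary_trait <- function(tree, mode = c("brownian_threshold", "shuffle"),
                                  prevalence = 0.5, seed = NULL) {
  mode <- match.arg(mode)
  if (prevalence <= 0 || prevalence >= 1)
    stop("prevalence must be strictly between 0 and 1")
  if (!is.null(seed)) set.seed(seed)
  n <- ape::Ntip(tree)
  m <- as.integer(ceiling(prevalence * n))
  if (m < 1L || m >= n)
    stop("prevalence yields a monomorphic trait at n = ", n)
  x <- stats::setNames(numeric(n), tree$tip.label)
  if (mode == "shuffle") {
    x[sample.int(n, m)] <- 1
  } else {
    z <- simulate_continuous_trait(tree, lambda_true = 1, sigma2_true = 1)
    x[order(z, decreasing = TRUE)[seq_len(m)]] <- 1
  }
  x
}

#' Simulate an annual seed-crop series
#'
#' Log production follows a stationary AR(1):
#' x_t = phi * x_(t-1) + eps_t with eps_t ~ Normal(0, innovation_sd^2) and
#' x_0 drawn from the stationary distribution; the series is
#' p_t = exp(crop_mean_log + x_t). phi sets the lag-1 autocorrelation and
#' innovation_sd the interannual variability that the disparity index
#' responds to.
#'
#' @param n_years series length (>= 2).
#' @param crop_mean_log mean of log production.
#' @param ar_phi lag-1 autocorrelation, |phi| < 1.
#' @param innovation_sd SD of the AR(1) innovations (0 gives a constant
#'   series).
#' @param seed optional integer seed.
#' @param species_id label attached to the series.
#' @return data frame with columns species, year, crop.
#' @export
simulate_seed_series <- function(n_years, crop_mean_log = 4, ar_phi = 0.3,
                                 innovation_sd = 1, seed = NULL,
                                 species_id = "sp1") {
  if (n_years < 2L) stop("n_years must be at least 2")
  if (abs(ar_phi) >= 1) stop("|ar_phi| must be < 1")
  if (innovation_sd < 0) stop("innovation_sd must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  x <- numeric(n_years)
  x[1] <- stats::rnorm(1, 0, innovation_sd / sqrt(1 - ar_phi^2))
  if (n_years > 1L) {
    eps <- stats::rnorm(n_years - 1L, 0, innovation_sd)
    for (t in 2:n_years) x[t] <- ar_phi * x[t - 1L] + eps[t - 1L]
  }
  data.frame(species = species_id, year = seq_len(n_years),
             crop = exp(crop_mean_log + x), stringsAsFactors = FALSE)
}

#' Configuration for a full synthetic comparative dataset
#'
#' Defaults emulate the study conditions of the masting analysis: 158
#' species; adult height (log10 scale) with strong phylogenetic signal
#' (lambda 0.926); binary pollination vector and Spermatophyte type clumped
#' on the tree (threshold model, prevalences 80/158 and 35/158) and life
#' form closer to random (shuffle, prevalence 0.5); response effects from
#' the multivariate model estimates (height 0.288, pollination 0.654, life
#' form -0.010, Spermatophyte -0.225, intercept -0.273); and a modest
#' phylogenetic share of the residual response variance. Seed-crop series
#' default to 20 years with lag-1 autocorrelation 0.3.
#'
#' @param n_species,birth_rate tree size and shape.
#' @param lambda_true,sigma2_true,trait_mean continuous-trait (height)
#'   generator parameters, on the log10 scale.
#' @param beta_intercept,beta_height,beta_lifeform,beta_spermatophyte,beta_pollination
#'   linear effects on the response (binary predictors coded 1 = tree,
#'   1 = gymnosperm, 1 = anemophilous).
#' @param sigma2_phylo_true,sigma2_resid_true response variance components.
#' @param prevalence named vector with elements \code{life_form},
#'   \code{pollination}, \code{spermatophyte}.
#' @param n_years,ar_phi,innovation_sd,crop_mean_log seed-crop series
#'   parameters.
#' @param series_link if TRUE, per-species series are generated whose
#'   realized disparity index replaces the simulated response (see
#'   \code{\link{simulate_full_dataset}}).
#' @param seed integer seed for the whole dataset.
#' @return list of class \code{"sim_config"}.
#' @export
sim_config <- function(n_species = 158L, birth_rate = 1,
                       lambda_true = 0.926, sigma2_true = 0.25,
                       trait_mean = 0.8,
                       beta_intercept = -0.273, beta_height = 0.288,
                       beta_lifeform = -0.010, beta_spermatophyte = -0.225,
                       beta_pollination = 0.654,
                       sigma2_phylo_true = 0.1, sigma2_resid_true = 0.3,
                       prevalence = c(life_form = 0.5,
                                      pollination = 80 / 158,
                                      spermatophyte = 35 / 158),
                       n_years = 20L, ar_phi = 0.3, innovation_sd = 1,
                       crop_mean_log = 4, series_link = FALSE,
                       seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_species >= 4L, cfg$sigma2_true > 0,
            cfg$sigma2_phylo_true >= 0, cfg$sigma2_resid_true >= 0,
            abs(cfg$ar_phi) < 1,
            all(cfg$prevalence > 0 & cfg$prevalence < 1),
            cfg$lambda_true >= 0, cfg$lambda_true <= 1)
  structure(cfg, class = "sim_config")
}

#' Simulate a complete comparative dataset with known ground truth
#'
#' Generates, under one seed: a pure-birth tree (height 1); a continuous
#' "height" trait with lambda-structured covariance; three binary traits
#' (threshold-model pollination and Spermatophyte type, shuffled life
#' form); and a response built as X beta + u + e with u ~ Normal(0,
#' sigma2_phylo * C) and e ~ Normal(0, sigma2_resid * I), all on the log10
#' analysis scale. With \code{series_link = TRUE} an AR(1) seed-crop series
#' is generated per species, its innovation SD chosen so the expected
#' disparity index matches the species' linear-predictor response, and the
#' realized log10 D replaces the response column (this changes the
#' response's noise distribution; both paths carry full ground truth).
#'
#' @param config a \code{\link{sim_config}} list.
#' @return list of class \code{"synthetic_dataset"}: \code{tree},
#'   \code{traits} (species, height, life_form, pollination, spermatophyte,
#'   D), \code{crops} (long data frame or NULL), \code{truth} (every
#'   generating parameter plus the latent components).
#' @export
simulate_full_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  tree <- simulate_tree(config$n_species, config$birth_rate)
  sp <- tree$tip.label
  C <- phylo_covariance(tree, normalize = TRUE)
  height <- simulate_continuous_trait(tree, config$lambda_true,
                                      config$sigma2_true, config$trait_mean)
  pol <- simulate_binary_trait(tree, "brownian_threshold",
                               config$prevalence[["pollination"]])
  spm <- simulate_binary_trait(tree, "brownian_threshold",
                               config$prevalence[["spermatophyte"]])
  lf <- simulate_binary_trait(tree, "shuffle",
                              config$prevalence[["life_form"]])
  n <- length(sp)
  u <- if (config$sigma2_phylo_true > 0)
    drop(crossprod(chol(C + diag(1e-10, n)),
                   stats::rnorm(n, 0, sqrt(config$sigma2_phylo_true))))
  else numeric(n)
  e <- stats::rnorm(n, 0, sqrt(config$sigma2_resid_true))
  xb <- config$beta_intercept + config$beta_height * height +
    config$beta_lifeform * lf + config$beta_spermatophyte * spm +
    config$beta_pollination * pol
  y <- xb + u + e

  crops <- NULL
  if (config$series_link) {
    # choose per-species innovation SD so that E[D] of the AR(1) series
    # matches 10^y: E|log increment| = sd_inc * sqrt(2/pi) with
    # sd_inc = innovation_sd * sqrt(2/(1+phi)) at large crop means
    target_D <- 10^y
    sd_i <- target_D * sqrt(pi / 2) / sqrt(2 / (1 + config$ar_phi))
    crops <- do.call(rbind, lapply(seq_along(sp), function(i)
      simulate_seed_series(config$n_years, config$crop_mean_log,
                           config$ar_phi, sd_i[i], species_id = sp[i])))
    dt <- disparity_table(crops)
    y <- log10_transform(stats::setNames(dt$D, dt$species))[sp]
  }

  traits <- data.frame(species = sp, height = as.numeric(height),
                       life_form = as.numeric(lf),
                       pollination = as.numeric(pol),
                       spermatophyte = as.numeric(spm),
                       D = as.numeric(y), stringsAsFactors = FALSE)
  structure(
    list(tree = tree, traits = traits, crops = crops,
         truth = c(unclass(config),
                   list(linear_predictor = xb, phylo_effect = u,
                        resid_effect = e))),
    class = "synthetic_dataset")
}

#' Write a synthetic dataset to plain-text files
#'
#' Writes \code{traits.csv}, \code{tree.nwk}, \code{crops.csv} (if present)
#' and \code{truth.yaml} (scalar ground-truth parameters) into a directory;
#' re-reading these files reproduces the identical analysis inputs.
#'
#' @param dataset a \code{"synthetic_dataset"}.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(traits = file.path(dir, "traits.csv"),
             tree = file.path(dir, "tree.nwk"),
             truth = file.path(dir, "truth.yaml"))
  utils::write.csv(dataset$traits, paths[["traits"]], row.names = FALSE)
  ape::write.tree(dataset$tree, paths[["tree"]])
  scalars <- Filter(function(v) is.atomic(v) && length(v) <= 3L,
                    dataset$truth)
  yaml::write_yaml(lapply(scalars, function(v)
    if (is.numeric(v)) as.numeric(v) else v), paths[["truth"]])
  if (!is.null(dataset$crops)) {
    paths[["crops"]] <- file.path(dir, "crops.csv")
    utils::write.csv(dataset$crops, paths[["crops"]], row.names = FALSE)
  }
  invisible(paths)
}
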