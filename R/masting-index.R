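#' Consecutive disparity index of a seed-crop series
#'
#' Quantifies mast-seeding intensity as the mean absolute natural-log ratio
#' of successive, pseudo-count-shifted annual seed (or fruit) crops:
#' \deqn{D = \frac{1}{n-1} \sum_{i=1}^{n-1}
#'   \left| \ln \frac{p_{i+1}+k}{p_i+k} \right|}
#' The index is sensitive both to interannual variability and to lag-1
#' autocorrelation of the series, and is zero if and only if the series is
#' constant. The pseudo-count \code{k} keeps the log ratio defined when a
#' crop fails completely (p = 0).
#'
#' @param values numeric vector of non-negative annual production values, in
#'   chronological order. Length at least 2.
#' @param k pseudo-count added to every value before taking ratios. Default 1.
#'   \code{k = 0} is allowed only when all values are strictly positive, in
#'   which case D is exactly invariant to rescaling the series.
#' @param species_id optional label carried into the result.
#' @return an object of class \code{"disparity_result"}: a list with
#'   \code{species_id}, \code{D}, \code{k}, \code{n_used} and a
#'   \code{zero_variance} flag.
#' @examples
#' consecutive_disparity(c(0, 10, 0, 10))$D   # log(11)
#' consecutive_disparity(c(5, 5, 5, 5))$D     # 0, with a warning
#' @export
consecutive_disparity <- function(values, k = 1, species_id = NA_character_) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2L)
    stop("series must contain at least 2 values (got ", n, ")")
  if (anyNA(values) || any(!is.finite(values)))
    stop("series contains missing or non-finite values",
         if (!is.na(species_id)) paste0(" [", species_id, "]") else "")
  if (any(values < 0))
    stop("series contains negative values")
  if (k < 0)
    stop("k must be non-negative")
  if (k == 0 && any(values == 0))
    stop("invalid k: k = 0 requires strictly positive series values")
  shifted <- values + k
  D <- mean(abs(diff(log(shifted))))
  zero_var <- length(unique(values)) == 1L
  if (zero_var)
    warning("constant series: D = 0",
            if (!is.na(species_id)) paste0(" [", species_id, "]") else "")
  structure(
    list(species_id = species_id, D = D, k = k, n_used = n,
         zero_variance = zero_var),
    class = "disparity_result"
  )
}

#' @export
print.disparity_result <- function(x, ...) {
  cat("Consecutive disparity index\n")
  if (!is.na(x$species_id)) cat("  species:", x$species_id, "\n")
  cat(sprintf("  D = %.4f  (n = %d years, k = %g)\n", x$D, x$n_used, x$k))
  if (x$zero_variance) cat("  note: zero-variance series\n")
  invisible(x)
}

#' Base-10 log transform with domain checking
#'
#' Trait values (adult height, masting D, ...) are log10-transformed before
#' analysis to correct for right skew. Non-positive values are a hard error
#' naming the offending entries rather than silently producing -Inf/NaN.
#'
#' @param values numeric vector, strictly positive.
#' @param labels optional names used in error messages (defaults to
#'   \code{names(values)}).
#' @return \code{log10(values)}, names preserved.
#' @export
log10_transform <- function(values, labels = names(values)) {
  force(labels)
  values <- as.numeric(values)
  bad <- which(!is.finite(values) | values <= 0)
  if (length(bad)) {
    who <- if (!is.null(labels)) labels[bad] else as.character(bad)
    stop("log10 transform requires strictly positive values; offending: ",
         paste(utils::head(who, 5L), collapse = ", "),
         if (length(bad) > 5L) ", ..." else "")
  }
  out <- log10(values)
  names(out) <- labels
  out
}

#' Screen seed-crop series before computing disparity
#'
#' Applies the inclusion rules for masting series: series shorter than
#' \code{min_length} (e.g. monocarpic species that fruit once) are excluded,
#' and zero-variance series are retained but flagged. Every exclusion is
#' logged with a reason code.
#'
#' @param crops long-format data frame with columns \code{species},
#'   \code{crop} and optionally \code{year}. When \code{year} is present,
#'   gaps inside a series are a hard error: no imputation rule is defined
#'   for missing years.
#' @param min_length minimum number of annual observations (default 2).
#' @return list with \code{retained} (the screened long data frame),
#'   \code{flags} (named character, "zero-variance" entries) and
#'   \code{exclusions} (data frame species/reason).
#' @export
screen_series <- function(crops, min_length = 2L) {
  crops <- validate_crops(crops)
  if (nrow(crops) == 0L) {
    warning("empty series set")
    return(list(retained = crops, flags = character(0),
                exclusions = data.frame(species = character(0),
                                        reason = character(0))))
  }
  excl <- list()
  flags <- character(0)
  keep <- character(0)
  for (sp in unique(crops$species)) {
    rows <- crops[crops$species == sp, , drop = FALSE]
    if (!is.null(rows$year)) {
      yrs <- sort(rows$year)
      if (anyDuplicated(yrs))
        stop("duplicated year for species ", sp)
      if (length(yrs) > 1L && any(diff(yrs) != 1))
        stop("missing years inside the series for species ", sp,
             "; gap handling is not defined")
    }
    if (nrow(rows) < min_length) {
      excl[[sp]] <- "too-short"
      next
    }
    if (length(unique(rows$crop)) == 1L)
      flags[sp] <- "zero-variance"
    keep <- c(keep, sp)
  }
  list(
    retained = crops[crops$species %in% keep, , drop = FALSE],
    flags = flags,
    exclusions = data.frame(species = names(excl),
                            reason = unlist(excl, use.names = FALSE),
                            stringsAsFactors = FALSE)
  )
}

#' Disparity index for a set of species
#'
#' Screens a long-format seed-crop table and computes the consecutive
#' disparity index per retained species.
#'
#' @inheritParams screen_series
#' @inheritParams consecutive_disparity
#' @return data frame with columns \code{species}, \code{n_used}, \code{D},
#'   \code{flags}; the exclusion log is attached as attribute
#'   \code{"exclusions"}.
#' @export
disparity_table <- function(crops, k = 1, min_length = 2L) {
  scr <- screen_series(crops, min_length = min_length)
  crops <- scr$retained
  species <- unique(crops$species)
  res <- lapply(species, function(sp) {
    rows <- crops[crops$species == sp, , drop = FALSE]
    if (!is.null(rows$year)) rows <- rows[order(rows$year), , drop = FALSE]
    d <- suppressWarnings(
      consecutive_disparity(rows$crop, k = k, species_id = sp))
    data.frame(species = sp, n_used = d$n_used, D = d$D,
               flags = if (sp %in% names(scr$flags)) scr$flags[[sp]] else "",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(species = character(0), n_used = integer(0),
                      D = numeric(0), flags = character(0))
  rownames(out) <- NULL
  attr(out, "exclusions") <- scr$exclusions
  out
}

#' Read a seed-crop table from CSV
#'
#' Accepts either a long table (columns \code{species}, \code{year},
#' \code{crop}) or a wide table (one row per species, first column the
#' species name, remaining columns the annual values; NA cells at the tail
#' are dropped per species).
#'
#' @param path CSV file, header required, "." decimal separator.
#' @return long-format data frame (species, year, crop).
#' @export
read_crops <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (all(c("species", "crop") %in% names(df)))
    return(validate_crops(df))
  # wide: first column species, the rest annual values
  sp_col <- names(df)[1L]
  long <- do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
    vals <- as.numeric(df[i, -1L])
    ok <- !is.na(vals)
    data.frame(species = df[[sp_col]][i],
               year = seq_len(sum(ok)),
               crop = vals[ok],
               stringsAsFactors = FALSE)
  }))
  validate_crops(long)
}

validate_crops <- function(crops) {
  if (!is.data.frame(crops) || !all(c("species", "crop") %in% names(crops)))
    stop("crops must be a data frame with columns 'species' and 'crop'")
  crops$crop <- as.numeric(crops$crop)
  if (nrow(crops) > 0L) {
    if (anyNA(crops$crop))
      stop("crop values contain NA")
    if (any(crops$crop < 0))
      stop("crop values must be non-negative")
  }
  crops
}
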