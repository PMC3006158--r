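#' Preprocessing parameters
#'
#' Settings for the clip / log / per-sample standardization pipeline applied
#' before any scoring. Defaults follow common Affymetrix practice: raw
#' intensities are clipped into \[10, 16000\] and log2-transformed, then each
#' sample (column) is standardized to zero mean and unit variance across
#' genes.
#'
#' @param floor lower clip bound (default 10). Must be positive so the log
#'   transform is defined.
#' @param ceiling upper clip bound (default 16000); must exceed `floor`.
#' @param log_base base of the log transform (default 2); must be > 1.
#' @param standardize whether to standardize samples (default TRUE).
#' @param sd_denominator `"n-1"` (sample standard deviation, default) or
#'   `"n"` (population) in the standardization step.
#'
#' @return A list of class `PreprocessParams`.
#' @export
preprocess_params <- function(floor = 10, ceiling = 16000, log_base = 2,
                              standardize = TRUE,
                              sd_denominator = c("n-1", "n")) {
  sd_denominator <- match.arg(sd_denominator)
  if (!is.numeric(floor) || !is.numeric(ceiling) || floor <= 0 ||
      floor >= ceiling)
    stop("require 0 < floor < ceiling")
  if (!is.numeric(log_base) || log_base <= 1)
    stop("log_base must be > 1")
  structure(list(floor = floor, ceiling = ceiling, log_base = log_base,
                 standardize = isTRUE(standardize),
                 sd_denominator = sd_denominator),
            class = "PreprocessParams")
}

#' Clip expression values into a fixed range
#'
#' Values below `params$floor` are raised to the floor and values above
#' `params$ceiling` lowered to the ceiling; in-range values are unchanged.
#'
#' @param ds an [expression_dataset()].
#' @param params a [preprocess_params()] object.
#' @return The dataset with clipped values.
#' @export
clip_values <- function(ds, params = preprocess_params()) {
  stopifnot(inherits(ds, "ExpressionDataset"),
            inherits(params, "PreprocessParams"))
  ds$values[] <- pmin(pmax(ds$values, params$floor), params$ceiling)
  ds
}

#' Log-transform expression values
#'
#' Elementwise logarithm in base `params$log_base`. All values must be
#' strictly positive; clip first (the default floor of 10 guarantees this).
#'
#' @inheritParams clip_values
#' @return The dataset with log-transformed values.
#' @export
log_transform <- function(ds, params = preprocess_params()) {
  stopifnot(inherits(ds, "ExpressionDataset"),
            inherits(params, "PreprocessParams"))
  if (any(ds$values <= 0))
    stop("non-positive values present; run clip_values() with a positive ",
         "floor before log_transform()")
  ds$values[] <- log(ds$values, base = params$log_base)
  ds
}

#' Standardize each sample to zero mean and unit variance
#'
#' Column-wise (per-sample, across genes) centring and scaling. Because the
#' operation uses no cross-sample statistics it is fold-independent under
#' leave-one-out cross-validation and can safely be applied once to the
#' whole matrix.
#'
#' @inheritParams clip_values
#' @param sd_denominator `"n-1"` (default) or `"n"`.
#' @return The dataset with each column at mean 0, sd 1.
#' @export
standardize_samples <- function(ds, sd_denominator = c("n-1", "n")) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  sd_denominator <- match.arg(sd_denominator)
  n <- nrow(ds$values)
  mu <- colMeans(ds$values)
  centred <- sweep(ds$values, 2L, mu, "-")
  ss <- colSums(centred^2)
  s <- sqrt(ss / if (sd_denominator == "n-1") n - 1L else n)
  if (any(s == 0))
    stop("zero-variance sample column: ",
         paste(colnames(ds$values)[s == 0], collapse = ", "))
  ds$values[] <- sweep(centred, 2L, s, "/")
  ds
}

#' Full preprocessing pipeline: clip, log, standardize
#'
#' @inheritParams clip_values
#' @return The preprocessed dataset.
#' @export
preprocess <- function(ds, params = preprocess_params()) {
  ds <- log_transform(clip_values(ds, params), params)
  if (params$standardize)
    ds <- standardize_samples(ds, params$sd_denominator)
  ds
}
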