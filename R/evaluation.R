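#' Leave-one-out cross-validation with in-fold doublet selection
#'
#' For each sample in turn: drop it, and (raw mode) fit the classifier on
#' all genes of the remaining samples, or (doublet modes) rerun the entire
#' selection pipeline — gene t-scores, gene ranking, doublet construction,
#' doublet t-scores, greedy unique-doublet pruning — on the training
#' samples only, fit on the training doublet features, map the held-out
#' sample through [transform_samples()], and predict. The held-out sample
#' influences no part of feature selection, so selection bias (feature
#' leakage) cannot inflate the estimate.
#'
#' @param ds a preprocessed [expression_dataset()] with >= 4 samples.
#' @param classifier a `ClassifierAdapter` (see [builtin_classifiers()]).
#' @param feature_mode `"raw"`, `"sumdiff"`, `"mul"` or `"sign"`. Raw mode
#'   uses all N genes (the baseline convention), not the top-K subset.
#' @param fraction_pct top-gene percentage for doublet modes (ignored for
#'   raw).
#' @param method t-score form passed to the selection pipeline.
#' @return A list of class `CVReport`: `config` (classifier name,
#'   hyperparams, feature_mode, fraction_pct, method), `per_fold`
#'   (data.frame: `sample_id`, `true`, `predicted`, `n_doublets`),
#'   `accuracy` (correct / M), and for doublet modes `doublets`, the
#'   selection refit on the full dataset (the reportable biomarker set).
#' @export
loocv <- function(ds, classifier, feature_mode = c("raw", "sumdiff", "mul",
                                                   "sign"),
                  fraction_pct = 10, method = c("welch", "pooled")) {
  stopifnot(inherits(ds, "ExpressionDataset"),
            inherits(classifier, "ClassifierAdapter"))
  feature_mode <- match.arg(feature_mode)
  method <- match.arg(method)
  M <- ncol(ds$values)
  if (M < 4L) stop("LOOCV needs at least 4 samples")

  sample_ids <- colnames(ds$values)
  predicted <- character(M)
  n_doublets <- integer(M)
  for (m in seq_len(M)) {
    train <- subset_samples(ds, -m)
    if (min(table(train$labels)) < 2L)
      stop("fold ", m, ": a training class has fewer than 2 samples; ",
           "use a larger dataset")
    if (feature_mode == "raw") {
      model <- classifier$fit(train$values, train$labels)
      newx <- ds$values[, m, drop = FALSE]
      n_doublets[m] <- 0L
    } else {
      dset <- select_unique_doublets(train, mode = feature_mode,
                                     fraction_pct = fraction_pct,
                                     method = method)
      model <- classifier$fit(transform_samples(train$values, dset),
                              train$labels)
      newx <- transform_samples(ds$values[, m, drop = FALSE], dset)
      n_doublets[m] <- nrow(dset)
    }
    predicted[m] <- classifier$predict(model, newx)[1L]
  }
  per_fold <- data.frame(sample_id = sample_ids,
                         true = unname(ds$labels),
                         predicted = predicted,
                         n_doublets = n_doublets,
                         stringsAsFactors = FALSE)
  report <- list(
    config = list(classifier = classifier$name,
                  hyperparams = classifier$hyperparams,
                  feature_mode = feature_mode,
                  fraction_pct = if (feature_mode == "raw") NULL
                                 else fraction_pct,
                  method = method),
    per_fold = per_fold,
    accuracy = sum(per_fold$true == per_fold$predicted) / M)
  if (feature_mode != "raw")
    report$doublets <- select_unique_doublets(ds, mode = feature_mode,
                                              fraction_pct = fraction_pct,
                                              method = method)
  class(report) <- "CVReport"
  report
}

#' @export
print.CVReport <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("CVReport: %s / %s%s — accuracy %.4f (%d/%d folds)\n",
              cfg$classifier, cfg$feature_mode,
              if (is.null(cfg$fraction_pct)) ""
              else sprintf(" @ top %g%%", cfg$fraction_pct),
              x$accuracy,
              sum(x$per_fold$true == x$per_fold$predicted),
              nrow(x$per_fold)))
  invisible(x)
}

#' Sweep classifiers, doublet modes and gene fractions under LOOCV
#'
#' Runs [loocv()] over the Cartesian product of the supplied classifiers,
#' doublet modes, and top-gene fractions, plus one fraction-independent raw
#' baseline per classifier when `"raw"` is among the modes. The default
#' fraction grid is the conventional top 0.2, 0.4, 0.6, 0.8, 1, 2, 4 and
#' 10 percent of genes; arbitrary fractions in (0, 100] are accepted.
#' Report order is deterministic: raw baselines first (classifier order),
#' then classifier x mode x fraction in the given grid order.
#'
#' @param ds a preprocessed [expression_dataset()].
#' @param classifiers list of `ClassifierAdapter`s (default
#'   [builtin_classifiers()]).
#' @param modes feature modes to evaluate.
#' @param fractions top-gene percentage grid for doublet modes.
#' @param method t-score form.
#' @return List of `CVReport`s.
#' @export
cv_sweep <- function(ds, classifiers = builtin_classifiers(),
                     modes = c("raw", "sumdiff", "mul", "sign"),
                     fractions = c(0.2, 0.4, 0.6, 0.8, 1, 2, 4, 10),
                     method = c("welch", "pooled")) {
  method <- match.arg(method)
  if (inherits(classifiers, "ClassifierAdapter"))
    classifiers <- list(classifiers)
  if (!length(classifiers)) stop("no classifiers given")
  modes <- match.arg(modes, several.ok = TRUE)
  doublet_modes <- setdiff(modes, "raw")
  if (length(doublet_modes) && !length(fractions))
    stop("doublet modes require a nonempty fraction grid")
  reports <- list()
  if ("raw" %in% modes)
    for (clf in classifiers)
      reports[[length(reports) + 1L]] <-
        loocv(ds, clf, feature_mode = "raw", method = method)
  for (clf in classifiers)
    for (mode in doublet_modes)
      for (f in fractions)
        reports[[length(reports) + 1L]] <-
          loocv(ds, clf, feature_mode = mode, fraction_pct = f,
                method = method)
  reports
}
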