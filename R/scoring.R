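#' Two-sample t-scores for every feature
#'
#' For each row of `values` computes the two-class t-score
#' \deqn{t = (\bar{x}_1 - \bar{x}_2) / \sqrt{s_1^2/n_1 + s_2^2/n_2}}
#' (Welch, unequal-variance form; the default) or the pooled-variance
#' Student form. Class 1 is the lexicographically smaller label, so a
#' positive score means higher expression in that class. Variances use the
#' n-1 denominator.
#'
#' A feature whose denominator is exactly zero (constant within each class)
#' gets t = 0 if the class means are also equal; otherwise it separates the
#' classes perfectly and is assigned sign(mean difference) times
#' (largest finite |t| in the table + 1) so it ranks first rather than
#' producing an infinity.
#'
#' @param values numeric feature x sample matrix with rownames.
#' @param labels two-class label vector, one per column (named vectors are
#'   matched by column name).
#' @param method `"welch"` (default) or `"pooled"`.
#'
#' @return A `data.frame` of class `GeneScoreTable` with columns
#'   `feature_id`, `t_score`, `mean_1`, `mean_2`, `var_1`, `var_2`, and
#'   attributes `classes` (label for class 1 and 2), `n_1`, `n_2`, `method`.
#' @export
t_scores <- function(values, labels, method = c("welch", "pooled")) {
  method <- match.arg(method)
  if (inherits(values, "ExpressionDataset")) {
    if (missing(labels)) labels <- values$labels
    values <- values$values
  }
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (!all(is.finite(values))) stop("non-finite values in matrix")
  labels <- as.character(labels)
  if (!is.null(names(labels)) && !is.null(colnames(values)))
    labels <- labels[colnames(values)]
  if (length(labels) != ncol(values))
    stop("length(labels) must equal ncol(values)")
  ci <- class_index(labels, min_per_class = 2L)
  n1 <- length(ci$idx1); n2 <- length(ci$idx2)

  x1 <- values[, ci$idx1, drop = FALSE]
  x2 <- values[, ci$idx2, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1L)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1L)

  se2 <- if (method == "welch") {
    v1 / n1 + v2 / n2
  } else {
    sp2 <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / (n1 + n2 - 2L)
    sp2 * (1 / n1 + 1 / n2)
  }
  diff <- m1 - m2
  t <- diff / sqrt(se2)
  degenerate <- se2 == 0
  if (any(degenerate)) {
    t[degenerate & diff == 0] <- 0
    sep <- degenerate & diff != 0
    if (any(sep)) {
      finite_max <- suppressWarnings(max(abs(t[is.finite(t)]), 0))
      t[sep] <- sign(diff[sep]) * (finite_max + 1)
    }
  }
  ids <- rownames(values)
  if (is.null(ids)) ids <- paste0("f", seq_len(nrow(values)))
  out <- data.frame(feature_id = ids, t_score = unname(t),
                    mean_1 = unname(m1), mean_2 = unname(m2),
                    var_1 = unname(v1), var_2 = unname(v2),
                    stringsAsFactors = FALSE)
  attr(out, "classes") <- ci$classes
  attr(out, "n_1") <- n1
  attr(out, "n_2") <- n2
  attr(out, "method") <- method
  class(out) <- c("GeneScoreTable", "data.frame")
  out
}

#' Rank features by decreasing absolute t-score
#'
#' Stable sort: ties in |t| preserve the input (table) order, so rankings
#' are deterministic across runs and platforms.
#'
#' @param table a [t_scores()] result.
#' @return Character vector of feature IDs, best first.
#' @export
rank_features <- function(table) {
  stopifnot(inherits(table, "GeneScoreTable") ||
              all(c("feature_id", "t_score") %in% names(table)))
  ord <- order(-abs(table$t_score), seq_len(nrow(table)))
  table$feature_id[ord]
}

#' Number of top genes selected by a percentage fraction
#'
#' `K = max(2, floor(N * fraction_pct / 100))`, clamped below at 2 because
#' doublet formation needs at least one pair, and never exceeding N.
#'
#' @param N total number of genes (>= 2).
#' @param fraction_pct percentage of genes to keep, in (0, 100].
#' @return Integer K.
#' @export
top_fraction_count <- function(N, fraction_pct) {
  if (!is.numeric(N) || N < 2) stop("N must be >= 2")
  if (!is.numeric(fraction_pct) || fraction_pct <= 0 || fraction_pct > 100)
    stop("fraction_pct must be in (0, 100]")
  min(as.integer(N), max(2L, as.integer(floor(N * fraction_pct / 100))))
}

#' Write a gene score table to TSV
#'
#' @param table a [t_scores()] result.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_scores <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
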