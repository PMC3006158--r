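#' Two-class expression dataset
#'
#' Bundles a genes-by-samples expression matrix with a two-class label
#' vector. Rows are genes (features), columns are samples, following the
#' usual microarray N x M convention. Exactly two distinct class labels are
#' required; the lexicographically smaller label is treated as class 1 in
#' all t-score computations so that t-score signs are reproducible.
#'
#' @param values numeric matrix, genes x samples, with unique rownames
#'   (gene IDs) and colnames (sample IDs).
#' @param labels class labels, one per sample. Either named by sample ID
#'   (matched to columns, order-independent) or unnamed in column order.
#' @param check_finite reject non-finite values (default TRUE). Loading
#'   rejects missing values; see `impute` in [read_expression()].
#'
#' @return An object of class `ExpressionDataset`: a list with elements
#'   `values` (the matrix) and `labels` (character vector named by sample
#'   ID, in column order).
#' @export
expression_dataset <- function(values, labels, check_finite = TRUE) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix (genes x samples)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have rownames (gene IDs) and colnames (sample IDs)")
  if (nrow(values) < 2L || ncol(values) < 2L)
    stop("need at least 2 genes and 2 samples")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene IDs: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample IDs: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  if (check_finite && !all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop("non-finite expression value at gene '", rownames(values)[bad[1L]],
         "', sample '", colnames(values)[bad[2L]], "'")
  }
  label_names <- names(labels)
  labels <- as.character(labels)   # drops names; re-attach below
  names(labels) <- label_names
  if (!is.null(names(labels))) {
    missing <- setdiff(colnames(values), names(labels))
    extra <- setdiff(names(labels), colnames(values))
    if (length(missing))
      stop("samples present only in the matrix: ",
           paste(missing, collapse = ", "))
    if (length(extra))
      stop("samples present only in the labels: ",
           paste(extra, collapse = ", "))
    labels <- labels[colnames(values)]
  } else {
    if (length(labels) != ncol(values))
      stop("length(labels) must equal the number of samples")
    names(labels) <- colnames(values)
  }
  if (anyNA(labels)) stop("missing class labels")
  classes <- sort(unique(labels))
  if (length(classes) != 2L)
    stop("exactly two classes required, found ", length(classes), ": ",
         paste(classes, collapse = ", "))
  if (any(table(labels) < 1L)) stop("each class needs at least one sample")
  structure(list(values = values, labels = labels),
            class = "ExpressionDataset")
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  tab <- table(x$labels)
  cat("ExpressionDataset: ", nrow(x$values), " genes x ", ncol(x$values),
      " samples\n", sep = "")
  cat("classes: ", paste(sprintf("%s (n=%d)", names(tab), tab),
                         collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.ExpressionDataset <- function(x) dim(x$values)

# Column subset retaining the class, without revalidating finiteness.
subset_samples <- function(ds, keep) {
  structure(list(values = ds$values[, keep, drop = FALSE],
                 labels = ds$labels[keep]),
            class = "ExpressionDataset")
}

# Class sample counts in lexicographic label order; errors if a class is
# too small for variance computation.
class_index <- function(labels, min_per_class = 2L) {
  classes <- sort(unique(labels))
  idx <- lapply(classes, function(cl) which(labels == cl))
  n <- lengths(idx)
  if (any(n < min_per_class))
    stop("class '", classes[which(n < min_per_class)[1L]], "' has fewer than ",
         min_per_class, " samples")
  list(classes = classes, idx1 = idx[[1L]], idx2 = idx[[2L]])
}
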