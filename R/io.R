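#' Read a genes-by-samples expression matrix
#'
#' Expects a TSV (or CSV, by extension or `sep`) whose first column holds
#' gene IDs and whose header row holds sample IDs — the layout written by
#' [write_expression()]. The returned dataset is unlabeled; attach the
#' class labels with [attach_labels()].
#'
#' @param path matrix file.
#' @param sep field separator; default inferred from extension (`.csv` →
#'   comma, otherwise tab).
#' @param transpose set TRUE if the file is samples x genes.
#' @param impute `"none"` (default: any missing value is an error) or
#'   `"gene_mean"` (replace NAs by the gene's row mean).
#' @return A list with `values` (matrix) — pass to [attach_labels()] to
#'   get a full `ExpressionDataset`.
#' @export
read_expression <- function(path, sep = NULL, transpose = FALSE,
                            impute = c("none", "gene_mean")) {
  impute <- match.arg(impute)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = NULL,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  if (ncol(df) < 2L) stop("matrix file needs an ID column plus data columns")
  ids <- as.character(df[[1L]])
  num <- df[, -1L, drop = FALSE]
  bad <- !vapply(num, is.numeric, logical(1))
  if (any(bad))
    stop("non-numeric cells in column(s): ",
         paste(names(num)[bad], collapse = ", "))
  values <- as.matrix(num)
  rownames(values) <- ids
  if (transpose) values <- t(values)
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene IDs in ", path)
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample IDs in ", path)
  if (anyNA(values)) {
    if (impute == "none") {
      bad <- which(is.na(values), arr.ind = TRUE)[1L, ]
      stop("missing value at gene '", rownames(values)[bad[1L]],
           "', sample '", colnames(values)[bad[2L]],
           "'; rerun with impute = \"gene_mean\" to impute")
    }
    for (i in which(rowSums(is.na(values)) > 0L)) {
      v <- values[i, ]
      v[is.na(v)] <- mean(v, na.rm = TRUE)
      values[i, ] <- v
    }
  }
  list(values = values)
}

#' Attach class labels to an expression matrix
#'
#' The label file has two columns (sample ID, class label), with or
#' without a header; samples are matched to matrix columns by ID,
#' order-independently. Samples present in only one of the two files are
#' an error, as are more or fewer than two classes.
#'
#' @param ds result of [read_expression()] (or an `ExpressionDataset`
#'   whose labels should be replaced).
#' @param path labels file (TSV; CSV by extension).
#' @return An [expression_dataset()].
#' @export
attach_labels <- function(ds, path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  lab <- utils::read.table(path, header = FALSE, sep = sep,
                           stringsAsFactors = FALSE, comment.char = "")
  if (ncol(lab) < 2L) stop("labels file needs two columns: sample ID, label")
  # tolerate a header row
  if (nrow(lab) == ncol(ds$values) + 1L &&
      !(lab[[1L]][1L] %in% colnames(ds$values)))
    lab <- lab[-1L, , drop = FALSE]
  labels <- as.character(lab[[2L]])
  names(labels) <- as.character(lab[[1L]])
  if (anyDuplicated(names(labels)))
    stop("duplicate sample IDs in labels file")
  expression_dataset(ds$values, labels)
}

#' Write an expression matrix (and optionally labels) to TSV
#'
#' Emits the same dialect [read_expression()] reads: gene IDs in the first
#' column (`gene_id` header), sample IDs as the remaining headers. With
#' `labels_path` also writes the two-column sample/label file.
#'
#' @param ds an `ExpressionDataset` (or list with `values`).
#' @param path output matrix file.
#' @param labels_path optional output labels file.
#' @return Invisibly, `path`.
#' @export
write_expression <- function(ds, path, labels_path = NULL) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(gene_id = rownames(ds$values), ds$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  if (!is.null(labels_path)) {
    if (is.null(ds$labels)) stop("dataset has no labels to write")
    utils::write.table(data.frame(names(ds$labels), unname(ds$labels)),
                       labels_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Write cross-validation reports to JSON
#'
#' One `CVReport` or a list of them; the JSON carries a schema version,
#' the configuration, per-fold records (from which the stored accuracy is
#' recomputable) and, for doublet modes, the full-data doublet set.
#'
#' @param report a `CVReport` or list of `CVReport`s.
#' @param path output JSON file.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path) {
  if (inherits(report, "CVReport")) report <- list(report)
  stopifnot(all(vapply(report, inherits, logical(1), "CVReport")))
  payload <- list(
    schema_version = 1L,
    reports = lapply(report, function(r) {
      out <- list(config = r$config, accuracy = r$accuracy,
                  per_fold = r$per_fold)
      if (!is.null(r$doublets))
        out$doublets <- as.data.frame(r$doublets)
      out
    }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Read a report file written by [write_report()]
#'
#' @param path JSON file.
#' @return List with `schema_version` and `reports` (each with `config`,
#'   `accuracy`, `per_fold` data.frame, optional `doublets`).
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  rows_to_df <- function(rows) {
    cols <- names(rows[[1L]])
    out <- lapply(cols, function(cn)
      unlist(lapply(rows, `[[`, cn), use.names = FALSE))
    names(out) <- cols
    as.data.frame(out, stringsAsFactors = FALSE)
  }
  raw$reports <- lapply(raw$reports, function(r) {
    r$accuracy <- as.numeric(r$accuracy)
    r$per_fold <- rows_to_df(r$per_fold)
    if (!is.null(r$doublets)) r$doublets <- rows_to_df(r$doublets)
    r
  })
  raw$schema_version <- as.integer(raw$schema_version)
  raw
}
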