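#' Build the doublet feature matrix for all gene pairs
#'
#' For every unordered pair (a, b) of the K input genes, taken with a
#' before b in the input (ranked) order, derives pair features:
#' \describe{
#'   \item{sumdiff}{the "positive doublet" g_a + g_b and the "negative
#'     doublet" g_a - g_b, elementwise; 2 rows per pair, K(K-1) in total,
#'     each sum row immediately followed by its diff row.}
#'   \item{mul}{g_a * g_b elementwise; K(K-1)/2 rows.}
#'   \item{sign}{sign(g_a - g_b) elementwise with sign(0) = 0; K(K-1)/2
#'     rows with values in \{-1, 0, +1\}. Invariant under any strictly
#'     increasing transform of the expression values.}
#' }
#' Pairs are enumerated in lexicographic (a, b) order of the input rows,
#' so the row order is deterministic.
#'
#' @param values numeric K x M matrix (K >= 2) with rownames; typically the
#'   top-K submatrix in ranked gene order.
#' @param mode `"sumdiff"`, `"mul"` or `"sign"`.
#' @return A list of class `DoubletMatrix` with elements `doublets` (a
#'   data.frame: `gene_a`, `gene_b`, `transform`), `values` (doublets x
#'   samples matrix, rownames are doublet IDs), and `mode`.
#' @export
make_doublets <- function(values, mode = c("sumdiff", "mul", "sign")) {
  mode <- match.arg(mode)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  K <- nrow(values)
  if (K < 2L) stop("need at least 2 genes to form doublets")
  ids <- rownames(values)
  if (is.null(ids)) ids <- paste0("g", seq_len(K))

  ia <- rep.int(seq_len(K - 1L), times = (K - 1L):1L)
  ib <- unlist(lapply(seq_len(K - 1L), function(i) (i + 1L):K),
               use.names = FALSE)
  A <- values[ia, , drop = FALSE]
  B <- values[ib, , drop = FALSE]

  if (mode == "sumdiff") {
    P <- length(ia)
    out <- matrix(0, nrow = 2L * P, ncol = ncol(values))
    odd <- seq.int(1L, 2L * P, by = 2L)
    out[odd, ] <- A + B
    out[odd + 1L, ] <- A - B
    gene_a <- rep(ids[ia], each = 2L)
    gene_b <- rep(ids[ib], each = 2L)
    transform <- rep(c("sum", "diff"), times = P)
  } else {
    out <- if (mode == "mul") A * B else sign(A - B)
    gene_a <- ids[ia]
    gene_b <- ids[ib]
    transform <- rep(mode, length(ia))
  }
  colnames(out) <- colnames(values)
  rownames(out) <- doublet_id(gene_a, gene_b, transform)
  structure(list(doublets = data.frame(gene_a = gene_a, gene_b = gene_b,
                                       transform = transform,
                                       stringsAsFactors = FALSE),
                 values = out, mode = mode),
            class = "DoubletMatrix")
}

doublet_id <- function(gene_a, gene_b, transform) {
  out <- character(length(transform))
  for (tr in unique(transform)) {
    i <- transform == tr
    out[i] <- switch(tr,
      sum = paste0(gene_a[i], "+", gene_b[i]),
      diff = paste0(gene_a[i], "-", gene_b[i]),
      mul = paste0(gene_a[i], "*", gene_b[i]),
      sign = paste0("sgn(", gene_a[i], "-", gene_b[i], ")"))
  }
  out
}

#' Greedy pruning to unique doublets
#'
#' Scans candidate doublets in the given (ranked) order and keeps a doublet
#' iff neither of its member genes appears in an already-kept doublet, so
#' that no gene occurs in more than one kept pair.
#'
#' @param doublets data.frame with columns `gene_a`, `gene_b` (plus any
#'   others, carried through), ordered by decreasing priority.
#' @return The kept rows, in kept order, with a `rank` column prepended.
#' @export
prune_unique_doublets <- function(doublets) {
  stopifnot(is.data.frame(doublets),
            all(c("gene_a", "gene_b") %in% names(doublets)))
  ga <- as.character(doublets$gene_a)
  gb <- as.character(doublets$gene_b)
  genes <- unique(c(ga, gb))
  ia <- match(ga, genes)
  ib <- match(gb, genes)
  used <- logical(length(genes))
  n_free <- length(genes)
  keep <- logical(length(ga))
  for (i in seq_along(ga)) {
    if (!used[ia[i]] && !used[ib[i]]) {
      keep[i] <- TRUE
      used[ia[i]] <- TRUE
      used[ib[i]] <- TRUE
      n_free <- n_free - 2L
      if (n_free < 2L) break   # no further doublet can be kept
    }
  }
  out <- doublets[keep, , drop = FALSE]
  rownames(out) <- NULL
  cbind(rank = seq_len(nrow(out)), out)
}

#' Select unique doublets from a two-class dataset
#'
#' The full feature-construction algorithm:
#' \enumerate{
#'   \item compute t-scores for all genes;
#'   \item rank genes by decreasing |t|;
#'   \item take the top K = [top_fraction_count()] genes;
#'   \item build all doublets of the K genes ([make_doublets()]);
#'   \item compute t-scores for the doublet matrix;
#'   \item rank doublets by decreasing |t| (ties keep construction order:
#'     lexicographic pair, sum before diff);
#'   \item--8. greedily keep a doublet iff neither member gene is already
#'     used;
#'   \item return the kept doublets in kept order.
#' }
#' In sumdiff mode the sum and diff doublets of the same pair compete as
#' distinct candidates in one ranked list; both consume both genes, so at
#' most one survives. The result holds at most floor(K/2) doublets and
#' never repeats a gene.
#'
#' @param ds a preprocessed [expression_dataset()]; each class needs >= 2
#'   samples.
#' @param mode doublet type: `"sumdiff"`, `"mul"` or `"sign"`.
#' @param fraction_pct percentage of top genes used for pairing, in
#'   (0, 100].
#' @param method t-score form, `"welch"` (default) or `"pooled"`.
#' @return A data.frame of class `DoubletSet`: `rank`, `gene_a`, `gene_b`,
#'   `transform`, `t_score`; attributes `mode`, `fraction_pct`, `K`,
#'   `method`.
#' @export
select_unique_doublets <- function(ds, mode = c("sumdiff", "mul", "sign"),
                                   fraction_pct = 10,
                                   method = c("welch", "pooled")) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  mode <- match.arg(mode)
  method <- match.arg(method)
  gene_tab <- t_scores(ds$values, ds$labels, method = method)
  ranked <- rank_features(gene_tab)
  K <- top_fraction_count(nrow(ds$values), fraction_pct)
  top <- ranked[seq_len(K)]
  dm <- make_doublets(ds$values[top, , drop = FALSE], mode = mode)
  dtab <- t_scores(dm$values, ds$labels, method = method)
  ord <- order(-abs(dtab$t_score), seq_len(nrow(dtab)))
  cand <- cbind(dm$doublets[ord, , drop = FALSE],
                t_score = dtab$t_score[ord])
  out <- prune_unique_doublets(cand)
  attr(out, "mode") <- mode
  attr(out, "fraction_pct") <- fraction_pct
  attr(out, "K") <- K
  attr(out, "method") <- method
  class(out) <- c("DoubletSet", "data.frame")
  out
}

#' Apply trained doublet definitions to new samples
#'
#' Rebuilds the selected doublet features for any sample set (for example a
#' held-out sample under cross-validation). Applying it to the training
#' samples reproduces the corresponding rows of the training doublet matrix
#' exactly. The input must be preprocessed identically to the data the
#' doublets were selected on.
#'
#' @param values genes x samples numeric matrix covering every gene named
#'   in `doublet_set` (rownames are gene IDs); a single sample may be given
#'   as a one-column matrix.
#' @param doublet_set a [select_unique_doublets()] result (or any
#'   data.frame with `gene_a`, `gene_b`, `transform`).
#' @return doublets x samples feature matrix, one row per doublet.
#' @export
transform_samples <- function(values, doublet_set) {
  stopifnot(is.data.frame(doublet_set),
            all(c("gene_a", "gene_b", "transform") %in% names(doublet_set)))
  if (!is.matrix(values)) values <- as.matrix(values)
  need <- unique(c(doublet_set$gene_a, doublet_set$gene_b))
  missing <- setdiff(need, rownames(values))
  if (length(missing))
    stop("missing gene ID(s) in sample matrix: ",
         paste(missing, collapse = ", "))
  A <- values[doublet_set$gene_a, , drop = FALSE]
  B <- values[doublet_set$gene_b, , drop = FALSE]
  out <- matrix(0, nrow = nrow(doublet_set), ncol = ncol(values))
  for (tr in unique(doublet_set$transform)) {
    i <- doublet_set$transform == tr
    out[i, ] <- switch(tr,
      sum = A[i, , drop = FALSE] + B[i, , drop = FALSE],
      diff = A[i, , drop = FALSE] - B[i, , drop = FALSE],
      mul = A[i, , drop = FALSE] * B[i, , drop = FALSE],
      sign = sign(A[i, , drop = FALSE] - B[i, , drop = FALSE]),
      stop("unknown transform '", tr, "'"))
  }
  rownames(out) <- doublet_id(doublet_set$gene_a, doublet_set$gene_b,
                              doublet_set$transform)
  colnames(out) <- colnames(values)
  out
}

#' Write a doublet set (biomarker report) to TSV
#'
#' Columns: rank, gene_a, gene_b, transform, t_score.
#'
#' @param doublet_set a [select_unique_doublets()] result.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_doublets <- function(doublet_set, path) {
  utils::write.table(as.data.frame(doublet_set), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
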