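# Small in-code fixtures shared across test files.

# Deterministic random dataset: N genes x (n1 + n2) samples, labels A/B.
random_dataset <- function(n_genes = 20, n1 = 6, n2 = 6, seed = 1,
                           mean = 0, sd = 1) {
  set.seed(seed)
  M <- n1 + n2
  values <- matrix(rnorm(n_genes * M, mean, sd), nrow = n_genes,
                   dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                   sprintf("s%03d", seq_len(M))))
  expression_dataset(values, rep(c("A", "B"), c(n1, n2)))
}

# Two widely separated class centroids: trivially separable.
separable_dataset <- function(n_genes = 10, n1 = 6, n2 = 6, gap = 20,
                              seed = 1) {
  ds <- random_dataset(n_genes, n1, n2, seed)
  ds$values[, ds$labels == "B"] <- ds$values[, ds$labels == "B"] + gap
  ds
}

# Independent Welch/pooled t oracle built on stats::t.test, one feature at
# a time (never used inside the package).
reference_t <- function(values, labels, var_equal = FALSE) {
  classes <- sort(unique(labels))
  unname(apply(values, 1L, function(v)
    unname(stats::t.test(v[labels == classes[1]], v[labels == classes[2]],
                         var.equal = var_equal)$statistic)))
}

# Independently coded greedy unique-pair oracle over an ordered pair list.
greedy_oracle <- function(gene_a, gene_b) {
  used <- character(0)
  keep <- integer(0)
  for (i in seq_along(gene_a)) {
    if (!(gene_a[i] %in% used) && !(gene_b[i] %in% used)) {
      keep <- c(keep, i)
      used <- c(used, gene_a[i], gene_b[i])
    }
  }
  keep
}
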