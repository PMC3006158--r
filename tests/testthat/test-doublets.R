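test_that("pair transforms are the stated elementwise operations", {
  v <- rbind(ga = c(1, 2), gb = c(3, 5))
  colnames(v) <- c("s1", "s2")
  sd_ <- make_doublets(v, "sumdiff")
  expect_equal(unname(sd_$values), rbind(c(4, 7), c(-2, -3)))
  expect_identical(sd_$doublets$transform, c("sum", "diff"))
  expect_equal(unname(make_doublets(v, "mul")$values[1, ]), c(3, 10))
  expect_equal(unname(make_doublets(v, "sign")$values[1, ]), c(-1, -1))
})

test_that("row counts follow the K(K-1) / K(K-1)/2 laws with sum before
           diff and lexicographic pair order", {
  set.seed(21)
  v <- matrix(rnorm(15), nrow = 3,
              dimnames = list(c("x", "y", "z"), paste0("s", 1:5)))
  sd_ <- make_doublets(v, "sumdiff")
  expect_identical(nrow(sd_$values), 6L)
  expect_identical(sd_$doublets$gene_a, rep(c("x", "x", "y"), each = 2))
  expect_identical(sd_$doublets$gene_b, rep(c("y", "z", "z"), each = 2))
  expect_identical(sd_$doublets$transform, rep(c("sum", "diff"), 3))
  expect_identical(nrow(make_doublets(v, "mul")$values), 3L)
  expect_identical(nrow(make_doublets(v, "sign")$values), 3L)
  expect_true(all(make_doublets(v, "sign")$values %in% c(-1, 0, 1)))
  expect_error(make_doublets(v[1, , drop = FALSE]), "at least 2")
})

test_that("every doublet row matches an independent elementwise
           recomputation", {
  set.seed(22)
  v <- matrix(rnorm(80), nrow = 10,
              dimnames = list(sprintf("g%02d", 1:10), sprintf("s%d", 1:8)))
  for (mode in c("sumdiff", "mul", "sign")) {
    dm <- make_doublets(v, mode)
    for (r in seq_len(nrow(dm$values))) {
      a <- v[dm$doublets$gene_a[r], ]
      b <- v[dm$doublets$gene_b[r], ]
      expected <- switch(dm$doublets$transform[r],
                         sum = a + b, diff = a - b, mul = a * b,
                         sign = sign(a - b))
      expect_equal(unname(dm$values[r, ]), unname(expected))
    }
  }
})

test_that("sign doublets use sign(0) = 0 and are antisymmetric in pair
           order; sum/mul are symmetric", {
  v <- rbind(p = c(1, 2, 3), q = c(1, 5, 0))
  colnames(v) <- paste0("s", 1:3)
  expect_equal(unname(make_doublets(v, "sign")$values[1, ]), c(0, -1, 1))
  rev <- v[2:1, ]
  expect_equal(unname(make_doublets(rev, "sign")$values[1, ]),
               -unname(make_doublets(v, "sign")$values[1, ]))
  expect_equal(unname(make_doublets(rev, "mul")$values[1, ]),
               unname(make_doublets(v, "mul")$values[1, ]))
  sd_f <- make_doublets(v, "sumdiff")$values
  sd_r <- make_doublets(rev, "sumdiff")$values
  expect_equal(unname(sd_r[1, ]), unname(sd_f[1, ]))    # sum symmetric
  expect_equal(unname(sd_r[2, ]), -unname(sd_f[2, ]))   # diff antisymmetric
})

test_that("greedy pruning keeps a doublet iff both genes are unused", {
  cand <- data.frame(gene_a = c("g1", "g1", "g3"),
                     gene_b = c("g2", "g3", "g4"),
                     t_score = c(5, 4, 3))
  kept <- prune_unique_doublets(cand)
  expect_identical(kept$gene_a, c("g1", "g3"))
  expect_identical(kept$gene_b, c("g2", "g4"))
  expect_identical(kept$rank, 1:2)
  # all candidates share one gene -> exactly one survives
  shared <- data.frame(gene_a = "g1", gene_b = paste0("g", 2:6))
  expect_identical(nrow(prune_unique_doublets(shared)), 1L)
})

test_that("greedy pruning matches the independent oracle on random
           instances", {
  set.seed(23)
  for (i in 1:50) {
    K <- sample(4:20, 1)
    pairs <- t(combn(sprintf("g%02d", seq_len(K)), 2))
    ord <- sample(nrow(pairs))
    cand <- data.frame(gene_a = pairs[ord, 1], gene_b = pairs[ord, 2])
    kept <- prune_unique_doublets(cand)
    oracle <- greedy_oracle(cand$gene_a, cand$gene_b)
    expect_identical(kept$gene_a, cand$gene_a[oracle])
    expect_identical(kept$gene_b, cand$gene_b[oracle])
  }
})

test_that("selection output never repeats a gene, respects floor(K/2), and
           is deterministic", {
  ds <- random_dataset(n_genes = 40, n1 = 8, n2 = 8, seed = 24)
  for (mode in c("sumdiff", "mul", "sign")) {
    dset <- select_unique_doublets(ds, mode, fraction_pct = 25)
    K <- attr(dset, "K")
    expect_identical(K, top_fraction_count(40, 25))
    genes <- c(dset$gene_a, dset$gene_b)
    expect_identical(anyDuplicated(genes), 0L)
    expect_lte(nrow(dset), floor(K / 2))
    expect_gte(nrow(dset), 1L)
    again <- select_unique_doublets(ds, mode, fraction_pct = 25)
    expect_identical(as.data.frame(dset), as.data.frame(again))
  }
})

test_that("selection is a maximal prefix-greedy matching: every rejected
           candidate conflicts with an earlier kept one", {
  ds <- random_dataset(n_genes = 30, n1 = 7, n2 = 7, seed = 25)
  dset <- select_unique_doublets(ds, "sumdiff", fraction_pct = 40)
  # rebuild the ranked candidate list the same way and walk it
  tab <- t_scores(ds$values, ds$labels)
  top <- rank_features(tab)[seq_len(attr(dset, "K"))]
  dm <- make_doublets(ds$values[top, ], "sumdiff")
  dt <- t_scores(dm$values, ds$labels)
  ord <- order(-abs(dt$t_score), seq_len(nrow(dt)))
  cand <- dm$doublets[ord, ]
  kept_key <- paste(dset$gene_a, dset$gene_b, dset$transform)
  used_before <- character(0)
  for (i in seq_len(nrow(cand))) {
    key <- paste(cand$gene_a[i], cand$gene_b[i], cand$transform[i])
    if (key %in% kept_key) {
      used_before <- c(used_before, cand$gene_a[i], cand$gene_b[i])
    } else {
      expect_true(cand$gene_a[i] %in% used_before ||
                    cand$gene_b[i] %in% used_before)
    }
  }
})

test_that("transform_samples round-trips training data and handles single
           held-out samples", {
  ds <- random_dataset(n_genes = 20, seed = 26)
  dset <- select_unique_doublets(ds, "sumdiff", fraction_pct = 50)
  feat <- transform_samples(ds$values, dset)
  dm_rows <- t(apply(dset, 1, function(r)
    switch(r[["transform"]],
           sum = ds$values[r[["gene_a"]], ] + ds$values[r[["gene_b"]], ],
           diff = ds$values[r[["gene_a"]], ] - ds$values[r[["gene_b"]], ])))
  expect_equal(unname(feat), unname(dm_rows))
  one <- matrix(c(2, 7), ncol = 1,
                dimnames = list(c("gx", "gy"), "snew"))
  dd <- data.frame(gene_a = "gx", gene_b = "gy", transform = "diff")
  expect_equal(unname(transform_samples(one, dd)[1, 1]), -5)
  expect_error(transform_samples(one[1, , drop = FALSE], dd), "gy")
})
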