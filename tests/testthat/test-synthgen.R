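test_that("generation is deterministic and balanced, with correct role
           bookkeeping", {
  cfg <- synthetic_config(n_genes = 60, n_samples_per_class = 10,
                          n_de_genes = 5, n_diff_pairs = 4,
                          n_reversal_pairs = 3, seed = 51)
  ds1 <- simulate_dataset(cfg)
  ds2 <- simulate_dataset(cfg)
  expect_identical(ds1$values, ds2$values)
  expect_identical(as.integer(table(ds1$labels)), c(10L, 10L))
  truth <- ground_truth(ds1)
  expect_identical(sum(truth$role == "de"), 5L)
  expect_identical(sum(truth$role == "diff_pair_member"), 8L)
  expect_identical(sum(truth$role == "reversal_pair_member"), 6L)
  pairs <- table(truth$pair_id[!is.na(truth$pair_id)])
  expect_true(all(pairs == 2L))
  expect_error(ground_truth(random_dataset()), "simulate_dataset")
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(n_genes = 10, n_de_genes = 5,
                                n_diff_pairs = 3), "exceed")
  expect_error(synthetic_config(p_reversal = 1.5))
  expect_error(synthetic_config(baseline_sd = 0))
})

test_that("null data t-scores are calibrated: tail mass near the reference
           two-sided tail", {
  cfg <- synthetic_config(n_genes = 2000, n_samples_per_class = 30,
                          seed = 52)
  ds <- simulate_dataset(cfg)
  t <- t_scores(ds$values, ds$labels)$t_score
  p_hat <- mean(abs(t) > 2)
  p_ref <- 2 * pt(-2, df = 58)          # Student tail at the pooled df
  se <- sqrt(p_ref * (1 - p_ref) / 2000)
  expect_lt(abs(p_hat - p_ref), 3 * se)
})

test_that("diff-pair doublet scores dominate their members' single-gene
           scores", {
  cfg <- synthetic_config(n_genes = 100, n_samples_per_class = 30,
                          n_diff_pairs = 10, sigma_shared = 3,
                          delta_pair = 2, seed = 53)
  ds <- simulate_dataset(cfg)
  truth <- ground_truth(ds)
  members <- truth$gene_id[truth$role == "diff_pair_member"]
  single_t <- t_scores(ds$values, ds$labels)
  member_t <- abs(single_t$t_score[match(members, single_t$feature_id)])
  pair_ids <- unique(truth$pair_id[truth$role == "diff_pair_member"])
  doublet_t <- vapply(pair_ids, function(p) {
    g <- truth$gene_id[which(truth$pair_id %in% p)]
    d <- ds$values[g[1], ] - ds$values[g[2], ]
    abs(t_scores(matrix(d, 1, dimnames = list("d", names(d))),
                 ds$labels)$t_score)
  }, 0)
  expect_gt(median(doublet_t), quantile(member_t, 0.95))
})

test_that("as sigma_shared tends to 0 a diff-pair member becomes an
           ordinary DE gene", {
  base <- list(n_genes = 50, n_samples_per_class = 25, n_diff_pairs = 1,
               delta_pair = 2, seed = 54)
  ds0 <- simulate_dataset(do.call(synthetic_config,
                                  c(base, sigma_shared = 1e-9)))
  dsde <- simulate_dataset(do.call(synthetic_config,
                                   c(base[-3], n_de_genes = 1,
                                     n_diff_pairs = 0, delta_de = 2)))
  t0 <- t_scores(ds0$values, ds0$labels)
  shifted <- ground_truth(ds0)$gene_id[1]   # first diff-pair member
  tde <- t_scores(dsde$values, dsde$labels)
  # both are a delta-2 shift on unit noise: comparable |t| magnitude
  expect_gt(abs(t0$t_score[t0$feature_id == shifted]), 3)
  expect_gt(abs(tde$t_score[1]), 3)
})

test_that("p_reversal = 1 gives perfectly class-separating sign features", {
  cfg <- synthetic_config(n_genes = 30, n_samples_per_class = 8,
                          n_reversal_pairs = 3, p_reversal = 1, seed = 55)
  ds <- simulate_dataset(cfg)
  truth <- ground_truth(ds)
  for (p in unique(na.omit(truth$pair_id))) {
    g <- truth$gene_id[which(truth$pair_id %in% p)]
    s <- sign(ds$values[g[1], ] - ds$values[g[2], ])
    expect_identical(unname(s[ds$labels == "A"]),
                     rep(1, sum(ds$labels == "A")))
    expect_identical(unname(s[ds$labels == "B"]),
                     rep(-1, sum(ds$labels == "B")))
  }
})

test_that("raw-scale export inverts cleanly through the preprocessing
           pipeline", {
  cfg <- synthetic_config(n_genes = 40, n_samples_per_class = 10,
                          n_de_genes = 4, seed = 56)
  ds <- simulate_dataset(cfg)
  raw <- as_raw_scale(ds)
  expect_true(all(raw$values >= 10 & raw$values <= 16000))
  back <- preprocess(raw)
  ref <- standardize_samples(ds)
  # identical up to the (rare) clipped values
  expect_equal(back$values, ref$values, tolerance = 1e-6)
  expect_identical(ground_truth(raw), ground_truth(ds))
})
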