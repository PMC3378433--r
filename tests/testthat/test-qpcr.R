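stages4 <- c("0", "397", "789", "1333")

ct_row <- function(gene, stage, ct, reps = 1) {
  data.frame(gene = gene, stage = stage, replicate = seq_len(reps), ct = ct)
}

test_that("global normalization subtracts the mean reference level", {
  qp <- qpcr_params(baseline = "0", ref_genes = "ref", stages = stages4)
  ct <- rbind(
    do.call(rbind, lapply(stages4, function(s) ct_row("g", s, 25))),
    do.call(rbind, lapply(stages4, function(s) ct_row("ref", s, 20))))
  d <- global_normalize(ct, qp)
  expect_equal(d$dct, rep(5, 4))

  # per-stage additive shifts of gene and references cancel
  ct2 <- ct
  ct2$ct[ct2$stage == "789"] <- ct2$ct[ct2$stage == "789"] + 3.2
  expect_equal(global_normalize(ct2, qp)$dct, d$dct)

  # two references at 19 and 21 -> reference level 20
  qp2 <- qpcr_params(baseline = "0", ref_genes = c("ra", "rb"),
                     stages = stages4)
  ct3 <- rbind(
    do.call(rbind, lapply(stages4, function(s) ct_row("g", s, 25))),
    do.call(rbind, lapply(stages4, function(s) ct_row("ra", s, 19))),
    do.call(rbind, lapply(stages4, function(s) ct_row("rb", s, 21))))
  expect_equal(global_normalize(ct3, qp2)$dct, rep(5, 4))

  # missing reference in one stage names stage and gene
  ct4 <- ct[!(ct$gene == "ref" & ct$stage == "789"), ]
  expect_error(global_normalize(ct4, qp), "ref.*789|789.*ref")
})

test_that("delta-delta-CT folds are powers of two with baseline fold 1", {
  qp <- qpcr_params(baseline = "0", ref_genes = "ref", stages = stages4)
  d <- data.frame(gene = "g", stage = stages4, dct = c(5, 4, 3, 5))
  f <- ddct_fold(d, qp)
  expect_equal(f$fold, c(1, 2, 4, 1))
  d2 <- data.frame(gene = "g", stage = stages4, dct = rep(2.5, 4))
  expect_equal(ddct_fold(d2, qp)$fold, rep(1, 4))
  # CT above the cap is truncated on load
  qp40 <- qpcr_params(max_ct = 40, baseline = "0", ref_genes = "ref",
                      stages = stages4)
  ct <- ct_row("g", "0", 43.7)
  expect_equal(read_ct_table(ct, qp40)$ct, 40)
})

test_that("fold profiles classify like read-frequency profiles", {
  qp <- qpcr_params(baseline = "0", ref_genes = "ref", stages = stages4)
  folds <- data.frame(gene = rep(c("g1", "g2"), each = 4),
                      stage = rep(stages4, 2),
                      fold = c(1, 2, 4, 1, 1, 1, 1, 1))
  tr <- qpcr_trends(folds, qp)
  expect_identical(tr$pattern[tr$gene == "g1"], "up_down")
  expect_identical(tr$pattern[tr$gene == "g2"], "flat")
})

test_that("a noise-free planted CT table round-trips to the planted trends", {
  cfg <- synthetic_config(seed = 61, n_transcripts = 15, effect_size = 2)
  sim <- generate_transcriptome(cfg)
  for (group in c("bud", "fruit")) {
    stages <- cfg$design$stage[cfg$design$group == group]
    tab <- generate_qpcr_table(sim$truth, cfg, noise_sd = 0, group = group,
                               ref_genes = c("hk1", "hk2"))
    qp <- qpcr_params(baseline = stages[1], ref_genes = c("hk1", "hk2"),
                      stages = stages)
    folds <- ddct_fold(global_normalize(tab$ct, qp), qp)
    # folds equal the planted per-stage effect multipliers exactly
    expect_true(all(folds$fold[folds$stage == stages[1]] == 1))
    tr <- qpcr_trends(folds, qp)
    truth <- tab$truth[match(tr$gene, tab$truth$gene), ]
    expect_identical(tr$pattern, truth$trend)
  }
})

test_that("concordance counts exact pattern matches symmetrically", {
  pairs <- read_tsv_report(extdata("qpcr_trend_pairs.tsv"))
  pred <- data.frame(gene = pairs$gene, pattern = pairs$predicted)
  obs <- data.frame(gene = pairs$gene, pattern = pairs$observed)
  res <- concordance(pred, obs)
  expect_identical(res$n_total, 17L)
  expect_identical(concordance(obs, pred)$n_match, res$n_match)
  # identity and disjoint extremes
  expect_identical(concordance(pred, pred)$percent, 100)
  flip <- obs
  flip$pattern <- "complex"
  expect_identical(concordance(pred, flip)$percent, 0)
  expect_error(concordance(pred, obs[-1, ]), "differ")
})
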