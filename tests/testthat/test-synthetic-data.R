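test_that("generation is deterministic in (config, seed) and differs across seeds", {
  cfg <- synthetic_config(seed = 101, n_transcripts = 10,
                          reads_per_library = 50)
  sim1 <- generate_transcriptome(cfg)
  sim2 <- generate_transcriptome(cfg)
  expect_identical(sim1, sim2)
  r1 <- sample_library_reads(sim1, "bud_0", cfg)
  r2 <- sample_library_reads(sim2, "bud_0", cfg)
  expect_identical(r1, r2)
  q1 <- generate_qpcr_table(sim1$truth, cfg)
  q2 <- generate_qpcr_table(sim2$truth, cfg)
  expect_identical(q1, q2)

  cfg3 <- synthetic_config(seed = 102, n_transcripts = 10,
                           reads_per_library = 50)
  sim3 <- generate_transcriptome(cfg3)
  expect_false(identical(sim1$transcripts, sim3$transcripts))
})

test_that("planted SSRs are copied in verbatim at the recorded coordinates", {
  cfg <- synthetic_config(
    seed = 7, n_transcripts = 3,
    ssr_plant_spec = data.frame(motif = "AG", repeats = 7,
                                transcript = 1, offset = 40))
  sim <- generate_transcriptome(cfg)
  expect_identical(substr(sim$transcripts[[1]], 41, 54), strrep("AG", 7))
  expect_identical(sim$truth$ssr$start, 40L)
  expect_identical(sim$truth$ssr$end, 54L)
})

test_that("a planted SSR exceeding transcript bounds is a configuration error", {
  cfg <- synthetic_config(
    seed = 7, n_transcripts = 2, transcript_length = c(120, 130),
    ssr_plant_spec = data.frame(motif = "AG", repeats = 10,
                                transcript = 1, offset = 115))
  expect_error(generate_transcriptome(cfg), "bounds")
})

test_that("SSR mining over a rejection-sampled pool returns exactly the planted loci", {
  plant <- data.frame(motif = c("AG", "AAG", "ACGT"),
                      repeats = c(6, 5, 4),
                      transcript = c(1, 50, 120),
                      offset = c(100, 200, 150))
  cfg <- synthetic_config(seed = 31, n_transcripts = 200,
                          transcript_length = c(400, 800),
                          ssr_plant_spec = plant)
  sim <- generate_transcriptome(cfg)
  loci <- find_ssrs(sim$transcripts, check_length = FALSE)
  expect_identical(nrow(loci), 3L)
  expect_setequal(loci$sequence_id, c("t0001", "t0050", "t0120"))
  got <- loci[order(loci$sequence_id), ]
  expect_identical(got$motif, c("AG", "AAG", "ACGT"))
  expect_identical(got$repeats, c(6L, 5L, 4L))
  expect_identical(got$start, c(100L, 200L, 150L))
})

test_that("library sampling conserves read counts and respects proportions", {
  cfg <- synthetic_config(seed = 11, n_transcripts = 8,
                          reads_per_library = 500, error_rate = 0)
  sim <- generate_transcriptome(cfg)
  # force one transcript to zero proportion in one library
  sim$truth$proportions["t0008", "bud_0"] <- 0
  sim$truth$proportions[, "bud_0"] <-
    sim$truth$proportions[, "bud_0"] / sum(sim$truth$proportions[, "bud_0"])
  reads <- sample_library_reads(sim, "bud_0", cfg)
  expect_identical(nrow(reads), 500L)
  expect_false(any(reads$source_transcript == "t0008"))
  # error-free reads are exact substrings of their source transcript
  hit <- vapply(seq_len(50), function(i) {
    grepl(reads$sequence[i], sim$transcripts[reads$source_transcript[i]],
          fixed = TRUE)
  }, logical(1))
  expect_true(all(hit))
  expect_error(sample_library_reads(sim, "root_0", cfg), "not in stage design")
})

test_that("sampled read lengths match the configured distribution (CLT bound)", {
  cfg <- synthetic_config(seed = 19, n_transcripts = 10,
                          transcript_length = c(800, 1500),
                          reads_per_library = 10000,
                          read_length = c(mean = 287, sd = 50, min = 50))
  sim <- generate_transcriptome(cfg)
  reads <- sample_library_reads(sim, "leaf_leaves", cfg)
  # sample mean within 2 sd / sqrt(n) of the configured mean
  expect_lt(abs(mean(nchar(reads$sequence)) - 287), 2 * 50 / sqrt(10000))
})

test_that("noise-free CT tables encode the planted log2 fold steps", {
  cfg <- synthetic_config(seed = 23, n_transcripts = 10, effect_size = 2)
  sim <- generate_transcriptome(cfg)
  tab <- generate_qpcr_table(sim$truth, cfg, noise_sd = 0, group = "bud",
                             ref_genes = "hk1")
  ct <- tab$ct
  flat_gene <- tab$truth$gene[tab$truth$trend == "flat"][1]
  f <- ct$ct[ct$gene == flat_gene]
  expect_true(all(f == f[1]))
  up_gene <- tab$truth$gene[tab$truth$trend == "up"][1]
  u <- aggregate(ct ~ stage, data = ct[ct$gene == up_gene, ], FUN = mean)
  r <- aggregate(ct ~ stage, data = ct[ct$gene == "hk1", ], FUN = mean)
  d <- (u$ct - r$ct)[match(c("0", "397", "789", "1333"), u$stage)]
  # gene-minus-reference CT falls by exactly log2(2) = 1 cycle per stage
  expect_equal(diff(d), rep(-1, 3), tolerance = 1e-12)
  expect_true(all(ct$ct <= 40))
})
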