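test_that("an exact 30-nt end overlap merges at threshold; 29 nt does not", {
  set.seed(2)
  A <- rnd_dna(100)
  tail70 <- rnd_dna(70)
  B30 <- paste0(substr(A, 71, 100), tail70)
  res <- assemble_greedy(read_table(c(A, B30), ids = c("a", "b")))
  expect_identical(nrow(res$contigs), 1L)
  expect_identical(nchar(res$contigs$sequence), 170L)
  expect_identical(res$contigs$n_members, 2L)
  expect_identical(res$contigs$sequence, paste0(A, tail70))

  B29 <- paste0(substr(A, 72, 100), rnd_dna(71))
  res29 <- assemble_greedy(read_table(c(A, B29), ids = c("a", "b")))
  expect_identical(nrow(res29$contigs), 0L)
  expect_identical(nrow(res29$singletons), 2L)
})

test_that("reverse-complement overlaps are found and flipped into the layout", {
  set.seed(5)
  A <- rnd_dna(100)
  B <- paste0(substr(A, 61, 100), rnd_dna(60))
  res <- assemble_greedy(read_table(c(A, rc_dna(B)), ids = c("a", "b")))
  expect_identical(nrow(res$contigs), 1L)
  expect_identical(nchar(res$contigs$sequence), 160L)
  expect_setequal(res$membership$strand, c(1L, -1L))
})

test_that("error-free coverage of one transcript reconstructs it exactly", {
  set.seed(3)
  tx <- rnd_dna(1000)
  starts <- seq(1, 701, by = 50)
  reads <- read_table(substring(tx, starts, starts + 299))
  res <- assemble_greedy(reads)
  expect_identical(nrow(res$contigs), 1L)
  expect_identical(res$contigs$sequence, tx)
  expect_identical(res$contigs$n_members, length(starts))
})

test_that("every read lands in exactly one contig or singleton (partition)", {
  cfg <- synthetic_config(seed = 13, n_transcripts = 8,
                          reads_per_library = 150, error_rate = 0.005)
  sim <- generate_transcriptome(cfg)
  reads <- sample_library_reads(sim, "fruit_green", cfg)
  res <- assemble_greedy(reads)
  expect_setequal(res$membership$read_id, reads$id)
  expect_identical(anyDuplicated(res$membership$read_id), 0L)
  expect_identical(sum(res$contigs$n_members) + nrow(res$singletons),
                   nrow(reads))
  expect_identical(as.integer(sum(res$library_counts)),
                   sum(res$contigs$n_members))
  # consensus at least as long as any member read it holds
  for (i in seq_len(nrow(res$contigs))) {
    mem <- res$membership[res$membership$contig_id == res$contigs$id[i], ]
    rl <- nchar(reads$sequence[match(mem$read_id, reads$id)])
    expect_true(all(mem$offset + rl <= nchar(res$contigs$sequence[i])))
  }
})

test_that("the result is invariant under input row order", {
  cfg <- synthetic_config(seed = 17, n_transcripts = 5,
                          reads_per_library = 80, error_rate = 0.005)
  sim <- generate_transcriptome(cfg)
  reads <- sample_library_reads(sim, "bud_789", cfg)
  res1 <- assemble_greedy(reads)
  set.seed(1)
  res2 <- assemble_greedy(reads[sample(nrow(reads)), ])
  expect_identical(res1$contigs, res2$contigs)
  expect_identical(res1$membership[order(res1$membership$read_id), ],
                   res2$membership[order(res2$membership$read_id), ])
})

test_that("assembly summaries satisfy their arithmetic identities", {
  cfg <- synthetic_config(seed = 29, n_transcripts = 6,
                          reads_per_library = 100, error_rate = 0)
  sim <- generate_transcriptome(cfg)
  reads <- sample_library_reads(sim, "fruit_blue", cfg)
  res <- assemble_greedy(reads)
  s <- assembly_summary(res, "fruit_blue")
  expect_identical(s$n_reads_assembled, nrow(reads))
  expect_identical(s$n_unigenes, s$n_contigs + s$n_singletons)
  expect_identical(s$n_reads_in_contigs + s$n_singletons, s$n_reads_assembled)
  expect_equal(s$mean_contig_length,
               round(mean(nchar(res$contigs$sequence)), 1))
  # empty input -> zero-filled row
  s0 <- assembly_summary(assemble_greedy(reads[0, ]), "empty")
  expect_identical(s0$n_reads_assembled, 0L)
  expect_identical(s0$n_unigenes, 0L)
  expect_identical(unigene_total(s0$n_contigs, s0$n_singletons), 0)
})

test_that("unigene sharing counts shared pool members and nothing else", {
  set.seed(41)
  pool <- setNames(replicate(12, rnd_dna(300)), sprintf("t%02d", 1:12))
  # identical sets share everything
  cmp <- compare_unigene_sets(pool[1:5], setNames(pool[1:5], paste0("x", 1:5)))
  expect_identical(cmp$shared, 5L)
  expect_identical(cmp$unique_a, 0L)
  expect_identical(cmp$unique_b, 0L)
  # unrelated random sequences share nothing at the E-value cutoff
  cmp0 <- compare_unigene_sets(pool[1:6], pool[7:12])
  expect_identical(cmp0$shared, 0L)
  expect_identical(cmp0$unique_a, 6L)
  expect_identical(cmp0$unique_b, 6L)
  # overlapping pools share exactly the intersection
  a <- pool[1:8]
  b <- setNames(pool[5:12], sprintf("b%02d", 5:12))
  cmp2 <- compare_unigene_sets(a, b)
  expect_identical(cmp2$shared, 4L)
  expect_identical(cmp2$unique_a, 4L)
  expect_identical(cmp2$unique_b, 4L)
})
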