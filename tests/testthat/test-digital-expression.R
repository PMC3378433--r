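test_that("read counting assigns each read to its best contig exactly once", {
  set.seed(51)
  tx <- rnd_dna(600)
  other <- rnd_dna(600)
  contigs <- c(cA = tx, cB = other)
  # 50 error-free reads from tx
  starts <- sample(1:300, 50, replace = TRUE)
  reads <- read_table(substring(tx, starts, starts + 249), lib = "bud_0")
  counts <- assign_reads(contigs, reads)
  expect_identical(counts["cA", "bud_0"], 50L)
  expect_identical(counts["cB", "bud_0"], 0L)
  # reads from an unrelated transcript count nowhere
  unrel <- read_table(replicate(20, rnd_dna(250)), lib = "bud_0")
  expect_true(all(assign_reads(contigs, unrel) == 0L))
})

test_that("a read matching two contigs counts once, toward the higher score", {
  set.seed(52)
  region <- rnd_dna(300)
  # cNear carries the region verbatim; cFar carries it with 6 mismatches
  mut <- strsplit(region, "")[[1]]
  pos <- seq(20, 270, by = 50)
  mut[pos] <- vapply(mut[pos],
                     function(b) setdiff(c("A", "C", "G", "T"), b)[1], "x")
  contigs <- c(cFar = paste0(rnd_dna(50), paste(mut, collapse = ""),
                             rnd_dna(50)),
               cNear = paste0(rnd_dna(50), region, rnd_dna(50)))
  reads <- read_table(region, lib = "L")
  hits <- seed_extend_search(setNames(reads$sequence, reads$id), contigs)
  expect_identical(nrow(hits), 2L)  # both contigs are genuine hits
  counts <- assign_reads(contigs, reads)
  expect_identical(counts["cNear", "L"], 1L)
  expect_identical(counts["cFar", "L"], 0L)
  expect_identical(sum(counts), 1L)
})

test_that("top_abundant ranks by count with deterministic tie-breaks", {
  counts <- matrix(c(10L, 5L, 1L, 0L), 4, 1,
                   dimnames = list(c("A", "B", "C", "D"), "L"))
  expect_identical(top_abundant(counts, "L", trend_params(top_n = 2)),
                   c("A", "B"))
  tie <- matrix(c(5L, 5L), 2, 1, dimnames = list(c("B", "A"), "L"))
  expect_identical(top_abundant(tie, "L", trend_params(top_n = 1)), "A")
  # only contigs with nonzero counts are returned
  expect_identical(length(top_abundant(counts, "L", trend_params(top_n = 30))),
                   3L)
})

test_that("frequencies are percent of per-library totals", {
  counts <- matrix(c(100L, 0L), 2, 1, dimnames = list(c("a", "b"), "L"))
  ft <- frequency_table(counts, c(L = 10000))
  expect_equal(ft$frequency, c(1, 0))
  expect_error(frequency_table(counts, c(L = 0)), "positive")
  # frequencies over all contigs never exceed 100% per library
  set.seed(53)
  big <- matrix(rpois(40, 5), 10, 4,
                dimnames = list(sprintf("c%d", 1:10), sprintf("L%d", 1:4)))
  storage.mode(big) <- "integer"
  tot <- setNames(colSums(big) + sample(0:20, 4), colnames(big))
  ftb <- frequency_table(big, tot)
  sums <- tapply(ftb$frequency, ftb$library_id, sum)
  expect_true(all(sums <= 100 + 1e-9))
})

test_that("the step-band trend rule reproduces the worked profiles", {
  p <- trend_params(fold_threshold = 1.5)
  expect_identical(classify_trend(c(2.0, 1.0, 0.5, 1.5), p), "down_up")
  expect_identical(classify_trend(c(0.2, 0.5, 1.0, 0.4), p), "up_down")
  expect_identical(classify_trend(c(1.0, 1.1, 0.9, 1.0), p), "flat")
  expect_identical(classify_trend(c(1, 2, 1, 2), p), "complex")
  expect_error(classify_trend(1, p), "2")
})

test_that("trend calls obey stage-reversal and scale invariance", {
  p <- trend_params()
  # time reversal swaps the monotone labels; a tent read backwards is
  # still a tent, so up_down/down_up (and flat/complex) are fixed points
  flip <- c(up = "down", down = "up", up_down = "up_down",
            down_up = "down_up", flat = "flat", complex = "complex")
  set.seed(54)
  for (i in 1:200) {
    f <- 10^runif(sample(3:6, 1), -1, 1)
    expect_identical(classify_trend(rev(f), p),
                     unname(flip[classify_trend(f, p)]))
    expect_identical(classify_trend(3.7 * f, p), classify_trend(f, p))
  }
})

test_that("the abundance report is deterministic and respects the row bound", {
  cfg <- synthetic_config(seed = 55, n_transcripts = 10,
                          reads_per_library = 300, error_rate = 0)
  sim <- generate_transcriptome(cfg)
  libs <- cfg$design$library_id
  reads <- do.call(rbind, lapply(libs, function(l) {
    sample_library_reads(sim, l, cfg)
  }))
  counts <- assign_reads(sim$transcripts, reads)
  totals <- setNames(rep(300L, length(libs)), libs)
  p <- trend_params(top_n = 5)
  rep1 <- abundance_report(counts, totals, cfg$design, p)
  rep2 <- abundance_report(counts, totals, cfg$design, p)
  expect_identical(rep1, rep2)
  expect_lte(nrow(rep1), 5 * length(libs))
  expect_true(all(c("pattern_bud", "pattern_fruit") %in% names(rep1)))
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_tsv_report(rep1, f1); write_tsv_report(rep2, f2)
  expect_identical(readLines(f1), readLines(f2))
})
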