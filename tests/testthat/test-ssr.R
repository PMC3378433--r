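embed_run <- function(motif, reps, flank = 60, seed = 1) {
  # repeat-free flanks so only the planted run can be reported
  set.seed(seed)
  repeat {
    s <- paste0(rnd_dna(flank), strrep(motif, reps), rnd_dna(flank))
    bare <- find_ssrs(c(x = paste0(substr(s, 1, flank),
                                   substr(s, flank + nchar(motif) * reps + 1,
                                          nchar(s)))),
                      check_length = FALSE)
    full <- find_ssrs(c(x = s), check_length = FALSE)
    clean <- nrow(full) <= 1 &&
      all(full$motif == motif & full$start == flank & full$repeats == reps)
    if (nrow(bare) == 0 && clean) return(s)
  }
}

test_that("repeat-count thresholds are applied per motif length", {
  cases <- list(list("AG", 5, TRUE), list("AG", 4, FALSE),
                list("CTG", 4, TRUE), list("CTG", 3, FALSE),
                list("ACGT", 3, TRUE), list("ACGT", 2, FALSE),
                list("AACGT", 3, TRUE), list("AACGT", 2, FALSE))
  for (cs in cases) {
    s <- embed_run(cs[[1]], cs[[2]])
    loci <- find_ssrs(c(x = s), check_length = FALSE)
    if (cs[[3]]) {
      expect_identical(nrow(loci), 1L)
      expect_identical(loci$motif, cs[[1]])
      expect_identical(loci$repeats, as.integer(cs[[2]]))
      expect_identical(loci$end - loci$start,
                       as.integer(nchar(cs[[1]]) * cs[[2]]))
    } else {
      expect_identical(nrow(loci), 0L)
    }
  }
})

test_that("a run is reported once, under its primitive motif only", {
  s <- embed_run("AT", 8)
  loci <- find_ssrs(c(x = s), check_length = FALSE)
  expect_identical(nrow(loci), 1L)
  expect_identical(loci$motif, "AT")
  expect_identical(loci$repeats, 8L)
  # homopolymers are never reported
  s2 <- paste0("GC", strrep("A", 30), "GC")
  expect_identical(nrow(find_ssrs(c(x = s2), check_length = FALSE)), 0L)
})

test_that("reported loci are maximal and their motifs primitive", {
  set.seed(71)
  for (i in 1:50) {
    motif <- rnd_dna(sample(2:5, 1))
    if (!est454:::is_primitive_motif(motif)) next
    s <- paste0(rnd_dna(40), strrep(motif, 6), rnd_dna(40))
    loci <- find_ssrs(c(x = s), check_length = FALSE)
    for (z in seq_len(nrow(loci))) {
      m <- loci$motif[z]; st <- loci$start[z]; en <- loci$end[z]
      expect_true(est454:::is_primitive_motif(m))
      # not extendable by a full motif unit either direction
      left <- substr(s, st - nchar(m) + 1, st)
      right <- substr(s, en + 1, en + nchar(m))
      if (st >= nchar(m)) expect_false(left == m)
      if (en + nchar(m) <= nchar(s)) expect_false(right == m)
      expect_identical(substr(s, st + 1, st + nchar(m)), m)
    }
  }
})

test_that("non-ACGT characters interrupt runs", {
  s <- paste0(strrep("AG", 4), "N", strrep("AG", 4))
  expect_identical(nrow(find_ssrs(c(x = s), check_length = FALSE)), 0L)
})

test_that("short sequences are skipped by the mining length filter", {
  s <- embed_run("AG", 6, flank = 20)  # 64 nt total < 120
  expect_identical(nrow(find_ssrs(c(x = s))), 0L)
  expect_identical(nrow(find_ssrs(c(x = s), check_length = FALSE)), 1L)
})

test_that("canonical classes are invariant under rotation and revcomp", {
  expect_identical(canonical_class("GA"), "AG")
  expect_identical(canonical_class("CTT"), "AAG")
  expect_identical(canonical_class("AT"), "AT")
  expect_error(canonical_class("AGAG"), "primitive")
  expect_error(canonical_class("A"), "length")
  set.seed(72)
  for (i in 1:100) {
    m <- rnd_dna(sample(2:5, 1))
    if (!est454:::is_primitive_motif(m)) next
    cl <- canonical_class(m)
    n <- nchar(m)
    rots <- vapply(seq_len(n) - 1, function(k) {
      paste0(substr(m, k + 1, n), substr(m, 1, k))
    }, character(1))
    for (r in rots) {
      expect_identical(canonical_class(r), cl)
      expect_identical(canonical_class(rc_dna(r)), cl)
    }
  }
})

test_that("category and class percentages are internally consistent", {
  set.seed(73)
  motifs <- c(rep("AG", 30), rep("AC", 10), rep("AAG", 20), rep("ACGT", 5),
              rep("AACGT", 3))
  loci <- data.frame(sequence_id = "s", motif = motifs,
                     stringsAsFactors = FALSE)
  s <- summarize_ssrs(loci, 100)
  expect_identical(s$total_ssrs, length(motifs))
  expect_identical(sum(s$categories$count), s$total_ssrs)
  expect_lte(abs(sum(s$categories$percent_of_ssrs) - 100), 0.2)
  for (cat in unique(s$classes$category)) {
    expect_identical(
      sum(s$classes$count[s$classes$category == cat]),
      s$categories$count[s$categories$category == cat])
  }
  # empty input -> zero table
  s0 <- summarize_ssrs(loci[0, ], 100)
  expect_identical(s0$total_ssrs, 0L)
})

test_that("primer candidacy applies the GC and flank rules with reasons", {
  p <- ssr_params()
  run <- strrep("AG", 6)
  embed_between <- function(left, right) {
    # rejection-screened so the planted run is the only locus reported
    repeat {
      s <- paste0(left(), run, right())
      loci <- find_ssrs(setNames(s, "x"), check_length = FALSE)
      if (nrow(loci) == 1 && loci$motif == "AG") return(s)
    }
  }
  gc_rich <- function(n) {
    paste(sample(c("G", "C", "A", "T"), n, TRUE,
                 prob = c(.45, .45, .05, .05)), collapse = "")
  }
  set.seed(81)
  # balanced GC, ample flanks -> pass
  bal <- embed_between(function() rnd_dna(60), function() rnd_dna(60))
  loci <- find_ssrs(c(ok = bal), check_length = FALSE)
  cand <- primer_candidates(loci, c(ok = bal), p)
  expect_true(all(cand$pass))
  expect_true(all(cand$gc >= 40 & cand$gc <= 60))
  # short left flank (10 nt < 20)
  shrt <- embed_between(function() rnd_dna(10), function() rnd_dna(120))
  cand2 <- primer_candidates(find_ssrs(c(s = shrt), check_length = FALSE),
                             c(s = shrt), p)
  expect_false(any(cand2$pass))
  expect_match(cand2$fail_reasons, "short_flank")
  # whole-sequence GC far above the window
  gcy <- embed_between(function() gc_rich(80), function() gc_rich(80))
  cand3 <- primer_candidates(find_ssrs(c(g = gcy), check_length = FALSE),
                             c(g = gcy), p)
  expect_false(any(cand3$pass))
  expect_match(cand3$fail_reasons, "gc_out_of_range")
})

test_that("marker screen rates are computed from amplification and calls", {
  rec <- read_tsv_report(extdata("marker_screen.tsv"))
  s <- marker_screen_summary(rec)
  expect_identical(s$n, 100L)
  # all-polymorphic input -> both rates 100
  poly <- rec[rec$call == "polymorphic", ]
  sp <- marker_screen_summary(poly)
  expect_identical(sp$amplification_rate, 100)
  expect_identical(sp$polymorphism_rate, 100)
  # a polymorphic call without any product is inconsistent
  bad <- rec[33, ]
  bad[, !names(bad) %in% c("primer_id", "call", "polymorphic_in")] <- "-"
  expect_error(marker_screen_summary(bad), "amplification")
})
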