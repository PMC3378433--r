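#' EST-SSR mining parameters
#'
#' Defaults follow common EST-SSR marker practice: dinucleotide repeats
#' need at least 5 repeat units, trinucleotide at least 4, tetra- and
#' pentanucleotide at least 3; sequences shorter than 120 nt are skipped;
#' primer candidates need whole-sequence GC between 40 and 60 percent and
#' at least 20 nt of flank on both sides of the repeat.
#'
#' @param min_seq_length Minimum sequence length mined (nt).
#' @param min_repeats Named/positional integer vector of minimum repeat
#'   counts for motif lengths 2, 3, 4, 5.
#' @param gc_range GC window in percent, `c(low, high)`.
#' @param min_flank Minimum flank on either side of a locus (nt).
#' @return List of class `ssr_params`.
#' @export
ssr_params <- function(min_seq_length = 120,
                       min_repeats = c(`2` = 5, `3` = 4, `4` = 3, `5` = 3),
                       gc_range = c(40, 60), min_flank = 20) {
  stopifnot(length(min_repeats) == 4, all(min_repeats >= 2),
            length(gc_range) == 2, gc_range[1] < gc_range[2],
            min_flank >= 0, min_seq_length >= 1)
  structure(list(min_seq_length = as.integer(min_seq_length),
                 min_repeats = as.integer(min_repeats),
                 gc_range = as.numeric(gc_range),
                 min_flank = as.integer(min_flank)),
            class = "ssr_params")
}

rotations <- function(x) {
  n <- nchar(x)
  vapply(seq_len(n) - 1L, function(i) {
    paste0(substr(x, i + 1, n), substr(x, 1, i))
  }, character(1))
}

is_primitive_motif <- function(motif) {
  n <- nchar(motif)
  for (d in seq_len(n - 1)) {
    if (n %% d != 0) next
    if (strrep(substr(motif, 1, d), n / d) == motif) return(FALSE)
  }
  TRUE
}

#' Canonical motif class of an SSR motif
#'
#' The equivalence class of a repeat motif under cyclic rotation and
#' reverse complementation (an AG repeat read in any phase or on either
#' strand is the same locus); the class label is the lexicographically
#' minimal string over all rotations of the motif and of its reverse
#' complement, so GA, TC and CT all map to "AG".
#'
#' @param motif Primitive motif of length 2-5 (vectorized).
#' @return Character vector of class representatives.
#' @export
canonical_class <- function(motif) {
  vapply(toupper(motif), function(m) {
    if (!nchar(m) %in% 2:5) stop("motif length must be 2-5: ", m)
    if (!is_primitive_motif(m)) {
      stop("motif is not primitive (a repetition of a shorter motif): ", m)
    }
    min(c(rotations(m), rotations(revcomp(m))))
  }, character(1), USE.NAMES = FALSE)
}

#' Find maximal perfect SSR loci
#'
#' Reports every maximal perfect tandem repeat with a primitive motif of
#' length 2-5 meeting the per-length repeat thresholds. A run is reported
#' once, under its primitive motif only (an AT run is never also reported
#' as ATAT); overlapping runs of different motif classes are both
#' reported. Non-ACGT characters interrupt runs. Coordinates are 0-based
#' half-open and satisfy `end - start = motif length x repeats`.
#'
#' @param sequences Named character vector (or single string).
#' @param params [ssr_params()].
#' @param check_length If `TRUE`, sequences shorter than `min_seq_length`
#'   are skipped (the mining convention); disable to scan everything.
#' @return `data.frame`: `sequence_id`, `motif` (as read on the sequence),
#'   `motif_len`, `repeats`, `start`, `end`, `class`.
#' @export
find_ssrs <- function(sequences, params = ssr_params(),
                      check_length = TRUE) {
  stopifnot(inherits(params, "ssr_params"))
  if (is.null(names(sequences))) {
    names(sequences) <- sprintf("seq%d", seq_along(sequences))
  }
  out <- list()
  for (i in seq_along(sequences)) {
    s <- toupper(sequences[i])
    if (check_length && nchar(s) < params$min_seq_length) next
    df <- cpp_find_ssrs(s, params$min_repeats)
    if (!nrow(df)) next
    df <- cbind(sequence_id = names(sequences)[i], df,
                stringsAsFactors = FALSE)
    out[[length(out) + 1]] <- df
  }
  if (!length(out)) {
    return(data.frame(sequence_id = character(), motif = character(),
                      motif_len = integer(), repeats = integer(),
                      start = integer(), end = integer(),
                      class = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$sequence_id, res$start, res$motif_len), ]
  rownames(res) <- NULL
  res$class <- canonical_class(res$motif)
  res
}

category_labels <- c(`2` = "DNR", `3` = "TNR", `4` = "TetraNR",
                     `5` = "PentaNR")

#' Summarize mined SSR loci by motif-length category and canonical class
#'
#' Category percentages are of the total SSR count; class percentages
#' within a category are of that category's count; "percent of total" is
#' of the number of mined sequences for categories, and of the total SSR
#' count for classes. All percentages are rounded to one decimal.
#'
#' @param loci Loci table from [find_ssrs()] (needs `motif`; `class` is
#'   derived if absent).
#' @param n_sequences Number of sequences mined (the denominator of the
#'   category percent-of-total column).
#' @return List with `total_ssrs`, `categories` and `classes` tables.
#' @export
summarize_ssrs <- function(loci, n_sequences) {
  stopifnot(n_sequences > 0)
  if (!nrow(loci)) {
    return(list(total_ssrs = 0L,
                categories = data.frame(category = unname(category_labels),
                                        count = 0L, percent_of_ssrs = 0,
                                        percent_of_total = 0,
                                        stringsAsFactors = FALSE),
                classes = data.frame(category = character(),
                                     class = character(), count = integer(),
                                     percent_of_category = numeric(),
                                     percent_of_total = numeric(),
                                     stringsAsFactors = FALSE)))
  }
  if (is.null(loci$class)) loci$class <- canonical_class(loci$motif)
  mlen <- nchar(loci$motif)
  total <- nrow(loci)
  cat_counts <- table(factor(mlen, levels = 2:5))
  categories <- data.frame(
    category = unname(category_labels),
    count = as.integer(cat_counts),
    percent_of_ssrs = round(100 * as.integer(cat_counts) / total, 1),
    percent_of_total = round(100 * as.integer(cat_counts) / n_sequences, 1),
    stringsAsFactors = FALSE)

  cls <- aggregate(list(count = loci$class),
                   by = list(category = category_labels[as.character(mlen)],
                             class = loci$class),
                   FUN = length)
  cls$percent_of_category <- round(
    100 * cls$count /
      categories$count[match(cls$category, categories$category)], 1)
  cls$percent_of_total <- round(100 * cls$count / total, 1)
  cls <- cls[order(match(cls$category, category_labels), cls$class), ]
  rownames(cls) <- NULL

  list(total_ssrs = total,
       total_percent_of_sequences = round(100 * total / n_sequences, 1),
       categories = categories, classes = cls)
}

gc_percent <- function(seq) {
  ch <- strsplit(toupper(seq), "")[[1]]
  100 * sum(ch %in% c("G", "C")) / sum(ch %in% c("A", "C", "G", "T"))
}

#' Flag SSR loci suitable for primer development
#'
#' A locus passes iff the whole sequence's GC content lies inside
#' `gc_range` and both flanks (locus start to sequence start, locus end to
#' sequence end) are at least `min_flank` nt. Failure reasons are
#' reported per locus.
#'
#' @param loci Loci from [find_ssrs()].
#' @param sequences Named character vector including every `sequence_id`.
#' @param params [ssr_params()].
#' @return `data.frame`: the loci plus `gc`, `left_flank`, `right_flank`,
#'   `pass`, `fail_reasons`.
#' @export
primer_candidates <- function(loci, sequences, params = ssr_params()) {
  missing_s <- setdiff(loci$sequence_id, names(sequences))
  if (length(missing_s)) {
    stop("sequence not provided for loci: ",
         paste(unique(missing_s), collapse = ", "))
  }
  seqs <- sequences[loci$sequence_id]
  gc <- vapply(seqs, gc_percent, numeric(1), USE.NAMES = FALSE)
  left <- loci$start
  right <- nchar(seqs) - loci$end
  gc_ok <- gc >= params$gc_range[1] & gc <= params$gc_range[2]
  fl_ok <- left >= params$min_flank & right >= params$min_flank
  reasons <- character(nrow(loci))
  reasons[!gc_ok] <- "gc_out_of_range"
  reasons[!fl_ok] <- ifelse(nzchar(reasons[!fl_ok]),
                            paste0(reasons[!fl_ok], ";short_flank"),
                            "short_flank")
  cbind(loci,
        data.frame(gc = round(gc, 2), left_flank = left,
                   right_flank = as.integer(right), pass = gc_ok & fl_ok,
                   fail_reasons = reasons, stringsAsFactors = FALSE))
}

#' Summarize a marker amplification/polymorphism screen
#'
#' Input rows describe one tested primer pair each: amplification entries
#' per accession column (`-` or empty meaning no product) and a
#' `call` of `no_product`, `monomorphic` or `polymorphic`. The
#' amplification rate is the percentage of primers amplifying in at least
#' one accession; the polymorphism rate the percentage called polymorphic;
#' both integer-rounded. An optional `polymorphic_in` column (comma-listed
#' population names) yields a per-population breakdown.
#'
#' @param records `data.frame` with `primer_id`, accession columns, `call`
#'   and optionally `polymorphic_in`.
#' @param accession_cols Names of the accession columns; defaults to every
#'   column except `primer_id`, `call`, `polymorphic_in`.
#' @return List with `amplification_rate`, `polymorphism_rate` (percent),
#'   `n`, and `by_population` (or `NULL`).
#' @export
marker_screen_summary <- function(records, accession_cols = NULL) {
  stopifnot(nrow(records) > 0, all(c("primer_id", "call") %in% names(records)))
  bad <- setdiff(unique(records$call),
                 c("no_product", "monomorphic", "polymorphic"))
  if (length(bad)) stop("unknown polymorphism call: ", paste(bad, collapse = ", "))
  if (is.null(accession_cols)) {
    accession_cols <- setdiff(names(records),
                              c("primer_id", "call", "polymorphic_in"))
  }
  amp_entry <- function(x) !(is.na(x) | x %in% c("", "-", "no_product"))
  amplified <- if (length(accession_cols)) {
    apply(records[, accession_cols, drop = FALSE], 1,
          function(r) any(amp_entry(r)))
  } else {
    records$call != "no_product"
  }
  if (any(records$call != "no_product" & !amplified)) {
    stop("a monomorphic/polymorphic call requires amplification in at ",
         "least one accession")
  }
  by_pop <- NULL
  if (!is.null(records$polymorphic_in)) {
    pops <- unique(unlist(strsplit(records$polymorphic_in[
      nzchar(records$polymorphic_in)], ",")))
    if (length(pops)) {
      by_pop <- data.frame(
        population = pops,
        n_polymorphic = vapply(pops, function(p) {
          sum(vapply(strsplit(records$polymorphic_in, ","),
                     function(v) p %in% v, logical(1)))
        }, numeric(1)),
        stringsAsFactors = FALSE)
      rownames(by_pop) <- NULL
    }
  }
  list(amplification_rate = round(100 * mean(amplified)),
       polymorphism_rate = round(100 * mean(records$call == "polymorphic")),
       n = nrow(records),
       by_population = by_pop)
}
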