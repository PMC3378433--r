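#' Trend-classification parameters
#'
#' The categorical stage-trend call formalizes "goes up / down / up then
#' down / down then up / stays fairly constant" with a fold band: a step
#' from frequency f1 to f2 is `up` if `(f2 + p) / (f1 + p) >= tau`, `down`
#' if `<= 1/tau`, else `flat`, where `p` is a pseudocount rescaled to
#' frequency space. The step string is then collapsed with flats absorbed.
#' `tau` and the pseudocount are configurable and echoed in report headers.
#'
#' @param top_n Number of most-abundant contigs taken per library.
#' @param fold_threshold The band `tau` (> 1).
#' @param pseudocount Pseudocount in reads (>= 0); rescaled per library as
#'   `100 * pseudocount / total reads` when frequencies are percentages.
#' @param evalue_cutoff E-value cutoff used when counting reads.
#' @return List of class `trend_params`.
#' @export
trend_params <- function(top_n = 30, fold_threshold = 1.5, pseudocount = 1,
                         evalue_cutoff = 1e-5) {
  stopifnot(top_n >= 1, fold_threshold > 1, pseudocount >= 0)
  structure(list(top_n = as.integer(top_n), fold_threshold = fold_threshold,
                 pseudocount = pseudocount, evalue_cutoff = evalue_cutoff),
            class = "trend_params")
}

#' Count homologous reads per contig across libraries
#'
#' Aligns every read against the contig set and counts each read toward at
#' most one contig: its best hit (highest score, ties to the
#' lexicographically smaller contig id) with E-value at or below the
#' cutoff. Unmatched reads contribute nowhere, so no read is ever counted
#' twice.
#'
#' @param contigs Named character vector of contig sequences.
#' @param reads Read table spanning one or more libraries.
#' @param scoring [scoring_params()].
#' @return Integer matrix contigs x libraries of read counts.
#' @export
assign_reads <- function(contigs, reads, scoring = scoring_params()) {
  stopifnot(length(contigs) > 0, nrow(reads) > 0)
  libs <- unique(reads$library_id)
  counts <- matrix(0L, length(contigs), length(libs),
                   dimnames = list(names(contigs), libs))
  hits <- seed_extend_search(setNames(reads$sequence, reads$id), contigs,
                             scoring)
  if (!nrow(hits)) return(counts)
  # best hit per read: max score, then smaller subject id
  hits <- hits[order(hits$query, -hits$score, hits$subject), ]
  best <- hits[!duplicated(hits$query), ]
  lib_of <- reads$library_id[match(best$query, reads$id)]
  tb <- table(factor(best$subject, levels = names(contigs)),
              factor(lib_of, levels = libs))
  counts[] <- counts + as.integer(tb)
  counts
}

#' Most abundant contigs in one library
#'
#' @param counts Contig x library count matrix from [assign_reads()].
#' @param library Library column to rank.
#' @param params [trend_params()].
#' @return Character vector of at most `top_n` contig ids with nonzero
#'   counts, descending by count, ties broken by contig id.
#' @export
top_abundant <- function(counts, library, params = trend_params()) {
  x <- counts[, library]
  x <- x[x > 0]
  if (!length(x)) return(character())
  ord <- order(-x, names(x))
  head(names(x)[ord], params$top_n)
}

#' Per-library read frequencies
#'
#' @param counts Contig x library count matrix.
#' @param totals Named per-library totals of assembled reads (the
#'   denominators; must be positive).
#' @return Long `data.frame`: `contig_id`, `library_id`, `count`, `total`,
#'   `frequency` (percent of total reads).
#' @export
frequency_table <- function(counts, totals) {
  libs <- colnames(counts)
  missing_t <- setdiff(libs, names(totals))
  if (length(missing_t)) {
    stop("no read total for library: ", paste(missing_t, collapse = ", "))
  }
  if (any(totals[libs] <= 0)) stop("library read totals must be positive")
  out <- data.frame(
    contig_id = rep(rownames(counts), times = length(libs)),
    library_id = rep(libs, each = nrow(counts)),
    count = as.integer(counts),
    total = rep(as.integer(totals[libs]), each = nrow(counts)),
    stringsAsFactors = FALSE)
  out$frequency <- 100 * out$count / out$total
  out
}

classify_steps <- function(f, tau, p) {
  r <- (f[-1] + p[-1]) / (f[-length(f)] + p[-length(p)])
  ifelse(r >= tau, "up", ifelse(r <= 1 / tau, "down", "flat"))
}

#' Classify a stage-ordered frequency profile into a trend pattern
#'
#' Consecutive steps are labelled with the fold band in `params`, then the
#' step string is collapsed with flats absorbed: monotone non-mixed gives
#' `up` or `down`; exactly one sign change gives `up_down` or `down_up`;
#' all flat gives `flat`; two or more sign changes give `complex`.
#'
#' @param freqs Ordered numeric frequencies (length >= 2), stage order as
#'   in the design.
#' @param params [trend_params()].
#' @param pseudo Pseudocount already rescaled to the scale of `freqs`
#'   (scalar or per-stage vector).
#' @return One of `"up"`, `"down"`, `"up_down"`, `"down_up"`, `"flat"`,
#'   `"complex"`.
#' @export
classify_trend <- function(freqs, params = trend_params(), pseudo = 0) {
  if (length(freqs) < 2) stop("at least 2 ordered stages are required")
  if (length(pseudo) == 1) pseudo <- rep(pseudo, length(freqs))
  steps <- classify_steps(freqs, params$fold_threshold, pseudo)
  core <- steps[steps != "flat"]
  if (!length(core)) return("flat")
  changes <- sum(core[-1] != core[-length(core)])
  if (changes == 0) return(core[1])
  if (changes == 1) return(if (core[1] == "up") "up_down" else "down_up")
  "complex"
}

#' Abundance report across libraries with trend calls
#'
#' One row per (source library, top-abundant contig): the contig's counts
#' and percent frequencies across every library in stage order, plus the
#' trend pattern over each trend-bearing organ group. The classification
#' parameters are recorded in the report header comments.
#'
#' @param counts Contig x library count matrix (columns in stage order).
#' @param totals Named per-library totals of assembled reads.
#' @param design A [stage_design()].
#' @param params [trend_params()].
#' @return `data.frame` with a `header_comments` attribute; see
#'   [write_tsv_report()].
#' @export
abundance_report <- function(counts, totals, design,
                             params = trend_params()) {
  libs <- intersect(design$library_id, colnames(counts))
  freq <- sweep(counts[, libs, drop = FALSE], 2, totals[libs], "/") * 100
  tg <- trend_groups(design)
  rows <- list()
  for (lib in libs) {
    top <- top_abundant(counts, lib, params)
    for (cg in top) {
      row <- data.frame(source_library = lib, contig_id = cg,
                        stringsAsFactors = FALSE)
      for (l2 in libs) {
        row[[paste0("count_", l2)]] <- counts[cg, l2]
        row[[paste0("freq_", l2)]] <- round(freq[cg, l2], 4)
      }
      for (g in tg) {
        glibs <- design$library_id[design$group == g]
        glibs <- intersect(glibs, libs)
        if (length(glibs) < 2) next
        p <- 100 * params$pseudocount / totals[glibs]
        row[[paste0("pattern_", g)]] <-
          classify_trend(freq[cg, glibs], params, pseudo = p)
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(source_library = character(), contig_id = character(),
               stringsAsFactors = FALSE)
  attr(out, "header_comments") <- c(
    sprintf("trend call: fold band tau = %g, pseudocount = %g reads",
            params$fold_threshold, params$pseudocount),
    sprintf("top_n = %d most abundant contigs per library", params$top_n),
    "frequencies are percent of total assembled reads per library")
  out
}
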