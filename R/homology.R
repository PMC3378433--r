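#' Scoring and statistics for the local-alignment search
#'
#' BLASTN-like defaults: match +1, mismatch -2, affine gaps where the first
#' gapped base costs `gap_open` and each further base `gap_extend`.
#' E-values use the Karlin-Altschul formula `E = K * m * n * exp(-lambda *
#' S)` with the classical ungapped nucleotide constants applied to gapped
#' scores (a standard approximation); `m` is the query length and `n` the
#' total subject length. The default reporting cutoff is E <= 1e-5.
#'
#' @param match,mismatch,gap_open,gap_extend Alignment scores.
#' @param kmer_size Seed length for the search index.
#' @param evalue_cutoff Maximum reported E-value.
#' @param karlin_k,karlin_lambda Karlin-Altschul constants.
#' @param band Half-width of the banded gapped refinement around seed
#'   diagonals.
#' @param max_bucket Seeds from k-mers occurring more often than this in
#'   the subject set are skipped (repeat guard).
#' @return A list of class `scoring_params`.
#' @export
scoring_params <- function(match = 1, mismatch = -2, gap_open = -5,
                           gap_extend = -2, kmer_size = 11,
                           evalue_cutoff = 1e-5, karlin_k = 0.621,
                           karlin_lambda = 1.33, band = 16,
                           max_bucket = 128) {
  stopifnot(match > 0, mismatch < 0, evalue_cutoff > 0, kmer_size >= 4,
            karlin_k > 0, karlin_lambda > 0)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 kmer_size = as.integer(kmer_size),
                 evalue_cutoff = evalue_cutoff,
                 karlin_k = karlin_k, karlin_lambda = karlin_lambda,
                 band = as.integer(band), max_bucket = as.integer(max_bucket)),
            class = "scoring_params")
}

#' Karlin-Altschul E-value
#'
#' `E = K * m * n * exp(-lambda * S)`: the expected number of chance local
#' alignments scoring at least `S` in a search space of query length `m`
#' times total subject length `n`. Monotone decreasing in `S`, linear in
#' `m` and `n`.
#'
#' @param score Raw alignment score(s).
#' @param query_len Query length (nt).
#' @param total_subject_len Summed subject lengths (nt).
#' @param scoring [scoring_params()].
#' @return Numeric E-value(s).
#' @export
evalue <- function(score, query_len, total_subject_len,
                   scoring = scoring_params()) {
  stopifnot(query_len > 0, total_subject_len > 0)
  scoring$karlin_k * query_len * total_subject_len *
    exp(-scoring$karlin_lambda * score)
}

#' Exact Smith-Waterman local alignment (testing oracle)
#'
#' Full Gotoh dynamic programming over the complete matrix: the exact
#' optimal local alignment score under the affine scheme in `scoring`.
#' Quadratic in sequence length and intended as the reference the
#' seed-and-extend heuristic is tested against, not for bulk searches.
#'
#' @param a,b Nucleotide strings (each at most 5000 nt).
#' @param scoring [scoring_params()].
#' @return List with `score` and 0-based half-open aligned spans `qstart`,
#'   `qend` (on `a`), `sstart`, `send` (on `b`).
#' @export
sw_align_oracle <- function(a, b, scoring = scoring_params()) {
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) > 5000 || nchar(b) > 5000) {
    stop("sw_align_oracle is a quadratic-time oracle; sequences over ",
         "5000 nt are refused")
  }
  cpp_sw_align(a, b, scoring$match, scoring$mismatch, scoring$gap_open,
               scoring$gap_extend)
}

#' Seed-and-extend local alignment search
#'
#' Builds a k-mer index over the subjects, collects seed diagonals for each
#' query on both strands, and refines each diagonal cluster with a banded
#' gapped alignment. The best hit per (query, subject) pair is kept and
#' reported iff its E-value is at or below `scoring$evalue_cutoff`. The
#' heuristic score never exceeds the [sw_align_oracle()] score, with
#' equality whenever an exact shared k-mer lies on the optimal alignment
#' within the band.
#'
#' @param queries Named character vector of query sequences.
#' @param subjects Named character vector of subject sequences.
#' @param scoring [scoring_params()].
#' @return `data.frame` with columns `query`, `subject`, `score`, `evalue`,
#'   `qstart`, `qend`, `sstart`, `send` (0-based half-open, query spans on
#'   the forward strand) and `strand` (`+`/`-`).
#' @export
seed_extend_search <- function(queries, subjects,
                               scoring = scoring_params()) {
  empty <- data.frame(query = character(), subject = character(),
                      score = integer(), evalue = numeric(),
                      qstart = integer(), qend = integer(),
                      sstart = integer(), send = integer(),
                      strand = character(), stringsAsFactors = FALSE)
  if (!length(subjects) || !length(queries)) return(empty)
  if (is.null(names(queries))) names(queries) <- paste0("q", seq_along(queries))
  if (is.null(names(subjects))) names(subjects) <- paste0("s", seq_along(subjects))
  hits <- cpp_search(toupper(unname(queries)), toupper(unname(subjects)),
                     scoring$kmer_size, scoring$match, scoring$mismatch,
                     scoring$gap_open, scoring$gap_extend, scoring$band,
                     scoring$max_bucket)
  if (!nrow(hits)) return(empty)
  n_total <- sum(nchar(subjects))
  ev <- evalue(hits$score, nchar(queries)[hits$qidx], n_total, scoring)
  keep <- ev <= scoring$evalue_cutoff
  out <- data.frame(query = names(queries)[hits$qidx][keep],
                    subject = names(subjects)[hits$sidx][keep],
                    score = hits$score[keep], evalue = ev[keep],
                    qstart = hits$qstart[keep], qend = hits$qend[keep],
                    sstart = hits$sstart[keep], send = hits$send[keep],
                    strand = hits$strand[keep], stringsAsFactors = FALSE)
  out[order(out$query, out$subject), , drop = FALSE]
}
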