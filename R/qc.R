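#' Pre-assembly QC parameters
#'
#' Mirrors the standard pre-assembly filtering of 454 EST projects:
#' adapter/primer masking at read ends followed by removal of reads shorter
#' than 50 nt. Adapter matching is exact-substring and end-anchored — a
#' read prefix matching an adapter suffix (or read suffix matching an
#' adapter prefix) over at least `min_adapter_match` bases is trimmed.
#' A mean-quality threshold can be supplied but is disabled by default;
#' synthetic reads carry no meaningful qualities.
#'
#' @param min_length Minimum retained read length in nt.
#' @param adapters Character vector of adapter/primer sequences (possibly
#'   empty). No sequence is hard-coded: primer sets are project-specific.
#' @param min_adapter_match Minimum exact end overlap in nt.
#' @param min_mean_quality Optional mean-quality cutoff; `NULL` disables.
#' @return A list of class `qc_params`.
#' @export
qc_params <- function(min_length = 50, adapters = character(),
                      min_adapter_match = 10, min_mean_quality = NULL) {
  stopifnot(min_length >= 1, min_adapter_match >= 1)
  structure(list(min_length = as.integer(min_length),
                 adapters = toupper(adapters),
                 min_adapter_match = as.integer(min_adapter_match),
                 min_mean_quality = min_mean_quality),
            class = "qc_params")
}

# longest L >= minm with suffix(adapter, L) == prefix(read, L)
prefix_trim_len <- function(seq, adapter, minm) {
  la <- nchar(adapter)
  for (L in rev(seq(minm, min(la, nchar(seq))))) {
    if (substr(seq, 1, L) == substr(adapter, la - L + 1, la)) return(L)
  }
  0L
}

suffix_trim_len <- function(seq, adapter, minm) {
  ls <- nchar(seq)
  for (L in rev(seq(minm, min(nchar(adapter), ls)))) {
    if (substr(seq, ls - L + 1, ls) == substr(adapter, 1, L)) return(L)
  }
  0L
}

#' Mask adapter sequence at read ends
#'
#' Trims any read prefix that matches an adapter's suffix, and any read
#' suffix that matches an adapter's prefix, over at least
#' `min_adapter_match` exact bases. Internal sequence is never altered and
#' reads are never lengthened; a read that is entirely adapter becomes
#' empty (and is then dropped by [filter_short()]).
#'
#' @param reads Read table ([read_fasta()] layout).
#' @param params [qc_params()].
#' @return The read table with trimmed sequences.
#' @export
mask_adapters <- function(reads, params = qc_params()) {
  stopifnot(inherits(params, "qc_params"))
  if (!length(params$adapters) || !nrow(reads)) return(reads)
  minm <- params$min_adapter_match
  seqs <- toupper(reads$sequence)
  for (ad in params$adapters) {
    if (nchar(ad) < minm) next
    for (i in seq_along(seqs)) {
      if (!nchar(seqs[i])) next
      tl <- prefix_trim_len(seqs[i], ad, minm)
      if (tl > 0) seqs[i] <- substr(seqs[i], tl + 1, nchar(seqs[i]))
      if (!nchar(seqs[i])) next
      tl <- suffix_trim_len(seqs[i], ad, minm)
      if (tl > 0) seqs[i] <- substr(seqs[i], 1, nchar(seqs[i]) - tl)
    }
  }
  reads$sequence <- seqs
  reads
}

#' Remove reads shorter than the minimum length
#'
#' A read is retained iff its length is at least `min_length` nt
#' (the 50-nt default drops a 49-nt read and keeps a 50-nt one).
#'
#' @param reads Read table.
#' @param params [qc_params()].
#' @return List with `reads` (retained rows) and `removed` (count);
#'   retained + removed equals the input row count.
#' @export
filter_short <- function(reads, params = qc_params()) {
  stopifnot(inherits(params, "qc_params"))
  keep <- nchar(reads$sequence) >= params$min_length
  list(reads = reads[keep, , drop = FALSE],
       removed = sum(!keep))
}

#' Per-library QC summary
#'
#' @param before Read table before QC.
#' @param after Read table after [mask_adapters()] + [filter_short()].
#' @return Per-library `data.frame`: input reads, masked reads (shortened
#'   by adapter trimming), removed reads, mean retained length.
#' @export
qc_summary <- function(before, after) {
  libs <- unique(before$library_id)
  rows <- lapply(libs, function(lib) {
    b <- before[before$library_id == lib, ]
    a <- after[after$library_id == lib, ]
    common <- intersect(b$id, a$id)
    masked <- sum(nchar(a$sequence[match(common, a$id)]) <
                    nchar(b$sequence[match(common, b$id)]))
    data.frame(library_id = lib,
               n_input = nrow(b),
               n_masked = masked,
               n_removed = nrow(b) - nrow(a),
               mean_length = if (nrow(a)) mean(nchar(a$sequence)) else 0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the full QC stage
#'
#' @param reads Read table.
#' @param params [qc_params()].
#' @return List with `reads` (QC'd table) and `summary` (per-library table).
#' @export
apply_qc <- function(reads, params = qc_params()) {
  masked <- mask_adapters(reads, params)
  flt <- filter_short(masked, params)
  list(reads = flt$reads, summary = qc_summary(reads, flt$reads))
}
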