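#' Greedy assembly parameters
#'
#' @param min_overlap Minimum end-overlap length in nt (30 by default,
#'   matching the relaxed overlap setting this pipeline targets).
#' @param min_identity Minimum identity over the overlap.
#' @param kmer_size Seed length for overlap candidate detection; must not
#'   exceed `min_overlap`.
#' @param kmer_diag Seed length used to enumerate overlap diagonals between
#'   a candidate pair (smaller than `kmer_size` for sensitivity on noisy
#'   overlaps).
#' @param max_bucket Repeat guard for the candidate index.
#' @return A list of class `assembly_params`.
#' @export
assembly_params <- function(min_overlap = 30, min_identity = 0.95,
                            kmer_size = 16, kmer_diag = 12,
                            max_bucket = 200) {
  stopifnot(min_overlap >= kmer_size, min_identity > 0, min_identity <= 1,
            kmer_diag <= kmer_size)
  structure(list(min_overlap = as.integer(min_overlap),
                 min_identity = min_identity,
                 kmer_size = as.integer(kmer_size),
                 kmer_diag = as.integer(kmer_diag),
                 max_bucket = as.integer(max_bucket)),
            class = "assembly_params")
}

#' Greedy overlap-consensus assembly
#'
#' Iteratively merges the read/contig pair with the highest-scoring end
#' overlap (score = matching bases in the overlap) of length at least
#' `min_overlap` and identity at least `min_identity`, until none remains.
#' Reverse-complement overlaps are considered. Consensus is per-column
#' majority vote with ties broken by the first-merged base. Ties between
#' equal-scoring overlaps prefer the longer overlap, then the
#' lexicographically smaller id pair; reads are ordered canonically by id
#' internally, so the result does not depend on input order.
#'
#' The layout is ungapped (diagonal): the overlap model assumes
#' substitution-type errors, which matches 454-style EST data after
#' removal of low-quality ends and the substitution-only synthetic reads.
#'
#' @param reads Read table ([read_fasta()] layout); ids must be unique.
#' @param params [assembly_params()].
#' @return A list of class `assembly_result`: `contigs` (`data.frame` of
#'   `id`, `sequence`, `n_members`), `singletons` (read table of unmerged
#'   reads), `membership` (`read_id`, `contig_id`, `library_id`, `offset`,
#'   `strand`; singleton reads carry their own id as `contig_id`), and
#'   `library_counts` (contig x library read-count matrix).
#' @export
assemble_greedy <- function(reads, params = assembly_params()) {
  stopifnot(inherits(params, "assembly_params"))
  if (anyDuplicated(reads$id)) stop("read ids must be unique for assembly")
  if (!nrow(reads)) {
    return(structure(list(
      contigs = data.frame(id = character(), sequence = character(),
                           n_members = integer(), stringsAsFactors = FALSE),
      singletons = reads,
      membership = data.frame(read_id = character(), contig_id = character(),
                              library_id = character(), offset = integer(),
                              strand = integer(), stringsAsFactors = FALSE),
      library_counts = matrix(0L, 0, 0)), class = "assembly_result"))
  }
  ord <- order(reads$id)
  r <- reads[ord, , drop = FALSE]
  res <- cpp_assemble(toupper(r$sequence), params$min_overlap,
                      params$min_identity, params$kmer_size,
                      params$kmer_diag, params$max_bucket)
  nunit <- length(res$consensus)
  is_contig <- res$n_members >= 2
  contig_ids <- character(nunit)
  contig_ids[is_contig] <- sprintf("contig_%05d", cumsum(is_contig)[is_contig])
  # singleton units are named after their single read
  single_units <- which(!is_contig)
  contig_ids[single_units] <- r$id[match(single_units, res$unit)]

  membership <- data.frame(read_id = r$id,
                           contig_id = contig_ids[res$unit],
                           library_id = r$library_id,
                           offset = res$offset,
                           strand = res$strand,
                           stringsAsFactors = FALSE)
  contigs <- data.frame(id = contig_ids[is_contig],
                        sequence = as.character(res$consensus)[is_contig],
                        n_members = res$n_members[is_contig],
                        stringsAsFactors = FALSE)
  singletons <- r[!is_contig[res$unit], , drop = FALSE]
  rownames(singletons) <- NULL

  libs <- unique(reads$library_id)
  counts <- matrix(0L, nrow(contigs), length(libs),
                   dimnames = list(contigs$id, libs))
  if (nrow(contigs)) {
    mc <- membership[membership$contig_id %in% contigs$id, ]
    tb <- table(factor(mc$contig_id, levels = contigs$id),
                factor(mc$library_id, levels = libs))
    counts[] <- as.integer(tb)
  }
  structure(list(contigs = contigs, singletons = singletons,
                 membership = membership, library_counts = counts),
            class = "assembly_result")
}

#' Assembly summary row
#'
#' Arithmetic summary of one assembly in the style of a sequencing-project
#' summary table: reads assembled, reads in contigs, contig/singleton
#' counts and mean lengths, and the unigene total (contigs + singletons).
#'
#' @param result An `assembly_result`.
#' @param label Row label (e.g. the library or organ set assembled).
#' @return One-row `data.frame`.
#' @export
assembly_summary <- function(result, label = "all") {
  stopifnot(inherits(result, "assembly_result"))
  n_in_contigs <- sum(result$contigs$n_members)
  n_reads <- n_in_contigs + nrow(result$singletons)
  data.frame(sample = label,
             n_reads_assembled = n_reads,
             n_reads_in_contigs = n_in_contigs,
             n_contigs = nrow(result$contigs),
             n_singletons = nrow(result$singletons),
             mean_contig_length = if (nrow(result$contigs))
               round(mean(nchar(result$contigs$sequence)), 1) else 0,
             mean_singleton_length = if (nrow(result$singletons))
               round(mean(nchar(result$singletons$sequence)), 1) else 0,
             n_unigenes = nrow(result$contigs) + nrow(result$singletons),
             stringsAsFactors = FALSE)
}

#' Unigene total from contig and singleton counts
#'
#' @param n_contigs,n_singletons Counts from an assembly summary.
#' @return `n_contigs + n_singletons`, the number of unique putative
#'   transcripts.
#' @export
unigene_total <- function(n_contigs, n_singletons) {
  as.numeric(n_contigs) + as.numeric(n_singletons)
}

#' Unigene sequences (contigs plus singletons) of an assembly
#'
#' @param result An `assembly_result`.
#' @return Named character vector of unigene sequences.
#' @export
unigene_sequences <- function(result) {
  c(setNames(result$contigs$sequence, result$contigs$id),
    setNames(result$singletons$sequence, result$singletons$id))
}

#' Compare two unigene sets by cross-homology
#'
#' A unigene is shared iff it has a homology hit (E-value at or below the
#' cutoff in `scoring`) in the other set; shared entities are counted as
#' connected components of the bipartite cross-hit graph that span both
#' sets, so identical sets of size n yield n shared unigenes.
#'
#' @param set_a,set_b Named character vectors of unigene sequences.
#' @param scoring [scoring_params()].
#' @return List with `shared`, `unique_a`, `unique_b` counts.
#' @export
compare_unigene_sets <- function(set_a, set_b,
                                 scoring = scoring_params()) {
  stopifnot(length(set_a) > 0, length(set_b) > 0)
  ab <- seed_extend_search(set_a, set_b, scoring)
  ba <- seed_extend_search(set_b, set_a, scoring)
  edges <- unique(rbind(
    data.frame(a = ab$query, b = ab$subject, stringsAsFactors = FALSE),
    data.frame(a = ba$subject, b = ba$query, stringsAsFactors = FALSE)))
  if (!nrow(edges)) {
    return(list(shared = 0L, unique_a = length(set_a),
                unique_b = length(set_b)))
  }
  va <- paste0("A|", names(set_a))
  vb <- paste0("B|", names(set_b))
  g <- igraph::graph_from_data_frame(
    data.frame(from = paste0("A|", edges$a), to = paste0("B|", edges$b)),
    directed = FALSE, vertices = data.frame(name = c(va, vb)))
  comp <- igraph::components(g)
  memb <- comp$membership
  shared <- 0L
  for (cid in seq_len(comp$no)) {
    vs <- names(memb)[memb == cid]
    has_a <- any(startsWith(vs, "A|"))
    has_b <- any(startsWith(vs, "B|"))
    if (has_a && has_b) shared <- shared + 1L
  }
  matched_a <- unique(edges$a)
  matched_b <- unique(edges$b)
  list(shared = shared,
       unique_a = length(set_a) - length(matched_a),
       unique_b = length(set_b) - length(matched_b))
}
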