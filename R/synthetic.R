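#' Stage design for a multi-organ EST study
#'
#' Describes the stage-ordered libraries the generator emulates and the
#' pipeline analyses: by default nine libraries — flower buds at four
#' cold-acclimation time points (0, 397, 789 and 1333 chill units, a chill
#' unit being one hour between 0 and 7 degrees C), fruit at four ripening
#' stages (green, white, pink, blue) and a single leaf library.
#'
#' @param groups A `data.frame` with columns `group`, `stage`, `ordinate`,
#'   or `NULL` for the default nine-library design. Stage ordinates must be
#'   strictly increasing within a group, and any trend-bearing group needs
#'   at least two stages.
#' @return A `data.frame` with columns `group`, `stage`, `ordinate` and a
#'   derived `library_id` (`<group>_<stage>`).
#' @export
stage_design <- function(groups = NULL) {
  if (is.null(groups)) {
    groups <- data.frame(
      group = c(rep("bud", 4), rep("fruit", 4), "leaf"),
      stage = c("0", "397", "789", "1333",
                "green", "white", "pink", "blue", "leaves"),
      ordinate = c(0, 397, 789, 1333, 1, 2, 3, 4, 1),
      stringsAsFactors = FALSE)
  }
  stopifnot(all(c("group", "stage", "ordinate") %in% names(groups)))
  for (g in unique(groups$group)) {
    o <- groups$ordinate[groups$group == g]
    if (any(diff(o) <= 0)) {
      stop("stage ordinates must be strictly increasing within group ", g)
    }
  }
  groups$library_id <- paste(groups$group, groups$stage, sep = "_")
  groups
}

# trend-bearing groups have >= 2 stages
trend_groups <- function(design) {
  tab <- table(design$group)
  names(tab)[tab >= 2]
}

#' Configuration for the synthetic transcriptome and read generator
#'
#' The generator emulates the study conditions the pipeline is built for:
#' several stage-ordered libraries sampled from one shared transcript pool,
#' 454-like read lengths (mean 287 nt by default), per-transcript expression
#' trends across stages (`up`, `down`, `up_down`, `down_up`, `flat`) encoded
#' as multiplicative per-step fold changes, and SSR motifs planted into
#' otherwise repeat-free background sequence.
#'
#' @param n_transcripts Number of transcripts in the shared pool.
#' @param transcript_length Length range `c(min, max)` in nt.
#' @param trend_assignment Optional `data.frame` (`transcript`, `group`,
#'   `trend`) overriding the default cyclic assignment of the five pattern
#'   labels within each trend-bearing group.
#' @param effect_size Fold change per trend step (> 1).
#' @param reads_per_library Reads drawn per library.
#' @param read_length `c(mean, sd, min)` of the read-length distribution in
#'   nt (normal, rounded, truncated to `[min, transcript length]`).
#' @param error_rate Per-base substitution probability in `[0, 1)`.
#'   Substitution-only: no homopolymer indel model.
#' @param adapter_seq Adapter prepended to every read (empty for none).
#' @param ssr_plant_spec `data.frame` (`motif`, `repeats`, `transcript`,
#'   `offset`) of SSR loci to plant; 0-based offsets.
#' @param seed Mandatory RNG seed (integer).
#' @param design A [stage_design()].
#' @param abundance_skew Exponent `a` of the rank-based base abundance
#'   `w_r = r^-a`; 0 gives a uniform pool.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_transcripts = 30,
                             transcript_length = c(600, 1500),
                             trend_assignment = NULL,
                             effect_size = 2,
                             reads_per_library = 400,
                             read_length = c(mean = 287, sd = 50, min = 50),
                             error_rate = 0.005,
                             adapter_seq = "",
                             ssr_plant_spec = NULL,
                             seed,
                             design = stage_design(),
                             abundance_skew = 0.5) {
  if (missing(seed)) stop("a seed is mandatory in synthetic_config()")
  stopifnot(n_transcripts >= 1, reads_per_library >= 1,
            length(transcript_length) == 2,
            transcript_length[1] >= 120,
            transcript_length[2] >= transcript_length[1],
            effect_size > 1,
            error_rate >= 0, error_rate < 1,
            length(read_length) == 3, read_length[[1]] > 0,
            read_length[[2]] >= 0, read_length[[3]] >= 1)
  if (is.null(ssr_plant_spec)) {
    ssr_plant_spec <- data.frame(motif = character(), repeats = integer(),
                                 transcript = integer(), offset = integer(),
                                 stringsAsFactors = FALSE)
  }
  stopifnot(all(c("motif", "repeats", "transcript", "offset") %in%
                  names(ssr_plant_spec)))
  cfg <- list(n_transcripts = as.integer(n_transcripts),
              transcript_length = as.integer(transcript_length),
              trend_assignment = trend_assignment,
              effect_size = effect_size,
              reads_per_library = as.integer(reads_per_library),
              read_length = setNames(as.numeric(read_length),
                                     c("mean", "sd", "min")),
              error_rate = error_rate,
              adapter_seq = toupper(adapter_seq),
              ssr_plant_spec = ssr_plant_spec,
              seed = as.integer(seed),
              design = design,
              abundance_skew = abundance_skew)
  class(cfg) <- "synthetic_config"
  cfg
}

transcript_ids <- function(n) sprintf("t%04d", seq_len(n))

# Per-stage log2 multiplier exponents for one trend over k stages.
# The tent patterns use double steps so a single rise or fall is still a
# clear 2-step signal after per-library renormalization of proportions.
trend_exponents <- function(trend, k) {
  tent <- 2 * pmin(0:(k - 1), (k - 1):0)
  switch(trend,
    flat = rep(0, k),
    up = 0:(k - 1),
    down = (k - 1):0,
    up_down = tent,
    down_up = max(tent) - tent,
    stop("unknown trend label: ", trend))
}

# Cycle of pattern labels: monotone trends kept to ~20% of the pool and
# tent pairs mirrored, so per-library totals stay nearly constant and
# renormalization does not push flat profiles across the call threshold.
default_trend_assignment <- function(n, design) {
  pats <- c("up", "down", "up_down", "down_up", "flat",
            "up_down", "down_up", "flat", "flat", "flat")
  tg <- trend_groups(design)
  out <- list()
  for (gi in seq_along(tg)) {
    # offset the cycle per group so bud/fruit combinations vary
    lab <- pats[((seq_len(n) - 1 + (gi - 1) * 2) %% length(pats)) + 1]
    out[[gi]] <- data.frame(transcript = transcript_ids(n), group = tg[gi],
                            trend = lab, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

plant_motif <- function(seq, motif, repeats, offset) {
  run <- strrep(motif, repeats)
  if (offset < 0 || offset + nchar(run) > nchar(seq)) {
    stop("planted SSR exceeds transcript bounds (offset ", offset,
         ", run length ", nchar(run), ", transcript length ", nchar(seq), ")")
  }
  paste0(substr(seq, 1, offset), run,
         substr(seq, offset + nchar(run) + 1, nchar(seq)))
}

#' Generate a synthetic transcriptome with planted trends and SSRs
#'
#' Background sequence is i.i.d. uniform over ACGT with rejection of
#' accidental SSRs: a transcript is resampled until [find_ssrs()] (at the
#' thresholds in `ssr_params`) reports exactly the planted loci, so SSR
#' mining over the pool returns planted truth and nothing else.
#'
#' @param config A [synthetic_config()].
#' @param ssr_params [ssr_params()] used for the rejection screen.
#' @return A list with `transcripts` (named character vector) and `truth`,
#'   itself a list of `trends` (transcript, group, trend), `proportions`
#'   (transcripts x libraries matrix of expected read proportions, each
#'   column summing to 1) and `ssr` (planted loci, 0-based half-open).
#' @export
generate_transcriptome <- function(config, ssr_params = est454::ssr_params()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_transcripts
  ids <- transcript_ids(n)
  design <- config$design

  plant <- config$ssr_plant_spec
  if (nrow(plant) &&
      (min(plant$transcript) < 1 || max(plant$transcript) > n)) {
    stop("ssr_plant_spec refers to a transcript outside 1..", n)
  }

  lens <- floor(runif(n, config$transcript_length[1],
                      config$transcript_length[2] + 1))
  seqs <- character(n)
  ssr_truth <- list()
  for (i in seq_len(n)) {
    spec_i <- plant[plant$transcript == i, , drop = FALSE]
    expected <- data.frame(
      transcript = rep(ids[i], nrow(spec_i)),
      motif = spec_i$motif,
      repeats = as.integer(spec_i$repeats),
      start = as.integer(spec_i$offset),
      end = as.integer(spec_i$offset + nchar(spec_i$motif) * spec_i$repeats),
      stringsAsFactors = FALSE)
    ok <- FALSE
    for (try in 1:200) {
      s <- random_dna(lens[i])
      for (z in seq_len(nrow(spec_i))) {
        s <- plant_motif(s, spec_i$motif[z], spec_i$repeats[z],
                         spec_i$offset[z])
      }
      found <- find_ssrs(s, ssr_params, check_length = FALSE)
      found <- found[order(found$start), , drop = FALSE]
      exp_o <- expected[order(expected$start), , drop = FALSE]
      same <- nrow(found) == nrow(exp_o) &&
        all(found$motif == exp_o$motif) &&
        all(found$repeats == exp_o$repeats) &&
        all(found$start == exp_o$start)
      if (same) { ok <- TRUE; break }
    }
    if (!ok) {
      stop("could not realize planted SSR layout for transcript ", ids[i],
           " after 200 attempts (motifs may extend into flanks)")
    }
    seqs[i] <- s
    ssr_truth[[i]] <- expected
  }
  names(seqs) <- ids

  trends <- config$trend_assignment %||% default_trend_assignment(n, design)
  stopifnot(all(c("transcript", "group", "trend") %in% names(trends)))

  base <- seq_len(n)^(-config$abundance_skew)
  prop <- matrix(0, n, nrow(design),
                 dimnames = list(ids, design$library_id))
  le <- log2(config$effect_size)
  for (g in unique(design$group)) {
    libs <- design$library_id[design$group == g]
    k <- length(libs)
    mult <- matrix(1, n, k)
    if (g %in% trends$group && k >= 2) {
      tg <- trends[trends$group == g, ]
      tg <- tg[match(ids, tg$transcript), ]
      for (i in seq_len(n)) {
        mult[i, ] <- 2^(le * trend_exponents(tg$trend[i], k))
      }
    }
    w <- base * mult
    prop[, libs] <- sweep(w, 2, colSums(w), "/")
  }

  list(transcripts = seqs,
       truth = list(trends = trends,
                    proportions = prop,
                    ssr = do.call(rbind, ssr_truth)))
}

apply_substitutions <- function(seqs, error_rate) {
  if (error_rate <= 0 || !length(seqs)) return(seqs)
  bases <- c("A", "C", "G", "T")
  for (i in seq_along(seqs)) {
    L <- nchar(seqs[i])
    ne <- rbinom(1, L, error_rate)
    if (ne == 0) next
    pos <- sample.int(L, ne)
    ch <- strsplit(seqs[i], "")[[1]]
    for (p in pos) {
      ch[p] <- sample(setdiff(bases, ch[p]), 1)
    }
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

#' Sample a 454-like read library from a synthetic transcriptome
#'
#' Draws exactly `reads_per_library` reads multinomially over transcripts by
#' their expected proportions in the requested library; each read is a
#' uniformly placed substring of its transcript with normal read length
#' (truncated to `[min, transcript length]`) and i.i.d. substitution errors.
#' Source-transcript metadata is carried in extra columns, visible to tests
#' but unused by the pipeline.
#'
#' Each library draws from its own seed derived from `config$seed` and the
#' library's position in the design, so single-library calls are
#' reproducible in isolation and independent of call order.
#'
#' @param sim Result of [generate_transcriptome()].
#' @param library A `library_id` present in the design.
#' @param config The [synthetic_config()] used to build `sim`.
#' @return A read table as from [read_fasta()], plus truth columns
#'   `source_transcript`, `source_start` (0-based).
#' @export
sample_library_reads <- function(sim, library, config) {
  design <- config$design
  li <- match(library, design$library_id)
  if (is.na(li)) stop("library not in stage design: ", library)
  set.seed((config$seed + 7919L * li) %% .Machine$integer.max)

  prop <- sim$truth$proportions[, library]
  nr <- config$reads_per_library
  counts <- as.integer(rmultinom(1, nr, prop))
  ids <- names(sim$transcripts)

  out_seq <- character(nr)
  out_src <- character(nr)
  out_start <- integer(nr)
  k <- 0L
  rl <- config$read_length
  for (i in seq_along(ids)) {
    ci <- counts[i]
    if (ci == 0) next
    tlen <- nchar(sim$transcripts[i])
    lens <- round(rnorm(ci, rl[["mean"]], rl[["sd"]]))
    lens <- pmin(pmax(lens, rl[["min"]]), tlen)
    starts <- floor(runif(ci, 0, tlen - lens + 1))
    sq <- substring(sim$transcripts[i], starts + 1, starts + lens)
    idx <- k + seq_len(ci)
    out_seq[idx] <- sq
    out_src[idx] <- ids[i]
    out_start[idx] <- as.integer(starts)
    k <- k + ci
  }
  out_seq <- apply_substitutions(out_seq, config$error_rate)
  if (nzchar(config$adapter_seq)) {
    out_seq <- paste0(config$adapter_seq, out_seq)
  }
  data.frame(id = sprintf("%s_r%05d", library, seq_len(nr)),
             library_id = library,
             sequence = out_seq,
             source_transcript = out_src,
             source_start = out_start,
             stringsAsFactors = FALSE)
}

#' Simulate a replicated qPCR CT table consistent with planted trends
#'
#' CT values follow the planted per-stage log2 expression path: the mean CT
#' of a gene decreases by `log2(effect_size)` per planted up-step relative
#' to the (flat) reference genes, plus Gaussian replicate noise; values are
#' capped at `max_ct`.
#'
#' @param truth The `truth` element of [generate_transcriptome()], or any
#'   list with a `trends` data.frame.
#' @param config The [synthetic_config()].
#' @param n_replicates Replicates per gene x stage (3 mirrors standard
#'   triplicate reactions).
#' @param ref_genes Character vector of reference (housekeeping) gene ids to
#'   synthesize as flat.
#' @param group Trend-bearing organ group whose stages the table spans.
#' @param genes Genes to include (default: all transcripts with a trend in
#'   `group`).
#' @param noise_sd Replicate noise in cycles.
#' @param base_ct Mean CT of an unshifted gene; reference genes sit at
#'   `base_ct - 6`.
#' @param max_ct CT cap (cycles).
#' @return List with `ct` (gene, stage, replicate, ct) and `truth`
#'   (gene, trend), stages in design order.
#' @export
generate_qpcr_table <- function(truth, config, n_replicates = 3,
                                ref_genes = c("ref1", "ref2"),
                                group = "bud", genes = NULL,
                                noise_sd = 0.15, base_ct = 26,
                                max_ct = 40) {
  stopifnot(n_replicates >= 1, length(ref_genes) >= 1)
  design <- config$design
  stages <- design$stage[design$group == group]
  if (length(stages) < 2) stop("group ", group, " has fewer than 2 stages")
  k <- length(stages)
  tr <- truth$trends[truth$trends$group == group, ]
  if (is.null(genes)) genes <- tr$transcript
  missing_tr <- setdiff(genes, tr$transcript)
  if (length(missing_tr)) {
    stop("no trend label for gene(s): ", paste(missing_tr, collapse = ", "))
  }
  set.seed((config$seed + 104729L) %% .Machine$integer.max)
  le <- log2(config$effect_size)

  rows <- list()
  all_genes <- c(genes, ref_genes)
  for (g in all_genes) {
    if (g %in% ref_genes) {
      path <- rep(0, k)
      lab <- "flat"
    } else {
      lab <- tr$trend[match(g, tr$transcript)]
      path <- le * trend_exponents(lab, k)
    }
    ct0 <- if (g %in% ref_genes) base_ct - 6 else base_ct
    for (s in seq_len(k)) {
      ct <- ct0 - path[s] + rnorm(n_replicates, 0, noise_sd)
      rows[[length(rows) + 1]] <- data.frame(
        gene = g, stage = stages[s], replicate = seq_len(n_replicates),
        ct = pmin(ct, max_ct), stringsAsFactors = FALSE)
    }
  }
  ct <- do.call(rbind, rows)
  truth_df <- data.frame(
    gene = all_genes,
    trend = c(tr$trend[match(genes, tr$transcript)],
              rep("flat", length(ref_genes))),
    stringsAsFactors = FALSE)
  list(ct = ct, truth = truth_df)
}

#' Write one FASTA per library plus truth tables
#'
#' @param sim Result of [generate_transcriptome()].
#' @param config The [synthetic_config()].
#' @param dir Output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
write_synthetic_libraries <- function(sim, config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  design <- config$design
  paths <- list()
  for (lib in design$library_id) {
    reads <- sample_library_reads(sim, lib, config)
    p <- file.path(dir, paste0(lib, ".fasta"))
    write_fasta(reads, p)
    paths[[lib]] <- p
  }
  tp <- file.path(dir, "transcripts.fasta")
  write_fasta(sim$transcripts, tp)
  paths$transcripts <- tp

  prop <- as.data.frame(sim$truth$proportions)
  prop <- cbind(transcript = rownames(sim$truth$proportions), prop)
  rownames(prop) <- NULL
  paths$truth_trends <- write_tsv_report(
    sim$truth$trends, file.path(dir, "truth_trends.tsv"))
  paths$truth_proportions <- write_tsv_report(
    prop, file.path(dir, "truth_proportions.tsv"))
  paths$truth_ssr <- write_tsv_report(
    sim$truth$ssr %||% data.frame(), file.path(dir, "truth_ssr.tsv"),
    comments = "coordinates are 0-based half-open")
  invisible(paths)
}
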