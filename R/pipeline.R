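#' Pipeline configuration
#'
#' Bundles the per-stage parameter blocks and the simulation settings for
#' an end-to-end run: simulate -> qc -> assemble -> dge -> ssr -> qpcr ->
#' report. Every artifact is regenerable from the config plus seed.
#'
#' @param seed Run seed (mandatory; drives the single RNG stream).
#' @param output_dir Directory for all artifacts.
#' @param synthetic Named list of overrides for [synthetic_config()]
#'   (ignored when `library_files` is given).
#' @param library_files Optional named character vector
#'   (`library_id` -> FASTA path) to analyse existing libraries instead of
#'   simulating; the qPCR concordance stage needs planted truth and is
#'   skipped in that mode.
#' @param qc,assembly,scoring,trend,ssr Parameter blocks
#'   ([qc_params()], [assembly_params()], [scoring_params()],
#'   [trend_params()], [ssr_params()]).
#' @param qpcr Named list: `n_genes` per trend-bearing group, `noise_sd`,
#'   `n_replicates`.
#' @param design A [stage_design()].
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed, output_dir,
                            synthetic = list(
                              ssr_plant_spec = data.frame(
                                motif = c("AG", "AAG", "ACAT", "AT"),
                                repeats = c(7, 5, 4, 6),
                                transcript = c(1, 2, 3, 5),
                                offset = c(60, 120, 200, 90))),
                            library_files = NULL,
                            qc = qc_params(),
                            assembly = assembly_params(),
                            scoring = scoring_params(),
                            trend = trend_params(),
                            ssr = ssr_params(),
                            qpcr = list(n_genes = 8, noise_sd = 0.15,
                                        n_replicates = 3),
                            design = stage_design()) {
  if (missing(seed)) stop("pipeline_config() requires a seed")
  if (missing(output_dir)) stop("pipeline_config() requires an output_dir")
  if (!is.null(library_files)) {
    missing_f <- library_files[!file.exists(library_files)]
    if (length(missing_f)) {
      stop("library file not found: ", paste(missing_f, collapse = ", "))
    }
  }
  structure(list(seed = as.integer(seed), output_dir = output_dir,
                 synthetic = synthetic, library_files = library_files,
                 qc = qc, assembly = assembly, scoring = scoring,
                 trend = trend, ssr = ssr, qpcr = qpcr, design = design),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Scalar fields map 1:1 onto [pipeline_config()] arguments; per-stage
#' blocks (`qc:`, `assembly:`, `scoring:`, `trend:`, `ssr:`, `qpcr:`,
#' `synthetic:`) override the corresponding parameter defaults field by
#' field.
#'
#' @param path YAML file.
#' @param ... Overrides applied after the file (flags beat config).
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  over <- list(...)
  for (nm in names(over)) y[[nm]] <- over[[nm]]
  args <- list(seed = y$seed, output_dir = y$output_dir,
               synthetic = y$synthetic %||% list(),
               library_files = if (!is.null(y$library_files))
                 unlist(y$library_files) else NULL)
  blocks <- list(qc = qc_params, assembly = assembly_params,
                 scoring = scoring_params, trend = trend_params,
                 ssr = ssr_params)
  for (nm in names(blocks)) {
    args[[nm]] <- do.call(blocks[[nm]], y[[nm]] %||% list())
  }
  if (!is.null(y$qpcr)) args$qpcr <- utils::modifyList(
    list(n_genes = 8, noise_sd = 0.15, n_replicates = 3), y$qpcr)
  do.call(pipeline_config, args)
}

plog <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full analysis pipeline
#'
#' Executes simulate, qc, assemble, dge, ssr, qpcr and report in order,
#' logging record counts per stage; any stage failure aborts with a
#' stage-named error. Two runs with identical config and seed produce
#' byte-identical TSV reports.
#'
#' @param config A [pipeline_config()].
#' @return Named list of artifact paths, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  design <- config$design
  artifacts <- list()
  stage <- "init"
  tryCatch({
      # ---- simulate ------------------------------------------------------
      stage <- "simulate"
      sim <- NULL
      if (is.null(config$library_files)) {
        scfg <- do.call(synthetic_config,
                        c(list(seed = config$seed, design = design),
                          config$synthetic))
        sim <- generate_transcriptome(scfg, ssr_params = config$ssr)
        paths <- write_synthetic_libraries(sim, scfg, file.path(out, "sim"))
        lib_files <- unlist(paths[design$library_id])
        plog(stage, "%d transcripts, %d libraries x %d reads",
             scfg$n_transcripts, nrow(design), scfg$reads_per_library)
      } else {
        scfg <- NULL
        lib_files <- config$library_files
        missing_f <- lib_files[!file.exists(lib_files)]
        if (length(missing_f)) {
          stop("library file not found: ", paste(missing_f, collapse = ", "))
        }
        plog(stage, "using %d existing library files", length(lib_files))
      }
      artifacts$library_files <- lib_files

      # ---- qc ------------------------------------------------------------
      stage <- "qc"
      reads <- do.call(rbind, lapply(names(lib_files), function(lib) {
        read_fasta(lib_files[[lib]], library_id = lib)
      }))
      plog(stage, "%d input reads", nrow(reads))
      qcres <- apply_qc(reads, config$qc)
      reads <- qcres$reads
      artifacts$qc_summary <- write_tsv_report(
        qcres$summary, file.path(out, "qc_summary.tsv"))
      plog(stage, "%d reads retained (%d removed)", nrow(reads),
           sum(qcres$summary$n_removed))

      # ---- assemble ------------------------------------------------------
      stage <- "assemble"
      all_res <- assemble_greedy(reads, config$assembly)
      summaries <- list()
      for (lib in unique(reads$library_id)) {
        r <- assemble_greedy(reads[reads$library_id == lib, ],
                             config$assembly)
        summaries[[length(summaries) + 1]] <- assembly_summary(r, lib)
      }
      organ_res <- list()
      for (g in unique(design$group)) {
        glibs <- design$library_id[design$group == g]
        r <- assemble_greedy(reads[reads$library_id %in% glibs, ],
                             config$assembly)
        organ_res[[g]] <- r
        summaries[[length(summaries) + 1]] <-
          assembly_summary(r, paste0("all_", g))
      }
      summaries[[length(summaries) + 1]] <- assembly_summary(all_res, "all")
      artifacts$assembly_summary <- write_tsv_report(
        do.call(rbind, summaries), file.path(out, "assembly_summary.tsv"))
      artifacts$contigs <- write_fasta(
        all_res$contigs, file.path(out, "contigs.fasta"))
      artifacts$membership <- write_tsv_report(
        all_res$membership, file.path(out, "membership.tsv"))
      plog(stage, "%d contigs, %d singletons from %d reads",
           nrow(all_res$contigs), nrow(all_res$singletons), nrow(reads))

      # ---- dge -----------------------------------------------------------
      stage <- "dge"
      contig_seqs <- setNames(all_res$contigs$sequence, all_res$contigs$id)
      if (!length(contig_seqs)) stop("no contigs assembled")
      counts <- assign_reads(contig_seqs, reads, config$scoring)
      totals <- table(reads$library_id)
      totals <- setNames(as.integer(totals), names(totals))
      report <- abundance_report(counts, totals, design, config$trend)
      artifacts$abundance_report <- write_tsv_report(
        report, file.path(out, "abundance_report.tsv"))
      plog(stage, "%d report rows over %d libraries", nrow(report),
           ncol(counts))

      # ---- ssr -----------------------------------------------------------
      stage <- "ssr"
      unigenes <- unigene_sequences(all_res)
      loci <- find_ssrs(unigenes, config$ssr)
      n_mined <- sum(nchar(unigenes) >= config$ssr$min_seq_length)
      artifacts$ssr_loci <- write_tsv_report(
        loci, file.path(out, "ssr_loci.tsv"),
        comments = "coordinates are 0-based half-open")
      summ <- summarize_ssrs(loci, n_mined)
      artifacts$ssr_summary <- write_tsv_report(
        summ$categories, file.path(out, "ssr_category_summary.tsv"),
        comments = c(sprintf("total SSRs: %d in %d mined sequences",
                             summ$total_ssrs, n_mined),
                     "percent_of_total is per mined sequence count"))
      artifacts$ssr_classes <- write_tsv_report(
        summ$classes, file.path(out, "ssr_class_summary.tsv"))
      cand <- primer_candidates(loci, unigenes, config$ssr)
      artifacts$primer_candidates <- write_tsv_report(
        cand, file.path(out, "primer_candidates.tsv"))
      plog(stage, "%d loci in %d mined sequences; %d primer candidates pass",
           nrow(loci), n_mined, sum(cand$pass))

      # ---- qpcr ----------------------------------------------------------
      stage <- "qpcr"
      if (!is.null(sim)) {
        conc_rows <- list()
        for (g in trend_groups(design)) {
          res <- qpcr_validate_group(sim, scfg, g, contig_seqs, report,
                                     config)
          if (is.null(res)) next
          artifacts[[paste0("qpcr_folds_", g)]] <- write_tsv_report(
            res$folds, file.path(out, sprintf("qpcr_folds_%s.tsv", g)))
          conc_rows[[g]] <- data.frame(
            group = g, n_match = res$concordance$n_match,
            n_total = res$concordance$n_total,
            percent = res$concordance$percent, stringsAsFactors = FALSE)
          plog(stage, "%s: %d/%d trends concordant (%d%%)", g,
               res$concordance$n_match, res$concordance$n_total,
               res$concordance$percent)
        }
        if (length(conc_rows)) {
          artifacts$qpcr_concordance <- write_tsv_report(
            do.call(rbind, conc_rows),
            file.path(out, "qpcr_concordance.tsv"))
        }
      } else {
        plog(stage, "skipped (no planted truth without simulation)")
      }

      # ---- report --------------------------------------------------------
      stage <- "report"
      groups <- names(organ_res)
      venn <- list()
      if (length(groups) >= 2) {
        for (i in seq_len(length(groups) - 1)) {
          for (j in (i + 1):length(groups)) {
            cmp <- compare_unigene_sets(
              unigene_sequences(organ_res[[groups[i]]]),
              unigene_sequences(organ_res[[groups[j]]]), config$scoring)
            venn[[length(venn) + 1]] <- data.frame(
              set_a = groups[i], set_b = groups[j], shared = cmp$shared,
              unique_a = cmp$unique_a, unique_b = cmp$unique_b,
              stringsAsFactors = FALSE)
          }
        }
        artifacts$unigene_sharing <- write_tsv_report(
          do.call(rbind, venn), file.path(out, "unigene_sharing.tsv"))
      }
      plog(stage, "pipeline complete; %d artifacts in %s",
           length(artifacts), out)
      invisible(artifacts)
    }, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE)
    })
}

# qPCR validation of one trend-bearing group: simulate CT tables for the
# transcripts behind the group's top contigs and compare observed trends
# with the read-frequency predictions.
qpcr_validate_group <- function(sim, scfg, group, contig_seqs, report,
                                config) {
  design <- config$design
  glibs <- design$library_id[design$group == group]
  rows <- report[report$source_library %in% glibs, , drop = FALSE]
  patt_col <- paste0("pattern_", group)
  if (!nrow(rows) || is.null(rows[[patt_col]])) return(NULL)
  # map contigs to source transcripts by homology (best hit)
  contig_ids <- unique(rows$contig_id)
  hits <- seed_extend_search(contig_seqs[contig_ids], sim$transcripts,
                             config$scoring)
  if (!nrow(hits)) return(NULL)
  hits <- hits[order(hits$query, -hits$score, hits$subject), ]
  best <- hits[!duplicated(hits$query), ]
  map <- setNames(best$subject, best$query)
  rows$gene <- map[rows$contig_id]
  rows <- rows[!is.na(rows$gene) & !duplicated(rows$gene), , drop = FALSE]
  rows <- head(rows, config$qpcr$n_genes)
  if (!nrow(rows)) return(NULL)

  ref_genes <- c("ref1", "ref2")
  tab <- generate_qpcr_table(sim$truth, scfg,
                             n_replicates = config$qpcr$n_replicates,
                             ref_genes = ref_genes, group = group,
                             genes = rows$gene,
                             noise_sd = config$qpcr$noise_sd)
  stages <- design$stage[design$group == group]
  qp <- qpcr_params(baseline = stages[1], ref_genes = ref_genes,
                    stages = stages)
  dct <- global_normalize(tab$ct, qp)
  folds <- ddct_fold(dct, qp)
  observed <- qpcr_trends(folds, qp, config$trend)
  predicted <- data.frame(gene = rows$gene, pattern = rows[[patt_col]],
                          stringsAsFactors = FALSE)
  list(folds = folds,
       concordance = concordance(predicted,
                                 observed[observed$gene %in% rows$gene, ]))
}
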