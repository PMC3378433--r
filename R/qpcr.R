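#' qPCR analysis parameters
#'
#' @param max_ct CT cap in cycles; CT values above it are truncated on
#'   load (40.0 is the conventional no-amplification ceiling).
#' @param baseline Baseline stage set to fold 1 (e.g. the unacclimated bud
#'   time point, or green fruit).
#' @param ref_genes Nonempty character vector of reference (housekeeping)
#'   gene ids used for global normalization.
#' @param stages Stage labels in order.
#' @return List of class `qpcr_params`.
#' @export
qpcr_params <- function(max_ct = 40, baseline, ref_genes, stages) {
  stopifnot(max_ct > 0, length(ref_genes) >= 1, length(stages) >= 2)
  if (!baseline %in% stages) stop("baseline stage not among stages")
  structure(list(max_ct = max_ct, baseline = baseline,
                 ref_genes = ref_genes, stages = stages),
            class = "qpcr_params")
}

#' Load and validate a CT table
#'
#' @param ct `data.frame` with columns `gene`, `stage`, `replicate`, `ct`,
#'   or a path to such a TSV.
#' @param params [qpcr_params()].
#' @return The validated table with CT truncated to `(0, max_ct]`.
#' @export
read_ct_table <- function(ct, params) {
  if (is.character(ct)) ct <- read_tsv_report(ct)
  stopifnot(all(c("gene", "stage", "replicate", "ct") %in% names(ct)))
  if (any(ct$ct <= 0)) stop("CT values must be positive")
  ct$ct <- pmin(ct$ct, params$max_ct)
  ct
}

#' Reference-gene global normalization to delta-CT
#'
#' For each gene and stage, replicates are summarized by their arithmetic
#' mean CT; the per-stage reference level is the mean over reference genes
#' of their mean CT; `dCT(gene, stage) = mean CT(gene, stage) - reference
#' level(stage)`. A per-stage additive CT shift affecting genes and
#' references alike therefore cancels.
#'
#' @param ct CT table ([read_ct_table()] layout).
#' @param params [qpcr_params()].
#' @return `data.frame` `gene`, `stage`, `dct` (reference genes excluded).
#' @export
global_normalize <- function(ct, params) {
  ct <- read_ct_table(ct, params)
  means <- aggregate(ct ~ gene + stage, data = ct, FUN = mean)
  for (st in params$stages) {
    miss <- setdiff(params$ref_genes, means$gene[means$stage == st])
    if (length(miss)) {
      stop("reference gene ", paste(miss, collapse = ", "),
           " missing in stage ", st)
    }
  }
  refs <- means[means$gene %in% params$ref_genes, ]
  ref_level <- tapply(refs$ct, refs$stage, mean)
  genes <- means[!means$gene %in% params$ref_genes, ]
  genes$dct <- genes$ct - as.numeric(ref_level[genes$stage])
  out <- genes[, c("gene", "stage", "dct")]
  out <- out[order(out$gene, match(out$stage, params$stages)), ]
  rownames(out) <- NULL
  out
}

#' Relative expression by the delta-delta-CT method
#'
#' `fold(gene, stage) = 2^-(dCT(gene, stage) - dCT(gene, baseline))`; the
#' baseline stage has fold exactly 1 for every gene.
#'
#' @param dct Output of [global_normalize()].
#' @param params [qpcr_params()].
#' @return `data.frame` `gene`, `stage`, `fold`, stages in design order.
#' @export
ddct_fold <- function(dct, params) {
  if (!params$baseline %in% dct$stage) {
    stop("baseline stage ", params$baseline, " absent from dCT table")
  }
  base <- dct[dct$stage == params$baseline, c("gene", "dct")]
  dct$fold <- 2^(-(dct$dct - base$dct[match(dct$gene, base$gene)]))
  out <- dct[, c("gene", "stage", "fold")]
  out[order(out$gene, match(out$stage, params$stages)), , drop = FALSE]
}

#' Trend calls from qPCR fold profiles
#'
#' Applies the same categorical trend classification used for read
#' frequencies ([classify_trend()]) to each gene's stage-ordered fold
#' profile.
#'
#' @param folds Output of [ddct_fold()].
#' @param params [qpcr_params()] (provides stage order).
#' @param trend [trend_params()].
#' @return `data.frame` `gene`, `pattern`.
#' @export
qpcr_trends <- function(folds, params, trend = trend_params()) {
  genes <- unique(folds$gene)
  pat <- vapply(genes, function(g) {
    f <- folds[folds$gene == g, ]
    classify_trend(f$fold[match(params$stages, f$stage)], trend, pseudo = 0)
  }, character(1))
  data.frame(gene = genes, pattern = unname(pat), stringsAsFactors = FALSE)
}

#' Concordance between predicted and observed trend patterns
#'
#' Exact pattern-equality matching over the same gene set: the strictest
#' formalization of "similar to what was predicted". Percent is rounded to
#' the nearest integer, so 14 matches of 17 reports 82.
#'
#' @param predicted,observed `data.frame`s with `gene` and `pattern`
#'   columns over identical gene sets.
#' @return List with `n_match`, `n_total`, `percent`.
#' @export
concordance <- function(predicted, observed) {
  if (!setequal(predicted$gene, observed$gene) ||
      nrow(predicted) != nrow(observed)) {
    stop("predicted and observed gene sets differ")
  }
  obs <- observed$pattern[match(predicted$gene, observed$gene)]
  n_match <- sum(predicted$pattern == obs)
  n_total <- nrow(predicted)
  list(n_match = n_match, n_total = n_total,
       percent = round(100 * n_match / n_total))
}
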