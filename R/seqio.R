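#' Read a FASTA file into a read table
#'
#' Reads are returned as a plain `data.frame` with one row per record, the
#' unit that flows through QC, assembly and read counting. The optional
#' `library_id` tags every record with its stage-ordered library of origin.
#'
#' @param path Path to a FASTA file.
#' @param library_id Library label attached to every record (single string),
#'   or `NULL` to leave the column `NA`.
#' @return A `data.frame` with columns `id`, `library_id`, `sequence`.
#'   An empty file yields a zero-row table.
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">r1", "ACGT"), tf)
#' read_fasta(tf, library_id = "bud_0")
#' @export
read_fasta <- function(path, library_id = NULL) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  if (file.size(path) == 0) {
    return(data.frame(id = character(), library_id = character(),
                      sequence = character(), stringsAsFactors = FALSE))
  }
  first <- readLines(path, n = 1L)
  if (!startsWith(trimws(first), ">")) {
    stop("malformed FASTA record at line 1 of ", path,
         ": expected '>' header, got: ", substr(first, 1, 40))
  }
  ss <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) stop("duplicate record ids in ", path)
  data.frame(id = ids,
             library_id = if (is.null(library_id)) NA_character_ else library_id,
             sequence = as.character(ss),
             stringsAsFactors = FALSE)
}

#' Write reads or contigs to FASTA
#'
#' @param x A `data.frame` with `id` and `sequence` columns, or a named
#'   character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  if (is.data.frame(x)) {
    seqs <- setNames(x$sequence, x$id)
  } else {
    seqs <- x
  }
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = 80L)
  invisible(path)
}

#' Write a rectangular table as a TSV report
#'
#' Tab-delimited UTF-8 with a header row; optional `# `-prefixed comment
#' lines (used to record classification parameters in report headers) are
#' taken from `comments` or from `attr(table, "header_comments")`.
#'
#' @param table A `data.frame`.
#' @param path Output path.
#' @param comments Optional character vector of comment lines (written as
#'   `# <line>` above the header).
#' @return `path`, invisibly.
#' @export
write_tsv_report <- function(table, path, comments = NULL) {
  stopifnot(is.data.frame(table))
  comments <- comments %||% attr(table, "header_comments")
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(comments) && length(comments)) {
    writeLines(paste0("# ", comments), con)
  }
  write.table(table, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' Read a TSV report written by [write_tsv_report()]
#'
#' @param path Input path.
#' @return A `data.frame`; `# ` comment lines are skipped.
#' @export
read_tsv_report <- function(path) {
  read.delim(path, sep = "\t", comment.char = "#", stringsAsFactors = FALSE)
}
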