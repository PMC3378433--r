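# shared helpers: tiny sequence builders used across the suite

rnd_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rc_dna <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

read_table <- function(seqs, lib = "L", ids = NULL) {
  data.frame(id = ids %||% sprintf("r%03d", seq_along(seqs)),
             library_id = lib, sequence = seqs, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

extdata <- function(f) system.file("extdata", f, package = "est454")
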