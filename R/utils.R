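# Internal helpers shared across modules.

NUC <- c("A", "C", "G", "T")

#' @importFrom Biostrings DNAStringSet reverseComplement
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Encode an upper-case nucleotide string as integers 0..3 (A,C,G,T); ambiguity
# codes become NA.
seq_to_codes <- function(seq) {
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  m <- match(v, NUC) - 1L
  m
}

codes_to_seq <- function(codes) {
  paste(NUC[codes + 1L], collapse = "")
}

# Translate in-frame coding sequences, trimming trailing partial codons and a
# terminal stop. Internal stops are tolerated with a warning: deposited viral
# ORFs occasionally contain them.
translate_cds <- function(cds, ids = names(cds)) {
  cds <- toupper(cds)
  trimmed <- substr(cds, 1L, (nchar(cds) %/% 3L) * 3L)
  aa <- as.character(suppressWarnings(
    Biostrings::translate(Biostrings::DNAStringSet(trimmed),
                          if.fuzzy.codon = "solve")
  ))
  has_term <- substring(aa, nchar(aa)) == "*"
  aa[has_term] <- substr(aa[has_term], 1L, nchar(aa[has_term]) - 1L)
  internal <- grepl("*", aa, fixed = TRUE)
  if (any(internal)) {
    warning(sprintf("internal stop codon(s) in %d coding sequence(s)%s",
                    sum(internal),
                    if (!is.null(ids)) paste0(": ", paste(utils::head(ids[internal], 5), collapse = ", ")) else ""))
  }
  aa
}

# 1-based inclusive (file dialect) <-> 0-based half-open (internal).
to_internal_coords <- function(start1, end1) {
  list(start = start1 - 1L, end = end1)
}

to_file_coords <- function(start0, end0) {
  list(start = start0 + 1L, end = end0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
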