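# Shared low-level helpers: classed conditions, nucleotide/codon utilities.

# All package errors carry a subclass so callers (and tests) can distinguish
# format errors from coordinate or consistency errors without string matching.
svp_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "svp_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Complement nucleotides on the forward strand
#' @param x character vector of nucleotide strings (A/C/G/T/N, either case)
#' @return complemented strings, case preserved
#' @keywords internal
complement_nt <- function(x) chartr("ACGTNacgtn", "TGCANtgcan", x)

#' Reverse-complement nucleotide strings
#' @param x character vector of nucleotide strings
#' @return reverse complement, uppercase input assumed
#' @keywords internal
reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Standard genetic code, keyed by DNA codon. Codons containing N (or any
# non-ACGT base) translate to X; fully ambiguous calls are never guessed.
codon_to_aa <- function(codons) {
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  unname(aa)
}

# Split a nucleotide string into complete codons (dangling 1-2 bases dropped).
split_codons <- function(nt) {
  n <- nchar(nt)
  ncod <- n %/% 3L
  if (ncod == 0L) return(character(0))
  substring(nt, seq(1L, by = 3L, length.out = ncod), seq(3L, by = 3L, length.out = ncod))
}

reverse_string <- function(x) {
  vapply(strsplit(x, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}
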