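# Transcript coordinate machinery: spliced CDS extraction, strand-aware
# genomic <-> CDS <-> protein mapping, and translation.
#
# Coordinate convention: files are 1-based inclusive; everything in this
# module is 0-based half-open. The conversion happens exactly once, here in
# build_transcript(), so there is a single locus of off-by-one risk.

#' Build a transcript model from a raw GTF structure
#'
#' Converts the 1-based inclusive intervals of a [read_gtf_transcripts()]
#' record to 0-based half-open segments sorted by genomic start, and computes
#' the total CDS length.
#'
#' @param raw a `GtfTranscriptRaw` structure
#' @return a `TranscriptModel`: list with `transcript_id`, `gene_name`,
#'   `chrom`, `strand`, `starts`/`ends` (0-based half-open, genomic order)
#'   and `cds_length`
#' @export
build_transcript <- function(raw) {
  starts <- as.integer(raw$starts) - 1L
  ends <- as.integer(raw$ends)
  ord <- order(starts)
  starts <- starts[ord]; ends <- ends[ord]
  if (any(ends <= starts)) {
    svp_error(sprintf("transcript %s: empty or inverted CDS interval",
                      raw$transcript_id), "svp_model_error")
  }
  if (length(starts) > 1L && any(starts[-1] < ends[-length(ends)])) {
    svp_error(sprintf("transcript %s: overlapping CDS intervals",
                      raw$transcript_id), "svp_model_error")
  }
  structure(
    list(transcript_id = raw$transcript_id,
         gene_name = raw$gene_name %||% "",
         chrom = raw$chrom, strand = raw$strand,
         starts = starts, ends = ends,
         cds_length = sum(ends - starts)),
    class = "TranscriptModel")
}

#' @export
print.TranscriptModel <- function(x, ...) {
  cat(sprintf("TranscriptModel %s (%s) %s:%s, %d segment(s), CDS %d nt\n",
              x$transcript_id, x$gene_name, x$chrom, x$strand,
              length(x$starts), x$cds_length))
  invisible(x)
}

.chrom_seq <- function(genome, chrom) {
  i <- match(chrom, genome$id)
  if (is.na(i)) {
    svp_error(sprintf(
      "chromosome '%s' not present in the genome (note: 'chr'-prefix mismatches are not auto-healed)",
      chrom), "svp_lookup_error")
  }
  genome$seq[i]
}

#' Extract the spliced coding sequence of a transcript
#'
#' Concatenates the CDS segments in genomic order; for minus-strand
#' transcripts the concatenation is reverse-complemented, so the result is
#' always 5'->3' in coding (mRNA) orientation.
#'
#' @param tx a `TranscriptModel`
#' @param genome nucleotide records from [read_fasta()]
#' @return a `CodingSequence`: list with `transcript_id`, `nucleotides`, and
#'   `complete_flag` (length divisible by 3)
#' @export
extract_cds <- function(tx, genome) {
  chrom <- .chrom_seq(genome, tx$chrom)
  if (any(tx$starts < 0L) || any(tx$ends > nchar(chrom))) {
    svp_error(sprintf("transcript %s: CDS segment outside chromosome %s (length %d)",
                      tx$transcript_id, tx$chrom, nchar(chrom)),
              "svp_coordinate_error")
  }
  nt <- paste(substring(chrom, tx$starts + 1L, tx$ends), collapse = "")
  if (tx$strand == "-") nt <- reverse_complement(nt)
  structure(
    list(transcript_id = tx$transcript_id, nucleotides = nt,
         complete_flag = nchar(nt) %% 3L == 0L),
    class = "CodingSequence")
}

#' Translate a coding sequence
#'
#' Standard genetic code. Translation stops at the first stop codon; a stop
#' before the final codon sets the `internal_stop` flag (the truncated
#' product is returned). A dangling 1-2 nt trailing codon is dropped and
#' flagged. Any codon containing a base outside A/C/G/T (e.g. N) translates
#' to `X`. Degenerate input produces flags, never an error.
#'
#' @param cds a `CodingSequence` (or a plain nucleotide string)
#' @return list with `protein` (no trailing stop) and logical `flags`:
#'   `incomplete_codon`, `internal_stop`, `missing_stop`, `no_start`
#' @export
translate_cds <- function(cds) {
  nt <- if (inherits(cds, "CodingSequence")) cds$nucleotides else cds
  aa <- codon_to_aa(split_codons(nt))
  ncod <- length(aa)
  flags <- c(incomplete_codon = nchar(nt) %% 3L != 0L,
             internal_stop = FALSE, missing_stop = FALSE, no_start = FALSE)
  stop_at <- which(aa == "*")
  if (length(stop_at) == 0L) {
    flags["missing_stop"] <- TRUE
    prot <- aa
  } else {
    first <- stop_at[1]
    if (first < ncod) flags["internal_stop"] <- TRUE
    prot <- if (first > 1L) aa[seq_len(first - 1L)] else character(0)
  }
  if (length(prot) == 0L || prot[1] != "M") flags["no_start"] <- TRUE
  list(protein = paste(prot, collapse = ""), flags = flags)
}

#' Map a genomic position to its spliced CDS index
#'
#' Strand-aware: on the minus strand, CDS index 0 is the genomic 3'-most
#' coding base. Returns `NA` for intronic or otherwise non-coding positions.
#'
#' @param tx a `TranscriptModel`
#' @param gpos 0-based genomic position
#' @return 0-based index into the spliced coding sequence, or `NA_integer_`
#' @export
genomic_to_cds_index <- function(tx, gpos) {
  seg <- which(gpos >= tx$starts & gpos < tx$ends)
  if (length(seg) == 0L) return(NA_integer_)
  before <- if (seg > 1L) sum(tx$ends[seq_len(seg - 1L)] - tx$starts[seq_len(seg - 1L)]) else 0L
  idx_plus <- before + (gpos - tx$starts[seg])
  if (tx$strand == "-") tx$cds_length - 1L - idx_plus else as.integer(idx_plus)
}

#' Inverse of [genomic_to_cds_index()] for a whole transcript
#'
#' @param tx a `TranscriptModel`
#' @return integer vector of 0-based genomic positions of the coding bases,
#'   ordered by CDS index (i.e. in transcript 5'->3' order)
#' @export
cds_genomic_positions <- function(tx) {
  pos <- unlist(mapply(function(s, e) seq.int(s, e - 1L), tx$starts, tx$ends,
                       SIMPLIFY = FALSE), use.names = FALSE)
  if (tx$strand == "-") rev(pos) else pos
}

#' Convert a CDS index to a protein coordinate
#'
#' @param idx 0-based CDS index (vectorized)
#' @return list with `residue_index` (1-based) and `codon_offset` (0..2)
#' @export
cds_index_to_protein <- function(idx) {
  idx <- as.integer(idx)
  stopifnot(all(idx >= 0L, na.rm = TRUE))
  list(residue_index = idx %/% 3L + 1L, codon_offset = idx %% 3L)
}
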