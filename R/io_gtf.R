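# GTF ingestion via rtracklayer. Only CDS features are consumed: this package
# models coding sequence, not UTRs or exon structure beyond the CDS.

#' Read transcript CDS structures from a GTF file
#'
#' Groups `CDS` feature lines by `transcript_id`. Transcripts without CDS
#' lines are omitted. Strand must be consistent (and stranded) within a
#' transcript. Intervals are returned 1-based inclusive, exactly as printed
#' in the file, sorted by genomic start; conversion to internal 0-based
#' half-open coordinates happens once, in [build_transcript()].
#'
#' @param path path to a GTF file (optionally gzip-compressed); attributes in
#'   `key "value";` form with a `transcript_id` key on every CDS line
#' @return a named list of raw transcript structures, each a list with
#'   `transcript_id`, `gene_name`, `chrom`, `strand`, `starts`, `ends`
#' @export
read_gtf_transcripts <- function(path) {
  if (!file.exists(path)) {
    svp_error(sprintf("GTF file not found: %s", path), "svp_io_error")
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = "gtf"),
    error = function(e) svp_error(
      sprintf("not a readable GTF file (%s): %s", path, conditionMessage(e)),
      "svp_format_error")
  )
  df <- as.data.frame(gr)
  df <- df[df$type == "CDS", , drop = FALSE]
  if (nrow(df) == 0L) return(structure(list(), names = character(0)))
  if (is.null(df$transcript_id) || anyNA(df$transcript_id)) {
    svp_error("CDS line without a transcript_id attribute", "svp_format_error")
  }
  if (is.null(df$gene_name)) df$gene_name <- NA_character_
  if (is.null(df$gene_id)) df$gene_id <- NA_character_

  out <- list()
  for (t in unique(df$transcript_id)) {
    g <- df[df$transcript_id == t, , drop = FALSE]
    chrom <- unique(as.character(g$seqnames))
    if (length(chrom) != 1L) {
      svp_error(sprintf("transcript %s has CDS lines on multiple chromosomes", t),
                "svp_format_error")
    }
    strand <- unique(as.character(g$strand))
    if (length(strand) != 1L || !strand %in% c("+", "-")) {
      svp_error(sprintf("transcript %s has inconsistent or missing strand", t),
                "svp_format_error")
    }
    ord <- order(g$start)
    starts <- as.integer(g$start[ord]); ends <- as.integer(g$end[ord])
    if (length(starts) > 1L && any(starts[-1] <= ends[-length(ends)])) {
      svp_error(sprintf("transcript %s has overlapping CDS intervals", t),
                "svp_format_error")
    }
    gn <- g$gene_name[!is.na(g$gene_name)]
    if (length(gn) == 0L) gn <- g$gene_id[!is.na(g$gene_id)]
    out[[t]] <- structure(
      list(transcript_id = t,
           gene_name = if (length(gn)) gn[1] else "",
           chrom = chrom, strand = strand,
           starts = starts, ends = ends),
      class = "GtfTranscriptRaw")
  }
  out
}

#' Write raw transcript structures to a GTF file
#'
#' One `CDS` line per interval, with `gene_id`, `transcript_id` and
#' `gene_name` attributes. Output is deterministic: transcripts in list
#' order, intervals in genomic order.
#'
#' @param transcripts named list as returned by [read_gtf_transcripts()]
#' @param path output path
#' @return invisibly, `path`
#' @export
write_gtf_transcripts <- function(transcripts, path) {
  lines <- unlist(lapply(transcripts, function(tx) {
    sprintf(
      '%s\tsnv2prot\tCDS\t%d\t%d\t.\t%s\t0\tgene_id "%s"; transcript_id "%s"; gene_name "%s";',
      tx$chrom, tx$starts, tx$ends, tx$strand,
      tx$gene_name, tx$transcript_id, tx$gene_name)
  }), use.names = FALSE)
  writeLines(lines, path)
  invisible(path)
}
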