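# FASTA input/output. Parsing is delegated to Biostrings; this layer enforces
# the package's record contract: first header token = identifier, remainder =
# description, residues uppercased and restricted to the declared alphabet.

.alphabets <- list(
  nucleotide = "ACGTN",
  protein    = "ACDEFGHIKLMNPQRSTVWYX*"
)

#' Read a FASTA file into sequence records
#'
#' Reads plain or gzip-compressed FASTA. Wrapped sequence lines are
#' concatenated, lowercase residues are uppercased, and file order is
#' preserved. The header is split at the first whitespace into an
#' identifier and a (possibly empty) description.
#'
#' @param path path to a FASTA file (optionally `.gz`)
#' @param alphabet `"nucleotide"` (A/C/G/T/N) or `"protein"`
#'   (20 amino-acid letters plus `X` and `*`)
#' @return a `data.frame` with columns `id`, `desc`, `seq`, one row per record
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">s1 demo", "ACGT", "acgt"), fa)
#' read_fasta(fa, "nucleotide")
read_fasta <- function(path, alphabet = c("nucleotide", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) {
    svp_error(sprintf("FASTA file not found: %s", path), "svp_io_error")
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) svp_error(
      sprintf("not a readable FASTA file (%s): %s", path, conditionMessage(e)),
      "svp_format_error")
  )
  if (length(set) == 0L) {
    svp_error(sprintf("empty FASTA file: %s", path), "svp_format_error")
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- toupper(as.character(set))
  if (any(ids == "")) {
    svp_error(sprintf("record %d has an empty identifier", which(ids == "")[1]),
              "svp_format_error")
  }
  if (any(nchar(seqs) == 0L)) {
    svp_error(sprintf("record '%s' has an empty sequence", ids[nchar(seqs) == 0L][1]),
              "svp_format_error")
  }
  bad_re <- sprintf("[^%s]", gsub("\\*", "\\\\*", .alphabets[[alphabet]]))
  bad <- grepl(bad_re, seqs)
  if (any(bad)) {
    .fasta_alphabet_error(path, bad_re, alphabet)
  }
  data.frame(id = unname(ids), desc = unname(desc), seq = unname(seqs),
             stringsAsFactors = FALSE)
}

# Re-scan the raw lines so the error can name a line number.
.fasta_alphabet_error <- function(path, bad_re, alphabet) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  for (i in seq_along(lines)) {
    if (startsWith(lines[i], ">")) next
    if (grepl(bad_re, toupper(lines[i]))) {
      svp_error(sprintf("line %d: character outside the %s alphabet", i, alphabet),
                "svp_format_error")
    }
  }
  svp_error(sprintf("sequence character outside the %s alphabet", alphabet),
            "svp_format_error")
}

#' Write sequence records to FASTA
#'
#' Output is a pure function of the records and wrap width: records in input
#' order, header `>id desc` (description omitted when empty), sequence wrapped
#' at `wrap_width` columns, trailing newline.
#'
#' @param records `data.frame` with columns `id`, `desc`, `seq`
#' @param path output path
#' @param wrap_width line width for the sequence (default 60)
#' @return invisibly, `path`
#' @export
write_fasta <- function(records, path, wrap_width = 60L) {
  stopifnot(is.data.frame(records), all(c("id", "desc", "seq") %in% names(records)))
  if (nrow(records) == 0L) {
    svp_error("refusing to write an empty FASTA file", "svp_io_error")
  }
  headers <- ifelse(records$desc == "", records$id, paste(records$id, records$desc))
  set <- Biostrings::BStringSet(records$seq)
  names(set) <- headers
  Biostrings::writeXStringSet(set, path, width = as.integer(wrap_width))
  invisible(path)
}
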