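# VCF ingestion. vcfR does the parsing; this layer normalizes records to
# single-nucleotide variants and accounts for everything it does not keep.

#' Read single-nucleotide variants from a VCF
#'
#' Keeps only biallelic-normalized SNVs: records whose REF and ALT alleles are
#' single A/C/G/T bases. Multi-allelic records are split into one variant per
#' ALT allele. Indels, MNVs and symbolic alleles are never silently lost: they
#' are counted in the skip report. By default only records with FILTER `PASS`
#' or `.` are kept (the convention of raw GATK output); `keep_filtered = TRUE`
#' retains everything.
#'
#' @param path path to a VCF file (plain, gzip or bgzip)
#' @param keep_filtered keep records whose FILTER is neither `PASS` nor `.`?
#' @return a list with
#'   * `variants`: `data.frame` with columns `chrom`, `pos` (1-based),
#'     `ref`, `alt`, `filter`, `record_index`
#'   * `skipped`: named integer vector with counts for `filtered`, `indel`,
#'     `mnv`, `symbolic`, `other`, and their `total`
#' @export
read_vcf_snvs <- function(path, keep_filtered = FALSE) {
  if (!file.exists(path)) {
    svp_error(sprintf("VCF file not found: %s", path), "svp_io_error")
  }
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) svp_error(
      sprintf("not a readable VCF file (%s): %s", path, conditionMessage(e)),
      "svp_format_error")
  )
  fix <- vcf@fix
  skipped <- c(filtered = 0L, indel = 0L, mnv = 0L, symbolic = 0L, other = 0L)
  out <- list()
  if (nrow(fix) > 0L) {
    pos <- suppressWarnings(as.integer(fix[, "POS"]))
    if (anyNA(pos)) {
      svp_error(sprintf("VCF record %d: POS is not an integer", which(is.na(pos))[1]),
                "svp_format_error")
    }
    ref <- toupper(fix[, "REF"])
    alt_field <- toupper(fix[, "ALT"])
    if (anyNA(ref) || anyNA(alt_field) || any(ref == "") || any(alt_field == "")) {
      bad <- which(is.na(ref) | is.na(alt_field) | ref == "" | alt_field == "")[1]
      svp_error(sprintf("VCF record %d: missing REF or ALT", bad), "svp_format_error")
    }
    filt <- fix[, "FILTER"]
    filt[is.na(filt) | filt == ""] <- "."
    for (i in seq_len(nrow(fix))) {
      alts <- strsplit(alt_field[i], ",", fixed = TRUE)[[1]]
      if (!keep_filtered && !(filt[i] %in% c("PASS", "."))) {
        skipped["filtered"] <- skipped["filtered"] + length(alts)
        next
      }
      for (a in alts) {
        cls <- .classify_allele(ref[i], a)
        if (cls == "snv") {
          out[[length(out) + 1L]] <- list(
            chrom = fix[i, "CHROM"], pos = pos[i], ref = ref[i], alt = a,
            filter = filt[i], record_index = i)
        } else {
          skipped[cls] <- skipped[cls] + 1L
        }
      }
    }
  }
  variants <- if (length(out)) {
    data.frame(
      chrom = vapply(out, `[[`, "", "chrom"),
      pos = vapply(out, `[[`, 0L, "pos"),
      ref = vapply(out, `[[`, "", "ref"),
      alt = vapply(out, `[[`, "", "alt"),
      filter = vapply(out, `[[`, "", "filter"),
      record_index = vapply(out, `[[`, 0L, "record_index"),
      stringsAsFactors = FALSE)
  } else {
    data.frame(chrom = character(0), pos = integer(0), ref = character(0),
               alt = character(0), filter = character(0),
               record_index = integer(0), stringsAsFactors = FALSE)
  }
  skipped <- c(skipped, total = sum(skipped))
  list(variants = variants, skipped = skipped)
}

.classify_allele <- function(ref, alt) {
  if (grepl("[][<>]", alt) || alt == "*") return("symbolic")
  nr <- nchar(ref); na <- nchar(alt)
  if (nr == 1L && na == 1L) {
    if (ref %in% c("A", "C", "G", "T") && alt %in% c("A", "C", "G", "T") && ref != alt) {
      return("snv")
    }
    return("other")  # N alleles, ref==alt and similar oddities
  }
  if (nr == na) return("mnv")
  "indel"
}

#' Write SNVs to a minimal sorted VCF
#'
#' Emits a VCFv4.2 file with the eight mandatory columns and no samples,
#' sorted by chromosome then position. Used by the simulator; output is
#' deterministic for a given variant table.
#'
#' @param variants `data.frame` with columns `chrom`, `pos`, `ref`, `alt`
#' @param path output path
#' @return invisibly, `path`
#' @export
write_snv_vcf <- function(variants, path) {
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(variants)))
  ord <- order(variants$chrom, variants$pos)
  v <- variants[ord, , drop = FALSE]
  lines <- c(
    "##fileformat=VCFv4.2",
    "##source=snv2prot",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.", v$chrom, v$pos, v$ref, v$alt))
  writeLines(lines, path)
  invisible(path)
}
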