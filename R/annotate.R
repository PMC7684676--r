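# Codon-level classification of SNVs against transcript models.
#
# Categories: missense, synonymous, stopgain, stoploss, startloss, noncoding.
# A change inside a stop codon that yields another stop is synonymous. Effects
# are returned as data.frame rows so collections stack naturally.

.effect_categories <- c("missense", "synonymous", "stopgain", "stoploss",
                        "startloss", "noncoding")

#' Format a protein change in HGVS-style shorthand
#'
#' One-letter residue codes, as conventionally printed for hotspot mutations
#' (p.L858R, p.V600E). Synonymous changes render as `p.K2=`; a gained stop
#' uses `*` as the alternate residue (`p.R123*`).
#'
#' @param ref_aa reference residue (one letter, `*` for stop)
#' @param residue_index 1-based protein position
#' @param alt_aa alternate residue
#' @return the notation string
#' @export
#' @examples
#' format_hgvs_p("L", 858, "R")  # "p.L858R"
#' format_hgvs_p("K", 2, "K")    # "p.K2="
format_hgvs_p <- function(ref_aa, residue_index, alt_aa) {
  ifelse(ref_aa == alt_aa,
         sprintf("p.%s%d=", ref_aa, as.integer(residue_index)),
         sprintf("p.%s%d%s", ref_aa, as.integer(residue_index), alt_aa))
}

.effect_row <- function(v, tx_id, gene, category, residue_index = NA_integer_,
                        codon_offset = NA_integer_, ref_codon = NA_character_,
                        alt_codon = NA_character_, ref_aa = NA_character_,
                        alt_aa = NA_character_, hgvs_p = NA_character_) {
  data.frame(chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
             transcript_id = tx_id, gene_name = gene, category = category,
             protein_pos = residue_index, codon_offset = codon_offset,
             ref_codon = ref_codon, alt_codon = alt_codon,
             ref_aa = ref_aa, alt_aa = alt_aa, hgvs_p = hgvs_p,
             stringsAsFactors = FALSE)
}

#' Annotate one SNV against one transcript
#'
#' Maps the variant position into the spliced CDS, rebuilds the affected
#' codon and classifies the consequence of the substitution. VCF alleles are
#' forward-strand; for minus-strand transcripts they are complemented before
#' codon substitution. The genome reference base at the variant position must
#' equal the REF allele — a mismatch raises a consistency error (the classic
#' symptom of annotating against the wrong genome build).
#'
#' @param v one variant: list or one-row data.frame with `chrom`, `pos`
#'   (1-based), `ref`, `alt`
#' @param tx a `TranscriptModel` on the same chromosome
#' @param genome nucleotide records from [read_fasta()]
#' @param cds optional pre-extracted `CodingSequence` for `tx` (a cache;
#'   must match `extract_cds(tx, genome)`)
#' @return a one-row `data.frame` (a `VariantEffect`): variant fields plus
#'   `transcript_id`, `gene_name`, `category`, `protein_pos`, `codon_offset`,
#'   `ref_codon`, `alt_codon`, `ref_aa`, `alt_aa`, `hgvs_p`
#' @export
annotate_variant <- function(v, tx, genome, cds = NULL) {
  gbase <- substr(.chrom_seq(genome, v$chrom), v$pos, v$pos)
  if (gbase != v$ref) {
    svp_error(sprintf(
      "reference allele mismatch at %s:%d (VCF says %s, genome has %s); wrong genome build?",
      v$chrom, v$pos, v$ref, gbase), "svp_consistency_error")
  }
  idx <- genomic_to_cds_index(tx, v$pos - 1L)
  if (is.na(idx)) {
    return(.effect_row(v, tx$transcript_id, tx$gene_name, "noncoding"))
  }
  if (is.null(cds)) cds <- extract_cds(tx, genome)
  pp <- cds_index_to_protein(idx)
  ri <- pp$residue_index; off <- pp$codon_offset
  ref_codon <- substr(cds$nucleotides, 3L * (ri - 1L) + 1L, 3L * ri)
  if (nchar(ref_codon) < 3L) {
    # variant in a dangling incomplete trailing codon: never translated
    return(.effect_row(v, tx$transcript_id, tx$gene_name, "noncoding"))
  }
  alt_nt <- if (tx$strand == "-") complement_nt(v$alt) else v$alt
  alt_codon <- ref_codon
  substr(alt_codon, off + 1L, off + 1L) <- alt_nt
  ref_aa <- codon_to_aa(ref_codon)
  alt_aa <- codon_to_aa(alt_codon)
  category <- if (ref_aa == alt_aa) {
    "synonymous"
  } else if (ri == 1L && ref_aa == "M") {
    "startloss"
  } else if (alt_aa == "*") {
    "stopgain"
  } else if (ref_aa == "*") {
    "stoploss"
  } else {
    "missense"
  }
  .effect_row(v, tx$transcript_id, tx$gene_name, category,
              ri, off, ref_codon, alt_codon, ref_aa, alt_aa,
              format_hgvs_p(ref_aa, ri, alt_aa))
}

#' Annotate all variants against all overlapping transcripts
#'
#' Emits one effect per (variant, overlapping transcript) pair; a variant
#' inside two overlapping transcripts yields two effects. A variant that
#' overlaps no transcript span yields a single `noncoding` effect with an
#' `NA` transcript. Reference-allele mismatches either abort (`"error"`,
#' default) or are counted and skipped (`"skip"`, used by the database
#' builder so one bad record cannot sink a build).
#'
#' @param variants variant `data.frame` from [read_vcf_snvs()]
#' @param transcripts list of `TranscriptModel`s
#' @param genome nucleotide records from [read_fasta()]
#' @param on_ref_mismatch `"error"` or `"skip"`
#' @return list with `effects` (stacked `VariantEffect` rows), `summary`
#'   (named counts over all six categories), and `n_ref_mismatch`
#' @export
annotate_all <- function(variants, transcripts, genome,
                         on_ref_mismatch = c("error", "skip")) {
  on_ref_mismatch <- match.arg(on_ref_mismatch)
  spans <- if (length(transcripts)) {
    data.frame(
      chrom = vapply(transcripts, `[[`, "", "chrom"),
      start = vapply(transcripts, function(t) min(t$starts), 0L),
      end = vapply(transcripts, function(t) max(t$ends), 0L),
      stringsAsFactors = FALSE)
  } else {
    data.frame(chrom = character(0), start = integer(0), end = integer(0))
  }
  cds_cache <- new.env(parent = emptyenv())
  rows <- vector("list", 0L)
  n_mismatch <- 0L
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    hit <- which(spans$chrom == v$chrom & v$pos - 1L >= spans$start &
                   v$pos - 1L < spans$end)
    res <- tryCatch({
      if (length(hit) == 0L) {
        # still validate the REF allele against the genome
        gbase <- substr(.chrom_seq(genome, v$chrom), v$pos, v$pos)
        if (gbase != v$ref) {
          svp_error(sprintf(
            "reference allele mismatch at %s:%d (VCF says %s, genome has %s)",
            v$chrom, v$pos, v$ref, gbase), "svp_consistency_error")
        }
        list(.effect_row(v, NA_character_, NA_character_, "noncoding"))
      } else {
        lapply(hit, function(j) {
          tx <- transcripts[[j]]
          key <- tx$transcript_id
          if (is.null(cds_cache[[key]])) {
            cds_cache[[key]] <- extract_cds(tx, genome)
          }
          annotate_variant(v, tx, genome, cds = cds_cache[[key]])
        })
      }
    }, svp_consistency_error = function(e) {
      if (on_ref_mismatch == "error") stop(e)
      NULL
    })
    if (is.null(res)) {
      n_mismatch <- n_mismatch + 1L
    } else {
      rows <- c(rows, res)
    }
  }
  effects <- if (length(rows)) {
    do.call(rbind, rows)
  } else {
    .effect_row(list(chrom = "x", pos = 1L, ref = "A", alt = "C"),
                NA_character_, NA_character_, "noncoding")[0, ]
  }
  rownames(effects) <- NULL
  smry <- vapply(.effect_categories, function(k) sum(effects$category == k), 0L)
  list(effects = effects, summary = smry, n_ref_mismatch = n_mismatch)
}
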