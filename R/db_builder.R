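# Variant protein database construction: translate the reference transcripts,
# substitute one amino acid per missense effect, emit a deterministic protein
# FASTA (reference section then variant section), plus reversed decoys.

#' Substitute one residue in a protein sequence
#'
#' The residue currently at `protein_pos` must equal `ref_aa`; a mismatch
#' signals that annotation and protein sequence have drifted apart and raises
#' a substitution error rather than corrupting the entry.
#'
#' @param protein protein sequence (character scalar)
#' @param protein_pos 1-based residue position
#' @param ref_aa expected reference residue
#' @param alt_aa replacement residue
#' @return the protein with exactly that one residue replaced
#' @export
apply_substitution <- function(protein, protein_pos, ref_aa, alt_aa) {
  protein_pos <- as.integer(protein_pos)
  if (protein_pos < 1L || protein_pos > nchar(protein)) {
    svp_error(sprintf("substitution position %d outside protein of length %d",
                      protein_pos, nchar(protein)), "svp_substitution_error")
  }
  have <- substr(protein, protein_pos, protein_pos)
  if (have != ref_aa) {
    svp_error(sprintf(
      "substitution mismatch at position %d: annotation expects %s, protein has %s",
      protein_pos, ref_aa, have), "svp_substitution_error")
  }
  substr(protein, protein_pos, protein_pos) <- alt_aa
  protein
}

#' Options for [build_database()]
#'
#' @param include_stopgain emit stopgain effects as stop-truncated proteins?
#'   Off by default: the database incorporates missense (non-synonymous)
#'   changes; truncated proteoforms are an opt-in.
#' @param include_reference include the reference protein section?
#' @param keep_filtered passed to the VCF reader by the CLI; recorded here so
#'   the resolved plan is complete
#' @param protein_fasta optional protein records ([read_fasta()]) used to
#'   cross-validate genome translations
#' @param id_map optional `data.frame` with columns `transcript_id`,
#'   `protein_id` mapping transcripts into `protein_fasta`
#' @return a list of resolved options
#' @export
db_options <- function(include_stopgain = FALSE, include_reference = TRUE,
                       keep_filtered = FALSE, protein_fasta = NULL,
                       id_map = NULL) {
  if (!is.null(protein_fasta) && is.null(id_map)) {
    svp_error("protein_fasta given without an id_map", "svp_config_error")
  }
  list(include_stopgain = include_stopgain,
       include_reference = include_reference,
       keep_filtered = keep_filtered,
       protein_fasta = protein_fasta, id_map = id_map)
}

#' Build the customized variant protein database
#'
#' Translates every transcript, annotates all variants, and emits one variant
#' protein entry per distinct (transcript, protein change) missense effect —
#' a reference protein with exactly one residue substituted. Synonymous and
#' noncoding effects are never emitted; stopgain effects are excluded unless
#' `options$include_stopgain` (then emitted as stop-truncated proteins). The
#' same protein change reached from different genomic variants is emitted
#' once, with all provenance concatenated in the header. Each transcript
#' contributes one entry per variant: multiple variants on a transcript yield
#' multiple single-substitution entries, never a combined haplotype.
#'
#' @param genome nucleotide records from [read_fasta()]
#' @param transcripts list of `TranscriptModel`s (see [build_transcript()])
#' @param variants variant table from [read_vcf_snvs()] (`$variants`)
#' @param options see [db_options()]
#' @param vcf_skipped optional skip report from [read_vcf_snvs()], folded
#'   into the build report
#' @return list with `reference` (data.frame `id`, `gene_name`, `seq`),
#'   `variants` (data.frame of variant entries with provenance columns),
#'   and `report` (a `BuildReport`)
#' @export
build_database <- function(genome, transcripts, variants,
                           options = db_options(), vcf_skipped = NULL) {
  if (length(transcripts) == 0L) {
    svp_error("no transcripts to translate", "svp_build_error")
  }
  ref <- .translate_reference(genome, transcripts)
  if (nrow(ref$table) == 0L) {
    svp_error("zero translatable transcripts", "svp_build_error")
  }
  n_protein_mismatch <- 0L
  if (!is.null(options$protein_fasta)) {
    val <- .validate_against_proteins(ref$table, options$protein_fasta, options$id_map)
    ref$table <- val$table
    n_protein_mismatch <- val$n_mismatch
    if (nrow(ref$table) == 0L) {
      svp_error("all transcripts failed protein cross-validation", "svp_build_error")
    }
  }

  ann <- annotate_all(variants, transcripts, genome, on_ref_mismatch = "skip")
  eff <- ann$effects
  keep_cat <- c("missense", if (isTRUE(options$include_stopgain)) "stopgain")
  inc <- eff[eff$category %in% keep_cat & eff$transcript_id %in% ref$table$transcript_id, ,
             drop = FALSE]
  n_excluded_tx <- sum(eff$category %in% keep_cat) - nrow(inc)

  entries <- .substitute_entries(inc, ref$table)
  ref_out <- ref$table[order(ref$table$transcript_id), , drop = FALSE]
  rownames(ref_out) <- NULL

  report <- structure(list(
    category_counts = ann$summary,
    n_effects = nrow(eff),
    n_reference = nrow(ref_out),
    n_variant = nrow(entries$table),
    n_dedup_merged = entries$n_merged,
    skipped = c(
      ref_mismatch = ann$n_ref_mismatch,
      flagged_transcript = ref$n_flagged,
      protein_mismatch = n_protein_mismatch,
      substitution_mismatch = entries$n_failed,
      effect_on_dropped_transcript = n_excluded_tx,
      if (!is.null(vcf_skipped)) vcf_skipped[names(vcf_skipped) != "total"]),
    flagged_transcripts = ref$flagged
  ), class = "BuildReport")

  list(reference = ref_out, variants = entries$table, report = report)
}

# Translate every transcript; keep those with a non-empty product. Transcripts
# whose translation is degenerate (no ATG start, internal stop, incomplete
# trailing codon) are kept but flagged so the report makes them visible.
.translate_reference <- function(genome, transcripts) {
  rows <- lapply(transcripts, function(tx) {
    tr <- translate_cds(extract_cds(tx, genome))
    data.frame(transcript_id = tx$transcript_id, gene_name = tx$gene_name,
               seq = tr$protein, flagged = any(tr$flags),
               flags = paste(names(tr$flags)[tr$flags], collapse = ","),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  drop <- nchar(tab$seq) == 0L
  flagged <- tab$transcript_id[tab$flagged | drop]
  tab <- tab[!drop, c("transcript_id", "gene_name", "seq")]
  list(table = tab, n_flagged = length(flagged), flagged = flagged)
}

.validate_against_proteins <- function(tab, protein_fasta, id_map) {
  stopifnot(all(c("transcript_id", "protein_id") %in% names(id_map)))
  pid <- id_map$protein_id[match(tab$transcript_id, id_map$transcript_id)]
  provided <- protein_fasta$seq[match(pid, protein_fasta$id)]
  mism <- !is.na(provided) & provided != tab$seq
  mism <- mism | is.na(provided) & !is.na(pid)  # mapped but absent: treat as mismatch
  list(table = tab[!mism, , drop = FALSE], n_mismatch = sum(mism))
}

# One entry per distinct (transcript_id, hgvs_p); genomic provenance of merged
# duplicates joined with ";" in file order.
.substitute_entries <- function(eff, ref_table) {
  if (nrow(eff) == 0L) {
    return(list(table = .empty_entry_table(), n_merged = 0L, n_failed = 0L))
  }
  key <- paste(eff$transcript_id, eff$hgvs_p, sep = "\r")
  n_merged <- nrow(eff) - length(unique(key))
  rows <- list(); n_failed <- 0L
  for (k in unique(key)) {
    g <- eff[key == k, , drop = FALSE]
    e <- g[1, ]
    base <- ref_table[match(e$transcript_id, ref_table$transcript_id), ]
    res <- tryCatch({
      if (e$category == "stopgain") {
        if (e$protein_pos <= 1L || e$protein_pos > nchar(base$seq) + 1L) {
          svp_error("stop gained at or before the first residue", "svp_substitution_error")
        }
        # truncation at the gained stop; a stop in the natural stop codon
        # position leaves the protein unchanged and is skipped
        if (e$protein_pos > nchar(base$seq)) {
          svp_error("stop gained in the natural stop codon", "svp_substitution_error")
        }
        substr(base$seq, 1L, e$protein_pos - 1L)
      } else {
        apply_substitution(base$seq, e$protein_pos, e$ref_aa, e$alt_aa)
      }
    }, svp_substitution_error = function(err) NULL)
    if (is.null(res)) { n_failed <- n_failed + 1L; next }
    rows[[length(rows) + 1L]] <- data.frame(
      base_id = e$transcript_id, hgvs_p = e$hgvs_p, gene_name = e$gene_name,
      category = e$category,
      var = paste(sprintf("%s:%d%s>%s", g$chrom, g$pos, g$ref, g$alt), collapse = ";"),
      seq = res, stringsAsFactors = FALSE)
  }
  tab <- if (length(rows)) do.call(rbind, rows) else .empty_entry_table()
  tab <- tab[order(tab$base_id, tab$hgvs_p), , drop = FALSE]
  rownames(tab) <- NULL
  list(table = tab, n_merged = n_merged, n_failed = n_failed)
}

.empty_entry_table <- function() {
  data.frame(base_id = character(0), hgvs_p = character(0),
             gene_name = character(0), category = character(0),
             var = character(0), seq = character(0), stringsAsFactors = FALSE)
}

#' Format the FASTA header of a variant database entry
#'
#' Variant entries: `{base_id}|{hgvs_p} gene={gene} var={chrom}:{pos}{ref}>{alt}
#' class={category}` (multiple provenance records joined with `;`).
#' Reference entries: `{id} gene={gene}`.
#'
#' @param entry one row of the variant entry table of [build_database()]
#' @return header string (without the leading `>`)
#' @export
make_header <- function(entry) {
  sprintf("%s|%s gene=%s var=%s class=%s",
          entry$base_id, entry$hgvs_p, entry$gene_name, entry$var, entry$category)
}

#' @rdname make_header
#' @param id,gene_name reference entry fields
#' @export
make_reference_header <- function(id, gene_name) {
  sprintf("%s gene=%s", id, gene_name)
}

#' Parse a database FASTA header back into its fields
#'
#' Inverse of [make_header()] / [make_reference_header()]. Decoy headers
#' (`rev_` prefix) are recognized and flagged.
#'
#' @param header header string without the leading `>`
#' @return list with `base_id`, `hgvs_p` (NA for reference entries),
#'   `gene_name`, `var`, `category`, `is_decoy`
#' @export
parse_db_header <- function(header) {
  is_decoy <- startsWith(header, "rev_")
  h <- sub("^rev_", "", header)
  id_tok <- sub("\\s.*$", "", h)
  rest <- ifelse(grepl("\\s", h), sub("^\\S+\\s+", "", h), "")
  grab <- function(key) {
    m <- regmatches(rest, regexec(sprintf("%s=(\\S*)", key), rest))[[1]]
    if (length(m) == 2L) m[2] else NA_character_
  }
  if (grepl("|", id_tok, fixed = TRUE)) {
    parts <- strsplit(id_tok, "|", fixed = TRUE)[[1]]
    list(base_id = parts[1], hgvs_p = parts[2], gene_name = grab("gene"),
         var = grab("var"), category = grab("class"), is_decoy = is_decoy)
  } else {
    list(base_id = id_tok, hgvs_p = NA_character_, gene_name = grab("gene"),
         var = NA_character_, category = NA_character_, is_decoy = is_decoy)
  }
}

#' Generate reversed decoy entries
#'
#' One decoy per target: residues reversed, identifier prefixed `rev_`.
#' Applying the generator twice restores every target sequence.
#'
#' @param records sequence records (`data.frame` with `id`, `desc`, `seq`)
#' @param mode decoy construction mode; only `"reverse"` is implemented
#' @return records of the same shape holding the decoys
#' @export
generate_decoy <- function(records, mode = c("reverse")) {
  mode <- match.arg(mode)
  data.frame(id = paste0("rev_", records$id), desc = records$desc,
             seq = reverse_string(records$seq), stringsAsFactors = FALSE)
}

#' Assemble a database build into writable FASTA records
#'
#' Reference section first (sorted by identifier), then variant entries
#' (sorted by identifier), then — when `decoy` — one reversed decoy per
#' target in the same order.
#'
#' @param db result of [build_database()]
#' @param decoy append reversed decoys?
#' @param include_reference include the reference section? (defaults to the
#'   build's option; pass `FALSE` for a variants-only database)
#' @return sequence records ready for [write_fasta()]
#' @export
database_records <- function(db, decoy = FALSE, include_reference = TRUE) {
  recs <- list()
  if (include_reference) {
    recs$ref <- data.frame(
      id = db$reference$transcript_id,
      desc = sprintf("gene=%s", db$reference$gene_name),
      seq = db$reference$seq, stringsAsFactors = FALSE)
  }
  if (nrow(db$variants) > 0L) {
    hdr <- vapply(seq_len(nrow(db$variants)),
                  function(i) make_header(db$variants[i, ]), character(1))
    recs$var <- data.frame(
      id = paste(db$variants$base_id, db$variants$hgvs_p, sep = "|"),
      desc = sub("^\\S+\\s+", "", hdr),
      seq = db$variants$seq, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, unname(recs))
  if (is.null(out)) {
    svp_error("database has no entries to write", "svp_build_error")
  }
  if (decoy) out <- rbind(out, generate_decoy(out))
  rownames(out) <- NULL
  out
}

#' @export
print.BuildReport <- function(x, ...) {
  cat("Variant protein database build report\n")
  cat(sprintf("  reference entries : %d\n", x$n_reference))
  cat(sprintf("  variant entries   : %d\n", x$n_variant))
  cat("  effects by category:\n")
  for (k in names(x$category_counts)) {
    cat(sprintf("    %-11s %d\n", k, x$category_counts[[k]]))
  }
  cat(sprintf("  deduplicated (merged) effects: %d\n", x$n_dedup_merged))
  cat("  skipped:\n")
  for (k in names(x$skipped)) {
    cat(sprintf("    %-22s %d\n", k, x$skipped[[k]]))
  }
  invisible(x)
}

#' Render a build report as a two-column table
#'
#' @param report a `BuildReport`
#' @return `data.frame` with columns `field`, `count`
#' @export
report_table <- function(report) {
  data.frame(
    field = c("reference_entries", "variant_entries",
              paste0("effects_", names(report$category_counts)),
              "dedup_merged",
              paste0("skipped_", names(report$skipped))),
    count = c(report$n_reference, report$n_variant,
              unname(report$category_counts), report$n_dedup_merged,
              unname(report$skipped)),
    stringsAsFactors = FALSE)
}
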