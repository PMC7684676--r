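# In-silico proteolysis (trypsin + LysC), variant peptide enumeration and
# pairing with wild-type counterparts.

#' Digestion parameters
#'
#' Defaults mirror common proteogenomic search settings: trypsin and LysC
#' together, at most one missed cleavage, minimum peptide length seven, no
#' maximum. `kp_cut` controls whether K followed by P is cleaved when LysC
#' is active (LysC, unlike trypsin, cleaves K-P bonds).
#'
#' @param enzymes subset of `c("trypsin", "lysc")`
#' @param max_missed_cleavages maximum internal cut sites per peptide
#' @param min_length minimum peptide length (residues)
#' @param max_length maximum peptide length, or `NULL` for none
#' @param kp_cut does LysC cleave K-P bonds?
#' @return a validated parameter list
#' @export
digest_params <- function(enzymes = c("trypsin", "lysc"),
                          max_missed_cleavages = 1L, min_length = 7L,
                          max_length = NULL, kp_cut = TRUE) {
  enzymes <- match.arg(enzymes, c("trypsin", "lysc"), several.ok = TRUE)
  if (max_missed_cleavages < 0L) {
    svp_error("max_missed_cleavages must be >= 0", "svp_config_error")
  }
  if (min_length < 1L) svp_error("min_length must be >= 1", "svp_config_error")
  list(enzymes = enzymes,
       max_missed_cleavages = as.integer(max_missed_cleavages),
       min_length = as.integer(min_length),
       max_length = if (!is.null(max_length)) as.integer(max_length),
       kp_cut = isTRUE(kp_cut))
}

#' Enumerate proteolytic cleavage sites
#'
#' Returns after-residue cut positions, strictly increasing; the protein
#' C-terminus is never listed. Trypsin cuts after K and R except before
#' proline; LysC cuts after K, including before proline (unless `kp_cut`
#' is disabled). With both enzymes active the union applies, so every K is
#' a site and R is a site except before P.
#'
#' @param residues protein sequence
#' @param enzymes subset of `c("trypsin", "lysc")`
#' @param kp_cut does LysC cleave K-P bonds?
#' @return integer vector of cut positions (cut is after the given residue)
#' @export
cleavage_sites <- function(residues, enzymes = c("trypsin", "lysc"),
                           kp_cut = TRUE) {
  n <- nchar(residues)
  if (n < 2L) return(integer(0))
  ch <- strsplit(residues, "", fixed = TRUE)[[1]]
  here <- ch[-n]; nxt <- ch[-1]
  cut <- rep(FALSE, n - 1L)
  if ("trypsin" %in% enzymes) {
    cut <- cut | (here %in% c("K", "R") & nxt != "P")
  }
  if ("lysc" %in% enzymes) {
    cut <- cut | (here == "K" & (kp_cut | nxt != "P"))
  }
  which(cut)
}

#' Digest a protein into peptides
#'
#' Peptides are every stretch between cut positions (or protein termini)
#' spanning at most `max_missed_cleavages` internal sites, filtered by
#' length. The zero-missed-cleavage peptides, before length filtering,
#' partition the protein exactly.
#'
#' @param protein protein sequence
#' @param params see [digest_params()]
#' @param parent_id identifier recorded on each peptide
#' @return `data.frame` with columns `parent_id`, `residues`, `start`, `end`
#'   (1-based inclusive in the parent), `missed_cleavages`, `has_x`
#'   (contains an X residue)
#' @export
digest <- function(protein, params = digest_params(), parent_id = "") {
  n <- nchar(protein)
  cuts <- cleavage_sites(protein, params$enzymes, params$kp_cut)
  b <- c(0L, cuts, n)  # fragment boundaries
  m <- length(b) - 1L  # number of 0-missed fragments
  starts <- integer(0); ends <- integer(0); missed <- integer(0)
  for (i in seq_len(m)) {
    jmax <- min(i + params$max_missed_cleavages, m)
    for (j in i:jmax) {
      starts <- c(starts, b[i] + 1L)
      ends <- c(ends, b[j + 1L])
      missed <- c(missed, j - i)
    }
  }
  len <- ends - starts + 1L
  keep <- len >= params$min_length
  if (!is.null(params$max_length)) keep <- keep & len <= params$max_length
  starts <- starts[keep]; ends <- ends[keep]; missed <- missed[keep]
  res <- if (length(starts)) substring(protein, starts, ends) else character(0)
  data.frame(parent_id = rep(parent_id, length(res)), residues = res,
             start = starts, end = ends, missed_cleavages = missed,
             has_x = grepl("X", res, fixed = TRUE),
             stringsAsFactors = FALSE)
}

#' Enumerate variant peptides and their wild-type pairs
#'
#' A variant peptide is a peptide of the variant protein that covers the
#' substituted residue and whose sequence is absent from the reference
#' digest. Each is paired with wild-type peptide(s) from the reference
#' protein: the peptide with the identical coordinate span when one exists,
#' otherwise all reference peptides overlapping the variant peptide's span
#' (the situation when the substitution creates or destroys a cleavage
#' site). Pairing is done against the unfiltered reference digest so that
#' short wild-type counterparts are still reported.
#'
#' @param reference_protein the wild-type sequence
#' @param variant_protein the variant sequence (same length, Hamming
#'   distance 1); alternatively a variant entry row with a `seq` column
#' @param params see [digest_params()]
#' @param parent_id identifier recorded on each peptide
#' @return `data.frame` with columns `parent_id`, `residues`, `start`,
#'   `end`, `missed_cleavages`, `variant_offset` (position of the
#'   substituted residue within the peptide) and `paired_wildtype`
#'   (`;`-joined wild-type peptide sequences). The attribute
#'   `all_filtered` is `TRUE` when peptides covering the substitution
#'   existed but were all removed by the length filter.
#' @export
variant_peptides <- function(reference_protein, variant_protein,
                             params = digest_params(), parent_id = "") {
  if (is.data.frame(variant_protein)) variant_protein <- variant_protein$seq
  if (nchar(reference_protein) != nchar(variant_protein)) {
    svp_error("variant and reference proteins differ in length",
              "svp_consistency_error")
  }
  diffs <- which(strsplit(reference_protein, "")[[1]] !=
                   strsplit(variant_protein, "")[[1]])
  if (length(diffs) != 1L) {
    svp_error(sprintf("expected exactly one substituted residue, found %d",
                      length(diffs)), "svp_consistency_error")
  }
  vpos <- diffs[1]
  ref_dig <- digest(reference_protein, params, parent_id)
  # unfiltered reference digest: pairing must see counterparts shorter than
  # min_length, and the novelty check must not mistake a short reference
  # peptide's absence for novelty
  params_all <- params; params_all$min_length <- 1L; params_all$max_length <- NULL
  ref_all <- digest(reference_protein, params_all, parent_id)
  var_dig <- digest(variant_protein, params, parent_id)

  cand <- var_dig[var_dig$start <= vpos & var_dig$end >= vpos &
                    !(var_dig$residues %in% ref_all$residues), , drop = FALSE]
  var_all <- digest(variant_protein, params_all, parent_id)
  had_coverage <- any(var_all$start <= vpos & var_all$end >= vpos &
                        !(var_all$residues %in% ref_all$residues))

  pair <- character(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    same <- ref_all$start == cand$start[i] & ref_all$end == cand$end[i]
    wt <- if (any(same)) {
      ref_all[same, , drop = FALSE]
    } else {
      ref_all[ref_all$start <= cand$end[i] & ref_all$end >= cand$start[i] &
                ref_all$missed_cleavages == 0L, , drop = FALSE]
    }
    pair[i] <- paste(unique(wt$residues), collapse = ";")
  }
  out <- cand[, c("parent_id", "residues", "start", "end", "missed_cleavages")]
  out$variant_offset <- vpos - out$start + 1L
  out$paired_wildtype <- pair
  rownames(out) <- NULL
  attr(out, "all_filtered") <- nrow(out) == 0L && had_coverage
  out
}

#' Digest a variant protein database into a variant peptide table
#'
#' Recognizes variant entries by the header grammar of the database builder
#' (`base|p.X#Y gene=... var=... class=...`), locates each entry's base
#' reference protein in the same record set, and enumerates variant/wild-type
#' peptide pairs. Decoy entries are ignored.
#'
#' @param records database records (e.g. [read_fasta()] of a built database)
#' @param params see [digest_params()]
#' @return `data.frame`: `parent_id`, `hgvs_p`, plus the columns of
#'   [variant_peptides()]
#' @export
digest_variant_db <- function(records, params = digest_params()) {
  headers <- ifelse(records$desc == "", records$id,
                    paste(records$id, records$desc))
  parsed <- lapply(headers, parse_db_header)
  is_var <- vapply(parsed, function(p) !is.na(p$hgvs_p) && !p$is_decoy, TRUE)
  is_ref <- vapply(parsed, function(p) is.na(p$hgvs_p) && !p$is_decoy, TRUE)
  ref_ids <- vapply(parsed[is_ref], `[[`, "", "base_id")
  ref_seqs <- records$seq[is_ref]
  rows <- list()
  for (i in which(is_var)) {
    p <- parsed[[i]]
    j <- match(p$base_id, ref_ids)
    if (is.na(j)) {
      svp_error(sprintf("variant entry %s|%s has no reference entry in the database",
                        p$base_id, p$hgvs_p), "svp_lookup_error")
    }
    vp <- variant_peptides(ref_seqs[j], records$seq[i], params,
                           parent_id = p$base_id)
    if (nrow(vp) > 0L) {
      vp <- cbind(vp[, "parent_id", drop = FALSE],
                  hgvs_p = p$hgvs_p,
                  vp[, setdiff(names(vp), "parent_id")])
      rows[[length(rows) + 1L]] <- vp
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(parent_id = character(0), hgvs_p = character(0),
               residues = character(0), start = integer(0), end = integer(0),
               missed_cleavages = integer(0), variant_offset = integer(0),
               paired_wildtype = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Export a variant/wild-type peptide table as TSV
#'
#' Fixed column order: `serial`, `parent_id`, `hgvs_p`, `variant_peptide`,
#' `start`, `end`, `missed_cleavages`, `paired_wildtype_peptides`.
#'
#' @param pairs table from [digest_variant_db()]
#' @param path output path
#' @return invisibly, `path`
#' @export
export_peptide_table <- function(pairs, path) {
  out <- data.frame(
    serial = seq_len(nrow(pairs)),
    parent_id = pairs$parent_id,
    hgvs_p = if (nrow(pairs)) pairs$hgvs_p else character(0),
    variant_peptide = pairs$residues,
    start = pairs$start, end = pairs$end,
    missed_cleavages = pairs$missed_cleavages,
    paired_wildtype_peptides = pairs$paired_wildtype,
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
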