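# Independent oracles used to cross-check the implementation. These are
# deliberately written with different primitives than the package code:
# character-vector arithmetic, per-residue scans and whole-CDS re-translation.

oracle_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]), collapse = "")
}

oracle_codon_aa <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa)) "X" else aa
}

# Spliced CDS extraction by explicit per-segment substring, 0-based half-open
# model coordinates taken as data.
oracle_extract <- function(tx, chrom_seq) {
  pieces <- character(length(tx$starts))
  for (k in seq_along(tx$starts)) {
    pieces[k] <- substr(chrom_seq, tx$starts[k] + 1L, tx$ends[k])
  }
  nt <- paste(pieces, collapse = "")
  if (tx$strand == "-") oracle_revcomp(nt) else nt
}

oracle_translate_full <- function(nt) {
  ncod <- nchar(nt) %/% 3L
  vapply(seq_len(ncod), function(k)
    oracle_codon_aa(substr(nt, 3L * k - 2L, 3L * k)), character(1))
}

# Whole-CDS re-translation oracle: mutate the chromosome, re-extract and
# re-translate the entire CDS, and diff the two amino-acid sequences.
oracle_annotate <- function(v, tx, chrom_seq) {
  in_cds <- FALSE
  for (k in seq_along(tx$starts)) {
    if (v$pos - 1L >= tx$starts[k] && v$pos - 1L < tx$ends[k]) in_cds <- TRUE
  }
  if (!in_cds) return(list(category = "noncoding", residue_index = NA_integer_,
                           ref_aa = NA_character_, alt_aa = NA_character_))
  mutated <- chrom_seq
  substr(mutated, v$pos, v$pos) <- v$alt
  aa_ref <- oracle_translate_full(oracle_extract(tx, chrom_seq))
  aa_alt <- oracle_translate_full(oracle_extract(tx, mutated))
  d <- which(aa_ref != aa_alt)
  if (length(d) == 0L) {
    # synonymous: locate the changed codon from the changed nucleotide
    nt_ref <- oracle_extract(tx, chrom_seq)
    nt_alt <- oracle_extract(tx, mutated)
    p <- which(strsplit(nt_ref, "")[[1]] != strsplit(nt_alt, "")[[1]])[1]
    if (is.na(p) || (p - 1L) %/% 3L + 1L > length(aa_ref)) {
      return(list(category = "noncoding", residue_index = NA_integer_,
                  ref_aa = NA_character_, alt_aa = NA_character_))
    }
    r <- (p - 1L) %/% 3L + 1L
    return(list(category = "synonymous", residue_index = r,
                ref_aa = aa_ref[r], alt_aa = aa_ref[r]))
  }
  r <- d[1]
  ref <- aa_ref[r]; alt <- aa_alt[r]
  cat_ <- if (r == 1L && ref == "M" && alt != "M") "startloss"
  else if (alt == "*") "stopgain"
  else if (ref == "*") "stoploss"
  else "missense"
  list(category = cat_, residue_index = r, ref_aa = ref, alt_aa = alt)
}

# Per-residue cleavage-rule scan (trypsin + LysC defaults).
oracle_cut_after <- function(ch, i, enzymes = c("trypsin", "lysc"), kp_cut = TRUE) {
  if (i >= length(ch)) return(FALSE)
  cut <- FALSE
  if ("trypsin" %in% enzymes && ch[i] %in% c("K", "R") && ch[i + 1] != "P") cut <- TRUE
  if ("lysc" %in% enzymes && ch[i] == "K" && (kp_cut || ch[i + 1] != "P")) cut <- TRUE
  cut
}

# Exhaustive substring oracle: every (i, j) pair checked against boundary,
# missed-cleavage and length rules.
oracle_digest <- function(protein, max_missed = 1L, min_len = 7L,
                          max_len = NULL, enzymes = c("trypsin", "lysc"),
                          kp_cut = TRUE) {
  n <- nchar(protein)
  ch <- strsplit(protein, "")[[1]]
  is_cut <- vapply(seq_len(n), function(i)
    oracle_cut_after(ch, i, enzymes, kp_cut), logical(1))
  cum <- cumsum(is_cut)
  out <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      len <- j - i + 1L
      if (len < min_len) next
      if (!is.null(max_len) && len > max_len) next
      start_ok <- i == 1L || is_cut[i - 1L]
      end_ok <- j == n || is_cut[j]
      if (!start_ok || !end_ok) next
      internal <- cum[j - 1L] - (if (i > 1L) cum[i - 1L] else 0L)
      if (j == i) internal <- 0L
      if (internal > max_missed) next
      out[[length(out) + 1L]] <- c(i, j, internal)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      missed_cleavages = integer(0), residues = character(0)))
  }
  m <- do.call(rbind, out)
  data.frame(start = m[, 1], end = m[, 2], missed_cleavages = m[, 3],
             residues = substring(protein, m[, 1], m[, 2]),
             stringsAsFactors = FALSE)
}

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

random_protein <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

# Canonical string form of a peptide set for set comparisons.
pep_key <- function(df) sprintf("%d-%d-%d", df$start, df$end, df$missed_cleavages)
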