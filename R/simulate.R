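# Deterministic simulator of a genome, gene models and planted SNVs with a
# machine-readable truth table. Every gene carries a valid ORF (ATG start,
# stop-free interior, terminal stop, CDS length divisible by 3), optionally
# split across several CDS segments on either strand, so the whole pipeline
# is testable without any external download.

.SENSE_CODONS <- NULL
.sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}
.STOP_CODONS <- c("TAA", "TAG", "TGA")

.random_nt <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulation configuration
#'
#' Defaults describe a compact but structurally realistic study: 60
#' multi-exon genes on 3 chromosomes of 60 kb, half on the minus strand,
#' proteins of 80-300 residues, introns of 20-200 nt, and a planted variant
#' population of 200 missense, 100 synonymous, 20 stopgain and 50 noncoding
#' SNVs. The seed fixes all randomness; genes must fit their chromosome or
#' the generator raises a configuration error rather than silently
#' truncating.
#'
#' @param n_chromosomes number of chromosomes
#' @param chromosome_length length of each chromosome (nt)
#' @param n_genes number of genes, distributed round-robin over chromosomes
#' @param exons_per_gene inclusive range of CDS segment counts per gene
#' @param fraction_minus_strand probability a gene lies on the minus strand
#' @param protein_length inclusive range of protein lengths (residues)
#' @param intron_length inclusive range of intron lengths (nt, minimum 20 so
#'   no variant is ambiguous between adjacent exons)
#' @param n_missense,n_synonymous,n_stopgain,n_noncoding planted SNV counts
#' @param seed integer seed fixing all randomness
#' @return a validated configuration list
#' @export
sim_config <- function(n_chromosomes = 3L, chromosome_length = 60000L,
                       n_genes = 60L, exons_per_gene = c(1L, 4L),
                       fraction_minus_strand = 0.5,
                       protein_length = c(80L, 300L),
                       intron_length = c(20L, 200L),
                       n_missense = 200L, n_synonymous = 100L,
                       n_stopgain = 20L, n_noncoding = 50L, seed = 1L) {
  counts <- c(n_missense, n_synonymous, n_stopgain, n_noncoding)
  if (any(counts < 0L)) svp_error("planted counts must be >= 0", "svp_config_error")
  if (intron_length[1] < 20L) {
    svp_error("intron_length minimum must be >= 20", "svp_config_error")
  }
  if (fraction_minus_strand < 0 || fraction_minus_strand > 1) {
    svp_error("fraction_minus_strand must be in [0, 1]", "svp_config_error")
  }
  list(n_chromosomes = as.integer(n_chromosomes),
       chromosome_length = as.integer(chromosome_length),
       n_genes = as.integer(n_genes),
       exons_per_gene = as.integer(exons_per_gene),
       fraction_minus_strand = fraction_minus_strand,
       protein_length = as.integer(protein_length),
       intron_length = as.integer(intron_length),
       n_missense = as.integer(n_missense),
       n_synonymous = as.integer(n_synonymous),
       n_stopgain = as.integer(n_stopgain),
       n_noncoding = as.integer(n_noncoding),
       seed = as.integer(seed))
}

#' Simulate a reference genome and gene models
#'
#' Builds `config$n_genes` genes, each a complete ORF split into 1 or more
#' CDS segments separated by introns, packed onto chromosomes with random
#' intergenic spacers and padded with random sequence to the configured
#' chromosome length. Deterministic under the configuration seed.
#'
#' @param config see [sim_config()]
#' @return list with `genome` (nucleotide records, one per chromosome) and
#'   `transcripts` (named list of `GtfTranscriptRaw` structures)
#' @export
simulate_reference <- function(config = sim_config()) {
  set.seed(config$seed)
  sense <- .sense_codons()
  chrom_names <- sprintf("chr%d", seq_len(config$n_chromosomes))
  chrom_seqs <- character(config$n_chromosomes)
  transcripts <- list()

  for (ci in seq_len(config$n_chromosomes)) {
    gene_ids <- seq(ci, config$n_genes, by = config$n_chromosomes)
    parts <- character(0)
    cursor <- 0L
    for (g in gene_ids) {
      spacer <- sample(100:300, 1)
      parts <- c(parts, .random_nt(spacer))
      cursor <- cursor + spacer

      n_aa <- sample(config$protein_length[1]:config$protein_length[2], 1)
      cds <- paste(c("ATG", sample(sense, n_aa - 1L, replace = TRUE),
                     sample(.STOP_CODONS, 1)), collapse = "")
      L <- nchar(cds)
      n_exons <- sample(config$exons_per_gene[1]:config$exons_per_gene[2], 1)
      bnd <- if (n_exons > 1L) sort(sample(6:(L - 6L), n_exons - 1L)) else integer(0)
      piece_start <- c(0L, bnd)
      piece_end <- c(bnd, L)
      pieces <- substring(cds, piece_start + 1L, piece_end)
      introns <- if (n_exons > 1L) {
        vapply(seq_len(n_exons - 1L), function(i)
          .random_nt(sample(config$intron_length[1]:config$intron_length[2], 1)),
          character(1))
      } else character(0)

      # region in transcript orientation: exon1 intron1 exon2 ...
      region_tx <- pieces[1]
      tx_off <- integer(n_exons); tx_off[1] <- 0L
      for (k in seq_len(n_exons - 1L)) {
        region_tx <- paste0(region_tx, introns[k], pieces[k + 1L])
        tx_off[k + 1L] <- nchar(region_tx) - nchar(pieces[k + 1L])
      }
      Lr <- nchar(region_tx)
      strand <- if (stats::runif(1) < config$fraction_minus_strand) "-" else "+"
      region_genomic <- if (strand == "-") reverse_complement(region_tx) else region_tx

      seg_s_tx <- tx_off
      seg_e_tx <- tx_off + nchar(pieces)
      if (strand == "+") {
        seg_s <- seg_s_tx; seg_e <- seg_e_tx
      } else {
        seg_s <- Lr - seg_e_tx; seg_e <- Lr - seg_s_tx
      }
      ord <- order(seg_s)
      seg_s <- seg_s[ord]; seg_e <- seg_e[ord]

      tid <- sprintf("tx%03d", g)
      transcripts[[tid]] <- structure(
        list(transcript_id = tid, gene_name = sprintf("GENE%03d", g),
             chrom = chrom_names[ci], strand = strand,
             starts = cursor + seg_s + 1L, ends = cursor + seg_e),
        class = "GtfTranscriptRaw")
      parts <- c(parts, region_genomic)
      cursor <- cursor + Lr
    }
    if (cursor > config$chromosome_length) {
      svp_error(sprintf(
        "genes do not fit: chromosome %s needs %d nt but chromosome_length is %d",
        chrom_names[ci], cursor, config$chromosome_length), "svp_config_error")
    }
    parts <- c(parts, .random_nt(config$chromosome_length - cursor))
    chrom_seqs[ci] <- paste(parts, collapse = "")
  }

  genome <- data.frame(id = chrom_names, desc = "", seq = chrom_seqs,
                       stringsAsFactors = FALSE)
  list(genome = genome, transcripts = transcripts[order(names(transcripts))])
}

#' Plant SNVs with a known truth table
#'
#' Picks coding bases and alternate alleles whose codon-level effect is the
#' requested category (verified by construction against the genetic code);
#' noncoding variants are placed in introns, falling back to intergenic
#' sequence. At most one variant per codon and per genomic position, so the
#' truth table maps one-to-one onto expected database entries. VCF REF
#' alleles are forward-strand genome bases; for minus-strand genes the
#' codon-level alternate is complemented accordingly.
#'
#' @param genome,transcripts output of [simulate_reference()]
#' @param config see [sim_config()]
#' @return list with `variants` (`chrom`, `pos`, `ref`, `alt`, sorted) and
#'   `truth` (`chrom`, `pos`, `ref`, `alt`, `transcript_id`, `category`,
#'   `hgvs_p`)
#' @export
plant_variants <- function(genome, transcripts, config = sim_config()) {
  set.seed(config$seed + 1L)
  models <- lapply(transcripts, build_transcript)
  cds_seq <- lapply(models, function(tx) extract_cds(tx, genome)$nucleotides)
  gpos <- lapply(models, cds_genomic_positions)
  used_pos <- new.env(parent = emptyenv())
  used_codon <- new.env(parent = emptyenv())
  rows <- list()

  plant_coding <- function(category, count) {
    planted <- 0L; attempts <- 0L
    while (planted < count) {
      attempts <- attempts + 1L
      if (attempts > 200000L) {
        svp_error(sprintf("insufficient eligible sites for %d %s variants",
                          count, category), "svp_config_error")
      }
      ti <- sample(length(models), 1)
      tx <- models[[ti]]
      n_codon <- tx$cds_length %/% 3L
      if (n_codon < 4L) next
      r <- sample(2:(n_codon - 1L), 1)  # internal sense codons only
      ck <- paste0(tx$transcript_id, ":", r)
      if (!is.null(used_codon[[ck]])) next
      codon <- substr(cds_seq[[ti]], 3L * r - 2L, 3L * r)
      o <- sample(0:2, 1)
      base <- substr(codon, o + 1L, o + 1L)
      alt <- sample(setdiff(c("A", "C", "G", "T"), base), 1)
      new_codon <- codon
      substr(new_codon, o + 1L, o + 1L) <- alt
      old_aa <- codon_to_aa(codon); new_aa <- codon_to_aa(new_codon)
      ok <- switch(category,
        missense = new_aa != old_aa && new_aa != "*",
        synonymous = new_aa == old_aa,
        stopgain = new_aa == "*")
      if (!ok) next
      pos0 <- gpos[[ti]][3L * (r - 1L) + o + 1L]
      pk <- paste0(tx$chrom, ":", pos0)
      if (!is.null(used_pos[[pk]])) next
      used_pos[[pk]] <- TRUE; used_codon[[ck]] <- TRUE
      vcf_ref <- substr(genome$seq[match(tx$chrom, genome$id)], pos0 + 1L, pos0 + 1L)
      vcf_alt <- if (tx$strand == "-") complement_nt(alt) else alt
      rows[[length(rows) + 1L]] <<- data.frame(
        chrom = tx$chrom, pos = pos0 + 1L, ref = vcf_ref, alt = vcf_alt,
        transcript_id = tx$transcript_id, category = category,
        hgvs_p = format_hgvs_p(old_aa, r, new_aa), stringsAsFactors = FALSE)
      planted <- planted + 1L
    }
  }

  plant_coding("missense", config$n_missense)
  plant_coding("synonymous", config$n_synonymous)
  plant_coding("stopgain", config$n_stopgain)

  if (config$n_noncoding > 0L) {
    pool <- list()
    for (ti in seq_along(models)) {
      tx <- models[[ti]]
      if (length(tx$starts) > 1L) {
        for (k in seq_len(length(tx$starts) - 1L)) {
          ip <- seq.int(tx$ends[k], tx$starts[k + 1L] - 1L)
          pool[[length(pool) + 1L]] <- data.frame(
            chrom = tx$chrom, pos0 = ip, transcript_id = tx$transcript_id,
            stringsAsFactors = FALSE)
        }
      }
    }
    pool <- if (length(pool)) do.call(rbind, pool) else
      data.frame(chrom = character(0), pos0 = integer(0),
                 transcript_id = character(0))
    if (nrow(pool) < config$n_noncoding) {
      svp_error(sprintf("insufficient intronic sites for %d noncoding variants",
                        config$n_noncoding), "svp_config_error")
    }
    pick <- pool[sample(nrow(pool), config$n_noncoding), , drop = FALSE]
    for (i in seq_len(nrow(pick))) {
      ref <- substr(genome$seq[match(pick$chrom[i], genome$id)],
                    pick$pos0[i] + 1L, pick$pos0[i] + 1L)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = pick$chrom[i], pos = pick$pos0[i] + 1L, ref = ref, alt = alt,
        transcript_id = pick$transcript_id[i], category = "noncoding",
        hgvs_p = NA_character_, stringsAsFactors = FALSE)
    }
  }

  truth <- do.call(rbind, rows)
  truth <- truth[order(truth$chrom, truth$pos), , drop = FALSE]
  rownames(truth) <- NULL
  list(variants = truth[, c("chrom", "pos", "ref", "alt")], truth = truth)
}

#' Simulate a complete dataset and optionally write it to disk
#'
#' Runs [simulate_reference()] and [plant_variants()]; when `dir` is given,
#' writes `genome.fa`, `genes.gtf`, `sample.vcf` and `truth.tsv` there.
#' Output bytes are a pure function of the configuration.
#'
#' @param config see [sim_config()]
#' @param dir optional output directory (created if needed)
#' @return list with `genome`, `transcripts`, `variants`, `truth`, and
#'   `paths` (when written)
#' @export
simulate_dataset <- function(config = sim_config(), dir = NULL) {
  sim <- simulate_reference(config)
  pv <- plant_variants(sim$genome, sim$transcripts, config)
  out <- list(genome = sim$genome, transcripts = sim$transcripts,
              variants = pv$variants, truth = pv$truth)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(genome = file.path(dir, "genome.fa"),
                  gtf = file.path(dir, "genes.gtf"),
                  vcf = file.path(dir, "sample.vcf"),
                  truth = file.path(dir, "truth.tsv"))
    write_fasta(sim$genome, paths$genome)
    write_gtf_transcripts(sim$transcripts, paths$gtf)
    write_snv_vcf(pv$variants, paths$vcf)
    utils::write.table(pv$truth, paths$truth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out$paths <- paths
  }
  out
}
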