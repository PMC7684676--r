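# Fixtures built in code. small_sim() is a compact simulated study reused by
# several files; memoised so each test file pays for it at most once.

small_config <- function(seed = 11, ...) {
  sim_config(n_chromosomes = 1L, chromosome_length = 20000L, n_genes = 10L,
             protein_length = c(60L, 150L),
             n_missense = 30L, n_synonymous = 20L, n_stopgain = 5L,
             n_noncoding = 10L, seed = seed, ...)
}

.sim_cache <- new.env(parent = emptyenv())
small_sim <- function(seed = 11) {
  key <- as.character(seed)
  if (is.null(.sim_cache[[key]])) {
    .sim_cache[[key]] <- simulate_dataset(small_config(seed = seed))
  }
  .sim_cache[[key]]
}

# A single-exon plus-strand transcript over an in-memory chromosome.
toy_genome <- function(seq, chrom = "chr1") {
  data.frame(id = chrom, desc = "", seq = seq, stringsAsFactors = FALSE)
}

toy_tx <- function(starts1, ends1, strand = "+", chrom = "chr1",
                   id = "tx1", gene = "G1") {
  build_transcript(structure(
    list(transcript_id = id, gene_name = gene, chrom = chrom,
         strand = strand, starts = starts1, ends = ends1),
    class = "GtfTranscriptRaw"))
}

snv <- function(chrom, pos, ref, alt) {
  data.frame(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
             filter = "PASS", record_index = 1L, stringsAsFactors = FALSE)
}

# Protein of n residues built from explicit codons; positions in `fix` force
# specific codons (e.g. CTG for L at 858). Returns the CDS string incl. stop.
cds_with_codons <- function(n, fix = list(), seed = 1) {
  set.seed(seed)
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*" & names(gc) != "ATG"]
  codons <- c("ATG", sample(sense, n - 1L, replace = TRUE), "TAA")
  for (pos in names(fix)) codons[as.integer(pos)] <- fix[[pos]]
  paste(codons, collapse = "")
}
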