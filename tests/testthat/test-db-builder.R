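test_that("apply_substitution replaces exactly one residue and guards mismatches", {
  expect_equal(apply_substitution("MKR", 1, "M", "V"), "VKR")
  expect_error(apply_substitution("MKR", 2, "R", "Q"),
               class = "svp_substitution_error")
  expect_error(apply_substitution("MKR", 9, "R", "Q"),
               class = "svp_substitution_error")
  # hotspot-style substitution on a 900-residue synthetic protein
  prot <- translate_cds(cds_with_codons(900, fix = list(`858` = "CTG")))$protein
  expect_equal(substr(prot, 858, 858), "L")
  out <- apply_substitution(prot, 858, "L", "R")
  expect_equal(nchar(out), nchar(prot))
  expect_equal(hamming(out, prot), 1L)
  expect_equal(substr(out, 858, 858), "R")
})

test_that("headers are bit-exact and parse back to their fields", {
  entry <- data.frame(base_id = "NM_0001", hgvs_p = "p.L858R",
                      gene_name = "EGFR", category = "missense",
                      var = "chr7:55259515T>G", stringsAsFactors = FALSE)
  expect_identical(make_header(entry),
                   "NM_0001|p.L858R gene=EGFR var=chr7:55259515T>G class=missense")
  expect_identical(make_reference_header("NM_0002", "BRAF"), "NM_0002 gene=BRAF")
  p <- parse_db_header(make_header(entry))
  expect_equal(p$base_id, "NM_0001")
  expect_equal(p$hgvs_p, "p.L858R")
  expect_equal(p$gene_name, "EGFR")
  expect_equal(p$var, "chr7:55259515T>G")
  expect_equal(p$category, "missense")
  expect_false(p$is_decoy)
  r <- parse_db_header("NM_0002 gene=BRAF")
  expect_true(is.na(r$hgvs_p)); expect_equal(r$gene_name, "BRAF")
  d <- parse_db_header("rev_NM_0001|p.L858R gene=EGFR var=chr7:55259515T>G class=missense")
  expect_true(d$is_decoy); expect_equal(d$base_id, "NM_0001")
})

test_that("decoy generation reverses sequences, prefixes ids, and is an involution", {
  recs <- data.frame(id = c("p1", "p2"), desc = c("", "g"),
                     seq = c("MKR", "MAAKGGGR"), stringsAsFactors = FALSE)
  d <- generate_decoy(recs)
  expect_equal(d$id, c("rev_p1", "rev_p2"))
  expect_equal(d$seq, c("RKM", "RGGGKAAM"))
  expect_equal(nrow(d), nrow(recs))
  expect_equal(generate_decoy(d)$seq, recs$seq)
})

test_that("build_database recovers the planted missense truth set exactly", {
  sim <- small_sim()
  models <- lapply(sim$transcripts, build_transcript)
  db <- build_database(sim$genome, models, sim$variants)
  truth_mis <- sim$truth[sim$truth$category == "missense", ]
  expect_setequal(paste(db$variants$base_id, db$variants$hgvs_p),
                  paste(truth_mis$transcript_id, truth_mis$hgvs_p))
  # Hamming distance exactly 1 from the base protein, equal lengths
  for (i in seq_len(nrow(db$variants))) {
    base <- db$reference$seq[match(db$variants$base_id[i],
                                   db$reference$transcript_id)]
    expect_equal(nchar(db$variants$seq[i]), nchar(base))
    expect_equal(hamming(db$variants$seq[i], base), 1L)
  }
  # report counts match planted truth
  want <- table(sim$truth$category)
  for (k in names(want)) {
    expect_equal(unname(db$report$category_counts[[k]]), unname(unclass(want)[[k]]))
  }
  expect_equal(db$report$n_variant, nrow(truth_mis))
  # conservation: category counts sum to the number of effects
  expect_equal(sum(db$report$category_counts), db$report$n_effects)
})

test_that("an empty VCF gives a byte-identical reference-only database", {
  sim <- small_sim()
  models <- lapply(sim$transcripts, build_transcript)
  empty <- sim$variants[0, ]
  db0 <- build_database(sim$genome, models, empty)
  expect_equal(db0$report$n_variant, 0L)
  f0 <- withr::local_tempfile(); f1 <- withr::local_tempfile()
  write_fasta(database_records(db0), f0)
  ref_only <- database_records(build_database(sim$genome, models, empty))
  write_fasta(ref_only, f1)
  expect_identical(readChar(f0, file.size(f0)), readChar(f1, file.size(f1)))
})

test_that("synonymous and noncoding effects are never emitted", {
  sim <- small_sim()
  models <- lapply(sim$transcripts, build_transcript)
  quiet <- sim$truth[sim$truth$category %in% c("synonymous", "noncoding"), ]
  db <- build_database(sim$genome, models,
                       quiet[, c("chrom", "pos", "ref", "alt")])
  expect_equal(db$report$n_variant, 0L)
  expect_equal(unname(db$report$category_counts[["synonymous"]]),
               sum(quiet$category == "synonymous"))
})

test_that("stopgain entries are excluded by default and truncated when included", {
  sim <- small_sim()
  models <- lapply(sim$transcripts, build_transcript)
  sg <- sim$truth[sim$truth$category == "stopgain", ]
  db <- build_database(sim$genome, models, sg[, c("chrom", "pos", "ref", "alt")])
  expect_equal(db$report$n_variant, 0L)
  db2 <- build_database(sim$genome, models, sg[, c("chrom", "pos", "ref", "alt")],
                        options = db_options(include_stopgain = TRUE))
  expect_equal(db2$report$n_variant, nrow(sg))
  for (i in seq_len(nrow(db2$variants))) {
    base <- db2$reference$seq[match(db2$variants$base_id[i],
                                    db2$reference$transcript_id)]
    pos <- as.integer(sub("^p\\.[A-Z]([0-9]+)\\*$", "\\1", db2$variants$hgvs_p[i]))
    expect_equal(db2$variants$seq[i], substr(base, 1, pos - 1L))
  }
})

test_that("the same protein change from different alleles deduplicates with merged provenance", {
  # codon AGA (R) at residue 2: pos 6 A->C gives AGC (S), A->T gives AGT (S)
  g <- toy_genome("ATGAGAAAATAA")
  tx <- list(tx1 = toy_tx(1L, 12L))
  vars <- rbind(snv("chr1", 6, "A", "C"), snv("chr1", 6, "A", "T"))
  db <- build_database(g, tx, vars)
  expect_equal(nrow(db$variants), 1L)
  expect_equal(db$variants$hgvs_p, "p.R2S")
  expect_equal(db$variants$var, "chr1:6A>C;chr1:6A>T")
  expect_equal(db$report$n_dedup_merged, 1L)
})

test_that("two builds from identical inputs are byte-identical", {
  sim <- small_sim()
  models <- lapply(sim$transcripts, build_transcript)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_fasta(database_records(build_database(sim$genome, models, sim$variants),
                               decoy = TRUE), f1)
  write_fasta(database_records(build_database(sim$genome, models, sim$variants),
                               decoy = TRUE), f2)
  expect_identical(readChar(f1, file.size(f1)), readChar(f2, file.size(f2)))
})

test_that("protein cross-validation skips mismatching transcripts, never substitutes", {
  sim <- small_sim()
  models <- lapply(sim$transcripts, build_transcript)
  prots <- vapply(models, function(tx)
    translate_cds(extract_cds(tx, sim$genome))$protein, character(1))
  pf <- data.frame(id = paste0("P_", names(prots)), desc = "",
                   seq = unname(prots), stringsAsFactors = FALSE)
  # corrupt one provided protein
  pf$seq[3] <- sub("^M", "MQ", pf$seq[3])
  im <- data.frame(transcript_id = names(prots), protein_id = pf$id,
                   stringsAsFactors = FALSE)
  db <- build_database(sim$genome, models, sim$variants[0, ],
                       options = db_options(protein_fasta = pf, id_map = im))
  expect_equal(unname(db$report$skipped[["protein_mismatch"]]), 1L)
  expect_equal(db$report$n_reference, length(models) - 1L)
  expect_false(names(prots)[3] %in% db$reference$transcript_id)
})
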