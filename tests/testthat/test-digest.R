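test_that("cleavage rules: K always cut with LysC, R not before P, terminus never a site", {
  # M A A K G G G R P G G G R: K4 is a site; R8 is followed by P; R13 is terminal
  expect_equal(cleavage_sites("MAAKGGGRPGGGR"), 4L)
  # LysC cleaves K-P, so MKPR cuts after K2 only (R4 terminal)
  expect_equal(cleavage_sites("MKPR"), 2L)
  expect_equal(cleavage_sites("MAGHILW"), integer(0))
  # trypsin alone does not cut K-P
  expect_equal(cleavage_sites("MKPR", enzymes = "trypsin"), integer(0))
  # kp_cut off suppresses the K-P cut even with LysC
  expect_equal(cleavage_sites("MKPR", kp_cut = FALSE), integer(0))
  # lysc alone ignores R
  expect_equal(cleavage_sites("MKAARA", enzymes = "lysc"), 2L)
})

test_that("digest filters by length and its 0-missed peptides partition the protein", {
  expect_equal(nrow(digest("MAGIL", digest_params())), 0L)
  set.seed(21)
  for (i in 1:20) {
    prot <- random_protein(sample(20:200, 1))
    d0 <- digest(prot, digest_params(max_missed_cleavages = 0L, min_length = 1L))
    d0 <- d0[order(d0$start), ]
    expect_equal(paste(d0$residues, collapse = ""), prot)
    expect_equal(d0$start[-1], d0$end[-nrow(d0)] + 1L)
  }
})

test_that("digest equals the exhaustive substring oracle on random proteins", {
  set.seed(77)
  for (i in 1:30) {
    prot <- random_protein(sample(10:200, 1))
    got <- digest(prot, digest_params())
    want <- oracle_digest(prot)
    expect_setequal(pep_key(got), pep_key(want))
    expect_setequal(got$residues, want$residues)
    # and under a different parameterization
    got2 <- digest(prot, digest_params(max_missed_cleavages = 2L,
                                       min_length = 5L, max_length = 30L))
    want2 <- oracle_digest(prot, max_missed = 2L, min_len = 5L, max_len = 30L)
    expect_setequal(pep_key(got2), pep_key(want2))
  }
})

test_that("peptide fields are internally consistent", {
  set.seed(31)
  prot <- random_protein(150)
  d <- digest(prot, digest_params(), parent_id = "p")
  expect_true(all(d$end - d$start + 1L == nchar(d$residues)))
  expect_true(all(nchar(d$residues) >= 7L))
  expect_true(all(d$missed_cleavages <= 1L))
  expect_true(all(substring(prot, d$start, d$end) == d$residues))
  expect_false(any(d$has_x))
  dx <- digest("MKAAAXAAAK", digest_params(min_length = 3L))
  expect_true(any(dx$has_x))
})

test_that("a site-preserving substitution only changes peptides covering the residue", {
  set.seed(13)
  aa_quiet <- strsplit("ACDEFGHILMNQSTVWY", "")[[1]]  # never K, R or P
  for (i in 1:25) {
    prot <- random_protein(sample(40:160, 1))
    ch <- strsplit(prot, "")[[1]]
    cand <- which(ch %in% aa_quiet)
    if (length(cand) == 0L) next
    pos <- sample(cand, 1)
    alt <- sample(setdiff(aa_quiet, ch[pos]), 1)
    var <- prot; substr(var, pos, pos) <- alt
    ref_d <- digest(prot, digest_params())
    var_d <- digest(var, digest_params())
    sym <- c(setdiff(pep_key(ref_d), pep_key(var_d)),
             setdiff(pep_key(var_d), pep_key(ref_d)))
    # keys are identical (same coordinates); sequence-level diffs all cover pos
    expect_setequal(pep_key(ref_d), pep_key(var_d))
    changed <- var_d$residues[!(var_d$residues %in% ref_d$residues)]
    spans <- var_d[!(var_d$residues %in% ref_d$residues), ]
    expect_true(all(spans$start <= pos & spans$end >= pos))
  }
})

test_that("variant peptides cover the substitution, are novel, and pair with wild types", {
  set.seed(17)
  prot <- random_protein(120)
  ch <- strsplit(prot, "")[[1]]
  pos <- which(!(ch %in% c("K", "R", "P")))[20]
  alt <- setdiff(c("G", "A", "S"), ch[pos])[1]
  var <- prot; substr(var, pos, pos) <- alt
  vp <- variant_peptides(prot, var, digest_params(), parent_id = "p1")
  expect_gt(nrow(vp), 0L)
  expect_true(all(vp$start <= pos & vp$end >= pos))
  expect_true(all(vp$variant_offset >= 1L &
                    vp$variant_offset <= nchar(vp$residues)))
  expect_true(all(substr(vp$residues, vp$variant_offset, vp$variant_offset) == alt))
  ref_set <- digest(prot, digest_params(min_length = 1L))$residues
  expect_false(any(vp$residues %in% ref_set))
  # the paired wild type differs from the variant peptide only at the offset
  for (i in seq_len(nrow(vp))) {
    wt <- strsplit(vp$paired_wildtype[i], ";", fixed = TRUE)[[1]]
    expect_true(any(vapply(wt, function(w)
      nchar(w) == nchar(vp$residues[i]) && hamming(w, vp$residues[i]) == 1L,
      logical(1))))
  }
})

test_that("a substitution creating a cleavage site yields new shorter fragments", {
  # X -> K inside a long tryptic peptide
  prot <- "MAAAAAAAASAAAAAAAAKGGGGGGGR"
  var <- prot; substr(var, 10, 10) <- "K"
  vp <- variant_peptides(prot, var, digest_params())
  expect_gt(nrow(vp), 0L)
  expect_true(any(grepl("K$", vp$residues)))  # new C-terminal K fragment
  ref_peps <- digest(prot, digest_params(min_length = 1L))$residues
  expect_false(any(vp$residues %in% ref_peps))
  # many-to-one pairing by coordinate overlap
  expect_true(all(nchar(vp$paired_wildtype) > 0L))
})

test_that("fragments below the length floor give an empty, flagged variant set", {
  prot <- "MAASAAAAR"  # no internal sites; S4 -> K creates two short fragments
  var <- prot; substr(var, 4, 4) <- "K"
  vp <- variant_peptides(prot, var,
                         digest_params(max_missed_cleavages = 0L))
  expect_equal(nrow(vp), 0L)
  expect_true(attr(vp, "all_filtered"))
})

test_that("peptide tables export and re-parse losslessly", {
  sim <- small_sim()
  models <- lapply(sim$transcripts, build_transcript)
  db <- build_database(sim$genome, models, sim$variants)
  recs <- database_records(db)
  pairs <- digest_variant_db(recs)
  expect_gt(nrow(pairs), 0L)
  expect_true(all(pairs$variant_offset >= 1L))
  f <- withr::local_tempfile(fileext = ".tsv")
  export_peptide_table(pairs, f)
  back <- utils::read.delim(f, stringsAsFactors = FALSE)
  expect_equal(names(back),
               c("serial", "parent_id", "hgvs_p", "variant_peptide", "start",
                 "end", "missed_cleavages", "paired_wildtype_peptides"))
  expect_equal(back$variant_peptide, pairs$residues)
  expect_equal(back$start, pairs$start)
  expect_equal(back$paired_wildtype_peptides, pairs$paired_wildtype)
  # empty set: header-only file
  export_peptide_table(pairs[0, ], f)
  expect_equal(length(readLines(f)), 1L)
})
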