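Package: snv2prot
Title: Sample-Specific Variant Protein Databases from Coding SNVs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds customized, sample-specific variant protein databases for
    proteogenomic mass-spectrometry searches. Coding single-nucleotide variants
    from a VCF are annotated at codon level against gene models (GTF) and a
    reference genome (FASTA), missense changes are substituted into the
    translated reference proteins, and the resulting variant protein FASTA
    (optionally with reversed decoys) is emitted together with in-silico
    proteolytic digests that pair each variant peptide with its wild-type
    counterpart. A deterministic simulator of genomes, gene models and planted
    variants with a machine-readable truth table supports end-to-end testing
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    vcfR,
    rtracklayer,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
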