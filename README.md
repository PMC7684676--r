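# snv2prot

Build **sample-specific variant protein databases** from coding
single-nucleotide variants, for proteogenomic mass-spectrometry searches.

A conventional proteomic search identifies spectra against a reference
protein database, which contains no sample-specific variation: a peptide
carrying EGFR p.L858R or BRAF p.V600E can never be matched, however good the
spectrum. `snv2prot` closes that gap. Starting from a reference genome
(FASTA), gene models (GTF, CDS features) and called variants (VCF), it

1. classifies every SNV at codon level against each overlapping transcript
   (missense / synonymous / stopgain / stoploss / startloss / noncoding),
2. substitutes each missense change into the translated reference protein
   (`p.<ref><position><alt>` notation, e.g. `p.L858R`: leucine 858 → arginine),
3. writes a customized protein FASTA — the reference proteome plus one entry
   per incorporated variant, optionally with reversed (`rev_`) decoy entries
   for target–decoy FDR estimation, and
4. digests the database in silico (trypsin + LysC, ≤ 1 missed cleavage,
   minimum length 7 by default) to enumerate the variant peptides it can
   contribute, each paired with its wild-type counterpart.

Only single-residue substitutions are incorporated; indels, frameshifts and
fusion proteoforms are out of scope by design. A deterministic simulator
(`simulate_dataset()`) generates genomes, gene models and planted variants
with a machine-readable truth table, so the entire pipeline is testable
without downloading anything.

## Worked example

```r
library(snv2prot)

cfg <- sim_config(n_genes = 12, n_missense = 25, n_synonymous = 10,
                  n_stopgain = 3, n_noncoding = 6, seed = 104,
                  n_chromosomes = 1, chromosome_length = 25000)
sim <- simulate_dataset(cfg, dir = "exdir")   # genome.fa, genes.gtf, sample.vcf, truth.tsv

genome      <- read_fasta("exdir/genome.fa", "nucleotide")
transcripts <- lapply(read_gtf_transcripts("exdir/genes.gtf"), build_transcript)
vcf         <- read_vcf_snvs("exdir/sample.vcf")

db <- build_database(genome, transcripts, vcf$variants, vcf_skipped = vcf$skipped)
print(db$report)
#> Variant protein database build report
#>   reference entries : 12
#>   variant entries   : 25
#>   effects by category:
#>     missense    25
#>     synonymous  10
#>     stopgain    3
#>     stoploss    0
#>     startloss   0
#>     noncoding   6
#>   ...
```

All 25 planted missense SNVs (and only those: synonymous, stopgain and
noncoding effects are counted but not emitted) became variant entries, each
a reference protein with exactly one residue substituted:

```r
make_header(db$variants[1, ])
#> "tx001|p.A207S gene=GENE001 var=chr1:182C>A class=missense"

write_fasta(database_records(db, decoy = TRUE), "exdir/db.fasta")
pep <- digest_variant_db(read_fasta("exdir/db.fasta", "protein"))
head(pep[, c("hgvs_p", "residues", "start", "end", "paired_wildtype")], 3)
#>    hgvs_p   residues start end   paired_wildtype
#> 1 p.A207S    SSRHGTS   201 207           SSRHGTA
#> 2 p.G140R IYRGNTTESR   131 140 IYR;GNTTESGVEVGVK
#> 3 p.G140R    GNTTESR   134 140     GNTTESGVEVGVK
```

Row 1 is the simple case: the substitution falls inside a tryptic peptide
and the wild-type pair differs at exactly one residue. Rows 2–3 show a
created cleavage site (G→R): the variant digest gains new fragments and the
pairing is many-to-one by coordinate overlap.

The same pipeline is available from the shell via the installed
`exec/snv2prot` script:

```sh
snv2prot simulate --out-dir exdir --genes 12 --seed 104 --plant 25,10,3,6
snv2prot build-db --genome exdir/genome.fa --gtf exdir/genes.gtf \
                  --vcf exdir/sample.vcf --out exdir/db.fasta --decoy \
                  --report exdir/report.tsv
snv2prot digest   --db exdir/db.fasta --out exdir/peptides.tsv
```

Every subcommand accepts `--dry-run`, which prints the fully resolved plan
(inputs, options, output paths) and writes nothing.

## Documentation

The vignette (`vignettes/variant-protein-databases.Rmd`) describes the
coordinate model, the annotation and database-construction policies, the
cleavage rules and wild-type pairing, what the simulator does and does not
emulate, and known limitations.
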