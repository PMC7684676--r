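---
title: "Building sample-specific variant protein databases from coding SNVs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building sample-specific variant protein databases from coding SNVs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snv2prot)
```

## The problem

Standard proteomic searches identify peptides against a reference protein
database, which by construction contains no sample-specific amino-acid
variation. A coding single-nucleotide variant (SNV) that changes a residue —
an EGFR p.L858R, a BRAF p.V600E — therefore produces tandem-MS spectra that
no reference peptide can explain. Whether such variants are actually
*expressed* at the protein level matters (mutant peptides presented by the
MHC act as neo-antigens), and answering it requires searching the spectra
against a database that contains the variant proteins of that very sample.

`snv2prot` builds that database. Given a reference genome (FASTA), gene
models (GTF with CDS features) and called variants (VCF), it classifies each
SNV at codon level against every overlapping transcript, substitutes each
missense change into the translated reference protein, and writes a protein
FASTA holding the reference proteome plus one entry per incorporated
variant, optionally with reversed decoy entries for FDR estimation. A
digestion module then enumerates the variant peptides such a database can
contribute and pairs each one with its wild-type counterpart.

Only single-residue substitutions are incorporated. Indels, frameshifts,
splice-altering and fusion proteoforms are a deliberate non-goal: they
change peptide space in ways a per-residue substitution model cannot
represent, and supporting them honestly would be a different tool.

## Coordinate model

Three conventions meet in this problem: VCF and GTF are 1-based inclusive on
disk, while interval arithmetic is far less error-prone half-open. The
package converts to 0-based half-open coordinates exactly once, at
`build_transcript()`, and converts back only when formatting output. Every
mapping in between — genomic position to spliced CDS index
(`genomic_to_cds_index()`), CDS index to residue and codon offset
(`cds_index_to_protein()`) — operates on the internal convention. On the
minus strand, CDS index 0 is the genomic 3'-most coding base, and VCF
alleles (always forward-strand) are complemented before codon substitution.

Frame (`phase`) attributes in the GTF are ignored: the first base of the
5'-most coding segment in transcript orientation is assumed to be codon
position 0. Annotations violating this assumption are not mis-translated
silently — the translation flags (`no_start`, `internal_stop`,
`incomplete_codon`, `missing_stop`) mark the transcript in the build report.

## Variant annotation

For each (variant, overlapping transcript) pair the affected codon is
rebuilt and the reference and alternate codons are translated under the
standard genetic code:

* same residue → `synonymous` (a stop codon mutating to another stop is also
  synonymous);
* change at residue 1 destroying the initiator M → `startloss`;
* residue → stop → `stopgain`; stop → residue → `stoploss`;
* anything else → `missense`.

Positions outside the CDS are `noncoding`; a variant overlapping no
transcript at all yields a single `noncoding` effect with an `NA`
transcript, so the summary always accounts for every variant. The genome
base at the variant position must equal the VCF REF allele; a mismatch is a
hard consistency error by default because it almost always means the wrong
genome build.

Protein changes are printed in the one-letter shorthand used for hotspot
mutations (`p.L858R`, `p.V600E`, `p.R123*`, `p.K2=`), with ref before alt as
the notation prescribes. Mitochondrial and other non-standard codon tables
are not supported; UGA is always read as stop (selenoproteins will be
flagged as internal-stop transcripts rather than translated through).

## Database construction

The reference section is the translation of every translatable transcript
(or, when a curated protein FASTA plus id map is supplied, the translations
are cross-validated against it and mismatching transcripts are skipped and
counted — never silently replaced). The variant section contains one entry
per distinct `(transcript, protein change)` missense effect: the base
protein with exactly that one residue substituted (the build asserts Hamming
distance 1). Design choices that were genuinely open:

* **One variant per entry.** Two missense variants on one transcript give
  two entries, never a combined haplotype protein: phase is unknowable from
  a plain VCF, and per-variant entries are what a search engine needs to
  localize a substitution.
* **Deduplication key `(transcript_id, hgvs_p)`.** The same protein change
  reachable from different genomic alleles is emitted once, with all
  genomic provenance joined by `;` in the header's `var=` field.
* **Stopgain excluded by default.** The database's purpose is substituted
  residues; truncated proteoforms are available with `include_stopgain`,
  emitted as stop-truncated sequences.
* **Synonymous and noncoding effects are never emitted**, only counted.

Output order is deterministic (reference entries sorted by identifier, then
variant entries sorted by identifier), so two builds from identical inputs
are byte-identical — a property the test suite asserts on whole files.
Headers follow a fixed grammar,
`base|p.X#Y gene=G var=chrom:posR>A class=missense`, and `parse_db_header()`
inverts it; downstream tools (including this package's own digestion module)
recognize variant entries purely from the header.

Decoys are reversed sequences with a `rev_` identifier prefix — reversal is
an involution, which makes the construction trivially auditable.

## Digestion and variant peptides

The digest module implements the search settings commonly used with this
kind of database: trypsin and LysC together, at most one missed cleavage,
minimum peptide length seven (all configurable via `digest_params()`).
The cleavage rule deserves a note: trypsin does not cut R-P bonds, but LysC
cleaves after K even before proline, so with both enzymes active every K is
a site and R is a site except before P. Because the K-P behavior is the one
genuinely debatable rule, it is exposed as `kp_cut` rather than hard-coded.

A *variant peptide* is a peptide of the variant protein that covers the
substituted residue and whose sequence does not occur in the reference
digest. Pairing with wild-type peptides uses coordinate overlap, not
sequence alignment: the reference peptide with the identical span when the
substitution preserves the cleavage pattern, otherwise the
zero-missed-cleavage reference peptides overlapping the variant peptide's
span (a created or destroyed site makes the pairing many-to-one). Both the
novelty check and the pairing run against the *unfiltered* reference digest:
a wild-type counterpart shorter than the length floor is still the correct
counterpart, and a variant peptide equal to some short reference fragment is
not novel. When every candidate fragment falls below the length floor the
result is an empty set with an `all_filtered` flag rather than an error.

## The simulator, and what passing tests mean

`simulate_dataset()` generates the fixture universe: chromosomes of random
uniform A/C/G/T sequence; genes with complete ORFs (ATG start, stop-free
interior, terminal stop, CDS length divisible by 3) split into 1-4 CDS
segments separated by introns of at least 20 nt; a configurable strand mix;
and planted SNVs whose codon-level consequence is chosen *by construction*
(verified against the genetic code at planting time) with a truth table of
intended `(transcript, category, protein change)`. At most one variant per
codon and per genomic position keeps the truth table in one-to-one
correspondence with expected database entries. All output is byte-
deterministic under the configuration seed.

Default generator conditions: 60 genes on 3 chromosomes of 60 kb, half on
the minus strand, proteins of 80-300 residues, and a planted population of
200 missense, 100 synonymous, 20 stopgain and 50 noncoding SNVs — small
enough to run in seconds, large enough that strand, splicing and category
mixtures are all exercised. The oracle-equivalence checks run on a larger
planting (600/300/60/60, giving >1000 SNVs across 60 transcripts); digest
checks use 100 random proteins of up to 200 residues against an exhaustive
substring oracle.

What the simulator does *not* emulate — and therefore what passing tests do
not show about real data: GC bias and repeat structure, overlapping genes
and shared exons, multiple transcripts per gene, annotation errors
(CDS phase offsets, historical RefSeq/genome mismatches), multi-nucleotide
and clustered variants, and any property of real mass spectra. The
cross-validation option against a curated protein FASTA exists precisely
because real annotations drift in ways the simulator does not reproduce.

## Degenerate inputs and numerical choices

Translation never fails: incomplete trailing codons are dropped with a
flag, codons containing N translate to X (X-containing peptides are flagged
downstream), and internal stops truncate with a flag. Variants landing in a
dangling incomplete codon are classified noncoding (they are never
translated). A substitution whose expected reference residue does not match
the protein — possible when an internal stop truncated the translation —
is skipped and counted, not applied. FILTER policy keeps `PASS` and `.`
records by default (the convention of raw GATK output); everything else is
kept only under `keep_filtered`, and every dropped or unusable allele
(indel, MNV, symbolic, filtered, other) is counted in a skip report so that
kept + skipped always equals the allele records in the file.

## Known limitations

* SNVs only; no indels, frameshifts, splice variants or fusions.
* One canonical reading frame per transcript, standard genetic code only.
* No genotype awareness: every ALT allele in the VCF is a candidate,
  regardless of GT fields or zygosity.
* Peptides are compared as bare sequences; modifications are a search-engine
  concern.
* GTF only (attribute syntax `key "value";`); GFF3 is not parsed.
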