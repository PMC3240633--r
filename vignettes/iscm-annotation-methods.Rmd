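---
title: "Methods: stop codon mutation annotation, strain comparison and branch attribution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stop codon mutation annotation, strain comparison and branch attribution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iscmscan)
```

# Scope and model

`iscmscan` annotates single-nucleotide variants against single-exon,
single-interval ORFs in a haploid genome, and compares the resulting
consequence calls across a cohort of strains resequenced against one
reference. The model of a coding gene is deliberately minimal and fits
the vast majority of *S. cerevisiae* ORFs: one genomic interval
[start, end] (1-based, inclusive, stop codon included), one strand, a
length divisible by three, an ATG start and a terminal stop.
Intron-containing ORFs are rejected with an explicit error rather than
mis-annotated; supporting spliced CDS models would change the codon
arithmetic throughout and is out of scope for this version.

All variant coordinates and alleles are expressed on the plus strand,
as in VCF; complementation happens in exactly one place, inside the
annotator, when the affected ORF lies on the minus strand. Coordinates
are converted at the I/O boundary only, so every internal computation
shares one frame.

## Consequence classification

For a variant at genomic position $g$ in an ORF on strand $\pm$, the
coding-frame offset is $c = g - \mathrm{start} + 1$ (plus) or
$c = \mathrm{end} - g + 1$ (minus), the codon index
$i = \lceil c/3 \rceil$, and the in-codon offset $c - 3(i-1)$. The
alternate codon substitutes the (strand-adjusted) alternate base into
the reference codon; reference and alternate amino acids under the
standard nuclear genetic code (64 codons, stops TAA/TAG/TGA rendered
`*`) decide the class:

* identical amino acids: synonymous (stop-retained when both are `*`);
* sense → stop: **nonsense**, an inactivating stop codon mutation
  (ISCM);
* stop → sense: stop-loss;
* a sense change in the ATG at codon 1: start-loss, kept as its own
  class and never counted as an ISCM;
* any codon containing N: undetermined, never silently synonymous.

Each SNP is annotated independently against the *reference* codon. Two
SNPs of one strain in the same codon are flagged as a "compound codon"
in the log but not jointly re-evaluated; joint evaluation would need
phased haplotypes, which SNP lists do not carry. A variant overlapping
several ORFs yields one record per ORF with no canonical-transcript
selection; cohort tallies count such a SNP once (see below). A variant
whose stated reference base disagrees with the genome is classified
undetermined and logged, not dropped silently.

## Truncation length and notation

For a nonsense change at codon $i$ of a protein of length $L$
(excluding the terminal stop), the reported truncation is $L - i$: the
residues strictly downstream of the mutated codon. The shipped
catalogue of known nonsense mutations in strains 74-D694 and G600 is
arithmetically consistent under exactly this convention
(`known_iscm_table()`; e.g. ADE1 $306 - 244 = 62$, ADE2
$571 - 64 = 507$, AFI1 $893 - 887 = 6$), which is why it was adopted
even though it excludes the mutated residue itself from the count.
Note that published protein-length annotations can differ by a few
residues between sources (AFI1 is variously given as 887 or 893
residues); the catalogue keeps the internally consistent
codon-index-plus-truncation arithmetic. Nonsense changes are written
`<ref aa><index><stop codon>` (`W244TGA`), residue-level changes
`<ref aa><index><alt aa>` (`H71L`).

## Stop-loss scanning

A variant converting an ORF's natural terminal stop to a sense codon
extends translation into downstream genomic sequence. The scanner
walks in-frame codons 3' of the ORF (5' of it, reverse-complemented,
for minus-strand ORFs) and reports the extension as the number of
*sense* codons gained strictly downstream of the read-through codon
before the next in-frame stop. If no stop occurs before the chromosome
end the record is flagged `terminator_found = FALSE` rather than given
an arbitrary length. A stop→stop change is stop-retained with
extension 0.

# Cohort comparison

Per-strain summaries count at the SNP level: a SNP overlapping two
ORFs adds one to "SNPs in ORFs", and counts as non-synonymous if *any*
of its ORF records is missense, nonsense, stop-loss or start-loss. The
non-synonymous tally therefore contains the ISCMs, which is how the
strain summaries here are conventionally reported. Whether a
two-ORF SNP should count once or twice is genuinely ambiguous in
strain-summary tables; "once" was chosen because the alternative makes
the column depend on annotation density rather than on the strain.

The ISCM matrix is per-ORF, not per-site: any nonsense call for
(ORF, strain) sets the cell to 1, and two different premature stops in
one ORF are distinguishable only in the long-format table. Sharing
classification is row-wise: an ORF is unique to a strain when its row
has exactly that one 1. The unique-ISCM frequency divides a strain's
unique ISCMs by its unique non-synonymous SNPs, rounded to three
decimals; a zero denominator is reported as undefined (`NA`), not 0.

# Tree building and branch attribution

Strain distances are symmetric-difference counts over
(chromosome, position, alt) keys — the same site with a different
alternate allele is a different SNP — with the reference included as
the empty profile. Neighbor joining (via `ape::nj`) turns the matrix
into a tree; input rows are sorted lexicographically so agglomeration
order, and hence output, is deterministic, and negative branch lengths
are clamped to zero with a warning. NJ is used deliberately instead of
likelihood methods: the scientific payload here is *attribution*, which
needs only a topology, and a user-supplied Newick tree bypasses tree
building entirely.

The tree is rooted on the branch leading to the reference, and every
branch is numbered in post-order (`b1`, `b2`, ...), so branch-level
reports are reproducible for a given topology. A SNP is attributed to
the unique branch whose subtended clade equals its carrier set exactly:
singleton sets land on leaf branches (strain-unique), clade-wide sets
on internal branches (lineage-specific), and all-strain sets on the
branch separating the cohort from the reference (species-specific).
Carrier sets matching no clade are homoplasious under the tree and are
reported in an explicit unassigned set; forcing them onto a
"best" branch would silently overstate lineage specificity. Counts are
kept in three layers per branch — all SNPs, non-synonymous SNPs,
ISCMs — mirroring the "unique non-synonymous / unique ISCM" numbers
usually drawn on strain phylogenies.

# The simulator: what it emulates and what it does not

`simulate_cohort()` generates a multi-chromosome genome with
non-overlapping single-exon ORFs on both strands (ATG start, terminal
stop, stop-free interior), a rooted strain tree, and per-strain SNP
sets built by planting mutations on branches so that each SNP is
carried by exactly one clade. Consequence classes are enforced
constructively: a nonsense SNP picks a codon one substitution from a
stop, a synonymous SNP a substitution that preserves the amino acid,
and so on, always avoiding codon 1 and the natural stop (except for
planted stop-losses) so classes stay unambiguous; no two SNPs share a
codon, so compound-codon ambiguity never contaminates ground truth.

Defaults describe a desk-scale cohort: 3 chromosomes of 30 kb, 40 ORFs
of 100–400 codons, 8 strains, 25 SNPs per branch plus 10 species-wide
SNPs, effect fractions 25% synonymous / 50% missense / 5% nonsense /
1% stop-loss with the remainder intergenic, and homoplasy 0. The
fractions keep coding SNPs in realistic proportion (roughly
three-quarters of SNPs in gene-dense yeast genomes fall in ORFs, and
nonsense changes are rare relative to missense); the per-branch counts
guarantee every branch is separated by many SNPs, so
symmetric-difference distances are additive and NJ provably recovers
the planted topology at homoplasy 0. One global seeded RNG drives all
choices; the same seed reproduces the dataset byte-for-byte.

What the simulator does not model — and therefore what passing tests do
*not* show about real data: sequencing error and coverage (inputs are
taken as called SNP lists), diploidy and heterozygosity (strains are
haploid profiles, as lab segregants are), linkage and recombination,
overlapping or spliced genes, mutation-rate heterogeneity along the
genome, and recurrent mutation beyond the explicit homoplasy knob.
Real cohorts will put some SNPs in the unassigned set and real trees
will have poorly supported branches; the planted-truth guarantees are
statements about the algorithms, not about biology.

The known-mutation catalogue fixture (`known_iscm_fixture()`) is
synthetic in the same sense: for each of the 26 catalogued nonsense
mutations it builds an ORF of the catalogued protein length and strand
whose mutated codon, reading frame and genomic SNP coordinate match the
catalogue, with random sense codons as filler. Only the catalogued
structure is faithful; the filler sequence is not yeast DNA.

# Numerical and degenerate-input choices

* Ties in NJ agglomeration are resolved by the lexicographic strain
  order of the input matrix.
* Multiallelic VCF records are rejected outright rather than split;
  one alternate allele per site per strain is an invariant the carrier
  set logic relies on.
* Indels in VCFs are skipped with a logged count; the annotator is a
  substitution annotator.
* Empty variant tables are legal everywhere and produce empty, typed
  outputs (and all-zero summaries), not errors.
* Output rows are sorted (chromosome, position, strain) and all
  writers are deterministic, so repeated runs are byte-identical.

# Test problem sizes

The test suite runs module tests on scaled-down cohorts (5 strains,
2 × 15 kb chromosomes, 15 ORFs, 6 SNPs per branch) and the end-to-end
checks on the default study conditions above; both complete in well
under a minute of simulation time on one CPU. Oracle-equivalence tests
compare the annotator against an independent brute-force oracle that
rebuilds the full mutant CDS, translates both alleles and diffs the
proteins — a different code path from the codon arithmetic it checks.
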