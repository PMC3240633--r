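# iscmscan

Strand-aware SNP consequence annotation and multi-strain comparison for
compact fungal genomes, centred on **inactivating stop codon mutations
(ISCMs)** — single-nucleotide changes that convert a sense codon inside
an ORF into a premature stop (TAA/TAG/TGA) and truncate the protein.

The package is aimed at yeast geneticists comparing resequenced
*Saccharomyces cerevisiae* strains against a reference (e.g. S288C): it
answers, for each strain, which SNPs are synonymous, missense or
nonsense, how long each nonsense truncation is, which ISCMs are unique
to a strain or shared across a cohort, and on which branch of the strain
phylogeny each variant arose. ISCMs matter particularly in
[*PSI*+] strains, where prion-mediated readthrough of stop codons can
phenotypically reactivate otherwise truncated genes.

## What it computes

For a SNP at genomic position *g* inside a single-exon ORF with 1-based
coordinates [*s*, *e*] on strand ±, the coding-frame position is
*c* = *g* − *s* + 1 (plus strand) or *c* = *e* − *g* + 1 (minus strand),
the codon index is *i* = ⌈*c*/3⌉, and the alternate codon is the
reference codon with the strand-adjusted base substituted. Comparing
amino acids under the standard nuclear code classifies the change:
synonymous, missense, **nonsense** (sense→stop, an ISCM), stop-loss
(natural stop→sense, extending the C-terminus to the next in-frame
stop), stop-retained, or start-loss. For a nonsense change in a protein
of length *L*, the reported truncation is

    truncation = L − i

residues lost strictly downstream of the mutated codon, written in the
notation `<ref aa><i><stop codon>` (e.g. `W244TGA`, a 62-residue
truncation of a 306-residue protein).

Cohort layers built on top of the annotator:

- per-strain tallies (total SNPs, SNPs in ORFs, non-synonymous, ISCM);
- an ORF-by-strain 0/1 ISCM presence matrix with unique-vs-shared
  classification and the unique-ISCM frequency (unique ISCMs per unique
  non-synonymous SNP);
- a neighbor-joining strain tree from pairwise SNP symmetric-difference
  distances (the reference enters as the all-reference profile), rooted
  at the reference;
- exact-clade branch attribution: a SNP whose carrier set equals the
  leaf set of a clade is assigned to that clade's branch
  (strain-unique, lineage-specific or species-specific); carrier sets
  matching no clade are reported as unassigned, never forced onto a
  branch.

A seeded simulator generates genomes, ORF sets, trees and per-strain
VCFs with planted consequences and branch assignments, so the whole
pipeline is testable against known ground truth.

## Worked example

The package ships a curated catalogue of the 26 known premature stop
mutations in strains 74-D694 and G600 (`known_iscm_table()`) and a
synthetic genome fixture that realises each of them
(`known_iscm_fixture()`):

```r
library(iscmscan)

f   <- known_iscm_fixture()
ann <- annotate_strain(f$variants, f$orfs, f$genome)
iscm_long_table(ann) |> subset(strain == "G600")
#>   orf_id  gene strain    pos notation truncation_len
#>  YBR074W  <NA>   G600 387247  Q323TAA            653
#>  YNL106C INP52   G600 422546  W651TAG            532
#>  YOR128C  ADE2   G600 566003   E64TAA            507
#>  YOR129C  AFI1   G600 566901  E887TAA              6
```

Every G600 SNP in the catalogue is an ISCM: the `ADE2` row is the
classic `ade2-1` allele (E64TAA), truncating 507 of 571 residues; the
`AFI1` change at codon 887 of 893 removes only 6 residues and is
unlikely to inactivate the protein. The strain-level summary and the
unique-ISCM frequency follow the same annotations:

```r
summarize_strain(subset(ann, strain == "G600"))
#>  strain_id n_snps_total n_snps_in_orfs n_nonsynonymous n_iscm
#>       G600            4              4               4      4

iscm_frequency(14, 680)   # 74-D694: unique ISCMs per unique non-syn SNP
#> [1] 0.021
```

For a full simulated cohort (`sim_config()`, `simulate_cohort()`), the
pipeline stages `run_annotate()`, `run_compare()`, `run_tree()`,
`run_attribute()` and `run_report()` go from FASTA + GFF3 + VCFs to
annotation tables, the ISCM matrix, a rooted NJ tree and per-branch
unique-SNP/ISCM counts. A thin command-line front-end with the same
stages as subcommands is in `inst/scripts/iscm-pipeline.R`.

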