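# phaseprint

Intron-phase fingerprinting and duplication-origin analysis for gene
families in allopolyploid genomes.

Large plant transcription-factor families — the motivating case is the
MIKC MADS-box family of an allotetraploid crop formed from two diploid
progenitors — carry two complementary evolutionary records. Inside the
K-box dimerization domain, the *positions and splicing phases* of
intron insertions are conserved far beyond the surrounding sequence:
each gene yields an ordered signature of `(alignment column, phase)`
pairs with `phase = (CDS nucleotides upstream) mod 3`, and the family
decomposes into a handful of discrete intron patterns (A, B, C, ...)
that track phylogenetic clades. At the genome scale, each family member
in the allotetraploid arose by one of a few routes — inheritance from
progenitor A or C at the syntenic position, tandem duplication,
segmental duplication, or homoeologous exchange (HE, replacement of a
region by the copy from the other subgenome) — distinguishable from
reciprocal-best-hit synteny and identity to the two progenitors.

`phaseprint` is for molecular-evolution researchers who want that whole
analysis as a reproducible pipeline: gene models from FASTA/GFF3,
intron sites/phases, PSSM domain screening, neighbor-joining phylogeny
(p-distance, pairwise deletion, bootstrap), pattern-signature
clustering with a clade-concordance permutation test, the
duplication-origin census, IUPAC promoter-element scanning, and
expression-conservation scoring of sister paralog pairs — all validated
on a bundled, fully deterministic synthetic allotetraploid generator
with truth tables.

## Worked example

The unit of the core analysis is the signature round trip — planting
introns into a CDS and recovering their sites and phases:

```r
library(phaseprint)
sig <- data.frame(codon_index = c(2L, 5L), phase = c(1L, 2L))
gm  <- plant_intron_signature(strrep("GCT", 10), sig)
compute_intron_sites(gm)
#>   cds_offset phase codon_index
#> 1          7     1           2
#> 2         17     2           5
```

The `analysis/` scripts run the full study on the synthetic
allotetraploid (execute them in order; `01` writes the dataset under
`results/synthetic_dataset`, later steps parse it back from FASTA/GFF3
like any real genome):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_gene_models.R
Rscript analysis/03_phylogeny_patterns.R
Rscript analysis/04_duplication_census.R
Rscript analysis/05_promoters_expression.R
```

Selected output (seed 1). Gene structure shows the family's bimodal
intron architecture — type-II members average 5.86 introns, type-I
members none:

```
       class n_genes mean_introns
  background     100         0.00
       typeI       8         0.00
      typeII      35         5.86
```

K-box signature clustering recovers seven pattern classes; the
dominant class holds 54% of classified genes, and patterns are
perfectly concordant with the phylogenetic clades (purity 1.0,
permutation p = 0.001):

```
 label size  frequency                     consensus
     A   19 0.543       96:2;112:0;130:2;148:0;166:1
     B    5 0.143      100:2;112:1;130:2;148:1;166:0
     ...
```

The consensus strings read `column:phase`; the class-A consensus is
the five-site phase pattern 2-0-2-0-1 spanning the K-box window.

The duplication census labels every family gene and recomputes the
percentage shares from its own counts (here 4.65% HE, 13.95% tandem,
13.95% segmental, 67.4% inherited from the progenitors), and sister
pairs show the expected identity gradient — binding domain 98.3%,
full-length protein 92.2%, promoter 91.1% — with 11 of 18
expression-profiled sister pairs scored `same`.

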