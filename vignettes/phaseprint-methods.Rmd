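---
title: "Intron-phase fingerprinting and duplication-origin analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Intron-phase fingerprinting and duplication-origin analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Large transcription-factor families in allopolyploid plant genomes — the
motivating case is the MIKC MADS-box family of an allotetraploid crop
derived from two diploid progenitors — pose two linked questions:

1. **Structure.** Family members share a highly conserved DNA-binding
   domain (the MADS box, ~58 aa, binding CArG boxes `CC(A/T)6GG`) and,
   in the type-II lineage, a coiled-coil dimerization domain (the
   K-box). Within the K-box, the *positions and splicing phases of
   intron insertions* are far better conserved than the surrounding
   sequence, and genes fall into a small number of discrete intron
   patterns that track phylogenetic clades.
2. **Expansion.** In an allotetraploid, each family member arose by one
   of a few routes: inheritance from progenitor A or C at the syntenic
   position, tandem duplication, segmental duplication, or homoeologous
   exchange (HE) — replacement of a chromosomal region by the copy from
   the other subgenome.

`phaseprint` implements both analyses end to end, plus the supporting
stages (domain screening, NJ phylogeny with bootstrap, promoter
cis-element scanning, expression-conservation scoring), and ships a
deterministic synthetic allotetraploid generator with full truth tables
so that every inference can be validated exactly.

# Intron sites and phases

A gene model is an ordered set of CDS segments in transcription order.
An intron site is summarized by the number of CDS nucleotides upstream
of it (`cds_offset`); its **phase** is `cds_offset mod 3` (0 = between
codons, 1 = after the first base, 2 = after the second) and its codon
index is `cds_offset %/% 3`. This is the classical splicing-phase
convention; it is distinct from the GFF3 CDS `phase` column (which
encodes the offset to the next codon start) — the GFF3 column is parsed
but never used as the phase.

Genes whose CDS length is not divisible by 3 (C-terminally truncated
models are common in draft annotations) are retained, flagged
`partial_orf`, and excluded only from protein-level stages. When a gene
has several mRNAs the longest-CDS isoform is used.

# Pattern signatures and clustering

For each family member the intron sites are projected through the
gene's row in the family protein alignment (so positions are
comparable across genes) and restricted to a configured K-box window of
alignment columns. The resulting ordered list of (column, phase) pairs
is the gene's **pattern signature**. Genes whose alignment row covers
less than 80% of the window columns are excluded as having an
incomplete K-box; genes with no intron in the window are reported as
"no K-box introns" and excluded from clustering.

Two signatures are linked when their phase sequences are identical and
each paired column differs by at most `column_tol` (default 2 columns —
the conservation statement in the source material is qualitative, so
the tolerance is exposed in the configuration). Classes are connected
components under single linkage, labelled `A, B, C, ...` in order of
decreasing size (ties broken by the smaller consensus first column),
with a consensus of median columns and modal phases. With
`column_tol = 0` the procedure reduces to exact signature equality,
which is the brute-force oracle used in the tests.

Two deliberate design choices:

* **Variable first site.** Empirically the first K-box intron wanders
  while the remaining 4 sites are fixed, and one pattern lacks an
  interior site while another lacks the last. The optional
  `allow_variable_first` rule lets one leading site differ, or one
  leading/trailing site be absent, between signatures whose lengths
  differ by one. It is **off by default**: with the allowance on, a
  pattern that is a leading/trailing subset of another would merge into
  a single class, collapsing genuinely distinct patterns. It exists for
  exploratory use on real data and is exercised in the unit tests.
* **Frequencies.** Class frequencies are reported over classified genes
  and the denominator is printed alongside, because the published
  percentages for such patterns leave their denominator unstated.
  Labels are size-ranked, not homology-matched to any published letter
  scheme; a user-supplied mapping table can translate them.

Clade-pattern concordance is scored as purity (mean over clades of the
largest within-clade pattern share) with a label-permutation test,
`p = (1 + #{permuted >= observed}) / (n_perm + 1)`.

# Domain screening

In place of a BLASTP + PROSITE screen, a position-specific scoring
matrix is built from a seed domain alignment: columns with non-gap
occupancy >= 0.5 are kept and scores are
`log2(((count + 1) / (n + 20)) / (1/20))` (uniform background,
pseudocount 1). Scanning slides the matrix, keeps windows with
normalized score (score / maximum attainable) >= 0.6, and selects
non-overlapping hits greedily, best score first, ties to the leftmost
start. All four constants are configuration-exposed; the source
procedure applied manual, qualitative removal criteria, so the
quantitative defaults here are this package's own choices.

# Phylogeny

Distances are p-distances (proportion of differing sites) with
pairwise deletion by default: each pair is compared over the sites
ungapped in both rows; complete deletion restricts to globally
ungapped columns. Pairs with no comparable site are flagged `NA` and
abort neighbor joining with an instruction to re-run under complete
deletion — silent imputation would distort the topology.

Neighbor joining is the Saitou–Nei algorithm with a deterministic
tie-break: Q-matrix minima are resolved toward the lexicographically
smallest pair of representative taxon ids, making the output invariant
to input order. Negative branch-length estimates are clamped to zero in
the returned tree (downstream tools reject negatives) with the
unclamped tree kept in an attribute. On additive matrices the tree and
its branch lengths are recovered exactly; the tests verify this against
independently generated random additive trees and a four-point-condition
quartet oracle, and cross-check the topology against `ape::nj`.

Bootstrap resamples alignment columns with replacement; supports are
the percentage of replicate NJ trees containing each internal
bipartition, mapped onto the full-data tree (no consensus tree is
computed, matching the display convention of the common desktop tools).
Clade assignment gives each unlabeled tip the subfamily of the smallest
bipartition side containing it and at least one reference taxon,
provided that side carries references of a single subfamily; otherwise
`unassigned`.

# Duplication-origin census

Anchors are reciprocal best hits under global Needleman–Wunsch
alignment (BLOSUM62, affine gaps: opening 10, extension 0.5), with
score ties broken by percent identity then lexicographic id. Anchors
are chained per chromosome pair into collinear blocks by dynamic
programming maximizing `anchors - 0.1 * skipped ranks`, rank gaps at
most `max_gap` on both genomes, both orientations searched; blocks
need `min_block` anchors. Defaults `max_gap = 25`, `min_block = 4`
(the original synteny-tool parameters are unreported).

Family genes of the derived genome are labelled with precedence:

1. **tandem** — same chromosome, rank difference <= 2, global identity
   >= 70%; both members of the pair are labelled.
2. **HE** — the gene is an anchor of, *or lies within the rank span
   of*, a derived-vs-progenitor block on its chromosome, and its
   best-hit identity to the opposite progenitor exceeds that to its own
   progenitor by >= 2 points, in a run of >= 2 consecutive such family
   genes. The span rule matters: after an exchange, the exchanged copy
   usually loses its reciprocal-best-hit anchor (the un-exchanged
   homoeolog on the other subgenome is closer to the progenitor), so an
   anchors-only rule would never fire. A known-HE-blocks interval table
   can replace detection.
3. **inherited_A / inherited_C** — anchor of a derived-progenitor
   block on the expected subgenome.
4. **segmental** — anchor of an intra-derived block *not explained by
   homoeology*. A block is called homoeologous when at least half of
   its anchor pairs link two genes that are each themselves anchored in
   derived-progenitor blocks; this keeps the genome-wide A-C
   homoeologous blocks from being mislabelled as segmental
   duplications.
5. **unassigned** otherwise.

Sister pairs are family proteins whose binding-domain identity (>= 90%)
and full-length identity (>= 80%) both clear thresholds, merged
greedily by descending full identity into mutual groups of up to four.
Promoter identity (2 kb upstream by default) uses the same aligner on
nucleotides. The thresholds are this package's operationalization of a
qualitative "very high identity" criterion, chosen so that recent
homoeologous/duplicate pairs qualify while clade-mates (typically well
under 70% full identity at the simulated divergences) do not.

# Promoters and expression

Promoter scanning is exact IUPAC-degenerate matching on both strands,
reverse-strand hits reported at forward coordinates; all overlapping
matches are reported, and summaries count a gene once per motif, which
makes them insensitive to that choice. The bundled catalog holds
literature consensus patterns for the classic light (group A), stress
(group B) and hormone (group C) elements and is explicitly replaceable
by a user catalog.

Expression profiles are FPKM vectors over tissues. Categories:
`not_expressed` if every tissue is below `t_off = 1` FPKM; `weak` if
the maximum is below `t_weak = 5`; `expressed` otherwise. The source
material quantifies neither boundary, so both are exposed and the
downstream threshold-sensitive percentages are not used for
validation. Expressed genes are clustered by average-linkage
hierarchical clustering on `1 - Pearson r` of `log2(FPKM + 1)`
profiles, cut into `k_blocks = 3` groups. Pair conservation: `same`
when `r >= 0.8` and the categories agree, `divergent` when `r < 0.3`
or exactly one member is not expressed, `similar` otherwise; constant
profiles (undefined r) fall back to category comparison. Note a
consequence of the rule as stated: a pair in which *both* members are
not expressed is judged by its (noise-dominated) correlation and will
usually come out `divergent`; the tests therefore assess conservation
on pairs with an expressed archetype.

# The synthetic allotetraploid generator

The generator is first-class, tested code — not a fixture. It builds an
ancestor gene complement on homoeologous chromosome sets, derives
progenitors A and C by one branch of i.i.d. per-site substitution each,
and derives the allotetraploid subgenomes from the progenitors by
another branch, then plants events on the derived genome (HE first,
then segmental window copies, then tandem insertions; duplicated copies
receive substitution at half the branch rate so source and copy are
distinguishable). Defaults — 3 homoeologous chromosome pairs of 20
genes, an 18-member family (15 type-II-like with K-box patterns from a
7-pattern library, 3 type-I-like), divergence 0.03 per site per
branch, 3 tandem + 4 segmental + 1 HE event, 800 bp promoters, 50
tissues, pair correlation target 0.9 — are the standing study
conditions; every figure in the tests and the acceptance report is
computed under them (or under explicitly stated smaller/larger
instances, listed below).

Modelling choices worth knowing:

* **Purifying selection on the family.** Family CDS mutate at half the
  neutral rate, and the binding domain (first 58 codons) at one tenth.
  This reproduces the empirical configuration of recent paralog pairs —
  near-complete binding-domain identity with visibly diverged
  full-length proteins and promoters — and keeps domain screening and
  reciprocal-best-hit anchoring meaningful at realistic divergences.
* **No indels in CDS.** Substitution-only evolution keeps ORFs intact
  and intron positions fixed, so pattern recovery is unconfounded by
  alignment error; internal stop codons created by substitution are
  repaired deterministically (third base -> C). The family protein
  "alignment" is therefore ungapped by construction.
* **Exact promoter truth.** Planted motif instances are drawn so they
  do not internally match any other catalog motif, are masked from
  mutation, and the background is re-randomized until the scan count
  equals the planted count — so truth-table motif counts are exact by
  construction, on both strands.
* **Expression archetypes.** Each clade has a mean log2 profile drawn
  with across-tissue sd `expr_noise_sd * sqrt(rho / (1 - rho))`, which
  makes the expected sister-pair correlation equal the `pair_rho`
  target; sister genes share the archetype and differ by independent
  noise. Planted not-expressed and weak genes use flat archetypes with
  reduced noise so the planted category is recoverable under the
  default thresholds.
* **Intron sequences** are fixed-length (90 bp) with canonical GT...AG
  termini, masked from mutation at the termini.

What the generator does **not** emulate: codon models or rate
heterogeneity, indels, transposable elements, UTRs and alternative
splicing, gene loss/fractionation after polyploidy, and real
read-count noise in expression. Passing tests therefore demonstrate
correctness of the inference machinery under a clean evolutionary
model, not robustness to annotation error or alignment ambiguity in
real genomes.

# Numerical conventions and problem sizes

Percentages in census tables are rounded half-up at the printed
precision (`round_half_up`); means per subgenome to one decimal;
per-class intron means to two. All randomness (generator, bootstrap,
permutation tests) runs under an explicit seed through a
save-and-restore RNG wrapper, so identical configurations give
byte-identical outputs.

Problem sizes used by the validation suite, chosen as desk-scale
instances of the study conditions: the shared unit-test dataset is a
2+2-chromosome, 8-family-gene allotetraploid; origin classification is
scored on the full default configuration (43 derived family genes);
pattern recovery on a 200-gene planted cohort at divergence 0.05;
neighbor joining on random additive trees of 4–8 taxa; collinear
chaining against an exhaustive-subset oracle on up to 10 anchors over
100 instances; IUPAC scanning against a regular-expression oracle over
1000 random promoter/catalog instances.

# Known limitations

* Pattern class labels are stable only within a run; comparing labels
  across datasets requires the consensus-matching presence matrix
  (`cross_set_pattern_presence`), not the letters.
* The PSSM has no insert/delete states; strongly indel-ed domains in
  real proteins would need a profile HMM.
* HE detection presumes progenitor genomes are available; with only
  published HE intervals, use the known-blocks input path.
* The segmental/homoeology discrimination relies on the 50%
  both-inherited anchor-share rule; exotic block structures (nested
  duplications inside HE regions) may need manual review.
* p-distances can violate the triangle inequality; nothing downstream
  assumes it.
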