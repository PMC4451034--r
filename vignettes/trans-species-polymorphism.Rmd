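---
title: "Detecting trans-species polymorphism in cloned gene families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting trans-species polymorphism in cloned gene families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transpoly)
```

## The problem

Antimicrobial peptide genes such as the cathelicidins of Atlantic cod
(*Gadus morhua*) and its relatives can carry allelic lineages that are
older than the species themselves. When alleles from different species
cluster together in a genealogy — rather than each species forming its
own clade — the variation is *trans-species*, the classic signature of
long-term balancing selection, familiar from vertebrate MHC. Detecting
this pattern in PCR-cloned Sanger libraries requires untangling three
confounded layers of variation:

1. **Paralogy.** A single primer pair can amplify several duplicated
   genes (here: three clusters, conventionally Cath1, Cath2, Cath3).
2. **Allelic variation** within each paralog, potentially ancient.
3. **PCR error**, which appears as singleton variants in individual
   clones.

`transpoly` implements each analysis step as a tested function and the
whole chain as `run_all()`: clone-label parsing, paralog clustering,
singleton screening, representative selection, neighbor-joining trees,
sliding-window diversity statistics, linkage disequilibrium, a
counting-based per-codon selection test, a permutation test for
allele-versus-species clustering, and DAPC. A synthetic clone-library
generator with known truth exercises every stage.

## The screening rule

Errors arise during PCR amplification and appear mostly as singletons
among the clones of one individual. The screening rule operates on
groups of clones keyed by individual x paralog cluster:

* A column where exactly one clone differs from an otherwise homogeneous
  group is a **singleton candidate**.
* The candidate is **masked** to the group majority unless the same
  column is also variable among the clones of at least one *other*
  individual in the same cluster, in which case it is **retained** as a
  real SNP (recurrence is evidence against PCR error).
* Groups of size one are never masked: there is no within-individual
  evidence.

Design choices the rule's statement leaves open, fixed here:

* **Two-clone disagreements.** Both variants are singletons. If neither
  recurs elsewhere, the clone disagreeing with the cluster-wide majority
  is masked; a cluster-wide tie masks neither and flags the column
  `unresolved`. This is the least destructive deterministic resolution,
  and it means an error that lands on the majority side of a two-clone
  group is inherently unremovable — the recovery tests condition on
  this.
* **Indels** count as a fifth character state, so a one-clone gap is
  maskable; columns containing `N` are skipped.
* **Masked singletons are replaced** by the group majority base (rather
  than dropping the column), and every decision is recorded, so the
  downstream statistics keep the full alignment length.
* Recurrence is evaluated **within the same cluster only**: variability
  in a different paralog is not evidence for an allelic SNP.

Screening is idempotent, and a clone that alone represents a cluster for
its individual is always kept. Identical corrected sequences within a
group collapse to a consensus record (`<barcode>-cons.<sp>.<loc>`), one
representative per distinct form — the step that reduced the study
design's 97 clones to the deposited 43.

## Statistics

**Diversity.** `site_stats()` computes segregating sites S and the mean
pairwise difference; windows (`sliding_windows()`, default 100 bp with a
25 bp step, the published windowing) report per-site pi, Watterson's
theta = S / (a1 * sites), and Tajima's D with the standard coefficients.
Columns containing a gap are excluded per window (complete deletion
within the window, the DnaSP-style convention), and windows with fewer
than 10 usable sites are flagged low-confidence. |D| > 2 is used as the
significance annotation. D is undefined at S = 0 and returned as `NA`.

**Linkage disequilibrium.** `ld_matrix()` computes D' = D / Dmax over
biallelic sites passing a minor-allele *count* threshold (e.g. 3 of 36
sequences, matching how such figures state their filters); sequences
with a gap at either site of a pair are dropped pairwise. Indel
presence/absence is not treated as a site by default.

**Codon selection test.** A counting (SLAC-style) test per codon:
ancestral codons by Fitch parsimony with deterministic tie-breaking
(alphabetically first codon), synonymous/non-synonymous changes counted
along every branch with Nei-Gojobori pathway averaging (orderings
through stop codons excluded), expected site proportions ES/EN averaged
equally over observed and reconstructed codons, and one-tailed binomial
tail probabilities. Parsimony rather than likelihood reconstruction is
used because NJ branch lengths are approximate and the counting test is
robust to the choice; ties are recorded. Regions are read in the
annotation's frame; codons containing an indel in any sequence are
reported `excluded`, so only codon positions present in all groups
contribute. Reporting thresholds are p < 0.05 and the relaxed p < 0.2.

The test is *valid but conservative*: per-codon totals are small
discrete counts, parsimony undercounts changes, and pathway averaging
produces fractional counts that dilute extreme tails. Under neutral
codon simulation (`simulate_codon_alignment()`, 24 sequences, 200
codons, tree length 8 — chosen so per-codon substitution counts average
above ten) the empirical rejection rate at p < 0.05 is about 0.5-2.5%,
not the nominal 5%; the test suite asserts size at-or-below nominal and
calibration of the realised non-synonymous fraction. Power against
dN/dS = 5 at 20% of codons is roughly 20-50% recall at p < 0.2 under
the same conditions.

**Trees.** Distances are p-distances (pairwise deletion by default);
trees are standard neighbor joining with negative branches clamped to
zero; bootstrap support resamples columns (default 100 replicates).
Externally built trees (e.g. maximum likelihood) can be supplied as
Newick and used everywhere a tree is accepted.

## Quantifying "clusters by allele, not by species"

The qualitative observation — species intermingled within each allele
clade — is operationalised as the **Fitch parsimony score of species
labels** on the tree. The score's minimum is (number of species - 1);
species-monophyletic trees achieve it, intermingled trees exceed it.
`transpecies_test()` reports:

* `p_species_clustering` = P(null <= observed) under label permutation —
  *small* means species cluster more than random (no trans-species
  signal);
* the **intermixing index** (observed - min) / (E[null] - min), 0 for
  species-monophyletic trees, near 1 for random intermixing.

Permutations are **stratified within paralog clusters** by default and
scores summed over the clusters' induced subtrees, because paralogy
itself scatters every species across clusters and would otherwise
masquerade as allelic trans-speciation. Two properties matter for
interpretation. First, even in the balancing regime each species retains
internal coherence *within* an allele class (its sequences are each
other's closest relatives), so the index typically lands well below 1
(0.3-0.9 across generator replicates) — the regime contrast is index = 0
(neutral) versus index > 0 (balancing), not 0 versus 1. Second, the
parsimony score is conservative: if only one species is split across
allele classes, a backbone assignment can still explain the tree with
the minimum number of changes, so occasional index-0 replicates occur
under genuine trans-species architecture. Detection of species
monophyly in the neutral control is similarly limited by permutation
granularity when clusters sample few species; replicates exist whose
exact permutation p cannot fall below 0.05.

DAPC (PCA on the one-hot genotype matrix, then linear discriminant
analysis on the retained scores; the reproduction profile keeps 10 PCs
and 3 discriminant functions) provides the complementary view:
allele-defined groups separate cleanly while species-defined groups
overlap, measured as reassignment accuracy.

## The generator

`simulate_dataset()` emulates the study conditions and is the testbed
for every stage:

* **Design**: 27 individuals (19 Atlantic cod across eight localities,
  two each of *G. chalcogrammus*, *G. macrocephalus*, *G. ogac*,
  *B. saida*), per-individual clone counts from the study's bookkeeping
  column (97 clones; mostly 3, up to 12), six-digit barcodes and
  species.locality labels.
* **Genealogy**: three paralogs duplicating 7.5 million generations ago;
  two allele classes per paralog originating 2.4 million generations ago
  — older than the deepest species split (1.6 million generations, i.e.
  ~8 mya at a 5-year generation), and far above the 4Ne neutral fixation
  time with Ne = 10,000 — so every species inherits every class: the
  balancing regime. Species splits follow the literature (~4 mya for the
  Atlantic/Pacific splits). `neutral_control()` instead lets allele
  variation arise within species (~2Ne generations deep): no
  trans-species classes, species monophyletic within paralogs.
* **Mutation**: Jukes-Cantor; the per-site per-generation rate 1e-8 puts
  within-cluster divergence in the observed 1-3% range and paralog
  divergence near 15%, comfortably split by the 0.10 single-linkage
  clustering threshold. No model is claimed for the real data; the rate
  is a configuration default, not an estimate.
* **Indels**: class- and paralog-private deletions confined to intron 3
  (where length variation concentrates in the real data), so exon frames
  stay intact. No recombination or gene conversion (none was detected in
  the source data); four-gamete pairs in generator output therefore
  reflect recurrent mutation at deep divergence, not recombination.
* **Clone sampling**: up to two allele copies per amplifiable paralog
  per individual, paralog dropout probability 0.5 (emulating primer
  bias/ascertainment; at least one paralog always amplifies), clones
  drawn uniformly from the copies, independent Poisson(e * L) singleton
  PCR errors per clone at rate e = 1e-3 per site.

What the generator does *not* emulate: demographic sweeps or expansions
(so the published negative-D gene has no synthetic counterpart),
chimeric/recombinant PCR artifacts, copy-number variation, gene
conversion, and sequencing quality structure. Passing recovery tests
therefore demonstrate correctness of the algorithms under the stated
genealogical model, not robustness to those processes.

## Problem sizes and determinism

Every stochastic step takes an explicit seed, and datasets are
byte-identical given the seed. The test suite uses 20 balancing
replicates at the full study design (97 clones x 1300 bp) for recovery
checks, 5 neutral controls, 200-codon simulations for the selection
test's size and power, and exhaustive enumeration oracles (all 61 sense
codons, all orderings of codon pathways, internal-state enumeration for
parsimony on trees of up to 6 leaves, 50-100 random cases for the
distance/NJ/diversity oracles). Thresholds for the stochastic
properties (intermixing index, codon-test recall) were fixed once from
pilot runs at these conditions and are documented where they appear.

## Worked example

```{r example, eval = FALSE}
library(transpoly)

d <- simulate_dataset(sim_config(seed = 1))
res <- run_all(d$aln, annotation = default_annotation(),
               n_perm = 999, seed = 1, out_dir = "run1")

res$transpecies
res$dapc_alleles$accuracy
head(res$windows[["C2"]])
```

The `analysis/` directory contains the same chain as numbered scripts
(`01_simulate.R` ... `05_codon_selection.R`) writing their tables under
`results/`.
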