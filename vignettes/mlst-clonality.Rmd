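---
title: "Typing, clonality and recombination analysis of MLST data"
author: "mlstkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Typing, clonality and recombination analysis of MLST data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlstkit)
```

## The analysis problem

Multilocus sequence typing characterises bacterial isolates by short
(400–650 bp) internal fragments of several housekeeping genes. The scheme
this package is built around uses eight protein-coding loci (clpX, groEL,
murC, murE, pheS, pyrG, recA, uvrC; `lp_study_loci()`), the configuration
used for typing *Lactobacillus plantarum*, a lactic acid bacterium found
in pickles, sourdough and fermented dairy foods. From one complete
sequence matrix — every isolate sequenced at every locus — the package
answers three families of questions:

1. **Who is related to whom?** Alleles, sequence types (STs), clonal
   complexes and spanning trees describe short-range relatedness at
   allele granularity.
2. **How diverse is each locus?** Polymorphic sites, nucleotide
   diversity, G+C content and dN/dS summarise sequence-level variation
   and selective constraint.
3. **Does the population recombine?** The index of association,
   permutation tests and split decomposition probe whether alleles at
   different loci assort independently (free recombination) or travel
   together (clonality).

## Models and procedures

### Typing

Each distinct nucleotide sequence at a locus is an allele; numbering is
dense (1..K) in first-observation order. An isolate's allelic profile is
the vector of its allele numbers in locus order, and identical profiles
share an ST. Because historical ST numbering in published schemes depends
on sample processing order, `assign_profiles()` makes its own numbering
deterministic by sorting isolates lexicographically by ID before
first-observation numbering; the partition of isolates into STs — the
scientifically meaningful object — is invariant to input order, and
comparisons with other numbering schemes are up to relabeling.

### Clonal complexes and founders

Two STs are linked when they share at least `group_threshold` of the L
alleles. The default is L − 1 (7 of 8 here), the natural generalisation
of the classic eBURST default of 6/7 at seven loci: a link means a single
locus variant (SLV). Clonal complexes are connected components with at
least two member STs; remaining STs are singletons. The founder of a
complex is its member with the most SLV partners — the genotype most
consistent with being the ancestor of a radial burst — with ties broken
by DLV count, then isolate count, then smallest ST number, and the
applied tie-break is reported. Raising the threshold can only refine the
partition (a property the tests assert).

### Minimum spanning tree

The MST is computed over the complete graph on STs weighted by allelic
distance. Because the commercial tool that popularised MLST spanning
trees does not publish its tie-breaking, edge selection here is made
fully deterministic and documented: a Kruskal scan sorted by (weight,
larger summed endpoint SLV counts, larger summed isolate counts, smaller
ST pair). Edges are annotated with the conventional display classes
(distance 1 bold, 2 thin, 3 dotted, larger suppressed in display only —
never removed from the tree itself). Exact topology can differ from
trees drawn by other software at tied weights; total weight cannot.

### Diversity statistics

* **Polymorphic sites**: a site counts iff at least two distinct
  determined (non-N) bases occur there.
* **π** is the mean, over all unordered isolate pairs, of the proportion
  of differing sites among the pair's mutually determined sites — the
  plain mean, no n/(n−1) small-sample factor, matching the "average
  difference between two randomly selected isolates" definition.
  Statistics default to all isolates rather than deduplicated STs
  (`unit = "sts"` switches), since frequency-weighted diversity is what
  the population sees.
* **sSNP/nSNP**: a polymorphic site is classified by comparing observed
  complete codons that differ only at that site; a site can carry both
  labels (e.g. a third position where Leu–Leu and Ile–Met contrasts
  coexist), so sSNP + nSNP ≥ polymorphic sites is legitimate.
* **dN/dS** follows Nei–Gojobori (1986): per-codon synonymous site
  fractions (mutations to stop codons excluded from the opportunity
  count), pairwise observed differences averaged equally over minimal
  mutational pathways that avoid stop codons, Jukes–Cantor correction
  d = −(3/4)·ln(1 − 4p/3), means over pairs. `dnds_correction = "none"`
  exposes the uncorrected proportions. Conventions for degenerate cases:
  dN = 0 reports a ratio of 0; dS = 0 < dN is reported as *undefined*,
  never as a number; a saturated proportion (p ≥ 3/4) drops the pair
  from the affected statistic's mean only, with a warning — this keeps
  dN estimable on very short fragments whose synonymous opportunity is
  a single site.

### Linkage disequilibrium

With V_D the population variance (divided by the number of pairs) of
pairwise allelic mismatch counts and V_e = Σ h_j(1 − h_j) its
expectation under inter-locus independence, I_A = V_D/V_e − 1 and
I_A^S = I_A/(l − 1). The per-locus mismatch probability h_j uses the
unbiased n/(n−1) factor by default (the LIAN convention;
`hj_bias = "biased"` switches), and the unit of analysis defaults to
isolates with a unique-ST mode, since published analyses use both and
rarely say which. Significance comes from independently permuting each
locus' allele column; p = (1 + #{V_D* ≥ V_D}) / (1 + n_perm), the +1
avoiding p = 0 artifacts. Default 1000 permutations.

### Phylogeny

Kimura two-parameter distances treat transitions and transversions
separately; positions containing N are excluded pairwise, consistent
with the diversity module. Neighbour joining is the standard Saitou–Nei
agglomeration with the Q criterion; ties in pair selection go to the
smallest node-index pair, and negative branch estimates are clamped to
zero with the deficit moved to the sibling branch, so output trees are
deterministic and non-negative. Trees are built on ST representatives
(one row per ST from the ST's allele sequences), not isolates, because
duplicate sequences carry no phylogenetic signal and only clutter the
leaf set. Bootstrap support resamples alignment columns with
replacement; taxa are canonically sorted before any draw so support
values are invariant to input row order. The replicate count defaults to
1000 and is configurable everywhere it appears.

### Split decomposition

The isolation index of a bipartition A|B is

α(A,B) = ½ · min over i,j∈A, k,l∈B of
[max(d(i,k)+d(j,l), d(i,l)+d(j,k), d(i,j)+d(k,l)) − d(i,j) − d(k,l)],

with i = j allowed (covering singleton sides). Splits with α > 0
(d-splits) are found by incremental taxon insertion — extend each held
split both ways when a taxon is added, keep candidates with positive α —
which is exact because d-splits form a weakly compatible system. An
exhaustive-enumeration mode (≤ 12 taxa) serves as an internal oracle.
For an additive (tree) metric the d-splits are exactly the tree's edges
with α equal to branch lengths and fit index 100; crossing d-splits
with positive weight are the box/network signature of recombination.
Trivial splits are always retained; any display threshold on α is a
presentation choice (default 0).

## The synthetic-data generator

`simulate_population()` provides ground-truth datasets in place of
downloaded sequence archives. The model: a random in-frame ancestral
coding sequence per locus; `n_founders` founder genotypes each diverged
from the ancestor at `founder_divergence` per site; isolates assigned to
founders with harmonically decaying lineage sizes (every founder keeps
at least one isolate, the largest lineage dominates — mirroring the
shape of real CC size distributions); then `generations` rounds of
per-site point mutation (transition probability titv/(titv+1)) followed
by whole-locus recombination (per isolate, probability
`recombination_rate` of replacing one uniformly chosen locus with the
same locus from a uniformly chosen other isolate). A coding guard
rejects substitutions that would create in-frame stop codons. Every
applied event is logged, and `replay_truth()` reconstructs the emitted
sequences bit-identically from founders plus logs — the correctness
contract of the generator.

Default parameters were chosen once to make the default dataset resemble
a natural *L. plantarum* MLST study population in its headline shape —
186 isolates, 8 coding loci of 415–641 bp, ten planted lineages,
concatenated π around 0.005, roughly 60–75 STs with a dominant complex
of ~70 isolates and a large fraction of single-isolate STs:

| parameter | default | rationale |
|---|---|---|
| `n_isolates` | 186 | study-scale population |
| `loci` | the eight study loci | 415–641 bp coding fragments |
| `n_founders` | 10 | one per planted complex |
| `founder_divergence` | 0.003 /site | inter-lineage π ≈ 0.005–0.006 |
| `mutation_rate` | 4 × 10⁻⁶ /site/gen | ~0.4 expected mutations per isolate over the run: ~40% of isolates acquire a private ST |
| `titv_ratio` | 2 | typical bacterial transition bias |
| `recombination_rate` | 0.002 /isolate/gen | "occasional" whole-locus exchange (a handful of events per run) |
| `generations` | 25 | with the rates above, sets the event budget |

**What the generator does not emulate** — and hence what passing tests
do and do not show about real data: there is no selection, so simulated
dN/dS scatters around 1 and nSNPs outnumber sSNPs, unlike real
housekeeping genes under purifying selection (dN/dS ≪ 1); the
within-lineage genealogy is star-like (all isolates descend
independently from their founder), so intermediate genotypes are rarer
than in a true birth–death genealogy; recombination is whole-locus
allele replacement with no intragenic breakpoints — appropriate for
allele-granularity linkage statistics, silent about gene-internal
mosaics; there is no demography, migration or sampling bias. Tests
passing on this generator validate the estimators and their mutual
consistency, not any biological claim about a particular species.

## Numerical and design choices

* Coordinates are 0-based half-open everywhere (boundaries, site lists).
* 'N' is accepted on input; every statistic excludes N-containing
  positions pairwise, never listwise. Sequences differing only by N
  placement are distinct alleles (conservative: no silent merging).
* Reading frames are auto-detected per locus as the frame with zero
  internal stop codons across distinct sequences, ties toward offset 0 —
  fragment trimming coordinates rarely come with frame annotations.
* The eight study loci's fragment lengths sum to 4270 bp while the
  concatenated alignment length reported alongside them in the
  literature is 4251 bp; the package surfaces its own computed total and
  forces no agreement.
* Degenerate inputs degrade softly where a report should still exist
  (single ST: one-leaf tree, empty split system, MST with no edges,
  linkage marked undefined) and hard-error where a number would be
  meaningless (π of one sequence, I_A with all loci monomorphic,
  saturated K2P pairs).
* The pipeline (`run_mlst_pipeline()`) runs type → eburst → mst →
  diversity → linkage → tree → splits with structured stage logs to
  stderr, results only in files, and a manifest (config echo, versions,
  seed, stage wall times) sufficient to re-run bit-identically; stage
  failures halt with the stage named and partial outputs preserved.

## Problem sizes used in validation

The test suite validates estimators against independent brute-force
oracles (double loops, exhaustive spanning-tree and bipartition
enumeration, BFS components) on 200+ random instances of ≤ 20 sequences
/ ≤ 8 taxa, checks closed forms (K2P, single-codon dN/dS cases, NJ
recovery of additive 4-taxon trees), and exercises ground-truth recovery
on 20 replicated 3-founder populations of 60 isolates with the
recombination response of I_A^S measured over 5 rates × 20 replicates.
The acceptance script analyses one 186-isolate default population with
1000 linkage permutations and 100 bootstrap replicates — sizes chosen to
keep a full from-scratch rerun comfortable on a laptop while leaving
Monte-Carlo error well below the effect sizes being checked.

## Known limitations

* ST and allele numbers are package-internal; mapping onto a published
  scheme's historical numbering requires that scheme's allele FASTAs.
* eBURST founder confidence (bootstrap on founder assignment) is not
  implemented; founder choice is a point estimate with documented
  tie-breaks.
* Split decomposition is exact but O(n⁴)-per-candidate; beyond ~100 taxa
  it becomes slow, which is acceptable for ST-level analyses.
* No Bayesian population-structure or ClonalFrame-style recombination
  rate estimation; the linkage and split-decomposition modules carry the
  recombination inference.
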