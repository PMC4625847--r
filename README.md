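# mlstkit

Multilocus sequence typing (MLST) and clonal population analysis for
bacterial isolates, built for housekeeping-gene fragment data of the kind
used to type *Lactobacillus plantarum* and other lactic acid bacteria:
eight protein-coding fragments of 415–641 bp per isolate, a complete
sequence matrix, and questions about clonality, recombination and niche
structure.

The package covers the full analysis chain in one place:

* **Typing** — every distinct nucleotide sequence at a locus is an allele;
  the vector of allele numbers (one per locus) is the isolate's allelic
  profile; identical profiles share a sequence type (ST).
* **Clonal complexes (eBURST-style)** — STs sharing at least *L* − 1 of
  *L* alleles with another member are linked; connected components with
  two or more STs form clonal complexes (CCs), and each CC's founder is
  the member with the most single-locus variants (SLVs), ties broken by
  DLV count, isolate count, then ST number.
* **Minimum spanning tree** — a deterministic Kruskal MST over the
  complete allelic-distance graph, with goeBURST-inspired tie-breaks
  (summed SLV counts, summed isolate counts, smallest ST pair).
* **Diversity statistics** — per-locus and concatenated polymorphic
  sites, nucleotide diversity π (mean pairwise difference per site),
  G+C%, synonymous/nonsynonymous site classification, and Nei–Gojobori
  (1986) *d*N/*d*S with Jukes–Cantor correction.
* **Linkage disequilibrium** — index of association
  *I*<sub>A</sub> = *V*<sub>D</sub>/*V*<sub>e</sub> − 1 and its
  standardized form *I*<sub>A</sub><sup>S</sup> = *I*<sub>A</sub>/(*l* − 1),
  with a seeded permutation test (per-locus column shuffling). Both are
  zero in expectation under free recombination and positive under
  clonality.
* **Phylogeny** — Kimura two-parameter distances
  (*d* = −½ ln(1 − 2*P* − *Q*) − ¼ ln(1 − 2*Q*)), neighbour joining with
  deterministic tie-breaks, and column-resampling bootstrap support.
* **Split decomposition** — Bandelt–Dress d-splits with isolation index
  α; incompatible splits with positive α render as network boxes, the
  classic signature of recombination.
* **A seeded population simulator** — clonal descent from planted
  founders with titv-weighted point mutation and whole-locus
  recombination, logging every event so datasets replay exactly from
  their truth records.

Everything is data-frame-first and pipe-friendly: tibbles in, tibbles
out, `tidy()`/`glance()` methods on fitted objects, `autoplot()` /
`plot_mst()` for figures, and a `run_mlst_pipeline()` orchestrator that
writes the standard report bundle (PubMLST-style profile TSV, allele
FASTAs, CC table, GraphML/DOT spanning tree, diversity TSV, linkage
JSON, newick tree, NEXUS splits, run manifest).

## Worked example

Simulate a 60-isolate population descended from three founders at the
eight study loci, type it, and test for linkage disequilibrium:

```r
library(mlstkit)

sim      <- simulate_population(sim_config(n_isolates = 60, n_founders = 3, seed = 42))
profiles <- assign_profiles(sim$dataset)
profiles
#> <mlst_profiles> 60 isolates -> 27 STs over 8 loci
#>   alleles per locus: clpX=9 groEL=7 murC=4 murE=8 pheS=6 pyrG=3 recA=6 uvrC=6

find_clonal_complexes(profiles)
#> <mlst_cc> 3 clonal complexes, 3 singletons (threshold: share >= 7 alleles)
#>   complex n_sts n_isolates founder_st founder_slv tie_break
#> 1 CC1        10         25          1           9 slv
#> 2 CC2         6         17         21           5 slv
#> 3 CC3         8         15         14           7 slv

index_of_association(profiles, n_perm = 999, seed = 42)
#> <mlst_linkage> 60 isolates x 8 loci
#>   V_D = 10.6, V_e = 1.72, I_A = 5.163, I_A^S = 0.7376
#>   permutation P = 0.001 (999 permutations, seed 42)
```

The three planted founder lineages come back as exactly three clonal
complexes, and the strong linkage (*I*<sub>A</sub><sup>S</sup> ≈ 0.74,
*P* = 0.001) reflects the absence of recombination in a clonal
population — with `recombination_rate` raised, the statistic collapses
toward zero. The diversity table completes the picture:

```r
diversity_report(sim$dataset, profiles)
#>          locus length_bp n_alleles n_polymorphic_sites      pi gc_percent
#> 1         clpX       443         9                  10 0.00423       53.2
#> 2        groEL       641         7                   8 0.00321       50.9
#> ...
#> 9 concatenated      4270        27                  67 0.00416       52.1
```

`pi` is the mean proportion of differing sites between two randomly
chosen isolates; `n_alleles` counts distinct sequences per locus; the
`concatenated` row pools all loci (4270 bp here).

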