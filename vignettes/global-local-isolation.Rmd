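---
title: "Global versus local evolutionary isolation: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Global versus local evolutionary isolation: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isolocal)
```

## The question

Species-level measures of evolutionary isolation are computed on a whole
clade's phylogeny when global conservation priorities are set, but the
communities where conservation acts contain only a subset of that tree.
A species on a long, lonely branch of the global tree may sit in a
community full of close relatives, and vice versa.  This package measures
how strongly the global and local versions of three isolation metrics
agree, community by community, and what is actually lost locally when the
globally top-ranked species are removed.

## Metrics and conventions

**ED (fair proportion).**  Every edge's length is divided equally among
the tips descending from it; a tip's ED is the sum of its shares along the
root-to-tip path.  Polytomies and zero-length edges need no special
casing: the per-edge share is `length / n_descendant_tips` regardless of
node degree.  ED exactly partitions the tree, so `sum(ED)` equals the
total tree length — the package asserts this identity to 1e-9 relative
tolerance in its tests, and it also implies `ED(i) >= PE(i)` for every
tip.

**PE (pendant edge).**  The terminal branch length, i.e. the PD lost if
only that species is pruned.  On a star tree PE and ED coincide.

**APD.**  Mean patristic distance to the other species.  The divisor is
`n - 1` (self-distance excluded) — the literal reading of "mean distance
to all *other* species"; a divide-by-`n` variant would only rescale ranks
by a common factor and leave every rank correlation unchanged.

**Rooted Faith PD.**  PD of a species set sums the edges on the union of
root-to-tip paths, *including* the path from the set's MRCA up to the
root.  This convention makes single-lineage contributions positive and
makes `sum(ED) = PD(all tips)` exact.  `faith_pd(..., include_root =
FALSE)` exposes the MRCA-rooted variant, but the pipeline does not use it.
Pruned community subtrees carry the MRCA-to-root path as their `root.edge`,
so `tree_length(prune_to_community(tree, S)) == faith_pd(tree, S)` always
holds, and local ED on a pruned subtree shares the root edge equally among
all community members, preserving the partition identity locally.

**Ensembles.**  Replicate trees (e.g. a posterior sample) must share one
tip set; species scores are aggregated by the per-species median, with the
arithmetic midpoint for even ensemble sizes.  Medians are robust to the
occasional aberrant branch length in a sampled tree, which is why they are
the default aggregation.

**Gower trait distances.**  For each species pair the distance averages
per-column contributions over the columns where *both* species are scored:
range-normalised absolute difference for quantitative traits, the same on
the rank scale for ordinal traits, and 0/1 mismatch for nominal traits.
Columns with zero range contribute 0 (with a warning), matching the
behaviour of the standard Gower implementation in `cluster::daisy`, which
the test suite uses as an independent cross-check.  A column missing in
either species simply drops out of that pair's average; only pairs with
*no* comparable column at all are special: they receive the median of all
computable off-diagonal distances and are flagged in an imputation mask.
"Standardised by the mean" is read as division by the column mean (not
centering) so that typically positive ecological traits stay positive;
since Gower range-normalises each column, this standardisation does not
change any distance, and it is kept for interpretability of the stored
table (a centering option exists but is off by default).

**Local trait scores.**  The default is reuse-and-restrict: local TU and
TAPD are recomputed on the principal submatrix of the *global* distance
matrix, not from a re-range-normalised community-level Gower computation.
Re-normalising within each community would make local distances
incommensurable across communities and let a single community outlier
rescale every distance; restricting keeps one common distance scale.

## Community assembly and filters

Survey records are collapsed so each route's community is the union of
species over all surveyed years, with counts summed.  Filters follow
fixed, tested boundary semantics:

- richness filter: communities with *fewer than* `min_richness` (default
  25) species are dropped — richness 24 goes, 25 stays;
- rare-species filter: within each community, species with *strictly less
  than* `rare_fraction` (default 1%) of all individuals are dropped —
  1/100 stays, 1/200 goes;
- alien filter: listed species are removed everywhere.

The richness filter is applied once, to the full dataset, *before* the
no-alien and no-rare variants are materialised, and is not re-applied
afterwards: the variants are meant to be the same communities minus the
targeted species, not a re-selected site set.  All filters are idempotent.
Name reconciliation applies the user synonym map first (sub-species
records merge into their parent species, counts summed; cycles are
rejected), then drops species absent from the phylogeny, with a logged
count.

## Concordance

Per community and per metric pair, Spearman's ρ is the Pearson correlation
of mid-ranks, with the two-sided p-value from the t approximation
`t = ρ √((n−2)/(1−ρ²))` on `n − 2` degrees of freedom (`|ρ| = 1` maps to
p = 0).  The t approximation is adequate because filtered communities have
n ≥ 25; an exact permutation test would change nothing at these sizes.
Records with fewer than 3 shared species or a constant score vector are
marked undefined and excluded from summaries rather than erroring the run.
Species lacking a trait row are excluded from trait-based pairs only.

## Removal experiment

For each global metric the pool is ranked (ties at the cutoff broken by
label order, with a message) and the top K species are removed from every
community.  Observed PD loss is `PD(community) − PD(community \ topset)`;
the trait measure is mean pairwise Gower distance before minus after, so a
*positive* value means the depleted community is more trait-similar.  The
null removes the same number of species per community uniformly at random
— uniform, not abundance-weighted, because the question is about species
identity, not encounter probability.  Empirical p-values use the add-one
estimator `p = (1 + #{null ≥ obs}) / (R + 1)`, one-sided "greater"
(the hypothesis is that targeted removal loses *more*), so p is never
exactly zero.  FDR control is Benjamini–Hochberg across communities
within each metric; pooling across metrics would mix hypotheses of
different kinds.  Communities left with fewer than 2 species contribute
their PD loss but are excluded from trait summaries.  Internally, PD over
many subsets is computed from a precomputed edge-by-tip incidence matrix
(`pd_context`), which makes the 100 000+ subset evaluations of a null run
cheap; PD is measured on a single representative tree (the first ensemble
member) while the ranking uses ensemble medians.

## The synthetic generator

The generator produces data with the statistical structure the analysis
assumes, not a mimic of any particular survey:

- **Pool tree**: a pure-birth (Yule) tree, ultrametric, default 300 tips —
  large enough that communities of 26–150 species are proper subsets but
  small enough for desk-scale runs.
- **Ensemble**: the base tree plus replicates whose branch lengths get
  i.i.d. multiplicative log-normal jitter (mean 1, default s.d. 0.1),
  keeping the topology and tip set fixed.  This is a cheap stand-in for a
  posterior sample; since scores are aggregated by medians, which are
  robust to local rearrangement, topology perturbation adds little and is
  omitted by default.
- **Traits**: quantitative traits evolve by Brownian motion along branches
  and are exponentiated (body-mass-like, positive, right-skewed); nominal
  traits follow an equal-rates Mk process.  The default table — 16
  quantitative plus 6 nominal columns with 8 states — mirrors the shape of
  a typical avian ecological trait set once diet composition is split into
  its component columns (mass, habitat/vertical/diet breadths, ten diet
  components, clutch size; habitat, guild, social structure, nest type,
  nest substrate, activity pattern).  Trait dimension matters: with many
  fewer columns the sampling noise of single Brownian/Mk realisations can
  overwhelm the phylogenetic signal in species-level trait summaries, and
  the APD–TAPD association becomes unreliable.  Cells are masked missing
  independently (default 5%), which also exercises the incomparable-pair
  median rule.
- **Communities**: richness is uniform on `[26, 150]`; a seed species is
  drawn uniformly and the rest are drawn without replacement with weight
  `exp(−α · d(i, seed))` on patristic distance.  `α = 0` (the default)
  gives uniform subsets; small α (≈ 0.15–0.25 on a depth-≈6 tree) gives
  the weak clustering typical of continental survey routes, whose
  within-community mean pairwise distance sits only a few percent below
  the pool expectation.  Abundances are integerised log-normal draws
  (default meanlog `log 20`, sdlog 1.5), giving a realistic tail of
  locally rare species below the 1% threshold.

What passing synthetic tests do *not* show: real communities have spatial
structure, observation error, richness–environment gradients and
non-Brownian trait evolution, none of which are emulated.  One genuine
limitation surfaced by the generator is worth flagging: the strong
global–local APD concordance depends on communities sampling the tree
broadly.  When communities are confined to single clades (large α) or are
tiny relative to the pool, the deep-tree structure that APD measures is
absent locally and the global–local APD ordering can invert.

## Verification scales

The shipped tests run the oracle suites on hundreds of small random trees
(exact agreement with brute-force edge enumeration, path sums and
union-of-paths PD), the conservation and dominance identities on Yule
trees up to 200 tips, Monte-Carlo removal nulls against exhaustive subset
enumeration on communities of up to 10 species, and the directional
properties on seeded replicate studies of a 300-species pool with 200
communities (top-30 removal, 200 null replicates).  The acceptance script
reruns the full default-scale study from scratch and reports its summary
quantities; all numbers it emits are computed at run time from the seeded
simulation.

## Known limitations

- No spatial regression of concordance on environmental covariates, and
  no map products; community coordinates are carried through but unused.
- Taxonomic reconciliation is exact-match plus a user synonym map; no
  fuzzy matching or taxonomy-service lookups.
- Trees must be rooted with branch lengths; unrooted trees are not
  supported.
- The removal experiment ranks species by scores alone; extinction
  probabilities, costs and complementarity-based (greedy PD) selection
  are out of scope.
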