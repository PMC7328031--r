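---
title: "From activation coordinates to gene lists: the aletx methods"
author: "aletx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From activation coordinates to gene lists: the aletx methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aletx)
```

`aletx` chains five analyses that are usually run through separate tools:
coordinate-based meta-analysis (ALE), meta-analytic connectivity modeling
(MACM), behavioral term profiling, activation–gene-expression association,
and gene-list overlap/enrichment statistics. This vignette explains each
model, its assumptions, the tunable parameters, and the design choices
made where the methods literature leaves the details open. The package's
interface is its exported functions; every randomized operation takes an
explicit `seed` and is bit-reproducible given it.

## Coordinate-based meta-analysis (ALE)

**Model.** Reported activation peaks are noisy observations of underlying
effects. A peak from an experiment with $n$ subjects is modeled as a 3-D
isotropic Gaussian with

$$\mathrm{FWHM}(n) = \sqrt{f_t^2 + f_s^2/n},$$

where $f_t$ (template uncertainty) defaults to 5.7 mm and $f_s$
(between-subject uncertainty) to 11.6 mm — the empirical constants of the
revised ALE algorithm. They are arguments of `kernel_spec()` because
different tool versions have used slightly different values. The Gaussian
is scaled to integrate to one over mm³ and expressed as a per-voxel
activation probability; within one experiment multiple foci combine by
voxel-wise **maximum** (so a study reporting many nearby peaks is not
counted as more evidence than one reporting a single peak; a probabilistic
union variant is available via `combine = "prob_union"`). Experiments
combine by the probabilistic union
$\mathrm{ALE} = 1-\prod_i (1-\mathrm{MA}_i)$, which is order-invariant,
bounded in $[0,1]$ and monotone in the corpus.

**Null and thresholds.** The spatial null relocates every experiment's
foci uniformly at random to in-mask voxel centers, preserving focus counts
and subject numbers (`ale_voxel_null()`). We use Monte-Carlo relocation
rather than the analytic histogram-convolution null of some ALE software
because it is simpler, seedable, and testable against exhaustive
enumeration on tiny grids. Voxel p-values use the add-one estimator
$(1+k)/(n_\mathrm{perm}+1)$, so p is never zero and the minimum attainable
p is $1/(n_\mathrm{perm}+1)$ — at the default cluster-forming threshold
$p<0.001$ you therefore need $n_\mathrm{perm}\ge 1000$.

Cluster-level FWE (`cluster_level_fwe()`, defaults: forming $p<0.001$,
FWE $p\le 0.05$, 1000 permutations) thresholds the observed map, groups
supra-threshold voxels by 26-neighbor connectivity (configurable), and
compares cluster sizes to the permutation null of the maximum cluster
size. One numerical subtlety matters for calibration: the per-voxel
cluster-forming critical value is computed from the **pooled** set of
observed + permuted maps (the value must rank within the top
$k_{\max}+1$ of all $n_\mathrm{perm}+1$ exchangeable maps at that voxel).
Deriving the critical value from the permutations alone treats the
observed map asymmetrically and inflates the family-wise error rate
noticeably at desk scale; with the pooled rule the empirical FWE rate
under null foci is 0.035 in the test suite's calibration (200 runs × 200
permutations on a 12³ grid, nominal 0.05).

`contrast()` permutes task labels over the pooled experiments (the
paper-style pooled-input design) and thresholds the ALE difference at an
uncorrected $p<0.01$ (configurable) inside the union of the two
thresholded maps; the contrast threshold itself is not stated in the
methods this package follows, so it is exposed rather than asserted.
`conjunction()` is the voxel-wise minimum of thresholded maps, and
`thresholded_overlap()` reports connected components where two thresholded
maps agree.

## MACM

`select_experiments()` includes a database experiment when at least one
focus lies in the seed: the focus is mapped to its containing voxel
(nearest center) and looked up in the seed mask. We chose voxelized
membership over Euclidean distance-to-surface because it matches
database-query semantics and is deterministic; the boundary convention
(focus on an edge voxel counts) is tested. `coactivation_map()` then runs
the ALE machinery over the selected experiments and thresholds voxel-wise
at Benjamini–Hochberg FDR $q<0.05$ computed over in-mask voxels, keeping
clusters strictly larger than 200 mm³ (the ">200 mm³" rule is read as
strict; the 200 mm³ = 25-voxel boundary case at 2 mm is tested). Note that
FDR resolution is limited by the permutation count: with $m$ in-mask
voxels, rejections require $p_{\min} \le q\,k/m$, so small grids need
$n_\mathrm{perm}$ in the high hundreds.

## Term profiling

`spatial_similarity()` is the Pearson correlation of two maps over a
shared mask — computed on unthresholded values by default since the
methods being emulated do not state that meta-maps were thresholded; a
threshold can be applied upstream. Zero-variance maps raise an error
rather than returning NaN; `profile_maps()` converts such entries to
recorded `NA`s. `rank_terms()` orders terms by column mean, ties broken
alphabetically for reproducibility. The 23-term list used in the emulated
analysis is configuration, not code: any `term_map_set` works.

## Activation–gene-expression association

The pipeline (`gene_association_table()`):

1. `aggregate_probes()` — probes average to genes (plain mean; no
   differential-stability probe selection — the aggregation rule is a
   config hook since only "aggregated" is specified upstream).
2. `map_values_at_sites()` — 4 mm-radius spherical ROI mean of the map at
   each retained site. Sites are retained by their per-site cortical flag
   (the cortical/subcortical distinction is an annotation-level concept in
   donor atlases, so the flag ships with the atlas rather than being
   inferred from a voxel mask). Sphere membership is by voxel-center
   distance; an empty sphere falls back to the nearest voxel so sub-voxel
   radii degrade to nearest-neighbor sampling.
3. `donor_correlations()` — per gene and donor, Pearson r between the
   gene's site vector and the map vector. Genes flat in a donor become
   `NA` for that donor; a map that is constant across a donor's sites is a
   hard error (silent zeros would poison everything downstream).
4. `combine_random_effects()` — Fisher-z per donor, one-sample t across
   donors, one-sided p for positive association (negative associations are
   deliberately not interpreted). Zero variance across donors with nonzero
   mean sets p to the smallest representable double and raises a flag.

`select_top_genes()` ranks positively-correlated genes by the combined
Fisher-z mean (descending, ties by symbol). Ranking by combined z and by
random-effects p coincide when all genes are measured in the same number
of donors; both are exposed via `rank_by` because the emulated analysis
does not say which was used.

## Overlap statistics

`constrained_random_null()` draws pairs of uniform random gene subsets of
the observed list sizes and records overlap counts; the expectation of the
unconstrained null is hypergeometric, $n_1 n_2 / N$ (the test suite checks
convergence). The optional similarity filter retains pairs whose pooled
expression-space similarity falls inside both a mean window (default
$[0.05, 0.07]$) and an sd window ($[0.25, 0.29]$) — the published control
for spatial autocorrelation. The pair statistic is computed by
`list_spatial_similarity()` on the **union** of the two lists (mean and sd
of pairwise Pearson correlations between site-expression vectors, per
donor, averaged over donors); the source prose says only "overall spatial
similarity between identified genes … for each donor", and the union
reading pools both lists the way that phrase suggests. On synthetic
atlases without spatial autocorrelation the filter retains few pairs; the
reference retention rates (1718/5000, 72/100) depend on real cortical
autocorrelation and are not reproduced here — this is the known gap
between the synthetic generator and real atlas data.

`parcel_permute_map()` operationalizes "relocation restricted by a
functional parcellation". The prose is ambiguous between value-level and
parcel-level relocation; the default permutes **parcel-mean values across
parcels** (each voxel receives the mean of the parcel its label maps to;
the multiset of parcel means is conserved exactly, background untouched),
and a `method = "within_parcel"` alternative shuffles voxel values inside
each parcel. Parcel-level permutation is the default because it preserves
within-parcel structure — the stated reason for restricting the relocation
in the first place. `permuted_map_null()` reruns the entire association
pipeline on each permuted pair.

`threshold_sweep()` computes mean overlap percentage per threshold
$x \in \{1, 11, \ldots, 1991\}$ (percent denominator is $x$ itself,
consistent with 1212/2000 = 60.6%) for the three category types, keeping
the per-(x, pair) observations. `compare_categories()` t-tests those
observations (Welch by default, Student via `var_equal = TRUE`); the
emulated analysis does not state its t-test's unit of observation or
variance assumption, so both are exposed.

## Enrichment

`overrepresentation_test()` is the one-sided hypergeometric upper tail
$P(X \ge k)$ per term (no depletion testing, matching the "binary
overrepresentation" design), with BH-FDR within each namespace (BP, MF,
CC and disease tables adjusted separately; the grouping is configurable by
splitting the annotation table). Annotations are taken as given — no GO
graph propagation, since term databases are versioned snapshots.
`word_frequency()` summarizes significant term names after removing a
small editable stopword list.

## The synthetic-data module

Every generator is a pure function of its parameters and seed, returns its
ground truth alongside the data, and writes/reads the same plain-text
formats the analysis functions consume. Defaults are chosen to emulate the
reference study's conditions at desk scale: 6 donors (the atlas design),
300 sites per donor and 500 genes by default (the real atlas has ~1000
sites and 20 787 genes; the full size is a parameter, not a limit), and
planted map–gene correlations implemented as
$\rho \cdot \mathrm{std}(\text{map at sites}) + \sqrt{1-\rho^2}\,\varepsilon$.
Donor heterogeneity is modeled as independent noise only (no donor-level
expression offsets — a flagged extension). The generator does **not**
reproduce distance-dependent spatial autocorrelation of cortical
transcription; consequences: similarity-filter retention rates on
synthetic data do not match the published ones, and passing recovery tests
demonstrates correctness of the machinery, not robustness to real
autocorrelation.

## Problem sizes used in the test suite

Chosen as the package's own desk-scale validation design:

* FWE calibration: 12³ grid (2 mm), 6 experiments × 2 foci, 200 runs ×
  200 permutations, cluster-forming p = 0.05. The forming threshold is
  0.05 here because 200 permutations cannot resolve p < 0.001 (minimum
  attainable p ≈ 0.005); the nominal default stays 0.001 at 1000
  permutations. Null foci are drawn at voxel centers — the same support
  the relocation null uses — so observed and permuted corpora are
  exchangeable and the measured rate reflects the procedure itself.
* Planted-focus recovery: 24³ grid (±23 mm, holding ~4 sd of the 6 mm
  scatter), 20 experiments × 2 foci, 20 seeds. A smaller box clips a
  third of the scattered foci and degrades recovery for reasons unrelated
  to the method.
* Gene recovery: ρ = 0.5, 6 donors × 300 sites, 20 planted among 500,
  50 seeds.
* End-to-end overlap: two task maps sharing a planted 40-gene module
  (ρ = 0.7) plus an independent control pattern with its own module,
  300 genes × 150 sites × 6 donors, 10-parcel permutation null with 20
  permutations.

## Known limitations

* Memory: permutation matrices are held in full (in-mask voxels ×
  permutations), which is fine for desk-scale grids but a whole-brain 2 mm
  grid at 1000 permutations needs several GB; stream-wise accumulation is
  a possible extension.
* The Talairach→MNI default is the inverse of the published icbm_spm2tal
  affine; conversion utilities differ between versions, so the transform
  is data, not a constant, and no equivalence with any specific tool is
  asserted.
* Anatomical labeling of clusters (region names, hemispheres) is out of
  scope; cluster tables report coordinates, sizes and statistics only.
* No command-line wrapper is shipped: the exported functions and the
  acceptance script are the interface, and all analyses are a few lines of
  R.
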