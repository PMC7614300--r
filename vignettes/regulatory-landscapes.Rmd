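---
title: "Two regulatory strategies in neural progenitors: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two regulatory strategies in neural progenitors: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regland)
```

## The scientific problem

Neural progenitors of the ventral neural tube (p0-1, p2, pMN, p3) acquire
their identity from graded Sonic hedgehog signaling. Cell-type-resolved
ATAC-seq of these progenitors reveals two distinct cis-regulatory
strategies. Most progenitor types (p0-1, p2, pMN) share a common landscape
of open chromatin and differ in which transcription factors occupy those
shared elements — a *differential binding* strategy, visible in TF
footprints rather than accessibility. The p3 type instead opens a private
set of elements — a *differential accessibility* strategy, driven by the
pioneer factor FOXA2.

`regland` implements the downstream analysis that supports this
distinction: differential accessibility testing with the standard
selection rule, two-stage clustering of element dynamics with semantic
labeling and regime classification, footprint/archetype analysis with
RNA-correlation ranking of candidate driver TFs, ChIP overlap enrichment,
and quantification of lineage-traced cell classes in section images.
Every stage is exercised end-to-end against a synthetic-data generator
that plants known ground truth.

## The synthetic-data generator

`sim_config()` fixes the simulated study design: one NMP condition at day
3 and the four neural types at days 4–6 (13 conditions), three replicates
each. Nine planted accessibility patterns (`default_patterns()`) emulate
the cluster dynamics of interest: an NMP-only program that is
decommissioned, a pan-neural program, p3-private programs (the unique
landscape), stage-dependent programs, and a program shared by p0-1/p2/pMN
only. By design the three shared-regime types never differ in
accessibility — they differ only in planted footprint scores — while p3
carries private patterns; this is the ground truth that regime
classification must recover.

Counts are negative binomial with the common dispersion convention
`variance = mu + alpha * mu^2`. Element *i* in sample *j* has mean
`baseline_mean * 2^(effect_log2fc * open) * lib[j]`, with library factors
drawn log-uniform in [0.5, 2] to exercise normalization. Defaults:
`baseline_mean = 50` (a realistic per-element fragment count for a
consensus peak at moderate depth), `effect_log2fc = 3` (open vs closed;
accessibility differences of ~8-fold are typical of clear cell-type
elements), `nb_dispersion = 0.2` (biological replicate-level dispersion
typical of ATAC count data). `simulate_footprints()` couples one planted
driver gene per motif archetype to the archetype score at expected
Pearson correlation `driver_correlation` (default 0.9), with independent
decoy TFs; the first archetype is the "pioneer" archetype, planted with
amplitude 1.8 relative to the unit-variance decoy archetypes and a score
profile elevated exactly in the unique-regime type's conditions, so the
variability ranking reliably puts it first — mirroring a dominant pioneer
footprint. `simulate_chip()` plants peak overlap at a chosen rate in one
pattern; `simulate_sections()` renders nuclei as disks with
class-determined marker channels (p3: SOX2+NKX2.2+; V3: NKX2.2 only),
a tdTomato lineage flag, optional far "background-binding" NKX2.2+ nuclei
for positional QC, and Gaussian noise.

What the generator does *not* emulate — and hence what green tests do not
show about real data: Tn5 sequence bias and fragment-size structure,
GC/mappability covariates, overlapping or irregular nuclei, per-element
dispersion trends, doublet or mis-sorted cells, and real genome
coordinates (elements sit on a toy contig). Results on real data depend
on upstream peak calling and bias correction, which are out of scope.

## Normalization and QC

Consensus peaks keep elements with a MACS q-value strictly below `1e-5`
in at least one sample (`filter_consensus()`). Library size uses
median-of-ratios size factors (`size_factors()`), the standard for count
data; note that any global normalization absorbs a shift shared by most
elements, so planted library factors are only recoverable on matrices that
are mostly non-differential. The variance-stabilizing transform is
`log2(count/size_factor + pseudocount)` — deliberately simpler than a
model-based VST; it is monotone, exact at zero
(`vst(0) = log2(pseudocount)`), and sufficient for clustering and PCA,
which only need high- and low-count elements on comparable scales.
`frip()` and `sample_correlation()` (squared Pearson, optionally on
promoter or distal elements from `annotate_tss()`) provide the usual QC.
Coordinates are BED-convention 0-based half-open throughout; a TSS is a
1-bp feature, so `window_bp = 0` tests overlap with the TSS base itself.
The default promoter window of 500 bp is a package choice — the
promoter/distal split is conventionally defined only as "overlapping a
TSS window".

## Differential accessibility

The test is a transparent negative-binomial Wald test on
`log2FC = log2(mB + c) − log2(mA + c)` over group means of normalized
counts (pseudo-fraction `c = 0.5 / median depth per element`), with a
delta-method standard error
`var(log2 mG) = (mG/sf + alpha mG^2)/(nG mG^2 ln(2)^2)`. It replaces a
full GLM with shrinkage because at desk scale the calibration can be
demonstrated directly. Three numerical choices matter:

* **Dispersion moderation.** With 3 replicates per group, per-element
  method-of-moments dispersion is extremely noisy, and plugging it into
  the Wald statistic produces a heavy-tailed null (~12% rejections at
  nominal 5%). `estimate_dispersion()` therefore shrinks the per-element
  estimate toward a matrix-wide ratio estimator with `prior_df = 50`
  pseudo-degrees of freedom, and `wald_test()` refers the statistic to a
  t distribution with residual + prior df — the empirical-Bayes logic of
  moderated statistics. Measured type-I error on null simulations is
  0.048–0.051. `prior_df = 0` gives the raw floored estimator.
* **Group-wise moments.** The moment excess is computed per group and
  df-pooled; evaluating the variance model at the pooled mean would
  overestimate dispersion for genuinely differential elements (the NB
  variance is convex in the mean), inflating standard errors exactly
  where power matters.
* **Denominator debiasing.** `m^2` overestimates `mu^2` by the sampling
  variance of the group mean; the denominator uses `m^2 − s^2/n`, without
  which the central dispersion is biased low and the test slightly
  anticonservative.

Selection uses the standard three-part rule with strict inequalities:
`padj < 0.01`, `|log2FC| > 2`, `baseMean > 100` (BH adjustment per
comparison; `baseMean` over the compared samples, with the whole-matrix
alternative deliberately not assumed). Summary counts per comparison
(`count_differential()`) follow the bar-graph convention of a *linear*
fold-change cutoff, `|FC| > 2`, i.e. `|log2FC| > 1`; both cutoffs are
exposed because the two conventions coexist in practice.
`build_plan()` enumerates exactly the all-pairs design: cell types within
a day, days within a cell type.

## Clustering, labels, regimes

Profiles are per-condition replicate means of the VST matrix, z-scored
per element so clusters capture the *shape* of dynamics rather than
amplitude (`scale = FALSE` disables this). Clustering is two-stage:
k-means with a deliberately large `k1 = 30` (Lloyd updates from centers
drawn among the canonically sorted distinct profiles, 10 restarts, fixed
seed — this makes the fit independent of element order), then
average-linkage hierarchical merging of the 30 centroids under
correlation distance (1 − Pearson), cut at `k_final = 9`. Correlation
distance matches the "similar dynamics" semantics of the merge; Euclidean
and other linkages are available. The stage-1 partition always refines
the merged partition. Recovery on planted data: ARI ≥ 0.97 against the
nine planted patterns; mean pairwise ARI across seeds ≥ 0.96.

Cluster labels are rule-based on the z-scored centroids. Because a
pattern open in most conditions has *small positive* z in its open state
(and strongly negative z in the few closed conditions), a fixed "high"
cutoff alone cannot see broad patterns; each centroid is therefore also
binarized at the midpoint of its range (flat centroids, range < 0.5, stay
unlabeled). Rules, in order: all high conditions NMP → `NMP`; a single
neural type high with others at or below zero → `<type>-specific`, with
others intermediate → `<type>-enriched`; every neural type open and no
NMP condition high → `pan-neural`; otherwise `other`.

`classify_regime()` formalizes the strategy call: for each cell type, the
fraction of differential elements accessible in that type (clusters open
in ≥ 1 of its conditions) that lie in clusters labeled specific/enriched
for it. Above `tau = 0.15` the type maintains a private program
(*differential accessibility*); below, its identity must be carried by
TF occupancy on shared elements (*differential binding*). `tau` is a
simulator-calibrated artifact default, prominently exposed, not a
biological constant. On planted data the unique-regime type and all
shared types are called correctly in 20/20 simulations.

## Footprints, archetypes, candidate drivers

`footprint_score()` measures flank-over-center insertion depletion,
`log2((flank + c)/(center + c))`; positive is protected.
`differential_footprints()` standardizes per-motif score differences
against the all-motif background with a robust z (median/1.4826·MAD; when
MAD degenerates with ≥ 50% tied deltas, 1.2533 × mean absolute deviation).
Score differences play the role of fold changes because the scores are
already log-like. `select_variable_motifs()` takes, per comparison, the
union ("or" read as union) of the top 5% by |difference| and the 5%
smallest p-values, ceiling-count boundary, deterministic tie-breaks, then
the union over comparisons — monotone in the percentage by construction.

Motifs are grouped into archetypes either by a supplied published mapping
(which wins when provided) or de novo: pairwise PWM similarity is the best
ungapped-alignment mean column correlation over all offsets and the
reverse complement (≥ 4 aligned columns), merged by average linkage at
similarity 0.8. Archetype scores are member means (mean rather than max or
a representative motif — the unweighted choice; a flag selects the
conditions used for the variability ranking). `rank_candidate_tfs()`
correlates each associated TF's expression with the archetype score
across shared conditions and ranks by decreasing r (ties by gene name;
zero-variance genes flagged and ranked last). With planted correlation
0.9, 5 decoys and 12 conditions, the planted driver ranks first in
essentially every simulation.

## Overlap enrichment

`overlaps()` flags a query interval sharing ≥ 1 bp (configurable) with
any reference interval, half-open arithmetic, via IRanges; tests hold it
to an exhaustive all-pairs oracle exactly. Cluster-level ChIP enrichment
is an upper-tail hypergeometric test on element counts (universe = all
clustered elements) with BH across clusters — a statistical companion to
coverage heatmaps, reported as such since visual coverage comparisons
carry no test. The closed-form p equals exhaustive subset enumeration to
1e-12 on toy cases. Per-element signal enters as precomputed scalars
(`mean_signal_matrix()`); pileup extraction from alignments is out of
scope.

## Section-image quantification

`segment_nuclei()`: Gaussian smoothing (σ = 2 px), global Otsu threshold,
8-connected components (4-connected labeling plus a vectorized diagonal
merge), area filter. `find_threshold()` applies 256-bin Otsu to
*per-nucleus mean* intensities pooled across sections — per-nucleus means
are far better separated than raw pixels, and pooling protects sections
that lack a class; a quantile mode exists for skewed data.
Classification: SOX2+NKX2.2+ → p3, NKX2.2-only → V3, else other;
tdTomato thresholded independently. Positional QC excludes NKX2.2+ cells
farther than `max_distance_px` from the domain center, formalizing the
qualitative "far from the p3 domain" exclusion of antibody background;
the default center is the component-wise *median* of NKX2.2+ positions,
which the outlying background cells themselves cannot drag. No watershed
splitting by default — the generator guarantees separation (center
distance > 2·radius + margin, default margin 7 px, chosen so tangent
disks cannot fuse after smoothing); real, touching nuclei would need a
distance-transform watershed, a stated limitation. At zero noise the
pipeline recovers nucleus counts, classes and tdTomato+ p3/V3 counts
exactly; at noise equal to 10% of the marker on/off separation,
aggregate counts over 50 sections stay within 5% (measured: exact).

## Problem sizes and determinism

The validation suite and `scripts/acceptance.R` use desk-scale sizes
chosen to make each property measurable in seconds: 20 × 1,000 null
elements for calibration (20,000 tests), 2,000 elements (10%
differential) for recovery, 1,800 elements for clustering, 20 × 540
end-to-end runs for regimes, 200 footprint simulations, 1,000 random
intervals for the overlap oracle, and 6 + 50 sections of 192 px with 20
nuclei for imaging. All generators are deterministic given
`sim_config(seed = ...)`: identical configs reproduce byte-identical
outputs.

## Interface note

The package's surface is its exported functions, this vignette, and the
acceptance script; an R analyst drives the pipeline from scripts or
notebooks, so no shell entry point is shipped.

## Known limitations

The NB test has no dispersion trend over the mean, no outlier handling
and no LFC shrinkage — thresholds act on unshrunk estimates. Median-of-
ratios normalization (like any global method) partially absorbs strongly
asymmetric differential signal. Cluster labels assume the condition
metadata distinguishes an NMP/day-3 state from neural types. The de novo
archetype similarity is ungapped. Segmentation assumes separable nuclei.
These mirror the stated non-goals: the package reproduces the downstream
reasoning of the analysis, not the upstream read processing.
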