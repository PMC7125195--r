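---
title: "Methods: kinase identification from inhibitor fingerprints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kinase identification from inhibitor fingerprints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The model

A phosphorylation event assayed in a cell extract under a panel of kinase
inhibitors yields, per inhibitor, an absorbance proportional to the
residual activity of whatever kinase (or mixture of kinases) generates
the signal. The package's inferential object is the **inhibition
fingerprint**: the vector of per-inhibitor %inhibition values of the
unknown activity. Identification rests on a single assumption: *the
fingerprint of the responsible kinase in the extract resembles, up to a
positive affine transformation and noise, that kinase's published in
vitro selectivity profile.* Pearson correlation is the natural match
score under this assumption, because it is exactly invariant to positive
affine maps of either vector — which is also why plate normalization does
not need to estimate absolute potencies.

## Plate normalization

Per plate: `s_i = (mean_A(i) − mean_A(DMSO)) / sd_A(DMSO)` with replicate
wells averaged on the absorbance scale first, and
`I_i = 100 · s_i / min(s)`, the minimum taken over all inhibitor scores
and all EDTA stop-control scores on that plate. Design points:

* **Sample sd (n−1)** for the DMSO spread: conventional for the small
  control counts involved (tens of wells) and makes results
  bit-reproducible across implementations.
* **EDTA wells are scored per well** by the same formula and compete for
  the plate minimum. A fully quenched well defines what 0 activity looks
  like; when no compound reaches full inhibition, this anchors the 100%
  point. EDTA wells are optional per plate.
* **Strictly per-plate controls** — never pooled across plates — since
  both the minimum and the DMSO statistics are plate-level quantities.
* **No clipping.** Activators produce `I < 0` and hyper-inhibitory noise
  can exceed nothing (the plate max is exactly 100 by construction);
  values outside [0, 100] in reference panels are likewise retained.
  Clipping would distort the very shape the correlation exploits.
* A plate whose minimum standard score is not negative has no inhibitory
  signal and cannot be normalized; this is an error, not a silent 0.

## Reference panels on a common scale

Each dataset declares its measurement semantics and is mapped so that
*larger = more inhibition*: remaining activity becomes `100 − v`;
dissociation constants become `100 / (1 + K_d / c)` with `c = 500` nM by
default (configurable; the single-site occupancy estimate at screening
concentration); thermal shifts pass through untransformed because
Pearson is location/scale invariant and larger shifts indicate stronger
binding. Two points were genuinely open and are resolved explicitly
rather than guessed: remaining-activity panels are *always*
sign-converted by this package (the transform is recorded in the
dataset's provenance so users can audit it), and thermal-shift values are
used raw, not thresholded. Mutant/engineered constructs are excluded
before correlation. Missing measurements are first-class: nothing is
imputed, and every correlation is computed over the pairwise-complete
inhibitor set.

## Ranking

Kinases with fewer than `min_overlap = 10` shared inhibitors, or with
zero variance on the overlap, are dropped with a logged reason. Ten is a
floor below which a correlation coefficient is mostly noise; the dropped
list keeps the choice auditable. Zero-variance profiles are dropped
rather than scored 0 because Pearson is undefined there and a fabricated
0 would silently enter the ranking. The overall ranking pools
per-dataset rows by raw ρ; no cross-dataset meta-score is computed, and
no adjustment is made for the screen concentration differing from the
profiling concentration (the method relies on profile shape, not
absolute potency). Ties break by higher z, larger overlap, then gene
symbol. An alternative z-based overall ordering is available by sorting
the table on `z`, but raw ρ is the default and the reported convention.

## Permutation null and confidence

The null asks: *how strong do correlations get when the fingerprint
carries no information?* Inhibitor labels of the fingerprint are randomly
permuted (the reference panel is untouched), all per-kinase correlations
recomputed under identical filters, and the coefficients pooled —
default `n_perm = 100` permutations, giving `100 × n_kinases` null
values per dataset. Then `z = (ρ − mean_null) / sd_null`. The null is
built per (screen, dataset) pair because datasets differ in inhibitor
count and value distribution; a pooled-across-datasets mode exists
behind `null_scope = "pooled"` and outputs label the mode. Confidence
flags follow the top z: below 6 caution, 6–10 intermediate, 10 or above
robust. Calibration is verified empirically: z-scoring 1,000 freshly
permuted fingerprints (not used to build the null) against a
300-inhibitor synthetic panel yields mean |z| < 0.1 and sd within
[0.9, 1.1].

## Downsampling robustness

From the N shared inhibitors, `n` are drawn without replacement
(`reps = 10,000` by default; tests use 1,000), kinases re-ranked on the
subsample, and the frequency with which the target lands in the top k
recorded, for `n = 3…N` and `k ∈ {1, 5, 10}` or the relative grid
`{size/100, size/20, size/10}`. The source text for the relative rule
reuses one symbol for both library size and panel size; both readings
are implemented (`basis = "kinases"` is the default, since top-k is a
rank among kinases). Two further choices: a subsample in which the
target fails the overlap or variance filter counts as *non-recovery*
(that is what a real library of that size would deliver), and ties at
rank k count as recovered (a kinase equal to the k-th coefficient is
indistinguishable from it). Monte-Carlo estimates are validated against
exhaustive subset enumeration on 6-inhibitor toys.

## Clustering with bootstrap support

Distance `d = 1 − ρ` over pairwise-complete inhibitors, agglomerated
with Ward.D2 — pinned to the Murtagh–Legendre definition
(Lance–Williams recurrence on squared dissimilarities, heights reported
on the d scale) because "Ward" implementations differ. On
pairwise-complete overlaps the matrix can be non-Euclidean; Ward.D2 is
applied regardless, as is standard for this kind of data, and documented
as such. Bootstrap support resamples *inhibitors* (the observations
underlying every correlation) with replacement, recomputes distance and
tree, and counts, for each internal node of the full-data tree, the
fraction of bootstrap trees containing that exact leaf set (BP; clade
identity is the unordered leaf set). Replicates in which a pair loses
all variance are skipped and excluded from the denominator. The
multiscale AU p-value is optional (`multiscale = TRUE`): resample sizes
are scaled over 0.5–1.4 in steps of 0.1, per-scale BP values are
probit-transformed and a two-parameter signed-distance/curvature model
is fitted by weighted least squares, with `AU = 1 − Φ(d − c)`. BP is
always produced; AU roughly doubles the cost per scale and is off by
default. Trees export as Newick (ultrametric, leaf depth = height/2)
with internal labels `AU/BP` in rounded percent (BP alone when AU was
not computed); labels with metacharacters are single-quoted.

# The synthetic generator

The simulator provides the study conditions under which the pipeline is
validated:

* **Profiles** (`simulate_profile_dataset()`): 200 kinases in 10 family
  blocks × 300 inhibitors by default. Each inhibitor hits
  `1 + Geometric` kinases (mean promiscuity 3), each extra target drawn
  from the primary target's family with probability 0.6 — producing the
  within-family profile similarity that makes close homologs genuinely
  hard to separate. True targets are inhibited at 85 ± 8 percent;
  everything rides on 5 percent-point Gaussian background noise. Mutant
  entries, when requested, are flagged duplicates of wild-type columns.
  A Kd-kind variant inverts the Hill relation so the conversion path is
  exercised end to end.
* **Plates** (`simulate_screen_plates()`): inhibitor-well absorbance is
  `baseline × Σ_j w_j (100 − I_j)/100` plus Gaussian read noise (default
  sd 5% of baseline), DMSO wells at baseline, EDTA wells at a quenched
  background — the simplest model consistent with an ELISA readout
  proportional to phosphorylated substrate. Duplicates are adjacent;
  wells spill across 384-well plates with per-plate controls (16 DMSO,
  4 EDTA), guaranteeing the EDTA normalization path is exercised.

What the generator does *not* emulate: spatial plate effects, systematic
concentration errors, phosphatase activity, kinase cascades, or the
heavy-tailed missingness patterns of real published panels. Passing
tests therefore demonstrate correctness of the computations and
calibration under exchangeable noise — not that any particular real
screen will identify its kinase.

Two deliberate edge behaviours: with *exactly* zero read noise the DMSO
controls have zero spread and normalization refuses to divide by it
(tests use negligible-but-nonzero noise for "noise-free" arguments), and
absorbances are floored at 0, so profiles exceeding 100% inhibition
break exact affinity — bounded-profile fixtures are used where exactness
to 1e−9 is asserted.

# Numerical and reproducibility choices

* Every stochastic operation takes an explicit integer seed and restores
  the caller's RNG state; identical inputs and seed give bit-identical
  outputs, and run manifests record all seeds.
* Delimited writers format numerics to 15 significant digits, so decimal
  inputs of up to 6 significant digits round-trip bit-exactly.
* Correlations are computed by `stats::cor(use =
  "pairwise.complete.obs")`; the test suite verifies equality with an
  independent textbook implementation to 1e−12 on a thousand random
  instances, and Ward.D2 against a step-by-step agglomeration oracle on
  all instances up to 8 leaves across 100 seeds.
* Problem sizes used by the validation suite: 200 simulated screens on
  the default 200 × 300 panel for recovery (≥ 95% top-1 at 5% noise;
  chance-level ≈ 1/200 under overwhelming noise), 1,000 held-out
  permutations for null calibration, 1,000 bootstrap iterations for the
  duplicate-clade support check, and 1,000-rep Monte-Carlo downsampling
  against exhaustive enumeration (±0.03).

# Known limitations

* Mixtures: when several kinases contribute, the fingerprint is a
  weighted blend and the ranking tends to surface the dominant
  contributor and relatives of both — the simulator's mixture mode
  exists precisely to document this behaviour, not to deconvolve it.
* Gene-symbol harmonization is only as good as the user-supplied alias
  table; the package bundles no annotation database and performs no
  network lookups.
* The AU approximation degrades for clades whose BP is pinned at 0 or 1
  across all scales (it is reported as the degenerate limit), and for
  very small inhibitor counts where rescaled resamples are tiny.
* Exact reproduction of published screen analyses requires the original
  screen data and third-party profiling matrices, which are not bundled.
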