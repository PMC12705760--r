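---
title: "Searchlight RSA with verifiable synthetic ground truth: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Searchlight RSA with verifiable synthetic ground truth: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`slrsa` implements a complete searchlight representational similarity
analysis (RSA) pipeline for event-related fMRI — trial-wise activation
estimation, model and neural representational dissimilarity matrices
(RDMs), whole-brain searchlight comparison, group inference with
cluster-level family-wise error (FWE) control, and localizer-overlap
reporting — together with a synthetic-data module that can *plant* a
known representational geometry into simulated BOLD volumes.  The
planting is exact, so every stage of the pipeline can be validated
against ground truth on a desk-scale grid, without any imaging data.

The intended scientific use case is the recovery of semantic similarity
structure from multi-voxel activation patterns: a set of word
conditions (here abstract psychological concepts presented in a lexical
decision task), a model RDM built either from distributional semantic
vectors ("language RDM") or from behavioral property-listing profiles
("experience RDM"), and the question of *where* in the brain the neural
pattern geometry resembles the model geometry.

# The model pipeline

## Trial-wise first-level estimation (LSS)

Each trial's activation is estimated with the Least-Squares-Single
(LSS) scheme: one general linear model (GLM) per trial of interest,
containing three task regressors — the trial itself, all other trials
of interest combined, and all baseline (pseudoword) trials combined —
plus discrete-cosine drift regressors for all periods longer than the
high-pass cutoff (default 128 s), optional nuisance columns, and a
constant.  Task regressors are boxcars over event durations convolved
with the canonical double-gamma haemodynamic response function
(response gamma with 6 s delay, undershoot gamma with 16 s delay,
dispersions 1, undershoot ratio 1/6, 32 s support, unit-sum kernel).
Convolution runs on a 16-bins-per-TR oversampled grid and is sampled at
volume midpoints, so sub-TR onset jitter is honoured at 1/16 TR
resolution.

Temporal autocorrelation is handled by a single pooled AR(1)
coefficient: lag-1 autocorrelation of ordinary-least-squares residuals
pooled over all mask voxels, followed by Cochrane–Orcutt-style
whitening of data and design.  This is a deliberately simple global
AR(1) model; it is estimated once per run, not per voxel.

## RDMs and their comparison

All dissimilarities are correlation distances, `1 - Pearson r`.  The
language RDM is built from a concepts-by-dimensions embedding matrix
(the study-scale object is 58 × 400); the experience RDM from a
concepts-by-11 matrix of feature-category proportions.  For the
experience matrix, each participant's category counts for a concept are
first converted to proportions of that cell's total and then averaged
across the participants for whom the concept is available; missing
cells are excluded, never imputed or zero-filled.  The sentence-level
ambiguity between "average raw frequencies" and "average proportions"
is resolved in favour of proportions, since the per-cell proportion is
the quantity defined at the participant level; the package documents
this choice here and nowhere silently switches.

Concepts absent from the embedding vocabulary are dropped *and
reported* (`semantic_rdm()` attaches a `dropped_concepts` attribute and
messages the labels); at study scale this is the 64 → 58 filter.

Two RDMs are compared by Spearman rank correlation over the
off-diagonal upper-triangle cells (row-major vectorization shared by
one helper across neural and model RDMs; average ranks for ties, which
occur naturally among correlation distances).  Significance comes
either from an asymptotic t approximation or from jointly relabeling
the conditions of one RDM (rows and columns permuted together).

## Searchlight mapping

Searchlights are voxel-unit spheres (radius 3 by default, inclusive
boundary: 123 voxels) centred on every mask voxel whose sphere contains
at least 50% in-mask voxels.  The denominator of that fraction is the
full geometric sphere size, the literal reading of a "50% of voxels
within each sphere" threshold; a config flag is not provided, but the
fraction itself is a parameter.  At every centre the neighborhood's
neural RDM (correlation distance between normalized multi-voxel
patterns — normalization is a no-op under Pearson and is stated for
transparency) is compared to the model RDM by Spearman correlation, and
the coefficient is written to the centre voxel; everything else is NaN.
Searchlights with a constant pattern or a degenerate (zero-variance)
neural RDM are skipped and logged rather than imputed.

Spearman coefficients are *not* Fisher-z transformed before group
statistics: the group test operates on the correlation coefficients
directly, matching the convention of t-testing searchlight rho maps.

`partial_rsa_map()` controls for nuisance RDMs (e.g. low-level visual,
phonological or valence structure) by ranking all cell vectors first
and then linearly residualizing both the neural and the model ranks on
the nuisance ranks; the map value is the correlation of the residuals.
The exact confound set of the original confound-controlled analysis is
not specified in the main text, so this partial-correlation design is
the package's own declared formulation, not a claim about the original.

## Group inference

Subject maps over a common mask are screened for normality
(Shapiro–Wilk per voxel, Benjamini–Hochberg FDR at 0.05), then tested
with one-sample, two-sample (pooled variance) or paired t statistics.
Conjunctions use the minimum statistic under the conjunction null (both
conjuncts must exceed the cluster-forming threshold), the conservative
choice given that the global-null/conjunction-null distinction is not
stated in the source analyses.

Cluster-level FWE control is nonparametric: voxels exceeding the
one-sided threshold `qt(1 - voxel_p, df)` (defaults `voxel_p = 0.001`)
are grouped by 18-connectivity, and each cluster's corrected p value is
`(1 + #{null maximum >= observed}) / (1 + n_perm)` under sign-flipping
of subjects (one-sample/paired) or group-label permutation
(two-sample).  Clusters with corrected `p < 0.05` form the significance
mask.  Random-field-theory correction is intentionally out of scope;
the permutation analogue is the validated route.

**Tie-breaking by cluster mass.**  At desk-scale voxel counts (a few
thousand voxels) and `voxel_p = 0.001`, the null maximum cluster *size*
takes only two or three discrete values, and a pure size comparison
makes the permutation test conservative (measured family-wise rate
about 0.014 instead of 0.05).  The package therefore compares clusters
lexicographically: first by size, then — among equal sizes — by cluster
mass, the summed excess of the statistic over the forming threshold.
The mass component is continuous, so the permutation test is exact,
while any comparison between clusters of different sizes is unchanged.
On smooth, well-powered brain maps the refinement is invisible; on
coarse synthetic maps it restores the nominal error rate (measured
0.0575 over 400 null datasets, consistent with 0.05).

Peak "z-score" columns are produced from t values by the
probability-matching transform `z = qnorm(pt(t, df))`, computed on the
log scale at the tails.

## Reporting

`overlap_percent()` is `100 |A ∩ B| / |A|`, the percentage of
significant voxels falling inside a localizer activation mask; it is
undefined (NA with a warning) for an empty numerator mask.
`cluster_table()` reports one row per local maximum (greedy selection
in decreasing statistic order, at least 8 mm separation, at most 16 per
cluster — the convention behind multi-row cluster listings; both knobs
are arguments), with cluster size, per-cluster and whole-map localizer
overlaps at one decimal, and peak coordinates in world mm.  World
coordinates place the origin at the volume centre
(`world = (ijk - (dim + 1) / 2) * voxel_size`); anatomical labelling is
out of scope.

## Inter-rater reliability

Property codings of two raters are compared per category with the
two-way, absolute-agreement, single-measure intraclass correlation
ICC(A,1), computed from the items × raters mean-squares decomposition;
items are concepts and ratings are each rater's classification
frequency for the category.  Absolute agreement (not consistency) is
the criterion, and the single-measure form is used because each
category's reliability is interpreted on the scale of one rater's
coding; the single- vs average-measures choice is not stated in the
source description and is fixed here as ICC(A,1).  The summary index is
the frequency-weighted mean of per-category ICCs, weighting by the mean
classification frequency of the two raters.

# The synthetic-data module

## What it emulates

* **Lexical decision run**: 64 word and 64 pseudoword trials of 2400 ms
  each, ITIs drawn from a right-skewed gamma distribution matched to
  mean 3173 ms and SD 3435 ms, truncated at zero by construction, with
  the condition sequence constrained to at most 3 consecutive repeats.
  The true ITI distribution of the optimized sequence is unknown (only
  its mean and SD are printed), so the gamma family is a declared
  stand-in matched to both printed moments; `iti_sd_ms = 0` gives a
  deterministic TR-locked design used by the exactness tests.
* **Localizer blocks**: visual (six 24 s blocks, 27.8 s rests), motor
  (eight 26 s blocks alternating with 26 s rests, hands merged into one
  condition), emotional (twelve 23.8 s blocks, six emotional + six
  neutral, 5.8 s fixation between blocks).
* **Pseudowords**: one vowel replaced by a different vowel and one
  consonant by a different consonant, length preserved; vowels include
  the German umlauts.
* **Semantic space**: concepts as positive mixtures of a few latent
  factors plus isotropic noise.  Positive mixing weights make the
  single-factor, zero-noise case perfectly correlated (an all-zero
  RDM), a useful degenerate test.
* **Property listings**: per participant × concept, a Poisson number of
  properties (mean 3.5, the instructed "three to four") multinomially
  distributed over the 11 feature categories according to a
  concept-specific profile shared across participants; cells are
  flagged missing with a small probability (default 2%, the observed
  order of magnitude), and missing cells carry no counts.
* **BOLD volumes**: HRF-convolved condition regressors scaled by
  per-voxel planted pattern values inside an ROI, stationary AR(1)
  Gaussian noise in the mask, optional slow sinusoidal/linear
  motion-like drifts, 2 s TR, 2 mm voxels, 20³ default grid with an
  ellipsoidal mask — desk-scale while leaving room for radius-3
  searchlights.

## What it does not emulate

No slice-timing structure, no realignment or normalization residuals,
no physiological noise, spatial noise correlations or susceptibility
dropout, no optimized-sequence efficiency structure, and no lexical
realism of pseudowords beyond the letter-class constraint.  Passing
tests therefore certify the *estimation and inference machinery*, not
robustness to every artefact of real acquisitions.  Two further honest
gaps: the synthetic semantic space and property listings are generated
independently of each other, so their model RDMs are uncorrelated
(near-zero Spearman rho), whereas real listings are weakly coupled to
word statistics; and synthetic concept profiles are more distinct than
real listings, so simulated two-rater agreement indices run higher than
the moderate reliability of human coders.

## Exact geometry planting

`embed_geometry()` turns a target RDM into per-condition voxel
patterns whose correlation-distance RDM *equals* the target.

With the default random basis, the similarity matrix `S = 1 - d` is
eigen-factorized and mixed with random centred orthonormal voxel basis
vectors; the sample correlation matrix over **all** ROI voxels is then
exactly `S`.  This requires `S` to be positive semidefinite (otherwise
the target is not correlation-realizable and the function says so) and
at least `rank(S) + 1` voxels — the `+ 1` pays for the centring.

A subtlety motivates the second construction: a searchlight sees only a
*subset* of the ROI, and sample correlations over a subset differ from
those over the full ROI for any generic pattern set (an extreme case:
over two voxels every correlation is ±1).  Exact searchlight-level
recovery is therefore impossible for arbitrary targets — but achievable
for rank-2 geometries.  With `basis = "harmonic"`, conditions are laid
on a spatial quadrature pair `cos(ω·v)`, `sin(ω·v)` whose frequency ω
is chosen (by grid scan plus Newton refinement, to ~1e-13) so that the
searchlight sphere's window transform vanishes at both ω and 2ω.  Sums
of the basis functions, their squares' difference and their cross
product over *every fully interior sphere* are then exactly zero, so
every such searchlight sees the exact target correlations, and a
noise-free pipeline returns Spearman rho = 1 at machine precision at
every ROI-interior centre.  The guarantee moves from the full ROI to
its interior spheres; the two modes are complementary and both
documented on the function.

One further condition makes the *estimation* stage exact: LSS
coefficients on noise-free data are free of cross-trial leakage when
all trials have identical regressor shape and disjoint temporal support
(onsets sharing their phase modulo TR, ITIs at least the 32 s HRF
support).  Under those conditions the projection geometry cancels all
other-trial contributions identically (verified to ~1e-15).  The
end-to-end validation therefore uses a slow, jitter-free event design;
with the study's fast jittered design LSS recovery is — as in real
fMRI — approximate.

# Validation design and problem sizes

The test suite validates each operation against an independent oracle
(hand-computed Pearson/Spearman, normal-equations solutions, anova
mean squares, offset enumeration, analytic Gaussian kernels, an
externally frozen Shapiro–Wilk reference value) and the pipeline as a
whole against planted ground truth.  The statistical checks use these
desk-scale conditions, chosen once:

* end-to-end planted geometry: 58 conditions, 20³ grid, ellipsoidal
  mask (~3100 voxels), 300-voxel spherical ROI, zero noise;
* LSS-vs-OLS: 64 + 64 trials, 500 voxels, unit Gaussian noise;
* FWE calibration: 200 null datasets, 12 subjects, 2000 voxels, 500
  sign-flip permutations, exact binomial 99% acceptance band;
* parameter recovery: pattern amplitude 8 at unit noise — calibrated
  once so the single-subject mean ROI rho is about 0.2 — 12 subjects,
  20 datasets, with a 300-voxel control region separated from the ROI
  by more than the searchlight radius plus both region radii;
* permutation-p uniformity: 500 null RDM pairs, 199 relabelings each.

`scripts/acceptance.R` re-runs these computations from scratch against
the installed package and writes the resulting quantities as JSON.

# Known limitations

Pooled (not voxel-wise) AR(1); no spatial covariance in the noise
model; harmonic planting limited to rank-2 targets; cluster inference
offers no TFCE or covariate models; partial Spearman correlation is the
rank-then-residualize formulation (not a full semi-partial rank
theory); BFS component labelling and R-level searchlight loops are
adequate at desk scale but not tuned for 1 mm whole-brain grids.
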