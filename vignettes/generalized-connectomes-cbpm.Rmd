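---
title: "Generalized functional connectomes and connectome-based predictive modeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generalized functional connectomes and connectome-based predictive modeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`genconn` implements an individual-differences pipeline for functional
connectomics: ROI time series are denoised and correlated into per-run
connectomes, averaged across runs into a "generalized" connectome per
subject, summarized at the network level, related to behavior through
covariate-adjusted linear models, and mined for predictive structure with
connectome-based predictive modeling (CBPM) under leave-one-out
cross-validation and permutation inference. A synthetic cohort generator
with planted edge–behavior effects makes every stage testable without
scanner data.

## The data model

An atlas of `R` regions defines the nodes. The default preset has 400
cortical parcels in 17 networks plus 6 hippocampal ROIs (head/body/tail per
hemisphere), for a 406 × 406 connectome. Two default-mode subnetworks play
named roles: DMN-C (13 parcels: 7 left, 6 right; parahippocampal,
retrosplenial, posterior angular regions) and DMN-A (34 parcels: 18 left,
16 right). Published sources are inconsistent about the size of the
remaining set (it is quoted both as completing 400 parcels and as 176 + 178
= 354 parcels, which would total 401); we keep the 400-parcel total and
distribute 353 parcels over the other 15 networks with plausible sizes and
a near-even hemisphere split. Edges are handled as the lower triangle in a
fixed order (pairs `(i, j)` with `i > j`, enumerated row by row), giving
`E = R(R-1)/2` edge positions that round-trip exactly between matrix and
vector form.

## Per-run denoising and the generalized connectome

The per-run pipeline order is fixed: confound regression, then band-pass
filtering, then Pearson correlation.

The confound design concatenates the six rigid-body motion parameters,
their temporal derivatives and quadratics, up to the first six
component-based noise regressors, framewise displacement, the global
signal (on by default; both modes run because its inclusion is known to
shift brain–behavior results), spike indicator columns for any timepoint
with FD > 0.6 mm or standardized DVARS > 2 (strict inequalities), and — for
sensorimotor task runs only — stimulus onsets convolved with a canonical
double-gamma HRF (response peak 5 s, undershoot peak 15 s, ratio 6).
Constant or duplicate columns are pruned with a warning; residual rank
deficiency is an error naming the collinear columns.

The band-pass (0.008–0.1 Hz) is a second-order Butterworth applied
forward-backward, so the phase is zero and the effective magnitude response
is the square of the prototype. Only the corner frequencies are contractual;
conformance is spectral (passband loss under 5%, stopband attenuation of
80% or more, DC removed), not coefficient-by-coefficient, since
published processing toolboxes do not document their exact filters.

Per-run Pearson connectomes are averaged into the generalized connectome on
the Fisher-z scale (`tanh(mean(atanh(r)))`), with raw-r averaging behind a
flag as a sensitivity variant. Per-edge values are sorted before summation,
which makes the average exactly invariant to run order despite
floating-point non-associativity. Participant QC applies the study rules: a
run is bad when its mean FD exceeds 0.3 mm strictly; a subject is dropped
at two or more bad runs, age outside 18–50, or missing age (listwise
deletion). A retained subject's single bad run is dropped from the average
by default; the alternative (keep it) is a documented option because the
source protocol does not state which was done.

## Behavioral scores and association models

Narrative recall is the mean of immediate and ~20-minute delayed
story-detail counts; the composite memory score is the mean of the z-scored
narrative and emotional-recall scores for subjects who have both.
Standardization uses the sample SD (n − 1). Association models are OLS with
all variables z-scored, so the reported coefficient is a standardized beta;
the binary sex indicator is z-scored along with the rest (the convention is
not stated in the source protocol, so the raw-scale beta is reported
alongside). Covariate sets are `none`, `motion_demographic` (age, sex, mean
FD), and `full` (adding fluid intelligence and the cognitive screen), with
listwise deletion per model and two-sided t tests.

## CBPM

For each left-out subject, every edge's partial correlation with behavior
given the nuisance covariates (age, sex, mean FD by default; plain Pearson
when none) is computed on the training subjects only. Edges with two-sided
`p < alpha` (default 0.01, from the exact t transform with
`df = n - 2 - c`) are split by sign; each training subject's selected edges
are summed into positive and negative strengths; an OLS of behavior on
intercept + positive + negative strengths is fit on the training rows and
applied to the held-out subject. Performance is the Pearson correlation
between observed and predicted behavior across subjects.

Numerical and degenerate-case choices:

* Selection uses the equivalence `p < alpha` ⇔ `|r| > r_crit`, with
  `r_crit` derived once per fold from the t quantile — identical to
  thresholding the p-values but cheaper at `E` edges. At `alpha = 1` this
  degrades gracefully to selecting every non-constant edge by sign.
* Constant edges are unselectable, logged, never fatal.
* A fold with no usable strength term predicts the training mean; the fold
  is logged, and a run in which every fold falls back is flagged
  `degenerate`. A prediction vector with zero variance leaves the
  performance correlation undefined (`NA` with status), not an error.
* The permutation test reruns the entire procedure — including per-fold
  edge reselection — on each of `n_permutations` (default 100) random
  re-pairings of behavior with connectomes; covariates stay attached to the
  connectome side (a joint-permutation variant is available). The p-value
  is the plain proportion of null runs performing at least as well (ties
  count against the observed result, so p = 0 is attainable); the
  conservative (b+1)/(m+1) estimator is reported alongside. Null runs with
  degenerate predictions count as not-better and are tallied.
* The lesion analysis removes every edge incident to each network in turn
  and reruns LOOCV + permutation on the reduced edge set.

The LOOCV engine is compiled (RcppArmadillo). Partial correlations are
computed from cross-products against the centered covariate design —
mathematically identical to correlating OLS residuals, and verified against
a residualize-then-Pearson oracle in the test suite. Each fold uses only
its training rows; no statistic of the held-out subject enters selection or
fitting, which the suite asserts by corrupting held-out rows and requiring
bit-identical fold masks and coefficients.

## The synthetic cohort generator

The generator emulates the statistical structure the analysis assumes, not
the physics of fMRI. Per subject, a connectome is built on the Fisher-z
scale as

```
z_edge = z_group(edge) + beta_edge * b_std + sum_j gamma_j * u_j + noise
```

where `z_group` is a network-block mean (within-network 0.35, between
0.05 — plausible magnitudes for denoised adult data, configurable, not
claims), `b_std` is the subject's standardized behavior, `beta_edge` is
nonzero only on planted signal edges, `u_j` are standardized nuisance
covariates (age uniform 18–50; sex Bernoulli(0.5) coded 1 = female; mean
FD, fluid intelligence and cognitive screen normal with magnitudes typical
of adult community samples), and the per-edge noise SD defaults to 0.1
Fisher-z units. Behavior is a loading-weighted sum of the covariates plus
noise; planting on the z scale keeps back-transformed correlations bounded
in (−1, 1) and matches the averaging scale used downstream. The covariate
edge loadings `gamma_j` are applied uniformly to all edges — a global
confound shift — because the source material characterizes covariate–edge
association only at the summary level. Observed memory scores are affine
transforms of the latent behavior with means and SDs matching a published
adult sample (narrative recall 15.28 ± 3.50; the emotional score exists for
half the cohort).

Time series are drawn iid multivariate normal with the subject's connectome
as population correlation (after eigenvalue-clipping repair to the nearest
positive-semidefinite matrix, re-scaled to unit diagonal, with the
Frobenius adjustment recorded), plus optional additive motion-drift and
AR(1) global-signal confound time courses with known loadings. What this
does **not** emulate: hemodynamics, autocorrelated BOLD noise,
spatially-structured artifact, realistic motion. Passing tests therefore
demonstrate the correctness of the estimators and the inference machinery
under the assumed model, not robustness to real scanner noise.

## Validation design and problem sizes

The suite validates each stage against independent oracles (nested-loop
summaries, residualize-then-Pearson selection, closed-form Fisher
averaging, Monte-Carlo planted-effect recovery) and then exercises the full
chain at deliberately chosen scales:

* **Planted-signal recovery** uses the study-scale design: 243 subjects, a
  64-ROI atlas (2016 edges), 50 signal edges at beta = 0.3 confined to one
  network, nuisance covariates loading on both edges and behavior. CBPM
  recovers the planted edges and the lesion analysis localizes them.
* **Calibration** uses 200 null cohorts (60 subjects, 528 edges from a
  33-ROI atlas — the nearest atlas-constrained size to a nominal 500 —
  100 permutations each). The rejection rate at the 0.05 level must stay
  within the binomial band [0.02, 0.10]; at these conditions it is 0.04.
  Nuisance covariates influence behavior and edges but are only partialled
  out during selection (as in the published protocol), not during
  prediction, so mild anticonservatism under heavily confounded nulls is a
  property of the method itself, worth remembering when interpreting small
  permutation p-values.
* **Connectome recovery** uses a 20-ROI target at T = 2000 (TR 2 s): the
  pipeline's mean absolute edge error must stay below `2/sqrt(T-3)`, twice
  the Fisher sampling SE, the factor 2 covering the autocorrelation the
  band-pass introduces.
* The demonstration workflow in `analysis/` runs a 120-subject, 30-ROI
  cohort (2 runs of 150 timepoints) end to end in a few minutes.

## Known limitations

Beyond the generator's idealizations: no image-level preprocessing (inputs
are ROI tables with precomputed FD/DVARS/component regressors), LOOCV only
(no k-fold variants), no multiple-comparison correction across the four
network summaries (matching the reference protocol, which reports
uncorrected per-model tests), and summed strengths are used raw (a
normalization flag exists but the reference protocol does not state one was
applied).
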