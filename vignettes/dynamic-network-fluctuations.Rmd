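---
title: "Dynamic network fluctuations: models, measures and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic network fluctuations: models, measures and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

fluctnet implements a time-resolved analysis of parcellated resting-state
BOLD data built for the study of cognitive fluctuations in Dementia with Lewy
bodies (DLB): how stationary a brain's activity configurations are over time,
how integrated or segregated its network topology is from moment to moment,
how stable each region's module membership is, how these properties relate to
sustained-attention performance through a diffusion model, and how regional
group differences co-locate with receptor gene expression. Because clinical
resting-state cohorts of this kind are rarely shareable, the package also
contains a fully seeded synthetic-cohort generator, and every analysis is
validated against data with known (planted) structure.

This vignette explains the models and the choices behind them. It states no
empirical result that the package's test suite or `scripts/acceptance.R` do
not themselves compute.

## The pipeline

For each subject, `run_study()` executes a fixed order:

1. **QC** — framewise displacement (FD) from the six rigid-body motion
   parameters (Power-style sum of absolute derivatives, rotations converted to
   arc length at a 50 mm head radius) and DVARS (RMS frame-to-frame signal
   change, as % of the grand-mean signal). Frames with FD > 0.25 mm or
   DVARS > 2.5% are flagged; a subject with strictly more than 10% of frames
   flagged is marked for exclusion.
2. **Nuisance regression** — OLS residualisation of every region on an
   intercept plus a caller-supplied regressor matrix. The pipeline uses the 6
   motion parameters, their temporal derivatives, FD and DVARS. The package
   deliberately exposes a generic regressor interface: anatomical-mask
   component regressors (aCompCor-style) exist only in voxel space, which is
   out of scope here, and published descriptions of "12 movement parameters
   (and their temporal derivatives)" are ambiguous about the exact set.
3. **Band-pass** — zero-phase (forward–backward) Butterworth of order 4 with
   pass band 0.071–0.125 Hz. Zero-phase filtering is chosen so that filtering
   cannot shift connectivity timing; the response is verified on sinusoids
   (passband amplitude preserved within 5% at 0.1 Hz, ≥ 90% attenuation at
   0.01 Hz, at TR = 3 s).
4. **MTD connectivity** — the coupling between regions i and j at time t is
   the product of their SD-normalised temporal derivatives, averaged over a
   15-sample rectangular sliding window (~45 s at TR = 3 s). The derivative
   SD is computed over the full series, not per window, so scores are
   comparable across windows; windows are "valid" (fully inside the series),
   giving `timepoints − window` windows; the diagonal is zeroed and excluded
   from all graph measures. Rectangular weighting is an assumption — the
   window shape used in the original description is unstated.

## Temporal similarity statistics

Patterns are compared across time with Pearson correlation, giving an
epochs × epochs similarity matrix. Two summaries:

* **Local similarity** `S_L`: the mean of the `n − 1` correlations between
  temporally adjacent patterns (first off-diagonal). High values mean
  stationary, slowly reconfiguring dynamics.
* **Global similarity** `S_G`: `(Σ|r| − n) / (n(n−1))` over the whole matrix
  — the mean absolute off-diagonal correlation. High values mean a small
  repertoire of recurring configurations. The diagonal-inclusive sum minus
  `n` is adopted because it makes the `n(n−1)` normaliser exact; `S_L` keeps
  signed correlations while `S_G` takes absolute values, deliberately.

Both an **activity** mode (one pattern per TR: the regions-long BOLD vector)
and a **connectivity** mode (one pattern per MTD window: the vectorised upper
triangle) are first-class. The package default for `similarity()` is
activity mode, but `run_study()` uses connectivity mode, for a reason worth
stating precisely: a 0.071–0.125 Hz band at TR = 3 s places the passband
centre at ~0.59 of Nyquist, which forces the lag-1 autocorrelation of every
filtered time course — and hence the correlation of adjacent *activity*
patterns — to be negative. Positive, large `S_L` values of the kind reported
for patient cohorts can only arise from patterns that change slowly by
construction, which the overlapping-window connectivity patterns are. The two
modes measure genuinely different things and should not be expected to agree
numerically; both are exposed and logged.

## Time-resolved topology

Each windowed MTD slice is treated as a signed weighted graph. Negative
weights are excluded from community detection and from both nodal measures —
a documented, configurable assumption (the convention in the source
literature is unreported).

* **Communities**: Louvain modularity maximisation per window (resolution
  γ = 1 by default), 10 seeded restarts, best modularity kept — a determinism
  contract the underlying algorithm does not provide by itself. An all-zero
  slice yields a single module with a warning.
* **Participation coefficient** `B_T`: `1 − Σ_s (κ_is/k_i)²` with positive
  strengths; 0 when all links stay in one module, bounded by `1 − 1/M`.
  Isolated regions get 0.
* **Module-degree z-score** `W_T`: within-module strength standardised within
  the module (sample SD; modules of size 1 or zero variance get 0).
* **Cartographic profile**: the joint 2-D histogram of `(B_T, W_T)` over all
  regions and windows; 100 × 100 bins by default, participation on [0, 1],
  z clipped to [−5, 5] so counts are always conserved. Bin edges travel with
  the object so group comparisons always share them.
* **Segregated-state occupancy**: k-means (k = 2) on a subject's pooled
  participation values; the lower-centroid cluster is "segregated", and each
  region's occupancy is the fraction of its windows spent there. Pooling
  across regions and windows (rather than clustering per region) gives
  "segregated" a single subject-level meaning.

## Label matching and flexibility

Module ids from per-window detection are arbitrary, so consecutive windows
are aligned by solving the maximum-overlap assignment between their module
labels with a Hungarian algorithm (written in-house; an exhaustive
permutation-search oracle verifies it in the tests). Matched modules inherit
the previous label; modules with no overlap at all onto any previous label
get fresh ids and count toward the subject's module total.

Regional **flexibility** is the fraction of consecutive window pairs in which
a region's matched label changes, divided by the number of modules. The
normaliser defaults to the subject-level count of distinct matched labels;
"normalised to the total number of modules" admits a per-window reading,
which is available behind `normalise = "per_window"`. The printed group means
in the source literature cannot disambiguate the two without the data.

## Behavior: closed-form diffusion fit

Sustained-attention performance is summarised by mean RT and RT variance of
correct trials plus accuracy, and inverted to the three-parameter diffusion
model (drift rate, boundary separation, non-decision time) with the standard
closed-form method-of-moments solution (EZ-style), diffusion coefficient
fixed at 0.1 to resolve the model's scale indeterminacy. Accuracies of
exactly 0, 1/2 or 1 are edge-corrected by 1/(2n) before fitting. The forward
moment equations are implemented too (`ddm_moments()`), and the fit inverts
them exactly (tested to 1e−10); parameter recovery from the package's own
trial simulator is tested at 10,000 trials within 10%. Correct-trial-only RT
moments are used; no starting-point or variability parameters are modelled.

## Inference

Group comparisons use permutation tests with covariate adjustment by prior
residualisation (Freedman–Lane style): the outcome is residualised on
intercept + covariates, group labels are permuted (5,000 by default), and the
two-sided p-value carries the +1 correction so it is never exactly zero.
Cohen's d is computed on the residualised values with pooled SD. This is the
package's key inferential assumption — "controlling for age and sex" admits
several constructions, and residualise-then-permute is the one implemented
and calibrated (type-I error within the binomial interval in the tests).
Rank or Pearson correlations use the same permutation machinery.
Mann-Whitney U is reported for the first sample, with an exact null when the
combined n ≤ 12 and no ties. FDR control is Benjamini–Hochberg throughout
(q = 0.05 for cartographic bins; q = 0.1 for gene screens and regional maps,
matching the conventions of the study this design follows).

Gene-expression mapping correlates (Spearman) each gene's regional mean
expression with a per-region group-difference map, aligned strictly by
region label; difference-map conventions are control − DLB for participation
(positive = less integration in the patient-like group) and DLB − control
for flexibility. Spatial autocorrelation of expression maps is *not*
corrected for — deliberately matching the analysis being reproduced; this is
a known limitation of that analysis, not an oversight.

## The synthetic cohort: what it emulates and what it does not

`simulate_subject()` draws a hidden state sequence with geometric
(memoryless) dwell times — the simplest process with a controllable mean
dwell, since no generative account of the fluctuations exists to copy — and
samples each timepoint from the active state's block-structured correlation
(compound-symmetric: one within-module and one between-module coupling) plus
white observation noise, via an exact latent-factor construction (global
factor, module factors, idiosyncratic residual). Ground truth (state
sequence, unstable-region host sequences, planted genes, true diffusion
parameters) is always returned with the data.

The frozen study presets, chosen once as this package's definition of the
two conditions:

| parameter | control-like | DLB-like |
|---|---|---|
| states in repertoire | 6 | 3 |
| mean dwell (samples) | 5 | 25 |
| within-module coupling | 0.6 | 0.7 |
| between-module coupling | 0.25 | 0.1 |
| unstable-allegiance regions | none | 20% (host dwell 16) |
| observation noise SD | 1 | 1 |

with 60 regions in 3 modules, 200 timepoints at TR = 3 s and 20 subjects per
group. Covariates are simulated with deliberate group offsets (age 74 ± 6 vs
70 ± 6 years; P(male) 0.5 vs 0.8) so covariate-adjusted inference has a real
confound to remove. The DLB-like condition is slower-switching, more
segregated (stronger within-, weaker between-module coupling) and contains
regions whose module allegiance itself drifts — the generative counterpart of
unstable module membership. Behavioral parameters are generated *from* each
subject's realised dynamics: drift rate is log-linear in the subject's
standardised local similarity (slope 0.2, lognormal noise 0.25), planting a
brain–behavior association of roughly Spearman 0.6 for the correlation
analyses to recover.

What the generator does **not** emulate: hemodynamic convolution and temporal
autocorrelation of BOLD, spatial smoothness of parcels, scanner drift,
voxel-level artefacts, atrophy, eye closure/sleep, and any non-stationarity
beyond discrete state switching. Tests passing on this generator demonstrate
that the measures recover the structure they claim to measure, under the
model's assumptions — not that the clinical effect sizes would reproduce on
real data.

### A structural trade-off worth knowing about

With 15-sample windows, per-window community detection is noisy, and measured
flexibility is dominated by label churn that grows with module *blurriness*
(the between/within coupling ratio as seen through estimation noise). This
couples the measures: a fast-mixing, relatively integrated condition (the
control-like preset) necessarily has window patterns that are less reliable —
which is exactly what makes its global similarity low *and* its label churn
high. Conversely, every mechanism that makes the patient-like condition
switch labels more (unstable allegiance, diluted attachment) also
decorrelates its connectivity patterns and erodes its global-similarity
advantage at close to one-for-one. In this generative family the package can
therefore plant and recover: higher S_L, higher S_G, lower mean B_T and
higher segregated occupancy in the DLB-like group, and higher flexibility of
*planted unstable regions relative to stable regions within a subject* — but
not simultaneously a group-level flexibility excess in the DLB-like group.
The group flexibility contrast in the synthetic study comes out level or
reversed, and the test suite reports that honestly rather than tuning the
generator around it. On real data the dissociation presumably arises from
features this generator deliberately lacks (e.g. non-uniform, hub-mediated
integration, which keeps healthy modules crisp despite high integration).

## Numerical and degenerate-input conventions

* Every generator and every stochastic analysis step is a pure function of
  its inputs and a seed; master seeds fan out to per-subject substreams
  (`derive_seeds()`), so cohorts are reproducible subject-by-subject.
* Zero-variance inputs are errors where a statistic is undefined (derivative
  of a constant region, constant pattern epochs, constant outcome vectors,
  zero pooled SD) and conventions where a bounded measure has a natural
  limit (isolated region: B = 0; size-1 or zero-SD module: W = 0).
* k-means occupancy re-seeds up to 5 times if a cluster comes back empty,
  then errors.
* Permutation p-values use the +1 correction; the smallest attainable p is
  1/(n_perm + 1).
* Per-window community detection has an estimation-noise floor: with
  15-sample windows, two planted module factors correlate by chance strongly
  enough that merging them is the modularity-optimal description of that
  window's data in roughly one window in ten, independent of coupling
  strength. Perfect per-window recovery of planted partitions should be
  expected only for windows of roughly twice that length.
* The problem sizes used by the test suite and the acceptance script (60
  regions, 200 timepoints, 20 subjects/group; 200-seed Monte-Carlo loops for
  planted-gene detection; 500–1,000 replicates for calibration) are the
  package's chosen synthetic-study scale, stated here so results are read at
  that scale.

## Worked example

```{r, eval = FALSE}
library(fluctnet)

# one subject under the DLB-like preset
model <- preset_state_model("dlb")
ts <- simulate_subject(model, n_timepoints = 200, seed = 1)
pp <- preprocess_subject(ts, simulate_motion(200, seed = 2))
dc <- mtd_tensor(pp$ts, window = 15)

sim <- similarity(ts = pp$ts, dc = dc, mode = "connectivity")
tidy(sim)

assign <- detect_communities(dc, seed = 1)
topo <- topology_series(dc, assign)
occ <- segregated_occupancy(topo, seed = 1)
flex <- regional_flexibility(match_labels(assign))

autoplot(cartographic_profile(topo, normalise = TRUE))

# the whole study, end to end
res <- run_study(default_config(), seed = 1)
res$group_tests
```
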