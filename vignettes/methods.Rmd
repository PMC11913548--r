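---
title: "Models and design choices in gilashift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in gilashift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

gilashift forecasts where a dispersal-limited desert reptile — the Gila
monster (*Heloderma suspectum*) of the northeastern Mojave — can plausibly
live under changing climate. It chains four models: a presence-only
ensemble habitat model, a Brownian bridge movement model fit to telemetry,
a decadal climate projection with a reachability-constrained occupancy
update, and a protected-area gap tabulation. Because real Gila monster
localities are withheld from public release (poaching risk), the package
ships a synthetic-data generator with a known truth so every stage can be
exercised and validated end to end. This vignette explains each model, its
assumptions, the tunable constants, and the design decisions that were
genuinely open.

## The habitat model

Habitat suitability is modeled from presence records only. Four learners
are fit to presences versus pseudo-absences: a regression-mode random
forest, gradient-boosted trees, a binomial GAM with smooth terms, and an
L1-regularized logistic model on linear + quadratic standardized features
fit against a uniform background — the standard convex-likelihood
equivalent of the MaxEnt family (exact parity with the Java implementation
is a non-goal). The MaxEnt-family learner draws its own uniform background
(up to 10,000 cells); the other three are fit with an equal number of
presence and pseudo-absence points.

Tree ensembles fit to presence–background data are prone to saturated,
near-binary probability surfaces when the background is easily separable,
which destroys rank calibration in the middle of the suitability range.
The defaults therefore follow presence-background practice for calibrated
probability surfaces: the random forest is fit in regression mode on the
0/1 response with large terminal nodes (`nodesize = 40`, 1000 trees), and
the boosted trees are shallow (`max_depth = 2`), slow (`eta = 0.05`, 300
rounds), row-subsampled and leaf-regularized. All hyperparameters are
overridable through `learner_spec()`.

**Occurrence preparation.** Raw records are rasterized to the 250 m
modeling grid (one presence per cell), then thinned on a 1000 m grid with
at most 4 points per coarse cell, the retained subset drawn uniformly.
Thinning is seeded and idempotent. Opportunistic records cluster in
easy-to-access places, so a sampling-effort surface is estimated by a 2-D
Gaussian kernel density over records of other readily reported reptiles,
with Scott's-rule bandwidth per axis, rescaled to (0, 1] with a 1e-6 floor
(whether the original analysis rescaled the raw density is unstated; the
rescaled form is used because only relative weights matter downstream).

**Pseudo-absences.** A Bioclim climate envelope is fit to the presence
values of the two climate covariates (empirical CDFs with the ≤
convention; the envelope is configurable to more covariates). A cell whose
two-sided tail score `2·min(F, 1−F)`, minimized over covariates, falls
below 0.05 is a pseudo-absence candidate: climatically outside the
species' envelope. Candidates are drawn without replacement with
probability proportional to the effort surface, so contrast points sit
where the species would have been recorded had it been present. The draw
weight is also forwarded as a case weight to learners that accept one —
the description of the original weighting is ambiguous between the two
mechanisms, so both are applied and each is configurable.

**Cross-validation and the ensemble.** Twenty iterations withhold a random
20% of presences, with a fresh pseudo-absence draw per iteration; a
separate 10-iteration 80/20 pass is available for importance work.
Covariates are screened greedily before fitting: while any pair correlates
at |r| ≥ 0.7, the member of the worst pair with the higher variance
inflation factor is dropped. Per algorithm, models above that algorithm's
median held-out AUC become candidates (a degenerate all-tied algorithm
keeps all its models, with a warning); candidates are averaged with
weights proportional to their TSS (negatives clipped to zero), and the
four algorithm ensembles are combined with weights proportional to mean
TSS. The pooled-versus-within-algorithm reading of the median-AUC rule is
ambiguous in the source; within-algorithm is used so each algorithm
contributes, and flat pooling remains available. The ensemble standard
error is the unweighted standard deviation across all candidates divided
by √k. The binary threshold maximizes sensitivity + specificity of the
ensemble prediction (ties resolved toward the lower threshold; separable
instances return the gap midpoint).

**Evaluation.** AUC is the Mann–Whitney pair statistic (ties = ½). TSS is
reported at each model's own max-sens+spec threshold, since no separate
TSS threshold is specified anywhere. The continuous Boyce index slides a
window of width 0.1 × score range across 101 midpoints and rank-correlates
the predicted/expected ratio with the midpoint; windows with zero expected
mass are dropped. Sørensen similarity `2TP/(2TP+FN+FP)` summarizes the
thresholded model. In the synthetic study the held-out evaluation uses a
fresh detection-*unbiased* presence draw from the truth — a validation set
real studies cannot have; with biased holdouts the Boyce index conflates
detection bias with calibration.

## The movement model

Telemetry is filtered to actual movements: animals with ≤ 40 fixes or ≤ 1
year of data are excluded; zero-displacement relocations and steps under
50 m are removed sequentially; and fixes separated by more than 36 h start
a new burst, so no Brownian bridge spans a long gap.

The Brownian bridge movement model treats the position at time fraction α
between consecutive fixes as Normal around the connecting line with
variance `T·α(1−α)·σ²m + (1−α)²δ² + α²δ²`, where σ²m is the Brownian
motion variance and δ the telemetry location error (default 15 m, typical
of VHF; the source never states its value). σ²m is estimated by
leave-one-out maximum likelihood over the odd-indexed interior fixes,
optimized on log σ²m. The occurrence surface integrates the bridge density
over 50 midpoint α-steps per segment, weights segments by duration,
multiplies by cell area and renormalizes to total mass one; halving the
step count changes cell masses by under 1%.

One hundred points are sampled per animal's surface, uniformly over the
cells above the 1e-8 cutoff — uniformly rather than
probability-weighted, because the regression response *is* the surface
value and weighted sampling would confound it. The response is the cell
probability mass (not density); under a fixed grid the two differ only by
an affine shift on the log scale. Log surface value is regressed on
movement covariates — linear + quadratic terms for slope, ruggedness and
shrub cover, linear topographic position and habitat suitability, and
log-distance terms for roads and paths — with a per-animal random
intercept, by REML. Animals from all sites are pooled at the regression
stage with the animal intercept absorbing site differences. Inference uses
Wald statistics. A singular random-intercept fit falls back to the
fixed-effects model with a warning. Prediction uses fixed effects only,
exponentiated and min–max rescaled, with heavily impervious cells masked
as movement barriers; validation reports the percentile of the mean
prediction at holdout telemetry among all cells.

## Climate projection and occupiable habitat

Future climates come as decadal averages: winter precipitation is the mean
over the decade of November–March totals, spring temperature the mean of
March–May means. Coarse forecasts are delta-downscaled against a fine
reference climatology — additive anomalies for temperature, multiplicative
ratios for precipitation (baseline floored, ratio clipped to [0.1, 10]) —
and climate layers are resampled to the modeling grid by a separable
natural cubic spline (bilinear for ordinary covariates); edge cells use
nearest-valid padding, a choice the source leaves open. Cells where any
covariate leaves its training range are flagged as extrapolation and
reported, but stay in the suitable set: projections there are uncertain,
not unsuitable.

Each decade's binary suitability uses the fitting-period threshold. The
occupancy update is:

* newly suitable `N = S \ O_prev`;
* reachable `R`: newly suitable cells within 3 km (center-to-center) of a
  previously occupiable cell, with movement prediction at or above the 1st
  percentile of movement values at the SDM localities, and impervious
  surface ≤ 20%;
* occupiable `O = (O_prev ∩ S) ∪ R`.

The initial mask is decade-0 suitability minus heavily impervious cells
(the source never defines the starting mask). Distance is measured to the
nearest prior *occupiable* cell center — prior suitable-but-unreachable
habitat cannot seed dispersal — configurable to prior suitable, and
differing from a polygonized edge by at most one cell diagonal. Masks are
applied per decade, not cumulatively. The summary ratio is final over
initial occupiable area; areas are cell counts × 6.25 ha.

## Gap analysis

Protection categories follow the protected-areas-database bookkeeping:
tribal and Department of Defense lands are removed; state/NGO-owned Fee
parcels merge into Proclamation; Designated areas nested in Proclamation
count as Proclamation; and each cell takes the highest-precedence category
covering it (Proclamation > Designated > Other > BLM — the treatment of
BLM cells inside Designated areas is not fully specified in the source;
Designated takes precedence here). Rasterization is by cell-center
containment, so boundary error is bounded by perimeter × cell size;
solar-development zones are tabulated as an overlay since they may overlap
BLM. Proportions are over habitat cells, with an uncategorized remainder
restoring exclusive categories to exactly one; an empty habitat mask is
flagged rather than divided by zero.

## The synthetic study system

`make_landscape()` builds Gaussian random fields (spectral smoothing of
white noise on the torus; correlation length configurable, default 8
cells) for the soil, texture and wash covariates, and a smooth synthetic
DEM from which slope, topographic position, ruggedness and a mountain-base
indicator are derived. Spring temperature follows a −6.5 °C/km lapse rate
with noise; winter precipitation increases with elevation but is only
moderately correlated with it, so both climate covariates survive
screening — on a landscape where the two climate axes are nearly collinear
the drying signal would be silently discarded. True suitability is a
logistic linear-quadratic form in standardized covariates, peaking on
moderately sloped, rugged, wash-bearing terrain at intermediate spring
temperature, so warming beyond the optimum degrades habitat. Detection
effort decays away from a road and a path, and occurrences are drawn with
probability ∝ suitability × effort, with duplicate cells retained to
exercise thinning.

Telemetry is a Metropolis-accepted Gaussian-step walk whose stationary
distribution follows the movement-preference surface (built with the
fitted model's sign structure: hump-shaped slope, ruggedness and shrub
responses, negative topographic position, positive suitability, negative
log-distances). Rejected steps leave zero-length fixes and 4% of fixes are
delayed by 48 h, so the telemetry filters all fire. The default
high-change climate scenario (+0.9 °C/decade, ×0.93 precipitation/decade)
pushes part of the landscape outside the training climate range by design,
exercising extrapolation flagging; the low-change scenario (+0.2,
×0.99) stays mostly inside.

What passing on this system does and does not show: the generator has
smooth stationary fields, noiseless covariates, a correctly specified
(logistic-quadratic) truth, and detection bias of known form — so recovery
here demonstrates the pipeline's internal correctness, not robustness to
misspecified responses, covariate error, non-stationarity, or the richer
spatial structure of real Mojave terrain.

## Problem sizes and numerics

The packaged study runs at 100 × 100 cells of 250 m with ~900 raw
occurrences (~500–600 after thinning), 20 cross-validation iterations, 4
telemetry animals × 800 fixes, 8 decades and 2 scenarios; these sizes give
stable metrics while keeping a full run in minutes. Numerical choices:
bridge densities are accumulated within ±5 sd windows; the variance search
is bounded on [1e-8, 100] m²/s; reachability uses an exact Euclidean disk
dilation (verified cell-exactly against an all-pairs oracle); the Boyce
index drops empty windows and returns NA for degenerate (constant) score
fields; percentile cutoffs use the linear-interpolation quantile
convention; and all stochastic stages take explicit seeds, making every
result reproducible from the configuration alone.

## Known limitations

The MaxEnt-family learner is an L1 logistic approximation, not the Java
implementation. Satterthwaite degrees of freedom for the mixed model are
deliberately out of scope (Wald statistics are reported). Rasters are
stored as plain-text ASCII grids with a CRS sidecar; no reprojection is
performed, and geographic inputs are rejected. The dispersal update is a
binary-mask model: it ignores demography, density, and behavior at
habitat edges, and treats the 3 km radius as a hard per-decade limit.
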