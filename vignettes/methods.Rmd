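---
title: "Models and methods behind campart"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind campart}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

campart implements the complete statistical workflow of a two-species
camera-trap niche-partitioning study: from raw photo records to spatial and
temporal overlap measures with uncertainty. This vignette explains the
models, the tunable parameters, the numerical choices, and what the
synthetic-data generator does and does not emulate.

## Study design and data model

The workflow targets a grid survey: one camera per cell of a roughly
1.7 km grid (83 sites by default), each deployed for about two weeks, with
three burst photos per trigger and a 1-min delay between triggers. Three
delimited tables describe a study: photo-level detections (site, species,
local timestamp), deployment intervals (site, start, end), and per-site
covariates extracted from 200 m buffers (mean slope; distances to the
nearest road, settlement, and water; land-cover areas of deciduous forest,
coniferous forest, grassland, and farmland).

Timestamps are local civil time taken at face value: no daylight-saving or
solar-time correction is applied, and sun-anchored transformations are a
deliberate non-goal. Trap-days are the exact deployment length in days
(fractional), not a rounded day count; where a study's reported effort
uses a different rounding rule, totals can differ by up to one day per
site. Each site has exactly one deployment interval; duplicated intervals
are rejected rather than summed, because a moved camera is a new site.

## Independent events and capture rates

Consecutive photos of the same species at the same camera belong to one
event while each gap to the *previous* photo is at most 30 min (gap-based
chaining); a gap strictly greater than the window opens a new event. The
boundary case — a gap of exactly 30:00 — continues the event, because
independence requires separation by *more than* the window. The event time
is the midpoint of the event's first and last photo, converted to radians
on the 24 h clock (`2*pi*seconds/86400`). The photographic capture rate is
independent events per camera-trap day, zero-filled over all deployed
sites; it serves three roles: the utilization measure for spatial overlap,
the count response of the occurrence model (as counts with a log-effort
offset), and — as the other species' rate — an occurrence covariate.

## Occurrence model

Counts of independent photographs $y_s$ at site $s$ follow a zero-inflated
Poisson: with probability $1-q$ the species is absent ($y_s = 0$); with
probability $q$ it is present and $y_s \sim \text{Poisson}(\lambda_s)$ with

$$\log \lambda_s = \beta_0 + \beta_1 z_1 + \dots + \beta_7 z_7 + \log T_s,$$

where $T_s$ is the trap-day offset and $z_1..z_7$ are the standardized
covariates (slope, road, settlement, water, deciduous, coniferous, and the
other species' capture rate). $q$ is intercept-only — a single presence
probability per fitted model, with no covariates on the zero part — and
one model is fitted per species.

Covariates are standardized to mean 0, SD 1 using the sample SD (n−1); the
means and SDs are stored for back-transformation. Before fitting,
covariates are screened for collinearity: the variance inflation factor
$\text{VIF}_j = 1/(1-R^2_j)$ is computed for every column, and the column
with the largest VIF is removed iteratively until all are below 5. Ties
break by column order. The screen is run per species model with that
model's own other-species rate included; on realistic landscapes it is the
grassland and farmland areas — near-complements of the forest areas within
a fixed buffer — that are removed.

"Non-informative priors" are made concrete as uniform(0,1) on $q$ and
normal(0, 10²) on each $\beta$; with standardized covariates an SD of 10
is effectively flat while keeping the posterior proper. The sampler is an
adaptive component-wise random-walk Metropolis on (logit $q$, $\beta$):
proposal scales adapt toward a 44% acceptance rate in 50-iteration batches
during warmup and are frozen afterwards, so retained draws target the
exact posterior. The protocol is 4 chains × 2000 iterations, the first
1000 discarded, unthinned. Convergence is declared when every parameter's
split-chain potential scale reduction (each chain halved, between/within
variance ratio) is below 1.1; identical constant chains define R-hat = 1
(the 0/0 case). A non-converged fit is returned flagged — rerunning with
more iterations is the caller's decision. Effect summaries report
posterior means with equal-tailed 80% and 95% credible intervals
(quantile, not HPD — reproducible without density estimation), flagging an
effect when the 95% interval excludes zero.

An independent maximum-likelihood oracle (`fit_zip_mle`, BFGS with seeded
multistart on the same likelihood) guards the sampler: on large simulated
data the posterior means must agree with the MLE within 2 posterior SDs,
and with $q$ fixed at 1 the MLE reproduces a plain Poisson GLM with offset
to 1e-6.

## Spatial overlap

Pianka's index normalizes each species' per-site rates to utilization
proportions $p$ and computes
$\alpha = \sum p_{A i} p_{B i} / \sqrt{\sum p_{A i}^2 \sum p_{B i}^2}$,
ranging 0 (disjoint site use) to 1 (identical use); it is symmetric and
invariant to rescaling either rate vector.

Overlap values are labelled low ($\le 0.50$), moderate ($\le 0.75$), or
high ($> 0.75$). The bounds are fixed thresholds on the index value — the
only reading under which a single value like $\alpha = 0.34$ can be
classified — and are configurable.

## Diel activity

Event times on the clock circle are smoothed with a von Mises kernel
density: $\hat f(\theta) = n^{-1} \sum_i \text{vM}(\theta; \theta_i,
\kappa)$, evaluated on a 512-point grid. The kernel concentration
$\kappa$ is selected by maximizing the leave-one-out cross-validated
log-likelihood over a 15-point logarithmic grid on $[1, 1000]$; a fixed
$\kappa$ override keeps results auditable. The CV kernel sums are computed
by FFT on a 2048-bin circle (~0.003 rad resolution, far finer than any
admissible kernel width); an exact $O(n^2)$ evaluation is retained as a
cross-check and selects identical concentrations in testing. Likelihood
cross-validation is noisy at moderate sample sizes: at n = 2000 from a
vM($\pi$, 2) the L1 error of the fitted density has mean ≈ 0.050 and
SD ≈ 0.012 across draws, which is close to the estimator family's
bias–variance floor at that n, so single-draw error bounds near 0.05
should be read as typical rather than guaranteed.

The activity level is $a = 1/(2\pi \max \hat f)$: the area under the
density (1) relative to the rectangle at peak height, i.e. the proportion
of the day active under the convention that animals are fully active at
the modal time. A flat density gives $a = 1$. Uncertainty comes from a
smoothed bootstrap: each replicate resamples n points from the fitted
density itself (a uniformly chosen data point plus von Mises kernel
noise — that is what "smoothed" means), refits with the same
$\kappa$-selection policy (re-selection by default; freezing $\kappa$ is a
switch), and recomputes $a$; the SD of replicates is the SE and the
percentile interval the 95% CI. The protocol uses 10,000 replicates.
Because densities live on a fixed grid, exact rotation equivariance holds
for shifts that are whole grid steps; arbitrary shifts agree to the grid's
quantization error (~1e-4 on the activity level).

Two species' activity levels are compared with a Wald statistic
$W = (a_1 - a_2)^2/(se_1^2 + se_2^2)$ against the chi-square(1) upper
tail, and their patterns with (i) Watson's two-sample U² (rank-based, with
midrank handling of cross-sample ties and the asymptotic series p-value,
intended for n ≥ 8 per sample) and (ii) a randomization test whose
statistic is the temporal overlap itself: pool the events, re-split into
the original sizes, refit, recompute, with
$p = (1 + \#\{\Delta_{null} \le \Delta_{obs}\})/(R+1)$. The randomization
statistic is a documented choice — the field's tooling does not name one —
and its null refits reuse the observed samples' kernel concentrations by
default (re-selection per permutation is a switch; it is quadratically
more expensive and moves p negligibly).

## Temporal overlap

The overlap coefficient estimates $\int \min(f_1, f_2)$ from density
ratios at the observed times:
$\hat\Delta_4 = \tfrac12[\,\overline{\min(f_2/f_1, 1)}_{t_1} +
\overline{\min(f_1/f_2, 1)}_{t_2}\,]$, with densities evaluated by linear
interpolation on their grids (exact kernel-sum evaluation is a switch;
the difference is below test tolerances). Evaluated densities are floored
at 1e-12 so ratios stay finite; the floor warns outside resampling loops.
Both the plug-in estimate and the smoothed-bootstrap mean are reported —
they differ, and published "mean" overlap values are bootstrap means — with
a percentile 95% CI (percentile rather than BCa or normal-theory; only a
"95% CI" is conventionally stated).

## The synthetic-data generator

Because the motivating field data are unpublished, the generator is a
first-class module that emulates the study conditions: 83 sites jittered
inside a 1.7 km grid, ~15 trap-days per site (uniform 13.5–16.5, staggered
in 20-camera batches), ZIP-distributed event counts driven by the
standardized environmental covariates through the log trap-day offset, and
diel times from von Mises mixtures — diurnal unimodal for the serow
(0.85 vM(noon, 2) + 0.15 uniform) and crepuscular bimodal for the deer
(0.45 vM(05:30, 4) + 0.45 vM(18:30, 4) + 0.10 uniform). The uniform
components keep both densities strictly positive, protecting the ratio
estimator. Default occurrence truth: serow q = 0.7, β₀ = −1, slope +0.5,
water −0.5; deer q = 0.55, β₀ = −1, settlement +0.5, water −0.5 (all other
slopes 0, on the standardized scale). The other-species coefficient is 0
in generation — a nonzero value would make the two species'
data-generating processes mutually circular — but is always estimated.

The landscape is planar and synthetic: a sinusoidal slope field sampled on
a 20 m point grid, random settlement points and road/water polylines, and
land cover classified from smooth fields. Buffer areas are exact fractions
of $\pi r^2$ (the grid count inside a 200 m circle varies with alignment,
so raw count × 400 m² could exceed the buffer). Grassland is a noisy fixed
share of the open land — whose complement is exactly the two forest
areas — and farmland tracks grassland almost exactly; this injects a
two-step collinearity calibrated so iterative VIF screening removes
exactly those two columns (the pair's mutual VIF is in the thousands, the
survivor's forest-linked VIF ~10, the forests' own VIFs < 5).

Two features guarantee testability at the cost of realism: events at a
site are re-spaced so consecutive bursts are separated by more than the
30-min window, making the independence filter exactly invertible (real
revisit clustering would merge events); and detection is perfect given
presence (no occupancy-style p < 1). Seasonal absence, animal movement,
and group-size structure are not emulated. Passing tests on synthetic data
therefore demonstrate the correctness of the estimators under the assumed
model, not robustness to the field phenomena the model ignores.

## Orchestration and reproducibility

`run_full_analysis` chains the stages (validate → filter → rates →
occurrence summary → Pianka → standardize + VIF screen → two ZIP models →
effect summaries → KDEs → activity levels + Wald → Δ₄ + bootstrap +
randomization + Watson → classification) and is fully deterministic given
inputs, configuration, and one master seed, from which per-stage seeds are
derived by fixed offsets. The two species' models and activity bootstraps
share one seed each, so swapping the species labels in the inputs mirrors
the per-species results exactly. All stage settings and seeds are echoed
in the result bundle; `write_report` serializes it (JSON at 6 significant
digits, CSV tables).

The fast configuration profile (2 chains × 500, 500 bootstrap replicates,
199 permutations) exists for exploration and continuous testing and is
labelled non-protocol. The package's own test suite runs the protocol-scale
checks at reduced problem sizes chosen for convergence of the quantity
under test: parameter recovery uses 20 studies of 83 sites with the fast
MCMC profile, test calibration uses 50 null runs with R = 199, and
bootstrap-consistency checks use B = 200–500; the acceptance script runs
the full protocol (4 × 2000 MCMC, B = 10,000, R = 999) on one 83-site
study.

## Known limitations

- Likelihood cross-validation can over-concentrate the kernel on a
  minority of samples (selection noise), inflating single-draw density
  error; medians over replicates are stable.
- The Watson p-value is the asymptotic series; no permutation fallback for
  tiny samples is provided (a warning fires below n = 8).
- The zero-inflation part is intercept-only by design; covariate-dependent
  presence requires a different model family.
- Local civil time conflates clock and solar cycles across a season-long
  survey; for mid-summer surveys at one site this shifts twilight by
  minutes, but analyses spanning equinoxes should anchor to sun times
  before using this package.
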