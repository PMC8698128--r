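# campart — spatial and temporal niche partitioning from camera traps

Camera-trap grids are the standard tool for asking how two ecologically
similar, potentially competing species manage to coexist: do they use
different places, different hours of the day, or both? `campart`
implements that analysis end-to-end for a two-species study (built around
the Japanese serow / sika deer system, where a historically allopatric
pair has recently become sympatric): photo records in, overlap measures
with uncertainty out. It is written for field ecologists and
biostatisticians who have three delimited tables — detections,
deployments, and site covariates — and want the complete workflow with a
single seed making every number reproducible.

## What it computes

- **Independent events** — same-species photos at one camera chain into
  one event while gaps are ≤ 30 min (strictly greater opens a new event);
  the event time is the midpoint of the first and last photo.
- **Capture rates** — events per camera-trap day per site and species,
  the common currency of the analysis.
- **Spatial overlap** — Pianka's index on utilization proportions *p*,
  α = Σ p_Ai p_Bi / √(Σ p_Ai² Σ p_Bi²) ∈ [0, 1], classified
  low (≤ 0.50) / moderate (≤ 0.75) / high (> 0.75).
- **Habitat selection** — a Bayesian zero-inflated Poisson model per
  species: with probability 1−q the site yields a structural zero; else
  y ~ Poisson(λ) with log λ = β₀ + β·z + log T (T = trap-days, z =
  standardized covariates, after iterative VIF > 5 screening). Fitted by
  adaptive Metropolis MCMC (4 × 2000, 1000 burn-in, split R-hat < 1.1),
  cross-checked against a maximum-likelihood oracle, summarized as 80/95%
  credible intervals.
- **Diel activity** — von Mises circular kernel densities with
  cross-validated bandwidth; activity level a = 1/(2π·max f̂) with
  10,000-rep smoothed-bootstrap SEs and CIs; Wald test on levels.
- **Temporal overlap** — the Δ₄ coefficient estimating ∫min(f₁, f₂), with
  smoothed-bootstrap mean and 95% CI, a randomization test on the overlap
  itself, and Watson's two-sample U².
- **Synthetic studies** — a generator with exposed ground truth (83 sites
  on a 1.7 km grid, ~15 trap-days, ZIP counts, diurnal vs crepuscular von
  Mises mixtures, 3-photo bursts) so the whole pipeline is testable
  without any field data.

## Worked example

```r
library(campart)

study <- simulate_study("default", seed = 42)   # or read your own tables
config <- analysis_config(seed = 42, fast = TRUE)  # fast profile for a demo
result <- run_full_analysis(study$detections, study$deployments,
                            study$covariates, config)
result
#> Two-species camera-trap partitioning analysis
#>   events: 389 serow, 270 deer at 83 sites
#>   sites: both 23 | serow only 28 | deer only 20 | neither 12
#>   spatial overlap: alpha = 0.425 (low)
#>   activity levels: serow 0.367, deer 0.474 (Wald W = 3.745, p = 0.053)
#>   temporal overlap: Delta4 = 0.442 (low), boot mean 0.483, 95% CI 0.426-0.541
#>   Watson U2 = 6.107 (p = 8.86e-53); randomization p = 0.005
```

The two species were generated with separated niches, and the pipeline
recovers that: spatial overlap is classified low; the diel densities
differ strongly (Watson and randomization tests), while the activity
*levels* — how much of the day each species is active, ignoring when — are
similar (Wald p = 0.053). The serow occurrence model recovers its
generating effects (slope +0.5, water −0.5, on the standardized scale):

```r
result$models$serow$effects
#>                     mean  lo95  hi95  significant
#> slope_mean_deg      0.52  0.42  0.62  TRUE
#> dist_water_km      -0.45 -0.59 -0.33  TRUE
#> rate_other_species -0.01 -0.12  0.07  FALSE
#> ...                                   (others not significant)
```

`write_report(result, "out/")` writes results.json plus events, rates,
effects, and activity tables. A thin command-line front end is installed
at `inst/cli/campart` (`campart simulate ...`, `campart run ...`).

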