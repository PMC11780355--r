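# whiskpop

Analysis of cerebellar population activity during voluntary whisking, and of
chemogenetic perturbations of glycinergic (GlyT2-positive) granule-layer
interneurons, in the style of a Neuropixels + high-speed videography
experiment in head-fixed mice.

The package is aimed at systems neuroscientists who have (a) tracked whisker
landmarks (DeepLabCut-style CSV at 299 frames/s) and (b) curated spike-sorting
output (Kilosort/Phy export layout), and who want to quantify how a local
pharmacological or chemogenetic manipulation changes population dynamics and
their coupling to behavior. Every stage also runs on a bundled synthetic-data
generator, so the full pipeline is testable without recordings.

## What it computes

* **Whisker kinematics** — azimuthal angle from tracked landmarks
  (protraction-positive), Hilbert decomposition of the angle into phase,
  amplitude and set point (zero-phase 4–25 Hz band-pass; 4 Hz set-point
  low-pass), and whisking-bout segmentation by a 10° amplitude threshold.
* **Single-unit tuning** — firing rate over 11 whisker-position bins (33 ms
  time bins), circular-shift shuffle controls, smoothing with seven cubic
  b-spline functions, k-means taxonomy (k = 8), Shannon entropy and KL
  divergence of tuning pmfs, population-average tuning.
* **Population dynamics** — bout-aligned PETHs (−2 to +3 s, 3.3 ms bins),
  PCA of the inter-unit correlation matrix, loading (excess-kurtosis)
  statistics, single-trial projections (Gaussian smoothing, SD = 20 bins),
  normalized cross-correlation between components and whisking with a
  lead-positive lag convention and one-sample t tests of peak lags, and
  linear set-point decoding from the first three components with a 94%
  highest-density band.
* **Chemogenetic effect on spike counts** — a hierarchical Bayesian model of
  normalized 5-min population spike counts

  ```
  s        ~ Inverse-Gamma(alpha, beta)
  alpha    = exp(th_a0 + th_ac[condition, period] + th_aa[animal] + th_at[bin])
  beta     = exp(th_b0 + th_bc[condition, period] + th_ba[animal] + th_bt[bin])
  th_*     ~ Normal(mu, sigma)            (mu_a = 1, mu_b = 1.2, sigma = 0.2)
  th_at,bt ~ MVNormal(mu, sigma^2 K),  K_ij = exp(-0.7 |t_i - t_j| / 5)
  ```

  fitted by an in-package Hamiltonian Monte Carlo sampler (JAGS available as
  an independent route), with post-minus-pre condition contrasts, derived
  inverse-Gamma mean/variance contrasts (`mu = beta/(alpha-1)`), 94% HDIs,
  cross-condition contrast differences and posterior predictive checks.
* **Movement-onset analyses** — per-unit PETH peak times in −0.7..1.3 s,
  their per-recording dispersion (SD) compared pre/post drug by a two-sided
  Wilcoxon signed-rank test, whisking protraction slope in −0.06..0.21 s,
  Levene's test on slope-contrast variances, and the neural–behavioral
  coupling r².

## Worked example

```r
library(whiskpop)
library(dplyr)

# a 4-minute synthetic session: bout-structured whisking plus a 20-unit
# population whose shared component leads the whisker by 40 ms
sim <- simulate_whisking(whisk_sim_params(duration = 240, seed = 1))
pop <- simulate_population(sim, pop_sim_params(
  n_units = 20, baseline_rate = 15, tuning_gain = 0.5,
  prop_ramp = 1, transient_gain = 0, neural_lead = 0.040, seed = 2))

kin   <- decompose_whisking(sim$trace)
bouts <- detect_whisking_bouts(kin)
peth  <- compute_peth(pop$spikes, bouts, t_range = c(0, 240),
                      smooth_sd_bins = 20)
pca   <- pca_population(peth)
avg   <- trial_average_whisking(sim$trace, bouts,
                                grid = sort(unique(peth$t)))
xc    <- crosscorr_pc_whisking(filter(pca$projections, pc <= 3),
                               avg[, c("t", "mean_angle")], max_lag = 0.5)
xc$peaks
#> # A tibble: 3 × 3
#>      pc peak_lag peak_value
#>   <int>    <dbl>      <dbl>
#> 1     1   0.0429     1
#> 2     2   0.492     -0.104
#> 3     3   0.413      0.0543
```

The first component's cross-correlation with the whisker peaks at +43 ms —
within one 3.3 ms grid bin of the planted 40 ms lead — meaning the dominant
population signal anticipates the whisker's position. `peak_value` is
normalized by the first component's absolute maximum, so component 1 peaks at
magnitude 1 by convention.

```r
pan <- simulate_count_panel(panel_sim_params(
  contrast_alpha = list("GlyT2-CNO" = 0.4),
  contrast_beta  = list("GlyT2-CNO" = 0.4), seed = 12))
fit <- fit_count_model(pan$panel, chains = 2, warmup = 600, iter = 1500, seed = 13)
tidy(condition_contrasts(fit)) |> filter(parameter == "alpha")
#> # A tibble: 3 × 6
#>   condition parameter contrast hdi_lower hdi_upper frac_defined
#>   <chr>     <chr>        <dbl>     <dbl>     <dbl>        <dbl>
#> 1 GlyT2-CNO alpha        0.452    0.151      0.737            1
#> 2 Veh       alpha       -0.106   -0.465      0.234            1
#> 3 WT-CNO    alpha        0.299   -0.0787     0.632            1
```

The planted GlyT2 post-drug shift of +0.4 on the shape predictor is recovered
(posterior mean 0.45, 94% HDI excluding 0) while the control conditions'
intervals straddle zero. Single panels are noisy — the test suite checks
recovery systematically over a 10-point planted-effect grid and 50
prior-draw replicates.

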