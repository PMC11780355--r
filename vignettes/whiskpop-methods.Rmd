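---
title: "Methods: cerebellar population dynamics during whisking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cerebellar population dynamics during whisking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

whiskpop analyzes simultaneous whisker tracking and Neuropixels population
recordings from the lateral cerebellar cortex (Crus 1) of head-fixed mice,
with and without chemogenetic downregulation of GlyT2-positive (Golgi and
Lugaro) interneurons via the inhibitory DREADD hM4Di and topically applied
CNO. This vignette explains the models and procedures, the parameters that
matter, the synthetic-data generator that the test suite runs on, and the
numerical and design choices that were genuinely open.

## Whisker kinematics

Tracked landmarks arrive as DeepLabCut-dialect CSV (three header rows, an
`x`/`y`/`likelihood` triplet per bodypart, 299 frames/s video). The whisker's
azimuthal angle is the arctangent of the first whisker segment (basal marker
to second marker) against the horizontal through the basal marker, in image
coordinates whose y axis points down; the sign is handled so that increasing
angle means protraction. Frames with tracking likelihood below 0.9 or
coincident markers are interpolated linearly for runs of at most 10 frames
(longer runs stay missing); these thresholds are exposed.

The angle trace is decomposed with the Hilbert analytic signal: the trace is
band-passed (zero-phase 4th-order Butterworth, 4–25 Hz) and the analytic
signal's argument and modulus give the whisking phase and the slowly varying
amplitude; the set point is the raw trace low-passed at 4 Hz. The band edges
and cutoffs are configurable — they bracket the rodent whisking band (~5–15
Hz, nominal 8 Hz here) rather than encode a biological claim. Two numerical
details matter: the trace is demeaned before band-passing because
`signal::filtfilt` starts from zero filter state, and the series is padded by
odd reflection before filtering because the FFT-based Hilbert kernel decays
only as 1/t and would smear boundary transients into the interior.

Whisking bouts are periods where the low-passed (6 Hz) amplitude exceeds a
10° threshold — a Heaviside discrimination of whisking from rest. Gaps
shorter than 0.25 s are merged and bouts shorter than 0.5 s dropped; both
limits are configurable and exist so that −2..+3 s onset-aligned windows are
well defined. An alternative set-point convention (midpoint of per-cycle
extrema) exists in the literature; the low-pass convention is implemented
because it is defined at every sample and commutes with the linear analyses
downstream, and the cutoff is exposed for users who prefer a stricter
separation.

## Single-unit tuning

Spike counts and mean whisker angle are computed in 33 ms bins; the angle
axis is split into 11 bins spanning the recording's range, and the firing
rate (with SE across contributing time bins) is averaged per angle bin.
Entropy and KL divergence are computed on the curve normalized to a
probability mass function over position bins; natural logarithms are used
(values in nats), unoccupied bins are excluded before normalization, and KL
zeros are regularized by an additive epsilon with renormalization. KL is
directed pre→post by default, with a symmetrized (Jeffreys) option, since
either direction is defensible.

The shuffle control shifts each unit's binned spike-count vector circularly
by a random offset of at least 1 s, which breaks the spike–angle pairing
while preserving the spike train's autocorrelation. Note one scope limit the
test suite respects: on a strictly periodic angle signal a circular shift is
a phase shift and does not flatten tuning; the generator's bout-structured,
drifting traces are aperiodic, as real behavior is.

Curve shapes are denoised by least squares onto seven cubic b-spline basis
functions over the bin index (ridge fallback, flagged, when fewer than 7
bins are occupied) and the coefficient vectors are clustered by Euclidean
k-means with k = 8, 10 restarts, and a fixed seed; duplicate-point
degeneracy reduces k with a message. Cluster means are reported as average
raw tuning curves. Units with fewer than one spike per minute of whisking
can be excluded as too sparse (configurable).

## Population dynamics

Per-unit PETHs are trial-averaged rates on a −2..+3 s grid around bout onset
with 3.3 ms bins, optionally Gaussian-smoothed. PCA is performed on the
inter-unit **correlation** matrix of these trial-averaged rates, so
eigenvalues sum to the number of units; eigenvector signs are fixed so the
largest-magnitude loading is positive (deterministic across platforms), and
projections are loading-weighted sums of the standardized rates. Single-trial
counts are smoothed with a Gaussian of SD 20 bins (≈66 ms; an SD of 5 gives
equivalent peak lags, which the tests check at 20 ms tolerance), centered by
their own within-window mean and scaled by the decomposition's per-unit SD.
Centering each trial by its own mean keeps projection exactly linear — the
mean of single-trial projections equals the projection of the trial
average — and makes a spikeless trial project to an identically zero
trajectory.

Cross-correlograms between the whisker angle and each of the first three
components are computed on the mean-subtracted trial-averaged window and all
are normalized by the absolute maximum of component 1's correlogram. The lag
convention is lead-positive: a peak at +40 ms means the neural signal's
features precede the whisker's by 40 ms. Peak lags across recordings are
compared to zero with a two-sided one-sample t test. Loading distributions
are summarized by Fisher excess kurtosis (type-1 estimator, normal = 0),
pooled across recordings by default with a per-recording option, since the
two estimator conventions give slightly different values.

The set point is decoded from components 1–3 by ordinary least squares fit
on a training subset of trials and evaluated on held-out trials; the
prediction band is a 94% highest-density interval from a residual bootstrap
of the training fit. OLS is used because the target is a linear readout
claim, not a best-possible decoder.

## The hierarchical inverse-Gamma count model

Population spike counts (summed over well-isolated units) are binned in
successive 5-min windows, the 0-min bin starting at drug application and
belonging to the post period, and every bin is scaled by the count in the
−5 min bin. The normalized counts `s` are modeled as

\[ s \sim \mathrm{InvGamma}(\alpha, \beta), \qquad
   \alpha = e^{\theta_\alpha + \theta_{\alpha c} + \theta_{\alpha a} + \theta_{\alpha t}}, \quad
   \beta  = e^{\theta_\beta + \theta_{\beta c} + \theta_{\beta a} + \theta_{\beta t}} \]

with a coefficient per condition-by-period cell (3 conditions × pre/post,
dim 6), per animal (dim 17 at the study design), and per post-baseline time
bin (dim 9; pre bins carry no time effect). All coefficients have Normal
priors (means 1 and 1.2, SDs 0.2 for the shape and scale sides — chosen so
prior-predictive counts span the observed scale of normalized counts,
including extremes); the time coefficients instead share a multivariate
normal prior whose covariance decays with time distance,
\(K_{ij} = \exp(-0.7\,|t_i - t_j|/5)\) with unit diagonal and 1e-6 jitter,
scaled by the prior variance so its marginals match the scalar priors. A
"literal" kernel that composes two exponentials is exposed behind a flag for
inspection; it increases with distance, contradicting the decaying-covariance
contract, and is generally not positive definite, so the decaying form is the
default. The inverse-Gamma mean and variance used for derived contrasts are
the standard \(\mu = \beta/(\alpha-1)\) (\(\alpha>1\)) and
\(\sigma^2 = \beta^2/((\alpha-1)^2(\alpha-2))\) (\(\alpha>2\)); draws where a
moment does not exist are dropped from that moment's summary and the defined
fraction is reported. Condition coefficients are used exactly as declared —
independent Normals with no sum-to-zero constraint — so the intercept,
condition, animal and time coefficients are separately identified only
through their priors, which is intentional: contrasts (post minus pre within
a condition) and contrast differences (between conditions) are the estimands,
and those are data-identified.

**Sampling.** The redundancy just described creates a prior-limited ridge in
the posterior on which single-site samplers mix pathologically (slice
sampling needed thousands of iterations per effective draw of a contrast).
The default sampler is therefore an in-package Hamiltonian Monte Carlo:
analytic gradients of the log posterior (compiled code), leapfrog
integration with a path length jittered ±20% around 24 steps, step size
tuned by dual averaging to a 0.8 acceptance rate, and a diagonal mass matrix
re-estimated mid-warmup. Defaults are 4 chains with 1000 warmup and 1000
retained draws; convergence is summarized by the potential scale reduction
factor and flagged above 1.1. The same model runs in JAGS
(`method = "jags"`, with the inverse-Gamma likelihood written through its
Gamma reciprocal; the Jacobian does not involve the coefficients, so the
posterior is identical) and the test suite checks that the two routes agree
— a deliberate dual-route validation of the sampler.

**Calibration.** The suite verifies, at the study design (19/5/9 recordings,
17 animals, 4 pre + 9 post bins), that posterior-mean contrasts track a
planted grid of GlyT2 effects with correlation above 0.9, and that when the
truth is drawn from the model's own priors the 94% HDI of the contrast
covers the truth at its nominal rate (50 replicates with shortened chains —
the HDI estimated from a finite, autocorrelated sample runs a few percent
narrow, which the binomial tolerance band absorbs). For zero-effect panels
(post coefficients set equal to pre), the rate at which cross-condition
contrast-difference HDIs exclude zero is *bounded above* by the nominal 6%
rather than equal to it: with a point null and a contrast prior centered at
zero, shrinkage makes exclusion strictly rarer than the prior-draw
(simulation-based-calibration) case, so the test uses a one-sided binomial
band around 6%.

## Movement-onset analyses

For each recording and period, unit peak times are the maxima of the
magnitude of smoothed, baseline-subtracted PETHs within −0.7..1.3 s
(baseline: mean over −2..−1 s, a choice the data do not dictate; smoothing
SD exposed; earliest time on exact ties; flat units excluded). The
per-recording SD of peak times is the neural dispersion measure; pre/post
SDs are compared per condition with a two-sided Wilcoxon signed-rank test
whose reported `T` is the smaller signed-rank sum. Whisking onset velocity
is the least-squares slope of the bout-averaged whisker position in
−0.06..0.21 s; its post-minus-pre contrast is compared between conditions by
Levene's test (median-centered by default). Coupling is the squared Pearson
correlation between per-recording neural dispersion changes and slope
contrasts. Recordings whose trial-averaged position is flat in the onset
window (range below 2°) are flagged poor-whisking and excluded from the
slope analysis, mirroring the exclusion of recordings without usable
behavior. Analysis periods are matched in duration with the post period
starting 5 min after drug application.

## The synthetic-data generator

The generator defines the conditions every test runs under; its defaults are
fixed once and are not tuned per test.

*Whisking* is an amplitude-modulated sinusoid on a slowly drifting set
point. Bouts arrive as a Poisson process (default 6/min, gamma-distributed
durations with mean 2 s, non-overlapping with ≥1 s gaps), the envelope rises
from 1° to 18° over a 0.15 s raised-cosine ramp that starts *at* onset, the
set point protracts by 6° during bouts over an Ornstein–Uhlenbeck drift
(SD 2°, τ = 5 s), and the oscillation (default 8 Hz, configurable — the
species-typical band, not an asserted value) phase-locks to bout onset so
that every bout begins protracting from rest, as real bouts do. Starting the
ramp at onset keeps the pre-onset window free of incoherent oscillation at
the previous bout's phase; without this, onset-aligned slopes acquire large
per-bout variance that real phase-locked protractions do not have. Frame
noise is 0.5°.

*Populations* are inhomogeneous-Poisson units whose rate is a gamma-
heterogeneous baseline plus a tuning function — monotonic ramps of either
sign or Gaussian bumps at preferred angles — evaluated on the angle a
configurable lead into the future (default 40 ms, per-unit jitter optional),
plus an optional Gaussian transient at bout onset, advanced by the same
lead. The lead is implemented by continuous interpolation at
`t + lead + dt/2`, so that spikes emitted uniformly within a frame lead the
angle by exactly the nominal value. Negative rates are clipped at zero with
a warning. Two deliberately different populations are used in testing: a
pure-ramp, transient-free population for lead/lag recovery (its first
component is then an angle copy and the cross-correlation peak is sharp) and
a transient-dominated population for peak-time analyses (real PETHs peak at
onset; the transient's per-unit jitter is the planted dispersion).

*Count panels* are drawn from the inverse-Gamma generative model itself at
the study design, with coefficients drawn from the model priors unless
supplied and planted condition contrasts injected as post = pre + Δ. The
simulated panels are model draws, so the −5 min bin is not identically 1 as
it is for panels built from spikes by `bin_and_normalize()`; recovery tests
are about the coefficients, not that bookkeeping identity.

*Onset cohorts* pair a pre and a post session per recording. The perturbed
("GlyT2-like") cohort halves the per-unit peak jitter post-drop (50 → 25 ms)
in every recording and draws the onset-velocity multiplier with inflated
variance and mixed sign (SD 0.5), independent of the neural change; the
control cohort drives both a mild jitter change (±30% of baseline) and a
proportional velocity change (±6%) from a single per-recording latent, so
neural and behavioral changes stay correlated. These effect sizes were
chosen once so that the planted control variability sits clearly above the
pipeline's measurement noise (~1 deg/s for slope contrasts, ~7 ms for
dispersion) and clearly below the perturbed cohort's inflation.

What the generator does *not* emulate: sorting contamination and unit drift,
whisker curvature and contact, multi-whisker interactions, non-Poisson
spiking (bursting, refractoriness), and state changes unrelated to whisking.
Passing tests therefore demonstrate that the analyses recover what they
claim from data with the assumed structure, not that real recordings satisfy
those assumptions.

## Problem sizes used by the test suite

Tests run on deliberately modest sizes chosen once: 60–240 s sessions,
8–40 units, 20 seeds for lead/lag recovery, a 10-point effect grid and 50
prior-draw replicates (shortened single chains) for model recovery and
coverage, 40 zero-effect panels for null calibration, and 12/13-recording
onset cohorts at 240 s per session — the study-scale design wherever the
quantity depends on it (recordings per condition, animals, bins, cohort
sizes), reduced only in per-session duration and chain length.

## Known limitations

* The HMC sampler uses a static jittered path length, not dynamic
  trajectory termination; for this posterior (near-Gaussian, ~70
  dimensions) that is sufficient, but the acceptance-rate and R-hat
  diagnostics should be consulted on new designs.
* The 94% HDI from finite MCMC output is biased slightly narrow; for
  reporting at publication precision, lengthen the chains.
* Cross-correlation peak lags are quantized to the 3.3 ms PETH grid.
* The entropy/KL statistics compare curves binned on each recording's own
  angle range; comparing across recordings with very different ranges
  compares different physical supports.
* The shuffle null assumes an aperiodic angle trajectory (see above).
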