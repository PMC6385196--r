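---
title: "Predicting intradialytic hypotension from heart rate variability: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting intradialytic hypotension from heart rate variability: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrvidh)
```

## The scientific question and the model

Intradialytic hypotension (IDH) is believed to arise in part from a failure
of autonomic compensation: when ultrafiltration contracts the intravascular
volume, a healthy autonomic system raises heart rate and peripheral
resistance, and that response leaves a spectral signature in beat-to-beat
heart-period variability. `hrvidh` operationalizes the hypothesis that the
*change* of HRV parameters within a dialysis session — specifically between
an early phase (first 10 minutes) and a middle phase (minutes 115–125) —
predicts how often a patient will experience IDH over the following month.

The outcome is a monthly event count over a fixed exposure of 12 dialysis
sessions, modelled as NB2 negative-binomial regression with log link:

$$y_i \sim \mathrm{NegBin}(\mu_i, \alpha), \qquad
  \log \mu_i = x_i^\top \beta, \qquad
  \mathrm{Var}(y_i) = \mu_i + \alpha \mu_i^2 .$$

The negative binomial is preferred over Poisson because small hemodialysis
cohorts show clear over-dispersion (many zero-event patients alongside
patients with several events per month). Because every patient contributes
the same 12 sessions, a log-exposure offset would be constant and is
absorbed by the intercept; none is used.

Discrimination is assessed on the *binary* outcome "at least one IDH event",
using the fitted linear predictor $\eta_i = x_i^\top\hat\beta$ as a
continuous risk score: ROC curves, Mann–Whitney AUCs, and DeLong's paired
test for the correlated AUC difference between a clinical basic model and
an HRV-augmented model.

## Preprocessing choices

**Ectopic rule.** A beat is removed when its RR interval differs by more
than 20% from the reference RR. We take the reference to be the most recent
*retained* beat, not the raw predecessor. The raw-predecessor reading lets a
single ectopic beat cascade: the short ectopic RR makes the following normal
RR look deviant, and so on. Under the retained-predecessor reading the
filter is idempotent — filtering a filtered series removes nothing — which
is the property the test suite enforces. Removed beats are simply excluded
from both the time-domain statistics and the resampling input; no
interpolated replacement is inserted.

**Segmentation.** Segments are defined on wall-clock beat time, 1-based and
half-open: segment $k$ covers $[(k-1)\cdot300, k\cdot300)$ s, so a beat at
exactly 300.0 s belongs to segment 2 and the 48 segments partition a
240-minute recording. Phases use fixed segment pairs — early (1, 2), middle
(24, 25), late (47, 48) — and each of the nine parameters is the arithmetic
mean of its two per-segment values. The LF/HF ratio is averaged as a ratio,
not recomputed from averaged LF and HF; with only two segments the
difference is small, but the choice must be fixed and this one keeps the
phase value interpretable as "mean of the per-segment ratios". Recordings
shorter than the full grid raise an error by default; `partial = TRUE`
returns the covered segments with a message, but the standard phases then
require the corresponding segments to exist.

## Spectral estimation

The tachogram (RR in ms as a step-like function of beat time) is linearly
interpolated onto a 4 Hz grid per 300-s segment (1200 samples), and the PSD
is estimated by Welch's method: 256-sample (64 s) windows, 75% overlap (15
windows per segment), per-window mean removal, and a periodic Hann taper
with power-correction $U = \overline{w^2}$ so that the one-sided PSD
integrates to the mean-removed signal variance (verified by a Parseval test
against broadband noise at 10% tolerance).

Band powers integrate PSD bins whose *center* frequency falls in the
half-open interval $[f_\mathrm{low}, f_\mathrm{high})$: VLF
$[0.003, 0.04)$, LF $[0.04, 0.15)$, HF $[0.15, 0.40)$ Hz. Half-open edges
assigned by bin center mean no bin is double-counted at the shared edges
0.04 and 0.15 Hz. Total power is defined as the integral over the *union*
of the three bands, which makes $\mathrm{VLF} + \mathrm{LF} + \mathrm{HF}
= \mathrm{TP}$ an exact identity on the bin grid (the alternative — all
power up to 0.4 Hz including below 0.003 Hz — differs negligibly at these
record lengths, because with 64-s windows no bin below 1/64 Hz ≈ 0.0156 Hz
exists anyway). That resolution limit also means the 0.003–0.0156 Hz part
of the VLF band is unobservable; `band_powers()` integrates what the grid
provides and flags this in an attribute.

Two quantitative caveats the tests encode explicitly:

* A pure sinusoidal modulation sampled *directly* at 4 Hz carries band
  power $a^2/2$ (1250 ms² for a 50 ms tone), reproduced within 15%
  (Hann leakage stays inside the band).
* The same tone generated through the *beat-sampled* path is attenuated,
  because RR is only observed once per beat (~1 Hz) and linear
  interpolation of ~1 Hz samples acts as a low-pass filter
  ($\mathrm{sinc}^2$-like, ≈0.8 power transfer at 0.25 Hz). Band
  *fractions* are unaffected — a 0.10 Hz tone keeps ≥90% of power in LF, a
  0.25 Hz tone ≥90% in HF — so tachogram-level checks are fraction-based
  while absolute-power checks use the directly sampled signal.

**Δ features.** For each parameter, Δ = middle − early, so positive values
mean the parameter rose as dialysis progressed. With this sign convention a
*protective* rate ratio (< 1) for ΔTP/ΔLF/ΔHF says: patients whose
variability rises more mid-dialysis have fewer IDH events — the expected
physiology. Reporting scales for modelling divide the band-power deltas by
100 (per 100 ms²) and ΔRRI by 100 ms. The 0.1 *ms* unit sometimes printed
for ΔRRI is physiologically implausible (a rate ratio of 0.44 per tenth of
a millisecond); we read it as 0.1 s and expose the divisor in
`scale_delta_features()` so either reading can be configured.

## Estimation and inference

`idh_nb()` maximizes the NB2 likelihood jointly over $(\beta, \log\alpha)$
by alternating Fisher-scoring IRLS steps for $\beta$ (with step-halving, so
the likelihood never decreases) and 1-D profile maximization for
$\log\alpha$ on $[-25, 10]$. The alternation is stable at the Poisson
boundary $\alpha \to 0$, where the tests require agreement with a Poisson
GLM to $10^{-3}$ at $n = 2000$. $\alpha$ is estimated by full ML (not
moments) — the conventional reading of "negative binomial model" — and the
Wald covariance comes from the observed information at the optimum. When
quasi-separation drives an indicator's coefficient toward the boundary the
information matrix flattens; a minimal ridge ($10^{-10}$ relative) keeps
the scoring step and covariance defined, yielding very large finite
variances in the flat directions rather than an aborted fit. Inference is
Wald throughout — $\exp(\hat\beta)$ rate ratios with
$\exp(\hat\beta \pm 1.96\,\mathrm{SE})$ intervals — matching the
rate-ratio-with-CI reporting style standard in this literature; AIC and BIC
count the dispersion as a parameter ($k = p + 1$).

**Screening and search.** Univariate screening keeps candidates with Wald
p < 0.10 plus a caller-supplied force-include list (coronary artery disease
and congestive heart failure are clinically mandated regardless of p, and
are the defaults in the pipeline configuration); failed univariate fits are
flagged unscreenable, never silently dropped. The model search fits the
basic model plus every subset of up to 4 Δ terms (the largest published
augmented models carry ≤ 4), excludes candidates with any VIF > 10 — VIF is
computed as $1/(1-R^2_j)$ from least-squares regressions with intercept —
or any pairwise $|r| > 0.8$ involving an added column (the mutual-strong-
correlation rule has no published numeric bound; 0.8 is the configurable
default), and ranks survivors by linear-predictor AUC.

**AUC and DeLong.** AUC uses midranks, so exact ties — which arise
naturally when binary covariates dominate a linear predictor — receive
half-credit, and the ROC curve's trapezoidal area equals the Mann–Whitney
estimate identically. DeLong's test computes per-subject placement values
(also midrank-based), forms the variance of the AUC difference from their
empirical covariances, and refers $z$ to a two-sided standard normal. A
zero variance with equal AUCs yields p = 1; a zero variance with unequal
AUCs is a degenerate pairing and an error.

## What the synthetic data emulate — and what they do not

**Tachograms** are generated in the time domain by integral pulse frequency
modulation: beat $k{+}1$ occurs $RR(t_k)/1000$ seconds after beat $k$,
where $RR(t)$ is a baseline plus one sinusoid per band plus white Gaussian
noise. Per-band amplitudes follow piecewise-linear trajectories between
anchors at the early/middle/late phase midpoints, which is enough to mimic
the published rise-then-fall phase patterns without a physiologic model.
Defaults (900 ms baseline; 20/30/25 ms VLF/LF/HF amplitudes at
0.03/0.10/0.25 Hz; 4 ms noise) give band powers of a few hundred ms² —
typical for resting adults — and the generator rejects any configuration
whose instantaneous RR falls below 1 ms (near a zero crossing the beat
step shrinks geometrically, so the floor at 1 ms rather than 0 is what
terminates the iteration). Ectopic injection shifts randomly flagged beats
by a fractional magnitude that must exceed 0.2, precisely so that the 20%
preprocessing rule *can* remove them; ground-truth indices ride along for
subset tests. Not emulated: raw ECG waveforms and R-peak detection error,
respiration-coupled nonstationarity, baroreflex feedback between blood
pressure and heart rate, and arrhythmias beyond isolated ectopy. Passing
tests therefore validate the measurement pipeline's arithmetic, not its
robustness to real recording artifacts.

**Cohorts** draw covariates directly on the count model's reporting scales
(age/10 y, UFR in kg, iPTH/100 pg/mL, binary indicators with the pooled
prevalences of the study population) so true and fitted coefficients are
directly comparable. Default effect sizes are the published multivariate
basic-model rate ratios, with the intercept solved numerically (once, by
Monte Carlo integration over the default covariate mix) so the population
mean count is ~1.20 events per patient-month — 85 events over 71
patient-months. Counts are drawn unbounded from the NB (matching the NB
likelihood the fitter assumes); a draw exceeding the 12 monthly sessions
triggers a warning rather than truncation, since truncating would bias the
dispersion the tests are trying to recover. The default dispersion
$\alpha = 1$ reproduces the zero-heavy, long-tailed count distribution of
such cohorts. Covariate distributions beyond the published summary
statistics are our parameterized defaults, not assertions about the study's
sample.

**The full simulated study** ties the two together: each patient's
tachogram gets per-patient lognormal middle/late amplitude multipliers, the
feature pipeline *measures* the resulting ΔHF, and the IDH rate depends on
that measured value (default rate ratio 0.60 per 100 ms², centered at the
cohort mean). The intercept is then re-anchored so the realized cohort mean
count equals a configured `target_mean_count` (default 85/71): without this
anchoring, the heavy-tailed HRV term would shift the marginal event burden
whenever tachogram settings change. Because the link runs through the
measured feature rather than a latent one, end-to-end discrimination tests
exercise the whole chain — generation, cleaning, spectral estimation,
modelling, ROC.

## Group-comparison layer

"As appropriate" test choices are pure functions of the data, so the same
input always yields the same test: Pearson chi-square *without* continuity
correction when all expected cell counts are ≥ 5, Fisher's exact otherwise
(the uncorrected chi-square is what reproduces the published drug-use
contrasts 0.023 and 0.040 from their printed 2×2 counts — the corrected
version does not); Student's t vs Mann–Whitney, and paired t vs Wilcoxon
signed-rank, by Shapiro–Wilk at α = 0.05 per group (overridable); Friedman
by default for phase trends, with repeated-measures ANOVA behind a flag,
because the spectral powers are strongly right-skewed. Display follows the
branch: mean ± SD for the parametric branch, median (IQR) otherwise. No
multiplicity adjustment is applied across table rows, matching the
descriptive intent of such tables.

## Validation scale

The shipped test-suite and acceptance-script problem sizes are the
package's chosen validation scale: coefficient recovery and CI coverage
over 200 cohorts of n = 500; Poisson-limit agreement at n = 2000; DeLong
type-I error over 2000 null replicates at n = 200; the basic-vs-augmented
discrimination comparison over 100 (tests) / 50 (acceptance script)
simulated cohorts of n = 71; full 240-minute tachograms wherever phase
structure matters. These sizes put Monte-Carlo error comfortably inside the
asserted tolerances while keeping a complete run in the low minutes.

## Known limitations

* The Welch/interpolation pathway attenuates high-frequency power at low
  heart rates (see above); absolute HF values are therefore comparable
  within a pipeline but not across resampling schemes.
* VLF at 64-s windows is resolution-limited; reported VLF covers
  0.0156–0.04 Hz in effect.
* The NB2 Wald intervals are asymptotic; at n ≈ 71 with ~10 parameters
  they are honest but not exact, and quasi-separated indicators receive
  essentially unbounded intervals rather than profile-likelihood ones.
* The model search is exhaustive only within its cap and uses AUC as the
  ranking criterion; it is a superset-style search, not a claim about any
  particular published enumeration.
* No zero-inflated or hurdle variants, no random effects, no nonlinear HRV
  indices (entropy, detrended fluctuation), no Lomb–Scargle alternative to
  resampling.
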