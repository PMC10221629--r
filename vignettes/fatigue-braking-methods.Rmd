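---
title: "Methods: EEG spectral fatigue scoring and ship braking distances"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EEG spectral fatigue scoring and ship braking distances}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fatiguebrake)
```

## The problem

Operator fatigue lengthens reaction times, and on a ship the reaction time
enters directly into the emergency stopping distance. This package
implements an analysis chain that (i) quantifies fatigue from
electroencephalography (EEG) via two spectral features, (ii) links those
features to subjective fatigue ratings with a small ridge-regression model,
and (iii) propagates the predicted fatigue score into a three-stroke
stopping-distance model. The packaged data are the published summary tables
of a 12-participant Stroop-task fatigue-induction study (14-channel EEG at
128 Hz; mean reaction times, Stroop effects, and 0-4 Fatigue Severity
Scale ratings for the first and fifth task sets, with channel-7 and
channel-10 spectral features). Raw recordings from that study are not
public, so a calibrated synthetic cohort generator stands in wherever
signal-level input is needed.

## Spectral features

For a one-sided power spectral density $P(f_i)$ on the retained band
(1-30 Hz by default), the two features are the centroid frequency

$$CF = \frac{\sum_i f_i\, P(f_i)}{\sum_i P(f_i)},$$

the power-weighted mean frequency, and the power spectral entropy

$$PSE = -\sum_i p_i \log_2 p_i, \qquad p_i = \frac{P(f_i)}{\sum_j P(f_j)},$$

the Shannon entropy of the normalized spectrum. Entropy of the *raw* PSD
is scale- and unit-dependent (it can be negative or unbounded), so the
implementation always normalizes first; this is the standard definition,
it makes $0 \le PSE \le \log_2 n$ hold, and it is consistent with the
packaged study feature values all lying in $(0,1)$ up to an unknown
rescaling. A `normalized` switch additionally divides by $\log_2 n$; the
default reports bits. The packaged per-session feature values are treated
as given features — they are not re-derived from raw EEG, which is
unavailable.

PSDs are estimated by Welch averaging: 2 s Hamming windows, 50 % overlap,
one-sided power-per-Hz scaling (so the band-integrated PSD matches the
signal variance; the test suite checks this against a direct variance
computation). No installed estimator provides segment-averaged
periodograms, so the ~30-line Welch loop is implemented here and tested
against that oracle.

Representative channels are selected by principal component analysis of
the column-standardized sessions-by-channels feature matrix: each of the
first $k$ components nominates the not-yet-selected channel with the
largest absolute loading (ties to the lower index; loading signs fixed by
making each component's largest-magnitude element positive). Because the
correlation-matrix eigenvectors compress within-group loading contrasts,
this selection is only reliable when the latent sources are well
separated; the tests use planted two-factor designs in that regime.

## Preprocessing

The published pipeline used ICA denoising, 1-30 Hz bandpass filtering
with a 12 dB/octave slope, normalization, and removal of motion artifacts
and faulty channels. Here the bandpass is a 2nd-order Butterworth
(12 dB/octave per edge) applied forward-backward, giving zero phase;
channels are reflect-padded (at least one second) so the filter settles
before the data start. Normalization is a per-channel z-score; constant
channels become zeros with a warning. ICA is not reproducible from the
published description and is out of scope; in its place two documented,
testable rules run after filtering and normalization: samples with
$|z| > 5$ on a channel are replaced by linear interpolation, and channels
whose variance deviates from the median channel by more than a factor of
10 are dropped. The reference montage of the original recordings is not
stated; per-channel z-scoring is used and the question left open. File
interchange is CSV (time column plus one column per channel); no EDF
reader is available in this build, so EDF input is not offered.

## The synthetic cohort generator

The generator defines the study conditions under which the pipeline is
exercised: 12 subjects, 5 sessions, 14 channels at 128 Hz, 60 s per
recording, 40 Stroop trials per session drawn from the 16 word-by-colour
combinations (4 congruent). Each channel is coloured noise shaped in the
frequency domain: a $1/f$ background plus Gaussian-envelope theta, alpha
and beta components. Rising latent fatigue (a 0-4 level) moves power into
the beta band — the beta gain is solved numerically so the *envelope*
centroid rises by `cf_gain` Hz per fatigue unit — and flattens the
background exponent, which raises spectral entropy. This is a statistical
emulation chosen to reproduce the sign and rough size of the observed
feature-fatigue correlations, not a claim about physiology: there is no
volume conduction, no dipole geometry, and no ocular/muscle artifact
model beyond planted test transients. Passing tests on synthetic cohorts
therefore demonstrate that the *pipeline arithmetic* recovers planted
structure, not that the features are physiologically valid.

Default effect sizes are calibrated from the packaged tables (first vs
fifth set means): `cf_gain = 0.7` Hz and `pse_gain = 0.06` bits per
fatigue unit, congruent reaction-time base 886 ms rising 60 ms per unit,
and a 230 ms Stroop cost. Reaction times are shifted lognormal (300 ms
shift, $\sigma_{\log} = 0.35$), positive and right-skewed, with the 2 s
response window marking non-responses; the published data report only
session means, so the trial-level distribution is unconstrained — the
lognormal is a conventional choice. The latent level rises linearly from
0.5 to 2.0 across sessions (the packaged tables show fifth-set ratings
above first-set ratings for all but one participant), subjects get a
Gaussian offset (sd 0.3), and FSS labels are the latent level plus
observer noise (sd 0.5) snapped to the half-point grid in $[0,4]$, the
grid the study's ratings use.

## Exclusion variants and what reproduces

One participant produced negative Stroop effects (faster incongruent than
congruent responses); the study's tables flag the fifth set and state it
was discarded from model construction. Three filters are implemented:
`none` (24 rows), `session` (drop the flagged row, 23), and `subject`
(drop both of that participant's rows, 22).

Recomputation fixes the conventions the original description leaves open:

- The published feature-FSS correlations are matched almost exactly by
  the **unfiltered** 24-row table (e.g. channel-7 CF: $r = 0.842$,
  $p = 2.5\times10^{-7}$), so `correlation_mode = "none"` is the default
  for the correlation reproduction. One published value — $r = 0.37$ for
  channel-10 CF — is not recoverable from the printed columns under any
  filter (all variants give $r \approx 0.51$); it is reported as a known
  discrepancy and the corresponding check is expected to fail.
- For the model, the stated rule (drop the single flagged set) is
  `session` mode, the default for fits and cross-validation; the
  `subject` variant is computed alongside.

## The ridge fatigue model

With features $x_j$ (channel-7 CF and PSE, channel-10 PSE) and response
$y$ (FSS), ridge regression minimizes
$\sum_i (y_i - \beta_0 - \sum_j \beta_j x_{ij})^2 + \alpha \sum_j \beta_j^2$.
Because $n$ is small the solve is analytic:
$(X^\top X + \alpha I)\,\beta = X^\top y$ on centered data, with the
intercept recovered from the training means and never penalized (the loss
above excludes $\beta_0$ from the penalty; penalizing a raw-data
intercept would make the fit depend on the response origin). By default
both features and response are z-scored — the published coefficient
magnitudes (0.86 on a centroid frequency of 6-9 Hz predicting ratings in
$[0,3]$, intercept $-0.04$) are only dimensionally coherent on a
standardized scale — and a raw-scale fit is available by flag.
Predictions are always mapped back to FSS units.

At $\alpha = 0.1$ (the published choice; `select_alpha()` re-derives a
grid minimizer by CV MSE) the standardized coefficient on channel-7 CF is
0.745 under `subject` filtering and 0.660 under `session`. The published
0.86 is unreachable from the printed tables under this convention for
*any* $\alpha \ge 0$: the coefficient path is monotone decreasing from
its least-squares value 0.754. The likely explanation is that the
published model used all five sets per participant (60 sessions), which
were never printed. The reproduction therefore reports its recomputed
vector side by side with the published one rather than matching it.

Cross-validation shuffles rows with an explicit seed into $k = 5$
near-equal folds; scaling parameters are recomputed on each training
split. The published "average validation error 0.36" does not name its
metric, but mean squared error is the only metric the original
description mentions (for $\alpha$ selection), and the recomputed
100-seed-averaged five-fold MSE is 0.357 (session mode); MAE (0.47) and
RMSE (0.57) are computed and reported alongside. Whether the published
predicted-vs-actual correlation of 0.83 is in-sample or cross-validated
is likewise unstated; the in-sample value is 0.851 (session mode) and the
cross-validated variant is reported next to it.

## The braking model

The emergency stop decomposes into reaction, reversing and braking
strokes, $S = S_1 + S_2 + S_3$, with $S_1 = u t_1$, $S_2 = u (t_2 - t_1)$
(the ship is taken to hold its initial speed $u$ until the engine has
fully reversed — the deliberately conservative simplification of the
trajectory), and

$$S_3 = \int_0^u \frac{m V^2}{R V + P}\, dV,$$

where $m$ is full-load displacement (kg), $P$ the maximum reverse
propeller power (W), and $R$ a resistance coefficient. The source model
never states $R$'s functional form; here $R V$ is read as a power term
(watts), i.e. resistive force $\propto V$, which makes the integrand
dimensionally consistent — an interpretation, recorded rather than
asserted. $R$ stays a user input; standards-based resistance computation
is out of scope, as is any hydrodynamic simulation.

Numerically, the textbook antiderivative
$m[u^2/2R - Pu/R^2 + (P^2/R^3)\ln(1+Ru/P)]$ cancels catastrophically when
$x = Ru/P \ll 1$. The implementation instead evaluates
$S_3 = (m u^3/P)\, g(x)$ with $g(x) = (x^2/2 - x + \ln(1+x))/x^3$
computed by its alternating series $\sum_{j\ge0} (-x)^j/(j+3)$ for
$x < 0.5$ (31 terms, truncation error $< 10^{-10}$ relative) and the log
form otherwise. This is continuous through $R = 0$ (where
$g(0) = 1/3$ gives $S_3 = m u^3 / 3P$) and agrees with adaptive
quadrature to better than $10^{-8}$ relative error across a 500-point
log-uniform sweep of $(u, m, R, P)$ in the test suite. No worked numeric
braking example exists to reproduce, so the braking checks are
property-based: monotonicity in each parameter, exact stroke additivity,
and the $R \to 0$, $P \to \infty$ limits.

The coupling from predicted fatigue to reaction time,
$t_1 = \min(t_\text{base} + s \cdot \text{FSS},\ t_\text{max})$ with
defaults 1 s base, 0.5 s per fatigue unit, 10 s cap, is an operational
assumption (the source model states only that fatigue lengthens reaction
time); composing it with the distance model is monotone, so a higher
fatigue score never shortens the predicted stop.

## Problem sizes and determinism

Every stochastic function takes a mandatory integer seed and is
bit-reproducible. The test suite exercises synthetic recordings of 4-8 s
and ensembles of 10-50 seeds, cohort checks at 12 subjects x 5 sessions
x 8 s with 1-2 channels, a 500-point braking sweep, a $10^5$-draw
permutation oracle for the correlation p-value, and 100 fold-shuffle
seeds for the CV averages — sizes chosen so the full suite completes in
about a minute while keeping Monte-Carlo error well inside the asserted
tolerances. The study-table computations themselves are exact and
instantaneous.

## Known limitations

- The channel-10 CF correlation and the exact published coefficient
  vector cannot be recovered from the printed tables (see above); both
  discrepancies are surfaced, not patched.
- Synthetic EEG is a spectral emulation only; conclusions about real
  recordings require real recordings.
- Session labels of the printed table rows are taken in printed order
  (first set, then fifth set); the tables do not label them explicitly.
- The artifact rules are simple thresholds, not source separation; they
  are meant to be auditable, not optimal.
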