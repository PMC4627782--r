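---
title: "Methods: longitudinal resting-state network outcome measures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal resting-state network outcome measures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsnlong)
```

`rsnlong` analyses densely sampled longitudinal resting-state fMRI studies
of a single subject: weekly scans over several years, with occasional
missed weeks. This vignette explains the models and procedures the package
implements, the parameters that matter, the synthetic-data module that
exercises the whole chain, and the numerical and design choices made where
the design was genuinely open.

## Study design and data model

The reference design is a 185-calendar-week span with 158 acquired weekly
sessions of 200 frames each (TR on the order of seconds; the package works
at the level of frame series, not pulse sequences). Week indices count
calendar weeks from the first session, so missed scans leave gaps rather
than compressing the time axis; all temporal analyses respect those gaps.
`make_calendar()` fixes the span, the observed weeks (uniform random
missingness, endpoints anchored) and the acquisition dates used for
covariate matching.

## Group ICA and the network outcome measures

Sessions enter as in-mask voxel-by-time matrices. The decomposition chain
(`gica()`) follows the standard group spatial-ICA construction:

1. **Order selection.** The Wax–Kailath minimum description length cost is
   evaluated on the eigenvalues of each session's time-dimension
   covariance, with the number of frames as the effective sample size; the
   group model order defaults to the median of the per-session estimates.
2. **Two-stage PCA.** Each session is reduced to `session_k` whitened
   components (default twice the model order, for robust
   backreconstruction, capped at the session's numerical rank); the
   reduced sessions are concatenated along the temporal direction and
   reduced again to the model order.
3. **Extended Infomax ICA.** Full-batch natural-gradient updates with
   sub/super-Gaussian switching. Because the empirical likelihood of small
   studies has partial-mixing fixed points, the optimiser runs a few random
   initialisations (default 4) and keeps the decomposition with the highest
   pseudo-likelihood; learning-rate annealing (factor 0.95, floor `1e-4`)
   and a relative weight-change tolerance of `1e-4` (matched to the
   annealed step size) govern convergence, with non-convergence flagged,
   never silent. The sign indeterminacy is resolved by flipping each
   component to positive skewness.
4. **Stability screen.** `stability_screen()` reruns the decomposition from
   randomised initialisations, matches components across runs by absolute
   spatial correlation, and scores each cluster by within-cluster mean
   absolute correlation minus the maximum correlation to any other cluster,
   clamped to [0, 1] — a simplified version of the ICASSO cluster-quality
   index (the full CCA-based procedure is out of scope). Components under
   the threshold (default 0.8) are flagged.
5. **GICA3 backreconstruction.** Per-session maps are
   \(S_i = M\,W\,G_i^-\,F_i^-\,Y_i\) and time courses
   \(R_i = F_i\,G_i\,A\); the mean of the session maps equals the aggregate
   map exactly, an algebraic identity the tests verify to `1e-6`.

Backreconstructed maps are regression weights, so "z-scoring" standardises
each map to mean 0 / SD 1 over in-mask voxels (the group-ICA toolbox
display convention); a correlation-to-z transform is undefined for weights
outside \([-1, 1]\) and is deliberately not used. The choice is recorded in
the fit's metadata. Time courses are scaled by the map SD and expressed in
percent of the session's mean signal when that mean is positive
(zero-baseline synthetic data stay in data units).

Three weekly outcome measures follow (`compute_outcomes()`):

* **Spatial-map similarity.** \(\eta^2\) between each session's z-scored
  map and the study mean map (mean over all backreconstructed sessions of
  the run; configurable),
  \[\eta^2 = 1 - \frac{\sum_i (a_i - m_i)^2 + (b_i - m_i)^2}
                      {\sum_i (a_i - \bar M)^2 + (b_i - \bar M)^2},\]
  with \(m\) the voxelwise mean image and \(\bar M\) its grand mean. It is
  1 only for identical images and, unlike a correlation, penalises
  differences in the actual values.
* **Temporal fluctuation magnitude.** Root mean square of the
  percent-signal-change network time course.
* **Between-network connectivity (BNC).** Pearson correlation of each
  network pair's time courses per session (scale-invariant, so the percent
  scaling is cosmetic; recorded for transparency).

Overlap maps threshold the z-scored session maps (default z > 1) and
express the supra-threshold count per voxel as a percentage of sessions.

## Reproducibility summaries

Week-to-week reproducibility is summarised by the coefficient of variation,
\(100\,\mathrm{SD}/\mathrm{mean}\) (sample SD throughout; the n−1
denominator is a package choice, the convention is not otherwise pinned
down). CV inflates near zero mean, so values with \(|\mathrm{mean}| <
2\,\mathrm{SD}\) carry a `near_zero_mean` flag and the SD should be read
alongside. Comparisons against a reference multi-session dataset use the
two-sided equal-variance F-test per network, corrected across the family of
networks (or the 105 network pairs) — Bonferroni by default for the F-test
family, Benjamini–Hochberg FDR elsewhere; both are available everywhere. A
`subset_first` option re-runs the longitudinal side on its first N sessions
to match a smaller reference dataset's size. The intraclass correlation is
deliberately absent: with a single subject there is no between-subject
class variance to anchor it.

## Temporal structure

Each weekly outcome series is screened for three separate structures; trend
and periodicity are tested on the raw series, persistence on
detrended/deseasonalized residuals (flags expose both choices), since the
three are reported as separate findings.

**Trend.** Ordinary least squares on the calendar week index;
significance by the slope's F statistic on (1, n−2) degrees of freedom,
FDR-corrected across networks. A permutation guard (statistic |r| with the
week index, add-one p-value, default 1000 iterations) is used for the
confound series. The permutation p-value for the trend statistic is
identical under |r| and the |t| of the slope (they are monotone transforms
of one another).

**Annual periodicity.** The spectrum is estimated by per-frequency
harmonic regression at the observed week indices — missing weeks simply
contribute no rows, no imputation — on the Fourier grid of the full span
(spacing 1/185 per week, Nyquist bin excluded because its sine regressor
vanishes on integer weeks). The annual frequency 1/52.18 ≈ 0.0192 per week
is not a Fourier grid point of a 185-week span, and a regression spectrum
has no reason to be confined to that grid, so when a target frequency is
supplied it is appended to the grid and evaluated exactly; with no missing
weeks the estimate reduces to the classical periodogram up to a global
scale factor (a tested invariant). Significance uses Fisher's exact g-test:
\(g = \max_j I_j / \sum_j I_j\) with the exact truncated alternating-sum
null tail. The test statistic is the spectral maximum — that is what
Fisher's null distribution describes and what keeps the test calibrated —
and the annual-periodicity flag additionally requires the spectral peak to
fall on the target bin; the target bin's power share is reported alongside.
An optional rank transform of the values guards against outliers.
Seasonality is corroborated by correlating each series with a daily
covariate (e.g. recorded daily maximum temperature), matched to session
dates by nearest day, with a permutation p-value.

**Persistence.** Low-order ARMA models, at most (3, 3), fitted without
imputation by a reduced-statistics route (maximum likelihood degrades for
the MA part when samples are missing):

1. a long AR (order 12 by default) is fitted by Burg's recursion pooled
   over the maximal runs of consecutive observed weeks; each reflection
   coefficient records how many prediction pairs informed it;
2. candidate (p, q) models are initialised from the long-AR-implied
   autocovariance by extended Yule–Walker (AR part) and Durbin's method
   (MA part: a long AR of the AR-filtered process, then Yule–Walker on
   that coefficient sequence itself);
3. each candidate is refined by least squares in reflection-coefficient
   space, weighting order k by its prediction-pair count \(n_k\) — the
   pooled Burg reflection coefficients are asymptotically independent with
   variance ≈ \(1/n_k\), so the weighted mismatch is on a χ² scale;
4. the order is selected by that model error plus a BIC-type penalty
   \((p+q)\log(\bar n)\); the selected model's innovation variance is the
   quadratic form of its truncated AR(∞) filter against the long-AR-implied
   autocovariance; stationarity and invertibility are enforced by root
   reflection.

A pairwise-lag autocovariance estimator (products over observed index
pairs per lag) was evaluated first and abandoned: the resulting sequence is
frequently not positive definite at the orders a long AR needs, which
destabilises the Levinson recursion and, in simulation, collapsed the order
selection. The segmented Burg estimator has no such failure mode and its
per-order sample sizes give the selection criterion a known scale. At the
study's sampling (158 of 185 weeks), white noise selects order (0, 0) in
about 95% of runs and an ARMA(1,1) with \(a_1 = -0.7, c_1 = 0.5\) is
identified in about 76%, with essentially unbiased coefficients.

Reported coefficients use the convention
\(y_t + a_1 y_{t-1} + a_2 y_{t-2} + a_3 y_{t-3} =
  e_t + c_1 e_{t-1} + c_2 e_{t-2} + c_3 e_{t-3}\),
so \(a_k\) is the negative of the textbook AR coefficient \(\phi_k\) while
\(c_k = \theta_k\). The simulators take `ar`/`ma` in the textbook
convention (an AR(1) with `ar = 0.6` has lag-1 autocorrelation +0.6); the
mapping is \(a_k = -\phi_k\).

## Motion and scanner confounds

Framewise displacement summarises head motion per frame:
\(\mathrm{FD}_t = \sum |\Delta d| + r \sum |\Delta \alpha|\) with
translations in mm, rotations in radians converted on a sphere of radius
\(r = 50\) mm. Rotation columns are assumed in radians (the SPM
realignment convention). The per-session summary is the mean FD (the
maximum is reported alongside; the summary statistic is a package choice).
The scanner-stability phantom contributes a weekly mean-intensity series.
Both series go through the same trend test plus permutation guard; in a
confound-free study neither shows a significant trend. Frame censoring is
deliberately not performed.

## The synthetic-data module

`simulate_outcome_series()` generates weekly series as
\(y_t = \beta_0 + \beta_1 t + A\sin(2\pi t/P + \phi) + \varepsilon_t\),
with \(P = 52.18\) weeks (one calendar year) and ARMA noise produced by
direct recursion with a 500-sample burn-in; values are kept at observed
weeks only and the generating truth is attached to every series.
`simulate_sessions()` builds toy 4D studies: compact Gaussian-blob sources
at well-separated centres inside an ellipsoidal mask (spatially sparse,
hence super-Gaussian — the regime spatial ICA assumes), mixed by smooth
session-specific time courses, plus Gaussian noise at a configurable
signal-to-noise ratio and a constant baseline (default 1000, a typical EPI
scale, so percent-signal-change scaling is meaningful). Motion tables are
random walks (translations in mm, rotations in radians, rotational step
scale tied to the 50 mm radius); the phantom series is constant plus white
noise — trendless by construction, matching its negative-control role; the
daily covariate is an annual sinusoid plus noise with defaults resembling
a mid-Atlantic daily maximum temperature (mean 17 °C, amplitude 12 °C,
noise SD 4 °C, minimum in mid-January for a study starting in December).
All generators are bit-reproducible under a fixed seed.

What the generator does *not* emulate: hemodynamics, physiological noise,
scanner artefacts, spatial normalisation error, or anatomically meaningful
network layouts. Passing tests therefore demonstrate that the estimators
recover known structure of this generative family at desk scale — linear
trends, annual sinusoids, ARMA persistence, low-rank spatial mixtures —
not that any particular neuroscientific finding would replicate.

## Problem sizes used in the tests

The test-suite simulations are sized for a laptop-class run: toy volumes of
12×12×8 voxels (about 600 in the ellipsoidal mask) with 40–60 frames and
3–5 sources; statistical calibration at 2000 replicates per test;
order-selection and recovery studies at 200 replicates on the 158/185
calendar; 20-study sweeps for source recovery. The ARMA(1,1) recovery truth
(\(a_1 = -0.7, c_1 = 0.5\)) was chosen once as a strongly persistent,
clearly identifiable pole/zero configuration at n = 158; calibration and
recovery tests fit with the detrend/deseasonalize options off, the
controlled null for series that carry neither structure.

## Known limitations

* The stability screen is a simplified compactness index, not the full
  ICASSO procedure; on very small studies individual ICA runs can land in
  inferior optima, which the screen flags rather than repairs.
* The regression spectrum's ordinates are treated as exchangeable in the
  exact g-test null; under heavy missingness the ordinates are mildly
  correlated and the test is approximate (calibration at 158/185 sampling
  is verified by simulation).
* Network identification (anatomical labelling of components, gray-matter
  checks) is a human judgement and out of scope; component indices stand in
  for network labels throughout.
* Trend detection is linear only, by design.
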