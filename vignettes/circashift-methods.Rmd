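---
title: "Methods: circadian rest-activity and temperature rhythm analysis for shift workers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: circadian rest-activity and temperature rhythm analysis for shift workers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`circashift` analyses one-week wearable telemetry (per-minute chest
accelerometry and chest-surface temperature) from day-shift (DS) and
night-shift (NS) health workers. This vignette documents the models, the
choices behind their implementation, and what the shipped tests do and do not
establish.

## Data model and preprocessing

A subject is a per-minute series (`pa`, `temp`) on a strict 1-minute local
clock grid with explicit missing values, a diary of work and sleep intervals,
and questionnaire metadata (shift type, age in years, chronotype score with
larger = more morning-oriented, years of past night work, ideal and reported
total sleep time). Time is handled as a naive local clock; daylight-saving
transitions are out of scope for one-week windows.

Activity is averaged into clock-aligned 5-min bins and square-root
transformed; temperature into hourly bins for whole-study spectra and 5-min
bins for within-bout analysis. A bin is missing only when *all* its minutes
are missing: with a median missing fraction near 3% that maximizes data use,
and the choice is explicit in `resample()` rather than buried in a default.

Each subject's monitoring span is partitioned into consecutive 24 h windows
anchored at 00:00 for DS and at the night-shift start for NS (taken from the
diary when it starts at 20:00 or 21:00, defaulting to the scheduled 21:00
when ambiguous). A window is a workday iff a diary work interval starts
inside it. Subjects enter the work/free comparison only with at least one
workday and one free day. Sleep debt is ideal minus reported total sleep
time, in hours, possibly negative.

## The harmonic hidden Markov model

Square-root 5-min activity is modelled by a 3-state Gaussian-emission HMM —
inactive/rest, moderately active, highly active, ordered by emission mean —
whose transition probabilities follow the 24 h clock. Each transition row is
a multinomial logit with the self-transition as the reference category; every
non-reference logit carries `H` harmonic sine/cosine pairs of fundamental
period 24 h. `H = 1` by default (configurable to 2): one pair per logit is
the smallest model that lets rest propensity rise and fall once per day, and
doubling `H` is an explicit user decision, judged by AICc, not a silent
default. The two-oscillator variant for work/free comparison shares
emissions and baseline logits across day types and estimates separate
harmonic coefficients per day type — the oscillator changes between work and
free days, not the states themselves.

Estimation is EM:

- **E-step** — scaled forward–backward with the time-varying transition
  matrices (compiled code). Missing bins contribute emission likelihood 1 to
  every state; transitions still apply, so posteriors across gaps follow the
  prior propagated by the chain.
- **M-step** — closed-form Gaussian updates for emissions (SD floored at
  1e-3); per-row weighted multinomial-logit optimization (BFGS with analytic
  gradient) for the transition coefficients, started at the current values so
  every iteration is a generalized EM step and the log-likelihood is
  non-decreasing (asserted each iteration, with a 1e-6 numerical allowance;
  violations flag the fit).

Initialization places the state means at the 25th/60th/95th percentiles of
the observed values — ordered initialization prevents label switching — with
equal SDs and diagonal-dominant transitions (0.9 self-transition). Five
restarts (default) jitter the percentile means; each restart runs 25
iterations, the best continues to convergence (|Δloglik| < 1e-5 or 500
iterations; non-convergence is flagged, never silent). The initial state
distribution is estimated (standard EM update). A constant series cannot
support three states and returns a flagged single-state fallback.

Decoding is *local*: the per-bin posterior argmax from forward–backward, not
Viterbi — the posteriors themselves are the product of interest (rest
profiles are posterior means), and the most-likely-state track is a display
summary.

## Circadian parameters

- **Rest profile**: mean posterior rest probability per 5-min clock slot
  across the days in scope (whole study, workdays, free days); bins that were
  missing are excluded from their slot's mean; the rare slot with no observed
  bin is filled circularly from its nearest slots. Profiles for clustering
  are anchored at 20:00.
- **p1-1**: the realized rest→rest transition probability P11(t) averaged
  over bins with weights equal to the posterior rest occupancy (an unweighted
  clock average is available). Weighting reflects transition behaviour
  during actual rest episodes; the rest row is in any case only identified at
  clock times the subject actually rests.
- **Rest amount**: area under the profile, `sum * 5/60` hours, in [0, 24].
- **Centre time of rest**: circular first moment of the profile on the 24 h
  clock. Circular (not linear) averaging is essential for NS rest that wraps
  midnight; a flat profile (mean resultant length < 1e-6) has no centre and
  is flagged undefined. A second phase marker, the timing of the maximum
  rest probability between 07:00 and 20:00 (ties to the earliest slot),
  targets the post-shift sleep of NS.
- **Rhythm Index**: with rest amount `A` and centre `c`, the mean profile
  value inside the circular window of width `A` centred at `c` minus the
  mean outside, clipped to [0, 1]. Conventions: `A = 0` or an undefined
  centre give 0; `A = 24` gives the profile mean. This
  inside-vs-outside-window contrast is this package's operationalization of
  the index (the original's exact formula is not published in enough detail
  to reimplement); it satisfies both defining boundary conditions — 1 for a
  perfectly regular probability-1 rest window, 0 in the absence of any
  circadian cycle — and is invariant under rotations of the clock. It is
  *not* invariant under adding a constant to the profile: the window width
  equals the rest amount, which such a shift changes. Treat RI values as
  comparable within this package, not interchangeable with other RI
  implementations.

## Spectral analysis

Whole-study temperature spectra use a missing-tolerant least-squares
periodogram: for each candidate period (2–40 h grid, 0.1 h steps, matching
the range over which both circadian and ultradian structure is expected at
one week of data) the demeaned series is regressed on a sine/cosine pair and
the power `(a² + b²)/2` recorded, then smoothed with a 3-point Daniell
window. Peaks are local maxima above a noise floor of 10× the median
smoothed density — under white noise the median estimates the null level
robustly, and the factor 10 corresponds to a ≲10% family-wise false-peak
rate at this grid's effective resolution (verified by simulation in the test
suite). The dominant period is the tallest peak; none above the floor means
"undetectable". Period CIs come from a day-block bootstrap: whole 24 h
blocks are resampled with replacement, the peak nearest each original peak
is located in each resample, and the 5th/95th percentiles (widened by one
grid step for quantization) give a 90% interval. A series shorter than
three cycles of the longest candidate period truncates the grid with a
warning. Dominant periods are classified circadian (20–28 h), circa-12 h
(10–14 h), circa-8 h (7–9 h), otherwise "other". The published band edges
exist only for the 12 h and 8 h classes; the circadian band 20–28 h is this
package's choice and is configurable. The spectral gravity centre is the
density-weighted mean period (trapezoid rule).

Ultradian analysis works inside rest bouts: maximal runs of decoded rest,
merged across interruptions shorter than 10 min (decode flicker should not
split a sleep episode), kept when 2–12 h long. Activity is first
LIDS-transformed — a 30-min moving average followed by `100/(PA + 1)` —
amplifying low activity so inactivity cycles during sleep become visible.
Per bout, the series is linearly detrended and the dominant least-squares
period on a 0.5 h to `min(6, duration/2)` h grid (0.05 h steps) recorded;
the subject's sub-period is the median over bouts.

## Clustering and inference

Subjects within a shift group are clustered on the concatenation of their
20:00-anchored workday and free-day rest profiles (576 values, left as
probabilities — no standardization, since all entries share the [0, 1]
scale). Ward linkage on Euclidean distance (`hclust`, `ward.D2`); the
dispersion `W_k` is computed with squared Euclidean distances so that it
equals the within-cluster sum of squares about the centroids. The number of
clusters is the elbow of `W_k`: the k in 2..kmax−1 (kmax = 8) maximizing the
second difference `W(k−1) − 2W(k) + W(k+1)`, ties to the smaller k; a
near-linear `W_k` has no elbow and returns k = 1 flagged. Cluster
comparisons use Kruskal–Wallis tests per parameter and scope.

Each circadian parameter's (workday, free-day) pair is regressed jointly on
shift type, age, chronotype score, years of night work and their pairwise
interactions through a bivariate copula model: two Gaussian margins
(identity or log link) bound by a one-parameter copula. Gaussian, Clayton,
Frank and Gumbel families ship; Gaussian is the default. Probabilities
(p1-1, RI) enter as log odds; rest amount and centre time in hours, with a
work/free centre-time pair differing by more than 12 h unwrapped past
midnight so the pair stays ordered (centre time is circular; the linear
treatment is a documented approximation). Estimation is joint ML started
from inference-for-margins (margins first, then the dependence parameter,
then everything jointly, BFGS); standard errors come from the observed
information. With the Gaussian copula and θ = 0 the likelihood factorizes
into two independent least-squares fits — used as a validation anchor in the
tests. Model selection is greedy backward elimination from the full
10-term-per-margin model, respecting marginality, minimizing AICc
(`AIC + 2k(k+1)/(n−k−1)`), ties to the smaller model; backward (not
exhaustive) search keeps the 2×10-term space tractable and the search path
is logged. Covariates are not centred. Group contrasts use Mann–Whitney,
Wilcoxon signed-rank, Spearman and chi-square tests via thin wrappers. The
power computation inverts the two-sided two-sample t-test through the
noncentral t distribution, returning the smallest integer per-group n
reaching the target power.

## The synthetic cohort

No public data accompany the analysis, so `generate_cohort()` defines the
study conditions the pipeline is tested under. The latent rest/activity
chain is simulated at the 5-min analysis resolution (288 steps/day) with a
24 h sinusoid on the transition logits — suppressing rest exit and boosting
rest entry around the rest acrophase — and per-minute Gaussian emissions on
the sqrt scale, squared to activity units (arbitrary non-negative units; the
sensor's units are not published). Simulating the chain at the analysis
resolution makes generator parameters directly comparable with fitted ones;
the only systematic gap is benign: the sqrt of a 5-min mean of squared
emissions concentrates around `sqrt(mu² + sigma²)`, which is the effective
emission mean the recovery tests use. DS rest peaks at 03:00 on work and
free days; NS at 11:00 on workdays (post-shift sleep) and 04:00 on free
days, with weaker harmonic amplitude and a higher rest-exit baseline than DS
— night shifters' fragmented, less rhythmic rest is a study condition, and
without it no analysis could find the DS/NS orderings. Temperature is a
35 °C offset plus 24/12/8 h harmonics (0.8/0.3/0.1 °C), an ultradian
sinusoid active only during rest whose phase restarts at each rest onset
(2.2 h DS, 1.8 h NS; amplitude 0.25 °C) and white noise (SD 0.15 °C).
Missingness is block-structured — geometric gap lengths of mean 30 min, as
telemetry dropouts are bursty — at a 2.76% default fraction. Metadata
covariates are drawn independently (age 22–62, chronotype 24–74, NS years of
night work 5–35, DS forced to 0 under a configurable flag).

What the generator does *not* emulate: posture and meal effects, activity
autocorrelation within a state beyond the chain, day-to-day habit drift,
covariate–rhythm dependence (ages do not influence simulated rhythms), and
any physiology beyond the Markov/spectral structure. Passing tests
therefore demonstrate that the estimators recover the structure they assume,
at realistic sizes and noise — not that the model is adequate for any
particular real cohort.

## Numerical and reproducibility notes

Every random stage takes an explicit seed, and generated cohorts are
byte-identical under the same seed. Fitted quantities are additionally
subject to floating-point reduction order: on multi-threaded BLAS, repeated
runs can differ at ~1e-7 per EM iteration, which convergence paths can
amplify to ~1e-5 in final parameters (and can flip a discrete argmax on a
near-flat curve, e.g. the daytime-maximum phase marker). On a single thread
runs are bit-identical. Degenerate inputs are handled explicitly: constant
activity (single-state fallback, flagged), all-missing spectra (error),
flat rest profiles (undefined centre, RI 0), boundary dependence parameters
(flagged), zero standard errors (flagged).

Problem sizes in the shipped tests are chosen for a laptop-scale run: 20
subjects × 7 days for HMM parameter recovery, 20 seeds for spectral
coverage, 50 seeds × n = 140 for regression coefficient recovery, 6 + 6
subjects for the end-to-end ordering check, with restart counts reduced
where only plumbing is under test.

## Known limitations

- The RI and the exact transition parameterization are this package's
  reconstructions of methods whose full details are unpublished; boundary
  behaviour is matched, magnitudes need not be.
- Centre time in the regression is treated linearly after pairwise
  unwrapping; a fully circular regression is out of scope.
- The spectral noise floor is a fixed multiple of the median density;
  heavy-tailed non-sinusoidal signals could shift it.
- Linear predictors only in the copula model (no smooth terms); 3-D sensor
  orientation, recruitment infrastructure and questionnaire scoring are out
  of scope.
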