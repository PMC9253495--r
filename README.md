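# circashift

Quantifying circadian rest–activity and temperature rhythm disruption in
telemonitored shift workers.

Hospital staff on permanent night shifts accumulate circadian disruption that
is invisible to conventional questionnaires. One week of per-minute chest
accelerometry (physical activity, PA) and chest-surface temperature from a
wearable sensor, together with a work/sleep diary, is enough to quantify it —
provided the analysis respects the structure of the data: rest–activity is a
latent-state process whose dynamics follow the 24 h clock, night shifters'
(NS) "days" start at the 21:00 shift onset rather than midnight, and work and
free days must be modelled jointly because they come from the same person.
`circashift` implements that analysis end to end for biostatisticians and
chronobiology researchers, and ships a synthetic-cohort generator so every
stage is testable without access to restricted participant data.

## The model

Square-root 5-min average PA is modelled by a three-state Gaussian-emission
hidden Markov model — inactive/rest (IA), moderately active (MA), highly
active (HA) — whose transition probabilities are modulated by a circadian
oscillator (harmonic HMM). Each transition row *j* is a multinomial logit
with the self-transition as reference:

    eta_jk(t) = alpha_jk + sum_h [ a_jkh cos(2*pi*h*t/24) + b_jkh sin(2*pi*h*t/24) ]
    P_jk(t)   = softmax over k of eta_jk(t),   eta_jj = 0

fitted by EM (forward–backward E-step; weighted multinomial-logit M-step).
The two-oscillator variant (2-HHMM) shares emissions and baseline logits but
estimates separate harmonic coefficients for work and free days. Four
circadian parameters summarize each subject, overall and per day type:

- **p1-1** — probability of remaining at rest given rest in the previous
  5-min period (occupancy-weighted mean of the realized P11(t) curve): rest
  *quality*;
- **rest profile** — 288-slot daily curve of posterior rest probability, and
  **rest amount**, its area (h);
- **centre time of rest** — circular gravity centre of the rest profile:
  rest *phase*;
- **Rhythm Index (RI)** — mean rest probability inside the circular window
  of width = rest amount centred at the centre time, minus the mean outside,
  clipped to [0, 1]: rest *regularity* (1 for a perfectly regular
  probability-1 rest window, 0 for a flat profile).

Around the HMM: least-squares periodogram spectra of hourly temperature with
day-block-bootstrap 90% CIs and dominant-period classification
(circadian/circa-12 h/circa-8 h); LIDS-transformed activity and 5-min
temperature spectra inside decoded 2–12 h rest bouts for ultradian
(0.5–6 h) sub-periods; Ward/Euclidean clustering of the concatenated
576-element work+free rest profiles with elbow selection of k; and bivariate
copula regression (Gaussian/Clayton/Frank/Gumbel) of each (workday, free-day)
parameter pair on shift type, age, chronotype score and years of night work,
with AICc backward selection and Wald z-tests.

## Worked example

```r
library(circashift)

cohort <- generate_cohort(n_ds = 1, n_ns = 1, n_days = 7, seed = 42)
s <- cohort$subjects$S001              # the day shifter

bins <- resample(s$series, "5min")     # clock-aligned 5-min means
bins$y <- sqrt_pa(bins$pa)
bins$clock <- (as.numeric(bins$timestamp) %% 86400) / 3600

fit <- fit_hhmm(bins$y, bins$clock, seed = 1)
fit
#> <hhmm_fit> 3 states, H=1, oscillator: single
#>   means: 1.114 3.123 6.127
#>   sds:   0.2235 0.4554 0.5414
#>   loglik -1569.92 (k=26, n=1964)

dec <- decode(fit, bins$y, bins$clock)
circadian_params(fit, dec)
#>   scope   p11 rest_amount_h centre_time centre_max_daytime rhythm_index
#> 1 whole 0.954          7.79        4.18                  8        0.681

spec <- sr_spectrum(resample(s$series, "hourly")$temp, n_boot = 100, seed = 1)
spec
#> <spectrum_estimate> grid 2.0-40.0 h, dominant 24.0 h
#>   period height ci_lo ci_hi
#> 1   24.0   0.32  23.9  24.1
#> 2   11.9   0.05  11.8  12.0
classify_dominant(spec)
#> [1] "circadian"
```

The day shifter rests ~7.8 h per day centred at ~04:10 with high rest
persistence (p1-1 = 0.95) and a clear rest rhythm (RI = 0.68); the
temperature spectrum has a dominant 24 h peak (90% CI 23.9–24.1 h) with a
secondary 12 h harmonic. `power_sample_size(0.5, 0.05, 0.8)` returns the 64
subjects per group needed to detect a medium effect on these parameters.

`run_pipeline(pipeline_config(...), out_dir)` executes the whole chain —
simulation or CSV input, eligibility (≥1 workday and ≥1 free day), HHMM and
2-HHMM fits, parameter tables, spectra, clustering, copula regressions,
ultradian analysis — writing flat CSVs plus a JSON manifest; `report(out_dir)`
summarizes a run.

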