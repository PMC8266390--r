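# photopit

Analysis of appetitive Pavlovian conditioning and outcome-selective
Pavlovian-to-instrumental transfer (PIT) experiments recorded with
two-channel fiber photometry — for behavioral-neuroscience labs that pair
operant event logs (food-port entries, lever presses, CS and reward
timestamps) with bulk calcium recordings and want the whole analysis chain
to be scripted, seeded and testable.

The package implements, end to end:

* **Isosbestic correction and Z-scored ΔF/F.** The 415-nm
  (calcium-independent) stream is interpolated onto the 470-nm time grid,
  fit to the 470 signal by ordinary least squares over the whole session,
  and the fractional change is
  ΔF/F = (F₄₇₀ − F̂₄₁₅)/F̂₄₁₅, Z-scored against the session mean and
  population SD. Session QC flags poor fits (r² < 0.6) and traces without
  transient calcium fluctuations.
* **Peri-event quantification.** Traces aligned to CS onset and reward
  retrieval (first food-port entry at or after a delivery); peak and
  trapezoidal AUC on 3-s pre/post windows; trial → CS → session averaging
  and phase binning (sessions 1, 2, 3/4, 5/6, 7/8).
* **Elevation-ratio behavioral scoring.** Conditional approach
  CS/(CS + preCS) from entry rates in the CS probe period vs the 2-min
  pre-CS baseline, and PIT lever scores splitting presses into Same vs
  Different levers via each subject's counterbalanced contingency.
* **Inference.** Paired/unpaired t tests, repeated-measures and mixed
  (split-plot) ANOVA with the Greenhouse-Geisser correction
  ε̂ = (Σλᵢ)²/((k−1)Σλᵢ²) applied unconditionally, and Bonferroni post
  hocs — with broom-style `tidy()`/`glance()` methods.
* **A seeded synthetic cohort generator** reproducing the session designs
  (30-s random-time reward schedules inside 2-min CSs, 2–4-min ITIs,
  pseudorandom stimulus orders, 15-s probe periods, random-ratio-20
  instrumental sessions, the 5-min-extinction/4-min-ITI PIT test) and the
  signal statistics (photobleaching, shared motion artifact, double-
  exponential calcium transients), so every stage is testable without any
  recorded data.

## Worked example

Simulate one photometry conditioning session, preprocess it, and score it:

```r
library(photopit)

cfg <- sim_config(photometry = TRUE, n_subjects = 4)
ct  <- make_contingency(0)                      # tone→sucrose, left→sucrose
sch <- generate_conditioning_session(cfg, ct, session_index = 5, seed = 11)
log <- simulate_behavior(sch, cfg, ct, seed = 12)
rec <- simulate_photometry(sch, log, cfg, seed = 13)

trace <- correct_photometry(rec)
attr(trace, "fit")
#> <isosbestic_fit> slope 1.274, intercept -0.3464, r^2 0.7755
qc_session(trace)[, c("transient_rate_per_min", "r_squared", "passed")]
#> # A tibble: 1 × 3
#>   transient_rate_per_min r_squared passed
#>                    <dbl>     <dbl> <lgl>
#> 1                  0.855     0.775 TRUE

quantify_session(trace, sch, log)$summary
#> # A tibble: 2 × 5
#>   peak_pre peak_post auc_pre auc_post event_kind
#>      <dbl>     <dbl>   <dbl>    <dbl> <chr>
#> 1    0.125      8.24  -0.275     5.59 cs_onset
#> 2    0.747     16.2    0.181    11.4  reward_retrieval
```

The QC report says the session is usable: the isosbestic fit explains 78%
of the 470-nm variance and transients are detected at 0.86/min. The
peri-event table shows the expected physiology: Z-scored activity is flat
in the 3-s baselines (peak_pre ≈ 0.1–0.7) and strongly elevated after CS
onset and reward retrieval (peak_post 8.2 and 16.2 Z; AUC 5.6 and
11.4 Z·s) — the retrieval transient is configured twice as large as the
CS transient.

Behavior from the same session, and a PIT test for the same subject:

```r
attr(pavlovian_elevation(sch, log), "summary")
#> [1] 0.778          # conditional approach well above the 0.5 indifference point

pit_sch <- generate_pit_session(cfg, seed = 14)
pit_log <- simulate_behavior(pit_sch, cfg, ct, seed = 15)
pit_lever_scores(pit_sch, pit_log, ct)
#> # A tibble: 1 × 2
#>   same_ratio different_ratio
#>        <dbl>           <dbl>
#> 1      0.602           0.563
```

The Same-lever elevation exceeding the Different-lever elevation is the
outcome-selective PIT signature. `run_experiment()` chains all of the
above over a whole cohort and writes tidy TSV tables plus a JSON manifest;
`plot_peri_event()`, `plot_elevation()` and `autoplot()` give the standard
figures. A thin CLI for cohort simulation and full runs is installed at
`inst/cli/photopit.R`.

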