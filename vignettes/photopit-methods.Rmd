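---
title: "Models and methods behind photopit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind photopit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photopit)
```

photopit analyses two-food-outcome appetitive Pavlovian conditioning and
outcome-selective Pavlovian-to-instrumental transfer (PIT) experiments
recorded with two-channel fiber photometry. This vignette explains the
models the package implements, the parameters that matter and their
defaults, what the synthetic-data generator does and does not emulate, and
the numerical and design choices that were genuinely open.

## The task

Animals learn that each of two 2-min auditory stimuli (tone, white noise)
predicts one specific food reward (sucrose solution or a chocolate pellet).
During each 2-min CS the associated reward arrives on a 30-s random-time
(RT) schedule — memoryless deliveries averaging one per 30 s, hence about 4
per CS — independent of behavior. Conditioning comprises 8 daily sessions
of 8 presentations of each CS (4 of each in photometry experiments, which
also impose a ≥15-s reward-free probe period after CS onset so CS- and
reward-evoked calcium signals can be separated), with intertrial intervals
uniform on 2–4 min (mean 3 min). Instrumental sessions teach two levers,
each earning one of the rewards on an escalating schedule ending at
random-ratio 20, terminating at 30 earned outcomes or 45 min. At the PIT
test both levers are available but unrewarded: after 5 min of extinction,
each CS is presented 4 times (fixed 4-min ITI, no rewards), and the key
measure is whether a CS selectively elevates pressing on the lever whose
training outcome matches the CS's predicted reward (Same) over the other
lever (Different).

## Photometry model and preprocessing

The acquisition interleaves 415-nm (isosbestic, calcium-independent) and
470-nm (calcium-dependent) excitation at 20 Hz per channel; we model the
two channels' sample times as offset by half a sample period. The phrase
"20 Hz, interleaved" is ambiguous between 20 Hz per channel and 20 Hz
total; we assume per channel, and nothing downstream depends on the choice
beyond the time resolution of the peri-event windows.

The generative model for the synthetic recordings is

$$F_{470}(t) = f^0_{470}\,B(t)\,\bigl(1 + \textstyle\sum_e a_e k(t-t_e)\bigr)
  + \sigma_m m(t) + \varepsilon(t), \qquad
  F_{415}(t) = f^0_{415}\,B(t) + g_{415}\,\sigma_m m(t) + \varepsilon(t),$$

where $B(t)$ is a two-exponential photobleaching factor common to both
channels (defaults 0.3/400 s and 0.3/2500 s, roughly halving fluorescence
over a 40-min session), $m(t)$ a zero-mean low-pass motion artifact shared
across channels ($\sigma_m = 10$ fluorescence units ≈ 10% of baseline,
autocorrelation time 0.3 s), $\varepsilon$ white measurement noise
(sd 0.5), and $k$ a peak-normalized double-exponential kernel
$(1 - e^{-t/\tau_r})e^{-t/\tau_d}$ with $\tau_r = 0.1$ s,
$\tau_d = 0.5$ s (fast-indicator kinetics), so transient amplitudes
$a_e$ are in dF/F units. Transients occur at CS onsets ($a = 1$; in
unpaired CS-only sessions decayed by the habituation rate per session) and
at reward retrievals — the first food-port entry at or after a delivery —
with $a = 2$. No calcium term enters the 415 channel.

Preprocessing follows the standard isosbestic-regression pipeline: the 415
stream is linearly interpolated onto the 470 time grid; ordinary
least-squares regression over the whole session maps the 415 signal onto
the 470 signal; dF/F is the fitted-reference-normalized residual
$(F_{470} - \widehat{F}_{415})/\widehat{F}_{415}$; and the dF/F series is
Z-scored against the whole-session mean and *population* standard
deviation (sample vs population is negligible at session length but must
be fixed for exact tests). The fit is global and unweighted: no windowed or
robust variant is offered, the simplest faithful reading of the method.

Two structural points are worth stating because the tests rely on them:

* **Exact artifact cancellation.** The motion process is an AR(1) sequence
  anchored at the 415 sample times and piecewise-linear in between, so the
  artifact sampled by the 470 channel (midway between 415 samples) is
  exactly the linear interpolation of the 415 samples. When the channel
  gains are affine-consistent ($g_{415} = f^0_{415}/f^0_{470}$, the
  default) and noise and transients are absent, the de-interleaved 470
  trace is an exact affine function of the interpolated 415 trace and
  dF/F vanishes to numerical precision. This is a deliberate idealization:
  a real rig's artifact is only approximately shared, and the band-limited
  construction is what makes "shared" well defined on an interleaved
  acquisition.
* **Bleach immunity, and its limits.** Bleaching common to both channels
  cancels exactly in the absence of transients (it appears in both the
  signal and the fitted reference). Once transients are present they
  perturb the global regression slightly, leaving a slow residual
  proportional to the transient duty cycle; in practice the injected
  transient profile is recovered to within ~10% relative RMS under ~50%
  bleaching. A time-varying (windowed) fit would reduce this residual but
  is out of scope.

Session QC mirrors the qualitative exclusion rules — no transient calcium
fluctuations, or a poor linear fit from excessive motion — with two
config-exposed thresholds: isosbestic-fit $r^2 \ge 0.6$ and a detected
transient rate $\ge 0.1$/min. Transients are local maxima exceeding three
robust standard deviations (1.4826 × MAD) of the dF/F trace, separated by
at least 1 s; candidate maxima are taken on a 0.25-s moving-average
smoothed copy, because on a raw 20-Hz white-noise trace single-sample
3-sigma excursions alone would register as "transients" at well above the
acceptance rate, which would defeat the purpose of the rule.

## Event quantification

Z-scored traces are aligned to CS onsets and reward retrievals. Each event
contributes one row sampled on the trace grid over a fixed window (3 s
pre, 3 s post); events whose window exceeds the recording are dropped and
counted rather than padded. Peak is the raw maximum within the pre
([-3, 0) s) or post ((0, 3] s) window — no baseline subtraction, since pre
and post are compared downstream — and AUC is the trapezoidal integral
over windows of equal length (units Z·s). A retrieval search is bounded by
the next delivery of the same trial so one entry cannot serve two
deliveries, and an entry exactly at the delivery time counts (the boundary
matters only on a discrete grid and is fixed inclusively for testability).
Per-trial measures are averaged within each CS and then across the two CSs
(unweighted), and sessions are binned into conditioning phases 1, 2, 3/4,
5/6, 7/8; subjects lacking a usable session in any bin are excluded and
listed.

A note on interpreting Z-scored peaks: because the session standard
deviation includes the transients themselves, the Z-peak is a saturating
(though strictly monotone) function of the underlying dF/F amplitude. The
parameter-recovery checks therefore operate in the physiological 2–14%
dF/F range, where measurement noise dominates the session sd and the
mapping is near-linear; at the generator's deliberately large default
amplitudes the Z-peak compresses.

## Behavioral scoring

Conditional food-port approach is scored per trial as an elevation ratio
$\mathrm{CS}/(\mathrm{CS} + \mathrm{pre})$ comparing the entry rate during
the CS probe period (onset up to the first delivery, or offset when none)
to the 2-min baseline immediately before onset; 0.5 is the indifference
point. PIT lever pressing is scored the same way per lever class after
splitting presses into Same/Different via the subject's counterbalanced
contingency, using full 2-min CS windows; PIT food-port entries likewise.
All windows are half-open ([start, end)), 0/0 ratios are undefined and
excluded from trial averages rather than imputed at 0.5 (imputation would
bias sparse-responding subjects toward indifference), and averaging is
trials-then-CSs throughout.

## Synthetic behavior

Food-port entries are an inhomogeneous Poisson process: baseline 2/min,
multiplied inside CSs by $1 + 0.5 \cdot \text{session}$, which produces
the acquisition pattern (elevation ratios rising from ~0.6 toward ~0.85
across 8 sessions). Each delivery is followed by one retrieval entry at an
exponential latency (mean 1 s) unless the CS has ended — a simplification
of real retrieval behavior. PIT pressing is Poisson at 5/min per lever,
elevated during CSs by $1 + \tau_{\text{same}}$ on the Same lever and
$1 + \tau_{\text{diff}}$ on the Different lever (defaults 1.0 and 0.2, the
control-like pattern); an inhibition-like cohort is emulated simply by
setting $\tau_{\text{same}} = \tau_{\text{diff}}$. These are phantoms for
pipeline validation: they have no within-session dynamics, no
satiety/extinction trends, no bout structure or refractoriness, and no
coupling between neural signal and behavior beyond shared event times.
Passing tests therefore demonstrate that the pipeline recovers known
structure from data with the right first-order statistics, not that it is
robust to every pathology of real recordings.

Design constants are drawn from the task description wherever stated
(trial counts, CS duration, RT mean interval, ITI range, probe period, PIT
structure, RR-20, termination rules); the signal and behavior rate
parameters are the package's own choices, set once to values a
practitioner would call realistic and left alone. Two consequences of the
stated design worth noting: the RT schedule is implemented as exponential
waits (memoryless), matching operant "random time" terminology and giving
the printed mean of 4 deliveries per 2-min CS; restricting arrivals to the
post-probe window in the photometry variant lowers the expectation to 3.5,
and whether the real scheduler compensated for this is not stated — we do
not compensate. The pseudorandom CS order is a uniform shuffle rejected
until no more than two identical CSs run consecutively. The ITI is uniform
on [120, 240] s, the simplest distribution consistent with the stated
range and mean.

## Statistics

Paired/unpaired two-tailed t tests wrap the classical formulas. The
repeated-measures ANOVA uses the orthonormal-contrast formulation: for
each within effect, subjects' scores on an orthonormal contrast basis give
the effect and error sums of squares (the error term is the effect's
interaction with subjects), and the Greenhouse-Geisser epsilon
$\hat\varepsilon = (\sum\lambda_i)^2 / (q \sum\lambda_i^2)$ is computed
from the covariance of those scores — equivalently, from the
double-centered covariance of the raw levels for a single factor. Crossed
within factors are supported through the same machinery (Kronecker
products of contrast bases), which is how three-way repeated-measures
designs are composed; unbalanced within-cells are rejected rather than
approximated. The mixed (split-plot) ANOVA tests the between factor
against between-subject variation within groups and the within and
interaction terms against the pooled subject-by-condition residual, with
epsilon from the pooled within-group covariance of the contrast scores.
Following the source convention, the GG correction is applied
unconditionally (no Mauchly pretest); it is the identity for two-level
factors. Degenerate inputs — zero-variance differences, all-identical
tables, groups of one subject — are errors, not silent NaNs. Bonferroni
correction is `min(1, m·p)` via `stats::p.adjust`.

Calibration: on null data (independent standard normals, 10 subjects × 4
levels) the GG-corrected test's type-I error at $\alpha = 0.05$ sits in
[0.03, 0.07] over thousands of replicates — mildly conservative, as
expected when the correction is applied under true sphericity.

## Reproducibility and problem sizes

Every generator takes an explicit seed (or inherits the caller's RNG
stream) and is a pure function of (configuration, seed);
`run_experiment()` writes byte-identical tables when re-run with the same
config and seed. The validation suite uses desk-scale problem sizes chosen
to estimate each quantity with comfortable margin: 10,000 RT trials and
ITIs, 2,000 unpaired sessions and null-ANOVA replicates, 500 PIT cohort
replicates of 10 subjects per group, and 8 subjects per amplitude level
for parameter recovery.

## Known limitations

* The isosbestic fit is global; slow drifts uncorrelated between channels
  (e.g. differential bleaching) are not modeled or corrected.
* QC thresholds are heuristics; the transient detector is intentionally
  simple (threshold + separation on a smoothed trace), not a
  deconvolution.
* The mixed ANOVA's within-effect test uses weighted group means when
  group sizes differ (identical to the balanced answer for equal n).
* File formats are canonical to this package; no parser for proprietary
  operant-box logs is provided (the event-log TSV documents the expected
  mapping: one timestamped row per press, entry, CS edge or delivery).
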