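---
title: "Methods: simulating and analysing pupillometry of cue-triggered mind wandering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing pupillometry of cue-triggered mind wandering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`pupilmw` re-implements, as a tested and fully synthetic pipeline, the
analysis of pupil-size dynamics around mind-wandering (MW) episodes in a
probe-caught vigilance task with task-irrelevant verbal cues. This
vignette documents the generative model behind the synthetic data, the
preprocessing and epoching conventions, the inferential machinery, and
the numerical and design choices a maintainer would want spelled out.

```{r setup}
library(pupilmw)
```

## The paradigm being emulated

One session is a fixed sequence of 1120 trials of 2 s each. Every trial
shows a pattern of white bars on black: horizontal bars are non-targets,
vertical bars (68 trials, separated by 9–31 trials) are targets to be
reported with a key press. On 210 trials a task-irrelevant cue-word is
shown under fixation, with balanced valence (70 neutral, 70 positive, 70
negative). At 28 fixed points the task halts and a thought-probe asks
what the participant was thinking immediately before: on-task,
spontaneous or intentional MW, external distraction, task-related
thought, or blank mind; MW reports also record whether a specific
cue-word triggered the episode. Probe positions are spaced 40 trials
apart on average. Pupil diameter is recorded binocularly at 30 Hz in mm.

Two quantitative facts about the fixed sequences matter for the
analyses and are built into the schedule generator:

* the mean probe gap is **exactly** 40 trials. The generator draws the 28
  start-anchored gaps from a rounded normal (SD 7.5), rescales them by
  unit steps to sum to 1120, and nudges probes off target trials while
  preserving the sum, so the last probe follows the final trial.
* cue-words are strongly enriched on the 4th trial before a probe
  (observed placement probability ≈ 75% in this paradigm versus an
  overall cue density of 210/1120 ≈ 19%). The generator places a cue
  there with probability 0.70; with the uniformly placed remainder the
  net probability is ≈ 0.75. This matters for the cue-placement confound
  check, which should come out flat across report categories.

Cue-words never land on target trials and probes never directly follow a
target trial, so that light-response analyses are not confounded by
target-evoked responses at reference positions.

## Latent states and probe reports

Each probe's pre-probe attentional state is drawn from a categorical
mixture whose defaults reproduce the per-subject report mix of the
emulated study: out of 28 probes, on average 7.36 on-task, 9.57
spontaneous-MW and 2.10 intentional-MW reports, the remainder split
evenly across external distraction, task-related thought and blank mind.
About 53% of spontaneous MW episodes (212/402 in the emulated data) are
cue-triggered; the cue-to-probe lag is `1 + Geometric` with mean 9
trials, matching the reported mean of ≈ 9 trials (SD ≈ 10).

MW states are realised as contiguous episodes ending on the pre-probe
trial. A cue-triggered episode starts on the trial **after** its cue:
the trial showing the cue is the epoching baseline (position 0), so
dilation must not leak into it. Episodes never cross the preceding
probe — a probe interrupts the task and, in this model, resets the
attentional stream. Probe reports are then *derived* from the latent
trace, never sampled separately, so reports and states cannot disagree;
`derive_reports()` is exposed and the test suite checks it is the
identity on generated sessions.

Intentional-MW episodes never carry a cue trigger (the emulated analyses
only attribute triggers to spontaneous MW). Episode duration is a
consequence of the lag draw rather than an independently asserted
distribution, because the emulated study does not report durations; the
lag parameter is exposed for users who want different dynamics.

## The pupil signal model

The continuous signal for one session is

```
diameter(t) = baseline
            - bar_amp  * sum_trials  k(t - trial_onset)
            - word_amp * sum_cues    k(t - cue_onset)
            + sum_episodes dilation_amplitude * ramp(t)
            + AR(1) noise (shared across eyes)
            + white noise (independent per eye)
```

with `k` the gamma-family pupillary impulse response parameterised by its
peak: `k(t) = (t/tmax)^n exp(n (1 - t/tmax))`, defaults `n = 10.1`,
`tmax = 0.93` s — the standard pupillometry response kernel. `k(0) = 0`
and `k(tmax) = 1`, so amplitudes are in mm of peak constriction. Words
constrict more than bars (defaults 0.35 vs 0.10 mm) because the bright
text adds luminance; that asymmetry is what makes cue trials visually
distinctive in the traces.

The MW dilation is a linear ramp over `mw_ramp_s` (default 2 s, one
trial) from episode onset, a plateau at `dilation_amplitude` (default
0.1 mm) until episode offset, and a symmetric release. The ramp shape is
motivated by the monotone divergence of trigger versus control traces
over the two trials after the cue; with the default ramp the programmed
amplitude is fully expressed from position 2 onwards, which the
noise-free recovery test exploits.

Noise defaults — AR(1) with coefficient 0.85 at the 30 Hz step and
marginal SD 0.15 mm, plus 0.05 mm per-eye white noise — give trial-level
summary noise around 0.1 mm, a realistic magnitude for task-state pupil
fluctuations. Blinks (12/min, 0.2 s) invalidate samples and leave
artifactually low readings on their flanking samples (half-occluded
pupil); longer tracking dropouts (2/min, exponential mean 1.2 s)
invalidate runs outright. With these defaults about 3–4% of trials fail
the 60% signal-loss rule, the order of the ≈ 4.5% exclusion rate of the
emulated recordings.

All randomness flows from one master seed; per-subject, per-component
streams are derived as `master * 8191 + subject * 16 + component`
(mod 2^31 − 1), so any subject regenerates in isolation and cohorts are
byte-reproducible.

## Preprocessing

Within each 2-s trial, the two eyes are averaged sample-by-sample over
the valid eyes (a sample is lost only when both eyes are invalid).
Artifact rejection masks samples strictly outside the central 90%
interval of the trial's tracker-valid samples — below the 5th or above
the 95th within-trial percentile (linear-interpolation percentile,
boundary values kept). "Outside the 90th percentile of each trial" is
ambiguous between a one-sided and a central reading; the central
interval is the default because blink artifacts produce both low
(occlusion) and high (recovery overshoot) outliers, and `upper_90` is
available as an option. Percentile thresholds are always computed from
the tracker-valid samples, which makes the masking rule idempotent.

Retained samples are linearly interpolated onto a fixed 20 Hz grid of 40
bin centers (`0.025 + k * 0.05` s). Grid points that fall just beyond
the outermost retained samples — as the first and last bin centers
always do relative to 30 Hz sampling — are extrapolated linearly from
the adjacent segment (limited to one raw sample period), so a noiseless
linear signal is reconstructed exactly; larger edge gaps left by masking
are filled with the nearest retained value. Trials are never
interpolated across; each 2-s trial is an independent unit.

A trial is excluded when strictly more than 60% of its 60 raw
time-points are lost (invalid or masked). The rule is deliberately
permissive: a trial containing a short blink survives, which is the
stated intent of the emulated procedure.

## Epoching and labelling

Cue occurrences are partitioned into four labels: `mw_trigger` (named by
a later probe as the trigger of a spontaneous MW episode),
`emotional_nontrigger` (positive/negative cue, not a trigger, whose
nearest following probe reports on-task), `control` (neither a trigger
nor an emotional cue with an adjacent on-task probe), and `excluded`
(everything else, e.g. triggers of intentional MW). "Followed/preceded
by an on-task period" is operationalised as the nearest following or
preceding probe reporting on-task — the minimal reading of an undefined
window. Trigger status takes precedence when a cue could qualify for
more than one class.

Cue-aligned epochs span trial offsets 0, 1, 2 after the cue; the
baseline is the mean diameter over all 40 grid points of trial 0, and
the per-position summary is the mean baseline-corrected diameter over
the trial's **last** second (grid points 20–39, farthest from the
reference). Epochs are kept only when all three trials are recorded and
non-excluded. Probe-aligned epochs span the three trials before a probe
(positions 3, 2, 1; 1 is the last trial before the probe, which is also
the baseline trial), with summaries over each trial's **first** second
(grid points 0–19). Conditions are MW (spontaneous only), OT, and
"other" (including intentional MW). The cue trial itself (position 0)
enters the model data: the residual-df arithmetic of the emulated
analysis — (194 + 215 + 7391) × 3 − 6 = 23394 — only works if three
positions per epoch are modelled.

Light responses use within-trial windows: baseline is the first 250 ms
(grid points 0–4), constriction is the mean over [0.5, 1.0) s (grid
points 10–19), where the bar-evoked constriction peaks. Candidate trials
are dropped when the trial or its predecessor carries a cue-word, whose
large constriction would shift the baseline. All windows are half-open
index ranges on the 20 Hz grid.

## Inference

The mixed model is `value ~ condition * position + (1 | subject)` with
`position` a **continuous** covariate. Both choices are forced by the
printed df of the emulated analyses: a categorical position would give 4
interaction df with 3 conditions, and only `N − 6` residual df matches
the denominator. Fitting is by profiled maximum likelihood, exploiting
the single-random-intercept structure: for a fixed variance ratio
`lambda = sigma2_u / sigma2_e` the per-subject marginal covariance is
`sigma2_e (I + lambda J)`, whose inverse and determinant are closed-form
(Sherman–Morrison), so coefficients come from closed-form GLS, `sigma2_e`
is profiled out, and a one-dimensional optimisation over `log(lambda)`
(with an explicit boundary check at `lambda = 0`) finishes the fit. The
test suite verifies agreement with `lme4::lmer` (ML) to 1e-6 in
coefficients and log-likelihood on random datasets. ML is the default
(REML available); with the residual-df F convention below, the
`lambda = 0` limit reproduces ordinary least squares exactly.

F tests use the residual-df convention: `df2 = N − p` with `p` the
number of fixed-effect columns, and the coefficient covariance scaled by
`RSS_gls / (N − p)`. This, not Satterthwaite or Kenward–Roger, is what
reproduces every printed df pair from the published group sizes,
including all post-hoc dfs (two-condition, single-position refits with
`df2 = n − 2`). No multiple-testing correction is applied, matching the
emulated reporting of raw post-hoc p values. Split-half reliability
re-runs the identical analysis on odd and even epochs (parity of the
epoch ordinal within subject).

The light-response comparison uses the pooled-variance two-sample t and
a default-prior (JZS) Bayes factor: a Cauchy prior with scale
`r = sqrt(2)/2` on the standardised effect, integrated over the
effect-variance hyperparameter `g ~ InverseGamma(1/2, r^2/2)` by
adaptive quadrature with the null likelihood factored out of the
integrand (so the integral is O(1) at any `t` and `n`). The exact method
behind the published Bayes factors is not documented in the source
text, so those values (0.089 and 0.043) are soft references; the
two-sample JZS default reproduces both to within a few percent, and the
implementation is verified against an independent fixed-grid quadrature
oracle to 1e-6 relative error. `BF10 * BF01 = 1` holds by construction.

## Monte-Carlo calibration and problem sizes

The statistical machinery is calibrated on a summary-level simulator
(`simulate_epoch_summaries`) that generates the epoch-summary tables the
model consumes directly — per-subject intercepts, per-condition position
slopes, i.i.d. residuals. The programmed 0.1 mm dilation corresponds to
a trigger-slope of 0.05 mm/position over positions 0–2. At the
published group sizes (194/215/7391 epochs, 42 subjects) the suite
checks: median slope-contrast recovery within ±10% over 200 cohorts,
interaction power ≥ 80% at α = 0.05, and a type-I rate within
[0.03, 0.07] over 2000 reduced-size null replicates (8 subjects,
30/30/120 epochs). Raw-trace fidelity is covered separately by exact
noise-free recovery tests through the full pipeline; generating 200 full
30 Hz cohorts for the same check would add nothing but runtime, so the
two concerns are deliberately split.

The bundled `analysis/` scripts run a 12-subject demonstration cohort;
the acceptance script (`scripts/acceptance.R`) runs the full 42-subject
design. At 12 subjects the cue-aligned interaction is reliably detected
but the probe-aligned interaction often is not — at a third of the
design's sample size that analysis is underpowered, which is itself a
faithful property of the design.

## What the generator does and does not emulate

It emulates: the fixed task structure and its exact counts; the report
mixture and its cue-trigger statistics; stimulus-evoked constrictions
with a realistic impulse response; sustained MW-linked dilation; shared
binocular signal with independent per-eye noise; blinks, dropouts and
the resulting trial-exclusion rate.

It does not emulate: luminance/photometric detail of the display, gaze
position or foreshortening artifacts, word-specific semantic or
emotional effects on the pupil (valence labels are exchangeable),
serial autocorrelation of attentional states beyond single episodes,
meta-awareness, or individual differences beyond a random intercept.
Passing tests therefore demonstrate that the pipeline measures what the
generative model injects, at realistic noise levels and sample sizes —
not that real recordings contain such effects.

## Known limitations

* The profiled-likelihood fitter supports exactly one random-intercept
  grouping factor; random slopes or crossed factors are out of scope
  (and unused by the emulated analyses).
* The percentile artifact rule is a per-trial filter; it does not
  attempt blink reconstruction, and extreme slow drifts within a trial
  can survive it.
* Usable-trace counts in the light-response analyses depend on the QC
  and cue-adjacency rules; published trace counts for those analyses
  imply additional unstated inclusion rules, so this implementation
  documents its own counts rather than chasing those.
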