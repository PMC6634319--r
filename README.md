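# pupilmw

Simulation and analysis of event-locked pupillometry for **cue-triggered
mind wandering (MW)** in a probe-caught vigilance task.

In this paradigm a participant watches 1120 two-second trials of white
bars (pressing a key for rare vertical-bar targets) while task-irrelevant
cue-words appear on 210 trials; at 28 fixed points a thought-probe asks
what they were thinking just before, and whether a specific cue-word
triggered the thought. Pupil diameter, recorded binocularly at 30 Hz in
mm, serves as a covert index of MW: the pupil dilates after cue-words
later reported as MW triggers, while the pupillary light reflex to the
bar stimuli is unchanged — evidence against perceptual decoupling for
simple stimuli.

`pupilmw` provides the full pipeline as a tested R package:

* **Synthetic cohorts** — task schedules honouring the exact design
  counts, latent attentional states with cue-triggered MW episodes,
  probe reports derived deterministically from those states, 30 Hz
  binocular pupil traces (gamma-kernel light reflexes, ramp-and-plateau
  MW dilation, AR(1) noise, blinks, dropout), and behavioural logs.
* **Preprocessing** — per-trial central-90% percentile artifact
  rejection, interpolation to a 40-point 20 Hz grid, strict >60%
  signal-loss exclusion.
* **Event-locked epoching** — cue-aligned (positions 0/1/2 after the
  cue, baseline = cue trial), probe-aligned (positions 3/2/1 before the
  probe, baseline = last pre-probe trial), and within-trial light
  responses (constriction over [0.5, 1.0) s relative to the first
  250 ms), with the cue-trigger/emotional/control labelling scheme and
  its selection rules.
* **Inference** — random-intercept linear mixed models fitted by
  profiled maximum likelihood,

  `value ~ condition * position + (1 | subject)`,

  with position a continuous covariate, ANOVA-style F tests on residual
  df (`df2 = N − p`), two-condition single-position post-hocs
  (`df2 = n − 2`), odd/even split-half re-analysis, pooled two-sample
  t tests, and default-prior (JZS, Cauchy scale `r = √2/2`) Bayes
  factors computed by adaptive quadrature.

## Worked example

The `analysis/` directory holds the numbered pipeline drivers:

```sh
Rscript analysis/01_simulate.R    # 12-subject synthetic cohort -> results/data/
Rscript analysis/02_preprocess.R  # clean.csv, qc.json
Rscript analysis/03_epoch.R       # epochs_cue.csv, epochs_probe.csv, light_responses.csv
Rscript analysis/04_analyze.R     # results.json, results.csv
Rscript analysis/05_report.R      # traces_*.csv and figures
```

A run of stages 1–4 prints, among other things:

```
  schedule: 1120 trials, 68 targets, 210 cue-words, 28 probes
  spontaneous MW cue-triggered: 53.6%
  excluded trials: 3.28% (per-subject range 2.32-4.11%)
Cue labels: control 1707, emotional_nontrigger 468, excluded 286, mw_trigger 59
== Cue-aligned analysis ==
  interaction (cue type x trials from cue): F(2,6189) = 7.479, p = 0.00057
  post-hoc emotional_nontrigger vs mw_trigger         pos 2: F(1,492) = 35.496, p = 0.00000
== Light responses ==
  target vs nontarget: t(1144) = 0.658, p = 0.511, BF10 = 0.083
```

Reading this: the generator reproduced the task design exactly; about
3% of trials were dropped for signal loss; the cue-type × time
interaction is significant because pupil diameter keeps rising after
MW-trigger cues (the programmed 0.1 mm dilation) but not after matched
emotional or control cues; and the light reflex does not differ between
target and non-target trials — the Bayes factor of 0.083 is strong
evidence for the null. At 12 subjects the probe-aligned interaction is
typically not significant; the full 42-subject design (used by the
acceptance script) detects it.

The same machinery is available programmatically:

```r
library(pupilmw)
cohort <- generate_cohort(n_subjects = 6, seed = 1)
prep   <- preprocess_cohort(cohort_table(cohort, "samples"))
labels <- classify_cues(cohort_table(cohort, "schedule"),
                        cohort_table(cohort, "reports"))
cue    <- epoch_cue_aligned(prep$clean, labels)
analyze_cue(cue$summaries)$interaction
```

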