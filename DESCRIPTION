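Package: pupilmw
Title: Pupillometry of Cue-Triggered Mind Wandering in a Vigilance Task
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for event-locked pupillometry
    of mind wandering (MW) in a probe-caught vigilance task with
    task-irrelevant verbal cues. Generates synthetic sessions (trial
    schedules with targets, valenced cue-words and thought-probes; latent
    attentional states; 30 Hz binocular pupil recordings in mm with
    stimulus-evoked constrictions, MW-linked dilation, blinks and dropout),
    preprocesses raw traces (within-trial percentile artifact rejection,
    20 Hz linear interpolation, signal-loss exclusion), builds cue-aligned,
    probe-aligned and light-response epochs with baseline correction, and
    fits random-intercept linear mixed models by profiled maximum
    likelihood with residual-df F tests, post-hoc contrasts, split-half
    reliability, pooled two-sample t tests and default-prior (JZS) Bayes
    factors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    readr,
    jsonlite,
    ggplot2,
    rlang,
    withr,
    stats,
    utils,
    tools
Suggests:
    lme4,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
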