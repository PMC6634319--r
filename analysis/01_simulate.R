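#!/usr/bin/env Rscript

# Stage 1: simulate a synthetic cohort for the vigilance-task MW paradigm.
#
# Generates per-subject session schedules (1120 2-s trials, 68 vertical-bar
# targets, 210 valenced cue-words, 28 thought-probes with mean gap 40
# trials), latent attentional states with cue-triggered MW episodes, 30 Hz
# binocular pupil recordings and behavioural logs, then writes the tidy
# CSV tables consumed by the later stages.
#
# A 12-subject cohort keeps this demonstration run light; the package
# functions scale to the 42-subject design used in the acceptance script.

suppressPackageStartupMessages(library(pupilmw))

seed <- 2018L
n_subjects <- 12L
out_dir <- "results/data"

message("Simulating ", n_subjects, " subjects (seed ", seed, ") ...")
cohort <- generate_cohort(n_subjects, seed = seed)

# design fidelity of the first subject's schedule
sch <- cohort$sessions[[1]]$schedule
invisible(validate_schedule(sch))
tr <- sch$trials
message(sprintf("  schedule: %d trials, %d targets, %d cue-words, %d probes",
                nrow(tr), sum(tr$stimulus == "V"), sum(!is.na(tr$word_id)),
                sum(tr$probe_after)))

reports <- cohort_table(cohort, "reports")
mix <- table(reports$category) / n_subjects
message("  mean reports/subject by category:")
for (k in names(mix)) message(sprintf("    %-22s %5.2f", k, mix[[k]]))

spont <- reports[reports$category == "mw_spontaneous", ]
message(sprintf("  spontaneous MW cue-triggered: %.1f%%",
                100 * mean(spont$trigger_type == "cue_word")))

write_cohort_csv(cohort, out_dir)
message("Wrote schedule/samples/reports/behaviour CSVs to ", out_dir)
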