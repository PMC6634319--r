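#!/usr/bin/env Rscript

# Stage 3: build the three event-locked data sets.
#
# (a) cue-aligned epochs (positions 0/1/2 after each labelled cue-word,
#     baseline = the cue trial, summaries over each trial's last second);
# (b) probe-aligned epochs (positions 3/2/1 before each probe, baseline =
#     the last pre-probe trial, summaries over each trial's first second);
# (c) within-trial light responses (constriction over [0.5,1.0) s relative
#     to the first 250 ms), for MW-vs-OT pre-probe trials and for
#     target-vs-nontarget trials, excluding cue-adjacent trials;
# (d) the cue-placement confound check (4th trial before each probe).

suppressPackageStartupMessages(library(pupilmw))

in_dir <- "results/data"
out_dir <- "results"

tabs <- read_cohort_csv(in_dir)
clean <- readr::read_csv(file.path(out_dir, "clean.csv"),
                         col_types = "ciidnl", progress = FALSE)

labels <- classify_cues(tabs$schedule, tabs$reports)
message("Cue labels: ", paste(names(table(labels$label)),
                              table(labels$label), collapse = ", "))

cue <- epoch_cue_aligned(clean, labels)
message(sprintf("Cue-aligned epochs: %d kept, %d dropped by the 2-trial rule",
                length(unique(cue$summaries$reference_id)), cue$n_dropped))
readr::write_csv(cue$summaries, file.path(out_dir, "epochs_cue.csv"))
readr::write_csv(cue$epochs, file.path(out_dir, "epochs_cue_traces.csv"))

probe <- epoch_probe_aligned(clean, tabs$reports)
message(sprintf("Probe-aligned epochs: %d kept, %d dropped by the 3-trial rule",
                length(unique(probe$summaries$reference_id)),
                probe$n_dropped))
readr::write_csv(probe$summaries, file.path(out_dir, "epochs_probe.csv"))
readr::write_csv(probe$epochs, file.path(out_dir, "epochs_probe_traces.csv"))

lr <- extract_light_responses(clean, tabs$schedule, tabs$reports, "mw_vs_ot")
lrt <- extract_light_responses(clean, tabs$schedule, tabs$reports,
                               "target_vs_nontarget")
readr::write_csv(rbind(lr, lrt), file.path(out_dir, "light_responses.csv"))
message(sprintf("Light responses: MW %d / OT %d; target %d / nontarget %d",
                sum(lr$group == "MW"), sum(lr$group == "OT"),
                sum(lrt$group == "target"), sum(lrt$group == "nontarget")))

cp <- cue_placement_check(tabs$schedule, tabs$reports)
jsonlite::write_json(cp$overall, file.path(out_dir, "cue_placement.json"),
                     auto_unbox = TRUE, digits = NA)
message("Cue on 4th trial before probe (%):")
for (i in seq_len(nrow(cp$overall)))
  message(sprintf("  %-6s %.2f +/- %.2f", cp$overall$category[i],
                  cp$overall$mean_pct[i], cp$overall$se_pct[i]))
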