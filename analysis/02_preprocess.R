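#!/usr/bin/env Rscript

# Stage 2: clean the raw 30 Hz recordings.
#
# Per trial: average the valid eyes, mask samples outside the central 90%
# within-trial percentile interval, interpolate the retained samples onto
# the 40-point 20 Hz grid, and exclude trials losing more than 60% of
# their raw time-points. Writes clean.csv and qc.json.

suppressPackageStartupMessages(library(pupilmw))

in_dir <- "results/data"
out_dir <- "results"

tabs <- read_cohort_csv(in_dir)
message("Preprocessing ", length(unique(tabs$samples$subject_id)),
        " subjects ...")
prep <- preprocess_cohort(tabs$samples)

message(sprintf("  excluded trials: %.2f%% (per-subject range %.2f-%.2f%%)",
                100 * mean(prep$qc$excluded),
                100 * min(prep$summary$excluded_fraction),
                100 * max(prep$summary$excluded_fraction)))

readr::write_csv(prep$clean, file.path(out_dir, "clean.csv"))
jsonlite::write_json(
  list(per_subject = prep$summary,
       overall_excluded_fraction = mean(prep$qc$excluded)),
  file.path(out_dir, "qc.json"), auto_unbox = TRUE, digits = NA)
message("Wrote clean.csv and qc.json to ", out_dir)
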