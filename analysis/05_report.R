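#!/usr/bin/env Rscript

# Stage 5: trace report tables and figures.
#
# Per-condition mean +/- s.e. of the baseline-corrected traces across
# epochs, for the cue-aligned and probe-aligned data sets, exported as CSV
# and (when an SVG device is available) as figures.

suppressPackageStartupMessages(library(pupilmw))

out_dir <- "results"
cue_tr <- readr::read_csv(file.path(out_dir, "epochs_cue_traces.csv"),
                          col_types = "cccdin", progress = FALSE)
probe_tr <- readr::read_csv(file.path(out_dir, "epochs_probe_traces.csv"),
                            col_types = "cccdin", progress = FALSE)

cue_rep <- make_trace_report(cue_tr)
probe_rep <- make_trace_report(probe_tr)
readr::write_csv(cue_rep, file.path(out_dir, "traces_cue.csv"))
readr::write_csv(probe_rep, file.path(out_dir, "traces_probe.csv"))

# headline numbers a reader should see in the tables
for (pos in c(1, 2)) {
  mw <- mean(cue_rep$mean_mm[cue_rep$condition == "mw_trigger" &
                               cue_rep$position == pos])
  ct <- mean(cue_rep$mean_mm[cue_rep$condition == "control" &
                               cue_rep$position == pos])
  message(sprintf(
    "cue-aligned position %d: MW-trigger mean %+.4f mm, control %+.4f mm",
    pos, mw, ct))
}

if (capabilities("cairo")) {
  fig_dir <- file.path(out_dir, "figures")
  dir.create(fig_dir, showWarnings = FALSE)
  svg(file.path(fig_dir, "traces_cue.svg"), width = 8, height = 5)
  print(plot_trace_report(cue_rep, "Cue-aligned pupil traces"))
  dev.off()
  svg(file.path(fig_dir, "traces_probe.svg"), width = 8, height = 5)
  print(plot_trace_report(probe_rep, "Probe-aligned pupil traces"))
  dev.off()
  message("Wrote figures to ", fig_dir)
} else {
  message("No cairo SVG device available; skipped figure rendering")
}
message("Wrote traces_cue.csv and traces_probe.csv to ", out_dir)
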