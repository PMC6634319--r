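#!/usr/bin/env Rscript

# Stage 4: inference.
#
# Random-intercept linear mixed models fitted by profiled ML, interaction
# F tests on residual df, two-condition single-position post-hocs,
# odd/even split-half re-analysis, and for the light responses a pooled
# two-sample t test with a default-prior (JZS) Bayes factor.

suppressPackageStartupMessages(library(pupilmw))

out_dir <- "results"
cue_sum <- readr::read_csv(file.path(out_dir, "epochs_cue.csv"),
                           col_types = "cccdn", progress = FALSE)
probe_sum <- readr::read_csv(file.path(out_dir, "epochs_probe.csv"),
                             col_types = "cccdn", progress = FALSE)
light <- readr::read_csv(file.path(out_dir, "light_responses.csv"),
                         col_types = "cicn", progress = FALSE)

fmt_f <- function(x) sprintf("F(%d,%d) = %.3f, p = %.5f", x$df1, x$df2,
                             x$F, x$p)

message("== Cue-aligned analysis ==")
cue_res <- analyze_cue(cue_sum)
message("  interaction (cue type x trials from cue): ",
        fmt_f(cue_res$interaction))
for (i in seq_len(nrow(cue_res$posthoc)))
  message(sprintf("  post-hoc %-42s pos %d: %s",
                  cue_res$posthoc$term[i], cue_res$posthoc$position[i],
                  fmt_f(cue_res$posthoc[i, ])))
message("  split-half interaction: odd ", fmt_f(cue_res$split_half$odd$interaction),
        "; even ", fmt_f(cue_res$split_half$even$interaction))

message("== Probe-aligned analysis ==")
probe_res <- analyze_probe(probe_sum)
message("  interaction (report type x trials before probe): ",
        fmt_f(probe_res$interaction))
if (!is.null(probe_res$posthoc))
  message("  MW vs OT at position 3: ", fmt_f(probe_res$posthoc))

message("== Light responses ==")
mwot <- analyze_light(light[light$group %in% c("MW", "OT"), ], "MW", "OT")
message(sprintf("  MW vs OT: t(%d) = %.3f, p = %.3f, BF10 = %.3f",
                mwot$t_test$df, mwot$t_test$t, mwot$t_test$p,
                mwot$bayes$BF10))
tnt <- analyze_light(light[light$group %in% c("target", "nontarget"), ],
                     "target", "nontarget")
message(sprintf("  target vs nontarget: t(%d) = %.3f, p = %.3f, BF10 = %.3f",
                tnt$t_test$df, tnt$t_test$t, tnt$t_test$p, tnt$bayes$BF10))

results <- list(cue = cue_res, probe = probe_res, light_mw_ot = mwot,
                light_target = tnt)
jsonlite::write_json(pupilmw:::results_to_json(results),
                     file.path(out_dir, "results.json"),
                     auto_unbox = TRUE, digits = NA)

flat <- rbind(
  cbind(analysis = "cue_interaction", cue_res$interaction[, -1]),
  cbind(analysis = paste0("cue_posthoc_", cue_res$posthoc$term, "_pos",
                          cue_res$posthoc$position),
        cue_res$posthoc[, c("F", "df1", "df2", "p")]),
  cbind(analysis = "probe_interaction", probe_res$interaction[, -1]))
readr::write_csv(flat, file.path(out_dir, "results.csv"))
message("Wrote results.json and results.csv to ", out_dir)
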