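#' Assemble a pipeline run configuration
#'
#' @param seed master seed for the run.
#' @param n_subjects cohort size.
#' @param design,states,pupil,behaviour generator parameter lists.
#' @param artifact_rule preprocessing artifact rule.
#' @param analyses character subset of
#'   `c("cue", "probe", "light", "target")`.
#' @param out_dir output directory (`NULL` for in-memory only).
#' @return a list of class `"mw_run_config"`.
#' @export
run_config <- function(seed = 1L, n_subjects = 42L,
                       design = design_params(), states = state_params(),
                       pupil = pupil_params(),
                       behaviour = behaviour_params(),
                       artifact_rule = "central_90",
                       analyses = c("cue", "probe", "light", "target"),
                       out_dir = NULL) {
  structure(list(seed = seed, n_subjects = n_subjects, design = design,
                 states = states, pupil = pupil, behaviour = behaviour,
                 artifact_rule = artifact_rule, analyses = analyses,
                 out_dir = out_dir), class = "mw_run_config")
}

#' Run the full simulate-preprocess-epoch-analyze pipeline
#'
#' Stages run in order; any stage error halts the run naming the stage.
#' When `config$out_dir` is set, every table is written as CSV, results as
#' JSON, the configuration is archived verbatim alongside the outputs, and
#' the manifest lists each file with its MD5 digest; re-running the same
#' configuration reproduces the digests exactly.
#'
#' @param config an [run_config()] list.
#' @return list: `cohort_tables`, `clean`, `qc`, `epochs`, `results`,
#'   `manifest` (tibble of files + digests when writing, else `NULL`),
#'   `skipped` (named reasons for skipped analyses).
#' @export
run_pipeline <- function(config = run_config()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  skipped <- list()

  cohort <- stage("simulate", generate_cohort(
    config$n_subjects, config$seed, config$design, config$states,
    config$pupil, config$behaviour))
  tables <- list(schedule = cohort_table(cohort, "schedule"),
                 samples = cohort_table(cohort, "samples"),
                 reports = cohort_table(cohort, "reports"),
                 behaviour = cohort_table(cohort, "behaviour"))

  prep <- stage("preprocess",
                preprocess_cohort(tables$samples, rule = config$artifact_rule))

  epochs <- list()
  results <- list()
  two_subjects <- config$n_subjects >= 2L

  if ("cue" %in% config$analyses) {
    labels <- stage("epoch", classify_cues(tables$schedule, tables$reports))
    cue <- stage("epoch", epoch_cue_aligned(prep$clean, labels))
    epochs$cue <- cue
    epochs$cue_labels <- labels
    if (two_subjects && length(unique(cue$summaries$condition)) >= 2L) {
      results$cue <- stage("analyze", analyze_cue(cue$summaries))
    } else skipped$cue <- "needs >= 2 subjects and >= 2 cue conditions"
  }
  if ("probe" %in% config$analyses) {
    probe <- stage("epoch", epoch_probe_aligned(prep$clean, tables$reports))
    epochs$probe <- probe
    if (two_subjects && length(unique(probe$summaries$condition)) >= 2L) {
      results$probe <- stage("analyze", analyze_probe(probe$summaries))
    } else skipped$probe <- "needs >= 2 subjects and >= 2 report conditions"
    results$cue_placement <- stage("analyze", cue_placement_check(
      tables$schedule, tables$reports))
  }
  if ("light" %in% config$analyses) {
    lr <- stage("epoch", extract_light_responses(
      prep$clean, tables$schedule, tables$reports, mode = "mw_vs_ot"))
    epochs$light_mw_ot <- lr
    results$light_mw_ot <- stage("analyze", analyze_light(lr, "MW", "OT"))
  }
  if ("target" %in% config$analyses) {
    lr <- stage("epoch", extract_light_responses(
      prep$clean, tables$schedule, tables$reports,
      mode = "target_vs_nontarget"))
    epochs$light_target <- lr
    results$light_target <- stage("analyze",
                                  analyze_light(lr, "target", "nontarget"))
  }

  manifest <- NULL
  if (!is.null(config$out_dir)) {
    manifest <- stage("report", write_run_outputs(config, tables, prep,
                                                  epochs, results, skipped))
  }
  list(cohort_tables = tables, clean = prep$clean, qc = prep$qc,
       qc_summary = prep$summary, epochs = epochs, results = results,
       manifest = manifest, skipped = skipped)
}

#' Cue-aligned LMM analysis with post-hocs and split-half re-analysis
#'
#' @param summaries cue-aligned summary table.
#' @return list: `fit`, `interaction`, `posthoc` (tibble over condition
#'   pairs and positions 1, 2), `split_half`.
#' @export
analyze_cue <- function(summaries) {
  summaries$condition <- factor(summaries$condition,
                                levels = c("control", "emotional_nontrigger",
                                           "mw_trigger"))
  summaries$condition <- droplevels(summaries$condition)
  fit <- fit_lmm(summaries, value_mm ~ condition * position)
  ia <- anova_interaction(fit)
  pairs <- utils::combn(levels(summaries$condition), 2, simplify = FALSE)
  ph <- dplyr::bind_rows(lapply(pairs, function(pr)
    dplyr::bind_rows(lapply(c(1, 2), function(pos) {
      res <- posthoc_pairwise(summaries, pr, pos)
      res$position <- pos
      res
    }))))
  sh <- split_half(summaries)
  list(fit = fit, interaction = ia, posthoc = ph, split_half = sh)
}

#' Probe-aligned LMM analysis
#'
#' @param summaries probe-aligned summary table (positions 3, 2, 1).
#' @return list: `fit`, `interaction`, `posthoc` (MW vs OT at position 3).
#' @export
analyze_probe <- function(summaries) {
  summaries$condition <- factor(summaries$condition,
                                levels = c("other", "OT", "MW"))
  summaries$condition <- droplevels(summaries$condition)
  fit <- fit_lmm(summaries, value_mm ~ condition * position)
  ia <- anova_interaction(fit)
  ph <- if (all(c("MW", "OT") %in% levels(summaries$condition)))
    posthoc_pairwise(summaries, c("OT", "MW"), 3) else NULL
  list(fit = fit, interaction = ia, posthoc = ph)
}

#' Light-response group comparison: F test, pooled t, JZS Bayes factor
#'
#' @param light tibble from [extract_light_responses()].
#' @param g1,g2 group labels to compare.
#' @return list: `f_test`, `t_test`, `bayes`, `n1`, `n2`.
#' @export
analyze_light <- function(light, g1, g2) {
  x <- light$constriction_mm[light$group == g1]
  y <- light$constriction_mm[light$group == g2]
  if (length(x) < 2L || length(y) < 2L)
    return(list(f_test = NULL, t_test = NULL, bayes = NULL,
                n1 = length(x), n2 = length(y)))
  d <- tibble::tibble(
    subject_id = light$subject_id[light$group %in% c(g1, g2)],
    condition = factor(light$group[light$group %in% c(g1, g2)],
                       levels = c(g2, g1)),
    position = 0,
    value_mm = light$constriction_mm[light$group %in% c(g1, g2)])
  fit <- fit_lmm(d, value_mm ~ condition)
  ft <- block_f_test(fit, which(fit$assign == 1L), paste(g1, "vs", g2))
  tt <- two_sample_t(x, y)
  bf <- bayes_factor_t(tt$t, tt$n1, tt$n2)
  list(f_test = ft, t_test = tt, bayes = bf, n1 = length(x), n2 = length(y))
}

#' Per-condition mean and standard-error trace tables (and figures)
#'
#' Computes, for each condition and grid time, the mean and s.e. across
#' epochs of the baseline-corrected traces, mirroring trial-averaged trace
#' plots with s.e. bands. The s.e. is across epochs (trial-level); with a
#' single epoch it is reported as missing.
#'
#' @param epochs epoch tibble from [epoch_cue_aligned()] or
#'   [epoch_probe_aligned()] (`$epochs` element).
#' @param trial_dur_s trial duration (s).
#' @return tibble: `condition`, `position`, `grid_index`, `time_s`
#'   (position-anchored), `mean_mm`, `se_mm`, `n_epochs`.
#' @export
make_trace_report <- function(epochs, trial_dur_s = 2) {
  if (!nrow(epochs)) stop("input error: no epochs supplied")
  out <- dplyr::summarise(
    dplyr::group_by(epochs, .data$condition, .data$position,
                    .data$grid_index),
    mean_mm = mean(.data$value_mm),
    se_mm = ifelse(dplyr::n() > 1L,
                   stats::sd(.data$value_mm) / sqrt(dplyr::n()), NA_real_),
    n_epochs = dplyr::n(), .groups = "drop")
  out$time_s <- out$position * trial_dur_s +
    grid_times(trial_dur_s)[out$grid_index + 1L]
  out[order(out$condition, out$position, out$grid_index), ]
}

#' Plot a trace report
#'
#' @param trace tibble from [make_trace_report()].
#' @param title plot title.
#' @return a ggplot object.
#' @export
plot_trace_report <- function(trace, title = "Event-locked pupil traces") {
  ggplot2::ggplot(trace, ggplot2::aes(x = .data$time_s, y = .data$mean_mm,
                                      colour = .data$condition)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3, colour = "grey50") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_mm - .data$se_mm,
                                      ymax = .data$mean_mm + .data$se_mm,
                                      fill = .data$condition),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "time from reference event (s)",
                  y = "baseline-corrected pupil diameter (mm)",
                  title = title) +
    ggplot2::theme_minimal()
}

# serialize results (tibbles and fits) into plain lists for JSON
results_to_json <- function(results) {
  strip <- function(x) {
    if (inherits(x, "mw_lmm"))
      return(list(beta = as.list(x$beta), sigma2_u = x$sigma2_u,
                  sigma2_e = x$sigma2_e, loglik = x$loglik, n_obs = x$n_obs,
                  p_fixed = x$p_fixed))
    if (inherits(x, "mw_bf"))
      return(list(t = x$t, df = x$df, n1 = x$n1, n2 = x$n2, r = x$r,
                  BF10 = x$BF10, BF01 = x$BF01))
    if (is.data.frame(x)) return(x)
    if (is.list(x)) return(lapply(x, strip))
    x
  }
  strip(results)
}

write_run_outputs <- function(config, tables, prep, epochs, results,
                              skipped) {
  dir <- config$out_dir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(x, f) readr::write_csv(x, file.path(dir, f))
  wcsv(tables$schedule, "schedule.csv")
  wcsv(tables$samples, "samples.csv")
  wcsv(tables$reports, "reports.csv")
  wcsv(tables$behaviour, "behaviour.csv")
  wcsv(prep$clean, "clean.csv")
  jsonlite::write_json(
    list(per_subject = prep$summary,
         overall_excluded_fraction = mean(prep$qc$excluded)),
    file.path(dir, "qc.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(epochs$cue)) wcsv(epochs$cue$summaries, "epochs_cue.csv")
  if (!is.null(epochs$probe)) wcsv(epochs$probe$summaries, "epochs_probe.csv")
  if (!is.null(epochs$light_mw_ot))
    wcsv(epochs$light_mw_ot, "light_responses.csv")
  if (!is.null(results$cue_placement))
    jsonlite::write_json(results$cue_placement$overall,
                         file.path(dir, "cue_placement.json"),
                         auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(results_to_json(results),
                       file.path(dir, "results.json"),
                       auto_unbox = TRUE, digits = NA)
  cfg <- config
  cfg$out_dir <- NULL
  jsonlite::write_json(results_to_json(unclass(cfg)),
                       file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  if (length(skipped))
    jsonlite::write_json(skipped, file.path(dir, "skipped.json"),
                         auto_unbox = TRUE)
  files <- sort(list.files(dir, full.names = FALSE))
  tibble::tibble(file = files,
                 md5 = unname(tools::md5sum(file.path(dir, files))))
}
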