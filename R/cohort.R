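#' Generate a full synthetic cohort
#'
#' One session per subject: schedule, latent states + probe reports, raw
#' binocular pupil recording and behavioural log. Per-subject,
#' per-component seeds are derived deterministically from the master seed
#' (`master * 8191 + subject_index * 16 + component`, reduced mod 2^31-1),
#' so any subject can be regenerated in isolation.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param seed master integer seed.
#' @param design a [design_params()] list.
#' @param states a [state_params()] list.
#' @param pupil a [pupil_params()] list.
#' @param behaviour a [behaviour_params()] list.
#' @param generate_pupil set `FALSE` to skip the (comparatively expensive)
#'   raw trace generation when only schedules/reports are needed.
#' @return a list of class `"mw_cohort"`: `sessions` (named list; each has
#'   `schedule`, `latent`, `samples`, `behaviour`) plus the parameter lists
#'   and the master seed.
#' @export
generate_cohort <- function(n_subjects, seed = 1L,
                            design = design_params(),
                            states = state_params(),
                            pupil = pupil_params(),
                            behaviour = behaviour_params(),
                            generate_pupil = TRUE) {
  stopifnot(n_subjects >= 1)
  sub_seed <- function(i, component)
    (as.numeric(seed) * 8191 + i * 16 + component) %% 2147483647
  sessions <- lapply(seq_len(n_subjects), function(i) {
    sid <- sprintf("s%02d", i)
    sch <- generate_schedule(sub_seed(i, 1), design, subject_id = sid)
    lat <- generate_latent_states(sch, states, seed = sub_seed(i, 2))
    smp <- if (generate_pupil)
      generate_pupil_recording(sch, lat, pupil, seed = sub_seed(i, 3))
    else NULL
    beh <- generate_behaviour(sch, lat, behaviour, seed = sub_seed(i, 4))
    list(schedule = sch, latent = lat, samples = smp, behaviour = beh)
  })
  names(sessions) <- vapply(sessions, function(s) s$schedule$subject_id, "")
  structure(list(sessions = sessions, seed = seed, design = design,
                 states = states, pupil = pupil, behaviour = behaviour),
            class = "mw_cohort")
}

#' Bind a cohort's tables across subjects
#'
#' @param cohort an `"mw_cohort"`.
#' @param what one of "schedule", "samples", "reports", "behaviour".
#' @return a tibble with one row per (subject, unit).
#' @export
cohort_table <- function(cohort,
                         what = c("schedule", "samples", "reports",
                                  "behaviour")) {
  what <- match.arg(what)
  pick <- switch(what,
    schedule = function(s) s$schedule$trials,
    samples = function(s) s$samples,
    reports = function(s) s$latent$reports,
    behaviour = function(s) s$behaviour)
  dplyr::bind_rows(lapply(cohort$sessions, pick))
}

#' Write a cohort to tidy CSV files
#'
#' Writes `schedule.csv`, `samples.csv`, `reports.csv` and `behaviour.csv`
#' in the documented tidy formats.
#'
#' @param cohort an `"mw_cohort"`.
#' @param dir output directory (created if missing).
#' @return the directory path, invisibly.
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(cohort_table(cohort, "schedule"),
                   file.path(dir, "schedule.csv"))
  if (!is.null(cohort$sessions[[1]]$samples))
    readr::write_csv(cohort_table(cohort, "samples"),
                     file.path(dir, "samples.csv"))
  readr::write_csv(cohort_table(cohort, "reports"),
                   file.path(dir, "reports.csv"))
  readr::write_csv(cohort_table(cohort, "behaviour"),
                   file.path(dir, "behaviour.csv"))
  invisible(dir)
}

#' Read cohort tables back from CSV
#'
#' @param dir directory written by [write_cohort_csv()].
#' @return a named list of tibbles (`schedule`, `samples` if present,
#'   `reports`, `behaviour`).
#' @export
read_cohort_csv <- function(dir) {
  rd <- function(f, types) {
    p <- file.path(dir, f)
    if (file.exists(p)) readr::read_csv(p, col_types = types,
                                        progress = FALSE) else NULL
  }
  out <- list(
    schedule = rd("schedule.csv", "cicccci"),
    samples = rd("samples.csv", "cidcdi"),
    reports = rd("reports.csv", "ciicccc"),
    behaviour = rd("behaviour.csv", "cii"))
  out[!vapply(out, is.null, TRUE)]
}
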