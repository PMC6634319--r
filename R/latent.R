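#' Parameters of the latent attentional-state mixture
#'
#' Each probe's pre-probe attentional state is drawn from a categorical
#' mixture over the report taxonomy used in probe-caught MW studies:
#' on-task, spontaneous MW, intentional MW, external distraction,
#' task-related interference, and blank mind. Defaults reproduce the
#' per-subject report mix observed in this paradigm (about 7.36 on-task,
#' 9.57 spontaneous-MW and 2.10 intentional-MW reports out of 28 probes,
#' the remainder split evenly over the other three categories), with about
#' 53% of spontaneous MW episodes triggered by an on-screen cue-word and a
#' geometric trigger-to-probe lag with mean 9 trials.
#'
#' @param p_on_task,p_mw_spont,p_mw_int,p_distraction,p_task_related,p_blank
#'   mixture probabilities over probe categories; must lie in `[0, 1]` and
#'   sum to 1.
#' @param p_cue_trigger probability that a spontaneous MW episode is
#'   triggered by a cue-word (given one is available before the probe).
#' @param trigger_lag_mean mean of the trigger-to-probe lag in trials;
#'   lags are drawn as `1 + Geometric` with this mean.
#' @param p_other_trigger probabilities over non-cue triggers
#'   (own_thoughts, environment, none) for untriggered spontaneous MW.
#' @param dilation_mm MW-linked pupil dilation amplitude (mm) programmed
#'   into each episode.
#' @return a list of class `"mw_state_params"`.
#' @export
state_params <- function(p_on_task = 7.36 / 28,
                         p_mw_spont = 9.57 / 28,
                         p_mw_int = 2.10 / 28,
                         p_distraction = 2.99 / 28,
                         p_task_related = 2.99 / 28,
                         p_blank = 2.99 / 28,
                         p_cue_trigger = 212 / 402,
                         trigger_lag_mean = 9,
                         p_other_trigger = c(own_thoughts = 0.5,
                                             environment = 0.25, none = 0.25),
                         dilation_mm = 0.1) {
  p <- c(on_task = p_on_task, mw_spontaneous = p_mw_spont,
         mw_intentional = p_mw_int, external_distraction = p_distraction,
         task_related = p_task_related, blank = p_blank)
  if (any(p < 0 | p > 1) || abs(sum(p) - 1) > 1e-8)
    stop("parameter error: category probabilities must lie in [0,1] and sum to 1")
  if (p_cue_trigger < 0 || p_cue_trigger > 1)
    stop("parameter error: p_cue_trigger must lie in [0,1]")
  if (trigger_lag_mean < 1)
    stop("parameter error: trigger_lag_mean must be >= 1 trial")
  structure(list(p_category = p, p_cue_trigger = p_cue_trigger,
                 trigger_lag_mean = trigger_lag_mean,
                 p_other_trigger = p_other_trigger / sum(p_other_trigger),
                 dilation_mm = dilation_mm),
            class = "mw_state_params")
}

#' Generate latent attentional states and probe reports for one session
#'
#' For each thought-probe a pre-probe state is drawn from the category
#' mixture. MW states come with a contiguous episode ending on the
#' pre-probe trial: cue-triggered episodes start on the trial after the
#' named cue-word (chosen so the cue-to-probe lag follows the configured
#' lag distribution), other episodes start `lag` trials before the probe.
#' Episodes never cross the preceding probe. Probe reports are then derived
#' deterministically from the latent trace ([derive_reports()]), so the
#' report at each probe is consistent with the state of the trial
#' immediately before it.
#'
#' @param schedule an `"mw_schedule"` object.
#' @param params a [state_params()] list.
#' @param seed integer seed for this stream.
#' @return a list of class `"mw_latent"` with `state_per_trial` (character
#'   vector over trials), `episodes` (tibble: `episode_id`, `onset_trial`,
#'   `offset_trial`, `spontaneity`, `trigger_type`, `trigger_word_id`,
#'   `dilation_mm`) and `reports` (tibble, see [derive_reports()]).
#' @export
generate_latent_states <- function(schedule, params = state_params(),
                                   seed = 1L) {
  stopifnot(inherits(schedule, "mw_schedule"))
  rng <- local_rng(seed)
  n <- schedule$config$n_trials
  probes <- schedule$probe_after
  cue_trials <- schedule$trials$trial_index[!is.na(schedule$trials$word_id)]
  word_ids <- schedule$trials$word_id[!is.na(schedule$trials$word_id)]

  state <- rep("on_task", n)
  eps <- list()
  cats <- names(params$p_category)
  draw_lag <- function() 1L + stats::rgeom(1L, 1 / params$trigger_lag_mean)

  prev_probe <- -1L
  for (k in seq_along(probes)) {
    p <- probes[k] # pre-probe trial: probe shown immediately after it
    cat_k <- sample(cats, 1L, prob = params$p_category)
    if (cat_k %in% c("mw_spontaneous", "mw_intentional")) {
      spont <- cat_k == "mw_spontaneous"
      trig_type <- "none"
      trig_word <- NA_character_
      onset <- NA_integer_
      if (spont && stats::runif(1L) < params$p_cue_trigger) {
        cand <- which(cue_trials > prev_probe & cue_trials < p)
        if (length(cand)) {
          lag <- draw_lag()
          i <- cand[which.min(abs((p - cue_trials[cand]) - lag))]
          trig_type <- "cue_word"
          trig_word <- word_ids[i]
          onset <- cue_trials[i] + 1L # MW starts on the trial after the cue
        }
      }
      if (is.na(onset)) {
        if (spont) {
          trig_type <- sample(names(params$p_other_trigger), 1L,
                              prob = params$p_other_trigger)
        }
        onset <- max(prev_probe + 1L, p - draw_lag() + 1L)
      }
      onset <- min(onset, p)
      state[(onset:p) + 1L] <- cat_k
      eps[[length(eps) + 1L]] <- tibble::tibble(
        onset_trial = onset, offset_trial = p,
        spontaneity = if (spont) "spontaneous" else "deliberate",
        trigger_type = trig_type, trigger_word_id = trig_word,
        dilation_mm = params$dilation_mm)
    } else if (cat_k != "on_task") {
      state[p + 1L] <- cat_k
    }
    prev_probe <- p
  }

  episodes <- if (length(eps)) dplyr::bind_rows(eps) else tibble::tibble(
    onset_trial = integer(), offset_trial = integer(),
    spontaneity = character(), trigger_type = character(),
    trigger_word_id = character(), dilation_mm = numeric())
  episodes$episode_id <- seq_len(nrow(episodes))
  latent <- structure(list(subject_id = schedule$subject_id,
                           state_per_trial = state, episodes = episodes),
                      class = "mw_latent")
  latent$reports <- derive_reports(latent, schedule)
  latent
}

#' Derive probe reports from a latent state trace
#'
#' Reports are a pure function of the latent trace: the report category at
#' each probe is the state of the trial immediately before the probe; for
#' MW states, spontaneity and trigger are copied from the episode that
#' contains that trial.
#'
#' @param latent an `"mw_latent"` object (its `reports` element is ignored).
#' @param schedule the matching `"mw_schedule"`.
#' @return tibble with `subject_id`, `probe_index` (0-based), `probe_after`
#'   (pre-probe trial index), `category`, `spontaneity`, `trigger_type`,
#'   `trigger_word_id`.
#' @export
derive_reports <- function(latent, schedule) {
  probes <- schedule$probe_after
  state <- latent$state_per_trial
  eps <- latent$episodes
  out <- lapply(seq_along(probes), function(k) {
    p <- probes[k]
    cat_k <- state[p + 1L]
    spont <- "not_applicable"
    trig <- "none"
    trig_w <- NA_character_
    if (cat_k %in% c("mw_spontaneous", "mw_intentional")) {
      e <- eps[eps$onset_trial <= p & eps$offset_trial >= p, ]
      stopifnot(nrow(e) == 1L)
      spont <- e$spontaneity
      trig <- e$trigger_type
      trig_w <- e$trigger_word_id
    }
    tibble::tibble(subject_id = schedule$subject_id, probe_index = k - 1L,
                   probe_after = p, category = cat_k, spontaneity = spont,
                   trigger_type = trig, trigger_word_id = trig_w)
  })
  dplyr::bind_rows(out)
}

#' Validate a latent trace against its structural invariants
#'
#' Checks that every MW-labelled trial belongs to exactly one episode, that
#' episodes are contiguous runs with matching state labels, that
#' cue-triggered episodes start after their named cue, and that reports
#' match the pre-probe states.
#'
#' @param latent an `"mw_latent"` object.
#' @param schedule the matching `"mw_schedule"`.
#' @return `TRUE` invisibly, or an error.
#' @export
validate_latent <- function(latent, schedule) {
  state <- latent$state_per_trial
  eps <- latent$episodes
  fail <- function(msg) stop("latent invariant violated: ", msg)
  covered <- integer(0)
  cue_idx <- function(w) schedule$trials$trial_index[
    !is.na(schedule$trials$word_id) & schedule$trials$word_id == w]
  for (i in seq_len(nrow(eps))) {
    run <- eps$onset_trial[i]:eps$offset_trial[i]
    lab <- if (eps$spontaneity[i] == "spontaneous") "mw_spontaneous"
           else "mw_intentional"
    if (!all(state[run + 1L] == lab)) fail("episode/state label mismatch")
    if (any(run %in% covered)) fail("overlapping episodes")
    covered <- c(covered, run)
    if (eps$trigger_type[i] == "cue_word" &&
        cue_idx(eps$trigger_word_id[i]) > eps$onset_trial[i])
      fail("cue trigger after episode onset")
  }
  mw_trials <- which(state %in% c("mw_spontaneous", "mw_intentional")) - 1L
  if (!setequal(mw_trials, covered)) fail("MW trial outside any episode")
  rep2 <- derive_reports(latent, schedule)
  if (!identical(as.data.frame(rep2), as.data.frame(latent$reports)))
    fail("reports inconsistent with latent states")
  invisible(TRUE)
}
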