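#' Behavioural response parameters
#'
#' Near-ceiling vigilance performance: defaults give an expected 0.33
#' misses out of 68 targets and 0.79 false alarms over the non-target
#' trials per session.
#'
#' @param p_miss per-target probability of a miss.
#' @param p_false_alarm per-non-target-trial probability of a key press.
#' @return a list of class `"mw_behaviour_params"`.
#' @export
behaviour_params <- function(p_miss = 0.33 / 68,
                             p_false_alarm = 0.79 / 1052) {
  if (p_miss < 0 || p_miss > 1 || p_false_alarm < 0 || p_false_alarm > 1)
    stop("parameter error: miss/false-alarm probabilities must lie in [0,1]")
  structure(list(p_miss = p_miss, p_false_alarm = p_false_alarm),
            class = "mw_behaviour_params")
}

#' Generate the behavioural key-press log for one session
#'
#' @param schedule an `"mw_schedule"`.
#' @param latent matching `"mw_latent"` (accepted for interface symmetry;
#'   performance is near-ceiling regardless of attentional state).
#' @param params a [behaviour_params()] list.
#' @param seed integer seed.
#' @return tibble with `subject_id`, `trial_index`, `key_press` (0/1), and
#'   attributes-free derived columns via [summarise_behaviour()].
#' @export
generate_behaviour <- function(schedule, latent = NULL,
                               params = behaviour_params(), seed = 1L) {
  stopifnot(inherits(schedule, "mw_schedule"))
  rng <- local_rng(seed)
  tr <- schedule$trials
  is_target <- tr$stimulus == "V"
  press <- ifelse(is_target,
                  stats::runif(nrow(tr)) >= params$p_miss,
                  stats::runif(nrow(tr)) < params$p_false_alarm)
  tibble::tibble(subject_id = tr$subject_id, trial_index = tr$trial_index,
                 key_press = as.integer(press))
}

#' Summarise a behavioural log into miss and false-alarm counts
#'
#' Misses are targets without a key press; false alarms are key presses on
#' non-target trials.
#'
#' @param behaviour tibble from [generate_behaviour()].
#' @param schedule the matching `"mw_schedule"`.
#' @return one-row tibble: `subject_id`, `misses`, `false_alarms`.
#' @export
summarise_behaviour <- function(behaviour, schedule) {
  is_target <- schedule$trials$stimulus == "V"
  tibble::tibble(
    subject_id = schedule$subject_id,
    misses = sum(is_target & behaviour$key_press == 0L),
    false_alarms = sum(!is_target & behaviour$key_press == 1L))
}
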