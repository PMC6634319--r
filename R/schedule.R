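#' Design parameters for a vigilance-task session
#'
#' The session layout mirrors a probe-caught vigilance task with
#' task-irrelevant verbal cues: a long fixed sequence of 2-s trials showing
#' horizontal (non-target) or vertical (target) bars, a subset of trials
#' additionally carrying a valenced cue-word, and a fixed set of
#' thought-probe positions at which the task is interrupted.
#'
#' @param n_trials total number of trials in the session.
#' @param trial_dur_s trial duration in seconds.
#' @param n_targets number of vertical-bar (target) trials.
#' @param target_gap_min,target_gap_max allowed range (inclusive, in trials)
#'   for the gap between consecutive targets.
#' @param n_cues number of cue-word trials; must be divisible by 3 so that
#'   neutral/positive/negative valences can be balanced.
#' @param n_probes number of thought-probes.
#' @param probe_gap_mean target mean gap (in trials) between consecutive
#'   probes, enforced exactly by construction (`n_probes * probe_gap_mean`
#'   must equal `n_trials`).
#' @param probe_gap_sd spread of the probe gaps around the mean (approximate;
#'   the mean is exact, the SD is not enforced).
#' @param p_cue_before_probe probability of directly placing a cue-word on
#'   the 4th trial before a probe. The fixed sequences used in this
#'   paradigm place cues preferentially just ahead of probes, so that a
#'   cue is present at that position for roughly three quarters of probes;
#'   remaining cues are placed uniformly over non-target trials, and that
#'   background density brings the default's net probability to about
#'   0.75.
#' @return a list of class `"mw_design"`.
#' @export
design_params <- function(n_trials = 1120L,
                          trial_dur_s = 2,
                          n_targets = 68L,
                          target_gap_min = 9L,
                          target_gap_max = 31L,
                          n_cues = 210L,
                          n_probes = 28L,
                          probe_gap_mean = 40L,
                          probe_gap_sd = 7.5,
                          p_cue_before_probe = 0.70) {
  cfg <- list(
    n_trials = as.integer(n_trials), trial_dur_s = trial_dur_s,
    n_targets = as.integer(n_targets),
    target_gap_min = as.integer(target_gap_min),
    target_gap_max = as.integer(target_gap_max),
    n_cues = as.integer(n_cues), n_probes = as.integer(n_probes),
    probe_gap_mean = as.integer(probe_gap_mean), probe_gap_sd = probe_gap_sd,
    p_cue_before_probe = p_cue_before_probe
  )
  class(cfg) <- "mw_design"
  check_design(cfg)
  cfg
}

check_design <- function(cfg) {
  if (cfg$n_trials < 1L) stop("design error: n_trials must be positive")
  if (cfg$target_gap_min > cfg$target_gap_max)
    stop("design error: target_gap_min exceeds target_gap_max")
  # targets occupy positions first..last with n_targets-1 gaps >= gap_min;
  # last target must stay clear of the final trial (reserved for a probe)
  need <- (cfg$n_targets - 1L) * cfg$target_gap_min + 1L
  if (need > cfg$n_trials - 1L)
    stop(sprintf(
      "infeasible design: %d targets with minimum gap %d do not fit in %d trials",
      cfg$n_targets, cfg$target_gap_min, cfg$n_trials))
  if (cfg$n_cues %% 3L != 0L)
    stop("infeasible design: n_cues must be divisible by 3 for balanced valence")
  if (cfg$n_cues > cfg$n_trials - cfg$n_targets)
    stop("infeasible design: more cue-words than non-target trials")
  if (cfg$n_probes * cfg$probe_gap_mean != cfg$n_trials)
    stop(sprintf(
      "infeasible design: n_probes * probe_gap_mean (%d) must equal n_trials (%d) for an exact mean probe gap",
      cfg$n_probes * cfg$probe_gap_mean, cfg$n_trials))
  invisible(TRUE)
}

#' Generate one session schedule
#'
#' Produces the fixed trial sequence for one subject: target placement with
#' bounded inter-target gaps, balanced cue-word placement (never on target
#' trials), and thought-probe positions whose start-anchored gaps have an
#' exactly enforced mean. Probes never fall on target trials. Identical
#' `seed` and `config` give an identical schedule.
#'
#' @param seed integer seed for this session's schedule stream.
#' @param config an [design_params()] list.
#' @param subject_id subject identifier stored in the table.
#' @return a list of class `"mw_schedule"` with elements `subject_id`,
#'   `trials` (a tibble: `trial_index` 0-based, `stimulus` "H"/"V",
#'   `word_id`, `word_text`, `valence`, `probe_after`), `probe_after`
#'   (integer trial indices) and `config`.
#' @export
generate_schedule <- function(seed, config = design_params(),
                              subject_id = "s01") {
  check_design(config)
  rng <- local_rng(seed)
  n <- config$n_trials

  targets <- place_targets(config)
  probes <- place_probes(config, targets)
  cues <- place_cues(config, targets, probes)

  stimulus <- rep("H", n)
  stimulus[targets + 1L] <- "V"

  word_id <- rep(NA_character_, n)
  word_text <- rep(NA_character_, n)
  valence <- rep(NA_character_, n)
  ids <- sprintf("w%03d", seq_len(config$n_cues))
  val <- sample(rep(c("neu", "pos", "neg"), config$n_cues / 3L))
  word_id[cues + 1L] <- ids
  word_text[cues + 1L] <- sprintf("cue phrase %03d", seq_len(config$n_cues))
  valence[cues + 1L] <- val

  trials <- tibble::tibble(
    subject_id = subject_id,
    trial_index = 0:(n - 1L),
    stimulus = stimulus,
    word_id = word_id,
    word_text = word_text,
    valence = valence,
    probe_after = as.integer(0:(n - 1L) %in% probes)
  )
  structure(list(subject_id = subject_id, trials = trials,
                 probe_after = probes, config = config),
            class = "mw_schedule")
}

# Targets placed sequentially; each gap drawn uniformly from the currently
# feasible subrange of [gap_min, gap_max] so the full set always fits before
# the final trial (which is reserved for the last probe).
place_targets <- function(cfg) {
  gmin <- cfg$target_gap_min
  gmax <- cfg$target_gap_max
  last_allowed <- cfg$n_trials - 2L # keep final trial target-free
  pos <- integer(cfg$n_targets)
  prev <- -1L
  for (k in seq_len(cfg$n_targets)) {
    remaining <- cfg$n_targets - k
    hi <- min(gmax, last_allowed - prev - remaining * gmin)
    if (hi < gmin)
      stop("infeasible design: target gaps cannot satisfy [gap_min, gap_max]")
    gap <- if (hi == gmin) gmin else sample(gmin:hi, 1L)
    prev <- prev + gap
    pos[k] <- prev
  }
  pos
}

# Probe gaps ~ round(Normal(mean, sd)), clipped to a sane range, rescaled
# by unit steps so they sum exactly to n_trials, then probes sitting on a
# target trial are nudged by one trial (sum-preserving). Positions are the
# cumulative gap sums minus one, so the last probe follows the final trial
# and the start-anchored mean gap is exact.
place_probes <- function(cfg, targets) {
  m <- cfg$n_probes
  lo <- max(4L, cfg$probe_gap_mean - 3L * ceiling(cfg$probe_gap_sd))
  hi <- cfg$probe_gap_mean + 3L * ceiling(cfg$probe_gap_sd)
  gaps <- pmin(pmax(as.integer(round(
    stats::rnorm(m, cfg$probe_gap_mean, cfg$probe_gap_sd))), lo), hi)
  for (iter in seq_len(100000L)) {
    d <- cfg$n_trials - sum(gaps)
    if (d == 0L) break
    i <- sample.int(m, 1L)
    if (d > 0L && gaps[i] < hi) gaps[i] <- gaps[i] + 1L
    if (d < 0L && gaps[i] > lo) gaps[i] <- gaps[i] - 1L
  }
  if (sum(gaps) != cfg$n_trials)
    stop("infeasible design: probe gaps cannot reach the required exact mean")
  is_target <- logical(cfg$n_trials)
  is_target[targets + 1L] <- TRUE
  # shift any probe off a target trial: move the boundary between gap i and
  # gap i+1 by one trial, which preserves the total
  for (iter in seq_len(1000L)) {
    pos <- cumsum(gaps) - 1L
    bad <- which(is_target[pos + 1L])
    if (!length(bad)) break
    i <- bad[1L]
    if (i == m)
      stop("infeasible design: final trial is a target") # precluded upstream
    step <- sample(c(-1L, 1L), 1L)
    if (gaps[i] + step >= 2L && gaps[i + 1L] - step >= 2L) {
      gaps[i] <- gaps[i] + step
      gaps[i + 1L] <- gaps[i + 1L] - step
    }
    if (iter == 1000L)
      stop("infeasible design: could not place probes off target trials")
  }
  cumsum(gaps) - 1L
}

# Cues: preferentially on the 4th trial before each probe (the trial at
# probe_position - 3), then uniformly over the remaining non-target trials.
place_cues <- function(cfg, targets, probes) {
  is_target <- logical(cfg$n_trials)
  is_target[targets + 1L] <- TRUE
  pre4 <- probes - 3L
  pre4 <- pre4[pre4 >= 0L & !is_target[pre4 + 1L]]
  take <- pre4[stats::runif(length(pre4)) < cfg$p_cue_before_probe]
  take <- take[seq_len(min(length(take), cfg$n_cues))]
  pool <- setdiff(which(!is_target) - 1L, take)
  rest <- sample(pool, cfg$n_cues - length(take))
  sort(c(take, rest))
}

#' Validate a session schedule against its design invariants
#'
#' Checks trial count, target count and inter-target gap range, cue-word
#' count and valence balance, cue/target exclusivity, probe count, exact
#' mean probe gap, and that no probe falls on a target trial.
#'
#' @param schedule an `"mw_schedule"` object.
#' @return `TRUE` (invisibly); otherwise an error naming the violated
#'   invariant.
#' @export
validate_schedule <- function(schedule) {
  tr <- schedule$trials
  cfg <- schedule$config
  fail <- function(msg) stop("schedule invariant violated: ", msg)
  if (nrow(tr) != cfg$n_trials) fail("trial count")
  if (!identical(tr$trial_index, 0:(cfg$n_trials - 1L))) fail("trial indexing")
  tpos <- tr$trial_index[tr$stimulus == "V"]
  if (length(tpos) != cfg$n_targets) fail("target count")
  gaps <- diff(tpos)
  if (any(gaps < cfg$target_gap_min | gaps > cfg$target_gap_max))
    fail("inter-target gap range")
  cues <- tr[!is.na(tr$word_id), ]
  if (nrow(cues) != cfg$n_cues) fail("cue-word count")
  if (anyDuplicated(cues$word_id)) fail("word_id uniqueness")
  if (!all(table(cues$valence) == cfg$n_cues / 3L)) fail("valence balance")
  if (any(cues$stimulus == "V")) fail("cue-word on a target trial")
  probes <- tr$trial_index[tr$probe_after == 1L]
  if (length(probes) != cfg$n_probes) fail("probe count")
  if (any(tr$stimulus[probes + 1L] == "V")) fail("probe on a target trial")
  mean_gap <- (probes[length(probes)] + 1L) / cfg$n_probes
  if (mean_gap != cfg$probe_gap_mean) fail("mean probe gap")
  invisible(TRUE)
}

# Seed one RNG stream locally; restores the caller's RNG state on exit.
local_rng <- function(seed, env = parent.frame()) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed %% 2147483647))
  withr::defer({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }, envir = env)
  invisible(NULL)
}
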