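#' 20 Hz analysis grid for one trial
#'
#' Grid times are bin centers: `0.025 + k * 0.05` s, `k = 0..39`, spanning
#' the 2-s trial with 40 points.
#'
#' @param trial_dur_s trial duration (s).
#' @param rate_hz grid rate (Hz).
#' @return numeric vector of grid times.
#' @export
grid_times <- function(trial_dur_s = 2, rate_hz = 20) {
  n <- as.integer(round(trial_dur_s * rate_hz))
  (seq_len(n) - 0.5) / rate_hz
}

#' Combine the two eyes into a single sample series
#'
#' Per-sample mean of the valid eyes; a combined sample is invalid only if
#' both eyes are invalid at that time-point.
#'
#' @param left,right numeric diameter vectors (mm), equal length.
#' @param left_valid,right_valid logical/0-1 validity vectors.
#' @return list with `diameter_mm` and `valid` (logical).
#' @export
combine_eyes <- function(left, right = NULL, left_valid = TRUE,
                         right_valid = TRUE) {
  if (is.null(left) && is.null(right)) stop("input error: no eyes supplied")
  if (is.null(right)) return(list(diameter_mm = left,
                                  valid = rep(as.logical(left_valid),
                                              length.out = length(left))))
  lv <- rep(as.logical(left_valid), length.out = length(left))
  rv <- rep(as.logical(right_valid), length.out = length(right))
  num <- ifelse(lv, left, 0) + ifelse(rv, right, 0)
  den <- as.integer(lv) + as.integer(rv)
  d <- ifelse(den > 0, num / pmax(den, 1L), NA_real_)
  list(diameter_mm = d, valid = den > 0L)
}

#' Mask artifactual samples within one trial
#'
#' Masks samples whose value lies strictly outside the central 90%
#' interval of the trial's tracker-valid samples (below the 5th or above
#' the 95th within-trial percentile, linear-interpolation percentile
#' definition; boundary values are kept). With `rule = "upper_90"` only
#' the upper tail is masked. The percentile thresholds are always computed
#' over the tracker-valid samples, so re-applying the rule to an
#' already-masked series (passing the previous result as `mask`) is
#' idempotent. Values are never modified, only the mask.
#'
#' @param diameter_mm numeric vector of one trial's samples.
#' @param valid logical vector: tracker validity (defines the percentile
#'   reference set; invalid samples are always masked).
#' @param rule `"central_90"` (default) or `"upper_90"`.
#' @param mask logical vector: the current retention mask (defaults to
#'   `valid`); the result never retains a sample this mask drops.
#' @return logical `retained` vector (TRUE = keep).
#' @export
reject_artifacts <- function(diameter_mm, valid = rep(TRUE, length(diameter_mm)),
                             rule = c("central_90", "upper_90"),
                             mask = valid) {
  rule <- match.arg(rule)
  valid <- rep(as.logical(valid), length.out = length(diameter_mm))
  mask <- rep(as.logical(mask), length.out = length(diameter_mm))
  keep <- mask & valid
  if (!any(valid)) return(keep & FALSE) # fully-masked series, no exception
  v <- diameter_mm[valid]
  if (rule == "central_90") {
    q <- stats::quantile(v, c(0.05, 0.95), names = FALSE, type = 7)
    inr <- diameter_mm >= q[1] & diameter_mm <= q[2]
  } else {
    q <- stats::quantile(v, 0.95, names = FALSE, type = 7)
    inr <- diameter_mm <= q
  }
  keep & inr
}

#' Interpolate one trial's retained samples onto the 20 Hz grid
#'
#' Linear interpolation of retained samples at the 40 grid times. Grid
#' points just beyond the outermost retained samples (within one raw
#' sample period, as the 20 Hz bin centers inevitably are at the trial
#' edges) are linearly extrapolated from the adjacent segment, so a
#' noiseless linear signal is reconstructed exactly; larger edge gaps left
#' by masking are filled with the nearest retained value. The trial is
#' flagged excluded when more than 60% of its raw time-points were removed
#' (strict `>`); with zero retained samples all grid values are missing
#' and the trial is excluded.
#'
#' @param t_s sample times (s, within trial).
#' @param diameter_mm sample values (mm).
#' @param retained logical mask from [reject_artifacts()].
#' @param n_raw denominator for the loss fraction (raw time-points per
#'   trial; defaults to `length(t_s)`).
#' @param trial_dur_s trial duration (s).
#' @return list: `t_grid`, `diameter_mm` (length-40), `loss_fraction`,
#'   `excluded`.
#' @export
interpolate_trial <- function(t_s, diameter_mm, retained,
                              n_raw = length(t_s), trial_dur_s = 2) {
  grid <- grid_times(trial_dur_s)
  loss <- (n_raw - sum(retained)) / n_raw
  excluded <- loss > 0.60
  if (sum(retained) == 0L)
    return(list(t_grid = grid, diameter_mm = rep(NA_real_, length(grid)),
                loss_fraction = 1, excluded = TRUE))
  x <- t_s[retained]
  y <- diameter_mm[retained]
  if (length(x) == 1L) {
    g <- rep(y, length(grid))
  } else {
    g <- stats::approx(x, y, xout = grid, method = "linear",
                       rule = 2, ties = "ordered")$y
    # short edge overhangs: extrapolate the adjacent segment linearly
    raw_step <- if (length(t_s) > 1L) min(diff(sort(t_s))) else Inf
    lo <- grid < x[1] & x[1] - grid <= raw_step + 1e-12
    hi <- grid > x[length(x)] & grid - x[length(x)] <= raw_step + 1e-12
    if (any(lo)) {
      s <- (y[2] - y[1]) / (x[2] - x[1])
      g[lo] <- y[1] + s * (grid[lo] - x[1])
    }
    if (any(hi)) {
      m <- length(x)
      s <- (y[m] - y[m - 1]) / (x[m] - x[m - 1])
      g[hi] <- y[m] + s * (grid[hi] - x[m])
    }
  }
  list(t_grid = grid, diameter_mm = g, loss_fraction = loss,
       excluded = excluded)
}

#' Preprocess one subject's raw recording
#'
#' Combines eyes, masks within-trial percentile outliers, interpolates each
#' trial to the 40-point 20 Hz grid and applies the >60% signal-loss
#' exclusion rule. Trials containing blinks are retained whenever they
#' survive that rule.
#'
#' @param samples tidy samples tibble (one subject): `subject_id`,
#'   `trial_index`, `t_s`, `eye`, `diameter_mm`, `valid`.
#' @param rule artifact rule passed to [reject_artifacts()].
#' @param trial_dur_s trial duration (s).
#' @return list: `clean` (tibble: `subject_id`, `trial_index`,
#'   `grid_index`, `t_s`, `diameter_mm`, `excluded`), `qc` (per-trial
#'   tibble with `loss_fraction`, `excluded`), `excluded_fraction`.
#' @export
preprocess_session <- function(samples, rule = "central_90",
                               trial_dur_s = 2) {
  sid <- samples$subject_id[1]
  l <- samples[samples$eye == "L", ]
  r <- samples[samples$eye == "R", ]
  if (nrow(r) == 0L && nrow(l) == 0L) stop("input error: no eyes supplied")
  base <- if (nrow(l)) l else r
  comb <- if (nrow(l) && nrow(r))
    combine_eyes(l$diameter_mm, r$diameter_mm, l$valid == 1, r$valid == 1)
  else list(diameter_mm = base$diameter_mm, valid = base$valid == 1)

  trial_ids <- sort(unique(base$trial_index))
  idx <- split(seq_len(nrow(base)), base$trial_index)
  grid <- grid_times(trial_dur_s)
  ng <- length(grid)

  rows <- lapply(seq_along(trial_ids), function(k) {
    i <- idx[[k]]
    keep <- reject_artifacts(comb$diameter_mm[i], comb$valid[i], rule = rule)
    interpolate_trial(base$t_s[i], comb$diameter_mm[i], keep,
                      n_raw = length(i), trial_dur_s = trial_dur_s)
  })
  qc <- tibble::tibble(
    subject_id = sid, trial_index = trial_ids,
    loss_fraction = vapply(rows, `[[`, 0, "loss_fraction"),
    excluded = vapply(rows, `[[`, TRUE, "excluded"))
  clean <- tibble::tibble(
    subject_id = sid,
    trial_index = rep(trial_ids, each = ng),
    grid_index = rep(0:(ng - 1L), length(trial_ids)),
    t_s = rep(grid, length(trial_ids)),
    diameter_mm = unlist(lapply(rows, `[[`, "diameter_mm")),
    excluded = rep(qc$excluded, each = ng))
  list(clean = clean, qc = qc, excluded_fraction = mean(qc$excluded))
}

#' Preprocess every subject in a cohort
#'
#' @param samples tidy samples tibble for one or more subjects.
#' @param rule artifact rule.
#' @return list: `clean` (all subjects), `qc` (per trial), `summary`
#'   (per-subject excluded-trial fraction).
#' @export
preprocess_cohort <- function(samples, rule = "central_90") {
  parts <- lapply(split(samples, samples$subject_id),
                  preprocess_session, rule = rule)
  clean <- dplyr::bind_rows(lapply(parts, `[[`, "clean"))
  qc <- dplyr::bind_rows(lapply(parts, `[[`, "qc"))
  summary <- dplyr::summarise(dplyr::group_by(qc, .data$subject_id),
                              excluded_fraction = mean(.data$excluded),
                              .groups = "drop")
  list(clean = clean, qc = qc, summary = summary)
}
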