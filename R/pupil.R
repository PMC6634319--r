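#' Pupil signal generation parameters
#'
#' The synthetic pupil trace is a sum of: a tonic baseline; negative-going
#' pupillary light-reflex responses to every bar onset and (larger) to
#' every cue-word onset, each a gamma-family impulse response; a
#' saturating MW-linked dilation (linear ramp then plateau) spanning each
#' MW episode; and AR(1) noise shared across eyes plus independent
#' per-eye white noise. Blinks invalidate short runs of samples and leave
#' artifactually low readings on their flanks; longer dropouts invalidate
#' runs outright.
#'
#' @param baseline_mm tonic pupil diameter (mm).
#' @param kernel_n,kernel_tmax_s shape and peak time (s) of the
#'   pupillary impulse response (Hoeks-Levelt style gamma family).
#' @param bar_constriction_mm peak constriction to a bar stimulus (mm).
#' @param word_constriction_mm peak constriction to a cue-word (mm); the
#'   bright text drives a stronger light reflex than the bars.
#' @param mw_dilation_mm default MW dilation amplitude (mm); overridden per
#'   episode by the latent trace.
#' @param mw_ramp_s rise time (s) of the MW dilation ramp.
#' @param noise_sd_mm marginal SD of the shared AR(1) noise (mm).
#' @param ar1_coef AR(1) coefficient at the 30 Hz sample step, in `[0, 1)`.
#' @param eye_noise_sd_mm SD of independent per-eye white noise (mm).
#' @param blink_rate_per_min,blink_dur_s blink rate and duration.
#' @param dropout_rate_per_min,dropout_dur_s rate and mean (exponential)
#'   duration of longer tracking dropouts.
#' @param sample_rate_hz raw sampling rate (Hz).
#' @return a list of class `"mw_pupil_params"`.
#' @export
pupil_params <- function(baseline_mm = 4.0,
                         kernel_n = 10.1,
                         kernel_tmax_s = 0.93,
                         bar_constriction_mm = 0.10,
                         word_constriction_mm = 0.35,
                         mw_dilation_mm = 0.1,
                         mw_ramp_s = 2,
                         noise_sd_mm = 0.15,
                         ar1_coef = 0.85,
                         eye_noise_sd_mm = 0.05,
                         blink_rate_per_min = 12,
                         blink_dur_s = 0.2,
                         dropout_rate_per_min = 2.0,
                         dropout_dur_s = 1.2,
                         sample_rate_hz = 30) {
  p <- list(baseline_mm = baseline_mm, kernel_n = kernel_n,
            kernel_tmax_s = kernel_tmax_s,
            bar_constriction_mm = bar_constriction_mm,
            word_constriction_mm = word_constriction_mm,
            mw_dilation_mm = mw_dilation_mm, mw_ramp_s = mw_ramp_s,
            noise_sd_mm = noise_sd_mm, ar1_coef = ar1_coef,
            eye_noise_sd_mm = eye_noise_sd_mm,
            blink_rate_per_min = blink_rate_per_min, blink_dur_s = blink_dur_s,
            dropout_rate_per_min = dropout_rate_per_min,
            dropout_dur_s = dropout_dur_s, sample_rate_hz = sample_rate_hz)
  if (p$sample_rate_hz <= 0) stop("parameter error: sample_rate_hz must be > 0")
  if (p$bar_constriction_mm < 0 || p$word_constriction_mm < 0)
    stop("parameter error: constriction amplitudes must be >= 0")
  if (p$ar1_coef < 0 || p$ar1_coef >= 1)
    stop("parameter error: ar1_coef must lie in [0, 1)")
  class(p) <- "mw_pupil_params"
  p
}

#' Pupillary impulse-response kernel
#'
#' Gamma-family kernel parameterized by its peak time:
#' `k(t) = (t / tmax)^n * exp(n * (1 - t / tmax))`, so `k(0) = 0`,
#' `k(tmax) = 1` is the unique interior maximum, and the response decays
#' smoothly afterwards. Defaults (`n = 10.1`, `tmax = 0.93` s) are the
#' standard pupillometry choice.
#'
#' @param t time since event onset, seconds; must be `>= 0`.
#' @param params a [pupil_params()] list.
#' @return unitless response weight in `[0, 1]`.
#' @export
pupil_kernel <- function(t, params = pupil_params()) {
  if (any(t < 0)) stop("domain error: pupil_kernel requires t >= 0")
  n <- params$kernel_n
  tmax <- params$kernel_tmax_s
  (t / tmax)^n * exp(n * (1 - t / tmax))
}

#' Generate a raw 30 Hz binocular pupil recording for one session
#'
#' Evaluates the generative model trial-by-trial on the session timeline:
#' every trial onset contributes a bar-evoked constriction, cue-word trials
#' a larger word-evoked constriction, and every MW episode a dilation ramp
#' (rising over `mw_ramp_s`, sustained to episode offset, then released
#' over the same ramp time). Shared AR(1) noise and per-eye white noise are
#' added, then blinks and dropouts mark samples invalid (blinks also leave
#' artifactually low readings on their flanking samples).
#'
#' @param schedule an `"mw_schedule"`.
#' @param latent the matching `"mw_latent"` (its episodes drive dilation).
#' @param params a [pupil_params()] list.
#' @param seed integer seed for this stream.
#' @return tibble with `subject_id`, `trial_index`, `t_s` (within-trial
#'   time, `[0, 2)`), `eye` ("L"/"R"), `diameter_mm`, `valid` (0/1).
#' @export
generate_pupil_recording <- function(schedule, latent,
                                     params = pupil_params(), seed = 1L) {
  stopifnot(inherits(schedule, "mw_schedule"), inherits(latent, "mw_latent"))
  rng <- local_rng(seed)
  cfg <- schedule$config
  fs <- params$sample_rate_hz
  spt <- as.integer(round(cfg$trial_dur_s * fs)) # samples per trial
  n_trials <- cfg$n_trials
  nt <- n_trials * spt
  tt <- (seq_len(nt) - 1L) / fs # session time of each sample

  sig <- rep(params$baseline_mm, nt)

  # event-evoked constrictions: truncate the kernel where it is negligible
  k_len <- as.integer(ceiling(4 * fs))
  k_t <- (seq_len(k_len) - 1L) / fs
  k_bar <- pupil_kernel(k_t, params) * params$bar_constriction_mm
  k_word <- pupil_kernel(k_t, params) * params$word_constriction_mm
  add_kernel <- function(sig, onsets_s, kern) {
    for (o in onsets_s) {
      i0 <- as.integer(round(o * fs)) + 1L
      i1 <- min(i0 + k_len - 1L, nt)
      sig[i0:i1] <- sig[i0:i1] - kern[seq_len(i1 - i0 + 1L)]
    }
    sig
  }
  trial_onsets <- (0:(n_trials - 1L)) * cfg$trial_dur_s
  sig <- add_kernel(sig, trial_onsets, k_bar)
  word_trials <- schedule$trials$trial_index[!is.na(schedule$trials$word_id)]
  sig <- add_kernel(sig, word_trials * cfg$trial_dur_s, k_word)

  # MW dilation: ramp up from episode onset, hold to offset, ramp down
  eps <- latent$episodes
  for (i in seq_len(nrow(eps))) {
    t_on <- eps$onset_trial[i] * cfg$trial_dur_s
    t_off <- (eps$offset_trial[i] + 1L) * cfg$trial_dur_s
    amp <- eps$dilation_mm[i]
    ramp <- params$mw_ramp_s
    up <- pmin(pmax((tt - t_on) / ramp, 0), 1)
    down <- pmin(pmax((tt - t_off) / ramp, 0), 1)
    sig <- sig + amp * (up - down)
  }

  # shared AR(1) noise with marginal SD noise_sd_mm
  if (params$noise_sd_mm > 0) {
    innov <- stats::rnorm(nt, 0,
                          params$noise_sd_mm * sqrt(1 - params$ar1_coef^2))
    sig <- sig + as.numeric(stats::filter(innov, params$ar1_coef,
                                          method = "recursive"))
  }

  dur_s <- n_trials * cfg$trial_dur_s
  draw_events <- function(rate_per_min, dur_fun) {
    n_ev <- stats::rpois(1L, rate_per_min * dur_s / 60)
    if (n_ev == 0L) return(cbind(numeric(0), numeric(0)))
    on <- sort(stats::runif(n_ev, 0, dur_s))
    cbind(on, on + dur_fun(n_ev))
  }
  blinks <- draw_events(params$blink_rate_per_min,
                        function(k) rep(params$blink_dur_s, k))
  drops <- draw_events(params$dropout_rate_per_min,
                       function(k) stats::rexp(k, 1 / params$dropout_dur_s))

  eye_tbl <- function(eye) {
    d <- sig + stats::rnorm(nt, 0, params$eye_noise_sd_mm)
    valid <- rep(TRUE, nt)
    mask_ev <- function(ev, flank_low) {
      for (r in seq_len(nrow(ev))) {
        i0 <- max(1L, as.integer(floor(ev[r, 1] * fs)) + 1L)
        i1 <- min(nt, as.integer(ceiling(ev[r, 2] * fs)))
        if (i1 < i0) next
        valid[i0:i1] <<- FALSE
        if (flank_low) { # half-occluded pupil reads artifactually small
          for (j in c(i0 - 1L, i1 + 1L))
            if (j >= 1L && j <= nt) d[j] <<- d[j] * 0.4
        }
      }
    }
    mask_ev(blinks, flank_low = TRUE)
    mask_ev(drops, flank_low = FALSE)
    d[d <= 0] <- 0.01
    tibble::tibble(subject_id = schedule$subject_id,
                   trial_index = rep(0:(n_trials - 1L), each = spt),
                   t_s = rep((0:(spt - 1L)) / fs, n_trials),
                   eye = eye, diameter_mm = d, valid = as.integer(valid))
  }
  dplyr::bind_rows(eye_tbl("L"), eye_tbl("R")) |>
    dplyr::arrange(.data$trial_index, .data$t_s, .data$eye)
}
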