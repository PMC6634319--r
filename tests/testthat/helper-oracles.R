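# Independent oracles used across the suite. Each reimplements the checked
# quantity from first principles, without calling the package's own path.

# OLS via normal equations: coefficients and the partial F test of a
# coefficient block, with residual variance on n - p df.
ols_oracle <- function(X, y, block_cols = NULL) {
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% beta
  n <- length(y)
  p <- ncol(X)
  s2 <- sum(res^2) / (n - p)
  out <- list(beta = drop(beta), s2 = s2, df2 = n - p)
  if (!is.null(block_cols)) {
    C <- s2 * solve(t(X) %*% X)
    b <- beta[block_cols]
    q <- length(block_cols)
    Fstat <- drop(t(b) %*% solve(C[block_cols, block_cols, drop = FALSE], b)) / q
    out$F <- Fstat
    out$p <- pf(Fstat, q, n - p, lower.tail = FALSE)
  }
  out
}

# JZS two-sample BF10 by fixed fine-grid trapezoid quadrature, written out
# from the definition: g ~ InvGamma(1/2, r^2/2) prior on the relative
# effect variance, marginal t likelihood ratio. Substitution g = u/(1-u).
bf_grid_oracle <- function(t, n1, n2, r = sqrt(2) / 2, n_grid = 400000L) {
  neff <- n1 * n2 / (n1 + n2)
  nu <- n1 + n2 - 2
  u <- seq(1e-9, 1 - 1e-9, length.out = n_grid)
  g <- u / (1 - u)
  jac <- 1 / (1 - u)^2
  log_prior <- 0.5 * log(r^2 / 2) - lgamma(0.5) - 1.5 * log(g) -
    r^2 / (2 * g)
  log_l1 <- -0.5 * log1p(neff * g) -
    (nu + 1) / 2 * log1p(t^2 / ((1 + neff * g) * nu))
  log_l0 <- -(nu + 1) / 2 * log1p(t^2 / nu)
  f <- exp(log_l1 + log_prior - log_l0) * jac
  du <- u[2] - u[1]
  sum((f[-1] + f[-length(f)]) / 2) * du
}

# Brute-force central-90 percentile mask (linear-interpolation percentile,
# keep-on-boundary), computed directly from the definition.
percentile_mask_oracle <- function(x, valid = rep(TRUE, length(x))) {
  v <- x[valid]
  q <- stats::quantile(v, c(0.05, 0.95), type = 7, names = FALSE)
  keep <- valid
  keep[valid] <- v >= q[1] & v <= q[2]
  keep
}

# 60-sample trial fixture: 57 clean values (rounded, so percentile
# boundaries fall on tied clean values) plus three artifact spikes at
# positions 21, 42 and 60; the central-90 rule must mask exactly those.
spike_fixture <- function() {
  x <- c(4.01, 3.99, 4.00, 4.01, 4.00, 4.00, 4.02, 4.00, 4.02, 4.00,
         4.01, 4.02, 3.99, 4.00, 4.00, 4.01, 4.00, 3.98, 3.98, 4.01,
         9.00, 4.00, 3.98, 4.00, 4.01, 4.02, 4.00, 4.00, 3.98, 4.00,
         3.99, 4.00, 4.01, 4.01, 3.99, 4.01, 3.98, 3.99, 3.99, 3.98,
         4.00, 9.00, 4.00, 4.00, 4.01, 3.99, 3.99, 4.00, 3.99, 4.01,
         4.00, 4.01, 4.00, 3.99, 4.02, 4.01, 4.00, 4.00, 4.01, 0.50)
  list(values = x, spikes = c(21L, 42L, 60L))
}

# A small handcrafted session: schedule + latent with fully controlled cue
# and episode placement, for exact noise-free pipeline checks.
# - cue at trial `trigger_cue`, MW episode onset = cue + 1, plateau to the
#   pre-probe trial of `mw_probe`;
# - a second neutral cue at `control_cue` whose nearest probes report
#   on-task or nothing (-> label "control").
toy_session <- function(n_trials = 120L,
                        trigger_cue = 30L, mw_probe = 39L,
                        control_cue = 80L, ot_probe = 99L,
                        valences = c("neu", "neu"),
                        dilation_mm = 0.1, subject_id = "s01") {
  cfg <- list(n_trials = n_trials, trial_dur_s = 2, n_targets = 0L,
              target_gap_min = 9L, target_gap_max = 31L, n_cues = 2L,
              n_probes = 2L, probe_gap_mean = NA, probe_gap_sd = NA,
              p_cue_before_probe = 0)
  class(cfg) <- "mw_design"
  word_id <- rep(NA_character_, n_trials)
  word_text <- rep(NA_character_, n_trials)
  valence <- rep(NA_character_, n_trials)
  word_id[c(trigger_cue, control_cue) + 1L] <- c("w001", "w002")
  word_text[c(trigger_cue, control_cue) + 1L] <- c("toy cue 1", "toy cue 2")
  valence[c(trigger_cue, control_cue) + 1L] <- valences
  probes <- c(mw_probe, ot_probe)
  trials <- tibble::tibble(
    subject_id = subject_id, trial_index = 0:(n_trials - 1L),
    stimulus = "H", word_id = word_id, word_text = word_text,
    valence = valence,
    probe_after = as.integer(0:(n_trials - 1L) %in% probes))
  sch <- structure(list(subject_id = subject_id, trials = trials,
                        probe_after = probes, config = cfg),
                   class = "mw_schedule")
  state <- rep("on_task", n_trials)
  state[(trigger_cue + 1L):mw_probe + 1L] <- "mw_spontaneous"
  episodes <- tibble::tibble(
    onset_trial = trigger_cue + 1L, offset_trial = mw_probe,
    spontaneity = "spontaneous", trigger_type = "cue_word",
    trigger_word_id = "w001", dilation_mm = dilation_mm, episode_id = 1L)
  lat <- structure(list(subject_id = subject_id, state_per_trial = state,
                        episodes = episodes), class = "mw_latent")
  lat$reports <- pupilmw::derive_reports(lat, sch)
  list(schedule = sch, latent = lat)
}

# Balanced dataset whose residuals are centred within subject, so the
# between-subject variance estimate sits exactly on the zero boundary and
# the GLS fit coincides with OLS.
make_ols_limit_data <- function(seed = 1, n_subj = 6, k = 8) {
  set.seed(seed)
  d <- expand.grid(subject_id = sprintf("s%02d", seq_len(n_subj)),
                   condition = c("a", "b", "c"), rep = seq_len(k),
                   position = c(0, 1, 2), stringsAsFactors = FALSE)
  e <- rnorm(nrow(d), 0, 0.1)
  e <- e - ave(e, d$subject_id) # zero residual mean per subject
  d$value_mm <- 0.02 * d$position * (d$condition == "c") + e
  tibble::tibble(d)
}

# Noise- and artifact-free pupil parameter set (overridable).
quiet_pupil <- function(...) {
  args <- utils::modifyList(
    list(noise_sd_mm = 0, eye_noise_sd_mm = 0,
         blink_rate_per_min = 0, dropout_rate_per_min = 0),
    list(...))
  do.call(pupil_params, args)
}
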