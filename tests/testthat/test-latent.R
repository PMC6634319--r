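test_that("a zero-MW mixture yields no episodes and no MW reports", {
  sch <- generate_schedule(5)
  p <- state_params(p_on_task = 1 - 3 * 2.99 / 28 - 0.05,
                    p_mw_spont = 0, p_mw_int = 0,
                    p_distraction = 2.99 / 28 + 0.05,
                    p_task_related = 2.99 / 28, p_blank = 2.99 / 28)
  lat <- generate_latent_states(sch, p, seed = 9)
  expect_equal(nrow(lat$episodes), 0L)
  expect_false(any(grepl("^mw_", lat$reports$category)))
})

test_that("invalid mixture probabilities raise parameter errors", {
  expect_error(state_params(p_on_task = 0.9), "sum to 1")
  expect_error(state_params(p_on_task = -0.1, p_distraction = 3 * 2.99 / 28 +
                              7.36 / 28 + 0.1 - 2 * 2.99 / 28), "sum to 1")
  expect_error(state_params(p_cue_trigger = 1.2), "p_cue_trigger")
})

test_that("reports are a deterministic function of the latent states", {
  sch <- generate_schedule(11)
  lat <- generate_latent_states(sch, seed = 12)
  expect_identical(derive_reports(lat, sch), lat$reports)
  expect_true(validate_latent(lat, sch))
  lat2 <- generate_latent_states(sch, seed = 12)
  expect_identical(lat$reports, lat2$reports)
})

test_that("the default mixture reproduces the expected report mix", {
  n_sessions <- 200L
  counts <- vapply(seq_len(n_sessions), function(s) {
    sch <- generate_schedule(1000 + s)
    rep_s <- generate_latent_states(sch, seed = 2000 + s)$reports
    c(spont = sum(rep_s$category == "mw_spontaneous"),
      ot = sum(rep_s$category == "on_task"),
      int = sum(rep_s$category == "mw_intentional"),
      trig = sum(rep_s$category == "mw_spontaneous" &
                   rep_s$trigger_type == "cue_word"))
  }, numeric(4))

  # per-subject spontaneous-MW mean: binomial(28, p) sampling error
  p_sp <- 9.57 / 28
  se_sp <- sqrt(28 * p_sp * (1 - p_sp)) / sqrt(n_sessions)
  expect_lt(abs(mean(counts["spont", ]) - 9.57), 3 * se_sp)
  p_ot <- 7.36 / 28
  se_ot <- sqrt(28 * p_ot * (1 - p_ot)) / sqrt(n_sessions)
  expect_lt(abs(mean(counts["ot", ]) - 7.36), 3 * se_ot)

  # fraction of spontaneous MW carrying a cue-word trigger ~ 212/402
  frac <- sum(counts["trig", ]) / sum(counts["spont", ])
  p_tr <- 212 / 402
  se_tr <- sqrt(p_tr * (1 - p_tr) / sum(counts["spont", ]))
  expect_lt(abs(frac - p_tr), 3 * se_tr + 0.01) # small slack: cue-less windows
})

test_that("trigger-to-probe lags have mean near 9 trials", {
  lags <- unlist(lapply(1:150, function(s) {
    sch <- generate_schedule(3000 + s)
    lat <- generate_latent_states(sch, seed = 4000 + s)
    eps <- lat$episodes
    eps <- eps[eps$trigger_type == "cue_word", ]
    cue_pos <- sch$trials$trial_index[match(eps$trigger_word_id,
                                            sch$trials$word_id)]
    eps$offset_trial - cue_pos
  }))
  # lag = 1 + Geometric(1/9), but truncated by the available cue windows
  expect_gt(mean(lags), 7)
  expect_lt(mean(lags), 10.5)
})

test_that("behavioural log matches the programmed lapse rates", {
  sch <- generate_schedule(21)
  b0 <- generate_behaviour(sch, params = behaviour_params(0, 0), seed = 1)
  s0 <- summarise_behaviour(b0, sch)
  expect_equal(s0$misses, 0L)
  expect_equal(s0$false_alarms, 0L)
  b1 <- generate_behaviour(sch, params = behaviour_params(p_miss = 1),
                           seed = 1)
  expect_equal(summarise_behaviour(b1, sch)$misses, 68L)

  perf <- vapply(1:500, function(s)
    unlist(summarise_behaviour(
      generate_behaviour(sch, seed = 5000 + s), sch)[, c("misses",
                                                         "false_alarms")]),
    numeric(2))
  se_miss <- sqrt(68 * (0.33 / 68) * (1 - 0.33 / 68)) / sqrt(500)
  expect_lt(abs(mean(perf["misses", ]) - 0.33), 3 * se_miss)
  se_fa <- sqrt(1052 * (0.79 / 1052) * (1 - 0.79 / 1052)) / sqrt(500)
  expect_lt(abs(mean(perf["false_alarms", ]) - 0.79), 3 * se_fa)
})

test_that("cohort generation is deterministic and round-trips through CSV", {
  co <- generate_cohort(2, seed = 31, generate_pupil = TRUE)
  expect_equal(nrow(cohort_table(co, "reports")), 2L * 28L)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort_csv(co, d1)
  write_cohort_csv(generate_cohort(2, seed = 31), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  back <- read_cohort_csv(d1)
  expect_equal(as.data.frame(back$schedule),
               as.data.frame(cohort_table(co, "schedule")))
  expect_equal(as.data.frame(back$samples),
               as.data.frame(cohort_table(co, "samples")), tolerance = 1e-12)
})
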