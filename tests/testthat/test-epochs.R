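# small helper: clean traces + tables for a noise-free toy session
toy_clean <- function(toy, pupil = quiet_pupil(bar_constriction_mm = 0,
                                               word_constriction_mm = 0)) {
  smp <- generate_pupil_recording(toy$schedule, toy$latent, pupil, seed = 1)
  pr <- preprocess_session(smp)
  list(clean = pr$clean, schedule = toy$schedule$trials,
       reports = toy$latent$reports)
}

test_that("cue classification partitions all occurrences into the four labels", {
  co <- generate_cohort(2, seed = 41, generate_pupil = FALSE)
  sch <- cohort_table(co, "schedule")
  reps <- cohort_table(co, "reports")
  lab <- classify_cues(sch, reps)
  expect_equal(nrow(lab), sum(!is.na(sch$word_id)))
  expect_true(all(lab$label %in% c("mw_trigger", "emotional_nontrigger",
                                   "control", "excluded")))
  # every cue named as a spontaneous-MW trigger is labelled mw_trigger
  named <- reps$trigger_word_id[reps$category == "mw_spontaneous" &
                                  reps$trigger_type == "cue_word"]
  lab_by <- dplyr::left_join(
    tibble::tibble(subject_id = reps$subject_id[reps$category ==
        "mw_spontaneous" & reps$trigger_type == "cue_word"],
      word_id = named),
    lab, by = c("subject_id", "word_id"))
  expect_true(all(lab_by$label == "mw_trigger"))
  # emotional non-triggers are positive/negative cues
  expect_true(all(lab$valence[lab$label == "emotional_nontrigger"] %in%
                    c("pos", "neg")))
})

test_that("cue classification resolves the toy session by hand rules", {
  # trigger cue -> mw_trigger; neutral cue before an on-task probe -> control
  toy <- toy_session()
  lab <- classify_cues(toy$schedule$trials, toy$latent$reports)
  expect_equal(lab$label[lab$word_id == "w001"], "mw_trigger")
  expect_equal(lab$label[lab$word_id == "w002"], "control")

  # an emotional cue whose next probe is on-task -> emotional_nontrigger
  toy2 <- toy_session(valences = c("neu", "pos"))
  toy2$latent$episodes$trigger_type <- "own_thoughts"
  toy2$latent$episodes$trigger_word_id <- NA_character_
  toy2$latent$reports <- derive_reports(toy2$latent, toy2$schedule)
  lab2 <- classify_cues(toy2$schedule$trials, toy2$latent$reports)
  expect_equal(lab2$label[lab2$word_id == "w002"], "emotional_nontrigger")
  # the first cue is now an untriggered neutral cue followed by MW -> control
  expect_equal(lab2$label[lab2$word_id == "w001"], "control")

  # unmatched trigger word ids are excluded with a warning
  toy3 <- toy_session()
  toy3$latent$reports$trigger_word_id[
    toy3$latent$reports$trigger_word_id == "w001"] <- "w999"
  expect_warning(lab3 <- classify_cues(toy3$schedule$trials,
                                       toy3$latent$reports), "w999")
  expect_equal(lab3$label[lab3$word_id == "w001"], "control")
})

test_that("epochs are baseline-anchored: reference-window mean is zero", {
  tc <- toy_clean(toy_session())
  lab <- classify_cues(tc$schedule, tc$reports)
  cue <- epoch_cue_aligned(tc$clean, lab)
  for (rid in unique(cue$epochs$reference_id)) {
    e <- cue$epochs[cue$epochs$reference_id == rid, ]
    expect_lt(abs(mean(e$value_mm[e$position == 0])), 1e-10)
  }
  probe <- epoch_probe_aligned(tc$clean, tc$reports)
  for (rid in unique(probe$epochs$reference_id)) {
    e <- probe$epochs[probe$epochs$reference_id == rid, ]
    expect_lt(abs(mean(e$value_mm[e$position == 1])), 1e-10)
  }
})

test_that("a constant-diameter session gives all-zero summaries", {
  toy <- toy_session(dilation_mm = 0)
  tc <- toy_clean(toy)
  lab <- classify_cues(tc$schedule, tc$reports)
  cue <- epoch_cue_aligned(tc$clean, lab)
  expect_true(all(abs(cue$summaries$value_mm) < 1e-12))
  probe <- epoch_probe_aligned(tc$clean, tc$reports)
  expect_true(all(abs(probe$summaries$value_mm) < 1e-12))
})

test_that("epochs drop cues and probes without enough recorded trials", {
  toy <- toy_session()
  tc <- toy_clean(toy)
  lab <- classify_cues(tc$schedule, tc$reports)
  # exclude trial trigger_cue + 2 (=32): the trigger epoch must disappear
  clean2 <- tc$clean
  clean2$excluded[clean2$trial_index == 32L] <- TRUE
  cue2 <- epoch_cue_aligned(clean2, lab)
  expect_false("s01_t30" %in% cue2$summaries$reference_id)
  expect_gt(cue2$n_dropped, 0L)

  # probe-aligned: kill one of the three pre-probe trials
  clean3 <- tc$clean
  clean3$excluded[clean3$trial_index == 37L] <- TRUE
  probe3 <- epoch_probe_aligned(clean3, tc$reports)
  expect_false("s01_t39" %in% probe3$summaries$reference_id)
})

test_that("probe-aligned conditions map report categories onto MW/OT/other", {
  toy <- toy_session()
  toy$latent$episodes$spontaneity <- "deliberate"
  toy$latent$state_per_trial[toy$latent$state_per_trial ==
                               "mw_spontaneous"] <- "mw_intentional"
  toy$latent$episodes$trigger_type <- "none"
  toy$latent$episodes$trigger_word_id <- NA_character_
  toy$latent$reports <- derive_reports(toy$latent, toy$schedule)
  tc <- toy_clean(toy)
  probe <- epoch_probe_aligned(tc$clean, tc$reports)
  cond <- unique(probe$summaries[, c("reference_id", "condition")])
  expect_equal(cond$condition[cond$reference_id == "s01_t39"], "other")
  expect_equal(cond$condition[cond$reference_id == "s01_t99"], "OT")
})

test_that("noise-free programmed dilation is recovered at position 2", {
  delta <- 0.1
  tc <- toy_clean(toy_session(dilation_mm = delta),
                  pupil = quiet_pupil()) # realistic constrictions retained
  lab <- classify_cues(tc$schedule, tc$reports)
  cue <- epoch_cue_aligned(tc$clean, lab)
  s <- cue$summaries
  trig2 <- s$value_mm[s$condition == "mw_trigger" & s$position == 2]
  ctrl2 <- s$value_mm[s$condition == "control" & s$position == 2]
  expect_equal(mean(trig2) - mean(ctrl2), delta, tolerance = 1e-6)
})

test_that("light responses equal the analytic kernel window means", {
  # flat trace -> zero constriction
  toy <- toy_session(dilation_mm = 0)
  tc <- toy_clean(toy)
  lr0 <- extract_light_responses(tc$clean, tc$schedule, tc$reports,
                                 "mw_vs_ot")
  expect_true(all(abs(lr0$constriction_mm) < 1e-12))

  # noiseless bar response: compare with direct quadrature of the kernel
  A <- 0.25
  p <- quiet_pupil(bar_constriction_mm = A, word_constriction_mm = 0)
  tc2 <- toy_clean(toy_session(dilation_mm = 0), pupil = p)
  lr <- extract_light_responses(tc2$clean, tc2$schedule, tc2$reports,
                                "mw_vs_ot")
  # steady-state trial response: kernel tails of preceding trials included
  resp <- function(t) -A * (pupil_kernel(t, p) + pupil_kernel(t + 2, p) +
                              pupil_kernel(t + 4, p))
  win <- stats::integrate(resp, 0.5, 1.0)$value / 0.5
  base <- stats::integrate(resp, 0, 0.25)$value / 0.25
  # absolute tolerance: 30 -> 20 Hz linear resampling of the curved
  # kernel biases window means by O(h^2 k'') ~ 1e-3 mm
  expect_lt(max(abs(lr$constriction_mm - (win - base))), 3e-3)
})

test_that("light-response selection excludes cue-adjacent trials", {
  # pre-probe trial carries a cue: that candidate must be dropped
  toy <- toy_session(control_cue = 99L) # cue on the OT pre-probe trial
  tc <- toy_clean(toy)
  lr <- extract_light_responses(tc$clean, tc$schedule, tc$reports,
                                "mw_vs_ot")
  expect_false(99L %in% lr$trial_index[lr$group == "OT"])
  # predecessor carries a cue: also dropped
  toy2 <- toy_session(control_cue = 98L)
  tc2 <- toy_clean(toy2)
  lr2 <- extract_light_responses(tc2$clean, tc2$schedule, tc2$reports,
                                 "mw_vs_ot")
  expect_false(99L %in% lr2$trial_index[lr2$group == "OT"])
})

test_that("target trials pair with their preceding non-target trials", {
  co <- generate_cohort(1, seed = 77,
                        pupil = quiet_pupil())
  sch <- cohort_table(co, "schedule")
  reps <- cohort_table(co, "reports")
  pr <- preprocess_session(co$sessions[[1]]$samples)
  lr <- extract_light_responses(pr$clean, sch, reps, "target_vs_nontarget")
  expect_true(all(lr$group %in% c("target", "nontarget")))
  tg <- sch$trial_index[sch$stimulus == "V"]
  expect_true(all(lr$trial_index[lr$group == "target"] %in% tg))
  expect_false(any(lr$trial_index[lr$group == "nontarget"] %in% tg))
  # no selected trial carries a cue, nor does its predecessor
  has_cue <- !is.na(sch$word_id)
  expect_false(any(has_cue[lr$trial_index + 1L]))
  expect_false(any(has_cue[pmax(lr$trial_index, 1L)]))
})

test_that("cue placement fractions match hand counts on a toy fixture", {
  # 6 probes; cues placed on the 4th-before trial for probes 1, 2 and 5
  n <- 240L
  probes <- c(39L, 79L, 119L, 159L, 199L, 239L)
  cue_at <- c(36L, 76L, 196L, 150L, 10L)
  trials <- tibble::tibble(
    subject_id = "s01", trial_index = 0:(n - 1L), stimulus = "H",
    word_id = ifelse(0:(n - 1L) %in% cue_at,
                     sprintf("w%03d", 1:n), NA_character_),
    word_text = NA_character_,
    valence = ifelse(0:(n - 1L) %in% cue_at, "neu", NA_character_),
    probe_after = as.integer(0:(n - 1L) %in% probes))
  reports <- tibble::tibble(
    subject_id = "s01", probe_index = 0:5, probe_after = probes,
    category = c("mw_spontaneous", "on_task", "mw_spontaneous",
                 "on_task", "task_related", "blank"),
    spontaneity = "not_applicable", trigger_type = "none",
    trigger_word_id = NA_character_)
  cp <- cue_placement_check(trials, reports)
  ov <- cp$overall
  # MW probes at 39 (cue at 36: hit) and 119 (116: miss) -> 50%
  expect_equal(ov$mean_pct[ov$category == "MW"], 50)
  # OT probes at 79 (76: hit) and 159 (156: miss) -> 50%
  expect_equal(ov$mean_pct[ov$category == "OT"], 50)
  # other probes at 199 (196: hit) and 239 (236: miss) -> 50%
  expect_equal(ov$mean_pct[ov$category == "other"], 50)

  # degenerate extremes
  trials2 <- trials
  trials2$word_id <- NA_character_
  cp0 <- cue_placement_check(trials2, reports)
  expect_true(all(cp0$overall$mean_pct == 0))
})
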