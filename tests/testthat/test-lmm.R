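test_that("the OLS limit reproduces the normal-equations oracle", {
  d <- make_ols_limit_data()
  fit <- fit_lmm(d)
  expect_equal(fit$lambda, 0)
  X <- model.matrix(~ condition * position, d)
  orc <- ols_oracle(X, d$value_mm, block_cols = 5:6)
  expect_equal(unname(fit$beta), unname(orc$beta), tolerance = 1e-8)
  ia <- anova_interaction(fit)
  expect_equal(ia$F, orc$F, tolerance = 1e-6)
  expect_equal(ia$df2, orc$df2)
  expect_equal(ia$p, orc$p, tolerance = 1e-6)
})

test_that("a balanced zero-noise fixture returns the cell means exactly", {
  d <- expand.grid(subject_id = c("s01", "s02"), condition = c("a", "b"),
                   position = c(0, 1), stringsAsFactors = FALSE)
  # programmed cell means: a: 1 + 0.5 pos; b: 2 + 0.25 pos
  d$value_mm <- ifelse(d$condition == "a", 1 + 0.5 * d$position,
                       2 + 0.25 * d$position)
  fit <- fit_lmm(tibble::tibble(d))
  expect_equal(unname(fit$beta),
               c(1, 1, 0.5, -0.25), tolerance = 1e-10)
  expect_lt(fit$sigma2_e, 1e-20)
})

test_that("profiled ML matches lme4 on random datasets", {
  skip_if_not_installed("lme4")
  for (i in 1:20) {
    n_subj <- sample(4:12, 1)
    k <- sample(4:15, 1)
    d <- simulate_epoch_summaries(
      n_subj, c(a = n_subj * k, b = n_subj * k, c = 2 * n_subj * k),
      slopes = c(a = 0, b = 0.01, c = 0.03),
      sigma_u = runif(1, 0.02, 0.1), sigma_e = runif(1, 0.05, 0.2),
      seed = 100 + i)
    fit <- fit_lmm(d)
    ref <- lme4::lmer(value_mm ~ condition * position + (1 | subject_id),
                      data = d, REML = FALSE)
    expect_equal(unname(fit$beta), unname(lme4::fixef(ref)),
                 tolerance = 1e-6)
    vc <- as.data.frame(lme4::VarCorr(ref))
    expect_equal(fit$sigma2_u, vc$vcov[1], tolerance = 1e-4)
    expect_equal(fit$sigma2_e, vc$vcov[2], tolerance = 1e-4)
    expect_equal(fit$loglik, as.numeric(stats::logLik(ref)),
                 tolerance = 1e-8)
  }
})

test_that("variance components are recovered in simulation", {
  est <- vapply(1:200, function(i) {
    d <- simulate_epoch_summaries(42, c(a = 400, b = 400),
                                  slopes = c(a = 0, b = 0.02),
                                  sigma_u = 0.2, sigma_e = 0.1,
                                  seed = 9000 + i)
    f <- fit_lmm(d)
    c(f$sigma2_u, f$sigma2_e)
  }, numeric(2))
  expect_lt(abs(median(est[1, ]) - 0.04) / 0.04, 0.2)
  expect_lt(abs(median(est[2, ]) - 0.01) / 0.01, 0.2)
})

test_that("rank-deficient designs and missing interactions raise errors", {
  d <- simulate_epoch_summaries(3, c(a = 9, b = 9), c(a = 0, b = 0),
                                seed = 5)
  d$position <- 1 # no position variation: interaction confounded
  expect_error(fit_lmm(d), "rank-deficiency")
  d2 <- simulate_epoch_summaries(3, c(a = 9, b = 9), c(a = 0, b = 0),
                                 seed = 6)
  f2 <- fit_lmm(d2, value_mm ~ condition + position)
  expect_error(anova_interaction(f2), "no interaction")
})

test_that("the residual-df convention reproduces the printed df arithmetic", {
  # cue-aligned interaction: (194 + 215 + 7391) epochs x 3 positions - 6
  d <- simulate_epoch_summaries(
    42, c(control = 7391, emotional_nontrigger = 215, mw_trigger = 194),
    slopes = c(control = 0, emotional_nontrigger = 0, mw_trigger = 0.05),
    seed = 77)
  ia <- anova_interaction(fit_lmm(d))
  expect_equal(ia$df1, 2L)
  expect_equal(ia$df2, 23394L)

  # probe-aligned interaction: (188 + 144 + 236) x 3 - 6
  dp <- simulate_epoch_summaries(
    42, c(other = 236, OT = 144, MW = 188),
    slopes = c(other = 0, OT = 0, MW = -0.03), positions = c(3, 2, 1),
    seed = 78)
  iap <- anova_interaction(fit_lmm(dp))
  expect_equal(iap$df2, 1698L)

  # post-hoc pairwise df2 = n1 + n2 - 2 for all printed pairs
  ph <- posthoc_pairwise(d, c("emotional_nontrigger", "mw_trigger"), 1)
  expect_equal(ph$df2, 407L)
  ph2 <- posthoc_pairwise(d, c("control", "mw_trigger"), 2)
  expect_equal(ph2$df2, 7583L)
  ph3 <- posthoc_pairwise(d, c("control", "emotional_nontrigger"), 1)
  expect_equal(ph3$df2, 7604L)
  php <- posthoc_pairwise(dp, c("OT", "MW"), 3)
  expect_equal(php$df2, 330L)
})

test_that("pairwise post-hocs reduce to the pooled two-group F", {
  # two subjects with identical data: between-subject variance is zero,
  # so the GLS contrast equals the pooled-variance t^2
  set.seed(8)
  x <- rnorm(30, 0.05, 0.1)
  y <- rnorm(40, 0.00, 0.1)
  d <- tibble::tibble(
    subject_id = rep(c("s01", "s02"), each = 70),
    reference_id = paste0("e", 1:140),
    condition = rep(rep(c("a", "b"), c(30, 40)), 2),
    position = 1,
    value_mm = rep(c(x, y), 2))
  ph <- posthoc_pairwise(d, c("a", "b"), 1)
  tt <- t.test(rep(x, 2), rep(y, 2), var.equal = TRUE)
  expect_equal(ph$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(ph$df2, 138L)
  # identical groups: F ~ 0, p ~ 1
  z <- rnorm(35, 0, 0.1)
  d0 <- tibble::tibble(
    subject_id = rep(c("s01", "s02"), each = 70),
    reference_id = paste0("e", 1:140),
    condition = rep(rep(c("a", "b"), each = 35), 2),
    position = 1,
    value_mm = rep(rep(z, 2), 2))
  ph0 <- posthoc_pairwise(d0, c("a", "b"), 1)
  expect_lt(ph0$F, 1e-20)
  expect_equal(ph0$p, 1, tolerance = 1e-12)
  expect_error(posthoc_pairwise(d, c("a", "zz"), 1), "empty")
})

test_that("split-half partitions epochs by parity and refits each half", {
  d <- simulate_epoch_summaries(4, c(a = 20, b = 20),
                                slopes = c(a = 0, b = 0.05), seed = 13)
  sh <- split_half(d)
  expect_equal(sh$odd$fit$n_obs + sh$even$fit$n_obs, nrow(d))
  expect_lte(abs(sh$odd$fit$n_obs - sh$even$fit$n_obs), 2 * 3)
  expect_s3_class(sh$odd$interaction, "tbl_df")

  # duplicate-epoch data: both halves give identical fits
  d2 <- d
  d2$reference_id <- paste0(d2$reference_id, "a")
  dd <- dplyr::bind_rows(d, d2)
  dd <- dd[order(dd$subject_id, dd$reference_id), ]
  sh2 <- split_half(dd)
  expect_equal(sh2$odd$fit$beta, sh2$even$fit$beta, tolerance = 1e-8)
})

test_that("interaction test power is high for the programmed dilation", {
  hits <- vapply(1:60, function(i) {
    d <- simulate_epoch_summaries(
      42, c(control = 7391, emotional_nontrigger = 215, mw_trigger = 194),
      slopes = c(control = 0, emotional_nontrigger = 0, mw_trigger = 0.05),
      seed = 400 + i)
    anova_interaction(fit_lmm(d))$p < 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.8)
})
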