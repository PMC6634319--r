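#' Fit a random-intercept linear mixed model by profiled maximum likelihood
#'
#' Fits `value_mm ~ condition * position + (1 | subject_id)` (or any fixed
#' formula) with a single random intercept per subject. For the
#' one-grouping-factor case the likelihood is profiled analytically: for a
#' given variance ratio `lambda = sigma2_u / sigma2_e`, the marginal
#' covariance per subject is `sigma2_e (I + lambda J)`, whose inverse and
#' determinant are closed-form (Sherman-Morrison), giving GLS estimates of
#' the coefficients and a closed-form `sigma2_e`; the scalar profile
#' likelihood is then maximised over `log(lambda)` with a boundary check at
#' `lambda = 0`. Estimation is ML by default (the residual-df F-test
#' convention supplies the small-sample correction downstream); REML is
#' available.
#'
#' @param data data frame with the response and predictors; no missing
#'   values are allowed.
#' @param formula fixed-effects formula (default
#'   `value_mm ~ condition * position`).
#' @param group name of the grouping column (random intercept).
#' @param reml use REML instead of ML.
#' @return an object of class `"mw_lmm"`: coefficients `beta`, `sigma2_u`,
#'   `sigma2_e`, `lambda`, `loglik`, `n_obs`, `p_fixed`, the unscaled GLS
#'   cross-products, term assignment, and `converged`.
#' @export
fit_lmm <- function(data, formula = value_mm ~ condition * position,
                    group = "subject_id", reml = FALSE) {
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  g <- factor(data[[group]])
  n <- length(y)
  p <- ncol(X)
  if (nlevels(g) < 1L) stop("specification error: empty grouping factor")
  if (qr(X)$rank < p)
    stop("rank-deficiency error: fixed-effect design is singular")

  n_g <- as.numeric(table(g))
  gi <- as.integer(g)
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  yty <- sum(y * y)
  # per-group column sums of X and y
  Sx <- rowsum(X, gi)
  Sy <- rowsum(y, gi)

  # GLS pieces for V* = I + lambda * J within each group:
  # X'V*^-1 X = X'X - sum_g w_g Sx_g Sx_g',  w_g = lambda / (1 + lambda n_g)
  gls <- function(lambda) {
    w <- lambda / (1 + lambda * n_g)
    XtVX <- XtX - crossprod(Sx * sqrt(w))
    XtVy <- Xty - crossprod(Sx, Sy * w)
    yVy <- yty - sum(w * Sy^2)
    beta <- solve(XtVX, XtVy)
    rss <- as.numeric(yVy - crossprod(beta, XtVy) -
                        crossprod(XtVy, beta) + crossprod(beta, XtVX %*% beta))
    list(beta = beta, XtVX = XtVX, rss = rss)
  }
  logdet_V <- function(lambda) sum(log1p(lambda * n_g))
  prof_nll <- function(loglambda) {
    lambda <- exp(loglambda)
    f <- gls(lambda)
    f$rss <- max(f$rss, 1e-300) # keep the profile finite for exact fits
    if (reml) {
      s2 <- f$rss / (n - p)
      0.5 * ((n - p) * log(2 * pi * s2) + logdet_V(lambda) +
               as.numeric(determinant(f$XtVX, logarithm = TRUE)$modulus) +
               (n - p))
    } else {
      s2 <- f$rss / n
      0.5 * (n * log(2 * pi * s2) + logdet_V(lambda) + n)
    }
  }
  nll0 <- prof_nll(-700) # exp(-700) underflows to exactly lambda = 0
  opt <- stats::optimize(prof_nll, interval = c(-12, 12), tol = 1e-10)
  if (opt$objective < nll0 - 1e-10) {
    lambda <- exp(opt$minimum)
    nll <- opt$objective
  } else {
    lambda <- 0
    nll <- prof_nll(-700)
  }
  f <- gls(lambda)
  sigma2_e <- if (reml) f$rss / (n - p) else f$rss / n
  fit <- structure(list(
    beta = drop(f$beta), sigma2_u = lambda * sigma2_e, sigma2_e = sigma2_e,
    lambda = lambda, loglik = -nll, n_obs = n, p_fixed = p,
    XtVX = f$XtVX, rss = f$rss, s2_resid = f$rss / (n - p),
    assign = attr(X, "assign"), term_labels = attr(stats::terms(mf), "term.labels"),
    formula = formula, group = group, reml = reml,
    converged = TRUE), class = "mw_lmm")
  fit
}

#' @export
print.mw_lmm <- function(x, ...) {
  cat("Random-intercept LMM (profiled ", if (x$reml) "REML" else "ML",
      ")\n", sep = "")
  cat(sprintf("  n = %d, p = %d, logLik = %.3f\n", x$n_obs, x$p_fixed,
              x$loglik))
  cat(sprintf("  sigma2_u = %.6g, sigma2_e = %.6g\n", x$sigma2_u, x$sigma2_e))
  print(round(x$beta, 6))
  invisible(x)
}

# Wald F test of a coefficient block, residual-df convention:
# df2 = n_obs - p_fixed, scale = rss / df2.
block_f_test <- function(fit, cols, term) {
  C <- fit$s2_resid * solve(fit$XtVX)
  b <- fit$beta[cols]
  Fstat <- as.numeric(crossprod(b, solve(C[cols, cols, drop = FALSE], b))) /
    length(cols)
  df1 <- length(cols)
  df2 <- fit$n_obs - fit$p_fixed
  tibble::tibble(term = term, F = Fstat, df1 = df1, df2 = df2,
                 p = stats::pf(Fstat, df1, df2, lower.tail = FALSE))
}

#' F test of the condition-by-position interaction
#'
#' Tests the full interaction block with the residual-df convention
#' (`df2 = N - p`), which reproduces the denominator-df arithmetic of
#' ANOVA tables computed on the marginal model: with three conditions and
#' a continuous position covariate, `df1 = 2` and
#' `df2 = 3 * n_epochs - 6`.
#'
#' @param fit an `"mw_lmm"` from [fit_lmm()].
#' @return one-row tibble: `term`, `F`, `df1`, `df2`, `p`.
#' @export
anova_interaction <- function(fit) {
  ia <- grep(":", fit$term_labels)
  if (!length(ia))
    stop("specification error: model has no interaction term")
  cols <- which(fit$assign == ia[length(ia)])
  block_f_test(fit, cols, fit$term_labels[ia[length(ia)]])
}

#' Post-hoc two-condition contrast at a single position
#'
#' Refits the model restricted to the two conditions at one position
#' (`value_mm ~ condition` with the subject random intercept) and tests
#' the condition coefficient; `df2 = n - 2` as in two-group post-hocs.
#'
#' @param summaries summary table (`subject_id`, `condition`, `position`,
#'   `value_mm`).
#' @param conditions length-2 character vector.
#' @param position the position at which to compare.
#' @return one-row tibble: `term`, `F`, `df1`, `df2`, `p`, plus `n1`,
#'   `n2`.
#' @export
posthoc_pairwise <- function(summaries, conditions, position) {
  d <- summaries[summaries$condition %in% conditions &
                   summaries$position == position, ]
  n1 <- sum(d$condition == conditions[1])
  n2 <- sum(d$condition == conditions[2])
  if (n1 == 0L || n2 == 0L)
    stop("specification error: a condition is empty at this position")
  d$condition <- factor(d$condition, levels = conditions)
  fit <- fit_lmm(d, value_mm ~ condition)
  res <- block_f_test(fit, which(fit$assign == 1L),
                      paste(conditions, collapse = " vs "))
  res$n1 <- n1
  res$n2 <- n2
  res
}

#' Split-half reliability re-analysis
#'
#' Splits epochs into odd and even halves by the parity of the epoch
#' ordinal within subject (epochs ordered by their reference trial), then
#' fits and tests each half exactly as the full set.
#'
#' @param summaries summary table with `reference_id`.
#' @param formula fixed-effects formula.
#' @return list with elements `odd` and `even`, each containing `fit` and
#'   `interaction` (the F-test row).
#' @export
split_half <- function(summaries, formula = value_mm ~ condition * position) {
  refs <- unique(summaries[, c("subject_id", "reference_id")])
  if (nrow(refs) < 2L) stop("specification error: need at least 2 epochs")
  refs <- refs[order(refs$subject_id, refs$reference_id), ]
  ord <- stats::ave(seq_len(nrow(refs)), refs$subject_id, FUN = seq_along)
  refs$half <- ifelse(ord %% 2L == 1L, "odd", "even")
  halves <- lapply(c(odd = "odd", even = "even"), function(h) {
    keep <- refs$reference_id[refs$half == h]
    d <- summaries[summaries$reference_id %in% keep, ]
    fit <- fit_lmm(d, formula)
    list(fit = fit, interaction = anova_interaction(fit))
  })
  halves
}

#' Ordinal parity of epochs within subject
#'
#' @param summaries summary table with `reference_id`.
#' @return the input with a `half` column ("odd"/"even") joined on.
#' @export
epoch_parity <- function(summaries) {
  refs <- unique(summaries[, c("subject_id", "reference_id")])
  refs <- refs[order(refs$subject_id, refs$reference_id), ]
  ord <- stats::ave(seq_len(nrow(refs)), refs$subject_id, FUN = seq_along)
  refs$half <- ifelse(ord %% 2L == 1L, "odd", "even")
  dplyr::left_join(summaries, refs, by = c("subject_id", "reference_id"))
}
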