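#' Classify cue-word occurrences by their relation to the probe reports
#'
#' Every cue occurrence receives exactly one label:
#' * `mw_trigger` — named by a later probe as the trigger of a spontaneous
#'   MW episode;
#' * `emotional_nontrigger` — positive/negative cue, not a trigger, whose
#'   nearest following probe reports on-task;
#' * `control` — neither an MW trigger nor an emotional cue whose nearest
#'   following or preceding probe reports on-task;
#' * `excluded` — everything else (triggers of intentional MW, emotional
#'   cues preceded but not followed by an on-task probe, cues named as
#'   triggers but absent from the schedule, which also raises a warning).
#'
#' @param schedule_tbl tidy schedule tibble (one or more subjects).
#' @param reports tidy reports tibble.
#' @return tibble: `subject_id`, `trial_index`, `word_id`, `valence`,
#'   `label`.
#' @export
classify_cues <- function(schedule_tbl, reports) {
  out <- lapply(split(schedule_tbl, schedule_tbl$subject_id), function(sch) {
    rep_s <- reports[reports$subject_id == sch$subject_id[1], ]
    cues <- sch[!is.na(sch$word_id), ]
    probes <- sch$trial_index[sch$probe_after == 1L]
    rep_s <- rep_s[order(rep_s$probe_after), ]

    spont_trig <- rep_s$trigger_word_id[
      rep_s$category == "mw_spontaneous" & rep_s$trigger_type == "cue_word"]
    int_trig <- rep_s$trigger_word_id[
      rep_s$category == "mw_intentional" & rep_s$trigger_type == "cue_word"]
    ghost <- setdiff(stats::na.omit(c(spont_trig, int_trig)), cues$word_id)
    if (length(ghost))
      warning("trigger word_id not found in schedule: ",
              paste(ghost, collapse = ", "))

    # trigger status only counts for probes at or after the cue trial
    trig_pos <- rep_s$probe_after[match(cues$word_id, rep_s$trigger_word_id)]
    is_spont_trig <- cues$word_id %in% spont_trig &
      !is.na(trig_pos) & trig_pos >= cues$trial_index
    is_int_trig <- cues$word_id %in% int_trig

    nxt <- findInterval(cues$trial_index - 1L, rep_s$probe_after) + 1L
    prv <- findInterval(cues$trial_index - 1L, rep_s$probe_after)
    cat_at <- function(i) ifelse(i >= 1L & i <= nrow(rep_s),
                                 rep_s$category[pmin(pmax(i, 1L), nrow(rep_s))],
                                 NA_character_)
    next_ot <- !is.na(cat_at(nxt)) & cat_at(nxt) == "on_task"
    prev_ot <- !is.na(cat_at(prv)) & cat_at(prv) == "on_task"
    emotional <- cues$valence %in% c("pos", "neg")

    label <- rep("control", nrow(cues))
    label[emotional & (next_ot | prev_ot)] <- "excluded"
    label[emotional & next_ot & !is_spont_trig] <- "emotional_nontrigger"
    label[is_int_trig] <- "excluded"
    label[is_spont_trig] <- "mw_trigger"

    tibble::tibble(subject_id = cues$subject_id,
                   trial_index = cues$trial_index,
                   word_id = cues$word_id, valence = cues$valence,
                   label = label)
  })
  dplyr::bind_rows(out)
}

# mean of grid values over an index window (0-based, inclusive)
window_mean <- function(values, grid_index, lo, hi)
  mean(values[grid_index >= lo & grid_index <= hi])

# lookup table: trial -> 40 grid values, plus excluded flags, per subject
trial_matrix <- function(clean_s) {
  ord <- order(clean_s$trial_index, clean_s$grid_index)
  cs <- clean_s[ord, ]
  ids <- unique(cs$trial_index)
  m <- matrix(cs$diameter_mm, nrow = 40L,
              dimnames = list(NULL, as.character(ids)))
  excl <- cs$excluded[seq(1L, nrow(cs), by = 40L)]
  names(excl) <- as.character(ids)
  list(m = m, excluded = excl)
}

#' Cue-aligned epochs and summaries
#'
#' For each labelled cue occurrence (labels `mw_trigger`,
#' `emotional_nontrigger`, `control`), builds an epoch over trial offsets
#' 0, 1, 2 after the cue. The baseline is the mean diameter over all 40
#' grid points of trial 0; epochs are kept only when all three trials are
#' recorded and non-excluded. Summaries are the mean baseline-corrected
#' diameter over each trial's last second (grid points 20-39).
#'
#' @param clean cleaned traces tibble from [preprocess_cohort()].
#' @param cue_labels tibble from [classify_cues()].
#' @return list: `epochs` (tibble: one row per epoch x position x grid
#'   point, baseline-corrected), `summaries` (tibble: `subject_id`,
#'   `reference_id`, `condition`, `position`, `value_mm`), `n_dropped`.
#' @export
epoch_cue_aligned <- function(clean, cue_labels) {
  build_epochs(clean,
               refs = cue_labels[cue_labels$label != "excluded", ],
               ref_trial = function(r) r$trial_index,
               offsets = c(0L, 1L, 2L), position_of = function(o) o,
               baseline_window = c(0L, 39L), baseline_position = 0,
               summary_window = c(20L, 39L),
               condition_of = function(r) r$label)
}

#' Probe-aligned epochs and summaries
#'
#' For each probe, builds an epoch over the three trials before it
#' (positions 3, 2, 1; position 1 is the trial immediately preceding the
#' probe). The baseline is the mean diameter over the position-1 trial;
#' probes are kept only when all three trials are recorded and
#' non-excluded. Conditions: `MW` (spontaneous MW only), `OT` (on-task),
#' `other` (everything else, including intentional MW). Summaries are the
#' mean corrected diameter over each trial's first second (grid points
#' 0-19).
#'
#' @param clean cleaned traces tibble.
#' @param reports tidy reports tibble.
#' @return as [epoch_cue_aligned()].
#' @export
epoch_probe_aligned <- function(clean, reports) {
  refs <- reports
  refs$condition <- ifelse(refs$category == "mw_spontaneous", "MW",
                           ifelse(refs$category == "on_task", "OT", "other"))
  build_epochs(clean, refs = refs,
               ref_trial = function(r) r$probe_after,
               offsets = c(-2L, -1L, 0L),
               position_of = function(o) -o + 1L, # trial offsets -> 3,2,1
               baseline_window = c(0L, 39L), baseline_position = 1,
               summary_window = c(0L, 19L),
               condition_of = function(r) r$condition)
}

build_epochs <- function(clean, refs, ref_trial, offsets, position_of,
                         baseline_window, baseline_position, summary_window,
                         condition_of) {
  epochs <- list()
  summaries <- list()
  n_dropped <- 0L
  for (sid in unique(refs$subject_id)) {
    tm <- trial_matrix(clean[clean$subject_id == sid, ])
    rs <- refs[refs$subject_id == sid, ]
    for (i in seq_len(nrow(rs))) {
      r <- rs[i, ]
      trials <- ref_trial(r) + offsets
      key <- as.character(trials)
      if (any(trials < 0L) || !all(key %in% colnames(tm$m)) ||
          any(tm$excluded[key])) {
        n_dropped <- n_dropped + 1L
        next
      }
      vals <- tm$m[, key, drop = FALSE]
      positions <- vapply(offsets, position_of, 0L)
      base <- mean(vals[, which(positions == baseline_position)])
      corr <- vals - base
      ref_id <- paste0(sid, "_t", ref_trial(r))
      epochs[[length(epochs) + 1L]] <- tibble::tibble(
        subject_id = sid, reference_id = ref_id,
        condition = condition_of(r),
        position = rep(positions, each = 40L),
        grid_index = rep(0:39, length(offsets)),
        value_mm = as.numeric(corr))
      summaries[[length(summaries) + 1L]] <- tibble::tibble(
        subject_id = sid, reference_id = ref_id,
        condition = condition_of(r), position = as.numeric(positions),
        value_mm = colMeans(corr[(summary_window[1] + 1L):
                                   (summary_window[2] + 1L), , drop = FALSE]))
    }
  }
  list(epochs = dplyr::bind_rows(epochs),
       summaries = dplyr::bind_rows(summaries), n_dropped = n_dropped)
}

#' Within-trial pupillary light responses
#'
#' Constriction is the mean of the baseline-corrected trace over
#' [0.5, 1.0) s (grid points 10-19), the window where the bar-evoked
#' constriction peaks; the baseline is the mean over the first 250 ms
#' (grid points 0-4). Candidate trials are excluded when the trial itself
#' or its predecessor carries a cue-word (which would shift the baseline),
#' or when flagged by QC.
#'
#' * mode `mw_vs_ot`: the last trial before each probe reporting
#'   spontaneous MW (group `MW`) or on-task (group `OT`);
#' * mode `target_vs_nontarget`: every target trial (group `target`) and
#'   the last non-target trial before each target (group `nontarget`).
#'
#' @param clean cleaned traces tibble.
#' @param schedule_tbl tidy schedule tibble.
#' @param reports tidy reports tibble.
#' @param mode selection mode.
#' @return tibble: `subject_id`, `trial_index`, `group`,
#'   `constriction_mm`.
#' @export
extract_light_responses <- function(clean, schedule_tbl, reports,
                                    mode = c("mw_vs_ot",
                                             "target_vs_nontarget")) {
  mode <- match.arg(mode)
  out <- list()
  for (sid in unique(schedule_tbl$subject_id)) {
    sch <- schedule_tbl[schedule_tbl$subject_id == sid, ]
    tm <- trial_matrix(clean[clean$subject_id == sid, ])
    has_cue <- !is.na(sch$word_id)
    cand <- if (mode == "mw_vs_ot") {
      rs <- reports[reports$subject_id == sid &
                      reports$category %in% c("mw_spontaneous", "on_task"), ]
      tibble::tibble(trial = rs$probe_after,
                     group = ifelse(rs$category == "mw_spontaneous",
                                    "MW", "OT"))
    } else {
      tg <- sch$trial_index[sch$stimulus == "V"]
      ntg <- vapply(tg, function(t) {
        prior <- sch$trial_index[sch$stimulus == "H" & sch$trial_index < t]
        if (length(prior)) max(prior) else NA_integer_
      }, 0L)
      tibble::tibble(trial = c(tg, ntg[!is.na(ntg)]),
                     group = c(rep("target", length(tg)),
                               rep("nontarget", sum(!is.na(ntg)))))
    }
    keep <- !has_cue[cand$trial + 1L] &
      (cand$trial == 0L | !has_cue[cand$trial]) # predecessor cue-free
    cand <- cand[keep, ]
    key <- as.character(cand$trial)
    ok <- key %in% colnames(tm$m)
    ok[ok] <- !tm$excluded[key[ok]]
    cand <- cand[ok, ]
    if (!nrow(cand)) next
    v <- tm$m[, as.character(cand$trial), drop = FALSE]
    constr <- colMeans(v[11:20, , drop = FALSE]) - colMeans(v[1:5, , drop = FALSE])
    out[[length(out) + 1L]] <- tibble::tibble(
      subject_id = sid, trial_index = cand$trial, group = cand$group,
      constriction_mm = as.numeric(constr))
  }
  dplyr::bind_rows(out)
}

#' Probability of a cue-word on the 4th trial before a probe
#'
#' Checks a potential confound of the probe-aligned analysis: whether the
#' trial just outside the analysed window (the 4th before each probe) is
#' equally likely to carry a cue-word regardless of the report category.
#'
#' @param schedule_tbl tidy schedule tibble.
#' @param reports tidy reports tibble.
#' @return list: `per_subject` (tibble: `subject_id`, `category`,
#'   `fraction`), `overall` (tibble: `category`, `mean_pct`, `se_pct`).
#'   Categories are `MW` (spontaneous), `OT`, `other`.
#' @export
cue_placement_check <- function(schedule_tbl, reports) {
  rep2 <- reports
  rep2$cat3 <- ifelse(rep2$category == "mw_spontaneous", "MW",
                      ifelse(rep2$category == "on_task", "OT", "other"))
  per <- lapply(split(rep2, rep2$subject_id), function(rs) {
    sch <- schedule_tbl[schedule_tbl$subject_id == rs$subject_id[1], ]
    has_cue <- !is.na(sch$word_id)
    t4 <- rs$probe_after - 3L
    hit <- t4 >= 0L & has_cue[t4 + 1L]
    dplyr::summarise(dplyr::group_by(
      tibble::tibble(subject_id = rs$subject_id, category = rs$cat3,
                     hit = hit),
      .data$subject_id, .data$category),
      fraction = mean(.data$hit), .groups = "drop")
  })
  per <- dplyr::bind_rows(per)
  overall <- dplyr::summarise(
    dplyr::group_by(per, .data$category),
    mean_pct = 100 * mean(.data$fraction),
    se_pct = 100 * stats::sd(.data$fraction) / sqrt(dplyr::n()),
    .groups = "drop")
  list(per_subject = per, overall = overall)
}
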