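#' Flag trial-level RT exclusions
#'
#' Applies the standard flanker exclusion rules to a trial table, setting an
#' `excluded_reason` column. Practice-block trials are flagged `practice` and
#' never scored. Among main-block trials, a trial is flagged `rt_lt_100` when
#' its RT is below 100 ms, `incorrect` when the response was wrong, and
#' `rt_gt_3mad` when `rt - median(rt) > 3 * MAD(rt)`, with the median and the
#' (unscaled) MAD -- the median of absolute deviations from the median --
#' computed per participant x session over that individual's main trials.
#' All flags are computed on the pre-exclusion trial set, so removing one
#' flagged trial never changes another trial's flag.
#'
#' By default the 3*MAD statistics (and the flag) are restricted to correct
#' trials, error RTs being generated by a different process; set
#' `mad_correct_only = FALSE` to pool them in. `mad_per_condition = TRUE`
#' computes the threshold per condition instead of pooling conditions within
#' an individual.
#'
#' @param trials Trial-level `data.frame` (any number of participants and
#'   sessions) with the columns written by [simulate_flanker()].
#' @param mad_correct_only Restrict the 3*MAD rule to correct trials
#'   (default `TRUE`).
#' @param mad_per_condition Compute median/MAD per condition rather than per
#'   individual pooled across conditions (default `FALSE`).
#' @return The input with an `excluded_reason` column (`"none"` for trials
#'   that enter the condition means). Reason precedence: `practice`,
#'   `rt_lt_100`, then `incorrect`/`rt_gt_3mad`.
#' @examples
#' trials <- simulate_flanker(flanker_params(seed = 2, n_participants = 3))
#' flagged <- flag_rt_exclusions(trials)
#' table(flagged$excluded_reason)
#' @export
flag_rt_exclusions <- function(trials, mad_correct_only = TRUE,
                               mad_per_condition = FALSE) {
  dt <- check_trials(trials)
  dt[, excluded_reason := "none"]
  dt[block == "practice", excluded_reason := "practice"]
  main <- dt$block != "practice"
  dt[main & rt_ms < 100, excluded_reason := "rt_lt_100"]
  in_mad_set <- main & dt$excluded_reason != "rt_lt_100" &
    (if (mad_correct_only) dt$correct else TRUE)
  key <- if (mad_per_condition) {
    c("participant", "session", "condition")
  } else {
    c("participant", "session")
  }
  # pre-exclusion statistics: median/MAD over the full flag set, no re-flagging
  stats_dt <- dt[main & (if (mad_correct_only) correct else TRUE), {
    if (.N < 4L) {
      stopf("participant %s session %s: %d trials; need >= 4 for a defined MAD",
            .BY[[1]], .BY[[2]], .N)
    }
    m <- median(rt_ms)
    list(thr = m + 3 * median(abs(rt_ms - m)))
  }, by = key]
  dt[stats_dt, thr := i.thr, on = key]
  dt[in_mad_set & rt_ms > thr & excluded_reason == "none",
     excluded_reason := "rt_gt_3mad"]
  dt[main & !correct & excluded_reason == "none",
     excluded_reason := "incorrect"]
  dt[, thr := NULL]
  as.data.frame(dt)
}

#' Score participants: condition means, flanker effect, exclusion tallies
#'
#' Computes per participant x session the mean correct RT per condition over
#' valid (correct, unflagged, main-block) trials, the flanker effect
#' (incongruent minus congruent mean), overall accuracy on main trials, and
#' the per-condition percentages of 3*MAD-flagged and incorrect trials as
#' reported in descriptive tables. Participants with a condition lacking any
#' valid trial in a session are dropped from the result with a warning and
#' listed in the `"dropped"` attribute.
#'
#' @param trials Trial table; if it lacks an `excluded_reason` column,
#'   [flag_rt_exclusions()] is applied first with default settings.
#' @return A `data.frame` with columns `participant`, `group`, `session`,
#'   `mean_rt_congruent`, `mean_rt_incongruent`, `flanker_effect`,
#'   `accuracy`, `pct_3mad_congruent`, `pct_3mad_incongruent`,
#'   `pct_incorrect_congruent`, `pct_incorrect_incongruent`,
#'   `n_valid_congruent`, `n_valid_incongruent`.
#' @examples
#' trials <- simulate_flanker(flanker_params(seed = 3, n_participants = 4))
#' scores <- score_participants(trials)
#' scores[, c("participant", "session", "flanker_effect")]
#' @export
score_participants <- function(trials) {
  if (!"excluded_reason" %in% names(trials)) {
    trials <- flag_rt_exclusions(trials)
  }
  dt <- check_trials(trials)
  main <- dt[block != "practice"]
  pct <- function(x) 100 * mean(x)
  res <- main[, {
    con <- condition == "congruent"
    corr <- correct
    valid <- excluded_reason == "none"
    list(
      mean_rt_congruent = mean(rt_ms[con & valid]),
      mean_rt_incongruent = mean(rt_ms[!con & valid]),
      accuracy = mean(corr),
      pct_3mad_congruent = pct(excluded_reason[con & corr] == "rt_gt_3mad"),
      pct_3mad_incongruent = pct(excluded_reason[!con & corr] == "rt_gt_3mad"),
      pct_incorrect_congruent = pct(!corr[con]),
      pct_incorrect_incongruent = pct(!corr[!con]),
      n_valid_congruent = sum(con & valid),
      n_valid_incongruent = sum(!con & valid)
    )
  }, by = .(participant, group, session)]
  res[, flanker_effect := mean_rt_incongruent - mean_rt_congruent]
  bad <- res$n_valid_congruent == 0L | res$n_valid_incongruent == 0L
  dropped <- res[bad, .(participant, session)]
  if (nrow(dropped)) {
    warnf("dropping %d participant-session(s) with a condition lacking valid trials: %s",
          nrow(dropped),
          paste(dropped$participant, dropped$session, sep = "/", collapse = ", "))
    res <- res[!bad]
  }
  out <- as.data.frame(res)[, c(
    "participant", "group", "session", "mean_rt_congruent",
    "mean_rt_incongruent", "flanker_effect", "accuracy",
    "pct_3mad_congruent", "pct_3mad_incongruent",
    "pct_incorrect_congruent", "pct_incorrect_incongruent",
    "n_valid_congruent", "n_valid_incongruent"
  )]
  attr(out, "dropped") <- as.data.frame(dropped)
  out
}

#' Apply the per-session accuracy inclusion criterion
#'
#' A participant is retained iff accuracy is at least `min_accuracy` in
#' *both* sessions (the rule excludes accuracies strictly below the cut, so
#' exactly 60% is retained). Participants missing a session are flagged
#' `incomplete` and excluded.
#'
#' @param scores Output of [score_participants()] covering both sessions.
#' @param min_accuracy Accuracy cut-point (default `0.60`).
#' @return A list with `retained` (character vector of participant ids) and
#'   `report` (one row per participant: per-session accuracies and a
#'   `status` of `retained`, `excluded_accuracy`, or `incomplete`).
#' @export
exclude_participants <- function(scores, min_accuracy = 0.60) {
  dt <- as.data.table(scores)
  wide <- dcast(dt, participant ~ session, value.var = "accuracy")
  ses_cols <- intersect(c("1", "2"), names(wide))
  for (s in setdiff(c("1", "2"), ses_cols)) wide[, (s) := NA_real_]
  setnames(wide, c("1", "2"), c("accuracy_s1", "accuracy_s2"))
  wide[, status := ifelse(
    is.na(accuracy_s1) | is.na(accuracy_s2), "incomplete",
    ifelse(accuracy_s1 >= min_accuracy & accuracy_s2 >= min_accuracy,
           "retained", "excluded_accuracy")
  )]
  report <- as.data.frame(wide[order(participant)])
  list(
    retained = report$participant[report$status == "retained"],
    report = report
  )
}

#' Group-level descriptives of flanker measures
#'
#' Per group x session: medians of the per-condition exclusion percentages,
#' means and SDs of the condition mean RTs and of the flanker effect, and
#' the Pearson correlation between participants' congruent and incongruent
#' mean RTs. With a single participant the SDs and correlation are `NA`.
#'
#' @param scores Output of [score_participants()].
#' @return A `data.frame`, one row per group x session.
#' @export
group_descriptives <- function(scores) {
  dt <- as.data.table(scores)
  res <- dt[, list(
    n = .N,
    median_pct_3mad_congruent = median(pct_3mad_congruent),
    median_pct_3mad_incongruent = median(pct_3mad_incongruent),
    median_pct_incorrect_congruent = median(pct_incorrect_congruent),
    median_pct_incorrect_incongruent = median(pct_incorrect_incongruent),
    mean_rt_congruent = mean(mean_rt_congruent),
    mean_rt_incongruent = mean(mean_rt_incongruent),
    sd_rt_congruent = if (.N > 1L) sd(mean_rt_congruent) else NA_real_,
    sd_rt_incongruent = if (.N > 1L) sd(mean_rt_incongruent) else NA_real_,
    cor_congruent_incongruent =
      if (.N > 1L) cor(mean_rt_congruent, mean_rt_incongruent) else NA_real_,
    mean_flanker_effect = mean(flanker_effect),
    sd_flanker_effect = if (.N > 1L) sd(flanker_effect) else NA_real_
  ), by = .(group, session)]
  as.data.frame(res[order(group, session)])
}

# validate a trial table and return a data.table copy
check_trials <- function(trials) {
  need <- c("participant", "session", "block", "condition", "rt_ms", "correct")
  missing <- setdiff(need, names(trials))
  if (length(missing)) {
    stopf("trial table lacks columns: %s", paste(missing, collapse = ", "))
  }
  dt <- as.data.table(trials)
  if (!"group" %in% names(dt)) dt[, group := "all"]
  dt
}
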