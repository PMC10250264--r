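#' Specify a split-half resampling scheme
#'
#' Captures how trials are split into halves and how the resulting
#' coefficients are combined.
#'
#' * `method = "permutated"`: within each stratum the valid trials are
#'   partitioned at random into two disjoint halves (sizes differ by at most
#'   one; the odd trial lands in a half at random).
#' * `method = "monte_carlo"`: each half is an independent sample *with
#'   replacement* of `ceiling(m/2)` trials per stratum (halves may share
#'   trials, which is what inflates Monte Carlo estimates for short tasks);
#'   `mc_half_size = "full"` draws full-length halves instead.
#'
#' Per replication, half scores are correlated across participants
#' (Pearson), optionally stepped up to full length with the Spearman-Brown
#' formula at `n_ratio = 2`, and the replications are combined by a simple
#' mean or by back-transforming the mean Fisher z.
#'
#' @param method Splitting method.
#' @param stratify_by Trial factors defining the strata (default congruency
#'   crossed with target direction).
#' @param n_replications Number of random splits.
#' @param adjust `"spearman_brown"` (default) or `"none"`.
#' @param aggregate `"mean"` (default) or `"fisher_mean"`.
#' @param session Which session's trials to split (default 1).
#' @param mc_half_size `"half"` (default) or `"full"`; Monte Carlo only.
#' @param seed Integer seed for the splits.
#' @return An object of class `split_spec`.
#' @export
split_spec <- function(method = c("permutated", "monte_carlo"),
                       stratify_by = c("condition", "direction"),
                       n_replications = 10000,
                       adjust = c("spearman_brown", "none"),
                       aggregate = c("mean", "fisher_mean"),
                       session = 1,
                       mc_half_size = c("half", "full"),
                       seed = 1) {
  spec <- list(
    method = match.arg(method),
    stratify_by = stratify_by,
    n_replications = check_count(n_replications, "n_replications", lower = 1L),
    adjust = match.arg(adjust),
    aggregate = match.arg(aggregate),
    session = check_count(session, "session", lower = 1L),
    mc_half_size = match.arg(mc_half_size),
    seed = check_count(seed, "seed")
  )
  structure(spec, class = "split_spec")
}

#' @export
print.split_spec <- function(x, ...) {
  cat(sprintf(
    "<split_spec> %s, %d replications, strata: %s, adjust: %s, aggregate: %s, session %d, seed %d\n",
    x$method, x$n_replications, paste(x$stratify_by, collapse = " x "),
    x$adjust, x$aggregate, x$session, x$seed))
  invisible(x)
}

#' Split one participant-session's trials into two scored halves
#'
#' Applies a single split (per [split_spec()]) to the valid trials of one
#' participant in one session and scores each half: per-condition mean RT
#' and the flanker effect. With permutated splitting the halves are disjoint
#' and their union is the valid trial set; with Monte Carlo splitting the
#' halves are independent with-replacement draws and may overlap. A stratum
#' with fewer than 2 valid trials under permutated splitting yields `NA`
#' half scores (callers skip and count such replications).
#'
#' @param trials Exclusion-flagged trials of a single participant-session.
#' @param spec A [split_spec()]; its `seed` governs the split.
#' @return List with `half_a` and `half_b`, each a list holding
#'   `mean_rt_congruent`, `mean_rt_incongruent`, `flanker_effect`.
#' @export
split_once <- function(trials, spec = split_spec()) {
  stopifnot(inherits(spec, "split_spec"))
  if (!"excluded_reason" %in% names(trials)) {
    trials <- flag_rt_exclusions(trials)
  }
  dt <- as.data.table(trials)
  if (length(unique(dt$participant)) != 1L ||
      length(unique(dt$session)) != 1L) {
    stopf("split_once() expects trials of a single participant-session")
  }
  valid <- dt[block != "practice" & excluded_reason == "none"]
  valid[, valid := 1]
  fr <- resample_frame(valid, spec$stratify_by)
  if (spec$method == "permutated" && any(fr$grp_size < 2L)) {
    warnf("a stratum has fewer than 2 valid trials; half scores are NA")
    na_half <- list(mean_rt_congruent = NA_real_,
                    mean_rt_incongruent = NA_real_,
                    flanker_effect = NA_real_)
    return(list(half_a = na_half, half_b = na_half))
  }
  hs <- with_seed(spec$seed, {
    engine_halves(fr, 0L, 1L, method_code(spec$method),
                  spec$mc_half_size == "full")
  })
  half <- function(s, c) {
    con <- !fr$g_inc
    mc <- sum(s[con, 1]) / sum(c[con, 1])
    mi <- sum(s[!con, 1]) / sum(c[!con, 1])
    list(mean_rt_congruent = mc, mean_rt_incongruent = mi,
         flanker_effect = mi - mc)
  }
  list(half_a = half(hs$sum_a, hs$cnt_a), half_b = half(hs$sum_b, hs$cnt_b))
}

method_code <- function(method) {
  switch(method, subsample = 0L, permutated = 1L, monte_carlo = 2L)
}

#' Split-half reliability of the flanker effect
#'
#' Estimates split-half reliability by repeated random splitting: per
#' replication, every participant's valid session trials are split per
#' stratum (see [split_spec()]), each half is scored, and the half effects
#' are correlated across participants (Pearson); the coefficient is
#' optionally Spearman-Brown adjusted to full length (`n_ratio = 2`) and
#' replications are aggregated by the spec's rule. Replications with zero
#' between-participant variance, or where fewer than 3 participants have
#' scorable halves, are dropped and counted.
#'
#' @param trials Trial table for one group (exclusion flags are applied with
#'   defaults if absent); only the spec's session is used.
#' @param spec A [split_spec()].
#' @return A [reliability_estimate()] (`source = "split_half"`) whose `meta`
#'   records the method, replication count, aggregation, adjustment, session,
#'   seed and the number of dropped replications.
#' @examples
#' trials <- simulate_flanker(flanker_params(seed = 5, n_participants = 20))
#' splithalf_reliability(trials, split_spec(n_replications = 50, seed = 2))
#' @export
splithalf_reliability <- function(trials, spec = split_spec()) {
  stopifnot(inherits(spec, "split_spec"))
  if (!"excluded_reason" %in% names(trials)) {
    trials <- flag_rt_exclusions(trials)
  }
  dt <- as.data.table(trials)
  valid <- dt[block != "practice" & excluded_reason == "none" &
                session == spec$session]
  if (!nrow(valid)) stopf("no valid trials in session %d", spec$session)
  valid[, valid := 1]
  fr <- resample_frame(valid, spec$stratify_by)
  if (fr$n_participants < 3L) stopf("need at least 3 participants")
  hs <- with_seed(spec$seed, {
    engine_halves(fr, 0L, spec$n_replications, method_code(spec$method),
                  spec$mc_half_size == "full")
  })
  ea <- half_effects(hs$sum_a, hs$cnt_a, fr)
  eb <- half_effects(hs$sum_b, hs$cnt_b, fr)
  r <- col_cors(ea, eb)
  if (spec$adjust == "spearman_brown") r <- 2 * r / (1 + r)
  dropped <- sum(!is.finite(r))
  reliability_estimate(
    aggregate_coefs(r, spec$aggregate),
    kind = "pearson",
    n_participants = fr$n_participants,
    source = "split_half",
    meta = list(method = spec$method, n_replications = spec$n_replications,
                adjust = spec$adjust, aggregate = spec$aggregate,
                session = spec$session, seed = spec$seed,
                n_dropped_replications = dropped)
  )
}
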