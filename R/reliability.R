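#' Reliability estimate container
#'
#' Light S3 wrapper recording a reliability coefficient together with its
#' type, sample size and provenance (how it was obtained).
#'
#' @param value Coefficient in `[-1, 1]` (possibly `NaN` when undefined).
#' @param kind `"icc_abs_agreement"` or `"pearson"`.
#' @param n_participants Number of paired observations.
#' @param source `"test_retest"` or `"split_half"`.
#' @param meta Free-form provenance list (splitting method, aggregation, ...).
#' @return An object of class `reliability_estimate`.
#' @export
reliability_estimate <- function(value, kind, n_participants, source,
                                 meta = list()) {
  structure(
    list(value = value, kind = kind, n_participants = n_participants,
         source = source, meta = meta),
    class = "reliability_estimate"
  )
}

#' @export
print.reliability_estimate <- function(x, ...) {
  extra <- if (length(x$meta)) {
    paste0("; ", paste(names(x$meta), unlist(lapply(x$meta, format)),
                       sep = " = ", collapse = ", "))
  } else ""
  cat(sprintf("<reliability_estimate> %s (%s) = %.4f, n = %d%s\n",
              x$source, x$kind, x$value, x$n_participants, extra))
  invisible(x)
}

# fast numeric core: single-measure absolute-agreement ICC from a two-way
# ANOVA decomposition, k raters = columns of cbind(x1, x2, ...)
icc_a1_value <- function(x1, x2) {
  n <- length(x1)
  k <- 2
  m_i <- (x1 + x2) / 2
  c1 <- mean(x1); c2 <- mean(x2)
  g <- (c1 + c2) / 2
  msr <- k * sum((m_i - g)^2) / (n - 1)
  msc <- n * ((c1 - g)^2 + (c2 - g)^2)
  mse <- (sum((x1 - m_i - c1 + g)^2) + sum((x2 - m_i - c2 + g)^2)) /
    ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

#' Test-retest intraclass correlation, ICC(A,1)
#'
#' Single-measure intraclass correlation for absolute agreement under a
#' two-way model, computed from the ANOVA mean squares
#' `(MS_R - MS_E) / (MS_R + (k-1) MS_E + (k/n)(MS_C - MS_E))` with `k = 2`
#' sessions. Unlike a Pearson correlation it penalizes mean shifts between
#' sessions, which is why it is the stricter test-retest coefficient.
#'
#' @param x1,x2 Paired score vectors (same participants, sessions 1 and 2).
#' @return A [reliability_estimate()] of kind `"icc_abs_agreement"`.
#' @examples
#' set.seed(1)
#' a <- rnorm(30); b <- a + rnorm(30, sd = 0.5)
#' icc_absolute_agreement(a, b)
#' @export
icc_absolute_agreement <- function(x1, x2) {
  check_paired(x1, x2)
  if (var(x1) + var(x2) < 1e-24 || var((x1 + x2) / 2) < 1e-24) {
    warnf("zero between-participant variance; ICC undefined")
    v <- NaN
  } else {
    v <- icc_a1_value(x1, x2)
  }
  reliability_estimate(v, "icc_abs_agreement", length(x1), "test_retest")
}

#' Test-retest Pearson correlation
#'
#' @inheritParams icc_absolute_agreement
#' @return A [reliability_estimate()] of kind `"pearson"`.
#' @export
pearson_reliability <- function(x1, x2) {
  check_paired(x1, x2)
  if (var(x1) < 1e-24 || var(x2) < 1e-24) {
    warnf("zero variance in a session; Pearson correlation undefined")
    v <- NaN
  } else {
    v <- cor(x1, x2)
  }
  reliability_estimate(v, "pearson", length(x1), "test_retest")
}

check_paired <- function(x1, x2) {
  if (length(x1) != length(x2)) stopf("x1 and x2 must have equal length")
  if (length(x1) < 3L) stopf("need at least 3 paired observations")
  if (anyNA(x1) || anyNA(x2)) stopf("missing values in scores")
  invisible(TRUE)
}

#' Fisher z-transform and its inverse
#'
#' `fisher_z()` is `atanh(r)`; `fisher_z_inverse()` is `tanh(z)`. Both are
#' vectorized; correlations with `|r| >= 1` are rejected (the transform
#' diverges).
#'
#' @param r Correlation(s) in `(-1, 1)`.
#' @param z Fisher z value(s).
#' @return Numeric vector.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1)) stopf("|r| must be < 1 for the Fisher z-transform")
  atanh(r)
}

#' @rdname fisher_z
#' @export
fisher_z_inverse <- function(z) tanh(z)

#' Compare two independent correlations (Fisher z-test)
#'
#' Tests the difference between two correlations observed in independent
#' samples. The effect size is Cohen's `q = atanh(r1) - atanh(r2)`; the test
#' statistic is `q / sqrt(1/(n1-3) + 1/(n2-3))`, referred to the standard
#' normal.
#'
#' @param r1,r2 Correlations (`|r| < 1`).
#' @param n1,n2 Sample sizes (`>= 4`).
#' @param alternative `"greater"` (H1: rho1 > rho2), `"less"`, or
#'   `"two.sided"`.
#' @return List with `q` (Cohen's q), `z_stat`, `p`, and `alternative`.
#' @examples
#' compare_correlations(0.61, 153, 0.55, 153, alternative = "greater")
#' @export
compare_correlations <- function(r1, n1, r2, n2,
                                 alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  if (abs(r1) >= 1 || abs(r2) >= 1) stopf("|r| must be < 1")
  n1 <- check_count(n1, "n1", lower = 4L)
  n2 <- check_count(n2, "n2", lower = 4L)
  q <- atanh(r1) - atanh(r2)
  se <- sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  z <- q / se
  p <- switch(alternative,
    greater = pnorm(z, lower.tail = FALSE),
    less = pnorm(z, lower.tail = TRUE),
    two.sided = 2 * pnorm(abs(z), lower.tail = FALSE)
  )
  list(q = q, z_stat = z, p = p, alternative = alternative)
}

#' Per-group sample size for the one-sided Fisher z-test
#'
#' Smallest equal group size `n` giving at least the target power for a
#' one-sided two-sample test on Fisher z-transformed correlations with
#' effect size `q`: `n = ceil(2 * ((z_{1-alpha} + z_{power}) / q)^2 + 3)`.
#'
#' @param q_effect Cohen's q under the alternative (`> 0`).
#' @param alpha One-sided type-1 error rate.
#' @param power Target power.
#' @return Integer sample size per group.
#' @examples
#' required_n_per_group(q_effect = 0.3, alpha = 0.05, power = 0.8)
#' @export
required_n_per_group <- function(q_effect, alpha = 0.05, power = 0.8) {
  q_effect <- check_number(q_effect, "q_effect", lower = 1e-12)
  alpha <- check_number(alpha, "alpha", lower = 1e-12, upper = 1 - 1e-12)
  power <- check_number(power, "power", lower = 1e-12, upper = 1 - 1e-12)
  as.integer(ceiling(2 * ((qnorm(1 - alpha) + qnorm(power)) / q_effect)^2 + 3))
}

#' Spearman-Brown prophecy formula and its length inverse
#'
#' `spearman_brown()` predicts the reliability of a test whose length is
#' `n_ratio` times the full length from the full-length reliability:
#' `rho* = n * rho / (1 + (n - 1) * rho)`. `sb_required_length()` inverts it,
#' returning the smallest integer trial count `t` such that
#' `spearman_brown(rho_full, t / full_trials) >= rho_target`.
#'
#' @param rho_full Full-length reliability in `[0, 1]` (strictly below 1 for
#'   the inverse).
#' @param n_ratio Length ratio (`> 0`); vectorized.
#' @param rho_target Target reliability (must be `< 1` when `rho_full < 1`).
#' @param full_trials Trial count defining full length (`>= 1`).
#' @return `spearman_brown()`: predicted reliability (vectorized);
#'   `sb_required_length()`: integer trial count.
#' @examples
#' spearman_brown(0.5, 2)               # 0.6667
#' sb_required_length(0.61, 0.8, 320)   # 819 trials
#' @export
spearman_brown <- function(rho_full, n_ratio) {
  if (any(rho_full < 0 | rho_full > 1)) stopf("rho_full must be in [0, 1]")
  if (any(n_ratio <= 0)) stopf("n_ratio must be > 0")
  n_ratio * rho_full / (1 + (n_ratio - 1) * rho_full)
}

#' @rdname spearman_brown
#' @export
sb_required_length <- function(rho_full, rho_target, full_trials) {
  rho_full <- check_number(rho_full, "rho_full", 0, 1 - 1e-12)
  rho_target <- check_number(rho_target, "rho_target", 0, 1)
  full_trials <- check_count(full_trials, "full_trials", lower = 1L)
  if (rho_target >= 1) stopf("rho_target >= 1 is unreachable for rho_full < 1")
  if (rho_target == 0) return(1L)
  if (rho_full == 0) stopf("rho_full = 0 cannot reach a positive target")
  n_star <- rho_target * (1 - rho_full) / (rho_full * (1 - rho_target))
  t <- max(1L, as.integer(ceiling(n_star * full_trials - 1e-9)))
  while (spearman_brown(rho_full, t / full_trials) < rho_target) t <- t + 1L
  t
}

#' Leave-k-out leverage analysis of the test-retest ICC
#'
#' Assesses whether a small set of outlier participants carries the
#' reliability estimate. Participants whose flanker score has `|z| >`
#' `z_threshold` in either session are flagged (the protected pair defaults
#' to them); the z-score is computed leave-one-out, against the mean and SD
#' of the *other* participants, since an ordinary z-score is bounded by
#' roughly `sqrt(n)`. Then, `n_reps` times, `k_exclude` participants are excluded at
#' random -- never a protected one -- and the ICC(A,1) recomputed; the
#' maximum of these is compared against the ICC with the protected pair
#' itself excluded. A protected pair whose exclusion yields an ICC well above
#' every random-exclusion ICC is a high-leverage outlier pair.
#'
#' @param scores Output of [score_participants()] (one group), both sessions.
#' @param k_exclude Number of random exclusions per replication.
#' @param n_reps Number of replications.
#' @param protected_pair Participant ids never excluded at random; `NULL`
#'   (default) uses the `|z|`-flagged participants.
#' @param seed Integer seed for the random exclusions.
#' @param z_threshold Flagging threshold on the per-session z-score of the
#'   flanker effect.
#' @return List with `max_icc_without_pair`, `icc_excluding_pair`,
#'   `full_icc`, `flagged` (ids), `k_exclude`, `n_reps`.
#' @export
leverage_analysis <- function(scores, k_exclude = 2, n_reps = 10000,
                              protected_pair = NULL, seed = 1,
                              z_threshold = 15) {
  k_exclude <- check_count(k_exclude, "k_exclude")
  n_reps <- check_count(n_reps, "n_reps", lower = 1L)
  w <- effects_wide(scores)
  n <- nrow(w)
  if (n <= k_exclude + 3L) stopf("need more than k_exclude + 3 participants")
  # leave-one-out z: a plain z-score is bounded by ~sqrt(n), so extreme
  # thresholds like 15 are only reachable against the other participants'
  # mean and SD
  loo_z <- function(x) {
    vapply(seq_along(x), function(i) {
      (x[i] - mean(x[-i])) / sd(x[-i])
    }, numeric(1))
  }
  z1 <- loo_z(w$s1)
  z2 <- loo_z(w$s2)
  flagged <- w$participant[pmax(abs(z1), abs(z2)) > z_threshold]
  if (is.null(protected_pair)) protected_pair <- flagged
  protected_idx <- which(w$participant %in% protected_pair)
  candidates <- setdiff(seq_len(n), protected_idx)
  if (length(candidates) < k_exclude) {
    stopf("fewer than k_exclude non-protected participants")
  }
  full_icc <- icc_a1_value(w$s1, w$s2)
  max_icc <- with_seed(check_count(seed, "seed"), {
    best <- -Inf
    for (r in seq_len(n_reps)) {
      drop <- if (k_exclude > 0L) sample(candidates, k_exclude) else integer()
      keep <- if (length(drop)) -drop else seq_len(n)
      v <- icc_a1_value(w$s1[keep], w$s2[keep])
      if (v > best) best <- v
    }
    best
  })
  icc_wo_pair <- if (length(protected_idx)) {
    icc_a1_value(w$s1[-protected_idx], w$s2[-protected_idx])
  } else {
    full_icc
  }
  list(
    max_icc_without_pair = max_icc,
    icc_excluding_pair = icc_wo_pair,
    full_icc = full_icc,
    flagged = flagged,
    k_exclude = k_exclude,
    n_reps = n_reps
  )
}

# wide (participant, s1, s2) flanker effects from a long score table,
# complete pairs only
effects_wide <- function(scores) {
  dt <- as.data.table(scores)
  wide <- dcast(dt, participant ~ session, value.var = "flanker_effect")
  if (!all(c("1", "2") %in% names(wide))) {
    stopf("scores must contain sessions 1 and 2")
  }
  setnames(wide, c("1", "2"), c("s1", "s2"))
  as.data.frame(wide[complete.cases(wide)])
}
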