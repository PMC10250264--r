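#' Generative parameters for synthetic flanker data
#'
#' Bundles and validates the population- and trial-level parameters of the
#' synthetic flanker model. Per participant `i`, a baseline speed
#' `b_i ~ N(mu_congruent, sd_between^2)` and a congruency (flanker) effect
#' `d_i ~ N(mu_effect, sd_effect^2)` are drawn once and shared by both
#' sessions (a stable trait); `baseline_effect_cor` sets the correlation
#' between `b_i` and `d_i` (slower participants tend to show larger effects,
#' which is what makes the congruent and incongruent mean RTs correlate at
#' the 0.97-0.99 level seen in real data). A correct trial's RT is
#' `b_i + d_i * [incongruent] - session2_speedup * [session 2] + noise`,
#' where the noise is ex-Gaussian (`rnorm(0, sigma) + rexp(1/tau)`), shifted
#' by `contaminant_shift` with probability `contaminant_rate` (attentional
#' lapses that populate the slow tail cut by the 3*MAD rule). Correctness is
#' Bernoulli per condition. The last `n_outlier_participants` participants
#' draw their effect with `sd_effect * outlier_effect_sd_multiplier`, and --
#' unlike ordinary participants, whose effect is a stable trait -- redraw it
#' independently in session 2: an extreme *and unstable* score pair is what
#' gives a participant high leverage on a test-retest coefficient, the
#' scenario probed by [leverage_analysis()].
#'
#' Defaults emulate a diverse adult sample on the 2 (congruency) x 2
#' (direction) x 10 (fixation) x 4 design with 160 trials per condition per
#' session: condition mean RTs around 500-535 ms, a mean flanker effect of
#' 35 ms with a trait SD of 11.5 ms (true-score reliability about 0.6 at 160
#' trials per condition), ~0.4-1% errors, and a 3-5% slow tail
#' beyond the per-individual 3*MAD threshold.
#'
#' @param seed Integer seed (mandatory); governs all simulation randomness.
#' @param n_participants Number of participants.
#' @param mu_congruent Population mean congruent-trial RT (ms).
#' @param sd_between Between-participant SD of baseline speed (ms).
#' @param mu_effect Population mean flanker effect (ms).
#' @param sd_effect Between-participant (trait) SD of the flanker effect (ms).
#' @param baseline_effect_cor Correlation between baseline speed and effect.
#' @param sigma,tau Ex-Gaussian trial-noise parameters (ms).
#' @param session2_speedup Mean RT decrease in session 2, applied equally to
#'   both conditions (ms); the effect score is unaffected.
#' @param error_rate_congruent,error_rate_incongruent Per-trial error
#'   probabilities; the incongruent rate must be at least the congruent one.
#' @param contaminant_rate Probability that a trial's noise draw is shifted.
#' @param contaminant_shift Shift (ms) applied to contaminant trials.
#' @param n_outlier_participants Number of high-leverage participants.
#' @param outlier_effect_sd_multiplier Multiplier on `sd_effect` for them.
#' @return An object of class `flanker_params` (a validated named list).
#' @seealso [simulate_flanker()], [true_reliability()],
#'   [calibrate_effect_sd()]
#' @examples
#' p <- flanker_params(seed = 1)
#' p
#' true_reliability(p, trials_per_condition = 160)
#' @export
flanker_params <- function(seed,
                           n_participants = 153,
                           mu_congruent = 500,
                           sd_between = 55,
                           mu_effect = 35,
                           sd_effect = 11.5,
                           baseline_effect_cor = 0.5,
                           sigma = 70,
                           tau = 40,
                           session2_speedup = 13,
                           error_rate_congruent = 0.004,
                           error_rate_incongruent = 0.01,
                           contaminant_rate = 0.015,
                           contaminant_shift = 300,
                           n_outlier_participants = 0,
                           outlier_effect_sd_multiplier = 1) {
  p <- list(
    seed = check_count(seed, "seed"),
    n_participants = check_count(n_participants, "n_participants", lower = 1L),
    mu_congruent = check_number(mu_congruent, "mu_congruent", lower = 0),
    sd_between = check_number(sd_between, "sd_between", lower = 0),
    mu_effect = check_number(mu_effect, "mu_effect"),
    sd_effect = check_number(sd_effect, "sd_effect", lower = 0),
    baseline_effect_cor =
      check_number(baseline_effect_cor, "baseline_effect_cor", -1, 1),
    sigma = check_number(sigma, "sigma", lower = 0),
    tau = check_number(tau, "tau", lower = 0),
    session2_speedup = check_number(session2_speedup, "session2_speedup"),
    error_rate_congruent =
      check_number(error_rate_congruent, "error_rate_congruent", 0, 1),
    error_rate_incongruent =
      check_number(error_rate_incongruent, "error_rate_incongruent", 0, 1),
    contaminant_rate = check_number(contaminant_rate, "contaminant_rate", 0, 1),
    contaminant_shift = check_number(contaminant_shift, "contaminant_shift"),
    n_outlier_participants =
      check_count(n_outlier_participants, "n_outlier_participants"),
    outlier_effect_sd_multiplier =
      check_number(outlier_effect_sd_multiplier, "outlier_effect_sd_multiplier",
                   lower = 0)
  )
  if (p$error_rate_incongruent < p$error_rate_congruent) {
    stopf("error_rate_incongruent must be >= error_rate_congruent")
  }
  if (p$n_outlier_participants > p$n_participants) {
    stopf("n_outlier_participants cannot exceed n_participants")
  }
  structure(p, class = "flanker_params")
}

#' @export
print.flanker_params <- function(x, ...) {
  cat("<flanker_params>\n")
  cat(sprintf("  %d participants; baseline %g (SD %g) ms; effect %g (SD %g) ms\n",
              x$n_participants, x$mu_congruent, x$sd_between,
              x$mu_effect, x$sd_effect))
  cat(sprintf("  trial noise exGaussian(sigma = %g, tau = %g) ms; %g%% contaminants (+%g ms)\n",
              x$sigma, x$tau, 100 * x$contaminant_rate, x$contaminant_shift))
  cat(sprintf("  error rates %g / %g (con/inc); session-2 speedup %g ms; seed %d\n",
              x$error_rate_congruent, x$error_rate_incongruent,
              x$session2_speedup, x$seed))
  if (x$n_outlier_participants > 0) {
    cat(sprintf("  %d outlier participants (effect SD x %g)\n",
                x$n_outlier_participants, x$outlier_effect_sd_multiplier))
  }
  invisible(x)
}

# --- ex-Gaussian + contaminant mixture numerics (noise centered at 0) ------

exg_pdf <- function(x, sigma, tau) {
  if (tau < 1e-8) return(stats::dnorm(x, 0, max(sigma, 1e-12)))
  if (sigma < 1e-8) return(stats::dexp(x, rate = 1 / tau))
  exp(-log(tau) + sigma^2 / (2 * tau^2) - x / tau +
        stats::pnorm(x / sigma - sigma / tau, log.p = TRUE))
}

exg_cdf <- function(x, sigma, tau) {
  if (tau < 1e-8) return(stats::pnorm(x, 0, max(sigma, 1e-12)))
  if (sigma < 1e-8) return(stats::pexp(x, rate = 1 / tau))
  stats::pnorm(x / sigma) -
    exp(sigma^2 / (2 * tau^2) - x / tau +
          stats::pnorm(x / sigma - sigma / tau, log.p = TRUE))
}

mix_pdf <- function(x, p) {
  (1 - p$contaminant_rate) * exg_pdf(x, p$sigma, p$tau) +
    p$contaminant_rate * exg_pdf(x - p$contaminant_shift, p$sigma, p$tau)
}

mix_cdf <- function(x, p) {
  (1 - p$contaminant_rate) * exg_cdf(x, p$sigma, p$tau) +
    p$contaminant_rate * exg_cdf(x - p$contaminant_shift, p$sigma, p$tau)
}

mix_var <- function(p) {
  c <- p$contaminant_rate
  p$sigma^2 + p$tau^2 + c * (1 - c) * p$contaminant_shift^2
}

# asymptotic exclusion threshold and retained-trial moments, relative to a
# participant's baseline; the pooled (both-condition) correct-trial RT mixture
# determines the median + 3*MAD threshold, evaluated at the population mean
# effect
noise_profile <- function(p) {
  d <- p$mu_effect
  span <- 10 * max(p$sigma, 1) + 20 * max(p$tau, 1) +
    abs(p$contaminant_shift) + abs(d) + 10
  pooled_cdf <- function(x) 0.5 * mix_cdf(x, p) + 0.5 * mix_cdf(x - d, p)
  med <- stats::uniroot(function(x) pooled_cdf(x) - 0.5,
                        lower = -span, upper = span, tol = 1e-10)$root
  mad_u <- stats::uniroot(
    function(u) pooled_cdf(med + u) - pooled_cdf(med - u) - 0.5,
    lower = 1e-9, upper = 2 * span, tol = 1e-10
  )$root
  thr <- med + 3 * mad_u
  trunc_moments <- function(upper) {
    pr <- mix_cdf(upper, p)
    m1 <- stats::integrate(function(x) x * mix_pdf(x, p), -Inf, upper,
                           rel.tol = 1e-10)$value / pr
    m2 <- stats::integrate(function(x) x^2 * mix_pdf(x, p), -Inf, upper,
                           rel.tol = 1e-10)$value / pr
    list(p = pr, mean = m1, var = m2 - m1^2)
  }
  con <- trunc_moments(thr)
  inc <- trunc_moments(thr - d)   # incongruent RTs sit d higher
  list(threshold = thr, median = med, mad = mad_u, con = con, inc = inc)
}

#' Expected exclusion rates under the generative model
#'
#' Asymptotic per-condition probabilities that a correct trial exceeds the
#' per-individual median + 3*MAD threshold, computed from the noise mixture
#' (threshold taken at its large-sample value on the pooled two-condition RT
#' distribution, evaluated at the population mean effect).
#'
#' @param params A [flanker_params()] object.
#' @return Named list with `pct_3mad_congruent`, `pct_3mad_incongruent`
#'   (percentages) and the `threshold` (ms above a participant's baseline).
#' @export
expected_exclusion_rates <- function(params) {
  stopifnot(inherits(params, "flanker_params"))
  if (mix_var(params) < 1e-12) {
    return(list(pct_3mad_congruent = 0, pct_3mad_incongruent = 0,
                threshold = NA_real_))
  }
  np <- noise_profile(params)
  list(
    pct_3mad_congruent = 100 * (1 - np$con$p),
    pct_3mad_incongruent = 100 * (1 - np$inc$p),
    threshold = np$threshold
  )
}

#' Closed-form true reliability of the synthetic flanker effect
#'
#' True-score reliability of the flanker difference score at a given task
#' length under the generative model:
#' `rho(L) = T^2 / (T^2 + V_con/L_con + V_inc/L_inc)`,
#' the classical true-variance over total-variance ratio for a difference of
#' two condition means. With `adjust_for_exclusions = TRUE` (default) the
#' quantities are those of the scores the exclusion pipeline actually
#' produces: the per-condition error variances `V` are the variance of the
#' noise mixture truncated at the asymptotic median + 3*MAD threshold, the
#' effective trial counts are `L * (1 - error_rate) * P(retain)`, and the
#' true-score SD is `T = lambda * sd_effect`, where `lambda` (slightly below
#' 1) is the attenuation of the observed effect induced by the truncation --
#' a larger trait effect pushes more incongruent trials past the shared
#' threshold, shrinking the measured difference. With
#' `adjust_for_exclusions = FALSE` the raw noise-mixture variance, the
#' nominal trial count and `lambda = 1` are used (the textbook formula
#' `sd_effect^2 / (sd_effect^2 + 2 * V / L)` for equal conditions).
#'
#' @param params A [flanker_params()] object.
#' @param trials_per_condition Trials per condition (per session), `>= 1`.
#' @param adjust_for_exclusions Account for the exclusion pipeline (default
#'   `TRUE`).
#' @return A list of class `true_reliability` with fields
#'   `length_trials_per_condition` and `value` (in `[0, 1]`, monotone
#'   non-decreasing in the length).
#' @examples
#' p <- flanker_params(seed = 1, sd_effect = 15, sigma = 100, tau = 0,
#'                     error_rate_congruent = 0, error_rate_incongruent = 0,
#'                     contaminant_rate = 0)
#' # raw formula: 225 / (225 + 2 * 100^2 / 160)
#' true_reliability(p, 160, adjust_for_exclusions = FALSE)$value
#' @export
true_reliability <- function(params, trials_per_condition,
                             adjust_for_exclusions = TRUE) {
  stopifnot(inherits(params, "flanker_params"))
  L <- check_count(trials_per_condition, "trials_per_condition", lower = 1L)
  s2 <- params$sd_effect^2
  value <- if (s2 == 0) {
    0
  } else if (mix_var(params) < 1e-12) {
    1
  } else {
    lam2 <- if (adjust_for_exclusions) effect_attenuation(params)^2 else 1
    lam2 * s2 / (lam2 * s2 + error_variance(params, L, adjust_for_exclusions))
  }
  structure(
    list(length_trials_per_condition = L, value = value),
    class = "true_reliability"
  )
}

#' @export
print.true_reliability <- function(x, ...) {
  cat(sprintf("True reliability at %d trials/condition: %.4f\n",
              x$length_trials_per_condition, x$value))
  invisible(x)
}

# expected observed effect for a participant with trait effect d: the 3*MAD
# truncation clips the incongruent tail harder the larger d is, so the
# observed effect is d plus a (negative, d-dependent) truncation offset
observed_effect_mean <- function(params, d) {
  p2 <- params
  p2$mu_effect <- d
  np <- noise_profile(p2)
  d + np$inc$mean - np$con$mean
}

# local slope of observed vs. trait effect at the population mean (delta
# method); this is the attenuation factor lambda of the true-score SD
effect_attenuation <- function(params) {
  h <- max(1, abs(params$mu_effect) * 0.05)
  (observed_effect_mean(params, params$mu_effect + h) -
     observed_effect_mean(params, params$mu_effect - h)) / (2 * h)
}

# error variance of the session flanker effect at L trials/condition
error_variance <- function(params, L, adjust_for_exclusions = TRUE) {
  if (mix_var(params) < 1e-12) return(0)
  if (!adjust_for_exclusions) {
    return(2 * mix_var(params) / L)
  }
  np <- noise_profile(params)
  l_con <- L * (1 - params$error_rate_congruent) * np$con$p
  l_inc <- L * (1 - params$error_rate_incongruent) * np$inc$p
  np$con$var / l_con + np$inc$var / l_inc
}

#' Calibrate the trait SD of the effect to a target true reliability
#'
#' Solves `sd_effect` so that [true_reliability()] at the stated task length
#' equals `target`:
#' `sd_effect^2 = target / (1 - target) * V_err(L) / lambda^2`, where
#' `V_err` is the error variance of the flanker effect under the exclusion
#' pipeline and `lambda` the truncation attenuation of the trait (see
#' [true_reliability()]). All other parameters are left untouched.
#'
#' @param params A [flanker_params()] object.
#' @param target Target reliability in `(0, 1)`.
#' @param trials_per_condition Task length at which the target holds.
#' @param adjust_for_exclusions Passed to the error-variance computation.
#' @return A `flanker_params` object with `sd_effect` replaced.
#' @examples
#' p <- calibrate_effect_sd(flanker_params(seed = 1), target = 0.6)
#' true_reliability(p, 160)$value
#' @export
calibrate_effect_sd <- function(params, target, trials_per_condition = 160,
                                adjust_for_exclusions = TRUE) {
  stopifnot(inherits(params, "flanker_params"))
  target <- check_number(target, "target", lower = 1e-6, upper = 1 - 1e-6)
  v <- error_variance(params, check_count(trials_per_condition,
                                          "trials_per_condition", 1L),
                      adjust_for_exclusions)
  if (v <= 0) stopf("trial noise is zero; any sd_effect > 0 gives reliability 1")
  lam <- if (adjust_for_exclusions) effect_attenuation(params) else 1
  params$sd_effect <- sqrt(target / (1 - target) * v) / lam
  params
}
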