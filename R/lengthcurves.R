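#' Stratified trial subsampling for one participant-session
#'
#' Draws a shortened task of `total_length` trials from one
#' participant-session by sampling `total_length / 4` trials without
#' replacement from each congruency x direction stratum. At the full length
#' the result is the original trial set in randomized order.
#'
#' @param trials Trials of a single participant-session.
#' @param total_length Total trial count; must be divisible by 4 (balanced
#'   across the 2 x 2 strata).
#' @param seed Integer seed.
#' @param stratify_by Stratification factors (default condition x direction).
#' @return A subset of `trials` (rows in randomized order).
#' @examples
#' trials <- simulate_flanker(flanker_params(seed = 4, n_participants = 2))
#' one <- trials[trials$participant == "P0001" & trials$session == 1 &
#'               trials$block != "practice", ]
#' nrow(subsample_trials(one, 40, seed = 9))
#' @export
subsample_trials <- function(trials, total_length, seed,
                             stratify_by = c("condition", "direction")) {
  total_length <- check_count(total_length, "total_length", lower = 4L)
  if (total_length %% 4L != 0L) {
    stopf("total_length must be divisible by 4, got %d", total_length)
  }
  dt <- as.data.table(trials)
  if (length(unique(dt$participant)) != 1L ||
      length(unique(dt$session)) != 1L) {
    stopf("subsample_trials() expects trials of a single participant-session")
  }
  k <- total_length %/% 4L
  dt[, stratum := do.call(paste, c(.SD, sep = "|")), .SDcols = stratify_by]
  sizes <- dt[, .N, by = stratum]
  if (any(sizes$N < k)) {
    stopf("stratum %s has %d trials; %d requested",
          sizes$stratum[which.min(sizes$N)], min(sizes$N), k)
  }
  picked <- with_seed(check_count(seed, "seed"), {
    rows <- dt[, list(row = .I[sample.int(.N, k)]), by = stratum]$row
    sample(rows)
  })
  out <- as.data.frame(dt[picked])
  out$stratum <- NULL
  out
}

#' Reliability as a function of task length
#'
#' Estimates a reliability coefficient for shortened tasks constructed by
#' stratified trial subsampling, at each requested length. Per length and
#' replication, `total_length / 4` trials per stratum are drawn without
#' replacement for every participant; then the coefficient is
#'
#' * `"test_retest"`: the Pearson correlation across participants between
#'   session-1 and session-2 flanker effects, with independent subsamples
#'   drawn per session;
#' * `"permutated"` / `"monte_carlo"`: a single split of the subsample (per
#'   the corresponding [split_spec()] method) on the spec's session,
#'   correlated across participants and (by default) Spearman-Brown
#'   adjusted.
#'
#' Replication coefficients are aggregated per length by a simple mean
#' (Fisher-z mean optional). Subsampling operates on all main trials; trials
#' flagged by the exclusion rules simply never contribute to a mean, exactly
#' as when the shortened task had been administered.
#'
#' @param trials Trial table for one group (both sessions for
#'   `"test_retest"`).
#' @param method Coefficient type per length.
#' @param lengths Total trial counts (default `seq(40, 320, by = 40)`).
#' @param n_replications Replications per length.
#' @param spec A [split_spec()] supplying strata, session, adjustment,
#'   aggregation and seed (its `method` is ignored in favor of `method`).
#' @param full_length Length treated as full task length by the
#'   Spearman-Brown fit (default the maximum of `lengths`).
#' @return An object of class `length_curve`: a list with `lengths`,
#'   `estimates`, `method`, `n_replications`, `full_length`, and room for
#'   the fit fields `best_fit_rho` / `sse` set by
#'   [fit_spearman_brown_curve()].
#' @export
reliability_curve <- function(trials,
                              method = c("test_retest", "permutated",
                                         "monte_carlo"),
                              lengths = seq(40L, 320L, by = 40L),
                              n_replications = 10000,
                              spec = split_spec(),
                              full_length = NULL) {
  method <- match.arg(method)
  n_replications <- check_count(n_replications, "n_replications", lower = 1L)
  lengths <- as.integer(sort(unique(lengths)))
  if (any(lengths %% 4L != 0L)) stopf("all lengths must be divisible by 4")
  if (!"excluded_reason" %in% names(trials)) {
    trials <- flag_rt_exclusions(trials)
  }
  dt <- as.data.table(trials)
  main <- dt[block != "practice"]
  main[, valid := as.numeric(excluded_reason == "none")]
  estimates <- vapply(lengths, function(L) {
    k <- L %/% 4L
    seed_l <- derive_seed(spec$seed, paste0(method, "_len", L))
    r <- if (method == "test_retest") {
      e1 <- session_subsample_effects(main[session == 1], k, spec,
                                      n_replications,
                                      derive_seed(seed_l, "s1"))
      e2 <- session_subsample_effects(main[session == 2], k, spec,
                                      n_replications,
                                      derive_seed(seed_l, "s2"))
      if (!identical(rownames(e1), rownames(e2))) {
        common <- intersect(rownames(e1), rownames(e2))
        e1 <- e1[common, , drop = FALSE]
        e2 <- e2[common, , drop = FALSE]
      }
      col_cors(e1, e2)
    } else {
      fr <- resample_frame(main[session == spec$session], spec$stratify_by)
      hs <- with_seed(seed_l, {
        engine_halves(fr, k, n_replications, method_code(method),
                      spec$mc_half_size == "full")
      })
      r1 <- col_cors(half_effects(hs$sum_a, hs$cnt_a, fr),
                     half_effects(hs$sum_b, hs$cnt_b, fr))
      if (spec$adjust == "spearman_brown") r1 <- 2 * r1 / (1 + r1) else r1
    }
    aggregate_coefs(r, spec$aggregate)
  }, numeric(1))
  structure(
    list(lengths = lengths, estimates = estimates, method = method,
         n_replications = n_replications,
         full_length = as.integer(full_length %||% max(lengths)),
         best_fit_rho = NA_real_, sse = NA_real_),
    class = "length_curve"
  )
}

# per-replication flanker effects from stratified subsamples of one session
session_subsample_effects <- function(session_trials, k, spec, n_reps, seed) {
  fr <- resample_frame(session_trials, spec$stratify_by)
  hs <- with_seed(seed, engine_halves(fr, k, n_reps, 0L))
  e <- half_effects(hs$sum_a, hs$cnt_a, fr)
  rownames(e) <- as.character(fr$pid_levels)
  e
}

#' @export
print.length_curve <- function(x, ...) {
  cat(sprintf("<length_curve> %s, %d replications/length\n",
              x$method, x$n_replications))
  print(data.frame(length = x$lengths, estimate = round(x$estimates, 4)),
        row.names = FALSE)
  if (is.finite(x$best_fit_rho)) {
    cat(sprintf("best-fitting Spearman-Brown curve: rho(full = %d) = %.2f (sse = %.5g)\n",
                x$full_length, x$best_fit_rho, x$sse))
  }
  invisible(x)
}

#' @export
as.data.frame.length_curve <- function(x, ...) {
  data.frame(method = x$method, length = x$lengths, estimate = x$estimates)
}

#' Fit a Spearman-Brown prophecy curve to a reliability-by-length curve
#'
#' Evaluates the 101 candidate full-length reliabilities 0.00, 0.01, ...,
#' 1.00: each candidate `rho` predicts, via the prophecy formula, the
#' reliability at every observed length `L` as
#' `spearman_brown(rho, L / full_length)`. The best-fitting candidate
#' minimizes the sum of squared differences between observed and predicted
#' values over lengths; ties break toward the smaller `rho`.
#'
#' @param curve A `length_curve` from [reliability_curve()] (at least 2
#'   lengths).
#' @return The curve with `best_fit_rho` and `sse` filled in, plus a
#'   `grid_sse` attribute holding the 101 candidate SSEs.
#' @examples
#' cv <- structure(list(lengths = seq(40, 320, 40),
#'                      estimates = spearman_brown(0.61, seq(40, 320, 40) / 320),
#'                      method = "test_retest", n_replications = 0,
#'                      full_length = 320L, best_fit_rho = NA_real_,
#'                      sse = NA_real_), class = "length_curve")
#' fit_spearman_brown_curve(cv)$best_fit_rho  # 0.61
#' @export
fit_spearman_brown_curve <- function(curve) {
  stopifnot(inherits(curve, "length_curve"))
  if (length(curve$lengths) < 2L) stopf("curve needs at least 2 lengths")
  grid <- seq(0, 100L) / 100
  ratios <- curve$lengths / curve$full_length
  sse <- vapply(grid, function(rho) {
    sum((curve$estimates - spearman_brown(rho, ratios))^2)
  }, numeric(1))
  best <- which.min(sse)  # first minimum = smallest rho on the ascending grid
  curve$best_fit_rho <- grid[best]
  curve$sse <- sse[best]
  attr(curve, "grid_sse") <- sse
  curve
}

#' Plot a reliability-by-length curve with its Spearman-Brown fit
#'
#' @param x A `length_curve` (fit first with [fit_spearman_brown_curve()] to
#'   overlay the prophecy curve).
#' @param ... Unused.
#' @return A ggplot object (requires the ggplot2 package).
#' @export
plot.length_curve <- function(x, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stopf("plotting needs the ggplot2 package")
  }
  df <- as.data.frame(x)
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = length, y = estimate)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(linetype = "dashed") +
    ggplot2::labs(x = "trials", y = "reliability estimate",
                  title = sprintf("%s reliability by task length", x$method)) +
    ggplot2::ylim(0, 1)
  if (is.finite(x$best_fit_rho)) {
    lens <- seq(min(df$length), max(df$length), length.out = 200)
    fit <- data.frame(length = lens,
                      estimate = spearman_brown(x$best_fit_rho,
                                                lens / x$full_length))
    gg <- gg + ggplot2::geom_line(data = fit, color = "grey40")
  }
  gg
}
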