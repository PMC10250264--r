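#' Simulate a two-session trial-level flanker dataset
#'
#' Draws a complete synthetic dataset for the two-session flanker design:
#' per participant, a stable baseline speed and flanker effect (shared by
#' both sessions), then per session a freshly shuffled schedule (8 practice +
#' 2 x 160 main trials) with ex-Gaussian trial noise, occasional contaminant
#' (lapse) trials, per-condition error rates, and an overall session-2
#' speed-up. See [flanker_params()] for the model. Practice trials carry RTs
#' but are flagged and never scored downstream.
#'
#' @param params A [flanker_params()] object; `params$seed` makes the output
#'   fully reproducible (same params, same dataset, bit for bit).
#' @param group Group label written to the `group` column.
#' @return A `data.frame`, one row per trial, with columns `participant`,
#'   `group`, `session`, `block`, `trial`, `condition`, `direction`,
#'   `fixation_ms`, `rt_ms`, `correct`.
#' @examples
#' trials <- simulate_flanker(flanker_params(seed = 7, n_participants = 4))
#' head(trials)
#' @export
simulate_flanker <- function(params, group = "synthetic") {
  stopifnot(inherits(params, "flanker_params"))
  if (params$n_participants < 2L) {
    stopf("n_participants must be >= 2 to simulate a dataset")
  }
  p <- params
  n <- p$n_participants
  with_seed(p$seed, {
    zb <- rnorm(n)
    zd <- rnorm(n)
    zd2 <- rnorm(n)  # used only by outlier participants (session-2 redraw)
    r <- p$baseline_effect_cor
    sd_eff <- rep(p$sd_effect, n)
    outlier <- rep(FALSE, n)
    if (p$n_outlier_participants > 0L) {
      idx <- seq(n - p$n_outlier_participants + 1L, n)
      sd_eff[idx] <- sd_eff[idx] * p$outlier_effect_sd_multiplier
      outlier[idx] <- TRUE
    }
    baseline <- p$mu_congruent + p$sd_between * zb
    effect_s1 <- p$mu_effect + sd_eff * (r * zb + sqrt(1 - r^2) * zd)
    # ordinary participants carry a stable trait; high-leverage outliers
    # redraw their (inflated) effect in session 2, which is what lets a
    # single pair wreck a test-retest coefficient
    effect_s2 <- ifelse(outlier,
                        p$mu_effect + sd_eff * (r * zb + sqrt(1 - r^2) * zd2),
                        effect_s1)

    per <- vector("list", 2L * n)
    ids <- sprintf("P%04d", seq_len(n))
    k <- 0L
    for (i in seq_len(n)) {
      for (s in 1:2) {
        sched <- schedule_draw()
        sched$participant <- ids[i]
        sched$session <- s
        k <- k + 1L
        per[[k]] <- sched
      }
    }
    trials <- do.call(rbind, per)

    i <- match(trials$participant, ids)
    inc <- trials$condition == "incongruent"
    eff <- ifelse(trials$session == 2L, effect_s2[i], effect_s1[i])
    base_rt <- baseline[i] + ifelse(inc, eff, 0) -
      ifelse(trials$session == 2L, p$session2_speedup, 0)
    m <- nrow(trials)
    noise <- rnorm(m, 0, p$sigma)
    if (p$tau > 0) noise <- noise + rexp(m, rate = 1 / p$tau)
    contaminated <- runif(m) < p$contaminant_rate
    noise[contaminated] <- noise[contaminated] + p$contaminant_shift
    err_rate <- ifelse(inc, p$error_rate_incongruent, p$error_rate_congruent)
    correct <- runif(m) >= err_rate

    data.frame(
      participant = trials$participant,
      group = group,
      session = trials$session,
      block = trials$block,
      trial = trials$trial,
      condition = trials$condition,
      direction = trials$direction,
      fixation_ms = trials$fixation_ms,
      rt_ms = pmax(base_rt + noise, 1),
      correct = correct,
      stringsAsFactors = FALSE
    )
  })
}

# schedule built from the *current* RNG stream (shared by make_schedule and
# simulate_flanker so one master seed drives everything)
schedule_draw <- function() {
  fixations <- fixation_durations()
  cells <- expand.grid(
    direction = c("left", "right"),
    condition = c("congruent", "incongruent"),
    fixation_ms = fixations,
    stringsAsFactors = FALSE
  )
  practice <- expand.grid(
    direction = c("left", "right"),
    condition = c("congruent", "incongruent"),
    stringsAsFactors = FALSE
  )
  prac <- practice[rep(seq_len(nrow(practice)), each = 2L), ]
  prac$fixation_ms <- sample(fixations, nrow(prac), replace = TRUE)
  prac <- prac[sample.int(nrow(prac)), ]
  prac$block <- "practice"
  blocks <- lapply(c("main1", "main2"), function(b) {
    mblk <- cells[rep(seq_len(nrow(cells)), times = 4L), ]
    mblk <- mblk[sample.int(nrow(mblk)), ]
    mblk$block <- b
    mblk
  })
  out <- rbind(prac, blocks[[1L]], blocks[[2L]])
  rownames(out) <- NULL
  out$trial <- seq_len(nrow(out))
  out[, c("block", "trial", "condition", "direction", "fixation_ms")]
}

#' Write / read trial-level flanker data as long-format CSV
#'
#' The on-disk dialect is one row per trial with header
#' `participant,group,session,block,trial,condition,direction,fixation_ms,rt_ms,correct`.
#' `read_trials()` validates structure and values and reports offending row
#' numbers.
#'
#' @param trials A trial-level `data.frame` as produced by
#'   [simulate_flanker()].
#' @param path File path.
#' @return `write_trials()` returns `path` invisibly; `read_trials()` returns
#'   a validated `data.frame`.
#' @export
write_trials <- function(trials, path) {
  cols <- trial_columns()
  missing <- setdiff(cols, names(trials))
  if (length(missing)) stopf("missing columns: %s", paste(missing, collapse = ", "))
  data.table::fwrite(as.data.table(trials)[, ..cols], path)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  dt <- data.table::fread(path, colClasses = list(character = "participant"))
  cols <- trial_columns()
  missing <- setdiff(cols, names(dt))
  if (length(missing)) {
    stopf("input CSV lacks required columns: %s", paste(missing, collapse = ", "))
  }
  df <- as.data.frame(dt)[, cols]
  if (is.numeric(df$correct) || is.integer(df$correct)) {
    bad <- which(!df$correct %in% c(0, 1))
    if (length(bad)) stopf("`correct` must be 0/1 or logical; bad rows: %s",
                           row_list(bad))
    df$correct <- as.logical(df$correct)
  }
  checks <- list(
    list(!df$session %in% c(1L, 2L), "`session` must be 1 or 2"),
    list(!df$condition %in% c("congruent", "incongruent"),
         "`condition` must be congruent/incongruent"),
    list(!df$direction %in% c("left", "right"),
         "`direction` must be left/right"),
    list(!is.finite(df$rt_ms) | df$rt_ms <= 0, "`rt_ms` must be > 0"),
    list(is.na(df$correct), "`correct` must be non-missing")
  )
  for (ch in checks) {
    bad <- which(ch[[1]])
    if (length(bad)) stopf("%s; bad rows: %s", ch[[2]], row_list(bad))
  }
  df
}

trial_columns <- function() {
  c("participant", "group", "session", "block", "trial", "condition",
    "direction", "fixation_ms", "rt_ms", "correct")
}

row_list <- function(idx, max_show = 5L) {
  shown <- paste(head(idx, max_show), collapse = ", ")
  if (length(idx) > max_show) shown <- paste0(shown, ", ...")
  sprintf("%s (%d total)", shown, length(idx))
}
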