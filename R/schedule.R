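#' Build one session's flanker trial schedule
#'
#' Constructs the trial list for a single session of the arrow flanker task:
#' one practice block of 8 trials balancing target direction and congruency
#' (2 trials per cell), followed by two main blocks of 160 trials each. Every
#' main block contains each of the 40 combinations of target direction (left,
#' right), congruency (congruent, incongruent) and fixation duration (500,
#' 550, ..., 950 ms) exactly four times, so a session presents 160 congruent
#' and 160 incongruent main trials. Trial order is a seeded uniform shuffle
#' within each block (no further run-length constraints).
#'
#' @param seed Integer seed governing the within-block shuffles.
#' @return A `data.frame` with one row per trial and columns `block`
#'   (`"practice"`, `"main1"`, `"main2"`), `trial` (1-based index within the
#'   session), `condition` (`"congruent"`/`"incongruent"`), `direction`
#'   (`"left"`/`"right"`) and `fixation_ms`.
#' @examples
#' sched <- make_schedule(seed = 1)
#' table(sched$block)
#' table(sched$condition[sched$block != "practice"])
#' @export
make_schedule <- function(seed) {
  seed <- check_count(seed, "seed")
  with_seed(seed, schedule_draw())
}

fixation_durations <- function() seq(500L, 950L, by = 50L)
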