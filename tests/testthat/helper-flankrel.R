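# Builders for tiny hand-checkable trial tables.

# one participant-session worth of main-block trials with given RTs
toy_trials <- function(rt_con, rt_inc, participant = "T01", session = 1,
                       correct_con = rep(TRUE, length(rt_con)),
                       correct_inc = rep(TRUE, length(rt_inc))) {
  n_con <- length(rt_con)
  n_inc <- length(rt_inc)
  data.frame(
    participant = participant,
    group = "toy",
    session = session,
    block = "main1",
    trial = seq_len(n_con + n_inc),
    condition = rep(c("congruent", "incongruent"), c(n_con, n_inc)),
    direction = rep(c("left", "right"), length.out = n_con + n_inc),
    fixation_ms = 500L,
    rt_ms = c(rt_con, rt_inc),
    correct = c(correct_con, correct_inc),
    stringsAsFactors = FALSE
  )
}

# default-model dataset, calibrated so that true reliability at 160
# trials/condition equals `target`
calibrated_dataset <- function(seed, n_participants, target = 0.6) {
  p <- calibrate_effect_sd(
    flanker_params(seed = seed, n_participants = n_participants), target)
  simulate_flanker(p)
}

# scores with both sessions and chosen per-session accuracies
fake_scores <- function(acc, participants = sprintf("P%02d", seq_len(nrow(acc)))) {
  do.call(rbind, lapply(seq_len(nrow(acc)), function(i) {
    data.frame(participant = participants[i], group = "toy", session = 1:2,
               mean_rt_congruent = 500, mean_rt_incongruent = 530,
               flanker_effect = 30, accuracy = unlist(acc[i, ]),
               pct_3mad_congruent = 0, pct_3mad_incongruent = 0,
               pct_incorrect_congruent = 0, pct_incorrect_incongruent = 0,
               n_valid_congruent = 100L, n_valid_incongruent = 100L)
  }))
}
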