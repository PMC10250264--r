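test_that("3MAD rule flags the slow outlier in the hand-worked example", {
  # RTs 400,410,420,430,1000: median 420, MAD 10, threshold 450
  tr <- toy_trials(rt_con = c(400, 410, 420), rt_inc = c(430, 1000))
  fl <- flag_rt_exclusions(tr)
  expect_identical(fl$excluded_reason[fl$rt_ms == 1000], "rt_gt_3mad")
  expect_true(all(fl$excluded_reason[fl$rt_ms < 1000] == "none"))
})

test_that("degenerate constant RTs give MAD zero and flag any larger RT", {
  tr <- toy_trials(rt_con = rep(500, 4), rt_inc = c(rep(500, 3), 500.01))
  fl <- flag_rt_exclusions(tr)
  expect_identical(fl$excluded_reason[fl$rt_ms > 500], "rt_gt_3mad")
  expect_true(all(fl$excluded_reason[fl$rt_ms == 500] == "none"))
  expect_false(any(fl$excluded_reason == "rt_lt_100"))
})

test_that("RTs below 100 ms are flagged by the floor rule, not the MAD rule", {
  tr <- toy_trials(rt_con = c(50, 400, 410), rt_inc = c(420, 430))
  fl <- flag_rt_exclusions(tr)
  expect_identical(fl$excluded_reason[fl$rt_ms == 50], "rt_lt_100")
})

test_that("flags are single-pass: no iterative re-flagging", {
  # with 1000 in the MAD set the threshold is 485 and 470 survives; an
  # iterative second pass would flag 470 as well
  tr <- toy_trials(rt_con = c(400, 410, 420), rt_inc = c(430, 470, 1000))
  fl <- flag_rt_exclusions(tr)
  expect_identical(fl$excluded_reason[fl$rt_ms == 1000], "rt_gt_3mad")
  expect_identical(fl$excluded_reason[fl$rt_ms == 470], "none")
})

test_that("fewer than four trials make the MAD undefined", {
  tr <- toy_trials(rt_con = c(400, 410), rt_inc = 420)
  expect_error(flag_rt_exclusions(tr), ">= 4")
})

test_that("incorrect trials are excluded from means and the MAD set by default", {
  tr <- toy_trials(rt_con = c(400, 410, 420, 5000), rt_inc = c(430, 440),
                   correct_con = c(TRUE, TRUE, TRUE, FALSE))
  fl <- flag_rt_exclusions(tr)
  expect_identical(fl$excluded_reason[fl$rt_ms == 5000], "incorrect")
  sc <- score_participants(fl)
  expect_equal(sc$mean_rt_congruent, mean(c(400, 410, 420)))
  # config switch: pooling errors into the MAD set flags the 5000 as slow
  fl2 <- flag_rt_exclusions(tr, mad_correct_only = FALSE)
  expect_identical(fl2$excluded_reason[fl2$rt_ms == 5000], "rt_gt_3mad")
})

test_that("per-condition MAD switch computes thresholds within condition", {
  tr <- toy_trials(rt_con = c(400, 401, 402, 403, 404, 480),
                   rt_inc = c(700, 701, 702, 703, 704, 779))
  pooled <- flag_rt_exclusions(tr)
  percond <- flag_rt_exclusions(tr, mad_per_condition = TRUE)
  # pooled threshold spans both condition clusters, flagging nothing slow;
  # per-condition thresholds sit tight around each cluster
  expect_false(any(pooled$excluded_reason == "rt_gt_3mad"))
  expect_setequal(percond$rt_ms[percond$excluded_reason == "rt_gt_3mad"],
                  c(480, 779))
})

test_that("flanker effect is the incongruent minus congruent mean", {
  sc <- score_participants(flag_rt_exclusions(
    toy_trials(rt_con = c(500, 520), rt_inc = c(540, 560))))
  expect_equal(sc$flanker_effect, 40)
  expect_equal(sc$mean_rt_congruent, 510)
  expect_equal(sc$mean_rt_incongruent, 550)
})

test_that("identical RT distributions in both conditions give a zero effect", {
  rts <- c(450, 480, 510, 540)
  sc <- score_participants(flag_rt_exclusions(
    toy_trials(rt_con = rts, rt_inc = rts)))
  expect_equal(sc$flanker_effect, 0)
})

test_that("scoring matches an independent brute-force pass", {
  tr <- simulate_flanker(flanker_params(seed = 41, n_participants = 8))
  sc <- score_participants(flag_rt_exclusions(tr))
  # brute force: per participant-session, recompute exclusions and means
  # with plain base R
  for (row in seq_len(nrow(sc))) {
    pid <- sc$participant[row]; ses <- sc$session[row]
    m <- tr[tr$participant == pid & tr$session == ses &
              tr$block != "practice", ]
    ok <- m$correct & m$rt_ms >= 100
    med <- median(m$rt_ms[ok])
    thr <- med + 3 * median(abs(m$rt_ms[ok] - med))
    keep <- ok & m$rt_ms <= thr
    eff <- mean(m$rt_ms[keep & m$condition == "incongruent"]) -
      mean(m$rt_ms[keep & m$condition == "congruent"])
    expect_equal(sc$flanker_effect[row], eff, tolerance = 1e-9)
    expect_equal(sc$accuracy[row], mean(m$correct), tolerance = 1e-12)
  }
})

test_that("scoring and descriptives are invariant to trial order", {
  tr <- simulate_flanker(flanker_params(seed = 42, n_participants = 5))
  fl <- flag_rt_exclusions(tr)
  shuffled <- fl[sample.int(nrow(fl)), ]
  a <- score_participants(fl)
  b <- score_participants(shuffled)
  b <- b[order(match(paste(b$participant, b$session),
                     paste(a$participant, a$session))), ]
  rownames(b) <- NULL
  expect_equal(a, b, ignore_attr = TRUE)
  expect_equal(group_descriptives(a), group_descriptives(b))
})

test_that("accuracy criterion is strict-below and needs both sessions", {
  sc <- fake_scores(data.frame(s1 = c(0.59, 0.60, 0.99),
                               s2 = c(0.99, 0.60, 0.98)))
  res <- exclude_participants(sc)
  expect_identical(res$report$status, c("excluded_accuracy", "retained", "retained"))

  one_session <- sc[sc$session == 1 | sc$participant != "P03", ]
  res2 <- exclude_participants(one_session)
  expect_identical(res2$report$status[res2$report$participant == "P03"],
                   "incomplete")
  expect_false("P03" %in% res2$retained)
})

test_that("realistic error rates produce zero accuracy exclusions", {
  sc <- score_participants(flag_rt_exclusions(
    simulate_flanker(flanker_params(seed = 43, n_participants = 40))))
  res <- exclude_participants(sc)
  expect_length(res$retained, 40L)
  expect_true(min(sc$accuracy) > 0.85)
})

test_that("group descriptives with a single participant report missing SDs", {
  sc <- score_participants(flag_rt_exclusions(
    toy_trials(rt_con = c(500, 520, 510), rt_inc = c(540, 560, 545))))
  d <- group_descriptives(sc)
  expect_true(is.na(d$sd_flanker_effect))
  expect_true(is.na(d$cor_congruent_incongruent))
})

test_that("a condition without valid trials drops the participant with a report", {
  tr <- toy_trials(rt_con = c(400, 410, 420, 415), rt_inc = c(430, 440),
                   correct_inc = c(FALSE, FALSE))
  expect_warning(sc <- score_participants(flag_rt_exclusions(tr)), "dropping")
  expect_equal(nrow(sc), 0L)
  expect_equal(nrow(attr(sc, "dropped")), 1L)
})
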