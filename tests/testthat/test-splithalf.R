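test_that("permutated halves partition the valid trials of each condition", {
  tr <- simulate_flanker(flanker_params(seed = 71, n_participants = 3))
  one <- flag_rt_exclusions(tr)
  one <- one[one$participant == "P0001" & one$session == 1, ]
  halves <- split_once(one, split_spec(seed = 5))
  valid <- one[one$block != "practice" & one$excluded_reason == "none", ]
  for (cond in c("congruent", "incongruent")) {
    col <- paste0("mean_rt_", cond)
    v <- valid$rt_ms[valid$condition == cond]
    # per stratum the halves differ in size by <= 1, so condition-level
    # half sizes are reconstructible; the weighted half means must combine
    # to the overall valid-trial mean (partition property)
    found <- FALSE
    for (ka in 0:length(v)) {
      kb <- length(v) - ka
      if (ka == 0 || kb == 0) next
      tot <- ka * halves$half_a[[col]] + kb * halves$half_b[[col]]
      if (isTRUE(all.equal(tot / length(v), mean(v), tolerance = 1e-9))) {
        found <- TRUE
        break
      }
    }
    expect_true(found)
  }
  expect_equal(halves$half_a$flanker_effect,
               halves$half_a$mean_rt_incongruent -
                 halves$half_a$mean_rt_congruent)
})

test_that("permutated partitions are uniform over the possible splits", {
  # 2 trials per condition stratum: each of the 2 assignments per stratum
  # should appear equally often across seeds
  tr <- toy_trials(rt_con = c(500, 520), rt_inc = c(540, 560))
  fl <- flag_rt_exclusions(tr)
  hits <- vapply(1:400, function(s) {
    h <- split_once(fl, split_spec(stratify_by = "condition", seed = s))
    h$half_a$mean_rt_congruent == 500
  }, logical(1))
  expect_gt(mean(hits), 0.40)
  expect_lt(mean(hits), 0.60)
})

test_that("Monte Carlo halves may share trials; a 1-trial stratum always does", {
  tr <- toy_trials(rt_con = c(500, 510, 505, 502), rt_inc = 510)
  fl <- flag_rt_exclusions(tr)
  h <- split_once(fl, split_spec(method = "monte_carlo",
                                 stratify_by = "condition", seed = 2))
  expect_equal(h$half_a$mean_rt_incongruent, 510)
  expect_equal(h$half_b$mean_rt_incongruent, 510)
})

test_that("a sub-2-trial stratum under permutated splitting yields NA halves", {
  tr <- toy_trials(rt_con = c(500, 510, 505), rt_inc = 515)
  fl <- flag_rt_exclusions(tr)
  expect_warning(h <- split_once(fl, split_spec(stratify_by = "condition")),
                 "fewer than 2")
  expect_true(is.na(h$half_a$flanker_effect))
})

test_that("split-half estimation is bit-reproducible under a fixed seed", {
  tr <- flag_rt_exclusions(simulate_flanker(
    flanker_params(seed = 72, n_participants = 15)))
  spec <- split_spec(n_replications = 100, seed = 6)
  expect_identical(splithalf_reliability(tr, spec)$value,
                   splithalf_reliability(tr, spec)$value)
  spec2 <- split_spec(n_replications = 100, seed = 7)
  expect_false(identical(splithalf_reliability(tr, spec)$value,
                         splithalf_reliability(tr, spec2)$value))
})

test_that("vanishing trial noise drives the split-half estimate to 1", {
  p <- flanker_params(seed = 73, n_participants = 12, sigma = 0.5, tau = 0,
                      contaminant_rate = 0)
  est <- splithalf_reliability(flag_rt_exclusions(simulate_flanker(p)),
                               split_spec(n_replications = 100, seed = 8))
  expect_gt(est$value, 0.999)
})

test_that("mean and Fisher-mean aggregation differ by at most 0.01", {
  tr <- flag_rt_exclusions(calibrated_dataset(seed = 74, n_participants = 60))
  base <- split_spec(n_replications = 300, seed = 9)
  fz <- split_spec(n_replications = 300, seed = 9, aggregate = "fisher_mean")
  a <- splithalf_reliability(tr, base)$value
  b <- splithalf_reliability(tr, fz)$value
  expect_lt(abs(a - b), 0.01)
})

test_that("unadjusted estimates sit below Spearman-Brown adjusted ones", {
  tr <- flag_rt_exclusions(calibrated_dataset(seed = 75, n_participants = 40))
  adj <- splithalf_reliability(tr, split_spec(n_replications = 200, seed = 10))
  raw <- splithalf_reliability(tr, split_spec(n_replications = 200, seed = 10,
                                              adjust = "none"))
  expect_gt(adj$value, raw$value)
  # adjusting per replication then averaging is slightly below adjusting the
  # average (the step-up formula is concave in r), so only near-equality holds
  expect_lt(abs(adj$value - 2 * raw$value / (1 + raw$value)), 0.05)
})

test_that("estimate provenance is recorded", {
  tr <- flag_rt_exclusions(simulate_flanker(
    flanker_params(seed = 76, n_participants = 10)))
  spec <- split_spec(method = "monte_carlo", n_replications = 50, seed = 11,
                     session = 2)
  est <- splithalf_reliability(tr, spec)
  expect_s3_class(est, "reliability_estimate")
  expect_identical(est$source, "split_half")
  expect_identical(est$meta$method, "monte_carlo")
  expect_identical(est$meta$session, 2L)
  expect_identical(est$meta$n_replications, 50L)
})
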