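test_that("ICC(A,1) is 1 for perfect agreement and penalizes mean shifts", {
  x <- c(31, 45, 12, 28, 39, 50, 22)
  expect_equal(icc_absolute_agreement(x, x)$value, 1)
  shifted <- icc_absolute_agreement(x, x + 40)
  expect_lt(shifted$value, 1)
  expect_equal(pearson_reliability(x, x + 40)$value, 1)
})

test_that("ICC(A,1) matches an independent two-way ANOVA oracle", {
  set.seed(61)
  for (i in 1:25) {
    n <- sample(4:12, 1)
    x1 <- rnorm(n, 30, 12)
    x2 <- 0.8 * x1 + rnorm(n, 8, 6)
    got <- icc_absolute_agreement(x1, x2)$value
    # oracle: mean squares from lm() on the long two-way layout
    long <- data.frame(y = c(x1, x2),
                       subj = factor(rep(seq_len(n), 2)),
                       rater = factor(rep(1:2, each = n)))
    ms <- anova(lm(y ~ subj + rater, data = long))[["Mean Sq"]]
    msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
    oracle <- (msr - mse) / (msr + mse + (2 / n) * (msc - mse))
    expect_equal(got, oracle, tolerance = 1e-9)
  }
})

test_that("degenerate inputs yield NaN with a warning", {
  expect_warning(est <- icc_absolute_agreement(rep(5, 5), rep(5, 5)), "variance")
  expect_true(is.nan(est$value))
  expect_warning(est2 <- pearson_reliability(rep(5, 5), 1:5), "variance")
  expect_true(is.nan(est2$value))
  expect_error(icc_absolute_agreement(1:2, 2:3), "at least 3")
})

test_that("Pearson reliability is affine-invariant and sign-sensitive", {
  x <- c(4, 9, 2, 7, 5)
  expect_equal(pearson_reliability(x, 2 * x + 5)$value, 1)
  expect_equal(pearson_reliability(c(1, 2, 3), c(3, 2, 1))$value, -1)
})

test_that("Fisher z round-trips and rejects the boundary", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.61), 0.70892, tolerance = 1e-5)
  for (r in seq(-0.95, 0.95, by = 0.19)) {
    expect_equal(fisher_z_inverse(fisher_z(r)), r, tolerance = 1e-12)
  }
  expect_error(fisher_z(1), "< 1")
  expect_error(fisher_z(-1.2), "< 1")
})

test_that("correlation comparison reproduces the printed effect sizes", {
  h1 <- compare_correlations(0.61, 153, 0.55, 153, alternative = "greater")
  expect_equal(round(h1$q, 2), 0.09)
  h2 <- compare_correlations(0.61, 153, 0.63, 141, alternative = "greater")
  expect_equal(round(h2$q, 2), -0.03)
})

test_that("equal correlations give q = 0 and one-sided p exactly 0.5", {
  res <- compare_correlations(0.4, 50, 0.4, 80, alternative = "greater")
  expect_identical(res$q, 0)
  expect_identical(res$p, 0.5)
  expect_error(compare_correlations(1, 50, 0.4, 50), "< 1")
  expect_error(compare_correlations(0.5, 3, 0.4, 50), "n1")
})

test_that("power analysis solves the one-sided two-sample Fisher-z test", {
  expect_identical(required_n_per_group(0.3, 0.05, 0.8), 141L)
  # swapping the z quantiles leaves the sum unchanged
  expect_identical(required_n_per_group(0.3, 0.2, 0.95), 141L)
  # power -> alpha limit: the z terms cancel and only the +3 correction stays
  expect_identical(required_n_per_group(0.3, 0.3, 0.3), 3L)
})

test_that("Spearman-Brown formula: identity, doubling, monotonicity, range", {
  expect_equal(spearman_brown(0.61, 1), 0.61)
  expect_equal(spearman_brown(0.5, 2), 2 / 3, tolerance = 1e-12)
  for (rho in c(0.05, 0.3, 0.61, 0.95)) {
    preds <- spearman_brown(rho, seq(0.125, 8, by = 0.125))
    expect_true(all(diff(preds) > 0))
    expect_true(all(preds >= 0 & preds <= 1))
  }
  expect_equal(spearman_brown(0, 5), 0)
  expect_equal(spearman_brown(1, 0.1), 1)
})

test_that("required length inverts the prophecy formula", {
  expect_identical(sb_required_length(0.61, 0.8, 320), 819L)
  # forward/inverse round trip on the reporting grid
  for (rho in c(0.2, 0.45, 0.61, 0.9)) {
    for (t in c(40L, 123L, 320L, 700L)) {
      pred <- spearman_brown(rho, t / 320)
      expect_lte(sb_required_length(rho, pred, 320), t)
      expect_gte(sb_required_length(rho, pred * (1 + 1e-9), 320), t)
    }
  }
  expect_error(sb_required_length(0.61, 1, 320), "unreachable")
  expect_error(sb_required_length(0, 0.5, 320), "rho_full")
})

test_that("leverage analysis: no exclusions reduce to the full-sample ICC", {
  sc <- score_participants(flag_rt_exclusions(
    simulate_flanker(flanker_params(seed = 51, n_participants = 20))))
  w <- flankrel:::effects_wide(sc)
  full <- flankrel:::icc_a1_value(w$s1, w$s2)
  lv <- leverage_analysis(sc, k_exclude = 0, n_reps = 5, seed = 1)
  expect_equal(lv$max_icc_without_pair, full)
  expect_equal(lv$icc_excluding_pair, full)
  expect_length(lv$flagged, 0L)
})

test_that("an injected unstable pair carries the ICC", {
  p <- flanker_params(seed = 21, n_participants = 155,
                      n_outlier_participants = 2,
                      outlier_effect_sd_multiplier = 25)
  sc <- score_participants(flag_rt_exclusions(simulate_flanker(p)))
  lv <- leverage_analysis(sc, k_exclude = 2, n_reps = 500,
                          protected_pair = c("P0154", "P0155"), seed = 3)
  expect_gt(lv$icc_excluding_pair, lv$max_icc_without_pair + 0.1)
  # the same pair is also caught by the leave-one-out |z| flagging here
  expect_setequal(lv$flagged, c("P0154", "P0155"))
})

test_that("homogeneous samples show only sampling-noise leverage", {
  sc <- score_participants(flag_rt_exclusions(
    simulate_flanker(flanker_params(seed = 52, n_participants = 120))))
  lv <- leverage_analysis(sc, k_exclude = 2, n_reps = 300, seed = 4)
  expect_length(lv$flagged, 0L)
  expect_lt(abs(lv$icc_excluding_pair - lv$max_icc_without_pair), 0.1)
})
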