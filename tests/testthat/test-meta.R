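test_that("2x2 tables give Woolf log odds ratios and standard errors", {
  null_tab <- effect_from_2x2(10, 10, 10, 10)
  expect_equal(null_tab$log_or, 0)
  expect_equal(null_tab$se, sqrt(0.4), tolerance = 1e-12)
  expect_false(null_tab$corrected)

  tab <- effect_from_2x2(20, 10, 10, 20)
  expect_equal(tab$log_or, log(4), tolerance = 1e-12)
  expect_equal(tab$se, sqrt(0.3), tolerance = 1e-12)

  # single zero cell: +0.5 applied to every cell
  z <- effect_from_2x2(5, 0, 10, 10)
  expect_true(z$corrected)
  expect_equal(z$log_or, log(5.5 * 10.5 / (0.5 * 10.5)), tolerance = 1e-12)
  expect_equal(z$se, sqrt(1 / 5.5 + 1 / 0.5 + 1 / 10.5 + 1 / 10.5),
               tolerance = 1e-12)

  expect_error(effect_from_2x2(0, 0, 5, 5), "zero cells")
  expect_error(effect_from_2x2(-1, 2, 3, 4), "nonnegative")
})

test_that("pooling handles the hand-computed cases", {
  one <- pool(data.frame(log_or = 0.3, se = 0.2))
  expect_equal(one$pooled_or, exp(0.3))
  expect_equal(one$ci_low, exp(0.3 - qnorm(0.975) * 0.2), tolerance = 1e-12)
  expect_null(one$heterogeneity)

  two_same <- pool(data.frame(log_or = c(0.4, 0.4), se = c(0.3, 0.3)))
  expect_equal(two_same$pooled_or, exp(0.4), tolerance = 1e-12)
  expect_equal(two_same$heterogeneity$Q, 0, tolerance = 1e-12)
  expect_equal(two_same$tau2, 0)
  expect_lt(two_same$ci_high - two_same$ci_low,
            exp(0.4 + qnorm(0.975) * 0.3) - exp(0.4 - qnorm(0.975) * 0.3))

  mix <- pool(data.frame(log_or = c(0, 1), se = c(1, 1)))
  expect_equal(mix$log_or, 0.5, tolerance = 1e-12)
  expect_equal(mix$heterogeneity$Q, 0.5, tolerance = 1e-12)
  expect_equal(mix$tau2, 0)
  expect_equal(mix$se, sqrt(0.5), tolerance = 1e-12)

  expect_error(pool(data.frame(log_or = numeric(), se = numeric())),
               "no studies")
  expect_error(pool(data.frame(log_or = 1, se = 0)), "positive se")
})

test_that("DerSimonian-Laird pooling matches metafor", {
  set.seed(61)
  for (rep in 1:5) {
    k <- sample(4:10, 1)
    eff <- data.frame(log_or = rnorm(k, 0.2, 0.4),
                      se = runif(k, 0.1, 0.5))
    ours <- pool(eff, model = "dersimonian_laird")
    ref <- metafor::rma(yi = eff$log_or, sei = eff$se, method = "DL")
    expect_equal(ours$log_or, as.numeric(ref$beta), tolerance = 1e-8)
    expect_equal(ours$se, ref$se, tolerance = 1e-8)
    expect_equal(ours$tau2, ref$tau2, tolerance = 1e-8)
    expect_equal(ours$heterogeneity$Q, ref$QE, tolerance = 1e-8)
    fe <- pool(eff, model = "fixed")
    ref_fe <- metafor::rma(yi = eff$log_or, sei = eff$se, method = "FE")
    expect_equal(fe$log_or, as.numeric(ref_fe$beta), tolerance = 1e-8)
  }
})

test_that("I-squared follows its closed form at the printed worked examples", {
  expect_equal(i_squared(21.1, 6), (21.1 - 6) / 21.1 * 100, tolerance = 1e-12)
  expect_equal(round(i_squared(21.1, 6)), 72)
  expect_equal(i_squared(3.04, 5), 0)
  expect_equal(i_squared(5, 5), 0)
  expect_equal(i_squared(0, 3), 0)
})

test_that("the test-based I-squared interval reproduces both printed intervals", {
  expect_equal(round(i_squared_ci(21.1, 6)), c(38, 87))
  expect_equal(round(i_squared_ci(3.04, 5)), c(0, 75))
  # Q at or below df: lower bound exactly zero
  expect_equal(i_squared_ci(4, 5)[1], 0)
  expect_equal(i_squared_ci(5, 5)[1], 0)
  expect_error(i_squared_ci(3, 1), "df")
})

test_that("heterogeneity_from_q mirrors a pooled analysis of the same data", {
  set.seed(62)
  eff <- data.frame(log_or = rnorm(6, 0.3, 0.5), se = runif(6, 0.1, 0.4))
  res <- pool(eff)
  h <- heterogeneity_from_q(res$heterogeneity$Q, res$heterogeneity$df)
  expect_equal(h$i2_percent, res$heterogeneity$i2_percent, tolerance = 1e-12)
  expect_equal(h$p_value, res$heterogeneity$p_value, tolerance = 1e-12)
  expect_equal(c(h$i2_ci_low, h$i2_ci_high),
               c(res$heterogeneity$i2_ci_low, res$heterogeneity$i2_ci_high),
               tolerance = 1e-12)
})

test_that("fixed-effect intervals are never wider than DerSimonian-Laird ones", {
  set.seed(63)
  for (rep in 1:30) {
    k <- sample(3:9, 1)
    eff <- data.frame(log_or = rnorm(k, 0, 0.6), se = runif(k, 0.1, 0.5))
    fe <- pool(eff, model = "fixed")
    dl <- pool(eff, model = "dersimonian_laird")
    expect_lte(fe$ci_high - fe$ci_low, dl$ci_high - dl$ci_low + 1e-12)
    # inverse-variance pooling stays within the span of the study effects
    expect_gte(dl$log_or, min(eff$log_or) - 1e-12)
    expect_lte(dl$log_or, max(eff$log_or) + 1e-12)
  }
})

test_that("quality-stratified sensitivity behaves at its boundaries", {
  eff <- data.frame(study_id = c("a", "b", "c"),
                    log_or = c(0.1, 0.2, 0.3), se = c(0.2, 0.2, 0.2),
                    quality = c("moderate", "high", "moderate"))
  sens <- sensitivity_by_quality(eff)
  expect_equal(sens$n_excluded, 0)
  expect_equal(sens$all$pooled_or, sens$excluding_low$pooled_or)
  expect_equal(sens$all$heterogeneity$Q, sens$excluding_low$heterogeneity$Q)

  two <- data.frame(study_id = c("a", "b"), log_or = c(0.9, 0.1),
                    se = c(0.2, 0.25), quality = c("low", "moderate"))
  sens2 <- sensitivity_by_quality(two)
  single <- pool(two[2, ])
  expect_equal(sens2$excluding_low$pooled_or, single$pooled_or)
  expect_equal(sens2$excluding_low$ci_low, single$ci_low)

  all_low <- data.frame(log_or = c(0, 1), se = c(1, 1),
                        quality = c("low", "low"))
  expect_error(sensitivity_by_quality(all_low), "all studies are low")
})

test_that("excluding a heterogeneity-driving low-quality outlier shrinks I2 and the CI", {
  set.seed(64)
  k <- 7
  eff <- data.frame(study_id = sprintf("s%d", 1:k),
                    log_or = c(rnorm(k - 1, 0.14, 0.02), 1.1),
                    se = c(runif(k - 1, 0.08, 0.15), 0.12),
                    quality = c(rep("moderate", k - 1), "low"))
  sens <- sensitivity_by_quality(eff)
  expect_gt(sens$all$heterogeneity$i2_percent, 50)
  expect_lt(sens$excluding_low$heterogeneity$i2_percent,
            sens$all$heterogeneity$i2_percent)
  expect_lt(sens$excluding_low$ci_high - sens$excluding_low$ci_low,
            sens$all$ci_high - sens$all$ci_low)
  expect_identical(sens$forest$included_after_exclusion,
                   c(rep(TRUE, k - 1), FALSE))
  expect_true(all(is.na(sens$forest$weight_excluding_low[!sens$forest$included_after_exclusion])))
})
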