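test_that("degenerate arrays decompose as expected", {
  # constant array: every component zero
  vc <- estimate_variance_components(rating_array(array(4, c(4, 3, 5))))
  expect_equal(unname(vc$components), rep(0, 7), tolerance = 1e-12)

  # study-effect-only array: sigma2_p > 0, everything else zero
  arr <- array(rep(c(1, 4, 7), 2 * 4), dim = c(3, 2, 4))
  vc <- estimate_variance_components(arr)
  expect_gt(vc$components[["p"]], 0)
  expect_equal(unname(vc$components[c("r", "i", "pr", "pi", "ri", "pri_e")]),
               rep(0, 6), tolerance = 1e-12)
})

test_that("crossed components equal the lm/anova mean-square oracle", {
  set.seed(11)
  for (rep in 1:5) {
    arr <- array(rnorm(5 * 3 * 4, mean = 4), dim = c(5, 3, 4))
    est <- estimate_variance_components(arr)
    expect_equal(est$raw, vc_aov_oracle(arr), tolerance = 1e-10)
  }
})

test_that("sums of squares decompose the total variance exactly", {
  set.seed(12)
  arr <- array(rnorm(6 * 4 * 5), dim = c(6, 4, 5))
  vc <- estimate_variance_components(arr)
  df <- c(p = 5, r = 3, i = 4, pr = 15, pi = 20, ri = 12, pri = 60)
  expect_equal(sum(vc$mean_squares * df), sum((arr - mean(arr))^2),
               tolerance = 1e-10)
})

test_that("design validation rejects missing cells and undersized facets", {
  arr <- array(4, c(3, 2, 4)); arr[1, 1, 1] <- NA
  expect_error(rating_array(arr), "missing cells")
  expect_error(estimate_variance_components(array(4, c(3, 1, 4))),
               "at least 2")
})

test_that("phi handles the closed-form cases", {
  vc <- c(p = 1, r = 0, i = 0, pr = 0, pi = 0, ri = 0, pri_e = 0)
  expect_equal(phi_coefficient(vc, c("raters", "items"),
                               n_prime = c(raters = 3, items = 5)), 1)
  expect_equal(phi_coefficient(vc, "raters", n_prime = c(raters = 1),
                               n_fixed = c(items = 4)), 1)
  vc["pri_e"] <- 1
  expect_equal(phi_coefficient(vc, c("raters", "items"),
                               n_prime = c(raters = 1, items = 1)), 0.5)
  zero <- setNames(rep(0, 7), names(vc))
  expect_error(phi_coefficient(zero, c("raters", "items"),
                               n_prime = c(raters = 2, items = 2)),
               "undefined")
})

test_that("phi matches the exhaustive-enumeration oracle in all facet configurations", {
  set.seed(13)
  for (rep in 1:50) {
    vc <- random_vc()
    np <- c(raters = sample(1:8, 1), items = sample(1:12, 1))
    nf <- c(raters = sample(1:8, 1), items = sample(1:12, 1))
    for (random in list(c("raters", "items"), "raters", "items")) {
      for (type in c("absolute", "relative")) {
        expect_equal(
          phi_coefficient(vc, random, n_prime = np, n_fixed = nf, type = type),
          phi_enum_oracle(vc, random, np, nf, type = type),
          tolerance = 1e-12)
      }
    }
  }
})

test_that("the relative coefficient never falls below the absolute one", {
  set.seed(14)
  for (rep in 1:100) {
    vc <- random_vc()
    np <- c(raters = sample(1:6, 1), items = sample(1:12, 1))
    rel <- phi_coefficient(vc, c("raters", "items"), n_prime = np,
                           type = "relative")
    abs_ <- phi_coefficient(vc, c("raters", "items"), n_prime = np,
                            type = "absolute")
    expect_gte(rel, abs_ - 1e-12)
  }
})

test_that("phi is non-decreasing in every D-study sample size", {
  set.seed(15)
  for (rep in 1:100) {
    vc <- random_vc()
    nr <- sort(sample(1:20, 2)); ni <- sample(1:12, 1)
    expect_lte(
      phi_coefficient(vc, c("raters", "items"),
                      n_prime = c(raters = nr[1], items = ni)),
      phi_coefficient(vc, c("raters", "items"),
                      n_prime = c(raters = nr[2], items = ni)) + 1e-12)
    ni2 <- sort(sample(1:20, 2))
    expect_lte(
      phi_coefficient(vc, c("raters", "items"),
                      n_prime = c(raters = nr[1], items = ni2[1])),
      phi_coefficient(vc, c("raters", "items"),
                      n_prime = c(raters = nr[1], items = ni2[2])) + 1e-12)
  }
})

test_that("nested components equal the lm/anova nested oracle", {
  set.seed(16)
  for (rep in 1:5) {
    n_p <- 8; n_g <- 2; n_r <- 3
    scores <- matrix(rnorm(n_p * n_g * n_r, 40, 5), n_p, n_g * n_r)
    groups <- rep(c("A", "B"), each = n_r)
    vc <- nested_variance_components(scores, groups)
    expect_equal(vc$raw, vc_nested_oracle(scores, groups), tolerance = 1e-10)
  }
})

test_that("inter-user phi degenerates to pooled inter-rater phi without group effects", {
  # with sigma2_g = sigma2_pg = 0 the nested formula collapses to a single
  # rater facet of n_g * n_r raters
  vc <- c(p = 1.3, g = 0, r_g = 0.4, pg = 0, pr_g_e = 0.9)
  n_g <- 2; n_r <- 2
  pooled <- 1.3 / (1.3 + 0.4 / (n_g * n_r) + 0.9 / (n_g * n_r))
  expect_equal(phi_nested(vc, n_g = n_g, n_r = n_r), pooled,
               tolerance = 1e-12)
})

test_that("inter-user estimation enforces balance and variation", {
  set.seed(17)
  sim <- simulate_ratings(sim_config(n_studies = 10), seed = 17)
  expect_error(inter_user_phi(sim$ratings, c("u", "u", "u", "n")),
               "unequal|balanced")
  const <- rating_array(array(4, c(6, 4, 3)))
  expect_error(inter_user_phi(const, c("u", "u", "n", "n")), "undefined")
})

test_that("reliability suite orders groups by their rater-agreement components", {
  # components tuned so the population inter-rater phi is ~0.74 for the
  # first group and ~0.45 for the second (n_r = 2, n_i = 11)
  base <- c(p = 1, r = 0.1, i = 0.2, pi = 0, ri = 0, pri_e = 0.8)
  cfg_hi <- sim_config(n_studies = 200, n_raters = 2, n_groups = 1,
                       components = c(base, pr = 0.53), discretize = "none")
  cfg_lo <- sim_config(n_studies = 200, n_raters = 2, n_groups = 1,
                       components = c(base, pr = 2.27), discretize = "none")
  arr_hi <- simulate_ratings(cfg_hi, seed = 18)$ratings
  arr_lo <- simulate_ratings(cfg_lo, seed = 19)$ratings
  arr <- array(NA_real_, dim = c(200, 4, 11))
  arr[, 1:2, ] <- unclass(arr_hi); arr[, 3:4, ] <- unclass(arr_lo)
  suite <- reliability_suite(rating_array(arr),
                             c("user", "user", "non_user", "non_user"))
  tab <- suite$per_group
  expect_gt(tab$inter_rater[tab$group == "user"],
            tab$inter_rater[tab$group == "non_user"])
  expect_true(all(tab$internal_consistency >= 0 & tab$internal_consistency <= 1))
  expect_true(suite$inter_user >= 0 && suite$inter_user <= 1)

  # near-zero rater components: inter-rater dependability approaches 1
  quiet <- sim_config(n_studies = 150, n_raters = 2, n_groups = 1,
                      components = c(p = 2, r = 1e-4, i = 0.2, pr = 1e-4,
                                     pi = 0.1, ri = 1e-4, pri_e = 1e-3),
                      discretize = "none")
  vc <- estimate_variance_components(simulate_ratings(quiet, seed = 20)$ratings)
  expect_gt(phi_coefficient(vc, "raters", n_prime = c(raters = 2),
                            n_fixed = c(items = 11)), 0.98)
})

test_that("estimated components are unbiased for the crossed model (small-scale check)", {
  truth <- c(p = 1, r = 0.1, i = 0.2, pr = 0.3, pi = 0.2, ri = 0.05,
             pri_e = 0.8)
  cfg <- sim_config(n_studies = 40, components = truth, discretize = "none")
  ests <- t(vapply(1:60, function(s)
    estimate_variance_components(simulate_ratings(cfg, seed = s)$ratings)$raw,
    numeric(7)))
  mc_se <- apply(ests, 2, sd) / sqrt(nrow(ests))
  expect_true(all(abs(colMeans(ests) - truth) < 4 * mc_se + 1e-8))
})
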