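test_that("Rubin pooling reproduces the hand-computed combination", {
  p <- rubin_pool(c(1.0, 2.0), c(0.5, 0.5))
  expect_equal(p$qbar, 1.5)
  expect_equal(p$ubar, 0.5)
  expect_equal(p$b, 0.5)
  expect_equal(p$t, 0.5 + (1 + 1 / 2) * 0.5)  # 1.25
  # identical estimates: no between-imputation variance
  p2 <- rubin_pool(c(1.3, 1.3, 1.3), c(0.2, 0.2, 0.2))
  expect_equal(p2$b, 0)
  expect_equal(p2$t, p2$ubar)
  # scaling equivariance
  p3 <- rubin_pool(3 * c(1.0, 2.0), 9 * c(0.5, 0.5))
  expect_equal(p3$qbar, 3 * p$qbar)
  expect_equal(p3$t, 9 * p$t)
  expect_error(rubin_pool(1, 0.5), "m >= 2")
  # Barnard-Rubin df never exceeds the classic large-sample df
  p4 <- rubin_pool(c(1, 2, 1.5), c(0.5, 0.4, 0.6), dfcom = 50)
  p5 <- rubin_pool(c(1, 2, 1.5), c(0.5, 0.4, 0.6), dfcom = Inf)
  expect_lt(p4$df, p5$df)
})

test_that("the imputation-count rule applies the ceiling with a floor of 5", {
  expect_equal(choose_m(17.3), 18L)
  expect_equal(choose_m(0), 5L)
  expect_equal(choose_m(100), 100L)
  expect_equal(choose_m(4.2), 5L)
  expect_error(choose_m(120), "0, 100")
})

test_that("complete data yield m identical copies and stacks are seed-stable", {
  tr <- simulate_trial(small_config(n_per_arm = 30, seed = 87))
  st <- mice_jav(tr, m = 3, seed = 5)
  expect_equal(st$m, 3L)
  expect_identical(st$data[[1]], st$data[[2]])
  expect_length(st$variables, 0)

  trm <- apply_missingness(tr, seed = 88)
  s1 <- mice_jav(trm, m = 3, iterations = 3, seed = 9)
  s2 <- mice_jav(trm, m = 3, iterations = 3, seed = 9)
  expect_identical(s1$data, s2$data)
  s3 <- mice_jav(trm, m = 3, iterations = 3, seed = 10)
  expect_false(identical(s1$data, s3$data))
})

test_that("observed cells are preserved exactly across imputations", {
  tr <- apply_missingness(simulate_trial(small_config(n_per_arm = 60, seed = 91)),
                          seed = 92)
  wide <- trial_wide(tr)
  st <- mice_jav(wide, m = 4, iterations = 3, seed = 3)
  obs <- !is.na(wide$cognitive_v1)
  for (im in 1:4) {
    expect_identical(st$data[[im]]$cognitive_v1[obs], wide$cognitive_v1[obs])
    expect_false(anyNA(st$data[[im]]$cognitive_v1))
  }
})

test_that("a variable fully missing within an arm is rejected", {
  tr <- apply_missingness(simulate_trial(small_config(n_per_arm = 20, seed = 93)),
                          seed = 94)
  wide <- trial_wide(tr)
  wide$cognitive_v1[wide$arm == "iron"] <- NA
  expect_error(mice_jav(wide, m = 2, seed = 1), "100% missing")
})

test_that("ferritin is imputed on the log scale and back-transformed positive", {
  cfg <- sim_config(n_per_arm = 60, outcomes = c("cognitive", "ferritin"),
                    seed = 95, include_morbidity = FALSE)
  tr <- apply_missingness(simulate_trial(cfg), seed = 96)
  st <- mice_jav(tr, m = 2, iterations = 3, seed = 4)
  for (im in 1:2) {
    expect_true(all(st$data[[im]]$ferritin_v1 > 0))
    expect_false(anyNA(st$data[[im]]$ferritin_v1))
  }
})

test_that("missingness descriptives match the imposed mechanism", {
  tr <- simulate_trial(small_config(n_per_arm = 400, seed = 97))
  ms0 <- missingness_summary(tr)
  expect_true(all(ms0$missingness$pct_missing == 0))

  trm <- apply_missingness(tr, seed = 98)
  ms <- missingness_summary(trm)
  m3 <- ms$missingness[ms$missingness$visit == 1, ]
  expect_lt(abs(m3$pct_missing / 100 - 0.20), 3 * sqrt(0.2 * 0.8 / 1200))

  # MAR on education: education means differ by missingness status
  trmar <- apply_missingness(
    tr, seed = 99,
    dropout = list(mechanism = "MAR", rate = 0.3,
                   mar_predictors = c(maternal_education = 0.8)))
  bym <- missingness_summary(trmar)$by_missingness
  row <- bym[bym$visit == 1 & bym$variable == "maternal_education", ]
  expect_gt(row$mean_missing, row$mean_observed)
})

test_that("under MCAR the pooled effect tracks the full-data effect", {
  cfg <- small_config(n_per_arm = 250, seed = 101,
                      effects = list(iron = list(cognitive = c(0, 2, 2))))
  tr <- simulate_trial(cfg)
  full <- estimate_effect(fit_clda(tr, "cognitive"), c("iron", "placebo"), 1)
  trm <- apply_missingness(tr, seed = 102)
  st <- mice_jav(trm, m = 5, iterations = 5, seed = 103)
  pooled <- pool_clda_effect(st, "cognitive", c("iron", "placebo"), 1)
  # agreement within Monte-Carlo error of the two estimates
  expect_lt(abs(pooled$qbar - full$estimate),
            3 * sqrt(pooled$t + full$se^2))
  # total variance never below the within-imputation component
  expect_gte(pooled$t, pooled$ubar)
})
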