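test_that("baseline distributions are common across arms by construction", {
  cfg <- small_config(n_per_arm = 1000, seed = 21)
  tr <- simulate_trial(cfg)
  v0 <- merge(tr$visits[tr$visits$visit == 0, ],
              tr$children[, c("child_id", "arm")], by = "child_id")
  means <- tapply(v0$cognitive, v0$arm, mean)
  # 3 standard errors of a difference of two arm means at n = 1000
  tol <- 3 * 15 * sqrt(2 / 1000)
  expect_lt(max(means) - min(means), tol)
})

test_that("a configured month-3 effect is recovered empirically", {
  cfg <- small_config(n_per_arm = 2000, seed = 31,
                      effects = list(iron = list(cognitive = c(0, 2, 2))))
  tr <- simulate_trial(cfg)
  v1 <- merge(tr$visits[tr$visits$visit == 1, ],
              tr$children[, c("child_id", "arm")], by = "child_id")
  diff <- mean(v1$cognitive[v1$arm == "iron"]) -
    mean(v1$cognitive[v1$arm == "placebo"])
  expect_lt(abs(diff - 2), 3 * 15 * sqrt(2 / 2000))
})

test_that("simulation is byte-identical under the same seed", {
  cfg <- small_config(n_per_arm = 40, seed = 5)
  expect_identical(simulate_trial(cfg), simulate_trial(cfg))
  t2 <- simulate_trial(cfg, seed = 6)
  expect_false(identical(simulate_trial(cfg)$visits$cognitive,
                         t2$visits$cognitive))
})

test_that("non-positive-definite covariance is rejected", {
  bad <- matrix(1, 3, 3) * 225
  expect_error(sim_config(covariance = list(cognitive = bad)),
               "positive-definite")
})

test_that("per-arm sizes match the configuration up to block truncation", {
  cfg <- small_config(n_per_arm = 200, seed = 77)
  tr <- simulate_trial(cfg)
  tab <- table(tr$children$arm)
  # 6 strata, each with at most one incomplete block of 6
  expect_true(all(abs(tab - 200) <= 12))
  expect_equal(sum(tab), 600L)
})

test_that("null-effect outcome distributions are exchangeable across arms", {
  # Kolmogorov-Smirnov comparison should be non-significant at the 5% level
  # in roughly 95% of replicates under the null
  reps <- 300
  nonsig <- 0L
  for (r in seq_len(reps)) {
    tr <- simulate_trial(small_config(n_per_arm = 40, seed = 5000 + r))
    v1 <- merge(tr$visits[tr$visits$visit == 1, ],
                tr$children[, c("child_id", "arm")], by = "child_id")
    p <- suppressWarnings(stats::ks.test(v1$cognitive[v1$arm == "iron"],
                                         v1$cognitive[v1$arm == "placebo"]))$p.value
    if (p > 0.05) nonsig <- nonsig + 1L
  }
  # expect ~0.95; 0.94 bound minus 3 binomial SDs at 300 replicates
  expect_gte(nonsig / reps, 0.94 - 3 * sqrt(0.95 * 0.05 / reps))
})

test_that("zero dropout leaves the dataset unchanged", {
  tr <- simulate_trial(small_config(seed = 8))
  expect_identical(apply_missingness(tr, dropout = list(rate = 0), seed = 1), tr)
})

test_that("MCAR dropout hits the configured rate", {
  cfg <- small_config(n_per_arm = 1100, seed = 13)
  tr <- apply_missingness(simulate_trial(cfg), seed = 14)
  v1 <- tr$visits[tr$visits$visit == 1, ]
  frac <- mean(is.na(v1$cognitive))
  expect_lt(abs(frac - 0.20), 3 * sqrt(0.2 * 0.8 / 3300))
  # monotone: missing at month 3 implies missing at month 12
  v2 <- tr$visits[tr$visits$visit == 2, ]
  expect_true(all(is.na(v2$cognitive[is.na(v1$cognitive)])))
})

test_that("MAR dropout tracks its covariate and validates predictors", {
  cfg <- small_config(
    n_per_arm = 800, seed = 17,
    dropout = list(mechanism = "MAR", rate = 0.25,
                   mar_predictors = c(maternal_education = 0.5)))
  tr <- apply_missingness(simulate_trial(cfg), seed = 18)
  v1 <- merge(tr$visits[tr$visits$visit == 1, ],
              tr$children[, c("child_id", "maternal_education")],
              by = "child_id")
  terts <- stats::quantile(v1$maternal_education, c(1 / 3, 2 / 3))
  hi <- mean(is.na(v1$cognitive[v1$maternal_education > terts[2]]))
  lo <- mean(is.na(v1$cognitive[v1$maternal_education <= terts[1]]))
  expect_gt(hi, lo)

  expect_error(
    apply_missingness(tr, seed = 1,
                      dropout = list(mechanism = "MAR", rate = 0.2,
                                     mar_predictors = c(not_a_column = 1))),
    "absent")
})

test_that("trials round-trip through the tidy CSV schema", {
  tr <- simulate_trial(sim_config(n_per_arm = 10, seed = 3))
  dir <- withr::local_tempdir()
  write_trial_csv(tr, dir)
  back <- read_trial_csv(dir)
  expect_equal(back$children$child_id, tr$children$child_id)
  expect_equal(back$visits$cognitive, tr$visits$cognitive)
  expect_equal(nrow(back$morbidity), nrow(tr$morbidity))
})
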