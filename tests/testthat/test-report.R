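test_that("CONSORT counts reconcile and sum across arms", {
  tr <- simulate_trial(sim_config(n_per_arm = 120, seed = 113))
  tr <- apply_missingness(tr, seed = 114)
  flags <- assign_populations(tr)
  cc <- consort(tr, flags)
  expect_equal(as.integer(cc$randomised),
               as.integer(cc$analysed_itt + cc$excluded_withdrawn))
  expect_equal(sum(cc$randomised), 360)
  expect_true(all(cc$analysed_safety <= cc$analysed_itt))
  expect_true(all(cc$analysed_per_protocol <= cc$analysed_itt))
})

test_that("a consent withdrawal moves one child out of every population", {
  tr <- simulate_trial(small_config(n_per_arm = 40, seed = 115))
  tr$children$consent_withdrawn_all_data[] <- FALSE
  cc0 <- consort(tr)
  expect_equal(as.integer(cc0$analysed_itt), as.integer(cc0$randomised))
  tr$children$consent_withdrawn_all_data[1] <- TRUE
  cc1 <- consort(tr)
  expect_equal(sum(cc1$excluded_withdrawn), 1)
  expect_equal(as.integer(cc1$randomised),
               as.integer(cc1$analysed_itt + cc1$excluded_withdrawn))
})

test_that("the baseline table is purely descriptive", {
  tr <- simulate_trial(sim_config(n_per_arm = 60, seed = 117))
  t1 <- build_table1(tr)
  expect_false(any(grepl("p", names(t1), ignore.case = TRUE) &
                     grepl("value", names(t1), ignore.case = TRUE)))
  expect_equal(ncol(t1), 4L)  # characteristic + one column per arm
  expect_gt(nrow(t1), 10)
})

test_that("secondary rows carry estimates and CIs but no p-values", {
  effects <- data.frame(
    endpoint = c("cognitive", "stunting"), visit = 1,
    tier = c("primary", "secondary"),
    comparison = "iron vs placebo", scale = c("difference", "ratio"),
    estimate = c(2.1, 0.9), ci_lower = c(0.5, 0.7), ci_upper = c(3.7, 1.2),
    p_unadjusted = c(0.01, 0.03), stringsAsFactors = FALSE)
  t2 <- build_table2(effects)
  expect_match(t2$p_unadjusted[t2$endpoint == "cognitive"], "0.01")
  expect_equal(t2$p_unadjusted[t2$endpoint == "stunting"], "")
  expect_match(t2$estimate_ci[t2$endpoint == "stunting"], "0.90")
})

test_that("the end-to-end pipeline emits all four tables deterministically", {
  cfg <- sim_config(n_per_arm = 80, seed = 119,
                    outcomes = c("cognitive", "language", "haemoglobin",
                                 "ferritin"))
  res <- run_pipeline(config = cfg, seed = 7,
                      key_secondary = data.frame(
                        outcome = c("language", "haemoglobin", "ferritin"),
                        transform = c("identity", "identity", "log"),
                        stringsAsFactors = FALSE))
  expect_named(res$tables, c("table1", "table2", "table3", "table4"))
  expect_s3_class(res$decisions[["1"]]$primary, "gatekeeper_result")
  expect_true(all(c("cognitive", "language") %in% names(res$fits)))
  # rerunning with the same config and seed reproduces identical numbers
  res2 <- run_pipeline(config = cfg, seed = 7,
                       key_secondary = data.frame(
                         outcome = c("language", "haemoglobin", "ferritin"),
                         transform = c("identity", "identity", "log"),
                         stringsAsFactors = FALSE))
  expect_identical(res$effects$estimate, res2$effects$estimate)
  expect_identical(res$tables$table2, res2$tables$table2)
})

test_that("the covariate sensitivity model changes only the intended fit", {
  cfg <- small_config(n_per_arm = 80, seed = 121)
  res <- run_pipeline(config = cfg, seed = 11,
                      key_secondary = data.frame(outcome = character(0),
                                                 transform = character(0)),
                      sensitivity = "covariates")
  main_terms <- names(coef(res$fits$cognitive))
  sens_terms <- names(coef(res$sensitivity$covariates))
  expect_true(all(c("fci_score", "maternal_education") %in% sens_terms))
  expect_false(any(c("fci_score", "maternal_education") %in% main_terms))
})

test_that("pipeline artefacts are written with a manifest", {
  dir <- withr::local_tempdir()
  cfg <- small_config(n_per_arm = 60, seed = 123)
  run_pipeline(config = cfg, seed = 3, out_dir = dir,
               key_secondary = data.frame(outcome = character(0),
                                          transform = character(0)))
  expect_true(file.exists(file.path(dir, "table1.csv")))
  expect_true(file.exists(file.path(dir, "effects.csv")))
  man <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  expect_equal(man$seed, 3)
})
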