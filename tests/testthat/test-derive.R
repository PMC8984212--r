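test_that("anaemia threshold is strict at 110 g/L with missing propagation", {
  expect_equal(classify_anaemia(c(109, 110, 111, NA)),
               c(TRUE, FALSE, FALSE, NA))
})

test_that("iron deficiency honours the CRP-conditional ferritin cutoffs", {
  expect_true(classify_iron_deficiency(11.9, 1.0))
  expect_true(classify_iron_deficiency(20, 6))
  expect_false(classify_iron_deficiency(20, 5.0))  # CRP strictly > 5
  expect_false(classify_iron_deficiency(35, 10))
  expect_false(classify_iron_deficiency(12, 1))    # ferritin strictly < 12
  # decidable branches ignore the missing CRP; the ambiguous band does not
  expect_true(classify_iron_deficiency(5, NA))
  expect_false(classify_iron_deficiency(40, NA))
  expect_equal(classify_iron_deficiency(20, NA), NA)
})

test_that("iron-deficiency anaemia is a three-valued conjunction", {
  expect_equal(classify_ida(c(TRUE, TRUE, TRUE, FALSE),
                            c(TRUE, FALSE, NA, NA)),
               c(TRUE, FALSE, NA, FALSE))
})

test_that("LMS z-scores follow the Box-Cox formula and faltering cutoffs", {
  ref <- data.frame(metric = "length_for_age", sex = "female",
                    age_days = c(200, 300), L = c(1, 1),
                    M = c(66, 71), S = c(0.035, 0.035))
  # measurement at the median maps to z = 0
  expect_equal(growth_zscore(66, 200, "female", ref, "length_for_age"), 0)
  # L = 1 reduces to (x - M) / (M * S)
  x <- 69
  expect_equal(growth_zscore(x, 300, "female", ref, "length_for_age"),
               (x - 71) / (71 * 0.035))
  # linear interpolation in age
  expect_equal(growth_zscore(68.5, 250, "female", ref, "length_for_age"), 0)
  # L = 0 uses the log form
  ref0 <- data.frame(metric = "weight_for_age", sex = "male",
                     age_days = c(200, 300), L = c(0, 0),
                     M = c(9, 9.5), S = c(0.11, 0.11))
  expect_equal(growth_zscore(9, 200, "male", ref0, "weight_for_age"), 0)
  expect_equal(growth_zscore(10, 200, "male", ref0, "weight_for_age"),
               log(10 / 9) / 0.11)
  expect_error(growth_zscore(66, 150, "female", ref, "length_for_age"),
               "extrapolate")
  expect_equal(classify_faltering(c(-2.01, -2.00, -1.99)),
               c(TRUE, FALSE, FALSE))
})

test_that("the bundled synthetic LMS reference loads and covers the cohort", {
  ref <- read_lms_reference()
  z <- growth_zscore(c(68, 72), c(244, 244), c("female", "male"), ref,
                     "length_for_age")
  expect_true(all(is.finite(z)))
})

test_that("scale sums conserve totals and missing items void one scale", {
  items <- as.data.frame(matrix(2, nrow = 3, ncol = 33,
                                dimnames = list(NULL, paste0("t", 1:33))))
  mapping <- split(paste0("t", 1:33), rep(1:7, c(5, 5, 5, 5, 5, 4, 4)))
  names(mapping) <- paste0("scale", 1:7)
  s <- score_scales(items, mapping, range = c(1, 4))
  expect_equal(unname(unlist(s[1, ])), c(10, 10, 10, 10, 10, 8, 8))
  # disjoint partition: totals of scale sums equal the total of all items
  expect_equal(rowSums(s), rowSums(items))
  # all items at the scale minimum
  expect_equal(unname(score_scales(items * 0 + 1, mapping,
                                   c(1, 4))[1, "scale1"]), 5)
  items$t3[2] <- NA
  s2 <- score_scales(items, mapping, c(1, 4))
  expect_true(is.na(s2$scale1[2]))
  expect_false(anyNA(s2[2, -1]))
  items$t3[2] <- 9
  expect_error(score_scales(items, mapping, c(1, 4)), "range")
})

test_that("compliance boundary is inclusive at 70% and absent data means 0%", {
  r <- compliance(c(63, 90, NA), c(90, 90, 90))
  expect_equal(r$compliance, c(70, 100, 0))
  expect_equal(r$complier, c(TRUE, TRUE, FALSE))
  expect_error(compliance(10, 0), "positive")
  expect_error(compliance(95, 90), "exceed")
})

test_that("population definitions nest as specified", {
  tr <- simulate_trial(sim_config(n_per_arm = 150, seed = 9))
  # force specific cases
  tr$children$received_any_dose[1] <- FALSE
  tr$children$consent_withdrawn_all_data[2] <- TRUE
  tr$children$intake_days[3] <- 90
  tr$children$has_intake_data[3] <- TRUE
  tr$children$eligibility_violation[3] <- FALSE
  tr$children$improper_unblinding[3] <- FALSE
  tr$children$last_contact_day[3] <- 365
  f <- assign_populations(tr)
  expect_true(f$in_itt[1] && !f$in_safety[1])       # never dosed
  expect_false(any(unlist(f[2, c("in_itt", "in_safety", "in_per_protocol")])))
  expect_true(all(unlist(f[3, c("in_itt", "in_safety", "in_per_protocol")])))
  # nesting invariants
  expect_true(all(f$in_safety <= f$in_itt))
  expect_true(all(f$in_per_protocol <= f$in_itt))
  expect_true(all(f$overall_compliance >= 0 & f$overall_compliance <= 100))
})

test_that("window filtering excludes only out-of-window assessments", {
  tr <- simulate_trial(small_config(n_per_arm = 30, seed = 4))
  tr$visits$day[tr$visits$visit == 1] <- 90    # all nominal
  tr$visits$day[tr$visits$visit == 0] <- 0
  tr$visits$day[tr$visits$visit == 2] <- 365
  unchanged <- window_filter(tr)
  expect_equal(unchanged$visits$cognitive, tr$visits$cognitive)

  tr$visits$day[tr$visits$visit == 1][1] <- 200
  filtered <- window_filter(tr)
  idx <- which(tr$visits$visit == 1)[1]
  expect_true(is.na(filtered$visits$cognitive[idx]))
  excl <- attr(filtered, "window_exclusions")
  expect_equal(nrow(excl), 1L)
  expect_equal(excl$day, 200)

  # widening windows never decreases the retained count
  wide <- window_filter(tr, visit_windows(month3 = c(30, 250)))
  expect_gte(sum(!is.na(wide$visits$cognitive)),
             sum(!is.na(filtered$visits$cognitive)))
  expect_error(visit_windows(month3 = c(118, 62)), "lower bound")
  expect_error(visit_windows(baseline = c(-14, 80)), "non-overlapping")
})

test_that("period aggregates are additive and truncate person-time at exit", {
  tr <- simulate_trial(sim_config(n_per_arm = 40, seed = 19))
  agg <- period_aggregates(tr)
  interv <- agg[agg$period == "intervention", ]
  ext <- agg[agg$period == "extended", ]
  study <- agg[agg$period == "study", ]
  for (tp in c("fever", "diarrhoea", "vomiting"))
    expect_equal(study[[tp]], interv[[tp]] + ext[[tp]])
  expect_equal(study$person_days, interv$person_days + ext$person_days)

  # child exiting at day 45: intervention person-time 45, extended 0
  tr$children$last_contact_day[1] <- 45
  tr$morbidity <- tr$morbidity[!(tr$morbidity$child_id == tr$children$child_id[1] &
                                   tr$morbidity$day > 45), ]
  agg2 <- period_aggregates(tr)
  cid <- tr$children$child_id[1]
  expect_equal(agg2$person_days[agg2$child_id == cid &
                                  agg2$period == "intervention"], 45)
  expect_equal(agg2$person_days[agg2$child_id == cid &
                                  agg2$period == "extended"], 0)

  # a known report pattern counts exactly
  tr$morbidity$fever[tr$morbidity$child_id == cid] <- 0
  rows <- which(tr$morbidity$child_id == cid &
                  tr$morbidity$period == "intervention")[1:2]
  tr$morbidity$fever[rows] <- 1
  agg3 <- period_aggregates(tr)
  expect_equal(agg3$fever[agg3$child_id == cid &
                            agg3$period == "intervention"], 2L)

  # reports after death are inconsistent input
  tr$children$death_day[2] <- 10
  expect_error(period_aggregates(tr), "after death")
})
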