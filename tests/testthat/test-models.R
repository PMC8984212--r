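make_binary_fixture <- function(events = c(iron = 40, mnp = 30, placebo = 20),
                                n = 200) {
  arms <- rep(names(events), each = n)
  y <- unlist(lapply(events, function(e) rep(c(1L, 0L), c(e, n - e))))
  data.frame(child_id = sprintf("B%04d", seq_along(arms)), arm = arms,
             visit = 1L, y = unname(y), stringsAsFactors = FALSE)
}

test_that("degenerate binomial model reproduces the 2x2-table prevalence ratio", {
  df <- make_binary_fixture()
  fit <- fit_binary_mixed(df, "y", link = "log", covariates = character(0),
                          random_intercept = FALSE)
  expect_equal(fit$scale_label, "prevalence-ratio")
  e <- fit$effects
  expect_equal(e$estimate[e$comparison == "iron vs placebo"],
               (40 / 200) / (20 / 200), tolerance = 1e-6)
  expect_equal(e$estimate[e$comparison == "iron vs mnp"],
               (40 / 200) / (30 / 200), tolerance = 1e-6)
})

test_that("log-link failure triggers the documented logit fallback", {
  # quasi-separated fixture: near-saturated prevalence breaks the log link
  set.seed(61)
  n <- 120
  df <- data.frame(
    child_id = rep(sprintf("S%03d", 1:n), each = 2),
    arm = rep(rep(c("iron", "mnp", "placebo"), each = n / 3), each = 2),
    visit = rep(1:2, n), stringsAsFactors = FALSE)
  p <- ifelse(df$arm == "iron", 0.98, 0.5)
  df$y <- rbinom(nrow(df), 1, p)
  fit <- fit_binary_mixed(df, "y", link = "log", covariates = character(0))
  if (fit$link_used == "logit") {
    expect_equal(fit$scale_label, "odds-ratio")
    expect_false(is.null(fit$fallback_reason))
  } else {
    # if the log link survived, fitted probabilities must be admissible
    expect_lt(max(stats::fitted(fit$model)), 1)
  }
})

test_that("a single-level outcome is rejected", {
  df <- make_binary_fixture(events = c(iron = 0, mnp = 0, placebo = 0))
  expect_error(fit_binary_mixed(df, "y", random_intercept = FALSE),
               "single observed level")
})

test_that("treatment-only Poisson model returns the crude rate ratios", {
  # 30 events over 100 child-months vs 20 over 100: IRR 1.5
  df <- data.frame(
    arm = rep(c("iron", "mnp", "placebo"), each = 50),
    events = c(rep(c(1L, 0L), c(30, 20)), rep(c(1L, 0L), c(24, 26)),
               rep(c(1L, 0L), c(20, 30))),
    pt = 2)  # 50 children x 2 months = 100 child-months per arm
  fit <- fit_poisson_rate(df, "events", "pt")
  e <- fit$effects
  expect_equal(e$estimate[e$comparison == "iron vs placebo"], 30 / 20,
               tolerance = 1e-6)
  expect_equal(e$estimate[e$comparison == "mnp vs placebo"], 24 / 20,
               tolerance = 1e-6)

  # offset contract: doubling exposures with counts fixed leaves IRRs
  # unchanged and halves each rate
  df2 <- df; df2$pt <- df$pt * 2
  fit2 <- fit_poisson_rate(df2, "events", "pt")
  expect_equal(fit2$effects$estimate, fit$effects$estimate, tolerance = 1e-8)
  r1 <- fit$events_per_arm / fit$person_time_per_arm
  r2 <- fit2$events_per_arm / fit2$person_time_per_arm
  expect_equal(unname(r2), unname(r1) / 2)
})

test_that("zero-event arms give non-estimable comparisons, not crashes", {
  df <- data.frame(arm = rep(c("iron", "mnp", "placebo"), each = 40),
                   events = c(rep(0L, 40), rep(c(1L, 0L), c(5, 35)),
                              rep(c(1L, 0L), c(4, 36))),
                   pt = 30)
  fit <- suppressWarnings(fit_poisson_rate(df, "events", "pt"))
  e <- fit$effects
  expect_false(e$estimable[e$comparison == "iron vs placebo"])
  expect_true(e$estimable[e$comparison == "mnp vs placebo"])
  expect_true(is.na(e$estimate[e$comparison == "iron vs placebo"]))
})

test_that("treatment-only log-binomial model returns observed risk ratios", {
  df <- make_binary_fixture(events = c(iron = 30, mnp = 24, placebo = 12),
                            n = 120)
  fit <- fit_log_binomial(df, "y")
  expect_equal(fit$method, "log-binomial")
  e <- fit$effects
  expect_equal(e$estimate[e$comparison == "iron vs placebo"],
               (30 / 120) / (12 / 120), tolerance = 1e-6)
})

test_that("log-binomial agrees with an independent likelihood-search oracle", {
  set.seed(67)
  n <- 240
  df <- data.frame(arm = rep(c("iron", "mnp", "placebo"), each = n / 3),
                   x = rbinom(n, 1, 0.5))
  eta <- log(0.25) + log(1.6) * (df$arm == "iron") +
    log(1.2) * (df$arm == "mnp") + log(1.3) * df$x
  df$y <- rbinom(n, 1, exp(eta))
  fit <- fit_log_binomial(df, "y", covariates = "x")
  skip_if(fit$method != "log-binomial")
  X <- stats::model.matrix(~ arm + x,
                           transform(df, arm = factor(arm,
                             levels = c("placebo", "iron", "mnp"))))
  oracle <- stats::optim(c(log(mean(df$y)), 0, 0, 0),
                         function(b) -logbinom_loglik(b, X, df$y),
                         method = "Nelder-Mead",
                         control = list(maxit = 5000, reltol = 1e-12))
  expect_equal(unname(stats::coef(fit$model)), oracle$par, tolerance = 1e-3)
})

test_that("an all-zero arm in the risk-ratio model is flagged non-estimable", {
  df <- make_binary_fixture(events = c(iron = 0, mnp = 10, placebo = 8), n = 60)
  fit <- suppressWarnings(fit_log_binomial(df, "y"))
  e <- fit$effects
  expect_false(e$estimable[e$comparison == "iron vs placebo"])
  expect_true(e$estimable[e$comparison == "mnp vs placebo"])
})
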