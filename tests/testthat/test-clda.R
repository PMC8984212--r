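make_two_visit_fixture <- function(seed = 7, n = 60, rho = 0.5) {
  set.seed(seed)
  arm <- sample(rep(c("iron", "mnp", "placebo"), each = n / 3))
  y0 <- rnorm(n, 100, 15)
  y1 <- 100 + 2 * (arm == "iron") - 1 * (arm == "mnp") +
    rho * (y0 - 100) + rnorm(n, 0, 10)
  list(df = two_visit_frame(n, arm, y0, y1), arm = arm, y0 = y0, y1 = y1)
}

test_that("cLDA on complete two-visit data equals the ANCOVA/GLS oracle", {
  fx <- make_two_visit_fixture()
  fit <- fit_clda(fx$df, "y", covariates = character(0),
                  control = list(reltol = 1e-14))
  anc <- stats::lm(y1 ~ y0 + arm,
                   data = data.frame(y0 = fx$y0, y1 = fx$y1,
                                     arm = factor(fx$arm,
                                                  levels = c("placebo", "iron", "mnp"))))
  expect_equal(unname(coef(fit)[c("iron:visit1", "mnp:visit1")]),
               unname(coef(anc)[c("armiron", "armmnp")]),
               tolerance = 1e-6)
  expect_true(fit$converged)
})

test_that("with a known diagonal covariance the baseline carries no information", {
  fx <- make_two_visit_fixture(seed = 11)
  fit <- fit_clda(fx$df, "y", covariates = character(0),
                  fixed_sigma = diag(c(225, 140)))
  # closed-form WLS oracle: delta = unadjusted difference in month-3 means
  d_iron <- mean(fx$y1[fx$arm == "iron"]) - mean(fx$y1[fx$arm == "placebo"])
  d_mnp <- mean(fx$y1[fx$arm == "mnp"]) - mean(fx$y1[fx$arm == "placebo"])
  expect_equal(unname(coef(fit)["iron:visit1"]), d_iron, tolerance = 1e-10)
  expect_equal(unname(coef(fit)["mnp:visit1"]), d_mnp, tolerance = 1e-10)
  expect_equal(fit$structure, "fixed")
})

test_that("adding a constant shifts only the baseline mean", {
  fx <- make_two_visit_fixture(seed = 13)
  f1 <- fit_clda(fx$df, "y", covariates = character(0))
  df2 <- fx$df
  df2$y <- df2$y + 7
  f2 <- fit_clda(df2, "y", covariates = character(0))
  expect_equal(unname(coef(f2)["(baseline)"]),
               unname(coef(f1)["(baseline)"]) + 7, tolerance = 1e-5)
  others <- setdiff(names(coef(f1)), "(baseline)")
  expect_equal(coef(f2)[others], coef(f1)[others], tolerance = 1e-4)
  expect_equal(f2$sigma, f1$sigma, tolerance = 1e-3)
})

test_that("three-visit fit with missing data matches the nlme GLS oracle", {
  skip_if_not_installed("nlme")
  cfg <- small_config(n_per_arm = 80, seed = 23,
                      effects = list(iron = list(cognitive = c(0, 2, 3))))
  tr <- simulate_trial(cfg)
  fit <- fit_clda(tr, "cognitive")
  af <- analysis_frame(tr)
  af$fv <- factor(af$visit)
  for (a in c("iron", "mnp")) for (v in 1:2)
    af[[paste0(a, v)]] <- (af$visit == v) * (af$arm == a)
  g <- nlme::gls(cognitive ~ fv + iron1 + iron2 + mnp1 + mnp2 + union + sex,
                 data = af,
                 correlation = nlme::corSymm(form = ~ as.integer(fv) | child_id),
                 weights = nlme::varIdent(form = ~ 1 | fv), method = "ML")
  nm <- c("iron:visit1", "iron:visit2", "mnp:visit1", "mnp:visit2")
  expect_equal(unname(coef(fit)[nm]),
               unname(coef(g)[c("iron1", "iron2", "mnp1", "mnp2")]),
               tolerance = 1e-4)
  expect_equal(fit$logLik, as.numeric(stats::logLik(g)), tolerance = 1e-6)
})

test_that("unstructured likelihood dominates every structured fallback", {
  tr <- apply_missingness(simulate_trial(small_config(n_per_arm = 100, seed = 29)),
                          seed = 30)
  ll <- sapply(c("unstructured", "ar1", "toeplitz", "cs"), function(st)
    fit_clda(tr, "cognitive", covariance = st)$logLik)
  expect_true(all(ll["unstructured"] >= ll[-1] - 1e-4))
})

test_that("the non-convergence cascade labels the structure that converged", {
  tr <- simulate_trial(small_config(n_per_arm = 60, seed = 31))
  fit <- fit_clda_cascade(tr, "cognitive")
  expect_true(fit$converged)
  expect_true(fit$structure %in% c("unstructured", "ar1", "toeplitz", "cs"))
})

test_that("a singular model matrix is rejected naming the offending term", {
  fx <- make_two_visit_fixture(seed = 37)
  fx$df$dup <- as.numeric(fx$df$arm == "iron" & fx$df$visit == 1)
  expect_error(fit_clda(fx$df, "y", covariates = c("dup")), "singular.*dup")
})

test_that("log transform requires positive values and flags ratio scale", {
  cfg <- sim_config(n_per_arm = 60, outcomes = "ferritin", seed = 41,
                    include_morbidity = FALSE, include_adherence = FALSE)
  tr <- simulate_trial(cfg)
  fit <- fit_clda(tr, "ferritin", transform = "log")
  eff <- estimate_effect(fit, c("iron", "placebo"), 1)
  expect_equal(eff$scale, "ratio")
  expect_true(eff$ci_lower > 0)
  # null simulated ferritin effect: geometric-mean ratio near 1
  expect_lt(abs(log(eff$estimate)), 3 * eff$se)
  tr$visits$ferritin[1] <- -2
  expect_error(fit_clda(tr, "ferritin", transform = "log"), "positive")
})
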