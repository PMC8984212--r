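# Multiple imputation by chained equations in wide ("just another variable")
# format: one row per child, one column per outcome-visit, imputed
# separately within each treatment arm so that imputation respects any
# treatment effect. Linear steps draw the error variance from its scaled
# inverse-chi-square posterior and the coefficients from their conditional
# normal; logistic steps draw coefficients from the large-sample normal
# approximation to their posterior. Ferritin is imputed on the natural-log
# scale and back-transformed.

#' Missing-data descriptives
#'
#' Per-outcome, per-visit missing counts and percentages, plus baseline and
#' demographic characteristics summarised by missing-versus-observed status
#' of the cognitive composite at each visit (the standard check for
#' auxiliary variables and the plausibility of the MAR assumption).
#'
#' @param trial a `trial_data` object.
#' @param outcomes outcome columns to summarise (default: all present).
#' @param baseline_vars numeric baseline covariates for the by-missingness
#'   comparison.
#' @return list with `missingness` (outcome x visit table) and
#'   `by_missingness` (per visit: covariate means in missing vs observed
#'   groups).
#' @export
missingness_summary <- function(trial,
                                outcomes = NULL,
                                baseline_vars = c("maternal_education",
                                                  "fci_score",
                                                  "food_insecurity",
                                                  "wealth_quintile")) {
  v <- trial$visits
  outcomes <- outcomes %||% intersect(outcome_registry()$outcome, names(v))
  rows <- list()
  for (out in outcomes) for (vis in sort(unique(v$visit))) {
    yy <- v[[out]][v$visit == vis]
    rows[[length(rows) + 1L]] <- data.frame(
      outcome = out, visit = vis, n = length(yy),
      n_missing = sum(is.na(yy)),
      pct_missing = 100 * mean(is.na(yy)), stringsAsFactors = FALSE)
  }
  miss_tab <- do.call(rbind, rows)

  by_miss <- NULL
  if ("cognitive" %in% names(v)) {
    baseline_vars <- intersect(baseline_vars, names(trial$children))
    by_miss <- do.call(rbind, lapply(sort(unique(v$visit)), function(vis) {
      sub <- v[v$visit == vis, c("child_id", "cognitive")]
      mrg <- merge(sub, trial$children[, c("child_id", baseline_vars)],
                   by = "child_id")
      miss <- is.na(mrg$cognitive)
      do.call(rbind, lapply(baseline_vars, function(bv) data.frame(
        visit = vis, variable = bv,
        mean_missing = mean(mrg[[bv]][miss]),
        mean_observed = mean(mrg[[bv]][!miss]),
        n_missing = sum(miss), n_observed = sum(!miss),
        stringsAsFactors = FALSE)))
    }))
  }
  list(missingness = miss_tab, by_missingness = by_miss)
}

#' Number of imputations rule
#'
#' The number of imputed data sets is at least the percentage of missing
#' data (rounded up), with a floor of `default_m`.
#'
#' @param missing_percentage percentage in [0, 100].
#' @param default_m floor (default 5).
#' @return integer m.
#' @export
choose_m <- function(missing_percentage, default_m = 5L) {
  if (missing_percentage < 0 || missing_percentage > 100)
    stop_cldagate("`missing_percentage` must be in [0, 100]")
  max(as.integer(default_m), as.integer(ceiling(missing_percentage)))
}

# one Bayesian-linear-regression imputation step (the classic "norm" draw)
impute_norm_draw <- function(y, X, miss) {
  obs <- !miss
  Xo <- X[obs, , drop = FALSE]; yo <- y[obs]
  qr_ <- qr(Xo)
  r <- qr_$rank
  if (r < ncol(Xo)) {
    keepc <- qr_$pivot[seq_len(r)]
    Xo <- Xo[, keepc, drop = FALSE]; X <- X[, keepc, drop = FALSE]
    qr_ <- qr(Xo)
  }
  beta_hat <- qr.coef(qr_, yo)
  res <- yo - drop(Xo %*% beta_hat)
  dfres <- max(length(yo) - ncol(Xo), 1L)
  sigma2 <- sum(res^2) / stats::rchisq(1, dfres)
  R <- qr.R(qr_)
  beta_star <- beta_hat + drop(backsolve(R, stats::rnorm(ncol(Xo)))) * sqrt(sigma2)
  drop(X[miss, , drop = FALSE] %*% beta_star) +
    stats::rnorm(sum(miss), 0, sqrt(sigma2))
}

# one logistic imputation step with a normal-approximation posterior draw
impute_logit_draw <- function(y, X, miss) {
  obs <- !miss
  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(X[obs, , drop = FALSE], y[obs],
                                    family = stats::binomial())),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged) {
    # degenerate/separated step: draw from the observed empirical distribution
    return(sample(y[obs], sum(miss), replace = TRUE))
  }
  beta_hat <- fit$coefficients
  w <- fit$weights
  V <- tryCatch(solve(crossprod(X[obs, , drop = FALSE] * sqrt(w))),
                error = function(e) NULL)
  if (is.null(V)) return(sample(y[obs], sum(miss), replace = TRUE))
  beta_star <- beta_hat + drop(chol(V) %*% stats::rnorm(length(beta_hat)))
  p <- stats::plogis(drop(X[miss, , drop = FALSE] %*% beta_star))
  stats::rbinom(sum(miss), 1, p)
}

#' Wide-format per-child table for imputation
#'
#' One row per child: baseline covariates plus `<outcome>_v<visit>` columns.
#'
#' @param trial a `trial_data` object.
#' @param outcomes outcomes to spread (default all present).
#' @return wide data.frame.
#' @export
trial_wide <- function(trial, outcomes = NULL) {
  outcomes <- outcomes %||% intersect(outcome_registry()$outcome,
                                      names(trial$visits))
  kids <- trial$children[!trial$children$consent_withdrawn_all_data, , drop = FALSE]
  wide <- kids
  for (out in outcomes) for (vis in sort(unique(trial$visits$visit))) {
    sub <- trial$visits[trial$visits$visit == vis, c("child_id", out)]
    names(sub)[2] <- paste0(out, "_v", vis)
    wide <- merge(wide, sub, by = "child_id", all.x = TRUE, sort = TRUE)
  }
  wide
}

#' Multiple imputation by chained equations, wide format
#'
#' Imputes the per-visit outcome columns of a wide per-child table by
#' chained univariate regressions — each incomplete column modelled on the
#' baseline predictors plus all other outcome-visit columns ("just another
#' variable") — separately within each treatment arm, with full
#' posterior-draw parameter uncertainty. Continuous columns use Bayesian
#' linear regression; binary columns use logistic regression. Columns whose
#' names start with `ferritin` are imputed on the natural-log scale and
#' back-transformed. Deterministic given the seed.
#'
#' @param data wide per-child data.frame (see [trial_wide()]) or a
#'   `trial_data` object (converted internally).
#' @param m number of completed data sets (see [choose_m()]).
#' @param variables columns to impute; default every `<outcome>_v<visit>`
#'   column with missing values.
#' @param predictors baseline predictor columns (default union, sex,
#'   fci_score, maternal_education plus any supplied auxiliaries).
#' @param iterations chained-equation cycles per imputation (default 10).
#' @param by_arm impute separately within each arm (default TRUE).
#' @param seed integer seed.
#' @return object of class `imputed_stack`: list with `data` (list of m
#'   completed data.frames), `m`, `iterations`, `variables`, `seed`,
#'   `model_types`.
#' @export
mice_jav <- function(data, m, variables = NULL,
                     predictors = c("union", "sex", "fci_score",
                                    "maternal_education"),
                     iterations = 10L, by_arm = TRUE, seed = 1L) {
  if (inherits(data, "trial_data")) data <- trial_wide(data)
  assert_count(m, "m")
  if (m < 1L) stop_cldagate("m must be >= 1")
  visit_cols <- grep("_v[0-9]+$", names(data), value = TRUE)
  variables <- variables %||% visit_cols[vapply(data[visit_cols],
                                                anyNA, TRUE)]
  if (!length(variables)) {
    stack <- replicate(m, data, simplify = FALSE)
    return(structure(list(data = stack, m = m, iterations = 0L,
                          variables = character(0), seed = seed,
                          model_types = character(0), by_arm = by_arm),
                     class = "imputed_stack"))
  }
  # chronological imputation order: visit index, then outcome name
  vord <- order(as.integer(sub(".*_v", "", variables)), variables)
  variables <- variables[vord]
  predictors <- intersect(predictors, names(data))

  is_binary <- vapply(variables, function(v) {
    u <- unique(data[[v]][!is.na(data[[v]])])
    length(u) <= 2L && all(u %in% c(0, 1, TRUE, FALSE))
  }, TRUE)
  model_types <- ifelse(is_binary, "logistic", "linear")
  names(model_types) <- variables
  log_scale <- grepl("^ferritin", variables)

  groups <- if (by_arm) split(seq_len(nrow(data)), data$arm)
            else list(all = seq_len(nrow(data)))
  for (g in names(groups)) {
    for (v in variables) {
      col <- data[[v]][groups[[g]]]
      if (all(is.na(col)))
        stop_cldagate("variable `", v, "` is 100% missing within arm `", g,
                      "`; cannot impute")
    }
  }

  work <- data
  for (j in which(log_scale)) work[[variables[j]]] <- log(work[[variables[j]]])
  miss_map <- lapply(variables, function(v) is.na(work[[v]]))
  names(miss_map) <- variables

  seeds <- spawn_seeds(seed, m)
  stack <- vector("list", m)
  for (im in seq_len(m)) {
    stack[[im]] <- with_seed(seeds[im], {
      cur <- work
      # initial fill: random draws from each column's observed values
      for (v in variables) {
        ms <- miss_map[[v]]
        cur[[v]][ms] <- sample(cur[[v]][!ms], sum(ms), replace = TRUE)
      }
      for (it in seq_len(iterations)) {
        for (v in variables) {
          ms <- miss_map[[v]]
          if (!any(ms)) next
          # JAV: every other outcome-visit column (complete or imputed)
          # joins the baseline predictors
          rhs <- c(predictors, setdiff(visit_cols, v))
          for (g in groups) {
            ms_g <- ms[g]
            if (!any(ms_g)) next
            sub <- cur[g, , drop = FALSE]
            # drop constant columns within the arm (e.g. single-union strata)
            rhs_g <- rhs[vapply(sub[rhs], function(x)
              length(unique(x[!is.na(x)])) > 1L, TRUE)]
            X <- if (length(rhs_g)) {
              pf <- sub[rhs_g]
              for (cc in rhs_g) if (is.character(pf[[cc]])) pf[[cc]] <- factor(pf[[cc]])
              stats::model.matrix(~ ., data = pf)
            } else matrix(1, nrow(sub), 1L)
            y <- sub[[v]]
            imp <- if (model_types[[v]] == "logistic")
              impute_logit_draw(as.integer(y), X, ms_g)
            else impute_norm_draw(y, X, ms_g)
            cur[[v]][g[ms_g]] <- imp
          }
        }
      }
      for (j in which(log_scale)) cur[[variables[j]]] <- exp(cur[[variables[j]]])
      cur
    })
  }
  structure(list(data = stack, m = m, iterations = iterations,
                 variables = variables, seed = seed,
                 model_types = model_types, by_arm = by_arm,
                 predictors = predictors),
            class = "imputed_stack")
}

#' @export
print.imputed_stack <- function(x, ...) {
  cat("<imputed_stack> m =", x$m, " iterations =", x$iterations,
      " by_arm =", x$by_arm, "\n")
  cat("  imputed variables:", paste(x$variables, collapse = ", "), "\n")
  invisible(x)
}

#' Pool per-imputation estimates by Rubin's rules
#'
#' Pooled estimate Q-bar is the mean of the per-imputation estimates;
#' within-imputation variance U-bar is the mean of the variances; between-
#' imputation variance B is the sample variance of the estimates; total
#' variance T = U-bar + (1 + 1/m) B. Degrees of freedom follow the
#' Barnard-Rubin small-sample formula when a finite complete-data df is
#' supplied, and the classic large-sample formula otherwise; the interval
#' uses the t reference.
#'
#' @param estimates per-imputation point estimates (m >= 2).
#' @param variances per-imputation squared standard errors.
#' @param ci_level confidence level.
#' @param dfcom complete-data degrees of freedom (Inf for the large-sample
#'   rule).
#' @return object of class `pooled_estimate`: list with `qbar`, `ubar`,
#'   `b`, `t`, `df`, `se`, `ci_lower`, `ci_upper`, `p_value`, `m`.
#' @export
rubin_pool <- function(estimates, variances, ci_level = 0.95, dfcom = Inf) {
  m <- length(estimates)
  if (m < 2L) stop_cldagate("Rubin pooling needs m >= 2 estimates")
  if (length(variances) != m) stop_cldagate("estimates/variances length mismatch")
  qbar <- mean(estimates)
  ubar <- mean(variances)
  b <- stats::var(estimates)
  tvar <- ubar + (1 + 1 / m) * b
  if (b > 0) {
    lambda <- (1 + 1 / m) * b / tvar
    df_old <- (m - 1) / lambda^2
    if (is.finite(dfcom)) {
      df_obs <- (dfcom + 1) / (dfcom + 3) * dfcom * (1 - lambda)
      df <- 1 / (1 / df_old + 1 / df_obs)
    } else df <- df_old
  } else df <- Inf
  se <- sqrt(tvar)
  crit <- if (is.finite(df)) stats::qt(1 - (1 - ci_level) / 2, df)
          else stats::qnorm(1 - (1 - ci_level) / 2)
  stat <- qbar / se
  p <- if (is.finite(df)) 2 * stats::pt(-abs(stat), df)
       else 2 * stats::pnorm(-abs(stat))
  structure(list(qbar = qbar, ubar = ubar, b = b, t = tvar, df = df,
                 se = se, ci_lower = qbar - crit * se,
                 ci_upper = qbar + crit * se, ci_level = ci_level,
                 p_value = p, m = m),
            class = "pooled_estimate")
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf("Pooled estimate %.4g (SE %.4g), %g%% CI [%.4g, %.4g], m = %d\n",
              x$qbar, x$se, 100 * x$ci_level, x$ci_lower, x$ci_upper, x$m))
  cat(sprintf("  within U = %.4g, between B = %.4g, total T = %.4g, df = %.1f\n",
              x$ubar, x$b, x$t, x$df))
  invisible(x)
}

#' Fit the cLDA on every completed data set and pool one effect
#'
#' Reshapes each completed wide data set back to child-visit format, fits
#' the constrained model, extracts the requested comparison-by-visit
#' effect, and pools with Rubin's rules.
#'
#' @param stack an `imputed_stack`.
#' @param outcome outcome name (its `<outcome>_v*` columns must exist).
#' @param comparison,visit as in [estimate_effect()].
#' @param ci_level confidence level.
#' @param ... passed to [fit_clda()].
#' @return a `pooled_estimate`.
#' @export
pool_clda_effect <- function(stack, outcome, comparison = c("iron", "placebo"),
                             visit = 1, ci_level = 0.95, ...) {
  ests <- vars <- numeric(stack$m)
  for (im in seq_len(stack$m)) {
    wide <- stack$data[[im]]
    vcols <- grep(paste0("^", outcome, "_v[0-9]+$"), names(wide), value = TRUE)
    long <- do.call(rbind, lapply(vcols, function(vc) {
      data.frame(child_id = wide$child_id, arm = wide$arm,
                 union = wide$union, sex = wide$sex,
                 visit = as.integer(sub(".*_v", "", vc)),
                 y = wide[[vc]], stringsAsFactors = FALSE)
    }))
    names(long)[names(long) == "y"] <- outcome
    fit <- fit_clda(long, outcome, ...)
    eff <- estimate_effect(fit, comparison, visit, ci_level = ci_level)
    if (eff$scale == "ratio") {
      ests[im] <- log(eff$estimate)
    } else ests[im] <- eff$estimate
    vars[im] <- eff$se^2
  }
  rubin_pool(ests, vars, ci_level = ci_level)
}
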