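# Safety and binary-outcome regression models. These are standard fits
# (lme4 / stats::glm) wrapped so every comparison is reported in the trial's
# house style: ratio estimate, Wald CI, unadjusted p, with documented
# fallbacks on convergence failure.

arm_factor <- function(x) factor(x, levels = intersect(ARMS[c(3, 1, 2)], unique(x)))

# Ratio effects (exp of contrasts) for the three pairwise comparisons from a
# coefficient vector containing `armiron` / `armmnp` terms (placebo
# reference), optionally plus an interaction adjustment vector.
pairwise_ratio <- function(coefs, V, extra = NULL, visit = NA,
                           ci_level = 0.95, scale_label = "ratio",
                           estimable = c(iron = TRUE, mnp = TRUE, placebo = TRUE)) {
  cmps <- list(c("iron", "placebo"), c("mnp", "placebo"), c("iron", "mnp"))
  rows <- lapply(cmps, function(cmp) {
    cvec <- stats::setNames(numeric(length(coefs)), names(coefs))
    for (sgn in c(1, -1)) {
      a <- cmp[if (sgn == 1) 1 else 2]
      if (a != "placebo") {
        nm <- paste0("arm", a)
        if (nm %in% names(cvec)) cvec[nm] <- cvec[nm] + sgn
        if (!is.null(extra)) {
          inm <- extra[[a]]
          if (!is.null(inm) && inm %in% names(cvec)) cvec[inm] <- cvec[inm] + sgn
        }
      }
    }
    ok <- all(estimable[cmp])
    est <- sum(cvec * coefs)
    se <- sqrt(drop(t(cvec) %*% V %*% cvec))
    crit <- stats::qnorm(1 - (1 - ci_level) / 2)
    data.frame(
      comparison = paste(cmp, collapse = " vs "), visit = visit,
      estimate = if (ok) exp(est) else NA_real_,
      ci_lower = if (ok) exp(est - crit * se) else NA_real_,
      ci_upper = if (ok) exp(est + crit * se) else NA_real_,
      se_log = if (ok) se else NA_real_, ci_level = ci_level,
      p_unadjusted = if (ok) 2 * stats::pnorm(-abs(est / se)) else NA_real_,
      scale = scale_label, estimable = ok, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Binomial mixed model for repeated binary outcomes
#'
#' Generalised linear mixed model with a binomial distribution, a child-level
#' random intercept (15-point adaptive Gauss-Hermite quadrature), and a log
#' link yielding prevalence ratios. If the log-link fit fails to converge or
#' produces fitted probabilities at or above 1, the documented fallback
#' refits with a logit link and the effects are labelled odds ratios. The
#' baseline status of the indicator enters as a covariate (the
#' common-baseline constraint of the continuous model does not transfer
#' cleanly to a nonlinear link).
#'
#' @param data `trial_data` or child-visit data.frame with a binary column.
#' @param outcome name of the binary (0/1 or logical) column.
#' @param link "log" (prevalence ratio) or "logit" (odds ratio).
#' @param covariates baseline adjustment covariates (default union, sex).
#' @param random_intercept set FALSE to drop the random intercept and fit a
#'   plain GLM (used for degenerate/oracle configurations).
#' @param baseline_adjust include the visit-0 value of the indicator as a
#'   covariate when available.
#' @param nagq quadrature points for the random intercept (default 15).
#' @return list of class `binary_mixed_fit`: `model`, `link_used`,
#'   `scale_label`, `fallback_reason` (NULL if none), and `effects` — one
#'   row per comparison per post-baseline visit.
#' @export
fit_binary_mixed <- function(data, outcome, link = c("log", "logit"),
                             covariates = c("union", "sex"),
                             random_intercept = TRUE, baseline_adjust = TRUE,
                             nagq = 15L) {
  link <- match.arg(link)
  if (inherits(data, "trial_data")) data <- analysis_frame(data)
  if (!outcome %in% names(data)) stop_cldagate("outcome `", outcome, "` not in data")
  df <- data
  df$.y <- as.integer(df[[outcome]])
  base <- df[df$visit == 0L, c("child_id", ".y")]
  names(base)[2] <- ".y0"
  post <- df[df$visit > 0L & !is.na(df$.y), , drop = FALSE]
  if (baseline_adjust && nrow(base)) {
    post <- merge(post, base, by = "child_id", all.x = TRUE)
    if (all(is.na(post$.y0))) post$.y0 <- NULL
    else post <- post[!is.na(post$.y0), , drop = FALSE]
  }
  if (length(unique(post$.y)) < 2L)
    stop_cldagate("outcome `", outcome, "` has a single observed level")
  post$arm <- arm_factor(post$arm)
  visits <- sort(unique(post$visit))
  post$fvisit <- factor(post$visit)

  rhs <- c(if (".y0" %in% names(post)) ".y0",
           if (length(visits) > 1L) "fvisit",
           "arm",
           if (length(visits) > 1L) "arm:fvisit",
           covariates)
  fml_fixed <- paste(".y ~", paste(rhs, collapse = " + "))

  fit_one <- function(lnk) {
    if (random_intercept) {
      fml <- stats::as.formula(paste(fml_fixed, "+ (1 | child_id)"))
      m <- lme4::glmer(fml, data = post, family = stats::binomial(link = lnk),
                       nAGQ = nagq)
      conv <- length(m@optinfo$conv$lme4$messages %||% character(0)) == 0L
      list(model = m, coefs = lme4::fixef(m),
           V = as.matrix(stats::vcov(m)),
           fitted_max = max(stats::fitted(m)), converged = conv)
    } else {
      fml <- stats::as.formula(fml_fixed)
      start <- NULL
      if (lnk == "log") {
        p <- ncol(stats::model.matrix(fml, post))
        start <- c(log(max(mean(post$.y), 1e-3)), rep(0, p - 1L))
      }
      m <- suppressWarnings(stats::glm(fml, data = post,
                                       family = stats::binomial(link = lnk),
                                       start = start))
      list(model = m, coefs = stats::coef(m), V = stats::vcov(m),
           fitted_max = max(stats::fitted(m)), converged = m$converged)
    }
  }

  fallback_reason <- NULL
  res <- tryCatch(fit_one(link), error = function(e) e)
  if (link == "log" &&
      (inherits(res, "error") || !res$converged || res$fitted_max >= 1 - 1e-8)) {
    fallback_reason <- if (inherits(res, "error")) conditionMessage(res)
      else if (!res$converged) "log-link fit did not converge"
      else "log-link fitted probability reached 1"
    link <- "logit"
    res <- fit_one("logit")
  }
  if (inherits(res, "error")) stop_cldagate("binary model failed: ",
                                            conditionMessage(res))
  scale_label <- if (link == "log") "prevalence-ratio" else "odds-ratio"

  effects <- do.call(rbind, lapply(visits, function(v) {
    extra <- NULL
    if (length(visits) > 1L && v != visits[1]) {
      extra <- list(iron = paste0("armiron:fvisit", v),
                    mnp = paste0("armmnp:fvisit", v))
    }
    pairwise_ratio(res$coefs, res$V, extra = extra, visit = v,
                   scale_label = scale_label)
  }))
  structure(list(model = res$model, link_used = link, scale_label = scale_label,
                 fallback_reason = fallback_reason, effects = effects,
                 converged = res$converged),
            class = "binary_mixed_fit")
}

#' Poisson incidence-rate-ratio model with person-time offset
#'
#' Maximum-likelihood Poisson regression of per-child event counts with the
#' natural log of the time at risk as offset; in the treatment-only model
#' the fitted incidence rate ratios equal the crude event-rate ratios. A
#' comparison involving an arm with zero total events is reported
#' non-estimable rather than as a numerical blow-up.
#'
#' @param data per-child data.frame with `arm`, a count column and an
#'   exposure column.
#' @param count name of the event-count column.
#' @param exposure name of the person-time column (positive; children with
#'   zero exposure are excluded).
#' @param covariates optional additional covariates.
#' @param ci_level confidence level.
#' @return list of class `rate_fit`: `model` and `effects` (IRRs per
#'   pairwise comparison).
#' @export
fit_poisson_rate <- function(data, count, exposure,
                             covariates = NULL, ci_level = 0.95) {
  df <- data[!is.na(data[[count]]) & !is.na(data[[exposure]]), , drop = FALSE]
  df <- df[df[[exposure]] > 0, , drop = FALSE]
  if (!nrow(df)) stop_cldagate("no children with positive exposure")
  df$arm <- arm_factor(df$arm)
  df$.off <- log(df[[exposure]])
  fml <- stats::as.formula(paste(count, "~ arm",
    if (length(covariates)) paste("+", paste(covariates, collapse = " + ")) else ""))
  m <- stats::glm(fml, data = df, family = stats::poisson(), offset = df$.off)
  tot <- tapply(df[[count]], df$arm, sum)
  estimable <- stats::setNames(tot > 0, names(tot))
  effects <- pairwise_ratio(stats::coef(m), stats::vcov(m),
                            ci_level = ci_level,
                            scale_label = "incidence-rate-ratio",
                            estimable = estimable)
  structure(list(model = m, effects = effects,
                 events_per_arm = tot,
                 person_time_per_arm = tapply(df[[exposure]], df$arm, sum)),
            class = "rate_fit")
}

#' Log-binomial risk-ratio model with a robust-Poisson fallback
#'
#' Fits a binomial GLM with log link (risk ratios), keeping fitted
#' probabilities below 1; on boundary non-convergence the documented
#' fallback is a Poisson model with robust (sandwich) standard errors,
#' labelled as such. Arms with no events yield non-estimable comparisons.
#'
#' @param data per-child data.frame with `arm` and a binary indicator.
#' @param outcome name of the 0/1 indicator column.
#' @param covariates optional additional covariates.
#' @param ci_level confidence level.
#' @return list of class `riskratio_fit`: `model`, `method`
#'   ("log-binomial" or "poisson-robust"), `fallback_reason`, `effects`.
#' @export
fit_log_binomial <- function(data, outcome, covariates = NULL,
                             ci_level = 0.95) {
  df <- data[!is.na(data[[outcome]]), , drop = FALSE]
  df$.y <- as.integer(df[[outcome]])
  df$arm <- arm_factor(df$arm)
  fml <- stats::as.formula(paste(".y ~ arm",
    if (length(covariates)) paste("+", paste(covariates, collapse = " + ")) else ""))
  X <- stats::model.matrix(fml, df)
  start <- c(log(max(mean(df$.y), 1e-4)), rep(0, ncol(X) - 1L))

  method <- "log-binomial"; fallback_reason <- NULL
  m <- tryCatch(
    suppressWarnings(stats::glm(fml, data = df,
                                family = stats::binomial(link = "log"),
                                start = start)),
    error = function(e) e)
  bad <- inherits(m, "error") || !m$converged ||
    max(stats::fitted(m)) >= 1 - 1e-8
  if (bad) {
    fallback_reason <- if (inherits(m, "error")) conditionMessage(m)
      else if (!m$converged) "log-binomial fit did not converge"
      else "fitted probability at the boundary"
    method <- "poisson-robust"
    m <- stats::glm(fml, data = df, family = stats::poisson())
    V <- sandwich::vcovHC(m, type = "HC0")
  } else {
    V <- stats::vcov(m)
  }
  tot <- tapply(df$.y, df$arm, sum)
  estimable <- stats::setNames(tot > 0, names(tot))
  effects <- pairwise_ratio(stats::coef(m), V, ci_level = ci_level,
                            scale_label = "risk-ratio", estimable = estimable)
  structure(list(model = m, method = method, fallback_reason = fallback_reason,
                 effects = effects, events_per_arm = tot),
            class = "riskratio_fit")
}
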