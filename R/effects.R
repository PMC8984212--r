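#' Treatment effect from a fitted cLDA model
#'
#' The effect of arm `a` versus arm `b` at a post-baseline visit is the
#' difference in mean change from baseline, `delta_{a,t} - delta_{b,t}`
#' (with the placebo deltas identically zero under the baseline constraint).
#' A Wald confidence interval is produced at the assigned level — under the
#' gatekeeping procedure the interval level matches the significance level
#' used for the test. For log-transformed outcomes the estimate and interval
#' are exponentiated and labelled ratio-scale (a geometric-mean ratio).
#'
#' @param fit a converged `clda_fit`.
#' @param comparison length-2 character, e.g. `c("iron", "placebo")`.
#' @param visit post-baseline visit code (1 = month 3, 2 = month 12).
#' @param ci_level confidence level (default 0.95).
#' @param df degrees of freedom for a t reference; `Inf` (default) uses the
#'   normal reference appropriate at the trial's scale.
#' @return one-row data.frame of class `effect_estimate` with columns
#'   `comparison`, `visit`, `estimate`, `se`, `ci_lower`, `ci_upper`,
#'   `ci_level`, `p_unadjusted`, `scale`.
#' @export
estimate_effect <- function(fit, comparison, visit, ci_level = 0.95, df = Inf) {
  if (!inherits(fit, "clda_fit")) stop_cldagate("`fit` must be a clda_fit")
  if (!fit$converged) stop_cldagate("model did not converge; effects not reported")
  if (length(comparison) != 2L || !all(comparison %in% fit$arms))
    stop_cldagate("`comparison` must name two arms present in the fit")
  if (!visit %in% fit$visits[-1])
    stop_cldagate("`visit` must be a post-baseline visit of the fit: ",
                  paste(fit$visits[-1], collapse = ", "))
  assert_prob(ci_level, "ci_level")

  cvec <- stats::setNames(numeric(length(fit$coefficients)),
                          names(fit$coefficients))
  for (sgn in c(1, -1)) {
    a <- comparison[if (sgn == 1) 1 else 2]
    if (a != "placebo") {
      nm <- paste0(a, ":visit", visit)
      cvec[nm] <- cvec[nm] + sgn
    }
  }
  est <- sum(cvec * fit$coefficients)
  se <- sqrt(drop(t(cvec) %*% fit$vcov %*% cvec))
  crit <- if (is.finite(df)) stats::qt(1 - (1 - ci_level) / 2, df)
          else stats::qnorm(1 - (1 - ci_level) / 2)
  zstat <- est / se
  p <- if (is.finite(df)) 2 * stats::pt(-abs(zstat), df)
       else 2 * stats::pnorm(-abs(zstat))
  lo <- est - crit * se; hi <- est + crit * se
  scale <- "difference"
  if (fit$transform == "log") {
    est <- exp(est); lo <- exp(lo); hi <- exp(hi); scale <- "ratio"
  }
  out <- data.frame(
    comparison = paste(comparison, collapse = " vs "),
    visit = visit, estimate = est, se = se,
    ci_lower = lo, ci_upper = hi, ci_level = ci_level,
    p_unadjusted = p, scale = scale, stringsAsFactors = FALSE)
  class(out) <- c("effect_estimate", "data.frame")
  out
}

#' Subgroup analysis on the cLDA model
#'
#' Adds the subgroup main effect, subgroup-by-visit, and
#' subgroup-by-treatment-by-visit interaction terms to the constrained
#' model. (A separate subgroup-by-treatment term without visit would encode
#' an arm-by-subgroup difference at baseline, which the common-baseline
#' constraint excludes; the effect-modification of interest is carried
#' entirely by the three-way block.) Reports a Wald chi-square test of the
#' three-way interaction block and per-level treatment effects with 95%
#' confidence intervals suitable for a forest display.
#'
#' @param data `trial_data` or child-visit data.frame.
#' @param outcome outcome column name.
#' @param subgroup name of a baseline variable (factor or dichotomised).
#' @param comparisons list of arm pairs; default the three pairwise
#'   comparisons.
#' @param ... passed to [fit_clda()].
#' @return list with `fit`, `interaction_test` (statistic, df, p_value),
#'   and `effects` (a data.frame with one row per subgroup level x
#'   comparison x visit).
#' @export
subgroup_analysis <- function(data, outcome, subgroup,
                              comparisons = list(c("iron", "placebo"),
                                                 c("mnp", "placebo"),
                                                 c("iron", "mnp")), ...) {
  if (inherits(data, "trial_data")) data <- analysis_frame(data)
  if (!subgroup %in% names(data)) stop_cldagate("subgroup `", subgroup, "` not in data")
  g <- data[[subgroup]]
  if (!is.factor(g)) g <- factor(g)
  empty <- levels(g)[!levels(g) %in% unique(g[!is.na(g)])]
  if (length(empty)) {
    warning("dropping empty subgroup level(s): ", paste(empty, collapse = ", "))
    g <- droplevels(g)
  }
  if (nlevels(g) < 2L) stop_cldagate("subgroup must have at least 2 non-empty levels")
  data$.subgroup <- g
  data <- data[!is.na(data$.subgroup), , drop = FALSE]

  visits <- sort(unique(data$visit))
  active <- setdiff(intersect(ARMS, unique(data$arm)), "placebo")
  lev <- levels(g)[-1]

  extra <- NULL; three_way <- character(0)
  for (l in lev) {
    gl <- as.numeric(data$.subgroup == l)
    extra <- cbind(extra, `colnames<-`(matrix(gl), paste0(subgroup, l)))
    for (v in visits[-1]) {
      extra <- cbind(extra, `colnames<-`(
        matrix(gl * (data$visit == v)), paste0(subgroup, l, ":visit", v)))
      for (a in active) {
        nm <- paste0(a, ":visit", v, ":", subgroup, l)
        extra <- cbind(extra, `colnames<-`(
          matrix(gl * (data$visit == v) * (data$arm == a)), nm))
        three_way <- c(three_way, nm)
      }
    }
  }
  fit <- fit_clda(data, outcome, extra_terms = extra, ...)
  itest <- wald_block_test(fit, three_way)

  rows <- list()
  for (l in levels(g)) for (cmp in comparisons) for (v in visits[-1]) {
    cvec <- stats::setNames(numeric(length(fit$coefficients)),
                            names(fit$coefficients))
    for (sgn in c(1, -1)) {
      a <- cmp[if (sgn == 1) 1 else 2]
      if (a != "placebo") {
        cvec[paste0(a, ":visit", v)] <- cvec[paste0(a, ":visit", v)] + sgn
        if (l != levels(g)[1]) {
          nm <- paste0(a, ":visit", v, ":", subgroup, l)
          cvec[nm] <- cvec[nm] + sgn
        }
      }
    }
    est <- sum(cvec * fit$coefficients)
    se <- sqrt(drop(t(cvec) %*% fit$vcov %*% cvec))
    rows[[length(rows) + 1L]] <- data.frame(
      subgroup = subgroup, level = l,
      comparison = paste(cmp, collapse = " vs "), visit = v,
      estimate = est, se = se,
      ci_lower = est - stats::qnorm(0.975) * se,
      ci_upper = est + stats::qnorm(0.975) * se,
      p_unadjusted = 2 * stats::pnorm(-abs(est / se)),
      stringsAsFactors = FALSE)
  }
  list(fit = fit, interaction_test = itest, effects = do.call(rbind, rows))
}

#' Complier-average causal effect by the instrumental-variable ratio
#'
#' Randomised assignment is the instrument: the CACE is the
#' intention-to-treat effect divided by the between-arm difference in
#' complier proportions. In a placebo-controlled trial the control arm has
#' no access to active treatment, so that difference is the active arm's
#' complier proportion. The standard error comes from the delta method
#' treating the ITT estimate and the complier proportion as independent.
#'
#' @param itt_estimate,itt_se intention-to-treat effect and its SE.
#' @param p_complier complier proportion in the active arm.
#' @param n_active number of children in the active arm (for the binomial
#'   variance of `p_complier`).
#' @param ci_level confidence level.
#' @return one-row data.frame with `cace`, `se`, CI bounds and a
#'   `weak_instrument` flag (complier-proportion difference of 0.05 or
#'   less).
#' @export
cace_iv <- function(itt_estimate, itt_se, p_complier, n_active,
                    ci_level = 0.95) {
  assert_prob(p_complier, "p_complier")
  weak <- p_complier <= 0.05
  if (p_complier <= 0) stop_cldagate("complier proportion must be positive")
  cace <- itt_estimate / p_complier
  var_p <- p_complier * (1 - p_complier) / n_active
  se <- sqrt(itt_se^2 / p_complier^2 +
               itt_estimate^2 * var_p / p_complier^4)
  crit <- stats::qnorm(1 - (1 - ci_level) / 2)
  out <- data.frame(cace = cace, se = se,
                    ci_lower = cace - crit * se, ci_upper = cace + crit * se,
                    ci_level = ci_level, p_complier = p_complier,
                    weak_instrument = weak)
  if (weak)
    warning("weak instrument: complier-proportion difference <= 0.05; ",
            "estimate returned but unstable")
  out
}

#' CACE for a trial outcome
#'
#' Convenience wrapper: fits the cLDA on the two arms of the comparison,
#' takes the ITT effect at the requested visit, computes the active arm's
#' complier proportion from the population flags, and applies [cace_iv()].
#'
#' @param trial a `trial_data` object.
#' @param outcome outcome column name.
#' @param comparison length-2 arm pair, active arm first; the second arm
#'   must be placebo.
#' @param visit post-baseline visit.
#' @param flags population flags from [assign_populations()]; computed if
#'   omitted.
#' @param ... passed to [fit_clda()].
#' @return as [cace_iv()], with the ITT effect attached.
#' @export
estimate_cace <- function(trial, outcome, comparison = c("iron", "placebo"),
                          visit = 1, flags = NULL, ...) {
  if (comparison[2] != "placebo")
    stop_cldagate("the IV identification here requires a placebo comparator")
  flags <- flags %||% assign_populations(trial)
  fit <- fit_clda(trial, outcome, ...)
  eff <- estimate_effect(fit, comparison, visit)
  kids <- trial$children
  act <- kids$arm == comparison[1] & !kids$consent_withdrawn_all_data
  p_c <- mean(flags$complier[match(kids$child_id[act], flags$child_id)])
  res <- cace_iv(eff$estimate, eff$se, p_c, sum(act))
  res$itt_estimate <- eff$estimate
  res$comparison <- paste(comparison, collapse = " vs ")
  res$visit <- visit
  res
}
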