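#' Outcome registry for the synthetic trial generator
#'
#' Continuous outcomes simulated at the three visits. Log-normal outcomes
#' (ferritin, C-reactive protein) are generated on the natural-log scale and
#' exponentiated, so configured means/SDs and treatment effects for them are
#' meanlog/sdlog/log-ratios.
#'
#' @return data.frame with columns `outcome` and `dist`.
#' @export
outcome_registry <- function() {
  data.frame(
    outcome = c("cognitive", "language", "motor", "haemoglobin",
                "ferritin", "crp", "laz", "waz", "wlz", "head_circumference"),
    dist = c("normal", "normal", "normal", "normal",
             "lognormal", "lognormal", "normal", "normal", "normal", "normal"),
    stringsAsFactors = FALSE
  )
}

default_visit_means <- function() {
  list(
    cognitive          = c(100, 100, 100),
    language           = c(100, 100, 100),
    motor              = c(100, 100, 100),
    haemoglobin        = c(105, 110, 114),   # g/L, rising with age
    ferritin           = log(c(22, 18, 15)), # meanlog, physiologic decline
    crp                = log(c(1.5, 1.5, 1.5)), # meanlog, mg/L
    laz                = c(-1.3, -1.5, -1.7),
    waz                = c(-1.2, -1.3, -1.4),
    wlz                = c(-0.6, -0.7, -0.7),
    head_circumference = c(43.5, 45.0, 46.8)  # cm
  )
}

default_sds <- function() {
  c(cognitive = 15, language = 15, motor = 15, haemoglobin = 12,
    ferritin = 0.7, crp = 0.9, laz = 1.0, waz = 1.0, wlz = 1.0,
    head_circumference = 1.3)
}

#' Configuration for the synthetic three-arm trial generator
#'
#' Bundles every knob of the generator: arm sizes, the stratified
#' permuted-block randomisation scheme, visit means and treatment effects for
#' the continuous outcomes, the within-child covariance across the three
#' visits, morbidity report rates, adherence, dropout, and protocol-violation
#' rates. Defaults encode the planning assumptions of a three-arm infant iron
#' supplementation trial: Bayley-type composites with SD 15, a 20% loss to
#' follow-up, 1100 children per arm, and 1:1:1 allocation in permuted blocks
#' stratified by union (3 levels) and sex.
#'
#' @param n_per_arm children recruited per arm (default 1100).
#' @param strata_weights named probability vector over the six union x sex
#'   cells (names "Union.sex"); default uniform across unions, equal sexes.
#' @param block_size permuted-block length, must be a multiple of 3.
#' @param visit_means named list: per outcome, length-3 vector of visit means
#'   (meanlog for log-normal outcomes). Baseline means are common to all arms.
#' @param effects named list `effects[[arm]][[outcome]]` of length-3 additive
#'   shifts on the model scale (log-ratio for log-normal outcomes); the
#'   baseline entry must be 0 (randomised arms share the baseline law).
#' @param sds named vector of per-visit SDs (sdlog for log-normal outcomes).
#' @param correlation exchangeable within-child correlation across visits
#'   (default 0.4), used unless `covariance` overrides it for an outcome.
#' @param covariance optional named list of 3x3 positive-definite matrices.
#' @param morbidity_rates expected reports per occasion per infection type.
#' @param morbidity_dispersion negative-binomial size for overdispersed
#'   morbidity counts; `NULL` (default) means Poisson.
#' @param adherence_shape Beta(a, b) parameters for the per-child daily
#'   intake probability; default Beta(5, 2) (median adherence ~75%).
#' @param dropout list with `mechanism` ("MCAR" or "MAR"), `rate` (default
#'   0.20), `monotone` (default TRUE: missing at month 3 implies missing at
#'   month 12), and for MAR `mar_predictors`, a named coefficient vector on
#'   baseline covariates (the intercept is calibrated to hit `rate`).
#' @param violation_rates probabilities for consent withdrawal (all data),
#'   never receiving a dose, improper unblinding, and eligibility violation.
#' @param death_rate probability of death during the 12-month study; deaths
#'   censor subsequent visits and morbidity reports.
#' @param intake_missing_rate probability a child has no intake records at
#'   all (their compliance is then taken as 0%).
#' @param outcomes optional character subset of outcomes to generate
#'   (default: all in [outcome_registry()]); trimming speeds up large
#'   simulation studies that only analyse one endpoint.
#' @param include_morbidity,include_adherence logical switches for the
#'   morbidity report series and adherence data.
#' @param seed integer seed giving byte-identical output.
#'
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_per_arm = 1100,
                       strata_weights = NULL,
                       block_size = 6,
                       visit_means = list(),
                       effects = list(),
                       sds = c(),
                       correlation = 0.4,
                       covariance = NULL,
                       morbidity_rates = c(fever = 0.20, diarrhoea = 0.10,
                                           bloody_stool = 0.01, vomiting = 0.08,
                                           cough_difficulty_breathing = 0.22,
                                           other = 0.15),
                       morbidity_dispersion = NULL,
                       adherence_shape = c(5, 2),
                       dropout = list(),
                       violation_rates = c(consent_withdrawn = 0.005,
                                           never_dosed = 0.01,
                                           improper_unblinding = 0.005,
                                           eligibility_violation = 0.005),
                       death_rate = 0.002,
                       intake_missing_rate = 0.02,
                       outcomes = NULL,
                       include_morbidity = TRUE,
                       include_adherence = TRUE,
                       seed = 1L) {
  assert_count(n_per_arm, "n_per_arm")
  assert_count(block_size, "block_size")
  if (block_size %% 3L != 0L)
    stop_cldagate("`block_size` must be divisible by 3 (1:1:1 allocation to 3 arms)")

  cells <- as.vector(outer(UNIONS, SEXES, paste, sep = "."))
  if (is.null(strata_weights)) {
    strata_weights <- stats::setNames(rep(1 / 6, 6), cells)
  } else {
    if (!setequal(names(strata_weights), cells))
      stop_cldagate("`strata_weights` must be named by the 6 union x sex cells: ",
                    paste(cells, collapse = ", "))
    strata_weights <- strata_weights[cells] / sum(strata_weights)
  }

  vm <- utils::modifyList(default_visit_means(), visit_means)
  sd_vec <- default_sds()
  if (length(sds)) sd_vec[names(sds)] <- sds

  registry <- outcome_registry()
  outcomes <- outcomes %||% registry$outcome
  bad <- setdiff(outcomes, registry$outcome)
  if (length(bad))
    stop_cldagate("unknown outcome(s): ", paste(bad, collapse = ", "))

  for (arm in names(effects)) {
    if (!arm %in% ARMS) stop_cldagate("effects for unknown arm: ", arm)
    for (out in names(effects[[arm]])) {
      e <- effects[[arm]][[out]]
      if (length(e) != 3L)
        stop_cldagate("effect vector for ", arm, "/", out, " must have length 3")
      if (e[1] != 0)
        stop_cldagate("baseline effect for ", arm, "/", out,
                      " must be 0: arms share the baseline distribution")
    }
  }

  # per-outcome 3x3 covariance, exchangeable unless overridden
  cov_list <- list()
  for (out in outcomes) {
    s <- sd_vec[[out]]
    sig <- covariance[[out]] %||%
      (s^2 * (diag(1 - correlation, 3) + matrix(correlation, 3, 3)))
    if (!isTRUE(all.equal(sig, t(sig))) || !is_pd(sig))
      stop_cldagate("covariance for `", out, "` is not symmetric positive-definite")
    cov_list[[out]] <- sig
  }

  dropout <- utils::modifyList(
    list(mechanism = "MCAR", rate = 0.20, monotone = TRUE, mar_predictors = NULL),
    dropout)
  dropout$mechanism <- match.arg(dropout$mechanism, c("MCAR", "MAR"))
  assert_prob(dropout$rate, "dropout$rate")
  assert_prob(violation_rates, "violation_rates")
  assert_prob(death_rate, "death_rate")
  assert_prob(intake_missing_rate, "intake_missing_rate")
  if (any(morbidity_rates < 0)) stop_cldagate("`morbidity_rates` must be non-negative")

  structure(list(
    n_per_arm = as.integer(n_per_arm),
    strata_weights = strata_weights,
    block_size = as.integer(block_size),
    visit_means = vm,
    effects = effects,
    sds = sd_vec,
    correlation = correlation,
    covariance = cov_list,
    morbidity_rates = morbidity_rates,
    morbidity_dispersion = morbidity_dispersion,
    adherence_shape = adherence_shape,
    dropout = dropout,
    violation_rates = violation_rates,
    death_rate = death_rate,
    intake_missing_rate = intake_missing_rate,
    outcomes = outcomes,
    include_morbidity = include_morbidity,
    include_adherence = include_adherence,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  arms: ", paste(ARMS, collapse = "/"),
      "  n/arm:", x$n_per_arm, " block:", x$block_size, "\n")
  cat("  outcomes:", paste(x$outcomes, collapse = ", "), "\n")
  cat("  dropout:", x$dropout$mechanism, x$dropout$rate,
      if (isTRUE(x$dropout$monotone)) "(monotone)" else "", "\n")
  eff <- names(x$effects)
  cat("  effects on:", if (length(eff)) paste(eff, collapse = ", ") else "none (global null)", "\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}
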