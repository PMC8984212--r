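report_schedule <- function() {
  weekly <- as.integer(ceiling(90 * (1:13) / 13))     # 13 weekly reports, days 7..90
  monthly <- as.integer(round(91 + (365 - 91) * (1:9) / 9)) # 9 monthly, days 121..365
  data.frame(
    occasion = seq_len(22L),
    day = c(weekly, monthly),
    period = rep(c("intervention", "extended"), c(13L, 9L)),
    stringsAsFactors = FALSE
  )
}

#' Simulate a complete three-arm trial
#'
#' Draws a full synthetic trial under a [sim_config()]: baseline household
#' and child covariates, stratified permuted-block allocation, correlated
#' continuous outcomes at the three visits (arm effects applied only
#' post-baseline, so baseline distributions are identical across arms by
#' construction), morbidity report series, adherence, deaths, and
#' protocol-violation flags. The dataset returned is complete apart from
#' death-censored visits; call [apply_missingness()] to impose loss to
#' follow-up.
#'
#' @param config a [sim_config()].
#' @param seed optional integer overriding `config$seed`.
#'
#' @return object of class `trial_data`: a list with data.frames `children`
#'   (one row per randomised child), `visits` (one row per child-visit), and
#'   `morbidity` (one row per report occasion), plus the config and seed.
#' @export
simulate_trial <- function(config, seed = NULL) {
  if (!inherits(config, "sim_config")) stop_cldagate("`config` must be a sim_config")
  seed <- as.integer(seed %||% config$seed)
  with_seed(seed, {
    n_total <- 3L * config$n_per_arm
    cells <- names(config$strata_weights)

    # --- strata and allocation -------------------------------------------
    stratum <- sample(cells, n_total, replace = TRUE, prob = config$strata_weights)
    n_cell <- table(factor(stratum, levels = cells))
    alloc <- generate_randomisation_list(cells, config$block_size,
                                         as.integer(n_cell),
                                         seed = sample.int(.Machine$integer.max - 1L, 1))
    arm <- character(n_total)
    for (cl in cells) {
      idx <- which(stratum == cl)
      arm[idx] <- alloc$arm[alloc$stratum == cl][seq_along(idx)]
    }
    us <- do.call(rbind, strsplit(stratum, ".", fixed = TRUE))

    children <- data.frame(
      child_id = sprintf("C%05d", seq_len(n_total)),
      union = us[, 1], sex = us[, 2], stratum = stratum, arm = arm,
      stringsAsFactors = FALSE
    )

    # --- baseline covariates (configurable in spirit; stated defaults) ---
    children$age_days <- 244L + sample(-14:14, n_total, replace = TRUE)
    children$wealth_quintile <- sample(1:5, n_total, replace = TRUE)
    children$maternal_education <- pmin(stats::rpois(n_total, 5), 16L)
    children$paternal_education <- pmin(stats::rpois(n_total, 5), 16L)
    children$food_insecurity <- pmin(stats::rpois(n_total, 3), 27L)
    children$maternal_depression <- pmin(stats::rpois(n_total, 7), 30L)
    children$fci_score <- round(pmin(pmax(stats::rnorm(n_total, 10, 3), 0), 18), 1)
    children$breastfed <- stats::rbinom(n_total, 1, 0.85)

    # --- participation, deaths, violations -------------------------------
    vr <- config$violation_rates
    children$consent_withdrawn_all_data <- stats::rbinom(n_total, 1, vr[["consent_withdrawn"]]) == 1
    children$received_any_dose <- stats::rbinom(n_total, 1, 1 - vr[["never_dosed"]]) == 1
    children$improper_unblinding <- stats::rbinom(n_total, 1, vr[["improper_unblinding"]]) == 1
    children$eligibility_violation <- stats::rbinom(n_total, 1, vr[["eligibility_violation"]]) == 1
    died <- stats::rbinom(n_total, 1, config$death_rate) == 1
    children$death_day <- ifelse(died, sample.int(365L, n_total, replace = TRUE), NA_integer_)
    children$randomisation_day <- 0L
    children$last_contact_day <- ifelse(died, children$death_day, 365L)

    # --- visit-level continuous outcomes ---------------------------------
    visit_day <- cbind(
      pmax(pmin(round(stats::rnorm(n_total, 0, 4)), 14), -14),
      pmax(pmin(round(stats::rnorm(n_total, 90, 8)), 130), 55),
      pmax(pmin(round(stats::rnorm(n_total, 365, 14)), 440), 300)
    )
    visits <- data.frame(
      child_id = rep(children$child_id, each = 3L),
      visit = rep(0:2, n_total),
      day = as.integer(t(visit_day)),
      stringsAsFactors = FALSE
    )
    registry <- outcome_registry()
    arm_idx <- match(children$arm, ARMS)
    for (out in config$outcomes) {
      mu <- config$visit_means[[out]]
      sig <- config$covariance[[out]]
      y <- rmvnorm_chol(n_total, mu, sig)
      for (a in names(config$effects)) {
        eff <- config$effects[[a]][[out]]
        if (!is.null(eff)) {
          rows <- children$arm == a
          y[rows, ] <- sweep(y[rows, , drop = FALSE], 2L, eff, "+")
        }
      }
      if (registry$dist[registry$outcome == out] == "lognormal") y <- exp(y)
      visits[[out]] <- as.vector(t(y))
    }
    # death censors later visits (administrative end does not)
    exit_day <- ifelse(died, children$death_day, 365L)
    censor_day <- ifelse(died, children$death_day, Inf)
    censored <- visits$day > censor_day[match(visits$child_id, children$child_id)]
    if (any(censored))
      visits[censored, config$outcomes] <- NA_real_

    # --- adherence --------------------------------------------------------
    if (config$include_adherence) {
      p_adh <- stats::rbeta(n_total, config$adherence_shape[1], config$adherence_shape[2])
      part90 <- pmin(exit_day, 90L)
      intake <- stats::rbinom(n_total, part90, p_adh)
      intake[!children$received_any_dose] <- 0L
      has_data <- stats::rbinom(n_total, 1, 1 - config$intake_missing_rate) == 1
      children$has_intake_data <- has_data & children$received_any_dose
      children$intake_days <- ifelse(children$has_intake_data, intake, 0L)
    }

    # --- morbidity report series -----------------------------------------
    morbidity <- NULL
    if (config$include_morbidity) {
      sched <- report_schedule()
      n_occ <- nrow(sched)
      morbidity <- data.frame(
        child_id = rep(children$child_id, each = n_occ),
        occasion = rep(sched$occasion, n_total),
        day = rep(sched$day, n_total),
        period = rep(sched$period, n_total),
        stringsAsFactors = FALSE
      )
      keep <- morbidity$day <= exit_day[match(morbidity$child_id, children$child_id)]
      morbidity <- morbidity[keep, , drop = FALSE]
      nr <- nrow(morbidity)
      for (tp in MORBIDITY_TYPES) {
        lam <- config$morbidity_rates[[tp]]
        cnt <- if (is.null(config$morbidity_dispersion))
          stats::rpois(nr, lam)
        else
          stats::rnbinom(nr, size = config$morbidity_dispersion, mu = lam)
        morbidity[[tp]] <- cnt
        # clinic visit for this reason; one visit may count under several reasons
        morbidity[[paste0("clinic_", tp)]] <- as.integer(cnt > 0 & stats::runif(nr) < 0.25)
      }
      morbidity$hospitalisation <- stats::rbinom(nr, 1, 0.002)
      morbidity$sae <- stats::rbinom(nr, 1, 0.001)
      rownames(morbidity) <- NULL
    }

    structure(list(children = children, visits = visits, morbidity = morbidity,
                   config = config, seed = seed, missingness_applied = FALSE),
              class = "trial_data")
  })
}

#' @export
print.trial_data <- function(x, ...) {
  cat("<trial_data>\n")
  cat("  children:", nrow(x$children), " per arm:",
      paste(table(x$children$arm)[ARMS], collapse = "/"), "\n")
  cat("  visits:", nrow(x$visits), "rows;  outcomes:",
      paste(intersect(outcome_registry()$outcome, names(x$visits)), collapse = ", "), "\n")
  if (!is.null(x$morbidity)) cat("  morbidity reports:", nrow(x$morbidity), "\n")
  cat("  missingness applied:", x$missingness_applied, "  seed:", x$seed, "\n")
  invisible(x)
}

#' Impose loss to follow-up on a simulated trial
#'
#' Applies MCAR or MAR dropout to the post-baseline visit outcomes. Under
#' MCAR each child is lost with the configured probability; under MAR the
#' per-child dropout probability is a logistic function of observed baseline
#' covariates, with the intercept calibrated so the marginal rate matches
#' `rate`. Monotone dropout (the default) makes a child missing at month 3
#' also missing at month 12 and truncates their participation interval and
#' morbidity series at the dropout day.
#'
#' @param trial a `trial_data` object.
#' @param dropout list overriding the config's dropout spec: `mechanism`
#'   ("MCAR"/"MAR"), `rate`, `monotone`, `mar_predictors` (named coefficient
#'   vector on numeric baseline covariate columns).
#' @param seed integer seed.
#' @return the modified `trial_data`.
#' @export
apply_missingness <- function(trial, dropout = NULL, seed = 1L) {
  if (!inherits(trial, "trial_data")) stop_cldagate("`trial` must be trial_data")
  dropout <- utils::modifyList(trial$config$dropout, dropout %||% list())
  rate <- dropout$rate
  assert_prob(rate, "dropout$rate")
  if (rate == 0) return(trial)
  n <- nrow(trial$children)

  with_seed(seed, {
    if (dropout$mechanism == "MAR") {
      coefs <- dropout$mar_predictors
      if (is.null(coefs) || is.null(names(coefs)))
        stop_cldagate("MAR dropout requires named `mar_predictors` coefficients")
      # predictors are baseline covariate columns; `baseline_<outcome>` takes
      # the visit-0 outcome value, and a `:arm=<arm>` suffix restricts the
      # term to one arm (differential, still MAR: everything is observed)
      base <- trial$visits[trial$visits$visit == 0L, , drop = FALSE]
      base <- base[match(trial$children$child_id, base$child_id), , drop = FALSE]
      get_col <- function(nm) {
        arm_sel <- rep(TRUE, n)
        if (grepl(":arm=", nm, fixed = TRUE)) {
          parts <- strsplit(nm, ":arm=", fixed = TRUE)[[1]]
          nm <- parts[1]
          arm_sel <- trial$children$arm == parts[2]
        }
        x <- if (startsWith(nm, "baseline_")) {
          oc <- sub("^baseline_", "", nm)
          if (!oc %in% names(base))
            stop_cldagate("MAR predictors absent from dataset: ", nm)
          base[[oc]]
        } else {
          if (!nm %in% names(trial$children))
            stop_cldagate("MAR predictors absent from dataset: ", nm)
          trial$children[[nm]]
        }
        if (!is.numeric(x)) stop_cldagate("MAR predictor `", nm, "` must be numeric")
        # centre so the calibrated intercept controls the marginal rate
        (x - mean(x, na.rm = TRUE)) * arm_sel
      }
      X <- vapply(names(coefs), get_col, numeric(n))
      eta <- drop(X %*% coefs)
      # calibrate the intercept so the marginal dropout probability equals `rate`
      a <- stats::uniroot(function(a) mean(stats::plogis(a + eta)) - rate,
                          c(-50, 50))$root
      p_drop <- stats::plogis(a + eta)
    } else {
      p_drop <- rep(rate, n)
    }
    dropped <- stats::runif(n) < p_drop

    outcome_cols <- intersect(trial$config$outcomes, names(trial$visits))
    id <- match(trial$visits$child_id, trial$children$child_id)
    if (isTRUE(dropout$monotone)) {
      drop_day <- ifelse(dropped, sample(15:89, n, replace = TRUE), NA_integer_)
      lost <- dropped[id] & trial$visits$visit > 0L
      trial$visits[lost, outcome_cols] <- NA_real_
      trial$children$last_contact_day <- ifelse(
        dropped, pmin(trial$children$last_contact_day, drop_day),
        trial$children$last_contact_day)
      if (!is.null(trial$children$intake_days)) {
        # intake records cannot extend past the participation interval
        part <- pmax(pmin(trial$children$last_contact_day, 90L), 1L)
        trial$children$intake_days <- pmin(trial$children$intake_days, part)
      }
      if (!is.null(trial$morbidity)) {
        mid <- match(trial$morbidity$child_id, trial$children$child_id)
        trial$morbidity <- trial$morbidity[
          trial$morbidity$day <= trial$children$last_contact_day[mid], , drop = FALSE]
      }
    } else {
      # non-monotone: each post-baseline visit independently missing
      for (v in 1:2) {
        miss_v <- stats::runif(n) < p_drop
        rows <- miss_v[id] & trial$visits$visit == v
        trial$visits[rows, outcome_cols] <- NA_real_
      }
    }
    trial$missingness_applied <- TRUE
    trial$dropout_used <- dropout
    trial
  })
}

#' Child-visit analysis table
#'
#' Long format used by the longitudinal models: one row per child-visit with
#' the allocation, stratification factors, and baseline covariates merged in.
#' Children who withdrew consent for use of all their data are excluded.
#'
#' @param trial a `trial_data` object.
#' @return data.frame, one row per child-visit.
#' @export
analysis_frame <- function(trial) {
  kids <- trial$children[!trial$children$consent_withdrawn_all_data, , drop = FALSE]
  cov_cols <- intersect(
    c("union", "sex", "arm", "stratum", "wealth_quintile", "maternal_education",
      "food_insecurity", "fci_score", "breastfed", "age_days"),
    names(kids))
  merge(kids[, c("child_id", cov_cols)], trial$visits, by = "child_id",
        sort = TRUE)
}

#' Write a trial to tidy CSV files with a JSON sidecar
#'
#' @param trial a `trial_data` object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trial_csv <- function(trial, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(trial$children, file.path(dir, "children.csv"), row.names = FALSE)
  utils::write.csv(trial$visits, file.path(dir, "visits.csv"), row.names = FALSE)
  if (!is.null(trial$morbidity))
    utils::write.csv(trial$morbidity, file.path(dir, "morbidity.csv"), row.names = FALSE)
  meta <- list(schema_version = "1.0", seed = trial$seed,
               missingness_applied = trial$missingness_applied,
               n_per_arm = trial$config$n_per_arm,
               outcomes = trial$config$outcomes)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, pretty = TRUE),
             file.path(dir, "trial_meta.json"))
  invisible(dir)
}

#' Read a trial written by [write_trial_csv()]
#'
#' Real-data mode: any tidy CSV pair following the same schema (a `children`
#' table and a child-visit `visits` table) can be loaded this way.
#'
#' @param dir directory containing `children.csv`, `visits.csv`, and
#'   optionally `morbidity.csv` / `trial_meta.json`.
#' @return a `trial_data` object (config limited to metadata).
#' @export
read_trial_csv <- function(dir) {
  children <- utils::read.csv(file.path(dir, "children.csv"), stringsAsFactors = FALSE)
  visits <- utils::read.csv(file.path(dir, "visits.csv"), stringsAsFactors = FALSE)
  morb_path <- file.path(dir, "morbidity.csv")
  morbidity <- if (file.exists(morb_path))
    utils::read.csv(morb_path, stringsAsFactors = FALSE) else NULL
  meta_path <- file.path(dir, "trial_meta.json")
  meta <- if (file.exists(meta_path)) jsonlite::fromJSON(meta_path) else list()
  if (anyDuplicated(children$child_id))
    stop_cldagate("`child_id` must be unique in children.csv")
  cfg <- sim_config(n_per_arm = max(1L, nrow(children) %/% 3L),
                    outcomes = intersect(outcome_registry()$outcome, names(visits)))
  structure(list(children = children, visits = visits, morbidity = morbidity,
                 config = cfg, seed = meta$seed %||% NA_integer_,
                 missingness_applied = isTRUE(meta$missingness_applied)),
            class = "trial_data")
}
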