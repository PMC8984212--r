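# Trial-profile accounting and output tables. Table builders mirror the
# pre-specified skeletons: descriptive baseline table with no between-group
# tests, the efficacy table with estimates/CIs and p-values only where the
# multiple-testing strategy permits them, and the two safety tables.

#' CONSORT-style participant accounting
#'
#' Fully reconciled flow counts: randomised per arm, excluded post
#' randomisation (consent withdrawn for all data), analysed per population,
#' and lost to follow-up per visit. Every randomised child must be either
#' analysed (ITT) or excluded with a reason; anything unclassifiable is an
#' error, not a silent residual.
#'
#' @param trial a `trial_data` object.
#' @param flags population flags from [assign_populations()].
#' @param outcome outcome whose missingness defines loss to follow-up
#'   (default "cognitive").
#' @return list of class `consort_counts`.
#' @export
consort <- function(trial, flags = assign_populations(trial),
                    outcome = "cognitive") {
  kids <- trial$children
  f <- flags[match(kids$child_id, flags$child_id), ]
  arm <- factor(kids$arm, levels = ARMS)
  randomised <- table(arm)
  excluded_withdrawn <- table(arm[kids$consent_withdrawn_all_data])
  analysed_itt <- table(arm[f$in_itt])
  analysed_safety <- table(arm[f$in_safety])
  analysed_pp <- table(arm[f$in_per_protocol])

  if (!all(randomised == analysed_itt + excluded_withdrawn))
    stop_cldagate("CONSORT counts do not reconcile: randomised != ITT + excluded")

  lost <- NULL
  if (outcome %in% names(trial$visits)) {
    v <- trial$visits
    lost <- do.call(rbind, lapply(sort(unique(v$visit)), function(vis) {
      sub <- v[v$visit == vis, c("child_id", outcome)]
      miss_ids <- sub$child_id[is.na(sub[[outcome]])]
      tab <- table(arm[kids$child_id %in% miss_ids & f$in_itt])
      data.frame(visit = vis, t(as.matrix(tab)))
    }))
  }
  structure(list(randomised = randomised,
                 excluded_withdrawn = excluded_withdrawn,
                 analysed_itt = analysed_itt,
                 analysed_safety = analysed_safety,
                 analysed_per_protocol = analysed_pp,
                 lost_to_followup = lost),
            class = "consort_counts")
}

#' @export
print.consort_counts <- function(x, ...) {
  cat("CONSORT accounting (per arm: ", paste(ARMS, collapse = "/"), ")\n", sep = "")
  for (nm in c("randomised", "excluded_withdrawn", "analysed_itt",
               "analysed_safety", "analysed_per_protocol"))
    cat(sprintf("  %-24s %s\n", nm, paste(x[[nm]], collapse = " / ")))
  if (!is.null(x$lost_to_followup)) {
    cat("  lost to follow-up by visit:\n")
    print(x$lost_to_followup, row.names = FALSE)
  }
  invisible(x)
}

fmt_mean_sd <- function(x, digits = 1) {
  x <- x[!is.na(x)]
  sprintf(paste0("%.", digits, "f (%.", digits, "f)"), mean(x), stats::sd(x))
}

fmt_median_iqr <- function(x, digits = 1) {
  x <- x[!is.na(x)]
  q <- stats::quantile(x, c(0.5, 0.25, 0.75))
  sprintf(paste0("%.", digits, "f (%.", digits, "f-%.", digits, "f)"),
          q[1], q[2], q[3])
}

fmt_n_pct <- function(ind) {
  ind <- ind[!is.na(ind)]
  sprintf("%d (%.1f)", sum(ind), 100 * mean(ind))
}

#' Baseline characteristics table (descriptive only)
#'
#' Summarises baseline household and child characteristics by arm:
#' frequencies and percentages (on the non-missing denominator) for
#' categorical rows, mean (SD) for symmetric continuous rows, median
#' (quartiles) for skewed rows (ferritin, CRP, count-like scores). Contains
#' no inferential columns: no between-group tests are performed at
#' baseline.
#'
#' @param trial a `trial_data` object.
#' @return data.frame, one row per characteristic, one column per arm.
#' @export
build_table1 <- function(trial) {
  kids <- trial$children[!trial$children$consent_withdrawn_all_data, ]
  v0 <- trial$visits[trial$visits$visit == 0L, ]
  v0 <- merge(kids[, c("child_id", "arm")], v0, by = "child_id")
  rows <- list()
  add <- function(label, fn, data, col) {
    vals <- vapply(ARMS, function(a) {
      x <- data[[col]][data$arm == a]
      if (!length(x) || all(is.na(x))) "-" else fn(x)
    }, "")
    rows[[length(rows) + 1L]] <<- data.frame(
      characteristic = label, t(vals), stringsAsFactors = FALSE)
  }
  for (u in UNIONS)
    add(paste0("Union: ", u), fmt_n_pct, transform(kids, .x = union == u), ".x")
  add("Female sex - no. (%)", fmt_n_pct, transform(kids, .x = sex == "female"), ".x")
  add("Age (months)", function(x) fmt_mean_sd(x / 30.44, 1), kids, "age_days")
  if ("maternal_education" %in% names(kids))
    add("Maternal education (years)", fmt_median_iqr, kids, "maternal_education")
  if ("fci_score" %in% names(kids))
    add("Family Care Indicator total score", fmt_mean_sd, kids, "fci_score")
  if ("wealth_quintile" %in% names(kids))
    for (qq in 1:5)
      add(paste0("Wealth quintile ", qq), fmt_n_pct,
          transform(kids, .x = wealth_quintile == qq), ".x")
  if ("haemoglobin" %in% names(v0)) {
    add("Haemoglobin (g/L)", fmt_mean_sd, v0, "haemoglobin")
    add("Anaemia - no. (%)", fmt_n_pct,
        transform(v0, .x = classify_anaemia(haemoglobin)), ".x")
  }
  if ("ferritin" %in% names(v0)) add("Ferritin (ug/L)", fmt_median_iqr, v0, "ferritin")
  if (all(c("ferritin", "crp") %in% names(v0)))
    add("Iron deficient - no. (%)", fmt_n_pct,
        transform(v0, .x = classify_iron_deficiency(ferritin, crp)), ".x")
  if ("crp" %in% names(v0)) add("C-reactive protein (mg/L)", fmt_median_iqr, v0, "crp")
  for (bs in c("cognitive", "language", "motor"))
    if (bs %in% names(v0))
      add(paste0(toupper(substring(bs, 1, 1)), substring(bs, 2),
                 " composite"), fmt_mean_sd, v0, bs)
  if ("laz" %in% names(v0)) {
    add("Length-for-age z-score", function(x) fmt_mean_sd(x, 2), v0, "laz")
    add("Stunting - no. (%)", fmt_n_pct,
        transform(v0, .x = classify_faltering(laz)), ".x")
  }
  out <- do.call(rbind, rows)
  names(out) <- c("characteristic", paste0(ARMS, "_N", as.integer(table(
    factor(kids$arm, levels = ARMS)))))
  out
}

#' Efficacy outcomes table
#'
#' One row per endpoint per visit, with per-arm descriptive summaries and
#' per-comparison estimates, confidence intervals at the assigned level,
#' and p-values. For endpoints flagged secondary/exploratory the p-value
#' cells are left empty: no p-values are presented where no multiplicity
#' adjustment is planned. Adjusted p-values come from the gatekeeping /
#' Hochberg machinery.
#'
#' @param effects data.frame stacking [estimate_effect()] rows with added
#'   columns `endpoint` and `tier` ("primary", "key_secondary",
#'   "secondary").
#' @param decisions optional list per visit from
#'   [multiplicity_procedure()], used to fill adjusted p-values.
#' @return data.frame in the table-2 layout.
#' @export
build_table2 <- function(effects, decisions = NULL) {
  fmt_est <- function(e)
    sprintf("%.2f (%.2f to %.2f)", e$estimate, e$ci_lower, e$ci_upper)
  rows <- lapply(seq_len(nrow(effects)), function(i) {
    e <- effects[i, ]
    show_p <- e$tier %in% c("primary", "key_secondary")
    p_adj <- ""
    if (show_p && !is.null(decisions)) {
      dec <- decisions[[as.character(e$visit)]]
      if (!is.null(dec)) {
        key <- gsub(" vs ", "_vs_", e$comparison)
        if (e$tier == "primary") {
          row <- dec$primary[dec$primary$hypothesis == key, ]
          if (nrow(row) && !is.na(row$p_adjusted))
            p_adj <- sprintf("%.4f", row$p_adjusted)
          if (nrow(row) && !row$tested) show_p <- FALSE
        } else if (!is.null(dec$secondary[[key]])) {
          sec <- dec$secondary[[key]]
          hit <- sec[sec$endpoint == e$endpoint, ]
          if (nrow(hit) && isTRUE(hit$tested[1]) && !is.na(hit$p_adjusted[1]))
            p_adj <- sprintf("%.4f", hit$p_adjusted[1])
        }
      }
    }
    data.frame(endpoint = e$endpoint, visit = e$visit, tier = e$tier,
               comparison = e$comparison, scale = e$scale,
               estimate_ci = fmt_est(e),
               p_unadjusted = if (show_p) sprintf("%.4f", e$p_unadjusted) else "",
               p_adjusted = p_adj, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Infectious-morbidity table (incidence rate ratios)
#'
#' Per infection type and period: per-arm median (quartiles) of report
#' counts and the pairwise incidence rate ratios with 95% CIs and
#' (multiplicity-unadjusted) p-values from [fit_poisson_rate()].
#'
#' @param trial a `trial_data` object.
#' @param flags population flags; the safety population is used.
#' @return list with `table` (formatted rows) and `fits` (per type/period).
#' @export
build_table3 <- function(trial, flags = assign_populations(trial)) {
  agg <- period_aggregates(trial)
  safety_ids <- flags$child_id[flags$in_safety]
  agg <- agg[agg$child_id %in% safety_ids, ]
  agg <- merge(agg, trial$children[, c("child_id", "arm", "union", "sex")],
               by = "child_id")
  rows <- list(); fits <- list()
  for (tp in MORBIDITY_TYPES) for (per in c("intervention", "extended", "study")) {
    sub <- agg[agg$period == per, ]
    fit <- tryCatch(fit_poisson_rate(sub, tp, "person_days"),
                    error = function(e) NULL)
    fits[[paste(tp, per, sep = ".")]] <- fit
    med <- vapply(ARMS, function(a) fmt_median_iqr(sub[[tp]][sub$arm == a], 0), "")
    irr <- if (is.null(fit)) rep("-", 3) else
      vapply(seq_len(3), function(j) {
        e <- fit$effects[j, ]
        if (!e$estimable) "NE" else
          sprintf("%.2f (%.2f to %.2f) p=%.3f", e$estimate, e$ci_lower,
                  e$ci_upper, e$p_unadjusted)
      }, "")
    rows[[length(rows) + 1L]] <- data.frame(
      infection = tp, period = per, t(med), t(irr), stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  names(tab) <- c("infection", "period", ARMS,
                  "iron_vs_placebo", "mnp_vs_placebo", "iron_vs_mnp")
  list(table = tab, fits = fits)
}

#' Death / SAE / hospitalisation / clinic-visit table (risk ratios)
#'
#' Per event indicator and period: per-arm n (%) on the non-missing
#' denominator and pairwise log-binomial p-values ([fit_log_binomial()],
#' with the documented robust-Poisson fallback).
#'
#' @param trial a `trial_data` object.
#' @param flags population flags; the safety population is used.
#' @return list with `table` and `fits`.
#' @export
build_table4 <- function(trial, flags = assign_populations(trial)) {
  agg <- period_aggregates(trial)
  agg <- agg[agg$child_id %in% flags$child_id[flags$in_safety], ]
  agg <- merge(agg, trial$children[, c("child_id", "arm")], by = "child_id")
  indicators <- c("died", "hospitalisation_any", "sae_any", "clinic_any",
                  paste0("clinic_", MORBIDITY_TYPES))
  rows <- list(); fits <- list()
  for (ind in indicators) for (per in c("intervention", "extended", "study")) {
    sub <- agg[agg$period == per, ]
    fit <- if (sum(sub[[ind]]) > 0)
      tryCatch(fit_log_binomial(sub, ind), error = function(e) NULL) else NULL
    fits[[paste(ind, per, sep = ".")]] <- fit
    np <- vapply(ARMS, function(a) fmt_n_pct(sub[[ind]][sub$arm == a] == 1), "")
    pv <- if (is.null(fit)) rep("-", 3) else
      vapply(seq_len(3), function(j) {
        e <- fit$effects[j, ]
        if (!e$estimable) "NE" else sprintf("%.3f", e$p_unadjusted)
      }, "")
    rows[[length(rows) + 1L]] <- data.frame(
      indicator = ind, period = per, t(np), t(pv), stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  names(tab) <- c("indicator", "period", ARMS,
                  "p_iron_vs_placebo", "p_mnp_vs_placebo", "p_iron_vs_mnp")
  list(table = tab, fits = fits)
}

#' Run the full pre-specified analysis pipeline
#'
#' End-to-end driver: simulate (or accept) a trial, impose missingness,
#' apply visit windows, derive populations, fit the primary and
#' key-secondary constrained longitudinal models, run the multiplicity
#' procedure at months 3 and 12, fit the safety models, and assemble the
#' output tables. Optionally runs the sensitivity analyses: covariate
#' adjustment (family-care indicator + maternal education), per-protocol,
#' multiple imputation, and CACE. Writes CSV/JSON artefacts plus a run
#' manifest when `out_dir` is given; reruns with the same config and seed
#' reproduce identical numbers.
#'
#' @param config a [sim_config()] (a trial is simulated) — or pass `trial`.
#' @param trial an existing `trial_data`, bypassing simulation.
#' @param seed integer seed for simulation/missingness/imputation.
#' @param key_secondary key-secondary endpoint spec: data.frame with
#'   columns `outcome` and `transform`.
#' @param sensitivity character subset of
#'   c("covariates", "per_protocol", "mi", "cace").
#' @param overall_alpha familywise level.
#' @param out_dir optional output directory.
#' @return list of class `pipeline_result` with elements `consort`,
#'   `fits`, `effects`, `decisions`, `tables`, `sensitivity`, `manifest`.
#' @export
run_pipeline <- function(config = NULL, trial = NULL, seed = 1L,
                         key_secondary = data.frame(
                           outcome = c("language", "motor", "laz", "waz",
                                       "haemoglobin", "ferritin"),
                           transform = c("identity", "identity", "identity",
                                         "identity", "identity", "log"),
                           stringsAsFactors = FALSE),
                         sensitivity = character(0),
                         overall_alpha = 0.05, out_dir = NULL) {
  if (is.null(trial)) {
    if (is.null(config)) stop_cldagate("supply `config` or `trial`")
    trial <- simulate_trial(config, seed = seed)
    if (config$dropout$rate > 0)
      trial <- apply_missingness(trial, seed = seed + 1L)
  }
  config <- trial$config
  trial <- window_filter(trial)
  flags <- assign_populations(trial)
  cons <- consort(trial, flags)

  endpoints <- data.frame(outcome = "cognitive", transform = "identity",
                          tier = "primary", stringsAsFactors = FALSE)
  if (nrow(key_secondary))
    endpoints <- rbind(endpoints, cbind(key_secondary, tier = "key_secondary"))
  endpoints <- endpoints[endpoints$outcome %in% names(trial$visits), ]

  cmp_list <- list(c("iron", "placebo"), c("mnp", "placebo"), c("iron", "mnp"))
  fits <- list(); eff_rows <- list()
  for (i in seq_len(nrow(endpoints))) {
    ep <- endpoints[i, ]
    fit <- fit_clda_cascade(trial, ep$outcome, transform = ep$transform)
    fits[[ep$outcome]] <- fit
    for (v in fit$visits[-1]) for (cmp in cmp_list) {
      ci <- 1 - if (identical(cmp, c("iron", "mnp"))) overall_alpha
                else overall_alpha / 2
      e <- estimate_effect(fit, cmp, v, ci_level = ci)
      e$endpoint <- ep$outcome; e$tier <- ep$tier
      eff_rows[[length(eff_rows) + 1L]] <- e
    }
  }
  effects <- do.call(rbind, eff_rows)

  decisions <- list()
  for (v in intersect(c(1, 2), unique(effects$visit))) {
    prim <- effects[effects$tier == "primary" & effects$visit == v, ]
    primary_p <- stats::setNames(prim$p_unadjusted,
                                 gsub(" vs ", "_vs_", prim$comparison))
    sec <- effects[effects$tier == "key_secondary" & effects$visit == v, ]
    secondary_p <- lapply(split(sec, gsub(" vs ", "_vs_", sec$comparison)),
                          function(s) stats::setNames(s$p_unadjusted, s$endpoint))
    decisions[[as.character(v)]] <-
      multiplicity_procedure(primary_p, secondary_p, overall_alpha)
  }

  tables <- list(table1 = build_table1(trial),
                 table2 = build_table2(effects, decisions))
  if (!is.null(trial$morbidity)) {
    tables$table3 <- build_table3(trial, flags)$table
    tables$table4 <- build_table4(trial, flags)$table
  }

  sens <- list()
  if ("covariates" %in% sensitivity) {
    sens$covariates <- fit_clda_cascade(
      trial, "cognitive",
      covariates = c("union", "sex", "fci_score", "maternal_education"))
  }
  if ("per_protocol" %in% sensitivity) {
    af <- analysis_frame(trial)
    pp_ids <- flags$child_id[flags$in_per_protocol]
    sens$per_protocol <- fit_clda_cascade(af[af$child_id %in% pp_ids, ],
                                          "cognitive")
  }
  if ("mi" %in% sensitivity) {
    ms <- missingness_summary(trial, outcomes = "cognitive")
    pct <- ms$missingness$pct_missing[ms$missingness$visit == 1]
    stack <- mice_jav(trial, m = choose_m(pct), seed = seed + 2L)
    sens$mi <- list(
      stack_meta = stack[c("m", "iterations", "variables")],
      pooled_iron = pool_clda_effect(stack, "cognitive", c("iron", "placebo"), 1),
      pooled_mnp = pool_clda_effect(stack, "cognitive", c("mnp", "placebo"), 1))
  }
  if ("cace" %in% sensitivity) {
    sens$cace <- estimate_cace(trial, "cognitive", c("iron", "placebo"),
                               visit = 1, flags = flags)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("cldagate")),
    seed = seed, overall_alpha = overall_alpha,
    n_per_arm = config$n_per_arm,
    endpoints = endpoints$outcome,
    sensitivity = sensitivity,
    timestamp = format(Sys.time(), tz = "UTC"))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(tables))
      utils::write.csv(tables[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    utils::write.csv(effects, file.path(out_dir, "effects.csv"),
                     row.names = FALSE)
    writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
               file.path(out_dir, "manifest.json"))
  }

  structure(list(consort = cons, flags = flags, fits = fits,
                 effects = effects, decisions = decisions, tables = tables,
                 sensitivity = sens, manifest = manifest),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$consort)
  cat("\nPrimary multiplicity decisions (month 3):\n")
  if (!is.null(x$decisions[["1"]])) print(x$decisions[["1"]]$primary)
  invisible(x)
}
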