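#' Anaemia classification
#'
#' Anaemia is haemoglobin below 110 g/L (strict inequality). Missing input
#' propagates to missing output.
#'
#' @param haemoglobin haemoglobin concentration in g/L.
#' @return logical vector.
#' @export
classify_anaemia <- function(haemoglobin) {
  if (any(haemoglobin <= 0, na.rm = TRUE))
    stop_cldagate("haemoglobin must be positive")
  haemoglobin < 110
}

#' Iron-deficiency classification with inflammation correction
#'
#' Iron deficient if ferritin < 12 ug/L, or ferritin < 30 ug/L when
#' C-reactive protein exceeds 5 mg/L (acute-phase ferritin elevation raises
#' the cut-off under inflammation). Strict inequalities on all three
#' thresholds; missing values propagate unless the observed branch already
#' decides the classification (ferritin < 12 is deficient regardless of CRP;
#' ferritin >= 30 is non-deficient regardless of CRP).
#'
#' @param ferritin serum ferritin, ug/L.
#' @param crp C-reactive protein, mg/L.
#' @return logical vector.
#' @export
classify_iron_deficiency <- function(ferritin, crp) {
  if (any(ferritin <= 0, na.rm = TRUE) || any(crp <= 0, na.rm = TRUE))
    stop_cldagate("ferritin and crp must be positive")
  out <- ferritin < 12 | (ferritin < 30 & crp > 5)
  # ferritin alone decides outside (12, 30); inside, missing CRP leaves it unknown
  out[!is.na(ferritin) & ferritin < 12] <- TRUE
  out[!is.na(ferritin) & ferritin >= 30] <- FALSE
  out
}

#' Iron-deficiency anaemia: the conjunction of the two classifications
#'
#' Logical AND with standard three-valued missing propagation: a missing
#' conjunct yields missing unless the other conjunct is FALSE.
#'
#' @param anaemia,iron_deficient logical vectors.
#' @return logical vector.
#' @export
classify_ida <- function(anaemia, iron_deficient) {
  anaemia & iron_deficient
}

#' Inflammation classification
#'
#' @param crp C-reactive protein, mg/L; inflammation is CRP > 5 mg/L.
#' @return logical vector.
#' @export
classify_inflammation <- function(crp) {
  if (any(crp <= 0, na.rm = TRUE)) stop_cldagate("crp must be positive")
  crp > 5
}

#' Read an LMS growth-reference table
#'
#' The LMS system expresses a growth reference as a Box-Cox power (L),
#' median (M) and coefficient of variation (S) per age and sex. A small
#' synthetic reference (clearly labelled, not WHO data) ships with the
#' package for tests and simulations; real WHO tables in the same CSV layout
#' (`metric, sex, age_days, L, M, S`) plug in directly.
#'
#' @param path CSV path; default the bundled synthetic reference.
#' @return data.frame with columns metric, sex, age_days, L, M, S.
#' @export
read_lms_reference <- function(path = system.file("extdata",
                                                  "lms_reference_synthetic.csv",
                                                  package = "cldagate")) {
  ref <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("metric", "sex", "age_days", "L", "M", "S")
  if (!all(need %in% names(ref)))
    stop_cldagate("LMS reference must have columns: ", paste(need, collapse = ", "))
  ref
}

#' Anthropometric z-score by the LMS method
#'
#' z = ((measure/M)^L - 1) / (L * S) for L != 0 and log(measure/M)/S for
#' L = 0, with L, M, S interpolated linearly in age within metric and sex.
#' Ages outside the reference range raise an error rather than silently
#' extrapolating.
#'
#' @param measure measurement (cm or kg, matching the metric).
#' @param age_days age in days.
#' @param sex "female" or "male".
#' @param reference LMS table from [read_lms_reference()].
#' @param metric one of "length_for_age", "weight_for_age",
#'   "weight_for_length", "head_circumference". For weight-for-length,
#'   `age_days` is read as length in cm (the reference's indexing variable).
#' @return numeric z-score vector.
#' @export
growth_zscore <- function(measure, age_days, sex, reference,
                          metric = c("length_for_age", "weight_for_age",
                                     "weight_for_length", "head_circumference")) {
  metric <- match.arg(metric)
  if (any(measure <= 0, na.rm = TRUE)) stop_cldagate("measure must be positive")
  n <- max(length(measure), length(age_days), length(sex))
  measure <- rep_len(measure, n); age_days <- rep_len(age_days, n)
  sex <- rep_len(sex, n)
  z <- rep(NA_real_, n)
  for (sx in unique(sex)) {
    rows <- reference$metric == metric & reference$sex == sx
    if (!any(rows)) stop_cldagate("reference does not cover sex `", sx,
                                  "` for metric `", metric, "`")
    tab <- reference[rows, , drop = FALSE]
    tab <- tab[order(tab$age_days), , drop = FALSE]
    sel <- which(sex == sx & !is.na(measure) & !is.na(age_days))
    if (!length(sel)) next
    a <- age_days[sel]
    if (any(a < min(tab$age_days) | a > max(tab$age_days)))
      stop_cldagate("age/sex outside the LMS reference range for `", metric,
                    "`; refusing to extrapolate")
    L <- stats::approx(tab$age_days, tab$L, a)$y
    M <- stats::approx(tab$age_days, tab$M, a)$y
    S <- stats::approx(tab$age_days, tab$S, a)$y
    r <- measure[sel] / M
    z[sel] <- ifelse(abs(L) < 1e-12, log(r) / S, (r^L - 1) / (L * S))
  }
  z
}

#' Growth-faltering flags from z-scores
#'
#' Stunting, underweight and wasting are z < -2 (strict) on length-for-age,
#' weight-for-age and weight-for-length respectively.
#'
#' @param z numeric z-score vector.
#' @return logical vector.
#' @export
classify_faltering <- function(z) z < -2

#' Sum instrument items into summary scales
#'
#' Behaviour/temperament-style scoring: each summary score is the sum of its
#' mapped items. Any missing constituent item makes that scale's sum missing
#' (no proration). Items outside the instrument range are rejected.
#'
#' @param item_scores data.frame or matrix of per-item scores (one row per
#'   record, columns named by item).
#' @param mapping named list: scale name -> character vector of item columns;
#'   items must exist and may not be shared between scales.
#' @param range length-2 numeric giving the admissible item range
#'   (e.g. c(1, 4) for a four-point temperament item, c(1, 9) for a
#'   nine-point behaviour item).
#' @return data.frame of scale sums, one column per scale.
#' @export
score_scales <- function(item_scores, mapping, range = c(1, 4)) {
  item_scores <- as.data.frame(item_scores)
  items <- unlist(mapping, use.names = FALSE)
  missing_items <- setdiff(items, names(item_scores))
  if (length(missing_items))
    stop_cldagate("items absent from data: ", paste(missing_items, collapse = ", "))
  if (anyDuplicated(items))
    stop_cldagate("mapping assigns some items to more than one scale")
  vals <- as.matrix(item_scores[items])
  if (any(vals < range[1] | vals > range[2], na.rm = TRUE))
    stop_cldagate("item scores outside the instrument range [",
                  range[1], ", ", range[2], "]")
  out <- lapply(mapping, function(cols)
    rowSums(item_scores[cols]))  # rowSums propagates NA without na.rm
  as.data.frame(out)
}

#' Overall compliance and complier status
#'
#' Compliance is 100 x (days both syrup and sachet were taken) /
#' (study participation duration over the intervention window); a complier
#' has compliance of at least 70%. Children with no intake data are assigned
#' 0% and classed non-compliers.
#'
#' @param intake_days days with recorded intake of both products.
#' @param participation_days participation duration in days (capped at the
#'   90-day intervention by the caller); must be positive where intake data
#'   exist.
#' @param has_intake_data logical; FALSE forces 0% compliance.
#' @return data.frame with `compliance` (percent) and `complier` (logical).
#' @export
compliance <- function(intake_days, participation_days,
                       has_intake_data = !is.na(intake_days)) {
  n <- max(length(intake_days), length(participation_days))
  intake_days <- rep_len(intake_days, n)
  participation_days <- rep_len(participation_days, n)
  has_intake_data <- rep_len(has_intake_data, n)
  with_data <- has_intake_data & !is.na(intake_days)
  if (any(with_data & (is.na(participation_days) | participation_days <= 0)))
    stop_cldagate("participation_days must be positive where intake data exist")
  if (any(with_data & intake_days > participation_days))
    stop_cldagate("intake_days cannot exceed participation_days")
  if (any(with_data & intake_days < 0)) stop_cldagate("intake_days must be >= 0")
  pct <- ifelse(with_data, 100 * intake_days / participation_days, 0)
  data.frame(compliance = pct, complier = pct >= 70)
}

#' Assign analysis populations
#'
#' Intention-to-treat: all randomised children except those who withdrew
#' consent for use of all their data. Safety: ITT children who received at
#' least one dose of study treatment (including control). Per-protocol: ITT
#' children who were compliers without protocol violations (eligibility
#' violation, improper unblinding).
#'
#' @param trial a `trial_data` object.
#' @return data.frame of class `population_flags`: one row per child with
#'   `in_itt`, `in_safety`, `in_per_protocol`, `complier`,
#'   `overall_compliance`.
#' @export
assign_populations <- function(trial) {
  kids <- trial$children
  participation <- pmax(pmin(kids$last_contact_day, 90L) - kids$randomisation_day, 1L)
  cp <- compliance(kids$intake_days %||% rep(NA_integer_, nrow(kids)),
                   participation,
                   kids$has_intake_data %||% rep(FALSE, nrow(kids)))
  in_itt <- !kids$consent_withdrawn_all_data
  flags <- data.frame(
    child_id = kids$child_id,
    in_itt = in_itt,
    in_safety = in_itt & kids$received_any_dose,
    in_per_protocol = in_itt & cp$complier &
      !kids$eligibility_violation & !kids$improper_unblinding,
    complier = cp$complier,
    overall_compliance = cp$compliance,
    stringsAsFactors = FALSE
  )
  class(flags) <- c("population_flags", "data.frame")
  flags
}

#' Default visit windows
#'
#' Inclusive day-offset windows around the nominal visit days: baseline at
#' day 0 (-14, +14), month 3 at day 90 (+/-28), month 12 at day 365 (+/-56).
#' Assessments outside the windows are excluded from analysis, never
#' reallocated to a neighbouring visit.
#'
#' @param baseline,month3,month12 length-2 inclusive (lower, upper) day
#'   bounds per visit.
#' @return object of class `visit_windows`.
#' @export
visit_windows <- function(baseline = c(-14, 14), month3 = c(62, 118),
                          month12 = c(309, 421)) {
  w <- rbind(baseline, month3, month12)
  if (any(w[, 1] > w[, 2])) stop_cldagate("window lower bound exceeds upper bound")
  if (w[1, 2] >= w[2, 1] || w[2, 2] >= w[3, 1])
    stop_cldagate("visit windows must be non-overlapping and ordered")
  structure(list(lower = w[, 1], upper = w[, 2], visit = 0:2),
            class = "visit_windows")
}

#' Exclude assessments outside the visit windows
#'
#' Sets outcome values of out-of-window assessments to missing and records
#' an exclusion log (`attr(, "window_exclusions")`): one row per excluded
#' child-visit with the offending day.
#'
#' @param trial a `trial_data` object.
#' @param windows a [visit_windows()] object.
#' @return the filtered `trial_data`.
#' @export
window_filter <- function(trial, windows = visit_windows()) {
  v <- trial$visits
  idx <- match(v$visit, windows$visit)
  out_of_window <- !is.na(v$day) &
    (v$day < windows$lower[idx] | v$day > windows$upper[idx])
  outcome_cols <- intersect(outcome_registry()$outcome, names(v))
  had_data <- out_of_window & rowSums(!is.na(v[outcome_cols])) > 0
  v[out_of_window, outcome_cols] <- NA_real_
  trial$visits <- v
  attr(trial, "window_exclusions") <-
    v[had_data, c("child_id", "visit", "day"), drop = FALSE]
  trial
}

#' Per-child period aggregates of the morbidity series
#'
#' Aggregates the weekly (intervention) and monthly (extended follow-up)
#' report series into the three reporting periods — intervention (days
#' 0-90), extended follow-up (days 91-365), study (0-365) — with counts per
#' infection type, person-time as observed participation days within the
#' period, and per-period indicators for death, any (overnight)
#' hospitalisation, any serious adverse event, and any clinic visit by
#' reason. Children who exited early contribute truncated person-time.
#'
#' @param trial a `trial_data` object with a morbidity series.
#' @return data.frame: one row per child x period.
#' @export
period_aggregates <- function(trial) {
  if (is.null(trial$morbidity)) stop_cldagate("trial has no morbidity series")
  kids <- trial$children
  morb <- trial$morbidity
  dd <- kids$death_day[match(morb$child_id, kids$child_id)]
  if (any(!is.na(dd) & morb$day > dd))
    stop_cldagate("inconsistent input: morbidity reports dated after death")

  exit_day <- pmin(kids$last_contact_day,
                   ifelse(is.na(kids$death_day), 365L, kids$death_day))
  bounds <- list(intervention = c(0, 90), extended = c(91, 365), study = c(0, 365))
  clinic_cols <- paste0("clinic_", MORBIDITY_TYPES)

  res <- lapply(names(bounds), function(per) {
    b <- bounds[[per]]
    in_per <- morb$day >= b[1] & morb$day <= b[2]
    m <- morb[in_per, , drop = FALSE]
    agg <- function(col) {
      s <- tapply(m[[col]], m$child_id, sum)
      out <- as.integer(s[kids$child_id])
      out[is.na(out)] <- 0L
      out
    }
    df <- data.frame(child_id = kids$child_id, period = per,
                     stringsAsFactors = FALSE)
    for (tp in MORBIDITY_TYPES) df[[tp]] <- agg(tp)
    for (cc in clinic_cols) df[[cc]] <- agg(cc)
    df$clinic_any <- as.integer(rowSums(df[clinic_cols]) > 0)
    for (cc in clinic_cols) df[[cc]] <- as.integer(df[[cc]] > 0)
    df$hospitalisation_any <- as.integer(agg("hospitalisation") > 0)
    df$sae_any <- as.integer(agg("sae") > 0)
    df$died <- as.integer(!is.na(kids$death_day) &
                            kids$death_day >= b[1] & kids$death_day <= b[2])
    df$person_days <- pmax(pmin(exit_day, b[2]) - pmax(0L, b[1] - 1L), 0L)
    df
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
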