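# Serial gatekeeping for a three-arm superiority trial.
#
# Two primary comparisons (iron vs placebo, MNPs vs placebo) share the
# overall two-sided alpha by Bonferroni: each is tested at alpha/2. The
# head-to-head comparison (iron vs MNPs) is gated: it is tested only if at
# least one primary null is rejected — at alpha/2 if exactly one primary is
# rejected, at the full alpha if both are. If neither gate opens, the
# head-to-head effect is reported with a 95% confidence interval and its
# p-value is suppressed. Confidence levels always match the assigned
# significance level (1 - assigned alpha).

#' Run the serial gatekeeping decision tree for the primary outcome
#'
#' @param p_iron,p_mnp unadjusted two-sided p-values for the two primary
#'   comparisons against placebo.
#' @param p_head_to_head unadjusted p-value for iron versus MNPs.
#' @param overall_alpha overall two-sided familywise level (default 0.05).
#' @return data.frame of class `gatekeeper_result`, one row per hypothesis
#'   (`iron_vs_placebo`, `mnp_vs_placebo`, `iron_vs_mnp`) with columns
#'   `p_unadjusted`, `tested`, `assigned_alpha` (NA when untested),
#'   `rejected`, `p_adjusted` (NA when suppressed), `ci_level`, and a
#'   decision trace in `attr(, "trace")`.
#' @export
gatekeeper_primary <- function(p_iron, p_mnp, p_head_to_head,
                               overall_alpha = 0.05) {
  assert_prob(c(p_iron, p_mnp, p_head_to_head), "p-values")
  assert_prob(overall_alpha, "overall_alpha")
  half <- overall_alpha / 2

  rej_iron <- p_iron <= half
  rej_mnp <- p_mnp <= half
  n_rej <- rej_iron + rej_mnp

  if (n_rej == 2L) {
    hh_alpha <- overall_alpha
  } else if (n_rej == 1L) {
    hh_alpha <- half
  } else {
    hh_alpha <- NA_real_
  }
  hh_tested <- n_rej >= 1L
  rej_hh <- hh_tested && p_head_to_head <= hh_alpha

  adj <- adjusted_pvalues(p_iron, p_mnp, p_head_to_head)

  out <- data.frame(
    hypothesis = c("iron_vs_placebo", "mnp_vs_placebo", "iron_vs_mnp"),
    p_unadjusted = c(p_iron, p_mnp, p_head_to_head),
    tested = c(TRUE, TRUE, hh_tested),
    assigned_alpha = c(half, half, hh_alpha),
    rejected = c(rej_iron, rej_mnp, rej_hh),
    p_adjusted = c(adj[["iron_vs_placebo"]], adj[["mnp_vs_placebo"]],
                   if (hh_tested) adj[["iron_vs_mnp"]] else NA_real_),
    ci_level = c(1 - half, 1 - half,
                 if (hh_tested) 1 - hh_alpha else 0.95),
    stringsAsFactors = FALSE
  )
  attr(out, "trace") <- c(
    sprintf("primaries tested at two-sided alpha = %.4g each", half),
    sprintf("iron vs placebo: p = %.4g -> %s", p_iron,
            if (rej_iron) "rejected" else "not rejected"),
    sprintf("MNPs vs placebo: p = %.4g -> %s", p_mnp,
            if (rej_mnp) "rejected" else "not rejected"),
    if (!hh_tested)
      "gate closed: head-to-head untested; 95% CI reported, p suppressed"
    else sprintf("gate open (%d primaries rejected): head-to-head tested at alpha = %.4g -> %s",
                 n_rej, hh_alpha, if (rej_hh) "rejected" else "not rejected")
  )
  class(out) <- c("gatekeeper_result", "data.frame")
  out
}

#' @export
print.gatekeeper_result <- function(x, ...) {
  cat("Serial gatekeeping decisions\n")
  for (ln in attr(x, "trace")) cat(" ", ln, "\n")
  cat("\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Multiplicity-adjusted p-values for the gatekeeping tree
#'
#' The adjusted p-value of each hypothesis is the smallest overall alpha at
#' which the full gatekeeping procedure rejects it. For the primaries this
#' is the Bonferroni doubling min(1, 2p). For the head-to-head comparison
#' it follows from the gate: writing q = 2 * (primary p), the procedure
#' rejects iron-vs-MNPs at overall alpha when either both gates are open
#' and p3 <= alpha, or one gate is open and p3 <= alpha/2, so the adjusted
#' p is min(max(q_max, p3), max(q_min, 2 p3)), capped at 1. Monotone in
#' every input.
#'
#' @param p_iron,p_mnp,p_head_to_head unadjusted p-values.
#' @return named numeric vector of adjusted p-values.
#' @export
adjusted_pvalues <- function(p_iron, p_mnp, p_head_to_head) {
  assert_prob(c(p_iron, p_mnp, p_head_to_head), "p-values")
  q <- 2 * c(p_iron, p_mnp)
  qmin <- min(q); qmax <- max(q)
  hh <- min(max(qmax, p_head_to_head), max(qmin, 2 * p_head_to_head))
  c(iron_vs_placebo = min(1, q[1]),
    mnp_vs_placebo = min(1, q[2]),
    iron_vs_mnp = min(1, hh))
}

#' Hochberg step-up testing for a key-secondary family
#'
#' For each pairwise comparison, the key-secondary endpoints form one family
#' tested by the Hochberg step-up procedure at the significance level that
#' the gatekeeper assigned to the corresponding primary comparison — and
#' only if that primary null hypothesis was rejected (the gate). With the
#' gate closed the family is untested and only descriptive output (estimates
#' and confidence intervals) is reported. Adjusted p-values are the standard
#' Hochberg ones (min over j >= i of (m - j + 1) p_(j), capped at 1,
#' monotone); ties are broken by original index, which cannot change any
#' decision.
#'
#' @param p_values unadjusted p-values of the family (may be named).
#' @param family_alpha significance level assigned to the family.
#' @param gate_open logical: was the corresponding primary hypothesis
#'   rejected?
#' @return data.frame with `p_unadjusted`, `p_adjusted`, `rejected`,
#'   `tested`; with the gate closed, `tested` is FALSE and the inferential
#'   columns are NA.
#' @export
hochberg_family <- function(p_values, family_alpha, gate_open) {
  if (!length(p_values))
    return(data.frame(p_unadjusted = numeric(0), p_adjusted = numeric(0),
                      rejected = logical(0), tested = logical(0)))
  assert_prob(p_values, "p_values")
  assert_prob(family_alpha, "family_alpha")
  nm <- names(p_values) %||% paste0("H", seq_along(p_values))
  if (!gate_open) {
    out <- data.frame(endpoint = nm, p_unadjusted = p_values,
                      p_adjusted = NA_real_, rejected = NA,
                      tested = FALSE, stringsAsFactors = FALSE)
    rownames(out) <- NULL
    return(out)
  }
  adj <- stats::p.adjust(p_values, method = "hochberg")
  out <- data.frame(endpoint = nm, p_unadjusted = p_values,
                    p_adjusted = adj, rejected = adj <= family_alpha,
                    tested = TRUE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Full month-level multiplicity procedure
#'
#' Convenience driver: runs the primary gatekeeper and then the three
#' key-secondary Hochberg families (one per pairwise comparison), each at
#' the primary's assigned level and gated on the primary's rejection. The
#' month-3 and month-12 procedures are independent; call this once per
#' time-point.
#'
#' @param primary_p named vector with `iron_vs_placebo`, `mnp_vs_placebo`,
#'   `iron_vs_mnp` unadjusted p-values for the primary endpoint.
#' @param secondary_p named list of p-value vectors per comparison (same
#'   three names), each across the key-secondary endpoints.
#' @param overall_alpha overall familywise level.
#' @return list with `primary` (a `gatekeeper_result`) and `secondary`
#'   (per-comparison Hochberg tables).
#' @export
multiplicity_procedure <- function(primary_p, secondary_p = NULL,
                                   overall_alpha = 0.05) {
  gk <- gatekeeper_primary(primary_p[["iron_vs_placebo"]],
                           primary_p[["mnp_vs_placebo"]],
                           primary_p[["iron_vs_mnp"]],
                           overall_alpha = overall_alpha)
  sec <- NULL
  if (!is.null(secondary_p)) {
    sec <- lapply(gk$hypothesis, function(h) {
      row <- gk[gk$hypothesis == h, ]
      pv <- secondary_p[[h]]
      if (is.null(pv)) return(NULL)
      gate <- isTRUE(row$tested) && isTRUE(row$rejected)
      alpha <- if (gate) row$assigned_alpha else NA_real_
      hochberg_family(pv, if (gate) alpha else 0.05, gate_open = gate)
    })
    names(sec) <- gk$hypothesis
  }
  list(primary = gk, secondary = sec)
}
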