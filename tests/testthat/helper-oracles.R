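# Independent oracles used to check the package's implementations. These
# deliberately re-derive every quantity from first principles and share no
# code with the functions under test.

# Direct transcription of the serial gatekeeping decision tree: primaries at
# alpha/2 by Bonferroni; head-to-head tested only if a gate opens, at
# alpha/2 (one primary rejected) or alpha (both rejected).
gatekeeper_oracle <- function(p1, p2, p3, alpha = 0.05) {
  r1 <- p1 <= alpha / 2
  r2 <- p2 <= alpha / 2
  r3 <- if (r1 && r2) p3 <= alpha else if (r1 || r2) p3 <= alpha / 2 else FALSE
  c(iron = r1, mnp = r2, head_to_head = r3)
}

# Smallest overall alpha on a grid at which the oracle rejects a hypothesis.
adjusted_p_oracle <- function(p1, p2, p3, which,
                              grid = seq(0.0005, 1, by = 0.0005)) {
  for (a in grid) {
    if (gatekeeper_oracle(p1, p2, p3, a)[[which]]) return(a)
  }
  1
}

# Hand-rolled Hochberg step-up: reject all hypotheses up to the largest
# ordered index j with p_(j) <= alpha / (m - j + 1).
hochberg_oracle <- function(p, alpha) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  jmax <- 0L
  for (j in seq_len(m)) if (ps[j] <= alpha / (m - j + 1)) jmax <- j
  rej <- logical(m)
  if (jmax > 0L) rej[ord[seq_len(jmax)]] <- TRUE
  rej
}

# Log-binomial log-likelihood, -Inf outside the admissible region.
logbinom_loglik <- function(beta, X, y) {
  p <- exp(drop(X %*% beta))
  if (any(p >= 1) || any(p <= 0)) return(-Inf)
  sum(y * log(p) + (1 - y) * log(1 - p))
}

# Compact generator configs used across tests.
small_config <- function(n_per_arm = 60, seed = 1, ...) {
  sim_config(n_per_arm = n_per_arm, outcomes = "cognitive",
             include_morbidity = FALSE, include_adherence = FALSE,
             death_rate = 0,
             violation_rates = c(consent_withdrawn = 0, never_dosed = 0,
                                 improper_unblinding = 0,
                                 eligibility_violation = 0),
             seed = seed, ...)
}

# Long child-visit frame for a hand-built two-visit trial.
two_visit_frame <- function(n, arm, y0, y1) {
  data.frame(child_id = rep(sprintf("C%04d", seq_len(n)), each = 2),
             arm = rep(arm, each = 2), visit = rep(0:1, n),
             y = as.vector(rbind(y0, y1)), stringsAsFactors = FALSE)
}

# Complete-case difference in mean change from baseline to month 3.
cc_change_diff <- function(trial, outcome = "cognitive",
                           arms = c("iron", "placebo")) {
  af <- analysis_frame(trial)
  w <- stats::reshape(af[, c("child_id", "arm", "visit", outcome)],
                      idvar = c("child_id", "arm"), timevar = "visit",
                      direction = "wide")
  c0 <- paste0(outcome, ".0"); c1 <- paste0(outcome, ".1")
  cc <- w[stats::complete.cases(w[, c(c0, c1)]), ]
  ch <- cc[[c1]] - cc[[c0]]
  mean(ch[cc$arm == arms[1]]) - mean(ch[cc$arm == arms[2]])
}
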