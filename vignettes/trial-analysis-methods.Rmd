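---
title: "Methods: simulating and analysing a three-arm supplementation trial"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing a three-arm supplementation trial}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cldagate)
```

## The problem this package addresses

`cldagate` implements, as reusable and tested code, the pre-specified
statistical machinery of a three-arm, placebo-controlled, individually
randomised superiority trial of infant iron supplementation: iron syrup
versus iron-containing micronutrient powders (MNPs) versus placebo, with a
developmental composite (population mean 100, SD 15) as the primary outcome
measured at baseline, month 3 (end of intervention) and month 12. Because
no individual-level data from such a trial are public, the package pairs
the analysis machinery with a synthetic-trial generator that reproduces the
statistical structure the analysis assumes — stratified permuted-block
randomisation, correlated repeated measures, laboratory and anthropometric
outcomes, morbidity report series, adherence, and loss to follow-up — so
that every stage can be exercised and its operating characteristics
(type-I error, power, bias, coverage) certified by simulation.

## The constrained longitudinal model

For a continuous outcome $y_{iv}$ of child $i$ at visit $v \in \{0,1,2\}$
the model is

$$E(y_{iv}) = \mu_0 + \mu_v + \delta_{a(i),v} + x_i^\top\gamma,
  \qquad \delta_{a,0} \equiv 0,\ \mu_0 \text{ shared},$$

with a joint within-child covariance $\Sigma$ across the three visits.
Because treatment assignment is randomised, all arms share the baseline
mean — the defining constraint. The treatment effect at visit $t$ is the
difference in mean change from baseline, $\delta_{a,t} - \delta_{b,t}$,
with the placebo deltas identically zero. The default covariance is
unstructured; AR(1), Toeplitz and compound symmetry are available as a
non-convergence cascade in that order (`fit_clda_cascade()`), and the fit
is labelled with the structure that converged.

Children with missing visits contribute the marginal multivariate-normal
likelihood of their observed sub-vector, which makes the estimator valid
under missing-at-random (MAR) dropout — the primary missing-data strategy.

### Numerical approach

The likelihood is profiled over the mean parameters: for fixed $\Sigma$
the coefficients are the GLS solution, so the optimiser (BFGS) searches
only the covariance parameters, using a log-Cholesky parameterisation for
the unstructured case and variance/correlation transforms (log, tanh,
scaled logistic) for the structured ones — all unconstrained and smooth.
Children are grouped by missingness pattern: within a pattern every child
shares the same weight matrix, so the per-pattern cross-products
$X_j^\top X_k$, $X_j^\top y_k$, $y_j^\top y_k$ split by visit pair are
precomputed once and each likelihood evaluation reduces to scalar-weighted
sums of small matrices. A full fit on 3300 children takes well under a
second, which is what makes 2000-replicate certification runs practical on
one CPU.

ML (not REML) is the default so that log-likelihoods are comparable across
mean structures; REML is available by flag. Convergence is declared on the
optimiser's own criterion with a tight relative tolerance (1e-12 on the
log-likelihood); a declared non-convergence is flagged, never silently
accepted. Inference uses Wald statistics with the normal reference — at
the trial's scale (hundreds to thousands of children) the difference from
a t reference is negligible; a t option with user degrees of freedom
exists for small samples. On complete two-visit data the model reproduces
the baseline-adjusted ANCOVA estimator exactly (a known equivalence the
test suite checks to 1e-6 against `lm()`), and the three-visit fit with
missing data is cross-checked against `nlme::gls` on complete data.

## Multiplicity: serial gatekeeping with Hochberg families

The two primary comparisons (iron vs placebo, MNPs vs placebo) are each
tested at the two-sided 2.5% level (Bonferroni split of the overall 5%).
The head-to-head comparison is gated: tested only if at least one primary
null is rejected, at 2.5% if exactly one, at 5% if both; if neither gate
opens, its estimate is reported with a 95% confidence interval and its
p-value is suppressed. Confidence levels always match the assigned
significance level. Adjusted p-values are defined as the smallest overall
alpha at which the full tree rejects the hypothesis; for the primaries
this reduces to min(1, 2p), and for the head-to-head comparison it has the
closed form min(max(q_max, p3), max(q_min, 2 p3)) with q = 2 x (primary
p), which the tests verify against a grid-search oracle. Key-secondary
endpoints form one Hochberg step-up family per pairwise comparison, tested
at the primary's assigned level only when the corresponding primary is
rejected. The month-3 and month-12 procedures run independently; no alpha
is shared across time-points. Secondary and exploratory endpoints receive
estimates and 95% intervals only — the reporting layer enforces the
absence of p-values rather than leaving it to convention.

The default key-secondary family comprises the six endpoints of the main
outcomes table (language and motor composites, length- and weight-for-age
z-score changes, haemoglobin change, log-ferritin); the family composition
is configurable since reasonable readings differ.

## Missing data

The likelihood-based cLDA is the primary strategy. The secondary strategy
is multiple imputation by chained equations in wide ("just another
variable") format: one row per child, one column per outcome-visit, each
incomplete column regressed on the baseline predictors plus *all* other
outcome-visit columns, separately within each treatment arm. Linear steps
use the standard normal–inverse-gamma posterior draw; binary steps use a
large-sample normal draw around the logistic MLE; ferritin is imputed on
the natural-log scale and back-transformed. Defaults: 10 chained cycles,
chronological visit order, m = max(5, ceiling(% missing)). Pooling follows
Rubin's rules with the Barnard–Rubin small-sample degrees of freedom when
a finite complete-data df is supplied.

## Compliance, populations, CACE

Compliance is 100 x (days both products were taken) / (participation days
within the 90-day intervention), complier at >= 70%, and 0% when no intake
data exist. Participation duration is min(last contact, day 90) − day 0 —
the plan leaves the formula open, and this reading truncates at the end of
the intervention, which is the period the products were dispensed for.
Populations: ITT = all randomised minus full-consent withdrawals; safety =
ITT who received at least one dose; per-protocol = ITT compliers without
protocol violations. The complier-average causal effect uses randomisation
as the instrument: CACE = ITT effect / complier proportion in the active
arm (the placebo arm has no access to active treatment), with a
delta-method interval and a weak-instrument flag when the complier
proportion difference is at most 0.05.

## The synthetic-data generator

The generator's defaults encode the design assumptions: 1100 children per
arm, 1:1:1 allocation in permuted blocks stratified by union (3 levels)
and sex, developmental composites with SD 15 and a configurable
exchangeable within-child correlation (default 0.4 — a typical
test–retest correlation for infant developmental composites; the design
documents never state one), and 20% loss to follow-up, MCAR by default
with a calibrated-logistic MAR option (predictors may include the baseline
outcome, optionally differentially by arm — still MAR, since everything
conditioned on is observed). The block size is fixed at 6 (the design says
"fixed size" without a number; 6 is the smallest multiple of 3 that does
not make allocations guessable near block ends, and it is configurable).

Laboratory outcomes: haemoglobin normal (rising means with age), ferritin
and C-reactive protein log-normal so the log-transform and the CRP > 5
mg/L inflammation rule are exercised. Morbidity is Poisson per report
occasion per infection type (negative-binomial overdispersion available),
on a calendar of 13 weekly reports in days 0–90 and 9 monthly reports in
days 91–365; deaths censor subsequent visits and reports. Adherence draws
a per-child daily-intake probability from Beta(5, 2) (median ~75%,
realistic for daily infant supplementation); intake is stored as a
per-child day count, which is all the compliance rule consumes. Baseline
covariates (wealth quintiles uniform, education truncated-Poisson, family
care indicator normal) are stated defaults, not claims about any
population, and are configurable.

What the generator does *not* emulate: item-level scoring of the
developmental instrument (composites are drawn directly), real WHO growth
references (a clearly labelled synthetic LMS table ships for tests; real
LMS tables in the same CSV layout plug straight in), wealth-index
construction, seasonality, site-level clustering beyond the union
stratification, or informative (MNAR) dropout. Passing tests therefore
certify the statistical machinery under the design's own assumptions, not
the behaviour of any real cohort.

## Operating characteristics and design arithmetic

`analytic_power()` and `required_n()` reproduce the published design
arithmetic: with difference 2, SD 15, power 80%, critical value 1.96 and
20% attrition, the analysed 883 per arm inflates to 1103.75 and rounds to
1100 recruited per arm (3300 total); inverting at 880 analysed per arm
returns 79.9% power. The design text says "two-sided 2.5% level", whose
critical value is 2.241, but only 1.96 reproduces both printed numbers —
the reconstruction defaults to 1.96 and both are selectable. Likewise the
baseline–follow-up correlation behind the 80% claim is never stated; the
zero-correlation change-score reading with 1.96 is the best-fitting
reconstruction and is recorded as such.

`simulate_operating_characteristics()` runs the full pipeline per
replicate — simulate, drop out, fit the cLDA cascade, gatekeep — and
aggregates rejection rates, the familywise error rate across the three
pairwise comparisons, bias, empirical SE, and CI coverage at the assigned
levels. The certification scenario uses 150 children per arm and 2000
replicates so the run completes in about two minutes on one CPU; the
familywise error under the global null lands just under 5% (Bonferroni
with a shared control arm is slightly conservative). Full-size scenarios
are the same call with the config's defaults. The heavy test-suite runs
use the same reduced scales (500 replicates at 500/arm for parameter
recovery; 200 replicates at 300/arm for the MAR/MI comparison), chosen so
the whole suite certifies every guarantee in a few minutes.

## Known limitations

- The log-link binomial mixed model inherits lme4's fragility near the
  boundary; the documented fallback (logit link, odds ratios, reason
  logged) is exercised in tests, as is the robust-Poisson fallback of the
  log-binomial model (the plan specifies a fallback only for the mixed
  model; the robust-Poisson choice for the marginal model is this
  package's, labelled as such in the output).
- The common-baseline device does not transfer cleanly to nonlinear links,
  so binary outcomes adjust for the baseline status of the indicator as a
  covariate instead — a documented divergence from analysing them
  "similarly" to the continuous outcomes.
- Rater effects (sensitivity models with rater terms) enter as fixed
  categorical covariates via the `covariates` argument; a random-rater
  formulation is not provided.
- Visit-window defaults (baseline ±14 d, month 3 = day 90 ± 28 d, month
  12 = day 365 ± 56 d) are this package's choice — the plan prescribes
  windows without defining them. Out-of-window assessments are excluded,
  never reallocated to the nearer visit.
- The gatekeeper's adjusted p for the head-to-head comparison is
  suppressed whenever the gate never opens, matching the CI-only
  reporting instruction for that branch.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_per_arm = 300, seed = 11,
                  effects = list(iron = list(cognitive = c(0, 2, 2))))
trial <- apply_missingness(simulate_trial(cfg), seed = 12)
fit <- fit_clda_cascade(trial, "cognitive")
estimate_effect(fit, c("iron", "placebo"), visit = 1, ci_level = 0.975)
gatekeeper_primary(p_iron = 0.004, p_mnp = 0.21, p_head_to_head = 0.03)
```
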