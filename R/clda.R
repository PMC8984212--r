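# Constrained longitudinal data analysis (cLDA).
#
# Model for a continuous outcome y_{iv} at visits v = 0..V:
#   E(y_{iv}) = mu_0 + mu_v + delta_{a(i),v} + x_i' gamma,   delta_{a,0} = 0,
# with a common baseline mean across randomised arms (the constraint) and a
# joint within-child covariance Sigma across visits. Children with missing
# visits contribute the marginal multivariate-normal likelihood of their
# observed sub-vector, so estimation is valid under MAR.
#
# The likelihood is profiled: for fixed Sigma the mean coefficients are the
# GLS solution, so the optimiser only searches the covariance parameters
# (log-Cholesky for unstructured; variance + correlation transforms for the
# structured alternatives). Because children sharing a missingness pattern
# share the same weight matrix, the per-pattern cross-products X'X, X'y, y'y
# split by visit-pair are precomputed once and every likelihood evaluation
# reduces to scalar-weighted sums of small matrices.

sigma_param_length <- function(structure, k) {
  switch(structure,
         unstructured = k * (k + 1L) / 2L,
         ar1 = 2L, cs = 2L,
         toeplitz = k,
         stop_cldagate("unknown covariance structure: ", structure))
}

sigma_from_theta <- function(theta, structure, k) {
  switch(structure,
    unstructured = {
      L <- matrix(0, k, k)
      diag(L) <- exp(theta[seq_len(k)])
      if (k > 1) L[lower.tri(L)] <- theta[-seq_len(k)]
      L %*% t(L)
    },
    ar1 = {
      s2 <- exp(2 * theta[1]); rho <- tanh(theta[2])
      s2 * rho^abs(outer(seq_len(k), seq_len(k), "-"))
    },
    cs = {
      s2 <- exp(2 * theta[1])
      lo <- -1 / (k - 1)
      rho <- lo + (1 - lo) * stats::plogis(theta[2])
      s2 * ((1 - rho) * diag(k) + rho)
    },
    toeplitz = {
      s2 <- exp(2 * theta[1]); rho <- tanh(theta[-1])
      R <- diag(k)
      for (l in seq_len(k - 1)) {
        idx <- which(abs(outer(seq_len(k), seq_len(k), "-")) == l)
        R[idx] <- rho[l]
      }
      s2 * R
    })
}

theta_init <- function(sigma0, structure, k) {
  sigma0 <- (sigma0 + t(sigma0)) / 2
  if (!is_pd(sigma0)) sigma0 <- diag(diag(sigma0), k)
  switch(structure,
    unstructured = {
      L <- t(chol(sigma0))
      c(log(diag(L)), L[lower.tri(L)])
    },
    ar1 = c(log(sqrt(mean(diag(sigma0)))),
            atanh(max(min(mean(stats::cov2cor(sigma0)[abs(row(sigma0) - col(sigma0)) == 1]),
                          0.95), -0.95))),
    cs = {
      rbar <- mean(stats::cov2cor(sigma0)[lower.tri(sigma0)])
      lo <- -1 / (k - 1)
      p <- min(max((rbar - lo) / (1 - lo), 0.02), 0.98)
      c(log(sqrt(mean(diag(sigma0)))), stats::qlogis(p))
    },
    toeplitz = {
      R <- stats::cov2cor(sigma0)
      rl <- vapply(seq_len(k - 1), function(l)
        mean(R[abs(row(R) - col(R)) == l]), 0)
      c(log(sqrt(mean(diag(sigma0)))), atanh(pmax(pmin(rl, 0.95), -0.95)))
    })
}

# Build the constrained design matrix: shared baseline intercept, visit main
# effects, treatment-by-visit deltas for non-reference arms at post-baseline
# visits, baseline covariates, and optional extra columns (subgroup terms).
clda_design <- function(df, covariates, extra = NULL) {
  visits <- sort(unique(df$visit))
  if (length(visits) < 2L)
    stop_cldagate("cLDA needs at least 2 observed visits")
  arms_present <- intersect(ARMS, unique(df$arm))
  active <- setdiff(arms_present, "placebo")

  n <- nrow(df)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(baseline)"))
  for (v in visits[-1])
    X <- cbind(X, `colnames<-`(matrix(as.numeric(df$visit == v)), paste0("visit", v)))
  delta_names <- character(0)
  for (a in active) for (v in visits[-1]) {
    nm <- paste0(a, ":visit", v)
    X <- cbind(X, `colnames<-`(matrix(as.numeric(df$arm == a & df$visit == v)), nm))
    delta_names <- c(delta_names, nm)
  }
  if (length(covariates)) {
    miss <- setdiff(covariates, names(df))
    if (length(miss))
      stop_cldagate("covariates absent from data: ", paste(miss, collapse = ", "))
    cf <- df[covariates]
    for (cc in covariates) if (is.character(cf[[cc]])) cf[[cc]] <- factor(cf[[cc]])
    mm <- stats::model.matrix(~ ., data = cf)[, -1, drop = FALSE]
    X <- cbind(X, mm)
  }
  if (!is.null(extra)) X <- cbind(X, extra)

  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop_cldagate("singular model matrix; offending term(s): ",
                  paste(bad, collapse = ", "))
  }
  list(X = X, visits = visits, arms = arms_present, delta_names = delta_names)
}

#' Fit a constrained longitudinal data analysis model
#'
#' Maximum-likelihood fit of a multivariate-normal longitudinal model with
#' visit as a categorical variable, treatment-by-visit effects, adjustment
#' covariates, a baseline mean constrained equal across randomised arms, and
#' a selectable within-child covariance structure (unstructured by default;
#' AR(1), Toeplitz and compound symmetry as fallbacks for non-convergence).
#' Children with missing visits contribute the marginal likelihood of their
#' observed sub-vector. Treatment effects are differences in mean change
#' from baseline and are read off as the `arm:visit` coefficients.
#'
#' @param data a `trial_data` object or a child-visit data.frame with
#'   columns `child_id`, `arm`, `visit`, the outcome, and any covariates.
#' @param outcome name of the outcome column.
#' @param covariance covariance structure: "unstructured", "ar1",
#'   "toeplitz", or "cs" (compound symmetry).
#' @param covariates adjustment covariates; default the stratification
#'   factors union and sex.
#' @param transform "identity" or "log" (natural log applied before
#'   fitting; effect estimates then exponentiate to ratios).
#' @param reml use REML instead of ML (default ML, for likelihood
#'   comparability across mean structures).
#' @param fixed_sigma optional known covariance matrix; the mean model is
#'   then a single GLS solve and no covariance estimation is done.
#' @param extra_terms optional numeric matrix of additional design columns
#'   (aligned to the rows of `data` after internal filtering is *not*
#'   supported; supply per-row columns for the full data and they are
#'   filtered together with the outcome). Used by [subgroup_analysis()].
#' @param control list: `maxit` (default 500), `reltol` (default 1e-12).
#'
#' @return object of class `clda_fit` with elements `coefficients`, `vcov`,
#'   `sigma`, `structure`, `logLik`, `converged`, `n_children`, `n_obs`.
#' @export
fit_clda <- function(data, outcome,
                     covariance = c("unstructured", "ar1", "toeplitz", "cs"),
                     covariates = c("union", "sex"),
                     transform = c("identity", "log"),
                     reml = FALSE, fixed_sigma = NULL, extra_terms = NULL,
                     control = list()) {
  covariance <- match.arg(covariance)
  transform <- match.arg(transform)
  if (inherits(data, "trial_data")) data <- analysis_frame(data)
  if (!outcome %in% names(data)) stop_cldagate("outcome `", outcome, "` not in data")
  ctrl <- utils::modifyList(list(maxit = 500L, reltol = 1e-12), control)

  y <- data[[outcome]]
  if (transform == "log") {
    if (any(y <= 0, na.rm = TRUE))
      stop_cldagate("log transform requires positive outcome values")
    y <- log(y)
  }
  cov_ok <- if (length(covariates))
    stats::complete.cases(data[covariates]) else rep(TRUE, nrow(data))
  keep <- !is.na(y) & cov_ok & !is.na(data$visit) & !is.na(data$arm)
  df <- data[keep, , drop = FALSE]
  y <- y[keep]
  if (!is.null(extra_terms)) extra_terms <- extra_terms[keep, , drop = FALSE]
  if (!nrow(df)) stop_cldagate("no usable observations for `", outcome, "`")

  des <- clda_design(df, covariates, extra_terms)
  X <- des$X; visits <- des$visits; q <- ncol(X)

  # group children by missingness pattern; precompute visit-pair cross-products
  ord <- order(df$child_id, df$visit)
  df <- df[ord, , drop = FALSE]; X <- X[ord, , drop = FALSE]; y <- y[ord]
  vpos <- match(df$visit, visits)
  pat_key <- vapply(split(vpos, df$child_id), function(s)
    paste(sort(s), collapse = ","), "")
  child_ids <- names(pat_key)
  n_children <- length(child_ids)
  row_child <- match(df$child_id, child_ids)

  patterns <- lapply(unique(pat_key), function(pk) {
    s <- as.integer(strsplit(pk, ",")[[1]])
    kids <- which(pat_key == pk)
    rows <- which(row_child %in% kids)
    # rows are ordered child-major, visit-minor; reshape into per-slot blocks
    slot <- match(vpos[rows], s)
    Xs <- lapply(seq_along(s), function(j) X[rows[slot == j], , drop = FALSE])
    ys <- lapply(seq_along(s), function(j) y[rows[slot == j]])
    kp <- length(s)
    SXX <- vector("list", kp * kp); SXY <- vector("list", kp * kp)
    SYY <- matrix(0, kp, kp)
    for (j in seq_len(kp)) for (l in seq_len(kp)) {
      SXX[[(j - 1) * kp + l]] <- crossprod(Xs[[j]], Xs[[l]])
      SXY[[(j - 1) * kp + l]] <- crossprod(Xs[[j]], ys[[l]])
      SYY[j, l] <- sum(ys[[j]] * ys[[l]])
    }
    list(s = s, n = length(kids), kp = kp, SXX = SXX, SXY = SXY, SYY = SYY)
  })
  N_obs <- length(y)

  gls_pieces <- function(sigma) {
    A <- matrix(0, q, q); b <- numeric(q); cc <- 0; ldsum <- 0
    for (p in patterns) {
      Ssub <- sigma[p$s, p$s, drop = FALSE]
      ch <- tryCatch(chol(Ssub), error = function(e) NULL)
      if (is.null(ch)) return(NULL)
      W <- chol2inv(ch)
      ldsum <- ldsum + p$n * 2 * sum(log(diag(ch)))
      kp <- p$kp
      for (j in seq_len(kp)) for (l in seq_len(kp)) {
        w <- W[j, l]
        if (w != 0) {
          A <- A + w * p$SXX[[(j - 1) * kp + l]]
          b <- b + w * p$SXY[[(j - 1) * kp + l]]
          cc <- cc + w * p$SYY[j, l]
        }
      }
    }
    chA <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(chA)) return(NULL)
    beta <- backsolve(chA, forwardsolve(t(chA), b))
    list(A = A, chA = chA, beta = beta,
         quad = cc - sum(b * beta), ldsum = ldsum)
  }

  negll <- function(theta) {
    sigma <- sigma_from_theta(theta, covariance, length(visits))
    gp <- gls_pieces(sigma)
    if (is.null(gp) || !is.finite(gp$quad)) return(1e10)
    nll <- 0.5 * (N_obs * log(2 * pi) + gp$ldsum + gp$quad)
    if (reml) nll <- nll + sum(log(diag(gp$chA)))
    if (!is.finite(nll)) 1e10 else nll
  }

  if (!is.null(fixed_sigma)) {
    if (!is_pd(fixed_sigma)) stop_cldagate("`fixed_sigma` must be positive-definite")
    gp <- gls_pieces(fixed_sigma)
    if (is.null(gp)) stop_cldagate("GLS solve failed at the supplied covariance")
    sigma_hat <- fixed_sigma
    ll <- -0.5 * (N_obs * log(2 * pi) + gp$ldsum + gp$quad)
    converged <- TRUE
    structure_label <- "fixed"
  } else {
    # initial covariance from OLS residuals (pairwise-complete correlations)
    beta0 <- qr.coef(qr(X), y)
    r <- y - drop(X %*% beta0)
    k <- length(visits)
    sigma0 <- diag(stats::var(r), k)
    rmat <- matrix(NA_real_, n_children, k)
    rmat[cbind(row_child, vpos)] <- r
    pc <- suppressWarnings(stats::cov(rmat, use = "pairwise.complete.obs"))
    if (all(is.finite(pc)) && is_pd(pc)) sigma0 <- pc
    th0 <- theta_init(sigma0, covariance, k)

    opt <- tryCatch(
      stats::optim(th0, negll, method = "BFGS",
                   control = list(maxit = ctrl$maxit, reltol = ctrl$reltol)),
      error = function(e) NULL)
    if (is.null(opt))
      opt <- stats::optim(th0, negll, method = "Nelder-Mead",
                          control = list(maxit = 5000L))
    sigma_hat <- sigma_from_theta(opt$par, covariance, k)
    gp <- gls_pieces(sigma_hat)
    converged <- !is.null(gp) && opt$convergence == 0L && opt$value < 1e9
    if (is.null(gp)) stop_cldagate("covariance estimate degenerate; refit with ",
                                   "a structured covariance")
    ll <- -opt$value
    structure_label <- covariance
  }

  beta <- stats::setNames(drop(gp$beta), colnames(X))
  V <- chol2inv(gp$chA)
  dimnames(V) <- list(colnames(X), colnames(X))
  dimnames(sigma_hat) <- list(paste0("visit", visits), paste0("visit", visits))

  structure(list(
    coefficients = beta, vcov = V, sigma = sigma_hat,
    structure = structure_label, logLik = ll, converged = converged,
    n_children = n_children, n_obs = N_obs, outcome = outcome,
    transform = transform, visits = visits, arms = des$arms,
    delta_names = des$delta_names, reml = reml,
    call = match.call()
  ), class = "clda_fit")
}

#' Fit a cLDA with the pre-specified non-convergence cascade
#'
#' Tries covariance structures in the stated order — unstructured, AR(1),
#' Toeplitz, compound symmetry — and returns the first converged fit,
#' labelled with the structure used.
#'
#' @inheritParams fit_clda
#' @param ... passed to [fit_clda()].
#' @return a `clda_fit`; its `structure` element records which covariance
#'   converged.
#' @export
fit_clda_cascade <- function(data, outcome, ...) {
  last <- NULL
  for (st in c("unstructured", "ar1", "toeplitz", "cs")) {
    fit <- tryCatch(fit_clda(data, outcome, covariance = st, ...),
                    error = function(e) NULL)
    if (!is.null(fit)) {
      last <- fit
      if (fit$converged) return(fit)
    }
  }
  if (is.null(last)) stop_cldagate("no covariance structure produced a fit")
  warning("no covariance structure converged; returning the last fit flagged non-converged")
  last
}

#' @export
print.clda_fit <- function(x, ...) {
  cat("Constrained longitudinal data analysis fit\n")
  cat("  outcome:", x$outcome,
      if (x$transform == "log") "(log scale)" else "", "\n")
  cat("  covariance:", x$structure, " | ",
      if (x$reml) "REML" else "ML",
      "logLik:", format(x$logLik, digits = 8),
      " | converged:", x$converged, "\n")
  cat("  children:", x$n_children, " observations:", x$n_obs, "\n\n")
  ct <- cbind(Estimate = x$coefficients, `Std. Error` = sqrt(diag(x$vcov)))
  print(round(ct, 4))
  invisible(x)
}

#' @export
coef.clda_fit <- function(object, ...) object$coefficients

#' @export
vcov.clda_fit <- function(object, ...) object$vcov

#' @export
logLik.clda_fit <- function(object, ...) {
  structure(object$logLik, df = length(object$coefficients) +
              sigma_param_length(if (object$structure %in%
                                     c("unstructured", "ar1", "toeplitz", "cs"))
                object$structure else "unstructured", length(object$visits)),
            class = "logLik")
}

# Wald chi-square test of a named coefficient block.
wald_block_test <- function(fit, terms) {
  idx <- match(terms, names(fit$coefficients))
  if (anyNA(idx)) stop_cldagate("unknown coefficient(s): ",
                                paste(terms[is.na(idx)], collapse = ", "))
  b <- fit$coefficients[idx]
  V <- fit$vcov[idx, idx, drop = FALSE]
  stat <- drop(t(b) %*% solve(V, b))
  df <- length(idx)
  list(statistic = stat, df = df, p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}
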