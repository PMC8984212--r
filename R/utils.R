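`%||%` <- function(x, y) if (is.null(x)) y else x

ARMS <- c("iron", "mnp", "placebo")
UNIONS <- c("Bhulta", "Golakandail", "Rupganj")
SEXES <- c("female", "male")
MORBIDITY_TYPES <- c("fever", "diarrhoea", "bloody_stool", "vomiting",
                     "cough_difficulty_breathing", "other")
VISIT_LABELS <- c("baseline", "month3", "month12")

#' @keywords internal
stop_cldagate <- function(...) stop(..., call. = FALSE)

assert_prob <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0 | x > 1))
    stop_cldagate(sprintf("`%s` must be a probability in [0, 1]", name))
  invisible(x)
}

assert_count <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) ||
      (positive && x <= 0) || (!positive && x < 0))
    stop_cldagate(sprintf("`%s` must be a %s integer", name,
                          if (positive) "positive" else "non-negative"))
  invisible(as.integer(x))
}

# Run `expr` with the RNG seeded to `seed`, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Derive independent sub-seeds from a master seed (kept below .Machine$integer.max).
spawn_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

is_pd <- function(sigma, tol = 1e-10) {
  ev <- tryCatch(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values,
                 error = function(e) NA_real_)
  all(is.finite(ev)) && min(ev) > tol * max(abs(ev), 1)
}

# Draws from N(mean, sigma) for n subjects; mean is length-k, sigma k x k.
rmvnorm_chol <- function(n, mean, sigma) {
  k <- length(mean)
  L <- chol(sigma)
  z <- matrix(stats::rnorm(n * k), n, k) %*% L
  sweep(z, 2L, mean, "+")
}
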