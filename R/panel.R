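#' Longitudinal growth panel
#'
#' Container for a balanced N x T panel of outcomes measured at occasions
#' coded 0, ..., T-1.  Panels produced by [simulate_panel()] additionally
#' carry the true subject-level intercepts and slopes and a contamination
#' mask marking cells replaced by outliers.
#'
#' @param outcomes numeric N x T matrix of measurements.
#' @param occasions occasion codes; defaults to 0, ..., T-1.
#' @param effects optional N x 2 matrix of true subject effects (L_i, S_i).
#' @param contaminated optional N x T logical mask of replaced cells.
#' @param sigma2_e optional true error variance used in generation.
#' @param seed optional integer seed recorded for provenance.
#' @return object of class `growth_panel`.
#' @export
growth_panel <- function(outcomes, occasions = NULL, effects = NULL,
                         contaminated = NULL, sigma2_e = NULL, seed = NULL) {
  outcomes <- as.matrix(outcomes)
  if (!is.numeric(outcomes)) stop("`outcomes` must be numeric")
  if (anyNA(outcomes)) {
    stop("missing cells are not supported: panels must be complete")
  }
  n <- nrow(outcomes)
  t_occ <- ncol(outcomes)
  if (is.null(occasions)) occasions <- seq_len(t_occ) - 1
  if (length(occasions) != t_occ) {
    stop("`occasions` must have one code per column of `outcomes`")
  }
  if (!is.null(effects)) {
    effects <- as.matrix(effects)
    if (nrow(effects) != n || ncol(effects) != 2L) {
      stop("`effects` must be an N x 2 matrix")
    }
  }
  if (is.null(contaminated)) {
    contaminated <- matrix(FALSE, n, t_occ)
  } else {
    contaminated <- as.matrix(contaminated)
    if (!is.logical(contaminated) || nrow(contaminated) != n ||
        ncol(contaminated) != t_occ) {
      stop("`contaminated` must be an N x T logical matrix")
    }
  }
  structure(
    list(outcomes = unname(outcomes), occasions = as.numeric(occasions),
         effects = effects, contaminated = contaminated,
         sigma2_e = sigma2_e, seed = seed),
    class = "growth_panel"
  )
}

#' @export
print.growth_panel <- function(x, ...) {
  cat("Longitudinal panel:", nrow(x$outcomes), "subjects x",
      ncol(x$outcomes), "occasions\n")
  n_bad <- sum(x$contaminated)
  if (n_bad > 0) {
    cat(sprintf("  %d contaminated cells (%.1f%%)\n", n_bad,
                100 * n_bad / length(x$outcomes)))
  }
  cat("  occasion codes:", paste(x$occasions, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.growth_panel <- function(x) dim(x$outcomes)

#' Simulate a clean (normal) longitudinal panel
#'
#' Generates y_i = Lambda b_i + e_i with subject effects
#' b_i ~ N(beta, Psi) and homoscedastic errors e_i ~ N(0, sigma2_e I).
#' Defaults reproduce a linear growth process with mean intercept 6.2,
#' mean slope 0.3, intercept variance 1, slope variance 0.1, zero
#' intercept-slope covariance, error variance 0.5, and four occasions.
#'
#' @param n number of subjects.
#' @param beta length-2 fixed effects (mean intercept, mean slope).
#' @param psi 2 x 2 random-effect covariance (see [ranef_cov()]).
#' @param sigma2_e error variance (>= 0).
#' @param design a [growth_design()]; defaults to [linear_design(4)].
#' @param seed optional integer seed; fixing it makes the panel
#'   reproducible.
#' @return a [growth_panel()] carrying the true effects.
#' @export
simulate_panel <- function(n, beta = c(6.2, 0.3),
                           psi = ranef_cov(1, 0.1, 0), sigma2_e = 0.5,
                           design = linear_design(4), seed = NULL) {
  stopifnot(n >= 1, sigma2_e >= 0)
  psi <- as.matrix(psi)
  q <- design$n_factors
  if (length(beta) != q) stop("`beta` must match the number of factors")
  ev <- eigen((psi + t(psi)) / 2, symmetric = TRUE)
  if (min(ev$values) < -1e-10) stop("`psi` must be positive semidefinite")
  if (!is.null(seed)) set.seed(seed)
  # b = beta + Psi^{1/2} z via eigendecomposition (works for singular Psi)
  root <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), q) %*% t(ev$vectors)
  b <- matrix(rep(beta, each = n), n, q) +
    matrix(stats::rnorm(n * q), n, q) %*% root
  t_occ <- design$n_occasions
  e <- matrix(stats::rnorm(n * t_occ, sd = sqrt(sigma2_e)), n, t_occ)
  y <- b %*% t(design$loadings) + e
  growth_panel(y, occasions = design$loadings[, min(2L, q)],
               effects = if (q == 2L) b else NULL,
               sigma2_e = sigma2_e, seed = seed)
}

#' Outlier contamination settings
#'
#' Describes the mean-shift contamination process: at each occasion a
#' fixed proportion of observations is replaced by draws from one of
#' `n_components` normal distributions centered `m_c` error standard
#' deviations above the subject's own trajectory, where the multipliers
#' `m_c` are distinct draws from a Poisson distribution truncated to
#' `m >= min_multiplier`.  Component variances equal the clean error
#' variance, so contamination shifts location only.
#'
#' @param proportion fraction of observations replaced per occasion, in
#'   \[0, 1).
#' @param n_components number of distinct outlier component distributions.
#' @param min_multiplier truncation floor for the mean-shift multiplier m.
#' @param multiplier_rate rate of the untruncated Poisson for m.
#' @param component_variance variance of each outlier component; `NULL`
#'   means "same as the clean error variance of the panel".
#' @return object of class `outlier_spec`.
#' @export
outlier_spec <- function(proportion, n_components = 10L,
                         min_multiplier = 5L, multiplier_rate = 5,
                         component_variance = NULL) {
  stopifnot(proportion >= 0, proportion < 1, n_components >= 1,
            min_multiplier >= 1, multiplier_rate > 0)
  structure(
    list(proportion = proportion, n_components = as.integer(n_components),
         min_multiplier = as.integer(min_multiplier),
         multiplier_rate = multiplier_rate,
         component_variance = component_variance),
    class = "outlier_spec"
  )
}

# Distinct draws from a Poisson truncated to >= floor; rejection sampling.
draw_multipliers <- function(n_components, floor_m, rate) {
  out <- integer(0)
  while (length(out) < n_components) {
    m <- stats::rpois(1, rate)
    if (m >= floor_m && !(m %in% out)) out <- c(out, m)
  }
  out
}

#' Contaminate a panel with mean-shifted outliers
#'
#' At each measurement occasion, `round(proportion * N)` subjects are
#' selected without replacement (independently across occasions) and their
#' measurement at that occasion is replaced by a draw from a randomly
#' chosen outlier component: normal with mean
#' L_i + S_i * code_j + m_c * sigma_e and variance equal to the clean
#' error variance.  Together with the clean law this makes the generating
#' distribution a mixture of `n_components + 1` distinct distributions.
#'
#' @param panel a [growth_panel()] carrying true effects.
#' @param spec an [outlier_spec()].
#' @param seed optional integer seed.
#' @return a new [growth_panel()] with updated outcomes and mask.
#' @export
contaminate <- function(panel, spec, seed = NULL) {
  stopifnot(inherits(panel, "growth_panel"), inherits(spec, "outlier_spec"))
  if (spec$proportion == 0) return(panel)
  if (is.null(panel$effects)) {
    stop("panel must carry true subject effects to position outliers")
  }
  if (is.null(panel$sigma2_e) && is.null(spec$component_variance)) {
    stop("component variance unknown: panel has no recorded sigma2_e")
  }
  n <- nrow(panel$outcomes)
  t_occ <- ncol(panel$outcomes)
  n_rep <- round(spec$proportion * n)  # round half to even
  if (n_rep < 1) {
    warning("proportion * N < 1: no observations replaced")
    return(panel)
  }
  if (!is.null(seed)) set.seed(seed)
  sigma_e <- sqrt(panel$sigma2_e %||% spec$component_variance)
  comp_var <- spec$component_variance %||% panel$sigma2_e
  mult <- draw_multipliers(spec$n_components, spec$min_multiplier,
                           spec$multiplier_rate)
  y <- panel$outcomes
  mask <- panel$contaminated
  for (j in seq_len(t_occ)) {
    idx <- sample.int(n, n_rep)
    comp <- sample.int(spec$n_components, n_rep, replace = TRUE)
    mu <- panel$effects[idx, 1] + panel$effects[idx, 2] * panel$occasions[j] +
      mult[comp] * sigma_e
    y[idx, j] <- stats::rnorm(n_rep, mean = mu, sd = sqrt(comp_var))
    mask[idx, j] <- TRUE
  }
  out <- panel
  out$outcomes <- y
  out$contaminated <- mask
  out$multipliers <- mult
  out$seed <- seed %||% panel$seed
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
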