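#' Growth curve factor-loading design
#'
#' A growth design holds the T x q factor loading matrix \eqn{\Lambda} that
#' maps q growth factors (for the linear model: a random intercept and a
#' random slope) onto T measurement occasions.  Occasions are coded
#' 0, 1, ..., T-1 so that the intercept is the occasion-0 mean.
#'
#' @param loadings numeric matrix with one row per occasion and one column
#'   per growth factor.
#' @return an object of class `growth_design` with elements `loadings`,
#'   `n_occasions` and `n_factors`.
#' @seealso [linear_design()] for the standard intercept + slope design.
#' @export
growth_design <- function(loadings) {
  loadings <- as.matrix(loadings)
  if (!is.numeric(loadings) || anyNA(loadings)) {
    stop("`loadings` must be a numeric matrix without missing values")
  }
  if (nrow(loadings) < 1L || ncol(loadings) < 1L) {
    stop("`loadings` must have at least one row and one column")
  }
  structure(
    list(
      loadings = unname(loadings),
      n_occasions = nrow(loadings),
      n_factors = ncol(loadings)
    ),
    class = "growth_design"
  )
}

#' Linear growth design (random intercept and slope)
#'
#' Builds the T x 2 loading matrix of the linear growth curve model: the
#' first column is all ones (intercept), the second is the occasion codes
#' 0, 1, ..., T-1 (slope).
#'
#' @param n_occasions number of measurement occasions T (>= 1).
#' @return a [growth_design()] object.
#' @examples
#' linear_design(4)$loadings
#' @export
linear_design <- function(n_occasions) {
  if (!is.numeric(n_occasions) || length(n_occasions) != 1L ||
      is.na(n_occasions) || n_occasions < 1 ||
      n_occasions != round(n_occasions)) {
    stop("`n_occasions` must be a positive integer")
  }
  n_occasions <- as.integer(n_occasions)
  growth_design(cbind(rep(1, n_occasions), seq_len(n_occasions) - 1))
}

#' @export
print.growth_design <- function(x, ...) {
  cat("Growth design:", x$n_occasions, "occasions,",
      x$n_factors, "growth factors\n")
  print(x$loadings)
  invisible(x)
}

#' Random-effect covariance matrix of the linear growth model
#'
#' Convenience constructor for the 2 x 2 covariance matrix \eqn{\Psi} of
#' the random intercept and slope.
#'
#' @param var_intercept variance of the random intercept (\eqn{\sigma^2_L}).
#' @param var_slope variance of the random slope (\eqn{\sigma^2_S}).
#' @param cov_int_slope intercept-slope covariance (\eqn{\sigma_{LS}});
#'   must satisfy \eqn{\sigma_{LS}^2 \le \sigma^2_L \sigma^2_S}.
#' @return a symmetric positive semidefinite 2 x 2 matrix.
#' @export
ranef_cov <- function(var_intercept, var_slope, cov_int_slope = 0) {
  if (var_intercept < 0 || var_slope < 0) {
    stop("variances must be nonnegative")
  }
  if (cov_int_slope^2 > var_intercept * var_slope + 1e-12) {
    stop("`cov_int_slope` makes the covariance matrix indefinite")
  }
  matrix(c(var_intercept, cov_int_slope, cov_int_slope, var_slope), 2, 2)
}

#' Model-implied mean and covariance of the observed outcomes
#'
#' For the growth curve model y_i = Lambda b_i + e_i with b_i ~ N(beta, Psi)
#' and homoscedastic errors e_i ~ N(0, sigma2_e I), the marginal moments of
#' y_i are mean = Lambda beta and covariance
#' Lambda Psi Lambda' + sigma2_e I.
#'
#' @param beta numeric vector of fixed effects (length q).
#' @param psi q x q random-effect covariance matrix (see [ranef_cov()]).
#' @param sigma2_e nonnegative error variance.
#' @param design a [growth_design()].
#' @return list with elements `mean` (length T) and `covariance` (T x T).
#' @examples
#' implied_moments(c(6.2, 0.3), ranef_cov(1, 0.1), 0.5, linear_design(4))
#' @export
implied_moments <- function(beta, psi, sigma2_e, design) {
  if (!inherits(design, "growth_design")) {
    stop("`design` must be a growth_design")
  }
  psi <- as.matrix(psi)
  q <- design$n_factors
  if (length(beta) != q) {
    stop("`beta` must have one entry per growth factor")
  }
  if (nrow(psi) != q || ncol(psi) != q) {
    stop("`psi` must be ", q, " x ", q)
  }
  if (max(abs(psi - t(psi))) > 1e-8) stop("`psi` must be symmetric")
  if (min(eigen(psi, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    stop("`psi` must be positive semidefinite")
  }
  if (length(sigma2_e) != 1L || sigma2_e < 0) {
    stop("`sigma2_e` must be a nonnegative scalar")
  }
  lam <- design$loadings
  covar <- lam %*% psi %*% t(lam) + diag(sigma2_e, design$n_occasions)
  list(mean = drop(lam %*% beta), covariance = (covar + t(covar)) / 2)
}
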