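#' Dirichlet-process-mixture model specification
#'
#' Collects every prior and truncation setting of the BNP growth curve
#' model.  Defaults: truncation C = 50 (well above the 95th percentile of
#' the occupied-cluster count for all studied precision/sample-size
#' combinations), Gamma(2, 2) precision prior, diffuse N(0, 1e6) priors
#' for the fixed effects, inverse-Wishart(identity scale, df 2) prior for
#' the random-effect covariance, and component means fixed at zero.
#'
#' Two base-measure structures are available for the component error
#' covariances.  The default, `"isotropic"`, draws
#' Phi^(j) = phi_j I with phi_j ~ Inverse-Gamma(n0/2, w0/2) and a
#' conjugate gamma hyperprior on the scale w0; since
#' Lambda Psi Lambda' + phi I is an identified decomposition, the
#' random-effect covariance and the error variance separate cleanly.
#' `"full"` draws unrestricted Phi^(j) ~ IW(n0, W0) with a conjugate
#' Wishart hyperprior on W0; the decomposition
#' Lambda Psi Lambda' + Phi is then not identified from the data and the
#' split between Psi and Phi is prior-driven (see the methods vignette).
#'
#' @param truncation maximum number of mixture components C (>= 2).
#' @param alpha_prior gamma prior for the precision parameter; a label
#'   accepted by [alpha_prior()] or a `c(shape, rate)` vector.
#' @param base_structure `"isotropic"` (default) or `"full"`.
#' @param base_df degrees of freedom n0 of the component base measure;
#'   `NULL` means 4 (isotropic: phi_j ~ IG(2, w0/2)) or T + 2 (full:
#'   weakest proper inverse-Wishart with finite mean), resolved at fit
#'   time.
#' @param base_scale_df,base_scale_matrix hyperprior for the base scale:
#'   isotropic, w0 ~ Gamma(base_scale_df/2, 1/(2 base_scale_matrix))
#'   with scalar scale (defaults 2 and 1); full, W0 ~
#'   Wishart(base_scale_df, base_scale_matrix) (defaults T + 2 and
#'   I/(T + 2), giving E(W0) = I).
#' @param beta_prior_var prior variance of each fixed effect.
#' @param psi_prior_df,psi_prior_scale inverse-Wishart prior for the
#'   random-effect covariance; `NULL` scale means the identity.
#' @param alpha_update `"augmented"` (default) for the Escobar-West
#'   beta-augmentation that draws alpha from its exact two-gamma mixture
#'   posterior given the occupied-cluster count, or `"stick"` for the
#'   conjugate gamma update implied by the truncated stick-breaking
#'   likelihood.  The two rules target genuinely different alpha
#'   posteriors under a truncated representation: the augmented rule
#'   follows the unconditional Dirichlet-process posterior of the
#'   precision parameter, while the stick rule's conditional gains
#'   truncation - 1 pseudo-observations and so depends visibly on the
#'   truncation level (see the methods vignette).
#' @return object of class `dpm_spec`.
#' @export
dpm_spec <- function(truncation = 50L,
                     alpha_prior = c(shape = 2, rate = 2),
                     base_structure = c("isotropic", "full"),
                     base_df = NULL,
                     base_scale_df = NULL, base_scale_matrix = NULL,
                     beta_prior_var = 1e6,
                     psi_prior_df = 2, psi_prior_scale = NULL,
                     alpha_update = c("augmented", "stick")) {
  if (is.character(alpha_prior)) alpha_prior <- bnpgrowth::alpha_prior(alpha_prior)
  stopifnot(length(alpha_prior) == 2L, all(alpha_prior > 0))
  names(alpha_prior) <- c("shape", "rate")
  if (truncation < 2 || truncation != round(truncation)) {
    stop("`truncation` must be an integer >= 2")
  }
  stopifnot(beta_prior_var > 0, psi_prior_df > 0)
  structure(
    list(truncation = as.integer(truncation), alpha_prior = alpha_prior,
         base_structure = match.arg(base_structure),
         base_df = base_df, base_scale_df = base_scale_df,
         base_scale_matrix = base_scale_matrix,
         beta_prior_var = beta_prior_var,
         psi_prior_df = psi_prior_df, psi_prior_scale = psi_prior_scale,
         alpha_update = match.arg(alpha_update)),
    class = "dpm_spec"
  )
}

#' @export
print.dpm_spec <- function(x, ...) {
  cat("DPM specification: truncation", x$truncation,
      sprintf("| %s base | alpha ~ Gamma(%g, %g) [%s update]\n",
              x$base_structure,
              x$alpha_prior["shape"], x$alpha_prior["rate"],
              x$alpha_update))
  invisible(x)
}

# Resolve the T-dependent defaults of a dpm_spec against a panel.
resolve_spec <- function(spec, t_occ) {
  if (spec$base_structure == "isotropic") {
    spec$base_df <- spec$base_df %||% 4
    if (spec$base_df <= 0) stop("`base_df` must be positive")
    spec$base_scale_df <- spec$base_scale_df %||% 2
    spec$base_scale_matrix <- spec$base_scale_matrix %||% 1
    if (length(spec$base_scale_matrix) != 1L) {
      stop("isotropic base scale must be a scalar")
    }
    spec$base_scale_matrix <- matrix(spec$base_scale_matrix, 1, 1)
  } else {
    spec$base_df <- spec$base_df %||% (t_occ + 2)
    if (spec$base_df <= t_occ - 1) {
      stop("`base_df` must exceed T - 1 for a proper base measure")
    }
    spec$base_scale_df <- spec$base_scale_df %||% (t_occ + 2)
    spec$base_scale_matrix <- spec$base_scale_matrix %||%
      diag(t_occ) / spec$base_scale_df
  }
  spec$psi_prior_scale <- spec$psi_prior_scale %||% diag(2)
  spec
}

monitored_names <- c("beta_L", "beta_S", "sigma2_L", "sigma2_S",
                     "sigma_LS", "sigma2_e", "alpha", "K")

#' Deterministic chain initialization
#'
#' Subject effects start at their per-subject least-squares fits, the
#' fixed effects at the mean of those fits, the random-effect covariance
#' at their sample covariance, all subjects in mixture component one with
#' every component covariance at the pooled residual covariance, the base
#' scale at the identity, and alpha at its prior mean.
#'
#' @param panel a [growth_panel()].
#' @param spec a [dpm_spec()].
#' @param design a [growth_design()] with two factors.
#' @return list with the full initial chain state.
#' @export
init_chain <- function(panel, spec = dpm_spec(),
                       design = linear_design(ncol(panel$outcomes))) {
  stopifnot(inherits(panel, "growth_panel"))
  y <- panel$outcomes
  t_occ <- ncol(y)
  if (t_occ < 2) stop("at least two occasions are needed (slope unidentifiable)")
  if (design$n_factors != 2L) {
    stop("fitting currently supports the two-factor (intercept + slope) design")
  }
  spec <- resolve_spec(spec, t_occ)
  lam <- design$loadings
  proj <- lam %*% solve(crossprod(lam))        # T x 2 least-squares map
  b0 <- y %*% proj                              # N x 2 per-subject fits
  beta0 <- if (nrow(y) > 0) colMeans(b0) else c(0, 0)
  psi0 <- if (nrow(y) > 2) stats::cov(b0) else diag(2)
  if (!all(is.finite(psi0)) ||
      min(eigen(psi0, symmetric = TRUE, only.values = TRUE)$values) < 1e-8) {
    psi0 <- psi0 + diag(1e-4, 2)
  }
  resid <- y - b0 %*% t(lam)
  s2 <- if (nrow(y) > 0) mean(resid^2) + 1e-4 else 1
  iso <- spec$base_structure == "isotropic"
  list(beta = beta0, b = b0, psi = psi0,
       phi = if (iso) array(0, c(1, 1, 1)) else
         array(crossprod(resid) / max(nrow(y), 1) + diag(1e-4, t_occ),
               c(t_occ, t_occ, spec$truncation)),
       phis = if (iso) rep(s2, spec$truncation) else numeric(0),
       w0 = if (iso) matrix(1, 1, 1) else diag(t_occ),
       allocations = rep(1L, nrow(y)),
       alpha = unname(spec$alpha_prior["shape"] / spec$alpha_prior["rate"]),
       spec = spec)
}

#' Fit a Bayesian non-parametric growth curve model
#'
#' Runs a blocked Gibbs sampler for the linear growth curve model whose
#' measurement errors follow a Dirichlet process mixture of zero-mean
#' multivariate normals, represented by a truncated stick-breaking
#' construction.  Monitored per iteration: the fixed effects, the three
#' random-effect (co)variances, the derived marginal error variance (the
#' occasion-averaged diagonal of the stick-weighted mixture covariance),
#' the precision parameter alpha, and the occupied-cluster count K.
#'
#' @param panel a [growth_panel()] (or an N x T numeric matrix).
#' @param spec a [dpm_spec()].
#' @param n_iter total chain length (default 50,000).
#' @param burn_in discarded initial iterations (default half the chain).
#' @param seed optional integer seed; fixing it makes the fit bit-for-bit
#'   reproducible.
#' @param design a [growth_design()]; defaults to the linear design for
#'   the panel's occasion count.
#' @param thin keep every `thin`-th post-burn-in draw (default 1, no
#'   thinning).
#' @return object of class `bnp_gcm` with elements `draws` (matrix of
#'   stored iterations by monitored quantity), `spec`, `n_iter`,
#'   `burn_in`, `seed`, `runtime` (seconds) and `final` (last state).
#' @examples
#' \donttest{
#' panel <- simulate_panel(50, seed = 1)
#' fit <- bnp_gcm(panel, n_iter = 2000, burn_in = 1000, seed = 1)
#' coef(fit)
#' }
#' @export
bnp_gcm <- function(panel, spec = dpm_spec(), n_iter = 50000L,
                    burn_in = n_iter %/% 2L, seed = NULL,
                    design = NULL, thin = 1L) {
  if (is.matrix(panel)) panel <- growth_panel(panel)
  stopifnot(inherits(panel, "growth_panel"), inherits(spec, "dpm_spec"))
  if (burn_in >= n_iter || burn_in < 0) {
    stop("`burn_in` must be nonnegative and below `n_iter`")
  }
  design <- design %||% linear_design(ncol(panel$outcomes))
  if (!is.null(seed)) set.seed(seed)
  state <- init_chain(panel, spec, design)
  rspec <- state$spec
  t0 <- proc.time()[["elapsed"]]
  res <- gibbs_bnp_gcm_cpp(
    panel$outcomes, design$loadings,
    state$beta, state$b, state$psi, state$phi, state$phis, state$w0,
    as.integer(state$allocations) - 1L, state$alpha,
    rspec$alpha_prior[["shape"]], rspec$alpha_prior[["rate"]],
    rspec$base_df, rspec$base_scale_df, rspec$base_scale_matrix,
    rspec$beta_prior_var, rspec$psi_prior_df, rspec$psi_prior_scale,
    as.integer(n_iter), as.integer(burn_in),
    if (rspec$alpha_update == "augmented") 1L else 0L,
    rspec$base_structure == "isotropic", rspec$truncation,
    as.integer(thin)
  )
  runtime <- proc.time()[["elapsed"]] - t0
  draws <- res$draws
  colnames(draws) <- monitored_names
  structure(
    list(draws = draws, spec = rspec, n_iter = as.integer(n_iter),
         burn_in = as.integer(burn_in), thin = as.integer(thin),
         seed = seed, runtime = runtime, n_jitter = res$n_jitter,
         final = res$final, design = design,
         n = nrow(panel$outcomes), call = match.call()),
    class = "bnp_gcm"
  )
}

#' Simulate from the model's own prior predictive distribution
#'
#' Draws every parameter from its prior (fixed effects, random-effect
#' covariance, precision parameter, sticks, base scale, component
#' covariances, allocations) and then a panel from the implied truncated
#' DPM growth model.  The generating process matches the fitted model
#' exactly, which is what simulation-based calibration of the sampler
#' requires.
#'
#' @param n number of subjects.
#' @param spec a [dpm_spec()].
#' @param design a [growth_design()] with two factors.
#' @param seed optional integer seed.
#' @return list with `panel` (a [growth_panel()]) and `truth` (named
#'   vector of the drawn monitored parameters).
#' @export
simulate_dpm_prior <- function(n, spec = dpm_spec(),
                               design = linear_design(4), seed = NULL) {
  stopifnot(n >= 1, design$n_factors == 2L)
  if (!is.null(seed)) set.seed(seed)
  t_occ <- design$n_occasions
  spec <- resolve_spec(spec, t_occ)
  C <- spec$truncation
  beta <- stats::rnorm(2, 0, sqrt(spec$beta_prior_var))
  psi <- solve(stats::rWishart(1, spec$psi_prior_df,
                               solve(spec$psi_prior_scale))[, , 1])
  a <- stats::rgamma(1, spec$alpha_prior[["shape"]],
                     rate = spec$alpha_prior[["rate"]])
  q <- c(stats::rbeta(C - 1, 1, a), 1)
  p <- stick_break(pmin(pmax(q, 1e-12), 1))$normalized
  if (spec$base_structure == "isotropic") {
    w0 <- stats::rgamma(1, spec$base_scale_df / 2,
                        rate = 1 / (2 * spec$base_scale_matrix[1, 1]))
    phi <- lapply(1 / stats::rgamma(C, spec$base_df / 2, rate = w0 / 2),
                  function(v) diag(v, t_occ))
  } else {
    w0 <- stats::rWishart(1, spec$base_scale_df, spec$base_scale_matrix)[, , 1]
    phi <- lapply(seq_len(C), function(j) {
      solve(stats::rWishart(1, spec$base_df, solve(w0))[, , 1])
    })
  }
  z <- sample.int(C, n, replace = TRUE, prob = p)
  b <- matrix(rep(beta, each = n), n, 2) +
    matrix(stats::rnorm(2 * n), n, 2) %*% chol(psi)
  e <- t(vapply(seq_len(n), function(i) {
    drop(crossprod(chol(phi[[z[i]]]), stats::rnorm(t_occ)))
  }, numeric(t_occ)))
  y <- b %*% t(design$loadings) + e
  s2e <- sum(p * vapply(phi, function(m) mean(diag(m)), numeric(1)))
  truth <- c(beta_L = beta[1], beta_S = beta[2],
             sigma2_L = psi[1, 1], sigma2_S = psi[2, 2],
             sigma_LS = psi[1, 2], sigma2_e = s2e, alpha = a,
             K = length(unique(z)))
  list(panel = growth_panel(y, occasions = design$loadings[, 2],
                            effects = b, seed = seed),
       truth = truth)
}

#' @export
print.bnp_gcm <- function(x, ...) {
  cat("Bayesian non-parametric growth curve model fit\n")
  cat(sprintf("  %d subjects, %d occasions | truncation %d | alpha ~ Gamma(%g, %g)\n",
              x$n, x$design$n_occasions, x$spec$truncation,
              x$spec$alpha_prior["shape"], x$spec$alpha_prior["rate"]))
  cat(sprintf("  %d iterations (%d burn-in), %d stored draws, %.1f s\n",
              x$n_iter, x$burn_in, nrow(x$draws), x$runtime))
  cat("Posterior means:\n")
  print(round(coef(x), 4))
  invisible(x)
}

#' @export
coef.bnp_gcm <- function(object, ...) colMeans(object$draws)

#' Posterior summary of a fitted BNP growth curve model
#'
#' @param object a [bnp_gcm()] fit.
#' @param mass HPD interval mass (default 0.95).
#' @param ... unused.
#' @return data frame with posterior mean, SD, HPD bounds, Geweke z and
#'   its convergence verdict for every monitored quantity.
#' @export
summary.bnp_gcm <- function(object, mass = 0.95, ...) {
  draws <- object$draws
  rows <- lapply(colnames(draws), function(nm) {
    x <- draws[, nm]
    hpd <- hpd_interval(x, mass)
    gz <- tryCatch(geweke_z(x)$z, error = function(e) NA_real_)
    data.frame(parameter = nm, mean = mean(x), sd = stats::sd(x),
               hpd_lower = hpd$lower, hpd_upper = hpd$upper,
               geweke_z = gz,
               converged = is.na(gz) || abs(gz) < 1.96)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("summary.bnp_gcm", "data.frame")
  out
}

#' @export
print.summary.bnp_gcm <- function(x, digits = 4, ...) {
  y <- x
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], round, digits)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' Trace plots for a fitted model
#'
#' @param x a [bnp_gcm()] fit.
#' @param parameters monitored quantities to plot.
#' @param ... passed to [graphics::plot()].
#' @export
plot.bnp_gcm <- function(x, parameters = colnames(x$draws), ...) {
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(parameters)),
                       mar = c(3, 4, 2, 1))
  on.exit(graphics::par(old))
  for (nm in parameters) {
    graphics::plot(x$draws[, nm], type = "l", xlab = "", ylab = nm,
                   main = nm, ...)
  }
  invisible(x)
}

#' Posterior mean growth trajectory
#'
#' @param object a [bnp_gcm()] fit.
#' @param occasions occasion codes at which to evaluate the mean curve.
#' @param ... unused.
#' @return named numeric vector of posterior mean outcomes per occasion.
#' @export
predict.bnp_gcm <- function(object,
                            occasions = object$design$loadings[, 2], ...) {
  cf <- coef(object)
  stats::setNames(cf["beta_L"] + cf["beta_S"] * occasions,
                  paste0("occ", occasions))
}

#' Save and reload stored draws as CSV
#'
#' One row per stored iteration, one column per monitored quantity.
#'
#' @param fit a [bnp_gcm()] fit.
#' @param path CSV file path.
#' @export
write_draws <- function(fit, path) {
  utils::write.csv(as.data.frame(fit$draws), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_draws
#' @export
read_draws <- function(path) {
  as.matrix(utils::read.csv(path, check.names = FALSE))
}
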