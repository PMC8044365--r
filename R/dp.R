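#' Posterior base-measure mixing weights of a Dirichlet process
#'
#' Given data of size N, the posterior of a DP(alpha, G0) is again a
#' Dirichlet process whose base measure is the mixture
#' alpha/(alpha + N) G0 + N/(alpha + N) G_N, where G_N is the empirical
#' distribution.  This returns the two mixing weights: as alpha -> 0 the
#' posterior mean collapses onto the empirical distribution, as
#' alpha -> Inf onto the prior base measure.
#'
#' @param alpha positive precision (concentration) parameter.
#' @param n sample size (positive integer).
#' @return named numeric vector `c(base = , empirical = )` summing to one.
#' @export
dp_posterior_weights <- function(alpha, n) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0,
            is.numeric(n), length(n) == 1L, n >= 1)
  c(base = alpha / (alpha + n), empirical = n / (alpha + n))
}

#' Truncated stick-breaking weights
#'
#' Turns raw stick fractions q_j in (0, 1] into mixture weights.  The
#' unnormalized weights are p'_j = q_j prod_{k < j} (1 - q_k); the final
#' weights renormalize these to sum to one.
#'
#' @param raw_sticks numeric vector of stick fractions, each in (0, 1].
#' @return object of class `stick_weights` with elements `raw`,
#'   `unnormalized`, `normalized` and `truncation`.
#' @examples
#' stick_break(c(0.5, 0.5, 0.5))$normalized  # 4/7, 2/7, 1/7
#' @export
stick_break <- function(raw_sticks) {
  if (!is.numeric(raw_sticks) || length(raw_sticks) < 1L ||
      anyNA(raw_sticks) || any(raw_sticks <= 0) || any(raw_sticks > 1)) {
    stop("all stick fractions must lie in (0, 1]")
  }
  remain <- cumprod(1 - raw_sticks)
  unnorm <- raw_sticks * c(1, remain[-length(raw_sticks)])
  structure(
    list(
      raw = raw_sticks,
      unnormalized = unnorm,
      normalized = unnorm / sum(unnorm),
      truncation = length(raw_sticks)
    ),
    class = "stick_weights"
  )
}

#' @export
print.stick_weights <- function(x, ...) {
  cat("Stick-breaking weights (truncation ", x$truncation, "):\n", sep = "")
  print(x$normalized)
  invisible(x)
}

euler_gamma <- 0.577215664901532860606512090082

cluster_rate <- function(alpha, n) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0,
            is.numeric(n), length(n) == 1L, n >= 1)
  alpha * (euler_gamma + log(n))
}

#' Asymptotic distribution of the number of occupied clusters
#'
#' In a Dirichlet process mixture with precision alpha and sample size N,
#' the number of occupied clusters K is asymptotically 1 + x with
#' x ~ Poisson(alpha * (gamma + log N)), gamma the Euler-Mascheroni
#' constant.  `cluster_count_pmf` evaluates P(K = k);
#' `cluster_count_quantile` returns the discrete quantile (smallest k whose
#' CDF reaches `prob`).
#'
#' @param alpha positive precision parameter.
#' @param n sample size.
#' @param k cluster count (integer >= 1); vectorized.
#' @param prob probability in (0, 1).
#' @return `cluster_count_pmf`: probabilities; `cluster_count_quantile`:
#'   an integer cluster count.
#' @examples
#' cluster_count_quantile(1, 200, 0.5)   # median K = 7
#' cluster_count_pmf(0.1, 200, 1)
#' @export
cluster_count_pmf <- function(alpha, n, k) {
  if (any(k < 1) || any(k != round(k))) {
    stop("`k` must contain integers >= 1")
  }
  stats::dpois(k - 1, cluster_rate(alpha, n))
}

#' @rdname cluster_count_pmf
#' @export
cluster_count_quantile <- function(alpha, n, prob) {
  if (!is.numeric(prob) || length(prob) != 1L || prob <= 0 || prob >= 1) {
    stop("`prob` must lie strictly in (0, 1)")
  }
  as.integer(1L + stats::qpois(prob, cluster_rate(alpha, n)))
}

#' Quantile table of the occupied-cluster distribution
#'
#' Tabulates [cluster_count_quantile()] over a grid of precision values,
#' sample sizes and percentiles.
#'
#' @param alpha vector of precision values.
#' @param n vector of sample sizes.
#' @param probs vector of probabilities.
#' @return data frame with columns `n`, `alpha`, `prob`, `k`.
#' @export
cluster_count_table <- function(alpha = c(0.1, 1, 2),
                                n = c(200, 600, 1000),
                                probs = c(0.05, 0.50, 0.95)) {
  grid <- expand.grid(prob = probs, alpha = alpha, n = n,
                      KEEP.OUT.ATTRS = FALSE)
  grid$k <- mapply(cluster_count_quantile, grid$alpha, grid$n, grid$prob)
  grid[, c("n", "alpha", "prob", "k")]
}

#' Exact conditional posterior of the DP precision parameter
#'
#' With a Gamma(a1, a2) prior on alpha, K occupied clusters among N
#' subjects, and the augmented variable x ~ Beta(alpha + 1, N), the
#' conditional posterior of alpha is the two-component gamma mixture
#' pi_x Gamma(a1 + K, a2 - log x) + (1 - pi_x) Gamma(a1 + K - 1,
#' a2 - log x), with odds pi_x / (1 - pi_x) = (a1 + K - 1) /
#' (N (a2 - log x)).
#'
#' @param shape,rate Gamma prior hyperparameters a1, a2 (both > 0).
#' @param n_clusters number of occupied clusters K (>= 1).
#' @param n sample size N.
#' @param x augmented beta variable in (0, 1).
#' @return object of class `alpha_mixture` with the mixture weight, the
#'   two gamma components, and a `density` function of alpha.
#' @export
alpha_posterior_mixture <- function(shape, rate, n_clusters, n, x) {
  stopifnot(shape > 0, rate > 0, n >= 1)
  if (n_clusters < 1 || n_clusters != round(n_clusters)) {
    stop("`n_clusters` must be an integer >= 1")
  }
  if (x <= 0 || x >= 1) stop("`x` must lie strictly in (0, 1)")
  post_rate <- rate - log(x)
  odds <- (shape + n_clusters - 1) / (n * post_rate)
  w <- odds / (1 + odds)
  obj <- list(
    mixture_weight = w,
    shape1 = shape + n_clusters,
    shape2 = shape + n_clusters - 1,
    rate = post_rate,
    augmented_x = x,
    n_clusters = n_clusters,
    n = n
  )
  obj$density <- function(a) {
    w * stats::dgamma(a, obj$shape1, rate = post_rate) +
      (1 - w) * stats::dgamma(a, obj$shape2, rate = post_rate)
  }
  class(obj) <- "alpha_mixture"
  obj
}

#' @export
print.alpha_mixture <- function(x, ...) {
  cat(sprintf(
    "Two-gamma posterior of alpha | K = %d, N = %d, x = %.4f\n",
    x$n_clusters, x$n, x$augmented_x))
  cat(sprintf("  %.4f * Gamma(%.3f, rate %.4f) + %.4f * Gamma(%.3f, rate %.4f)\n",
              x$mixture_weight, x$shape1, x$rate,
              1 - x$mixture_weight, x$shape2, x$rate))
  invisible(x)
}

#' Augmented-variable sampler for the DP precision parameter
#'
#' Alternates x | alpha ~ Beta(alpha + 1, N) with a draw of alpha from the
#' exact two-gamma mixture of [alpha_posterior_mixture()].  The long-run
#' draws target p(alpha | K, N) proportional to
#' Gamma(alpha; a1, a2) alpha^K Gamma(alpha) / Gamma(alpha + N).
#'
#' @inheritParams alpha_posterior_mixture
#' @param n_sweeps number of alternation sweeps; one alpha draw per sweep.
#' @param init positive starting value for alpha.
#' @return numeric vector of `n_sweeps` alpha draws.
#' @export
sample_alpha_augmented <- function(shape, rate, n_clusters, n,
                                   n_sweeps = 1000L, init = 1) {
  stopifnot(shape > 0, rate > 0, n >= 1, init > 0, n_sweeps >= 1)
  if (n_clusters < 1) stop("`n_clusters` must be >= 1")
  draws <- numeric(n_sweeps)
  a <- init
  for (s in seq_len(n_sweeps)) {
    x <- stats::rbeta(1, a + 1, n)
    post_rate <- rate - log(x)
    odds <- (shape + n_clusters - 1) / (n * post_rate)
    comp1 <- stats::runif(1) < odds / (1 + odds)
    a <- stats::rgamma(1, shape + n_clusters - if (comp1) 0 else 1,
                       rate = post_rate)
    draws[s] <- a
  }
  draws
}

#' Gamma approximation to the precision-parameter posterior
#'
#' The conditional posterior of alpha given K occupied clusters is
#' approximately Gamma(a1 + K - 1, a2 + gamma + log N), gamma the
#' Euler-Mascheroni constant.  The quality of this approximation is not
#' established in general; [alpha_approx_tvd()] measures its total
#' variation distance from the exact posterior.
#'
#' @inheritParams alpha_posterior_mixture
#' @return named vector `c(shape = , rate = )`.
#' @export
alpha_posterior_approx <- function(shape, rate, n_clusters, n) {
  stopifnot(shape > 0, rate > 0, n >= 1, n_clusters >= 1)
  if (shape + n_clusters - 1 <= 0) stop("approximate shape must be positive")
  c(shape = shape + n_clusters - 1,
    rate = rate + euler_gamma + log(n))
}

# Unnormalized log target p(alpha | K, N) for the augmented sampler.
alpha_log_target <- function(a, shape, rate, n_clusters, n) {
  (shape + n_clusters - 1) * log(a) - rate * a + lgamma(a) - lgamma(a + n)
}

#' Exact normalized posterior density of alpha on a grid
#'
#' Brute-force normalization of the marginal target of the augmented
#' sampler, p(alpha | K, N), on a supplied grid.  Used as an independent
#' check of the sampler and to score the gamma approximation.
#'
#' @inheritParams alpha_posterior_mixture
#' @param grid increasing positive grid of alpha values.
#' @return data frame with columns `alpha` and `density`.
#' @export
alpha_posterior_grid <- function(shape, rate, n_clusters, n, grid) {
  stopifnot(all(grid > 0), !is.unsorted(grid))
  lt <- alpha_log_target(grid, shape, rate, n_clusters, n)
  d <- exp(lt - max(lt))
  z <- sum((d[-1] + d[-length(d)]) / 2 * diff(grid))
  data.frame(alpha = grid, density = d / z)
}

#' @rdname alpha_posterior_approx
#' @param grid grid of alpha values used for the numerical comparison.
#' @return `alpha_approx_tvd`: the total variation distance in \[0, 1\]
#'   between the gamma approximation and the exact posterior.
#' @export
alpha_approx_tvd <- function(shape, rate, n_clusters, n,
                             grid = seq(1e-6, 60, length.out = 60000L)) {
  exact <- alpha_posterior_grid(shape, rate, n_clusters, n, grid)
  ap <- alpha_posterior_approx(shape, rate, n_clusters, n)
  dap <- stats::dgamma(grid, ap["shape"], rate = ap["rate"])
  diffs <- abs(exact$density - dap)
  sum((diffs[-1] + diffs[-length(diffs)]) / 2 * diff(grid)) / 2
}
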