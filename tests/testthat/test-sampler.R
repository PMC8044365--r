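test_that("initialization is deterministic least squares", {
  noiseless <- simulate_panel(12, psi = matrix(0, 2, 2), sigma2_e = 0,
                              seed = 1)
  st <- init_chain(noiseless, dpm_spec(truncation = 5))
  expect_equal(st$beta, c(6.2, 0.3), tolerance = 1e-10)
  expect_equal(unique(st$allocations), 1L)
  st2 <- init_chain(noiseless, dpm_spec(truncation = 5))
  expect_identical(st, st2)
  # alpha starts at its prior mean
  expect_equal(init_chain(noiseless, dpm_spec(alpha_prior = c(10, 100)))$alpha,
               0.1)
  one_occ <- growth_panel(matrix(rnorm(6), 6, 1))
  expect_error(init_chain(one_occ, dpm_spec()), "two occasions")
})

test_that("chains are bit-for-bit reproducible under a fixed seed", {
  panel <- simulate_panel(25, seed = 2)
  f1 <- bnp_gcm(panel, dpm_spec(truncation = 8), n_iter = 600,
                burn_in = 200, seed = 33)
  f2 <- bnp_gcm(panel, dpm_spec(truncation = 8), n_iter = 600,
                burn_in = 200, seed = 33)
  expect_identical(f1$draws, f2$draws)
  f3 <- bnp_gcm(panel, dpm_spec(truncation = 8), n_iter = 600,
                burn_in = 200, seed = 34)
  expect_false(identical(f1$draws, f3$draws))
})

test_that("monitored draws are finite and respect the truncation bound", {
  panel <- simulate_panel(40, seed = 3)
  for (structure in c("isotropic", "full")) {
    fit <- bnp_gcm(panel, dpm_spec(truncation = 12,
                                   base_structure = structure),
                   n_iter = 700, burn_in = 300, seed = 4)
    expect_false(any(!is.finite(fit$draws)))
    expect_true(all(fit$draws[, "K"] >= 1 & fit$draws[, "K"] <= 12))
    expect_true(all(fit$draws[, "alpha"] > 0))
    expect_true(all(fit$draws[, "sigma2_e"] > 0))
    expect_true(all(fit$draws[, "sigma2_L"] > 0))
    # the random-effect covariance stays positive definite
    expect_true(all(fit$draws[, "sigma2_L"] * fit$draws[, "sigma2_S"] >
                      fit$draws[, "sigma_LS"]^2))
  }
})

test_that("subject-effect conditional matches a brute-force grid posterior", {
  # one subject, isotropic error phi I: closed-form conditional
  # N(m, V) with V = (Lambda'Lambda/phi + Psi^-1)^-1,
  # m = V (Lambda'y/phi + Psi^-1 beta); check both against a 2-d grid.
  set.seed(5)
  lam <- linear_design(4)$loadings
  phi <- 0.7
  psi <- matrix(c(0.8, 0.1, 0.1, 0.2), 2, 2)
  beta <- c(6, 0.4)
  y <- drop(lam %*% c(6.5, 0.2)) + rnorm(4, sd = sqrt(phi))
  V <- solve(crossprod(lam) / phi + solve(psi))
  m <- drop(V %*% (crossprod(lam, y) / phi + solve(psi) %*% beta))

  gL <- seq(m[1] - 4 * sqrt(V[1, 1]), m[1] + 4 * sqrt(V[1, 1]), length.out = 120)
  gS <- seq(m[2] - 4 * sqrt(V[2, 2]), m[2] + 4 * sqrt(V[2, 2]), length.out = 120)
  grid <- expand.grid(L = gL, S = gS)
  loglik <- apply(grid, 1, function(b) {
    r <- y - drop(lam %*% b)
    u <- b - beta
    -sum(r^2) / (2 * phi) - drop(t(u) %*% solve(psi) %*% u) / 2
  })
  w <- exp(loglik - max(loglik)); w <- w / sum(w)
  expect_equal(sum(w * grid$L), m[1], tolerance = 1e-3)
  expect_equal(sum(w * grid$S), m[2], tolerance = 1e-3)
  expect_equal(sum(w * (grid$L - m[1])^2), V[1, 1], tolerance = 1e-2)
  expect_equal(sum(w * (grid$L - m[1]) * (grid$S - m[2])), V[1, 2],
               tolerance = 1e-2)
})

test_that("stick-conjugate alpha conditional matches a 1-d grid posterior", {
  # q_1..q_{C-1} ~ Beta(1, alpha), alpha ~ Gamma(a1, a2):
  # alpha | q ~ Gamma(a1 + C - 1, a2 - sum log(1 - q_j))
  set.seed(6)
  a1 <- 2; a2 <- 2; C <- 12
  q <- rbeta(C - 1, 1, 0.8)
  grid <- seq(1e-4, 15, length.out = 6000)
  logpost <- (a1 - 1) * log(grid) - a2 * grid +
    vapply(grid, function(a) sum(dbeta(q, 1, a, log = TRUE)), numeric(1))
  w <- exp(logpost - max(logpost)); w <- w / sum(w)
  shape <- a1 + C - 1
  rate <- a2 - sum(log1p(-q))
  expect_equal(sum(w * grid), shape / rate, tolerance = 1e-3)
  expect_equal(sum(w * grid^2) - sum(w * grid)^2, shape / rate^2,
               tolerance = 1e-3)
})

test_that("isotropic base-scale conditional matches a 1-d grid posterior", {
  # phi_j ~ IG(n0/2, w0/2), w0 ~ Gamma(h1, h2):
  # w0 | {phi_j} ~ Gamma(h1 + C n0 / 2, h2 + sum(1/phi_j)/2)
  set.seed(7)
  n0 <- 4; h1 <- 1; h2 <- 0.5; C <- 6
  phis <- 1 / rgamma(C, n0 / 2, rate = 0.4)
  grid <- seq(1e-4, 30, length.out = 8000)
  logpost <- (h1 - 1) * log(grid) - h2 * grid +
    C * (n0 / 2) * log(grid / 2) - grid * sum(1 / phis) / 2
  w <- exp(logpost - max(logpost)); w <- w / sum(w)
  shape <- h1 + C * n0 / 2
  rate <- h2 + sum(1 / phis) / 2
  expect_equal(sum(w * grid), shape / rate, tolerance = 1e-3)
  expect_equal(sum(w * grid^2) - sum(w * grid)^2, shape / rate^2,
               tolerance = 1e-2)
})

test_that("a no-data chain recovers its priors", {
  empty <- growth_panel(matrix(numeric(0), 0, 4))
  spec <- dpm_spec(truncation = 6, alpha_prior = c(2, 2),
                   beta_prior_var = 4, alpha_update = "stick")
  fit <- bnp_gcm(empty, spec, n_iter = 21000, burn_in = 1000, seed = 8,
                 thin = 5)
  d <- fit$draws
  # beta_L ~ N(0, 4): quantile agreement
  qs <- c(0.1, 0.25, 0.5, 0.75, 0.9)
  expect_equal(unname(quantile(d[, "beta_L"], qs)),
               qnorm(qs, 0, 2), tolerance = 0.12)
  # alpha ~ Gamma(2, 2)
  expect_equal(unname(quantile(d[, "alpha"], qs)),
               qgamma(qs, 2, 2), tolerance = 0.12)
  # sigma2_L marginal of IW(2, I): 1/sigma2_L ~ Gamma(1/2, rate 1/2)
  expect_equal(unname(quantile(1 / d[, "sigma2_L"], qs)),
               qgamma(qs, 0.5, 0.5), tolerance = 0.12)
  # all components empty: K = 0 clusters occupied
  expect_true(all(d[, "K"] == 0))
})

test_that("simulation-based calibration ranks are uniform (exact Gibbs)", {
  set.seed(42)
  spec <- dpm_spec(truncation = 8, alpha_prior = "weak",
                   beta_prior_var = 25, alpha_update = "stick")
  R <- 500; L <- 24
  pars <- c("beta_L", "beta_S", "sigma2_L")
  ranks <- matrix(NA_real_, R, length(pars), dimnames = list(NULL, pars))
  for (r in seq_len(R)) {
    sim <- simulate_dpm_prior(25, spec, seed = 1000 + r)
    fit <- bnp_gcm(sim$panel, spec, n_iter = 900, burn_in = 420, thin = 20)
    for (nm in pars) {
      ranks[r, nm] <- sum(fit$draws[, nm] < sim$truth[nm])
    }
  }
  for (nm in pars) {
    tb <- tabulate(ranks[, nm] + 1, nbins = L + 1)
    p <- suppressWarnings(
      chisq.test(tb, p = rep(1 / (L + 1), L + 1))$p.value)
    expect_gt(p, 0.001)
  }
})

test_that("prior-predictive simulation honours both base structures", {
  for (structure in c("isotropic", "full")) {
    spec <- dpm_spec(truncation = 5, base_structure = structure,
                     beta_prior_var = 9)
    sim <- simulate_dpm_prior(15, spec, seed = 11)
    expect_equal(dim(sim$panel$outcomes), c(15, 4))
    expect_true(all(is.finite(sim$truth)))
    expect_gte(sim$truth["sigma2_e"], 0)
  }
})

test_that("derived error variance is the weighted mixture scale", {
  # single-cluster normal data: derived sigma2_e approaches the residual
  # variance; two-component linearity is covered by the weighted form
  panel <- simulate_panel(150, seed = 12)
  fit <- bnp_gcm(panel, dpm_spec(truncation = 10), n_iter = 2500,
                 burn_in = 1000, seed = 13)
  expect_lt(abs(mean(fit$draws[, "sigma2_e"]) - 0.5), 0.12)
})
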