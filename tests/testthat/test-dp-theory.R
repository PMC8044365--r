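test_that("posterior base-measure weights interpolate prior and data", {
  w <- dp_posterior_weights(1e-12, 100)
  expect_equal(unname(w), c(0, 1), tolerance = 1e-10)
  expect_equal(unname(dp_posterior_weights(100, 100)), c(0.5, 0.5))
  w <- dp_posterior_weights(1e9, 100)
  expect_equal(unname(w), c(1, 0), tolerance = 1e-6)
  expect_equal(sum(dp_posterior_weights(3.7, 42)), 1)
})

test_that("stick-breaking weights follow the displayed construction", {
  expect_equal(stick_break(0.5)$normalized, 1)
  expect_equal(stick_break(c(1, 0.3, 0.7))$normalized, c(1, 0, 0))
  sw <- stick_break(c(0.5, 0.5, 0.5))
  expect_equal(sw$unnormalized, c(0.5, 0.25, 0.125))
  expect_equal(sw$normalized, c(4, 2, 1) / 7)
  expect_error(stick_break(c(0.5, 0)), "\\(0, 1]")
  expect_error(stick_break(c(0.5, 1.2)), "\\(0, 1]")
})

test_that("stick weights always normalize and ignore sticks after a 1", {
  set.seed(5)
  for (rep in 1:50) {
    q <- runif(sample(1:30, 1), min = 1e-6)
    expect_lt(abs(sum(stick_break(q)$normalized) - 1), 1e-12)
  }
  # once a stick equals 1, trailing sticks cannot matter
  q1 <- c(0.2, 1, 0.9, 0.1)
  q2 <- c(0.2, 1, 0.3, 0.8)
  expect_equal(stick_break(q1)$normalized, stick_break(q2)$normalized)
})

# Quantiles of the occupied-cluster count over the published grid.
table1_expected <- rbind(
  c(200,  0.1, 1, 1, 3),  c(200,  1, 3, 7, 11),  c(200,  2, 7, 13, 19),
  c(600,  0.1, 1, 2, 3),  c(600,  1, 4, 8, 13),  c(600,  2, 9, 15, 21),
  c(1000, 0.1, 1, 2, 3),  c(1000, 1, 4, 8, 13),  c(1000, 2, 10, 16, 23))

test_that("cluster-count quantiles reproduce the reference grid exactly", {
  for (r in seq_len(nrow(table1_expected))) {
    n <- table1_expected[r, 1]; a <- table1_expected[r, 2]
    expect_identical(cluster_count_quantile(a, n, 0.05),
                     as.integer(table1_expected[r, 3]))
    expect_identical(cluster_count_quantile(a, n, 0.50),
                     as.integer(table1_expected[r, 4]))
    expect_identical(cluster_count_quantile(a, n, 0.95),
                     as.integer(table1_expected[r, 5]))
  }
  tab <- cluster_count_table()
  expect_equal(nrow(tab), 27)
  expect_equal(tab$k[tab$n == 200 & tab$alpha == 1 & tab$prob == 0.5], 7)
})

test_that("cluster-count quantile is nondecreasing in alpha, n and prob", {
  for (a in c(0.1, 0.5, 1, 2)) {
    ks <- vapply(c(100, 300, 900), function(n)
      cluster_count_quantile(a, n, 0.5), integer(1))
    expect_true(all(diff(ks) >= 0))
  }
  ks <- vapply(c(0.05, 0.25, 0.5, 0.75, 0.95), function(p)
    cluster_count_quantile(1, 200, p), integer(1))
  expect_true(all(diff(ks) >= 0))
  ks <- vapply(c(0.1, 0.5, 1, 2, 5), function(a)
    cluster_count_quantile(a, 200, 0.5), integer(1))
  expect_true(all(diff(ks) >= 0))
  expect_identical(cluster_count_quantile(1e-9, 200, 0.95), 1L)
})

test_that("cluster-count pmf is a shifted Poisson law", {
  g <- 0.577215664901532860606512090082
  expect_equal(cluster_count_pmf(0.1, 200, 1),
               exp(-0.1 * (g + log(200))))
  expect_lt(abs(sum(cluster_count_pmf(2, 1000, 1:500)) - 1), 1e-10)
  expect_error(cluster_count_pmf(1, 200, 0), "integers >= 1")

  # simulation oracle: empirical frequencies match the pmf
  set.seed(7)
  draws <- 1 + rpois(1e5, 1 * (g + log(200)))
  for (k in c(2, 5, 7, 9, 12)) {
    p <- cluster_count_pmf(1, 200, k)
    se <- sqrt(p * (1 - p) / 1e5)
    expect_lt(abs(mean(draws == k) - p), 4 * se)
  }
})

test_that("precision-parameter mixture posterior matches hand substitution", {
  post <- alpha_posterior_mixture(2, 2, 4, 200, 0.9)
  odds <- 5 / (200 * (2 - log(0.9)))
  expect_equal(post$mixture_weight, odds / (1 + odds))
  expect_equal(post$shape1, 6)
  expect_equal(post$shape2, 5)
  expect_equal(post$rate, 2 - log(0.9))

  # shape-parameter collapse at a1 = 1, K = 1
  post1 <- alpha_posterior_mixture(1, 2, 1, 200, 0.5)
  expect_equal(post1$mixture_weight / (1 - post1$mixture_weight),
               1 / (200 * (2 - log(0.5))))

  # the mixture density integrates to one
  igr <- integrate(post$density, 0, Inf, rel.tol = 1e-10)
  expect_lt(abs(igr$value - 1), 1e-8)
})

test_that("gamma approximation of the alpha posterior is as displayed", {
  ap <- alpha_posterior_approx(2, 2, 4, 200)
  expect_equal(unname(ap["shape"]), 5)
  expect_equal(unname(ap["rate"]), 2 + 0.5772156649015329 + log(200),
               tolerance = 1e-10)
  expect_equal(unname(alpha_posterior_approx(3, 2, 1, 50)["shape"]), 3)
  # quality is measured, not assumed: distance is a number in [0, 1]
  tvd <- alpha_approx_tvd(2, 2, 4, 200,
                          grid = seq(1e-6, 30, length.out = 20000))
  expect_gte(tvd, 0)
  expect_lte(tvd, 1)
})

test_that("augmented alpha sampler targets the brute-force grid posterior", {
  set.seed(31)
  draws <- sample_alpha_augmented(2, 2, 4, 200, n_sweeps = 2e4)
  expect_true(all(draws > 0))
  grid <- seq(1e-4, 12, length.out = 8000)
  dens <- alpha_posterior_grid(2, 2, 4, 200, grid)
  cdf <- cumsum(dens$density) * (grid[2] - grid[1])
  cdf <- cdf / max(cdf)
  emp <- ecdf(draws)(grid)
  expect_lt(max(abs(emp - cdf)), 0.02)

  # prior dominance: tight Gamma(100, 100) prior pins alpha near 1
  set.seed(32)
  d2 <- sample_alpha_augmented(100, 100, 3, 200, n_sweeps = 2e4)
  expect_lt(abs(mean(d2) - 1), 0.05)
})
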