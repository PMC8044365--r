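mk_hpd <- function(lo, hi) structure(list(lower = lo, upper = hi, mass = 0.95),
                                     class = "hpd_interval")

test_that("estimate summaries reproduce hand arithmetic", {
  row <- summarize_estimates(c(1, 2, 3), c(0.1, 0.1, 0.1),
                             list(mk_hpd(0, 4), mk_hpd(1, 3), mk_hpd(2.5, 3.5)),
                             truth = 2)
  expect_equal(row$est, 2)
  expect_equal(row$bias, 0)
  expect_equal(row$ase, 0.1)
  expect_equal(row$ese, 1)
  expect_equal(row$mse, 2 / 3)
  expect_equal(row$cp, 2 / 3)

  perfect <- summarize_estimates(rep(2, 4), rep(0.1, 4),
                                 replicate(4, mk_hpd(1.9, 2.1),
                                           simplify = FALSE), truth = 2)
  expect_equal(perfect$bias, 0)
  expect_equal(perfect$mse, 0)
  expect_equal(perfect$cp, 1)
  expect_error(summarize_estimates(1, 0.1, list(mk_hpd(0, 2)), 1),
               "at least two")
})

test_that("MSE identity mse = bias^2 + ese^2 (R-1)/R holds on fixtures", {
  set.seed(14)
  for (rep in 1:20) {
    R <- sample(3:40, 1)
    est <- rnorm(R, 2, 0.5)
    row <- summarize_estimates(est, runif(R, 0.05, 0.2),
                               replicate(R, mk_hpd(-10, 10),
                                         simplify = FALSE), truth = 2)
    expect_equal(row$mse, row$bias^2 + row$ese^2 * (R - 1) / R,
                 tolerance = 1e-12)
  }
})

test_that("undefined truths propagate as absent bias/MSE/CP", {
  row <- summarize_estimates(c(1, 2), c(0.1, 0.2),
                             list(mk_hpd(0, 3), mk_hpd(0, 3)),
                             truth = NA_real_)
  expect_true(is.na(row$bias) && is.na(row$mse) && is.na(row$cp))
  expect_equal(row$est, 1.5)
  expect_equal(row$ase, 0.15)
})

test_that("condition aggregation uses converged replications only", {
  cond <- study_condition(10, 0, "weak", n_replications = 4,
                          n_iter = 200, burn_in = 100, base_seed = 1)
  # fixture replications with known constants; replication 4 not converged
  reps <- lapply(1:4, function(r) {
    list(means = setNames(rep(r, 8), bnpgrowth:::monitored_names),
         sds = setNames(rep(0.1, 8), bnpgrowth:::monitored_names),
         hpd = replicate(8, mk_hpd(-100, 100), simplify = FALSE),
         converged = r < 4, runtime = 1)
  })
  keep <- vapply(reps, function(x) x$converged, logical(1))
  s <- bnpgrowth:::summarize_condition(reps[keep], cond,
                                       convergence_rate = mean(keep))
  expect_equal(attr(s, "convergence_rate"), 0.75)
  expect_equal(attr(s, "n_converged"), 3)
  # Est averages the three converged constants only
  expect_equal(s$est[s$parameter == "beta_L"], 2)
  expect_equal(s$bias[s$parameter == "beta_L"], 2 - 6.2)
})

test_that("outlier conditions blank the error-variance truth (dash pattern)", {
  cond <- study_condition(10, 0.2, "weak", n_replications = 3,
                          n_iter = 200, burn_in = 100)
  reps <- lapply(1:3, function(r) {
    list(means = setNames(rep(1, 8), bnpgrowth:::monitored_names),
         sds = setNames(rep(0.1, 8), bnpgrowth:::monitored_names),
         hpd = replicate(8, mk_hpd(0, 2), simplify = FALSE),
         converged = TRUE, runtime = 1)
  })
  s <- bnpgrowth:::summarize_condition(reps, cond, convergence_rate = 1)
  for (nm in c("sigma2_e", "alpha", "K")) {
    expect_true(is.na(s$bias[s$parameter == nm]))
    expect_true(is.na(s$mse[s$parameter == nm]))
    expect_true(is.na(s$cp[s$parameter == nm]))
  }
  # growth parameters keep their truths under contamination
  expect_false(is.na(s$bias[s$parameter == "beta_L"]))
  # clean-data conditions do define the error-variance truth
  cond0 <- study_condition(10, 0, "weak", n_replications = 3,
                           n_iter = 200, burn_in = 100)
  s0 <- bnpgrowth:::summarize_condition(reps, cond0, convergence_rate = 1)
  expect_false(is.na(s0$bias[s0$parameter == "sigma2_e"]))
})

test_that("a full study grid runs end to end at toy scale", {
  conds <- list(
    study_condition(25, 0, "weak", n_replications = 2,
                    n_iter = 400, burn_in = 200, base_seed = 41,
                    spec = dpm_spec(truncation = 8)),
    study_condition(25, 0.2, "inaccurate", n_replications = 2,
                    n_iter = 400, burn_in = 200, base_seed = 42,
                    spec = dpm_spec(truncation = 8)))
  study <- run_study(conds)
  expect_length(study, 2)
  tab <- convergence_table(study)
  expect_equal(nrow(tab), 2)
  expect_true(all(tab$convergence_rate >= 0 & tab$convergence_rate <= 1))
  # empty grid yields an empty collection
  expect_length(run_study(list()), 0)
  # outputs round-trip to CSV
  dir <- tempfile()
  write_study(study, dir)
  expect_true(file.exists(file.path(dir, "convergence_rates.csv")))
  files <- list.files(dir, pattern = "^N25")
  expect_length(files, 2)
})

test_that("replication seeds derive deterministically from the base seed", {
  cond <- study_condition(20, 0, "weak", n_replications = 2,
                          n_iter = 300, burn_in = 100, base_seed = 5,
                          spec = dpm_spec(truncation = 6))
  s1 <- run_condition(cond)
  s2 <- run_condition(cond)
  for (col in c("est", "bias", "ase", "ese", "mse", "cp")) {
    expect_equal(s1[[col]], s2[[col]])
  }
  expect_equal(attr(s1, "convergence_rate"), attr(s2, "convergence_rate"))
})
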