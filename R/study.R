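true_values <- c(beta_L = 6.2, beta_S = 0.3, sigma2_L = 1,
                 sigma2_S = 0.1, sigma_LS = 0, sigma2_e = 0.5,
                 alpha = NA_real_, K = NA_real_)

#' Define one simulation-study condition
#'
#' A condition is a sample size, an outlier proportion, a precision-
#' parameter prior, and chain settings.  Replication r uses seed
#' `base_seed + r`, so a condition is reproducible from its definition
#' alone.
#'
#' @param n subjects per replication.
#' @param outlier_proportion fraction of observations replaced per
#'   occasion, in \[0, 1).
#' @param alpha_prior label or `c(shape, rate)` vector (see
#'   [alpha_prior()]).
#' @param n_replications datasets per condition (default 500).
#' @param n_iter,burn_in chain settings (defaults 50,000 with half
#'   burn-in).
#' @param base_seed integer seed stem for the replication stream.
#' @param spec optional [dpm_spec()] overriding the model defaults; its
#'   `alpha_prior` is replaced by this condition's prior.
#' @return object of class `study_condition`.
#' @export
study_condition <- function(n, outlier_proportion = 0,
                            alpha_prior = "weak", n_replications = 500L,
                            n_iter = 50000L, burn_in = n_iter %/% 2L,
                            base_seed = 1L, spec = NULL) {
  ap <- if (is.character(alpha_prior)) bnpgrowth::alpha_prior(alpha_prior)
        else bnpgrowth::alpha_prior(as.numeric(alpha_prior))
  stopifnot(n >= 1, outlier_proportion >= 0, outlier_proportion < 1,
            n_replications >= 1, burn_in < n_iter)
  structure(
    list(n = as.integer(n), outlier_proportion = outlier_proportion,
         alpha_prior = ap, n_replications = as.integer(n_replications),
         n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
         base_seed = as.integer(base_seed), spec = spec,
         label = if (is.character(alpha_prior)) alpha_prior else
           sprintf("Gamma(%g,%g)", ap["shape"], ap["rate"])),
    class = "study_condition"
  )
}

#' @export
print.study_condition <- function(x, ...) {
  cat(sprintf(
    "Condition: N = %d, %g%% outliers, alpha ~ Gamma(%g, %g), %d reps x %d iters\n",
    x$n, 100 * x$outlier_proportion, x$alpha_prior["shape"],
    x$alpha_prior["rate"], x$n_replications, x$n_iter))
  invisible(x)
}

#' Summarize replication-level estimates for one parameter
#'
#' Est is the mean point estimate, bias its deviation from the truth, ASE
#' the mean posterior standard deviation, ESE the standard deviation of
#' the point estimates, MSE the mean squared deviation from the truth,
#' and CP the fraction of credible intervals containing the truth.  When
#' no truth is defined (`truth = NA`) bias, MSE and CP are reported as
#' `NA`.
#'
#' @param point_estimates numeric vector of per-replication point
#'   estimates (length >= 2).
#' @param posterior_sds matching vector of posterior standard deviations.
#' @param hpd_intervals list of [hpd_interval()] objects (or two-column
#'   matrix of bounds), one per replication.
#' @param truth true parameter value, or `NA` when undefined.
#' @return one-row data frame with columns `est`, `bias`, `ase`, `ese`,
#'   `mse`, `cp`.
#' @export
summarize_estimates <- function(point_estimates, posterior_sds,
                                hpd_intervals, truth) {
  r <- length(point_estimates)
  if (r < 2) stop("need at least two replications to summarize")
  if (length(posterior_sds) != r) stop("length mismatch: posterior_sds")
  if (is.matrix(hpd_intervals)) {
    lo <- hpd_intervals[, 1]; hi <- hpd_intervals[, 2]
  } else {
    if (length(hpd_intervals) != r) stop("length mismatch: hpd_intervals")
    lo <- vapply(hpd_intervals, function(h) h$lower, numeric(1))
    hi <- vapply(hpd_intervals, function(h) h$upper, numeric(1))
  }
  est <- mean(point_estimates)
  if (is.na(truth)) {
    data.frame(est = est, bias = NA_real_, ase = mean(posterior_sds),
               ese = stats::sd(point_estimates), mse = NA_real_,
               cp = NA_real_)
  } else {
    data.frame(est = est, bias = est - truth, ase = mean(posterior_sds),
               ese = stats::sd(point_estimates),
               mse = mean((point_estimates - truth)^2),
               cp = mean(lo <= truth & truth <= hi))
  }
}

#' Run all replications of one condition
#'
#' For each replication: generate a panel, contaminate it if the
#' condition asks for outliers, fit the model, and run the Geweke
#' diagnostics.  Estimation summaries aggregate converged replications
#' only; the convergence rate is computed over all replications.  Under
#' contamination the true marginal error variance is undefined, so bias,
#' MSE and CP for it are reported as `NA` (as are those of alpha and K,
#' which have no true value).
#'
#' @param cond a [study_condition()].
#' @param verbose print per-replication progress.
#' @return object of class `condition_summary`: a data frame with one row
#'   per monitored parameter (columns `parameter`, `truth`, `est`,
#'   `bias`, `ase`, `ese`, `mse`, `cp`) carrying attributes
#'   `convergence_rate`, `n_converged`, `n_replications`, `aet`
#'   (mean per-replication fit time in seconds, converged replications
#'   only) and `condition`.
#' @export
run_condition <- function(cond, verbose = FALSE) {
  stopifnot(inherits(cond, "study_condition"))
  spec <- cond$spec %||% dpm_spec()
  spec$alpha_prior <- cond$alpha_prior
  reps <- vector("list", cond$n_replications)
  for (r in seq_len(cond$n_replications)) {
    seed <- cond$base_seed + r
    panel <- simulate_panel(cond$n, seed = seed)
    if (cond$outlier_proportion > 0) {
      panel <- contaminate(panel, outlier_spec(cond$outlier_proportion))
    }
    fit <- bnp_gcm(panel, spec, n_iter = cond$n_iter,
                   burn_in = cond$burn_in)
    diag <- diagnose(fit)
    reps[[r]] <- list(
      means = colMeans(fit$draws),
      sds = apply(fit$draws, 2, stats::sd),
      hpd = lapply(colnames(fit$draws),
                   function(nm) hpd_interval(fit$draws[, nm])),
      converged = attr(diag, "model_converged"),
      runtime = fit$runtime
    )
    if (verbose) {
      message(sprintf("  replication %d/%d: %s", r, cond$n_replications,
                      if (reps[[r]]$converged) "converged" else "not converged"))
    }
  }
  converged <- vapply(reps, function(x) x$converged, logical(1))
  summarize_condition(reps[converged], cond,
                      convergence_rate = mean(converged))
}

# Aggregate converged replications into the per-parameter summary table.
summarize_condition <- function(kept, cond, convergence_rate) {
  pars <- monitored_names
  no_truth_sigma2e <- cond$outlier_proportion > 0
  if (length(kept) < 2) {
    out <- data.frame(parameter = pars, truth = unname(true_values[pars]),
                      est = NA_real_, bias = NA_real_, ase = NA_real_,
                      ese = NA_real_, mse = NA_real_, cp = NA_real_)
  } else {
    rows <- lapply(seq_along(pars), function(k) {
      nm <- pars[k]
      truth <- true_values[[nm]]
      if (nm == "sigma2_e" && no_truth_sigma2e) truth <- NA_real_
      cbind(parameter = nm, truth = truth, summarize_estimates(
        vapply(kept, function(x) x$means[[nm]], numeric(1)),
        vapply(kept, function(x) x$sds[[nm]], numeric(1)),
        lapply(kept, function(x) x$hpd[[k]]),
        truth))
    })
    out <- do.call(rbind, rows)
  }
  attr(out, "convergence_rate") <- convergence_rate
  attr(out, "n_converged") <- length(kept)
  attr(out, "n_replications") <- cond$n_replications
  attr(out, "aet") <- if (length(kept))
    mean(vapply(kept, function(x) x$runtime, numeric(1))) else NA_real_
  attr(out, "condition") <- cond
  class(out) <- c("condition_summary", "data.frame")
  out
}

#' @export
print.condition_summary <- function(x, digits = 3, ...) {
  cond <- attr(x, "condition")
  print(cond)
  cat(sprintf("Convergence rate: %.2f (%d/%d); mean fit time %.1f s\n",
              attr(x, "convergence_rate"), attr(x, "n_converged"),
              attr(x, "n_replications"), attr(x, "aet")))
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], round, digits)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Run a grid of simulation conditions
#'
#' Executes [run_condition()] for every condition, never aborting the
#' grid: a failing condition is recorded as an error entry and the rest
#' proceed.
#'
#' @param conditions list of [study_condition()] objects.
#' @param verbose print per-condition progress.
#' @return object of class `study_result`: a list of
#'   [run_condition()] summaries (or `try-error` entries) with the
#'   condition labels as names.
#' @export
run_study <- function(conditions, verbose = FALSE) {
  out <- vector("list", length(conditions))
  for (k in seq_along(conditions)) {
    if (verbose) message("condition ", k, "/", length(conditions))
    out[[k]] <- tryCatch(run_condition(conditions[[k]], verbose = verbose),
                         error = function(e) e)
  }
  names(out) <- vapply(conditions, function(cc) {
    sprintf("N%d_out%g_%s", cc$n, 100 * cc$outlier_proportion, cc$label)
  }, character(1))
  class(out) <- "study_result"
  out
}

#' Convergence-rate table across conditions
#'
#' @param study a [run_study()] result.
#' @return data frame with one row per condition: sample size, outlier
#'   percentage, prior label, and convergence rate.
#' @export
convergence_table <- function(study) {
  rows <- lapply(study, function(s) {
    if (inherits(s, "error") || inherits(s, "try-error")) return(NULL)
    cond <- attr(s, "condition")
    data.frame(n = cond$n, outlier_pct = 100 * cond$outlier_proportion,
               prior = cond$label,
               convergence_rate = attr(s, "convergence_rate"))
  })
  do.call(rbind, rows)
}

#' Write study outputs as CSV
#'
#' One estimation table per condition (columns parameter, truth, est,
#' bias, ase, ese, mse, cp) plus `convergence_rates.csv`.
#'
#' @param study a [run_study()] result.
#' @param dir output directory (created if missing).
#' @export
write_study <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in names(study)) {
    s <- study[[nm]]
    if (inherits(s, "error")) next
    utils::write.csv(as.data.frame(s),
                     file.path(dir, paste0(nm, ".csv")), row.names = FALSE)
  }
  utils::write.csv(convergence_table(study),
                   file.path(dir, "convergence_rates.csv"),
                   row.names = FALSE)
  invisible(dir)
}
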