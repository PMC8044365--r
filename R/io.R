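#' Read and write longitudinal panels as CSV
#'
#' Long layout has columns `id`, `occasion`, `y` and optionally
#' `contaminated`; wide layout has `id`, `y1`, ..., `yT`.  Panels must be
#' balanced and complete: any missing cell is an error, since the model
#' assumes every subject is measured at every occasion.
#'
#' @param path CSV file path.
#' @param layout `"long"` or `"wide"`.
#' @return `read_panel`: a [growth_panel()]; `write_panel`: `path`,
#'   invisibly.
#' @export
read_panel <- function(path, layout = c("long", "wide")) {
  layout <- match.arg(layout)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (layout == "wide") {
    ycols <- grep("^y[0-9]+$", names(df), value = TRUE)
    if (length(ycols) < 1L || !"id" %in% names(df)) {
      stop("wide panel needs columns id, y1..yT")
    }
    ycols <- ycols[order(as.integer(sub("^y", "", ycols)))]
    y <- as.matrix(df[, ycols, drop = FALSE])
    if (!is.numeric(y)) stop("non-numeric outcome values in ", path)
    if (anyNA(y)) stop("missing cells are not supported (balanced complete panels only)")
    return(growth_panel(y))
  }
  need <- c("id", "occasion", "y")
  if (!all(need %in% names(df))) {
    stop("long panel needs columns id, occasion, y")
  }
  if (!is.numeric(df$y)) stop("non-numeric outcome values in ", path)
  if (anyNA(df$y)) stop("missing cells are not supported (balanced complete panels only)")
  ids <- unique(df$id)
  occ <- sort(unique(df$occasion))
  key <- interaction(factor(df$id, ids), factor(df$occasion, occ))
  if (anyDuplicated(key) || nrow(df) != length(ids) * length(occ)) {
    stop("long panel is unbalanced or has duplicate (id, occasion) rows")
  }
  y <- matrix(NA_real_, length(ids), length(occ))
  y[cbind(match(df$id, ids), match(df$occasion, occ))] <- df$y
  mask <- NULL
  if ("contaminated" %in% names(df)) {
    mask <- matrix(FALSE, length(ids), length(occ))
    mask[cbind(match(df$id, ids), match(df$occasion, occ))] <-
      as.logical(df$contaminated)
  }
  growth_panel(y, occasions = occ, contaminated = mask)
}

#' @rdname read_panel
#' @param panel a [growth_panel()].
#' @export
write_panel <- function(panel, path, layout = c("long", "wide")) {
  stopifnot(inherits(panel, "growth_panel"))
  layout <- match.arg(layout)
  n <- nrow(panel$outcomes)
  t_occ <- ncol(panel$outcomes)
  if (layout == "wide") {
    df <- data.frame(id = seq_len(n))
    for (j in seq_len(t_occ)) df[[paste0("y", j)]] <- panel$outcomes[, j]
  } else {
    df <- data.frame(
      id = rep(seq_len(n), each = t_occ),
      occasion = rep(panel$occasions, times = n),
      y = as.vector(t(panel$outcomes)),
      contaminated = as.vector(t(panel$contaminated))
    )
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write the generator sidecar describing a panel
#'
#' Records seed, dimensions and contamination settings alongside a panel
#' file so a run can be reproduced bit for bit.
#'
#' @param panel a [growth_panel()].
#' @param path output JSON path.
#' @param spec optional [outlier_spec()] used to contaminate the panel.
#' @export
write_panel_sidecar <- function(panel, path, spec = NULL) {
  info <- list(
    n = nrow(panel$outcomes), n_occasions = ncol(panel$outcomes),
    occasions = panel$occasions, seed = panel$seed,
    sigma2_e = panel$sigma2_e,
    n_contaminated = sum(panel$contaminated),
    multipliers = panel$multipliers
  )
  if (!is.null(spec)) info$outliers <- unclass(spec)
  jsonlite::write_json(info, path, auto_unbox = TRUE, null = "null",
                       digits = NA)
  invisible(path)
}

named_alpha_priors <- list(
  noninformative = c(shape = 0.001, rate = 0.001),
  weak = c(shape = 2, rate = 2),
  accurate = c(shape = 100, rate = 100),
  inaccurate = c(shape = 10, rate = 100)
)

#' Named precision-parameter priors
#'
#' The four gamma priors studied for the DP precision parameter:
#' `"noninformative"` Gamma(0.001, 0.001), `"weak"` Gamma(2, 2),
#' `"accurate"` Gamma(100, 100) (mean 1, small variance) and
#' `"inaccurate"` Gamma(10, 100) (mean 0.1, very small variance).
#'
#' @param label prior label, or a numeric length-2 vector (shape, rate).
#' @return named numeric vector `c(shape = , rate = )`.
#' @export
alpha_prior <- function(label = "weak") {
  if (is.numeric(label)) {
    stopifnot(length(label) == 2L, all(label > 0))
    return(c(shape = label[[1]], rate = label[[2]]))
  }
  label <- match.arg(label, names(named_alpha_priors))
  named_alpha_priors[[label]]
}

#' Load a model/study configuration from YAML
#'
#' An empty or absent file yields the full set of defaults: the linear
#' four-occasion design, truncation 50, Gamma(2, 2) precision prior,
#' diffuse N(0, 1e6) fixed-effect priors, inverse-Wishart(I, 2) prior for
#' the random-effect covariance, and 50,000-iteration chains with the
#' first half discarded.  Recognized top-level keys: `model` (passed to
#' [dpm_spec()], with `alpha_prior` given either as a label or as
#' `{shape, rate}`), `chain` (`n_iter`, `burn_in`), and `conditions` (a
#' list of [study_condition()] argument sets).  Unknown keys are an error.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return list with elements `spec` ([dpm_spec()]), `chain`, `conditions`.
#' @export
load_config <- function(path = NULL) {
  cfg <- list()
  if (!is.null(path)) {
    raw <- yaml::read_yaml(path)
    if (!is.null(raw)) cfg <- raw
  }
  known <- c("model", "chain", "conditions")
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stop("unknown configuration keys: ",
                        paste(bad, collapse = ", "))
  model <- cfg$model %||% list()
  if (!is.null(model$alpha_prior)) {
    ap <- model$alpha_prior
    model$alpha_prior <- if (is.character(ap)) alpha_prior(ap) else {
      if (!all(c("shape", "rate") %in% names(ap))) {
        stop("alpha_prior must be a label or have fields shape and rate")
      }
      alpha_prior(c(ap$shape, ap$rate))
    }
  }
  spec <- do.call(dpm_spec, model)
  chain <- cfg$chain %||% list()
  chain$n_iter <- chain$n_iter %||% 50000L
  chain$burn_in <- chain$burn_in %||% (chain$n_iter %/% 2L)
  if (chain$burn_in >= chain$n_iter) stop("burn_in must be below n_iter")
  conditions <- lapply(cfg$conditions %||% list(), function(cc) {
    # YAML 1.1 parses a bare `n` key as boolean; accept it and a
    # spelled-out alias
    names(cc)[names(cc) %in% c("FALSE", "n_subjects")] <- "n"
    if (!is.null(cc$alpha_prior) && is.character(cc$alpha_prior)) {
      cc$alpha_prior <- alpha_prior(cc$alpha_prior)
    }
    cc$n_iter <- cc$n_iter %||% chain$n_iter
    cc$burn_in <- cc$burn_in %||% chain$burn_in
    do.call(study_condition, cc)
  })
  list(spec = spec, chain = chain, conditions = conditions)
}

#' Write a machine-readable run manifest
#'
#' @param path output JSON path.
#' @param ... named fields (configuration snapshot, seeds, timings,
#'   warnings) stored verbatim.
#' @export
write_manifest <- function(path, ...) {
  fields <- list(...)
  fields$package_version <- as.character(utils::packageVersion("bnpgrowth"))
  fields$created <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(fields, path, auto_unbox = TRUE, null = "null",
                       digits = NA, force = TRUE)
  invisible(path)
}
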