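#' Read and validate a binary-outcome dataset from CSV
#'
#' Rows with missing values in the named columns are dropped (with a
#' message); the outcome must contain only 0 and 1.
#'
#' @param path CSV file path.
#' @param outcome Outcome column name.
#' @param covariates Character vector of covariate column names.
#' @return A tibble with the named columns.
#' @export
read_dataset <- function(path, outcome, covariates) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, comment.char = "#")
  need <- c(outcome, covariates)
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  df <- df[need]
  cc <- stats::complete.cases(df)
  if (any(!cc)) {
    message(sum(!cc), " row(s) dropped due to missing values")
    df <- df[cc, , drop = FALSE]
  }
  if (nrow(df) == 0) stop("no complete rows after filtering")
  if (!all(df[[outcome]] %in% c(0, 1))) {
    stop("outcome column must contain only 0 and 1")
  }
  message("read ", nrow(df), " rows from ", path)
  tibble::as_tibble(df)
}

default_fit_config <- function() {
  list(outcome = "y", smooth_terms = list(), fixed_terms = character(0),
       penalty = "lasso", gamma_prior = "uniform", basis = "lrtp",
       knots = 20, iters = 55000, burnin = 5000, thin = 50, chains = 2,
       seed = 1, strict = TRUE, out = ".")
}

merge_config <- function(config, defaults) {
  bad <- setdiff(names(config), c(names(defaults), "data"))
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  out <- defaults
  out[names(config)] <- config
  out
}

#' Fit an additive penalized-spline model and write its artifacts
#'
#' Wraps \code{\link{build_additive_design}}, \code{\link{fit_spmm}} and the
#' summary extractors. Writes retained draws (long CSV: chain, iteration,
#' parameter, value), a parameter-summary CSV including odds ratios for the
#' fixed effects, one smooth-curve CSV per smoother, and a plain-text report.
#'
#' @param config Named list (or path to a YAML file): keys \code{data}
#'   (CSV path or data frame), \code{outcome}, \code{smooth_terms}
#'   (character vector of covariate names), \code{fixed_terms},
#'   \code{penalty}, \code{gamma_prior}, \code{basis}, \code{knots}
#'   (integer or "wand"), \code{iters}, \code{burnin}, \code{thin},
#'   \code{chains}, \code{seed}, \code{strict}, \code{out} (output dir).
#' @return A \code{fit_report} list (invisibly): model description, data
#'   digest, parameter and odds-ratio summaries, smooth-curve tables,
#'   diagnostics, seeds and a convergence flag.
#' @export
cmd_fit <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(config, default_fit_config())
  if (length(cfg$smooth_terms) == 0) stop("config must name smooth_terms")
  df <- if (is.character(cfg$data)) {
    read_dataset(cfg$data, cfg$outcome,
                 c(unlist(cfg$smooth_terms), cfg$fixed_terms))
  } else {
    tibble::as_tibble(cfg$data)
  }
  K <- if (identical(cfg$knots, "wand")) "wand_rule" else as.integer(cfg$knots)
  st <- stats::setNames(
    replicate(length(cfg$smooth_terms),
              basis_spec(cfg$basis, K = K), simplify = FALSE),
    unlist(cfg$smooth_terms))
  dat <- build_additive_design(df, cfg$outcome, st, cfg$fixed_terms)
  spec <- spmm_spec(penalty = cfg$penalty, gamma_prior = cfg$gamma_prior,
                    basis = basis_spec(cfg$basis, K = K))
  mc <- mcmc_config(n_iter = cfg$iters, burn_in = cfg$burnin, thin = cfg$thin,
                    n_chains = cfg$chains, seed = cfg$seed)
  fit <- fit_spmm(dat, spec, mc)

  dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
  # draws in long format
  long <- do.call(rbind, lapply(seq_along(fit$draws), function(cc) {
    m <- cbind(fit$draws[[cc]]$theta, fit$draws[[cc]]$gamma)
    data.frame(chain = cc, iteration = rep(seq_len(nrow(m)), ncol(m)),
               parameter = rep(colnames(m), each = nrow(m)),
               value = as.vector(m))
  }))
  utils::write.csv(long, file.path(cfg$out, "draws.csv"), row.names = FALSE)

  summ <- fit$summaries
  if (!is.null(fit$diagnostics$rhat)) {
    summ$rhat <- fit$diagnostics$rhat[summ$parameter]
  }
  # odds ratios for non-intercept fixed effects
  fx <- intersect(cfg$fixed_terms, summ$parameter)
  or_tab <- summ[summ$parameter %in% fx, ]
  if (nrow(or_tab)) {
    or_tab <- tibble::tibble(parameter = or_tab$parameter,
                             or = exp(or_tab$median),
                             or_lower = exp(or_tab$lower),
                             or_upper = exp(or_tab$upper))
  }
  utils::write.csv(summ, file.path(cfg$out, "summary.csv"), row.names = FALSE)

  curves <- lapply(unlist(cfg$smooth_terms), function(v) {
    sc <- smooth_curve(fit, v)
    utils::write.csv(sc, file.path(cfg$out, paste0("smooth_", v, ".csv")),
                     row.names = FALSE)
    sc
  })
  names(curves) <- unlist(cfg$smooth_terms)

  rhat_max <- if (is.null(fit$diagnostics$rhat)) NA_real_ else
    max(fit$diagnostics$rhat)
  converged <- is.na(rhat_max) || rhat_max <= 1.03
  report <- list(
    model = list(penalty = cfg$penalty, basis = cfg$basis, knots = cfg$knots,
                 gamma_prior = cfg$gamma_prior),
    data_digest = list(n = length(dat$y), prevalence = mean(dat$y),
                       ranges = lapply(df[unlist(cfg$smooth_terms)], range)),
    summaries = summ, odds_ratios = if (nrow(or_tab)) or_tab,
    curves = curves,
    diagnostics = list(rhat_max = rhat_max, converged = converged,
                       boundary_frac = fit$diagnostics$boundary_frac),
    seeds = list(master = cfg$seed, chains = fit$chain_seeds))
  class(report) <- "fit_report"

  txt <- c(
    sprintf("Penalized-spline logistic mixed model (%s penalty, %s basis, K = %s)",
            cfg$penalty, cfg$basis, as.character(cfg$knots)),
    sprintf("n = %d, prevalence = %.3f", length(dat$y), mean(dat$y)),
    sprintf("chains = %d, iterations = %d (burn-in %d, thin %d), master seed = %d",
            cfg$chains, cfg$iters, cfg$burnin, cfg$thin, cfg$seed),
    if (!is.na(rhat_max)) sprintf("max sqrt(R-hat) = %.4f (%s)", rhat_max,
            if (converged) "converged" else "NOT converged"),
    "", "Parameter summaries (posterior median [2.5%, 97.5%]):",
    sprintf("  %-14s %10.4f [%10.4f, %10.4f]", summ$parameter, summ$median,
            summ$lower, summ$upper),
    if (nrow(or_tab)) c("", "Odds ratios (95% CI):",
      sprintf("  %-14s %6.2f (%5.2f, %5.2f)", or_tab$parameter, or_tab$or,
              or_tab$or_lower, or_tab$or_upper)))
  writeLines(txt, file.path(cfg$out, "report.txt"))

  if (cfg$strict && !converged) {
    warning("convergence criterion sqrt(R-hat) <= 1.03 not met")
  }
  invisible(report)
}

#' Simulate a benchmark dataset and write it to CSV
#'
#' @param config Named list (or YAML path) with keys \code{fn}, \code{n},
#'   \code{seed}, \code{out} (output CSV path).
#' @return The output path (invisibly).
#' @export
cmd_simulate <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(config, list(fn = "linear", n = 500, seed = 1,
                                   out = "simulated.csv"))
  fn <- calibrate_function(cfg$fn)
  d <- generate_dataset(fn, n = cfg$n, seed = cfg$seed)
  con <- file(cfg$out, "w")
  writeLines(sprintf("# fn: %s  n: %d  seed: %d", cfg$fn, cfg$n, cfg$seed), con)
  utils::write.csv(data.frame(x = d$x, y = d$y, m_true = d$m_true,
                              p_true = d$p_true), con, row.names = FALSE)
  close(con)
  invisible(cfg$out)
}

#' Run a simulation study from a config and write its metric tables
#'
#' @param config Named list (or YAML path) with \code{\link{sim_config}}
#'   fields plus \code{out} (output dir). Per-replicate checkpoints are
#'   written under \code{out/checkpoints} and reused on re-invocation.
#' @return The \code{metrics_table} (invisibly).
#' @export
cmd_study <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(fn = "linear", n = 500, K = 7, penalty = "lasso",
                   gamma_prior = "uniform", basis = "lrtp",
                   n_replicates = 100, iters = 10000, burnin = 1000,
                   thin = 10, seed = 1, out = ".")
  cfg <- merge_config(config, defaults)
  sc <- sim_config(fn = cfg$fn, n = cfg$n, K = cfg$K, penalty = cfg$penalty,
                   gamma_prior = cfg$gamma_prior, basis_kind = cfg$basis,
                   n_replicates = cfg$n_replicates,
                   mcmc = mcmc_config(n_iter = cfg$iters, burn_in = cfg$burnin,
                                      thin = cfg$thin, n_chains = 1),
                   master_seed = cfg$seed)
  dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
  res <- run_study(sc, checkpoint_dir = file.path(cfg$out, "checkpoints"))
  write_metrics(res, file.path(cfg$out, "metrics.csv"))
  invisible(res)
}

#' Recompute parameter summaries from a stored draws file
#'
#' Reads a long-format draws CSV (columns chain, iteration, parameter,
#' value) as written by \code{\link{cmd_fit}} and recomputes the posterior
#' medians, 95% intervals and, when several chains are present, the
#' Gelman-Rubin scale-reduction factors.
#'
#' @param draws_path Path to a draws CSV.
#' @param out Optional output path for the recomputed summary CSV.
#' @return A tibble with one row per parameter.
#' @export
cmd_summarize <- function(draws_path, out = NULL) {
  dr <- utils::read.csv(draws_path)
  need <- c("chain", "iteration", "parameter", "value")
  if (!all(need %in% names(dr))) {
    stop("draws file must have columns: ", paste(need, collapse = ", "))
  }
  pars <- unique(dr$parameter)
  chains <- sort(unique(dr$chain))
  summ <- do.call(rbind, lapply(pars, function(pn) {
    v <- dr$value[dr$parameter == pn]
    s <- posterior_summary(v)
    rhat <- if (length(chains) >= 2) {
      gelman_rubin(lapply(chains, function(cc)
        dr$value[dr$parameter == pn & dr$chain == cc]))
    } else NA_real_
    tibble::tibble(parameter = pn, median = s[["median"]],
                   lower = s[["lower"]], upper = s[["upper"]], rhat = rhat)
  }))
  if (!is.null(out)) utils::write.csv(summ, out, row.names = FALSE)
  summ
}
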