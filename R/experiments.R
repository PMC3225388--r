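#' Experiment configuration
#'
#' Bundles an experiment name with its parameter grid and simulation
#' settings.  Every parameter defaults to the reference study design
#' of that experiment (100 risk SNPs, 3,500-subject
#' cohorts at 1:1 for the equal-effects grids, 5,000 subjects for the
#' heterogeneous architecture, 10,000 replicates); pass overrides to
#' scale an experiment down.
#'
#' @param experiment One of `"fig1_model_curve"`,
#'   `"fig2_prevalence_grid"`, `"fig2_maf_grid"`, `"fig3_nsnp_grid"`,
#'   `"fig4_r2_grids"`, `"fig5_heterogeneous"`.
#' @param ... Named parameter overrides (see
#'   [experiment_defaults()]).
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(experiment, ...) {
  experiments <- c("fig1_model_curve", "fig2_prevalence_grid",
                   "fig2_maf_grid", "fig3_nsnp_grid", "fig4_r2_grids",
                   "fig5_heterogeneous")
  if (length(experiment) != 1L || !experiment %in% experiments)
    stop_config("unknown experiment: ", paste(experiment, collapse = ", "))
  params <- experiment_defaults(experiment)
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(params))
    if (length(bad) || is.null(names(overrides)) ||
        any(names(overrides) == ""))
      stop_config("unknown parameter(s): ", paste(bad, collapse = ", "))
    params[names(overrides)] <- overrides
  }
  validate_params(params)
  structure(list(experiment = experiment, parameters = params),
            class = "experiment_config")
}

#' Default parameters of each experiment
#'
#' @param experiment Experiment name as in [experiment_config()].
#' @return Named list of default parameter values.
#' @export
experiment_defaults <- function(experiment) {
  base <- list(n_replicates = 10000L, estimator = "logistic", seed = 1L,
               or_grid = seq(1, 5, by = 0.1))
  switch(experiment,
    fig1_model_curve = list(prevalence = 0.01, or_true = 1.6,
                            maf = 0.25, n_snps = 100L,
                            sample_size = 10000L, seed = 1L),
    fig2_prevalence_grid = c(base, list(
      prevalences = c(0.001, 0.01, 0.1, 0.2), maf = 0.25,
      n_snps = 100L, n_cases = 1750L, n_controls = 1750L)),
    fig2_maf_grid = c(base, list(
      mafs = c(0.01, 0.1, 0.25, 0.5), prevalence = 0.01,
      n_snps = 100L, n_cases = 1750L, n_controls = 1750L)),
    fig3_nsnp_grid = c(base[names(base) != "or_grid"], list(
      or_grid = c(1.5, 2, 3, 4),
      n_snps_grid = c(1L, 2L, 5L, 10L, 25L, 50L, 100L, 250L, 500L),
      prevalence = 0.01, maf = 0.25,
      n_cases = 1750L, n_controls = 1750L)),
    fig4_r2_grids = c(base, list(
      mafs = c(0.01, 0.1, 0.25, 0.5),
      prevalences = c(0.001, 0.01, 0.1, 0.2),
      n_snps_grid = c(10L, 50L, 100L, 200L),
      prevalence = 0.01, maf = 0.25, n_snps = 100L,
      n_cases = 1750L, n_controls = 1750L)),
    fig5_heterogeneous = list(
      n_snps = 100L, exp_rate = 5, maf_low = 0.05, maf_high = 0.95,
      prevalence = 0.01, n_replicates = 10000L,
      n_cases = 2500L, n_controls = 2500L, estimator = "logistic",
      seed = 1L, architecture_seed = 1L, calibration_draws = 1e6,
      pin_or = NULL, pin_snp = 1L),
    stop_config("unknown experiment: ", experiment))
}

validate_params <- function(p) {
  chk <- function(ok, what)
    if (!isTRUE(ok)) stop_config("invalid parameter: ", what)
  probs <- c(p$prevalence, p$prevalences, p$maf, p$mafs,
             p$maf_low, p$maf_high)
  chk(all(probs > 0 & probs < 1), "probabilities must lie in (0,1)")
  ors <- c(p$or_grid, p$or_true, p$pin_or)
  chk(all(ors > 0), "odds ratios must be positive")
  ns <- c(p$n_snps, p$n_snps_grid, p$n_replicates,
          p$n_cases, p$n_controls, p$sample_size)
  chk(all(ns >= 1), "counts must be >= 1")
  if (!is.null(p$estimator))
    chk(p$estimator %in% c("logistic", "allele_table"),
        "estimator must be logistic or allele_table")
  invisible(TRUE)
}

stop_config <- function(...) {
  stop(structure(class = c("collapsim_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' @export
print.experiment_config <- function(x, ...) {
  cat("Experiment:", x$experiment, "\n")
  utils::str(x$parameters, give.attr = FALSE)
  invisible(x)
}

#' Serialize / parse an experiment configuration
#'
#' @param config An `experiment_config`.
#' @param path File path for the JSON document.
#' @return `read_experiment_config()` returns the parsed
#'   `experiment_config`; `write_experiment_config()` its path,
#'   invisibly.
#' @export
write_experiment_config <- function(config, path) {
  jsonlite::write_json(list(experiment = config$experiment,
                            parameters = config$parameters),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$experiment)) stop_config("config file lacks `experiment`")
  params <- as.list(x$parameters)
  int_par <- c("n_snps", "n_replicates", "n_cases", "n_controls",
               "sample_size", "seed", "architecture_seed", "pin_snp",
               "n_snps_grid")
  for (nm in intersect(names(params), int_par))
    params[[nm]] <- as.integer(params[[nm]])
  do.call(experiment_config, c(list(experiment = x$experiment), params))
}

#' Run a grid experiment
#'
#' Executes the configured experiment and (optionally) writes a TSV
#' result table plus a JSON sidecar recording all parameters, the
#' master seed and the package version.
#'
#' @param config An [experiment_config()].
#' @param out Optional output stem: writes `<out>.tsv` and
#'   `<out>.json`.
#' @param verbose Emit progress messages (default `TRUE`).
#' @return The result data frame, invisibly when `out` is given.
#' @export
run_experiment <- function(config, out = NULL, verbose = TRUE) {
  stopifnot(inherits(config, "experiment_config"))
  p <- config$parameters
  t0 <- Sys.time()
  say <- function(...) if (verbose) message(sprintf(...))
  say("experiment %s (seed %d)", config$experiment,
      as.integer(p$seed %||% 1L))
  res <- switch(config$experiment,
    fig1_model_curve = exp_model_curve(p),
    fig2_prevalence_grid = exp_or_grid(p, vary = "prevalence"),
    fig2_maf_grid = exp_or_grid(p, vary = "maf"),
    fig3_nsnp_grid = exp_nsnp_grid(p),
    fig4_r2_grids = exp_r2_grids(p),
    fig5_heterogeneous = exp_heterogeneous(p, say))
  say("done in %.1f s; %d rows", as.numeric(Sys.time() - t0, units = "secs"),
      nrow(res))
  if (!is.null(out)) {
    utils::write.table(res, paste0(out, ".tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    sidecar <- list(experiment = config$experiment, parameters = p,
                    package_version =
                      as.character(utils::packageVersion("collapsim")),
                    n_corrected_total =
                      if ("n_corrected" %in% names(res))
                        sum(res$n_corrected) else 0L)
    jsonlite::write_json(sidecar, paste0(out, ".json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    say("wrote %s.tsv and %s.json", out, out)
    return(invisible(res))
  }
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# penetrance curve + risk-allele histogram of a large sample
exp_model_curve <- function(p) {
  m <- 2L * p$n_snps
  model <- fixed_effect_model(p$prevalence, or_true = p$or_true,
                              risk_allele_freq = p$maf,
                              n_effect_alleles = m)
  g <- 0:m
  draws <- local_seed(p$seed, stats::rbinom(p$sample_size, m, p$maf))
  data.frame(g = g,
             penetrance = penetrance(model, g),
             pmf = allele_count_pmf(model),
             sample_count = tabulate(draws + 1L, m + 1L))
}

# median + asymptotic OR across a grid of true ORs, varying either
# prevalence or risk allele frequency
exp_or_grid <- function(p, vary) {
  vals <- if (vary == "prevalence") p$prevalences else p$mafs
  grid <- expand.grid(value = vals, or_true = p$or_grid,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    K <- if (vary == "prevalence") grid$value[i] else p$prevalence
    maf <- if (vary == "maf") grid$value[i] else p$maf
    one_or_cell(K, grid$or_true[i], maf, 2L * p$n_snps, p,
                seed_offset = i, varied = grid$value[i])
  })
  out <- do.call(rbind, rows)
  names(out)[names(out) == "varied"] <- vary
  out
}

exp_nsnp_grid <- function(p) {
  grid <- expand.grid(n_snps = p$n_snps_grid, or_true = p$or_grid,
                      KEEP.OUT.ATTRS = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i)
    one_or_cell(p$prevalence, grid$or_true[i], p$maf,
                2L * grid$n_snps[i], p, seed_offset = i,
                varied = grid$n_snps[i])))
  names(out)[names(out) == "varied"] <- "n_snps"
  out
}

one_or_cell <- function(K, or_true, maf, m, p, seed_offset, varied) {
  model <- fixed_effect_model(K, or_true = or_true,
                              risk_allele_freq = maf,
                              n_effect_alleles = m)
  sim <- if (or_true == 1)
    list(or_median = 1.0, n_corrected = 0L)
  else
    median_or_experiment(model, n_replicates = p$n_replicates,
                         n_cases = p$n_cases, n_controls = p$n_controls,
                         method = p$estimator,
                         seed = p$seed + seed_offset)
  data.frame(varied = varied,
             or_true = or_true,
             or_median = sim$or_median,
             or_asymptotic = asymptotic_marginal_or(model),
             n_corrected = sim$n_corrected)
}

exp_r2_grids <- function(p) {
  panel <- function(name, vals, field) {
    do.call(rbind, lapply(seq_along(vals), function(j) {
      q <- p
      q[[field]] <- vals[j]
      do.call(rbind, lapply(seq_along(p$or_grid), function(i) {
        or <- p$or_grid[i]
        cmp <- r2_loss_experiment(
          prevalence = q$prevalence, or_true = or,
          risk_allele_freq = q$maf,
          n_effect_alleles = 2L * q$n_snps,
          n_replicates = q$n_replicates, n_cases = q$n_cases,
          n_controls = q$n_controls, method = q$estimator,
          seed = q$seed + 1000L * j + i)
        data.frame(panel = name, value = vals[j], or_true = or,
                   or_est_median = cmp$or_est_median,
                   r2_true = cmp$r2_true, r2_est = cmp$r2_estimated,
                   loss_points = cmp$loss_points,
                   loss_relative = cmp$loss_relative,
                   n_corrected = cmp$n_corrected)
      }))
    }))
  }
  rbind(panel("maf", p$mafs, "maf"),
        panel("prevalence", p$prevalences, "prevalence"),
        panel("n_snps", p$n_snps_grid, "n_snps"))
}

exp_heterogeneous <- function(p, say) {
  arch <- draw_architecture(p$n_snps, p$exp_rate, p$maf_low,
                            p$maf_high, seed = p$architecture_seed)
  if (!is.null(p$pin_or)) {
    arch$betas[p$pin_snp] <- log(p$pin_or)
    say("pinned SNP %d at true OR %.3f", p$pin_snp, p$pin_or)
  }
  model <- heterogeneous_model(p$prevalence, arch$betas, arch$freqs,
                               n_draws = p$calibration_draws,
                               seed = p$seed)
  say("intercept %.4f (MC prevalence %.5f)", model$intercept,
      model$calibration$achieved_prevalence)
  res <- heterogeneous_experiment(model, n_replicates = p$n_replicates,
                                  n_cases = p$n_cases,
                                  n_controls = p$n_controls,
                                  seed = p$seed, method = p$estimator)
  res$freq <- model$freqs[res$snp]
  as.data.frame(res)
}
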