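#' Case-control sample container
#'
#' Holds either focal-SNP genotype counts (equal-effects path) or full
#' genotype matrices (heterogeneous path) for cases and controls.
#'
#' @param case A length-3 vector of genotype counts over x = 0, 1, 2,
#'   or an n_cases x S genotype matrix.
#' @param control Same for controls.
#' @return An object of class `case_control_sample` with fields
#'   `case_genotype_counts` / `control_genotype_counts` (or
#'   `case_genotypes` / `control_genotypes`), `n_cases`, `n_controls`.
#' @keywords internal
new_case_control_sample <- function(case, control) {
  if (is.matrix(case)) {
    stopifnot(is.matrix(control), ncol(case) == ncol(control),
              all(case %in% 0:2), all(control %in% 0:2))
    out <- list(case_genotypes = case, control_genotypes = control,
                n_cases = nrow(case), n_controls = nrow(control))
  } else {
    stopifnot(length(case) == 3L, length(control) == 3L,
              all(case >= 0), all(control >= 0))
    out <- list(case_genotype_counts = stats::setNames(as.integer(case),
                                                       paste0("x", 0:2)),
                control_genotype_counts = stats::setNames(as.integer(control),
                                                          paste0("x", 0:2)),
                n_cases = sum(case), n_controls = sum(control))
  }
  structure(out, class = "case_control_sample")
}

#' @export
print.case_control_sample <- function(x, ...) {
  cat(sprintf("Case-control sample: %d cases, %d controls",
              x$n_cases, x$n_controls))
  if (!is.null(x$case_genotypes))
    cat(sprintf(", %d SNPs (genotype matrices)", ncol(x$case_genotypes)))
  cat("\n")
  if (!is.null(x$case_genotype_counts)) {
    print(rbind(case = x$case_genotype_counts,
                control = x$control_genotype_counts))
  }
  invisible(x)
}

#' Simulate a focal-SNP case-control sample (equal-effects model)
#'
#' Case genotypes are drawn i.i.d. from the exact conditional
#' distribution P(X | Y = 1) and control genotypes from P(X | Y = 0);
#' the polygenic background is marginalised analytically, so only the
#' focal SNP is simulated.
#'
#' @param model A calibrated [fixed_effect_model()].
#' @param n_cases,n_controls Stratum sizes (defaults 1750/1750: a
#'   3,500-subject study with a 1:1 case:control ratio).
#' @param seed Optional integer seed for reproducibility.
#' @param focal_dist Optional precomputed [focal_genotype_distribution()]
#'   (avoids recomputation across replicates).
#' @return A `case_control_sample` with genotype counts.
#' @export
sample_fixed_effect_cohort <- function(model, n_cases = 1750L,
                                       n_controls = 1750L, seed = NULL,
                                       focal_dist = NULL) {
  if (is.null(focal_dist)) focal_dist <- focal_genotype_distribution(model)
  draw <- function() {
    ca <- stats::rmultinom(1L, n_cases, focal_dist$probs_case)[, 1L]
    co <- stats::rmultinom(1L, n_controls, focal_dist$probs_control)[, 1L]
    new_case_control_sample(ca, co)
  }
  if (is.null(seed)) draw() else local_seed(seed, draw())
}

#' Estimate the single-SNP odds ratio from a case-control sample
#'
#' `method = "logistic"` fits the standard per-allele (additive)
#' logistic regression of case status on genotype count and returns
#' exp(slope).  `method = "allele_table"` returns the 2x2 allele-table
#' odds ratio.  On complete separation or a zero cell the logistic fit
#' falls back to the Haldane-Anscombe (+0.5) corrected allele-table OR
#' and the estimate is flagged via `attr(, "corrected")`.
#'
#' @param sample A `case_control_sample` (counts, or matrices with
#'   `snp` naming the column to test).
#' @param method `"logistic"` (default) or `"allele_table"`.
#' @param snp Column index of the SNP to test when the sample holds
#'   genotype matrices.
#' @return Odds ratio (numeric scalar) with logical attribute
#'   `corrected` indicating a separation/zero-cell fallback.
#' @export
estimate_or <- function(sample, method = c("logistic", "allele_table"),
                        snp = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(sample, "case_control_sample"))
  if (!is.null(sample$case_genotypes)) {
    if (is.null(snp)) stop("`snp` must name a column for matrix samples")
    n1 <- tabulate(sample$case_genotypes[, snp] + 1L, 3L)
    n0 <- tabulate(sample$control_genotypes[, snp] + 1L, 3L)
  } else {
    n1 <- sample$case_genotype_counts
    n0 <- sample$control_genotype_counts
  }
  estimate_or_counts(n1, n0, method)
}

# core estimator on collapsed 3x2 genotype counts
estimate_or_counts <- function(n1, n0, method) {
  if (method == "allele_table") {
    or <- allele_table_or(n1, n0)
    return(or)
  }
  # degenerate designs (all mass at one genotype) cannot identify a slope
  tot <- n1 + n0
  if (sum(tot > 0) < 2L || all(n1 == 0) || all(n0 == 0))
    return(allele_table_or(n1, n0, force_correct = TRUE))
  fit <- wlogit_genotype(n1, n0)
  if (!fit$converged)
    return(allele_table_or(n1, n0, force_correct = TRUE))
  structure(exp(fit$slope), corrected = FALSE)
}

# 2x2 allele-table OR with Haldane-Anscombe +0.5 on any zero cell
allele_table_or <- function(n1, n0, force_correct = FALSE) {
  x <- 0:2
  a <- sum(x * n1)            # risk alleles in cases
  b <- 2 * sum(n1) - a        # non-risk alleles in cases
  cc <- sum(x * n0)           # risk alleles in controls
  d <- 2 * sum(n0) - cc
  corrected <- force_correct
  if (any(c(a, b, cc, d) == 0)) {
    a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5
    corrected <- TRUE
  }
  structure((a * d) / (b * cc), corrected = corrected)
}

#' Median odds ratio over repeated case-control samples
#'
#' Repeats [sample_fixed_effect_cohort()] + [estimate_or()] and reports
#' the median estimated odds ratio, which for many replicates
#' approximates the asymptotic marginal odds ratio of single-SNP
#' analysis.  Replicate r uses a substream seed derived once from the
#' master seed, so the experiment is a pure function of (parameters,
#' seed).
#'
#' @param model A calibrated [fixed_effect_model()].
#' @param n_replicates Number of case-control samples (default 10000).
#' @param n_cases,n_controls Stratum sizes (defaults 1750/1750).
#' @param method OR estimator, as in [estimate_or()].
#' @param seed Master seed.
#' @param keep_replicates Keep the per-replicate OR vector?
#' @return An object of class `median_or_result`: list with `or_true`,
#'   `or_median`, `n_replicates`, `n_corrected` (separation-corrected
#'   replicates), and optionally `replicate_ors`.
#' @export
median_or_experiment <- function(model, n_replicates = 10000L,
                                 n_cases = 1750L, n_controls = 1750L,
                                 method = c("logistic", "allele_table"),
                                 seed = 1L, keep_replicates = FALSE) {
  method <- match.arg(method)
  stopifnot(n_replicates >= 1L)
  fd <- focal_genotype_distribution(model)
  seeds <- local_seed(seed,
                      sample.int(.Machine$integer.max, n_replicates))
  ors <- numeric(n_replicates)
  corrected <- logical(n_replicates)
  for (r in seq_len(n_replicates)) {
    s <- sample_fixed_effect_cohort(model, n_cases, n_controls,
                                    seed = seeds[r], focal_dist = fd)
    est <- estimate_or(s, method = method)
    ors[r] <- est
    corrected[r] <- isTRUE(attr(est, "corrected"))
  }
  structure(
    list(or_true = exp(model$beta), or_median = stats::median(ors),
         n_replicates = n_replicates, n_corrected = sum(corrected),
         replicate_ors = if (keep_replicates) ors else NULL),
    class = "median_or_result")
}

#' @export
print.median_or_result <- function(x, ...) {
  cat(sprintf(
    "Median single-SNP OR over %d replicates: %.4f (true conditional OR %.4f)\n",
    x$n_replicates, x$or_median, x$or_true))
  if (x$n_corrected > 0)
    cat(sprintf("  %d replicate(s) used the corrected allele-table fallback\n",
                x$n_corrected))
  invisible(x)
}

#' Draw a heterogeneous genetic architecture
#'
#' Per-SNP log odds ratios are i.i.d. Exponential(rate) -- small
#' effects frequent, large effects rare; with the default rate 5 the
#' mean log OR is 0.2 and the expected allelic OR is
#' rate/(rate - 1) = 1.25.  Allele frequencies are i.i.d.
#' Uniform(maf_low, maf_high), avoiding rare variants by default.
#' The architecture is drawn once and then held fixed across all
#' simulation replicates.
#'
#' @param n_snps Number of risk SNPs (default 100).
#' @param exp_rate Rate of the exponential effect-size distribution
#'   (default 5; must exceed 1 for the expected OR to be finite).
#' @param maf_low,maf_high Allele-frequency bounds (defaults 0.05, 0.95).
#' @param seed Integer seed.
#' @return List with numeric vectors `betas` and `freqs`.
#' @export
draw_architecture <- function(n_snps = 100L, exp_rate = 5,
                              maf_low = 0.05, maf_high = 0.95,
                              seed = 1L) {
  stopifnot(n_snps >= 1L, 0 < maf_low, maf_low < maf_high, maf_high < 1)
  if (exp_rate <= 1)
    warning("exp_rate <= 1: expected allelic odds ratio is infinite")
  local_seed(seed, list(
    betas = stats::rexp(n_snps, rate = exp_rate),
    freqs = stats::runif(n_snps, maf_low, maf_high)))
}

#' Rejection-sample a case-control cohort (heterogeneous model)
#'
#' Draws subjects until the case and control quotas are filled.
#' `proposal = "population"` is the direct scheme: genotypes
#' g_j ~ Binomial(2, p_j), disease Y ~ Bernoulli(logistic(b0 + score)),
#' subjects kept in draw order; it needs about n_cases/K draws.
#' `proposal = "tilted"` draws each stratum from exactly the same
#' conditional laws P(genotypes | Y) with high acceptance: case
#' candidates come from per-SNP exponentially tilted binomials
#' (success probability p e^b / (p e^b + 1 - p)) and control
#' candidates from the population distribution, and a candidate of
#' either stratum is accepted with probability
#' 1 / (1 + exp(b0 + score)).  The two proposals are distributionally
#' identical; "tilted" is the default for large experiments.
#'
#' @param model A calibrated [heterogeneous_model()].
#' @param n_cases,n_controls Stratum sizes (defaults 2500/2500).
#' @param seed Optional integer seed.
#' @param proposal `"tilted"` (default) or `"population"`.
#' @param max_draws Iteration guard against miscalibrated models
#'   (default 1e9).
#' @return A `case_control_sample` with genotype matrices and
#'   attribute `n_draws` (total proposal draws consumed).
#' @export
rejection_sample_cohort <- function(model, n_cases = 2500L,
                                    n_controls = 2500L, seed = NULL,
                                    proposal = c("tilted", "population"),
                                    max_draws = 1e9) {
  proposal <- match.arg(proposal)
  stopifnot(inherits(model, "heterogeneous_model"),
            n_cases >= 1L, n_controls >= 1L)
  run <- function() {
    if (proposal == "population")
      cohort_population_rejection(model, n_cases, n_controls, max_draws)
    else
      cohort_tilted_rejection(model, n_cases, n_controls, max_draws)
  }
  if (is.null(seed)) run() else local_seed(seed, run())
}

# draw an n x S genotype matrix, SNP j ~ Binomial(2, p[j])
draw_genotype_matrix <- function(n, p) {
  S <- length(p)
  matrix(stats::rbinom(n * S, 2L, rep(p, each = n)), nrow = n, ncol = S)
}

cohort_population_rejection <- function(model, n_cases, n_controls,
                                        max_draws) {
  S <- length(model$betas)
  cases <- matrix(0L, 0L, S); controls <- matrix(0L, 0L, S)
  total <- 0L
  chunk <- max(1024L, min(65536L,
                          as.integer(ceiling(n_cases / model$prevalence / 8))))
  while ((nrow(cases) < n_cases || nrow(controls) < n_controls)) {
    if (total >= max_draws)
      stop("max_draws exceeded; is the model calibrated?")
    G <- draw_genotype_matrix(chunk, model$freqs)
    prob <- stats::plogis(model$intercept + as.vector(G %*% model$betas))
    y <- stats::rbinom(chunk, 1L, prob)
    need_ca <- n_cases - nrow(cases)
    need_co <- n_controls - nrow(controls)
    idx_ca <- which(y == 1L); idx_co <- which(y == 0L)
    take_ca <- idx_ca[seq_len(min(need_ca, length(idx_ca)))]
    take_co <- idx_co[seq_len(min(need_co, length(idx_co)))]
    # draws consumed sequentially: stop at the subject that fills the
    # last open quota; later subjects in the chunk are never drawn
    fill_at <- max(if (need_ca > 0 && length(idx_ca) >= need_ca)
                     idx_ca[need_ca] else if (need_ca > 0) chunk else 0L,
                   if (need_co > 0 && length(idx_co) >= need_co)
                     idx_co[need_co] else if (need_co > 0) chunk else 0L)
    total <- total + fill_at
    cases <- rbind(cases, G[take_ca, , drop = FALSE])
    controls <- rbind(controls, G[take_co, , drop = FALSE])
  }
  out <- new_case_control_sample(cases, controls)
  attr(out, "n_draws") <- total
  out
}

cohort_tilted_rejection <- function(model, n_cases, n_controls,
                                    max_draws) {
  p <- model$freqs; b <- model$betas; b0 <- model$intercept
  p_tilt <- p * exp(b) / (p * exp(b) + 1 - p)
  fill <- function(n_target, prop_freqs, total0) {
    kept <- matrix(0L, 0L, length(p)); total <- total0
    while (nrow(kept) < n_target) {
      if (total >= max_draws)
        stop("max_draws exceeded; is the model calibrated?")
      need <- n_target - nrow(kept)
      chunk <- as.integer(ceiling(need * 1.1) + 16L)
      G <- draw_genotype_matrix(chunk, prop_freqs)
      s <- as.vector(G %*% b)
      acc <- stats::runif(chunk) < stats::plogis(-(b0 + s))
      take <- which(acc)[seq_len(min(need, sum(acc)))]
      kept <- rbind(kept, G[take, , drop = FALSE])
      total <- total + chunk
    }
    list(kept = kept, total = total)
  }
  ca <- fill(n_cases, p_tilt, 0L)
  co <- fill(n_controls, p, ca$total)
  out <- new_case_control_sample(ca$kept, co$kept)
  attr(out, "n_draws") <- co$total
  out
}

#' Per-SNP median odds ratios under the heterogeneous architecture
#'
#' Generates repeated case-control cohorts from a heterogeneous model
#' and, for each SNP, reports the median single-SNP logistic odds
#' ratio across replicates alongside its true conditional odds ratio
#' exp(beta_j).
#'
#' @param model A calibrated [heterogeneous_model()].
#' @param n_replicates Number of cohorts (default 10000).
#' @param n_cases,n_controls Stratum sizes (defaults 2500/2500:
#'   5,000-subject cohorts at 1:1).
#' @param seed Master seed (replicates use derived substream seeds).
#' @param snps Integer vector of SNP indices to estimate (default all).
#' @param method OR estimator, as in [estimate_or()].
#' @param proposal Sampler proposal, as in [rejection_sample_cohort()].
#' @param keep_replicates Keep the replicate x SNP OR matrix?
#' @return A data frame of class `heterogeneous_or_result` with one row
#'   per SNP: `snp`, `or_true`, `or_median`, `n_corrected`; the number
#'   of replicates and (optionally) the replicate OR matrix are
#'   attached as attributes `n_replicates` / `replicate_ors`.
#' @export
heterogeneous_experiment <- function(model, n_replicates = 10000L,
                                     n_cases = 2500L, n_controls = 2500L,
                                     seed = 1L, snps = NULL,
                                     method = c("logistic", "allele_table"),
                                     proposal = c("tilted", "population"),
                                     keep_replicates = FALSE) {
  method <- match.arg(method)
  proposal <- match.arg(proposal)
  S <- length(model$betas)
  if (is.null(snps)) snps <- seq_len(S)
  stopifnot(all(snps >= 1L), all(snps <= S), n_replicates >= 1L)
  seeds <- local_seed(seed,
                      sample.int(.Machine$integer.max, n_replicates))
  ors <- matrix(NA_real_, n_replicates, length(snps))
  corrected <- matrix(FALSE, n_replicates, length(snps))
  for (r in seq_len(n_replicates)) {
    coh <- rejection_sample_cohort(model, n_cases, n_controls,
                                   seed = seeds[r], proposal = proposal)
    for (k in seq_along(snps)) {
      est <- estimate_or(coh, method = method, snp = snps[k])
      ors[r, k] <- est
      corrected[r, k] <- isTRUE(attr(est, "corrected"))
    }
  }
  out <- data.frame(snp = snps,
                    or_true = exp(model$betas[snps]),
                    or_median = apply(ors, 2L, stats::median),
                    n_corrected = colSums(corrected))
  attr(out, "n_replicates") <- n_replicates
  if (keep_replicates) attr(out, "replicate_ors") <- ors
  class(out) <- c("heterogeneous_or_result", "data.frame")
  out
}
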