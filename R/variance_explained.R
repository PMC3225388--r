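#' McKelvey-Zavoina explained variance on the log-odds scale
#'
#' For a logistic disease model with linear predictor
#' b0 + sum_j beta_j g_j, the McKelvey-Zavoina pseudo-R-squared is
#' V / (V + pi^2/3), where V = sum_j beta_j^2 * 2 p_j (1 - p_j) is the
#' variance of the genetic score under Hardy-Weinberg and linkage
#' equilibrium and pi^2/3 is the variance of the standard logistic
#' error distribution.  For the equal-effects model with m effect
#' alleles this reduces to V = beta^2 * m * p (1 - p).
#'
#' @param betas Per-SNP log odds ratios (scalar recycled against
#'   `freqs`).
#' @param freqs Per-SNP risk allele frequencies in (0, 1).
#' @return Proportion of explained variance in \[0, 1).
#' @examples
#' mz_r2(rep(log(1.6), 100), rep(0.25, 100))
#' @export
mz_r2 <- function(betas, freqs) {
  if (length(betas) == 1L) betas <- rep(betas, length(freqs))
  stopifnot(length(betas) == length(freqs),
            all(freqs > 0), all(freqs < 1))
  v <- sum(betas^2 * 2 * freqs * (1 - freqs))
  v / (v + pi^2 / 3)
}

#' Effect size achieving a target explained variance
#'
#' Inverse of [mz_r2()] for the equal-effects model: the per-allele
#' log odds ratio beta such that a disease with m effect alleles of
#' frequency p has McKelvey-Zavoina R-squared equal to `target_r2`:
#' beta = sqrt(target_r2 * (pi^2/3) / ((1 - target_r2) * m * p * (1 - p))).
#'
#' @param target_r2 Target explained variance, in (0, 1); 0 is allowed
#'   and returns beta = 0.
#' @param risk_allele_freq Risk allele frequency p.
#' @param n_effect_alleles Total effect alleles m.
#' @return The per-allele log odds ratio (numeric scalar).
#' @export
solve_beta_for_r2 <- function(target_r2, risk_allele_freq,
                              n_effect_alleles) {
  stopifnot(target_r2 >= 0, target_r2 < 1,
            risk_allele_freq > 0, risk_allele_freq < 1)
  if (target_r2 == 0) return(0)
  vpg <- n_effect_alleles * risk_allele_freq * (1 - risk_allele_freq)
  sqrt(target_r2 * (pi^2 / 3) / ((1 - target_r2) * vpg))
}

#' Loss of explained variance due to single-SNP estimation
#'
#' Builds an equal-effects disease model (either from a target true
#' R-squared or from an explicit odds ratio), simulates the median
#' single-SNP odds ratio, and plugs the median estimated log odds
#' ratio into the same McKelvey-Zavoina formula with the true allele
#' frequencies.  Because marginal estimates are attenuated toward 1,
#' the estimated explained variance falls short of the true one; the
#' shortfall is the non-collapsibility contribution to missing
#' heritability.
#'
#' @param prevalence Disease prevalence.
#' @param target_r2 True explained variance to model (used to solve
#'   beta); alternatively give `or_true`.
#' @param or_true True conditional odds ratio (alternative to
#'   `target_r2`).
#' @param risk_allele_freq Risk allele frequency.
#' @param n_effect_alleles Total effect alleles m.
#' @param n_replicates,n_cases,n_controls,method,seed Simulation
#'   settings passed to [median_or_experiment()].
#' @param asymptotic If `TRUE`, skip simulation and use the analytic
#'   [asymptotic_marginal_or()] for the estimated effect size.
#' @return An object of class `r2_comparison`: list with `or_true`,
#'   `or_est_median`, `r2_true`, `r2_estimated`, `loss_points`
#'   (percentage points, 100 * (r2_true - r2_estimated)),
#'   `loss_relative`, and `n_corrected`.
#' @export
r2_loss_experiment <- function(prevalence, target_r2 = NULL,
                               or_true = NULL, risk_allele_freq,
                               n_effect_alleles,
                               n_replicates = 10000L, n_cases = 1750L,
                               n_controls = 1750L,
                               method = c("logistic", "allele_table"),
                               seed = 1L, asymptotic = FALSE) {
  method <- match.arg(method)
  if (is.null(target_r2) == is.null(or_true))
    stop("supply exactly one of `target_r2` and `or_true`")
  beta <- if (!is.null(target_r2))
    solve_beta_for_r2(target_r2, risk_allele_freq, n_effect_alleles)
  else log(or_true)
  freqs <- rep(risk_allele_freq, n_effect_alleles %/% 2L)
  r2_true <- mz_r2(rep(beta, length(freqs)), freqs)
  if (beta == 0) {
    or_est <- 1.0
    n_corrected <- 0L
  } else {
    model <- fixed_effect_model(prevalence, beta = beta,
                                risk_allele_freq = risk_allele_freq,
                                n_effect_alleles = n_effect_alleles)
    if (asymptotic) {
      or_est <- asymptotic_marginal_or(model)
      n_corrected <- 0L
    } else {
      res <- median_or_experiment(model, n_replicates = n_replicates,
                                  n_cases = n_cases,
                                  n_controls = n_controls,
                                  method = method, seed = seed)
      or_est <- res$or_median
      n_corrected <- res$n_corrected
    }
  }
  r2_est <- mz_r2(rep(log(or_est), length(freqs)), freqs)
  structure(
    list(or_true = exp(beta), or_est_median = or_est,
         r2_true = r2_true, r2_estimated = r2_est,
         loss_points = 100 * (r2_true - r2_est),
         loss_relative = if (r2_true > 0) (r2_true - r2_est) / r2_true
                         else 0,
         n_corrected = n_corrected),
    class = "r2_comparison")
}

#' @export
print.r2_comparison <- function(x, ...) {
  cat("McKelvey-Zavoina explained variance (log-odds scale)\n")
  cat(sprintf("  true OR %.4f -> R2 = %.4f\n", x$or_true, x$r2_true))
  cat(sprintf("  est. OR %.4f -> R2 = %.4f\n", x$or_est_median,
              x$r2_estimated))
  cat(sprintf("  loss: %.2f percentage points (%.1f%% relative)\n",
              x$loss_points, 100 * x$loss_relative))
  invisible(x)
}
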