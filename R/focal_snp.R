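#' Genotype distribution of a focal SNP given disease status
#'
#' Splits the total risk-allele count G into the focal SNP's allele
#' count X in \{0, 1, 2\} and the background count Z = G - X.  Under
#' linkage equilibrium X ~ Binomial(2, p_a) independent of
#' Z ~ Binomial(m - 2, p_a), so by Bayes' rule
#' \deqn{P(X = x \mid Y = y) \propto
#'   \mathrm{Binom}(x; 2, p_a) \sum_z P(Y = y \mid G = x + z)\,
#'   \mathrm{Binom}(z; m - 2, p_a).}
#' This is the exact distribution single-SNP case-control sampling
#' draws from; the sum over the background is computed in log-space.
#'
#' @param model A calibrated [fixed_effect_model()] with m >= 2.
#' @param y Disease status, 0 (control) or 1 (case).
#' @return Numeric probability vector of length 3 (x = 0, 1, 2).
#' @export
focal_genotype_pmf <- function(model, y) {
  stopifnot(inherits(model, "fixed_effect_model"),
            length(y) == 1L, y %in% c(0L, 1L))
  m <- model$n_effect_alleles
  if (m < 2) stop("focal SNP requires n_effect_alleles >= 2")
  p <- model$risk_allele_freq
  z <- 0:(m - 2L)
  lbz <- stats::dbinom(z, m - 2L, p, log = TRUE)
  logp <- vapply(0:2, function(x) {
    eta <- model$intercept + model$beta * (x + z)
    lpen <- if (y == 1L) stats::plogis(eta, log.p = TRUE)
            else stats::plogis(eta, log.p = TRUE, lower.tail = FALSE)
    stats::dbinom(x, 2L, p, log = TRUE) + logsumexp(lbz + lpen)
  }, numeric(1))
  out <- exp(logp - logsumexp(logp))
  out / sum(out)
}

#' Case and control genotype distributions of the focal SNP
#'
#' @param model A calibrated [fixed_effect_model()].
#' @return An object of class `focal_genotype_distribution`: list with
#'   `probs_case` and `probs_control`, each a probability vector over
#'   x = 0, 1, 2.
#' @export
focal_genotype_distribution <- function(model) {
  structure(
    list(probs_case = focal_genotype_pmf(model, 1L),
         probs_control = focal_genotype_pmf(model, 0L)),
    class = "focal_genotype_distribution")
}

#' @export
print.focal_genotype_distribution <- function(x, ...) {
  m <- rbind(case = x$probs_case, control = x$probs_control)
  colnames(m) <- paste0("x=", 0:2)
  cat("Focal SNP genotype distribution by disease status\n")
  print(round(m, 6))
  invisible(x)
}

#' Asymptotic marginal odds ratio of the focal SNP
#'
#' The large-sample limit of the single-SNP per-allele logistic odds
#' ratio in a case-control study: the weighted maximum-likelihood
#' logistic fit to the exact three-point genotype design x in
#' \{0, 1, 2\}, with design weights case_fraction * P(x | Y = 1) for
#' cases and (1 - case_fraction) * P(x | Y = 0) for controls.  For a
#' single-SNP disease (m = 2) this equals the conditional odds ratio
#' exp(beta); for polygenic backgrounds (m > 2, beta > 0) it is
#' strictly smaller -- the non-collapsibility attenuation.
#'
#' @param model A calibrated [fixed_effect_model()].
#' @param case_fraction Proportion of cases in the study design
#'   (default 0.5, a 1:1 case-control ratio).
#' @return The asymptotic marginal odds ratio (numeric scalar).
#' @export
asymptotic_marginal_or <- function(model, case_fraction = 0.5) {
  stopifnot(case_fraction > 0, case_fraction < 1)
  if (model$beta == 0) return(1.0)
  d <- focal_genotype_distribution(model)
  w1 <- case_fraction * d$probs_case
  w0 <- (1 - case_fraction) * d$probs_control
  keep <- (w1 + w0) > 1e-14
  if (!all(keep))
    warning("degenerate design point(s) dropped from the asymptotic fit")
  fit <- wlogit_genotype(n1 = w1[keep], n0 = w0[keep], x = (0:2)[keep])
  exp(fit$slope)
}

# Weighted per-allele logistic ML fit on the collapsed genotype design.
# n1, n0: (possibly fractional) case/control weights at genotypes x.
# Returns slope/intercept and a convergence flag; used both for the
# asymptotic design and for per-replicate 3x2 count tables.
wlogit_genotype <- function(n1, n0, x = 0:2) {
  yy <- c(rep(1, length(x)), rep(0, length(x)))
  xx <- c(x, x)
  ww <- c(n1, n0)
  pos <- ww > 0
  fit <- suppressWarnings(
    stats::glm.fit(cbind(1, xx[pos]), yy[pos], weights = ww[pos],
                   family = stats::binomial()))
  co <- stats::coef(fit)
  list(intercept = co[[1]], slope = co[[2]],
       converged = fit$converged && all(is.finite(co)) && abs(co[[2]]) < 15)
}
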