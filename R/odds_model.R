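#' Multi-locus odds model of dichotomous disease
#'
#' Disease status Y is generated from the total number of risk alleles G
#' through a logistic penetrance function
#' \deqn{P(Y = 1 \mid G = g) = \mathrm{logistic}(\beta_0 + \beta g),}
#' while G follows Binomial(m, p_a) under Hardy-Weinberg and linkage
#' equilibrium.  The model has four user-facing parameters: disease
#' prevalence K, the per-allele (conditional) odds ratio exp(beta), the
#' risk allele frequency p_a, and the total number of effect alleles m
#' (twice the number of risk SNPs).  The intercept beta0 is not a free
#' parameter: it is calibrated so that the model-implied disease
#' probability equals the target prevalence.
#'
#' @param prevalence Target disease prevalence K, in (0, 1).
#' @param or_true True conditional per-allele odds ratio exp(beta).
#'   Exactly one of `or_true` and `beta` must be supplied.
#' @param beta Log odds ratio per risk allele.
#' @param risk_allele_freq Risk allele frequency p_a, in (0, 1).
#' @param n_effect_alleles Total number of effect alleles m (an even
#'   integer >= 2; m/2 risk SNPs).
#'
#' @return An object of class `fixed_effect_model`: a list with elements
#'   `prevalence`, `beta`, `risk_allele_freq`, `n_effect_alleles` and the
#'   calibrated `intercept`.
#'
#' @examples
#' m <- fixed_effect_model(prevalence = 0.01, or_true = 1.6,
#'                         risk_allele_freq = 0.25, n_effect_alleles = 200)
#' penetrance(m, 50)
#' @seealso [penetrance()], [joint_pmf()], [solve_intercept()]
#' @export
fixed_effect_model <- function(prevalence, or_true = NULL, beta = NULL,
                               risk_allele_freq, n_effect_alleles) {
  if (is.null(beta) == is.null(or_true))
    stop("supply exactly one of `beta` and `or_true`")
  if (is.null(beta)) beta <- log(or_true)
  stopifnot(is.numeric(prevalence), length(prevalence) == 1L,
            prevalence > 0, prevalence < 1,
            is.numeric(beta), length(beta) == 1L, is.finite(beta),
            is.numeric(risk_allele_freq), length(risk_allele_freq) == 1L,
            risk_allele_freq > 0, risk_allele_freq < 1)
  m <- n_effect_alleles
  if (length(m) != 1L || m != round(m) || m < 2 || m %% 2 != 0)
    stop("`n_effect_alleles` must be an even integer >= 2")
  m <- as.integer(m)
  intercept <- solve_intercept(prevalence, beta, risk_allele_freq, m)
  structure(
    list(prevalence = prevalence, beta = beta,
         risk_allele_freq = risk_allele_freq, n_effect_alleles = m,
         intercept = intercept),
    class = "fixed_effect_model")
}

#' @export
print.fixed_effect_model <- function(x, ...) {
  cat("Multi-locus odds model (equal effects)\n")
  cat(sprintf("  prevalence K        : %g\n", x$prevalence))
  cat(sprintf("  conditional OR      : %g  (beta = %g)\n",
              exp(x$beta), x$beta))
  cat(sprintf("  risk allele freq p_a: %g\n", x$risk_allele_freq))
  cat(sprintf("  effect alleles m    : %d  (%d risk SNPs)\n",
              x$n_effect_alleles, x$n_effect_alleles %/% 2L))
  cat(sprintf("  calibrated intercept: %.6f\n", x$intercept))
  invisible(x)
}

#' Heterogeneous-architecture odds model
#'
#' Extension of the equal-effects model in which each risk SNP j has its
#' own log odds ratio beta_j and risk allele frequency p_j; the linear
#' predictor is beta0 + sum_j beta_j g_j with g_j ~ Binomial(2, p_j)
#' independent across SNPs.  The intercept is calibrated to the target
#' prevalence by Monte-Carlo bisection over a fixed population of score
#' draws (common random numbers, so the result is deterministic given
#' the seed).
#'
#' @param prevalence Target disease prevalence, in (0, 1).
#' @param betas Numeric vector of per-SNP log odds ratios.
#' @param freqs Numeric vector of per-SNP risk allele frequencies, each
#'   in (0, 1); same length as `betas`.
#' @param n_draws Number of Monte-Carlo score draws used for intercept
#'   calibration (default 1e6).
#' @param seed Integer seed for the calibration draws.
#'
#' @return An object of class `heterogeneous_model`: a list with
#'   elements `prevalence`, `betas`, `freqs`, `intercept`, and
#'   `calibration` (n_draws, seed, achieved Monte-Carlo prevalence).
#' @examples
#' arch <- draw_architecture(n_snps = 20, seed = 1)
#' hm <- heterogeneous_model(0.01, arch$betas, arch$freqs,
#'                           n_draws = 1e5, seed = 2)
#' @export
heterogeneous_model <- function(prevalence, betas, freqs,
                                n_draws = 1e6, seed = 1L) {
  stopifnot(length(betas) == length(freqs), length(betas) >= 1L,
            all(is.finite(betas)), all(freqs > 0), all(freqs < 1),
            prevalence > 0, prevalence < 1)
  cal <- solve_intercept_mc(betas, freqs, prevalence,
                            n_draws = n_draws, seed = seed)
  structure(
    list(prevalence = prevalence, betas = as.numeric(betas),
         freqs = as.numeric(freqs), intercept = cal$intercept,
         calibration = cal[c("n_draws", "seed", "achieved_prevalence")]),
    class = "heterogeneous_model")
}

#' @export
print.heterogeneous_model <- function(x, ...) {
  cat("Multi-locus odds model (heterogeneous effects)\n")
  cat(sprintf("  prevalence K        : %g (MC achieved %.6f)\n",
              x$prevalence, x$calibration$achieved_prevalence))
  cat(sprintf("  risk SNPs           : %d\n", length(x$betas)))
  cat(sprintf("  OR range            : %.3f .. %.3f\n",
              exp(min(x$betas)), exp(max(x$betas))))
  cat(sprintf("  calibrated intercept: %.6f\n", x$intercept))
  invisible(x)
}

#' Penetrance: probability of disease given risk-allele count
#'
#' @param model A calibrated [fixed_effect_model()].
#' @param g Integer vector of total risk-allele counts, each in
#'   0..m.
#' @return Numeric vector of disease probabilities
#'   logistic(beta0 + beta * g).
#' @export
penetrance <- function(model, g) {
  stopifnot(inherits(model, "fixed_effect_model"))
  if (any(g < 0 | g > model$n_effect_alleles | g != round(g)))
    stop("`g` must be integer(s) in 0..n_effect_alleles")
  stats::plogis(model$intercept + model$beta * g)
}

#' Population distribution of the total risk-allele count
#'
#' Under Hardy-Weinberg and linkage equilibrium the total risk-allele
#' count G over m effect alleles is Binomial(m, p_a).
#'
#' @param model A [fixed_effect_model()].
#' @return Numeric vector of length m + 1 with P(G = g), g = 0..m.
#' @export
allele_count_pmf <- function(model) {
  stopifnot(inherits(model, "fixed_effect_model"))
  stats::dbinom(0:model$n_effect_alleles, model$n_effect_alleles,
                model$risk_allele_freq)
}

#' Joint distribution of disease status and risk-allele count
#'
#' @param model A calibrated [fixed_effect_model()].
#' @return A 2 x (m + 1) matrix with rows `y0`, `y1` and entries
#'   P(Y = y, G = g); entries sum to 1 and the `y1` row sums to the
#'   model prevalence.
#' @export
joint_pmf <- function(model) {
  pg <- allele_count_pmf(model)
  pen <- penetrance(model, 0:model$n_effect_alleles)
  out <- rbind(y0 = (1 - pen) * pg, y1 = pen * pg)
  colnames(out) <- as.character(0:model$n_effect_alleles)
  out
}

#' Calibrate the model intercept to a target prevalence (exact path)
#'
#' Finds beta0 such that the model-implied disease probability
#' sum_g logistic(beta0 + beta g) Binom(g; m, p_a) equals the target
#' prevalence.  The prevalence is strictly increasing in beta0, so the
#' root is unique; it is found by bisection/interpolation (uniroot) on
#' the bracket [-60, 60].
#'
#' @param prevalence Target prevalence, in (0, 1).
#' @param beta Log odds ratio per risk allele.
#' @param risk_allele_freq Risk allele frequency, in (0, 1).
#' @param n_effect_alleles Total number of effect alleles m.
#' @param tol Convergence tolerance on the prevalence scale
#'   (default 1e-12; the achieved |prevalence error| is checked
#'   against 1e-10).
#' @return The calibrated intercept beta0 (numeric scalar).
#' @export
solve_intercept <- function(prevalence, beta, risk_allele_freq,
                            n_effect_alleles, tol = 1e-12) {
  stopifnot(prevalence > 0, prevalence < 1)
  m <- as.integer(n_effect_alleles)
  lw <- stats::dbinom(0:m, m, risk_allele_freq, log = TRUE)
  # model prevalence as a function of the intercept, in log-space:
  # log K(b0) = logsumexp(log Binom(g) + log logistic(b0 + beta g))
  prev_fun <- function(b0)
    exp(logsumexp(lw + stats::plogis(b0 + beta * (0:m), log.p = TRUE)))
  # the root satisfies b0 in [logit(K) - max(beta g), logit(K) - min(beta g)];
  # widen the +-60 baseline bracket by the span of the genetic score
  span <- abs(beta) * m
  lo <- -60 - span; hi <- 60 + span
  if (prev_fun(lo) > prevalence || prev_fun(hi) < prevalence)
    stop("calibration failure: prevalence root not bracketed")
  root <- stats::uniroot(function(b0) prev_fun(b0) - prevalence,
                         lower = lo, upper = hi,
                         f.lower = prev_fun(lo) - prevalence,
                         f.upper = prev_fun(hi) - prevalence,
                         tol = 1e-14, maxiter = 2000L)$root
  # polish by a few Newton steps on the monotone prevalence function
  for (i in 1:6) {
    p <- prev_fun(root)
    dp <- sum(exp(lw) * stats::plogis(root + beta * (0:m)) *
                stats::plogis(-(root + beta * (0:m))))
    if (dp <= 0) break
    step <- (prevalence - p) / dp
    root <- root + step
    if (abs(step) < 1e-15) break
  }
  if (abs(prev_fun(root) - prevalence) > 1e-10)
    stop("calibration failure: residual prevalence error above 1e-10")
  root
}

#' Calibrate the intercept of a heterogeneous model (Monte-Carlo path)
#'
#' Draws a fixed population of n_draws genetic scores
#' sum_j beta_j g_j with g_j ~ Binomial(2, p_j), then bisects beta0 on
#' the Monte-Carlo mean of logistic(beta0 + score) over those same
#' draws (common random numbers) until the mean matches the target
#' prevalence to within `tol`.
#'
#' @param betas Per-SNP log odds ratios.
#' @param freqs Per-SNP risk allele frequencies.
#' @param prevalence Target prevalence.
#' @param n_draws Number of score draws (>= 1e5 recommended).
#' @param seed Integer seed for the draws.
#' @param tol Tolerance on |MC prevalence - target| (default 1e-6).
#' @return List with `intercept`, `achieved_prevalence`, `n_draws`,
#'   `seed`, and `mc_se` (the Monte-Carlo standard error of the
#'   prevalence estimate at the solution).
#' @export
solve_intercept_mc <- function(betas, freqs, prevalence,
                               n_draws = 1e6, seed = 1L, tol = 1e-6) {
  stopifnot(length(betas) == length(freqs), prevalence > 0, prevalence < 1)
  n_draws <- as.integer(n_draws)
  scores <- local_seed(seed, draw_scores(betas, freqs, n_draws))
  prev_fun <- function(b0) mean(stats::plogis(b0 + scores))
  span <- 2 * sum(abs(betas))
  lo <- -60 - span; hi <- 60 + span
  if (prev_fun(lo) > prevalence || prev_fun(hi) < prevalence)
    stop("calibration failure: prevalence root not bracketed")
  while (hi - lo > 1e-11) {
    mid <- (lo + hi) / 2
    if (prev_fun(mid) < prevalence) lo <- mid else hi <- mid
  }
  b0 <- (lo + hi) / 2
  ach <- prev_fun(b0)
  if (abs(ach - prevalence) > tol)
    stop("calibration failure: residual MC prevalence error above tol")
  pi_hat <- stats::plogis(b0 + scores)
  list(intercept = b0, achieved_prevalence = ach,
       n_draws = n_draws, seed = as.integer(seed),
       mc_se = stats::sd(pi_hat) / sqrt(n_draws))
}

# draw n genetic scores sum_j beta_j g_j, g_j ~ Binomial(2, p_j)
draw_scores <- function(betas, freqs, n) {
  s <- numeric(n)
  for (j in seq_along(betas))
    s <- s + betas[j] * stats::rbinom(n, 2L, freqs[j])
  s
}

# numerically stable log(sum(exp(x)))
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# evaluate `expr` under a temporary RNG state seeded with `seed`
local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Model-implied disease prevalence
#'
#' @param model A `fixed_effect_model` or `heterogeneous_model`.
#' @return For the fixed-effects model, the exact model prevalence
#'   sum_g P(Y = 1 | g) P(g); for the heterogeneous model, the
#'   Monte-Carlo estimate achieved at calibration.
#' @export
model_prevalence <- function(model) {
  if (inherits(model, "fixed_effect_model"))
    return(sum(joint_pmf(model)["y1", ]))
  if (inherits(model, "heterogeneous_model"))
    return(model$calibration$achieved_prevalence)
  stop("unsupported model class")
}
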