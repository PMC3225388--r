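test_that("fixed-effects cohorts have the right sizes and are reproducible", {
  m <- fig1_model()
  s <- sample_fixed_effect_cohort(m, 1750L, 1750L, seed = 5L)
  expect_s3_class(s, "case_control_sample")
  expect_identical(sum(s$case_genotype_counts), 1750L)
  expect_identical(sum(s$control_genotype_counts), 1750L)
  s2 <- sample_fixed_effect_cohort(m, 1750L, 1750L, seed = 5L)
  expect_identical(s, s2)
  s3 <- sample_fixed_effect_cohort(m, 1750L, 1750L, seed = 6L)
  expect_false(identical(s, s3))
})

test_that("null-model cohorts converge to HWE genotype frequencies", {
  m0 <- fixed_effect_model(0.1, beta = 0, risk_allele_freq = 0.25,
                           n_effect_alleles = 100L)
  s <- sample_fixed_effect_cohort(m0, 2e4, 2e4, seed = 3L)
  hwe <- dbinom(0:2, 2, 0.25)
  expect_equal(as.numeric(s$case_genotype_counts) / 2e4, hwe,
               tolerance = 0.02)
  expect_equal(as.numeric(s$control_genotype_counts) / 2e4, hwe,
               tolerance = 0.02)
})

test_that("odds-ratio estimators agree with direct arithmetic", {
  # allele table: cases 100 risk/100 non-risk, controls 50/150 -> OR 3
  s <- new_sample_from_counts(c(50, 0, 50), c(75, 0, 25))
  expect_equal(as.numeric(estimate_or(s, method = "allele_table")), 3.0)
  # identical strata: no association, both methods
  s1 <- new_sample_from_counts(c(30, 40, 30), c(30, 40, 30))
  expect_equal(as.numeric(estimate_or(s1, "allele_table")), 1.0)
  expect_equal(as.numeric(estimate_or(s1, "logistic")), 1.0,
               tolerance = 1e-8)
})

test_that("logistic OR matches an independent grid-search ML fit", {
  n1 <- c(300, 800, 650); n0 <- c(520, 880, 350)
  s <- new_sample_from_counts(n1, n0)
  est <- estimate_or(s, "logistic")
  oracle <- oracle_grid_wlogit(n1, n0)
  expect_equal(as.numeric(est), exp(oracle$slope), tolerance = 1e-3)
  expect_false(attr(est, "corrected"))
})

test_that("zero cells and separation fall back to the corrected table OR", {
  # no risk alleles among controls: zero cell in the allele table
  s <- new_sample_from_counts(c(10, 5, 5), c(20, 0, 0))
  est <- estimate_or(s, "allele_table")
  expect_true(attr(est, "corrected"))
  a <- 15.5; b <- 25.5; cc <- 0.5; d <- 40.5
  expect_equal(as.numeric(est), (a * d) / (b * cc))
  # complete separation: logistic flags and falls back
  s2 <- new_sample_from_counts(c(0, 0, 20), c(20, 0, 0))
  est2 <- estimate_or(s2, "logistic")
  expect_true(attr(est2, "corrected"))
  expect_true(is.finite(est2) && est2 > 1)
})

test_that("median OR experiments are calibrated under the null", {
  m0 <- fixed_effect_model(0.05, beta = 0, risk_allele_freq = 0.25,
                           n_effect_alleles = 100L)
  res <- median_or_experiment(m0, n_replicates = 1000L, n_cases = 500L,
                              n_controls = 500L, seed = 11L,
                              keep_replicates = TRUE)
  expect_equal(res$or_median, 1.0, tolerance = 0.02)
  # sign test on the replicate log ORs at alpha = 0.01
  signs <- sum(log(res$replicate_ors) > 0)
  pval <- binom.test(signs, length(res$replicate_ors))$p.value
  expect_gt(pval, 0.01)
})

test_that("single-SNP diseases are estimated without attenuation", {
  m2 <- fixed_effect_model(0.01, or_true = 1.6, risk_allele_freq = 0.25,
                           n_effect_alleles = 2L)
  res <- median_or_experiment(m2, n_replicates = 800L, seed = 21L)
  expect_equal(res$or_median, 1.6, tolerance = 0.02)
})

test_that("experiments are pure functions of parameters and master seed", {
  m <- fig1_model()
  r1 <- median_or_experiment(m, n_replicates = 50L, seed = 17L)
  r2 <- median_or_experiment(m, n_replicates = 50L, seed = 17L)
  expect_identical(r1, r2)
})

test_that("architecture draws follow the exponential/uniform design", {
  a <- draw_architecture(n_snps = 2e4, seed = 8L)
  expect_length(a$betas, 2e4)
  expect_equal(mean(a$betas), 0.2, tolerance = 0.01)        # 1/rate
  expect_equal(mean(exp(a$betas)), 1.25, tolerance = 0.02)  # rate/(rate-1)
  expect_true(all(a$freqs > 0.05 & a$freqs < 0.95))
  expect_identical(a, draw_architecture(n_snps = 2e4, seed = 8L))
  expect_warning(draw_architecture(10L, exp_rate = 0.9, seed = 1L),
                 "infinite")
})

test_that("rejection sampling returns exact stratum sizes", {
  a <- draw_architecture(5L, seed = 2L)
  hm <- heterogeneous_model(0.3, a$betas, a$freqs, n_draws = 5e4, seed = 2L)
  for (prop in c("tilted", "population")) {
    s <- rejection_sample_cohort(hm, 120L, 80L, seed = 9L, proposal = prop)
    expect_identical(nrow(s$case_genotypes), 120L)
    expect_identical(nrow(s$control_genotypes), 80L)
    expect_true(all(s$case_genotypes %in% 0:2))
  }
})

test_that("population rejection consumes about 1/K draws per case", {
  # null effects at 50% prevalence: expected draws ~ n_cases + n_controls
  hm <- heterogeneous_model(0.5, rep(0, 3), rep(0.5, 3),
                            n_draws = 1e4, seed = 1L)
  draws <- vapply(1:20, function(i)
    attr(rejection_sample_cohort(hm, 50L, 50L, seed = i,
                                 proposal = "population"), "n_draws"),
    numeric(1))
  expect_equal(mean(draws), 100, tolerance = 0.15)
  # rarer disease: geometric waiting time ~ n_cases / K
  hm2 <- heterogeneous_model(0.1, rep(0, 3), rep(0.5, 3),
                             n_draws = 1e4, seed = 1L)
  draws2 <- vapply(1:20, function(i)
    attr(rejection_sample_cohort(hm2, 30L, 30L, seed = i,
                                 proposal = "population"), "n_draws"),
    numeric(1))
  expect_equal(mean(draws2), 300, tolerance = 0.25)
})

test_that("tilted and population proposals draw from the same laws", {
  a <- draw_architecture(4L, seed = 13L)
  hm <- heterogeneous_model(0.2, a$betas, a$freqs, n_draws = 1e5, seed = 13L)
  s_t <- rejection_sample_cohort(hm, 2000L, 2000L, seed = 31L,
                                 proposal = "tilted")
  s_p <- rejection_sample_cohort(hm, 2000L, 2000L, seed = 32L,
                                 proposal = "population")
  for (j in 1:4) {
    f_t <- tabulate(s_t$case_genotypes[, j] + 1L, 3L) / 2000
    f_p <- tabulate(s_p$case_genotypes[, j] + 1L, 3L) / 2000
    expect_equal(f_t, f_p, tolerance = 0.06)
  }
})

test_that("tilted case sampling matches the analytic focal distribution", {
  # equal-effects architecture: per-SNP case genotype law is the exact
  # focal-SNP conditional of the equivalent fixed-effects model
  S <- 10L; beta <- log(1.5); p <- 0.3
  hm <- heterogeneous_model(0.05, rep(beta, S), rep(p, S),
                            n_draws = 2e5, seed = 5L)
  fm <- fixed_effect_model(0.05, beta = beta, risk_allele_freq = p,
                           n_effect_alleles = 2L * S)
  s <- rejection_sample_cohort(hm, 20000L, 20000L, seed = 55L)
  f_case <- tabulate(s$case_genotypes[, 3] + 1L, 3L) / 20000
  f_ctrl <- tabulate(s$control_genotypes[, 3] + 1L, 3L) / 20000
  expect_equal(f_case, focal_genotype_pmf(fm, 1L), tolerance = 0.03)
  expect_equal(f_ctrl, focal_genotype_pmf(fm, 0L), tolerance = 0.03)
})

test_that("null heterogeneous experiments estimate OR 1 for every SNP", {
  hm <- heterogeneous_model(0.2, rep(0, 4), c(0.2, 0.4, 0.6, 0.8),
                            n_draws = 1e4, seed = 3L)
  res <- heterogeneous_experiment(hm, n_replicates = 120L, n_cases = 400L,
                                  n_controls = 400L, seed = 41L)
  expect_equal(res$or_true, rep(1, 4))
  expect_equal(res$or_median, rep(1, 4), tolerance = 0.1)
})
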