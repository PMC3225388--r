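# Independent oracles used to freeze expected values.  These deliberately
# avoid the package's own code paths: brute-force enumeration over phased
# allele configurations, dense grid searches, and plain bisection with
# direct (non-log-space) arithmetic.

# joint P(Y, G) by enumerating all 2^m phased allele configurations
oracle_joint_enum <- function(intercept, beta, p, m) {
  stopifnot(m <= 12)
  configs <- as.matrix(expand.grid(rep(list(0:1), m)))
  pr <- apply(configs, 1, function(a) prod(ifelse(a == 1, p, 1 - p)))
  g <- rowSums(configs)
  pen <- 1 / (1 + exp(-(intercept + beta * g)))
  out <- matrix(0, 2, m + 1, dimnames = list(c("y0", "y1"), 0:m))
  for (i in seq_along(g)) {
    out["y1", g[i] + 1] <- out["y1", g[i] + 1] + pr[i] * pen[i]
    out["y0", g[i] + 1] <- out["y0", g[i] + 1] + pr[i] * (1 - pen[i])
  }
  out
}

# P(X = x | Y = y) for the focal SNP by enumerating focal + background alleles
oracle_focal_enum <- function(intercept, beta, p, m, y) {
  stopifnot(m <= 12)
  configs <- as.matrix(expand.grid(rep(list(0:1), m)))
  pr <- apply(configs, 1, function(a) prod(ifelse(a == 1, p, 1 - p)))
  x <- rowSums(configs[, 1:2, drop = FALSE])   # first two alleles are focal
  g <- rowSums(configs)
  pen <- 1 / (1 + exp(-(intercept + beta * g)))
  py <- if (y == 1) pen else 1 - pen
  num <- vapply(0:2, function(k) sum(pr[x == k] * py[x == k]), numeric(1))
  num / sum(num)
}

# intercept calibration by plain bisection on the direct binomial sum
oracle_bisect_intercept <- function(K, beta, p, m, lo = -200, hi = 200) {
  prev <- function(b0)
    sum(dbinom(0:m, m, p) / (1 + exp(-(b0 + beta * (0:m)))))
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (prev(mid) < K) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# intercept calibration by iteratively refined dense grid search
oracle_grid_intercept <- function(K, beta, p, m, lo = -200, hi = 200) {
  prev <- function(b0)
    vapply(b0, function(b)
      sum(dbinom(0:m, m, p) / (1 + exp(-(b + beta * (0:m))))), numeric(1))
  for (i in 1:8) {
    grid <- seq(lo, hi, length.out = 401)
    best <- grid[which.min(abs(prev(grid) - K))]
    step <- (hi - lo) / 400
    lo <- best - step; hi <- best + step
  }
  (lo + hi) / 2
}

# weighted per-allele logistic ML by dense grid search over (b0, b1)
oracle_grid_wlogit <- function(n1, n0, x = 0:2,
                               b0_range = c(-8, 8), b1_range = c(-5, 5)) {
  ll <- function(b0, b1) {
    eta <- b0 + b1 * x
    sum(n1 * plogis(eta, log.p = TRUE) + n0 * plogis(-eta, log.p = TRUE))
  }
  for (i in 1:6) {
    b0s <- seq(b0_range[1], b0_range[2], length.out = 81)
    b1s <- seq(b1_range[1], b1_range[2], length.out = 81)
    vals <- outer(b0s, b1s, Vectorize(ll))
    best <- arrayInd(which.max(vals), dim(vals))
    s0 <- diff(b0_range) / 80; s1 <- diff(b1_range) / 80
    b0_range <- b0s[best[1]] + c(-s0, s0)
    b1_range <- b1s[best[2]] + c(-s1, s1)
  }
  list(intercept = mean(b0_range), slope = mean(b1_range))
}

# build a counts-based case-control sample directly
new_sample_from_counts <- function(n1, n0)
  collapsim:::new_case_control_sample(n1, n0)

# quick fixed-effects model used across tests (Figure-1 setting)
fig1_model <- function()
  fixed_effect_model(prevalence = 0.01, or_true = 1.6,
                     risk_allele_freq = 0.25, n_effect_alleles = 200L)
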