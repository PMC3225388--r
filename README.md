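# collapsim

Single-SNP association tests of dichotomous phenotypes estimate
*marginal* odds ratios — the effect of a variant averaged over every
possible genetic background.  Under a multi-locus logistic disease
model, the quantity of biological interest is the *conditional* odds
ratio, the effect holding the rest of the background fixed.  Because
the odds ratio is a non-collapsible effect measure, the two differ
even without any confounding: for a polygenic disease the marginal OR
is systematically attenuated toward 1, and the attenuation grows with
the number of risk SNPs, the risk allele frequency and the disease
prevalence.  `collapsim` simulates this mechanism end to end and
quantifies its consequences, including the loss of explained variance
("missing heritability") it induces.  It is aimed at statistical
geneticists and methodologists who want to reproduce, probe or extend
these simulation results.

## The model

Disease status $Y$ is generated from the total risk-allele count
$G \sim \mathrm{Binomial}(m, p_a)$ (Hardy-Weinberg and linkage
equilibrium over $m = 2S$ effect alleles) through a logistic
penetrance

$$P(Y=1 \mid G=g) = \mathrm{logistic}(\beta_0 + \beta g),$$

with $e^\beta$ the true conditional per-allele OR and $\beta_0$
calibrated so the model prevalence equals $K$.  The package provides:

* exact intercept calibration (`solve_intercept`, and a Monte-Carlo
  analogue for per-SNP effect sizes);
* the exact focal-SNP genotype distribution given disease status and
  the analytic asymptotic marginal OR a single-SNP logistic
  regression converges to (`focal_genotype_pmf`,
  `asymptotic_marginal_or`);
* case-control cohort simulators for the equal-effects model and for
  a heterogeneous architecture with Exponential(5) effect sizes and
  Uniform(0.05, 0.95) allele frequencies (`median_or_experiment`,
  `draw_architecture`, `rejection_sample_cohort`,
  `heterogeneous_experiment`);
* McKelvey-Zavoina explained variance on the log-odds scale,
  $R^2 = V/(V + \pi^2/3)$ with $V = \sum_j \beta_j^2\,2p_j(1-p_j)$,
  and the loss experiment comparing true with single-SNP-estimated
  heritability (`mz_r2`, `r2_loss_experiment`);
* reproducible grid experiments over prevalence, allele frequency and
  number of risk SNPs with TSV + JSON outputs (`run_experiment`) and
  a thin command-line wrapper.

## Worked example

A disease with 1% prevalence caused by 100 risk SNPs (risk allele
frequency 0.25), each with a true conditional OR of 2:

```r
library(collapsim)
model <- fixed_effect_model(prevalence = 0.01, or_true = 2,
                            risk_allele_freq = 0.25, n_effect_alleles = 200)
model
#> Multi-locus odds model (equal effects)
#>   prevalence K        : 0.01
#>   conditional OR      : 2  (beta = 0.693147)
#>   risk allele freq p_a: 0.25
#>   effect alleles m    : 200  (100 risk SNPs)
#>   calibrated intercept: -45.628532

asymptotic_marginal_or(model)
#> [1] 1.462401

median_or_experiment(model, n_replicates = 1000, seed = 7)
#> Median single-SNP OR over 1000 replicates: 1.4632 (true conditional OR 2.0000)
```

A single-SNP analysis of this disease converges to an odds ratio of
about 1.46, not 2: the simulated median over 1,000 case-control
samples (3,500 subjects, 1:1) lands on the analytic asymptote, and no
increase in sample size moves it.  The explained-variance consequence
for a disease whose true log-odds heritability is 80%:

```r
r2_loss_experiment(prevalence = 0.01, target_r2 = 0.80,
                   risk_allele_freq = 0.5, n_effect_alleles = 200,
                   n_replicates = 1000, seed = 7)
#> McKelvey-Zavoina explained variance (log-odds scale)
#>   true OR 1.6703 -> R2 = 0.8000
#>   est. OR 1.3978 -> R2 = 0.6303
#>   loss: 16.97 percentage points (21.2% relative)
```

Effect sizes estimated by single-SNP analysis recover only 63% of the
80% true heritability — roughly 17 percentage points of explained
variance are lost to non-collapsibility alone, with every SNP known
and measured without error.

Grid experiments (and their command-line form) reproduce the full
curves, e.g.:

```sh
Rscript inst/cli/collapsim.R fig2_maf_grid \
    --n-replicates 1000 --seed 1 --out maf_grid
```

writes `maf_grid.tsv` (true OR, median OR, asymptotic OR per grid
cell) and a `maf_grid.json` parameter sidecar.

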