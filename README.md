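# gblmm — grid-based Bayesian mixed models for longitudinal genetic association

Genome-wide association studies of longitudinal traits (body weight,
cholesterol, blood pressure, ...) usually analyse one measurement per person
and one variant at a time, losing the information in repeated measurements
and missing variants that act through interactions or time-varying effects.
`gblmm` is for statistical geneticists and biostatisticians who want to
analyse such cohorts jointly: it fits a Bayesian mixed model with built-in
variable selection over all SNP main effects, SNP–SNP (epistatic) products
and SNP–time/environment products, for phenotypes measured at irregular,
subject-specific time points.

## The model

For subject *i* with *n<sub>i</sub>* observations,

y*<sub>i</sub>* = μ**1** + x*<sub>i</sub>* Γ β + p*<sub>i</sub>* ν*<sub>i</sub>* + e*<sub>i</sub>*,  e*<sub>i</sub>* ~ N(0, σ²I)

with latent indicators γ selecting among the d = p + p(p−1)/2 + pq
candidate genetic terms. Within-subject dependence comes from random
effects ν*<sub>i</sub>* ~ N(0, D) attached to *k* grid time points; each
observation time is mapped onto its two bracketing grid points by linear
interpolation (p*<sub>i</sub>*), so one fixed-dimensional covariance D
serves arbitrarily unbalanced designs. D is factored by the modified
Cholesky decomposition D = ΔΨΨᵀΔ (Δ ≥ 0 diagonal, Ψ unit lower
triangular), which gives every variance component a conjugate
normal/half-normal/scaled-inverse-χ² full conditional; (γ, λ) moves by
Metropolis–Hastings within Gibbs over a composite model space. The package
also provides:

- a rank test deciding whether (D, σ²) are identifiable from the marginal
  covariance (and a σ² = 0 fallback when they are not),
- Bayes-factor genome profiles (2 log BF with weak/moderate/strong
  thresholds 3/10/30), HPD intervals, Geweke and Gelman–Rubin diagnostics,
  ROC utilities,
- DIC / simplified-BPIC selection of the number of grid points,
- a simulation engine for longitudinal GWAS designs with heritability
  calibration.

## A worked example

```r
library(gblmm)
sim <- sim_study(setup = 1, n = 120, N = 600, p = 150,
                 causal_prop = 1/15, h2 = 0.4, seed = 1)
fit <- gblmm(sim$phenotypes, sim$genotypes, grid = 3,
             control = gblmm_control(n_iter = 2e4, burn_in = 1000,
                                     thin = 20, seed = 1))
summary(fit)
```

```
Posterior summaries (1000 samples)
        mean median    sd hpd_lower hpd_upper
mu     1.745  1.780 0.518     0.726     2.683
sigma2 0.885  0.878 0.068     0.751     1.016
delta1 1.142  1.135 0.191     0.803     1.578
delta2 1.469  1.470 0.217     1.014     1.867
delta3 0.769  0.754 0.186     0.441     1.179
psi21  0.702  0.685 0.266     0.143     1.196
psi31  0.489  0.464 0.322    -0.112     1.152
psi32  0.826  0.787 0.374     0.112     1.592
tstd   0.520  0.521 0.087     0.349     0.702

Top SNPs by Bayes factor:
 snp  prob prob_main prob_epi prob_gt    bf two_log_bf category floored
 120 1.000     1.000    0.000   0.002   Inf        Inf   strong   FALSE
 123 1.000     1.000    0.039   0.004   Inf        Inf   strong   FALSE
  98 0.689     0.655    0.040   0.000 53.97       7.98   strong   FALSE
  17 0.547     0.534    0.010   0.004 29.42       6.76 moderate   FALSE
 117 0.252     0.250    0.001   0.001  8.21       4.21     weak   FALSE
 ...
```

The study was simulated with ten causal SNPs (here 17, 54, 76, 88, 97, 98,
105, 117, 120, 123) and true σ² = 1, δ = (1, 1.2, 0.8),
ψ = (0.6, 0.4, 0.6): eight of the ten top-ranked SNPs are causal, and every
variance-component HPD interval covers its true value. `prob` is the
posterior probability that any active effect involves the SNP; `bf`
compares it with the prior inclusion probability (posterior of exactly 1
prints as `Inf`). `plot(fit)` draws the 2 log BF profile;
`scan_k(sim$phenotypes, sim$genotypes, 2:4, ...)` scores candidate grid
sizes by DIC and simplified BPIC (= DIC + P_D).

A thin command-line wrapper with `simulate`, `identifiability`, `fit`,
`select-k` and `summarize` subcommands is installed at
`inst/cli/gblmm.R` (run `Rscript $(Rscript -e 'cat(system.file("cli/gblmm.R", package="gblmm"))')`).

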