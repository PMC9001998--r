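test_that("simulated genotypes respect HWE frequencies and the MAF floor", {
  set.seed(24)
  G <- sim_genotypes(5000, 8, maf_range = c(0.2, 0.2))
  freq <- apply(G, 2, function(g) tabulate(g + 1, 3) / length(g))
  # HWE at maf 0.2: (0.64, 0.32, 0.04), 3.5 SE Monte Carlo band (absolute)
  for (j in 1:8) {
    expect_lt(abs(freq[1, j] - 0.64), 3.5 * sqrt(0.64 * 0.36 / 5000))
    expect_lt(abs(freq[2, j] - 0.32), 3.5 * sqrt(0.32 * 0.68 / 5000))
  }
  G2 <- sim_genotypes(200, 50)
  maf <- pmin(colMeans(G2) / 2, 1 - colMeans(G2) / 2)
  expect_true(all(maf >= 0.025)) # redraw enforces half the lower bound
  expect_true(all(G2 %in% 0:2))
  # balanced allele frequency: column mean near 1
  G3 <- sim_genotypes(4000, 3, maf_range = c(0.5, 0.5))
  expect_true(all(abs(colMeans(G3) - 1) < 3.5 * sqrt(0.5 / 4000)))
})

test_that("observation schedules hit N exactly with counts in range", {
  set.seed(25)
  tt <- sim_times(400, 2000)
  expect_equal(sum(tt$ni), 2000)
  expect_true(all(tt$ni >= 3 & tt$ni <= 7))
  expect_equal(mean(tt$ni), 5)
  expect_equal(mean(tt$tstd), 0, tolerance = 1e-12)
  expect_equal(var(tt$tstd), 1, tolerance = 1e-12)
  expect_equal(sim_times(1, 3)$ni, 3)
  expect_error(sim_times(10, 200), "infeasible")
})

test_that("heritability calibration solves the variance identity", {
  # h2 = 0.4, V_re + sigma2 = 3, Var(S) = 2 -> c_g = 1
  A <- matrix(1, 10, 1) # k = 1, all weights 1
  D <- matrix(2, 1, 1)  # V_re = 2, sigma2 = 1
  S <- rep(c(0, 2), 5) * sqrt(2 / var(rep(c(0, 2), 5))) # Var(S) = 2
  expect_equal(calibrate_cg(0.4, S, A, D, 1), 1)
  expect_equal(calibrate_cg(0, S, A, D, 1), 0)
  expect_error(calibrate_cg(0.4, rep(1, 10), A, D, 1), "zero variance")
})

test_that("simulated studies realise the target heritability", {
  set.seed(26)
  h2 <- replicate(12, sim_study(setup = 1, n = 100, N = 500, p = 30, k = 3,
                                causal_prop = 0.1, h2 = 0.4)$truth$h2_realized)
  expect_true(all(abs(h2 - 0.4) < 0.02))
})

test_that("effect models generate their stated structures", {
  set.seed(27)
  # setup 6: pure SNP-time signal vanishes at standardised time 0
  sim6 <- sim_study(setup = 6, n = 80, N = 400, p = 60, k = 3,
                    causal_prop = 1 / 6, h2 = 0.4, sigma2 = 0, delta = rep(0, 3),
                    psi = rep(0, 3), seed = 27)
  tstd <- as.numeric(scale(sim6$phenotypes$time))
  expect_equal(sim6$phenotypes$y[which.min(abs(tstd))], 0, tolerance = 0.05)
  # noise-free, random-effect-free setup 1 equals c_g * (signal + time)
  sim1 <- sim_study(setup = 1, n = 40, N = 200, p = 20, k = 3,
                    causal_prop = 0.5, h2 = 0.4, sigma2 = 0,
                    delta = rep(0, 3), psi = rep(0, 3), seed = 28)
  tr <- sim1$truth
  tstd1 <- as.numeric(scale(sim1$phenotypes$time))
  S <- rowSums(sim1$genotypes[sim1$phenotypes$subject, tr$causal]) + tstd1
  expect_equal(sim1$phenotypes$y, tr$c_g * S, tolerance = 1e-12)
  expect_error(sim_study(setup = 2, n = 40, N = 200, p = 20, causal_prop = 0.1),
               "at least 10")
})

test_that("genotype-stratified mean curves separate main from SNP-time effects", {
  set.seed(29)
  sim <- sim_study(setup = 5, n = 400, N = 2000, p = 60, k = 3,
                   causal_prop = 1 / 6, h2 = 0.4, seed = 29)
  ph <- sim$phenotypes
  tstd <- as.numeric(scale(ph$time))
  cz <- sim$truth$causal
  g_main <- sim$genotypes[ph$subject, cz[1]]   # main-effect-only SNP
  g_gt <- sim$genotypes[ph$subject, cz[10]]    # SNP-time SNP
  # slope contrast: interaction coefficient in a linear model
  fit_main <- lm(ph$y ~ tstd * g_main)
  fit_gt <- lm(ph$y ~ tstd * g_gt)
  t_main <- summary(fit_main)$coefficients["tstd:g_main", "t value"]
  t_gt <- summary(fit_gt)$coefficients["tstd:g_gt", "t value"]
  expect_lt(abs(t_main), 3.5)  # parallel curves: no slope contrast
  expect_gt(t_gt, 4)           # time-varying SNP: slopes differ by genotype
})

test_that("a stored seed regenerates the identical study", {
  s1 <- sim_study(setup = 3, n = 30, N = 150, p = 40, causal_prop = 0.25,
                  seed = 30)
  s2 <- sim_study(setup = 3, n = 30, N = 150, p = 40, causal_prop = 0.25,
                  seed = 30)
  expect_identical(s1$phenotypes, s2$phenotypes)
  expect_identical(s1$genotypes, s2$genotypes)
  expect_identical(s1$truth$causal, s2$truth$causal)
})
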