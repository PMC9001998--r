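make_chain <- function() {
  # handcrafted 5-sample chain over 6 SNPs
  data.frame(
    sample = c(1L, 1L, 2L, 3L, 3L, 3L, 5L),
    type = factor(c("main", "epi", "main", "main", "gt", "epi", "main"),
                  levels = c("main", "epi", "gt")),
    snp1 = c(1L, 2L, 1L, 4L, 1L, 1L, 6L),
    snp2 = c(NA, 3L, NA, NA, 1L, 4L, NA),
    beta = c(0.5, -0.2, 0.4, 0.1, 0.2, -0.1, 0.3)
  )
}

test_that("inclusion probability counts one indicator per sample per SNP", {
  eff <- make_chain()
  # SNP 1: samples 1 (main), 2 (main), 3 (gt and epi -> once) => 3/5
  expect_equal(inclusion_prob(eff, 1, n_samples = 5), 0.6)
  # SNP 3 appears only as the partner of an epistatic pair in sample 1
  expect_equal(inclusion_prob(eff, 3, n_samples = 5), 0.2)
  expect_equal(inclusion_prob(eff, 5, n_samples = 5), 0)
})

test_that("Bayes factors are posterior odds over prior odds with guarded bounds", {
  expect_equal(bayes_factor(0.5, 0.01), 99)
  expect_equal(bayes_factor(0.3, 0.3), 1)
  expect_equal(bayes_factor(1, 0.1), Inf)
  expect_error(bayes_factor(0.5, 0), "strictly in")
  expect_error(bayes_factor(0.5, 1), "strictly in")
  # monotone in the posterior for a fixed prior
  post <- seq(0.05, 0.95, 0.05)
  expect_true(all(diff(bayes_factor(post, 0.02)) > 0))
  expect_equal(bf_category(c(1, 5, 20, 50)),
               c("none", "weak", "moderate", "strong"))
})

test_that("genome profiles match brute-force per-SNP recomputation", {
  eff <- make_chain()
  prof <- genome_profile(eff, n_samples = 5, p = 6, prior = 0.05)
  for (s in 1:6) {
    pr <- inclusion_prob(eff, s, n_samples = 5)
    expect_equal(prof$prob[s], pr)
    pb <- max(pr, 1 / 10) # zero counts floored at 1/(2T)
    expect_equal(prof$bf[s], bayes_factor(pb, 0.05))
    expect_equal(prof$two_log_bf[s], 2 * log(prof$bf[s]))
  }
  expect_true(all(prof$floored == (prof$prob == 0)))
  # combined inclusion dominates each per-type inclusion
  expect_true(all(prof$prob >= prof$prob_main - 1e-12))
  expect_true(all(prof$prob >= prof$prob_epi - 1e-12))
  expect_true(all(prof$prob >= prof$prob_gt - 1e-12))
  # 2 log BF of the worked example: posterior 0.5, prior 0.01 -> 2 log 99
  expect_equal(2 * log(bayes_factor(0.5, 0.01)), 9.1905, tolerance = 1e-4)
})

test_that("HPD intervals are shortest mass-covering windows", {
  set.seed(16)
  u <- runif(2e4)
  h <- hpd(u, 0.95)
  expect_equal(h[2] - h[1], 0.95, tolerance = 0.02)
  expect_equal(hpd(rep(3.3, 500)), c(3.3, 3.3))
  z <- rnorm(1e5)
  expect_equal(hpd(z, 0.95), c(-1.96, 1.96), tolerance = 0.05)
  expect_equal(hpd(z, 1), range(z))
  # shorter than the equal-tail interval for a skewed sample
  x <- rexp(1e5)
  expect_lt(diff(hpd(x, 0.9)), diff(quantile(x, c(0.05, 0.95))))
})

test_that("Geweke Z is near zero for stationary noise and large under drift", {
  set.seed(17)
  z <- replicate(40, geweke_z(rnorm(2000)))
  expect_lt(mean(abs(z) > 2.5), 0.15)
  drift <- c(rnorm(1000, 5), rnorm(1000, 0)) # 5-SD mean shift
  expect_gt(abs(geweke_z(drift)), 4)
  expect_warning(geweke_z(rep(1, 500)), "constant")
})

test_that("PSRF approaches 1 for identical-law chains and exceeds it under dispersion", {
  set.seed(18)
  same <- replicate(4, rnorm(5000), simplify = FALSE)
  gr <- gelman_rubin(same)
  expect_lt(gr$psrf, 1.01)
  expect_gte(gr$upper, gr$psrf)
  apart <- list(rnorm(500, 0), rnorm(500, 3), rnorm(500, -3))
  expect_gt(gelman_rubin(apart)$psrf, 1.5)
})

test_that("ROC points match a brute-force threshold sweep", {
  scores <- c(5, 4, 3, 2, 1, 0)
  truth <- c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE)
  roc <- roc_points(scores, truth)
  for (i in seq_len(nrow(roc))) {
    expect_equal(roc$fpr[i], mean(scores[!truth] >= roc$threshold[i]))
    expect_equal(roc$tpr[i], mean(scores[truth] >= roc$threshold[i]))
  }
  # perfect separation reaches TPR 1 at FPR 0
  perf <- roc_points(c(9, 8, 7, 1, 2, 3), c(1, 1, 1, 0, 0, 0))
  expect_equal(max(perf$tpr[perf$fpr == 0]), 1)
  expect_error(roc_points(scores, rep(FALSE, 6)), "no causal")
  # random scores give a near-diagonal curve
  set.seed(19)
  auc <- mean(replicate(60, partial_auc(rnorm(300), rep(c(TRUE, FALSE), 150),
                                        max_fpr = 1)))
  expect_equal(auc, 0.5, tolerance = 0.03)
})
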