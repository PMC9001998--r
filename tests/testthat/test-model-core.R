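test_that("effect catalog counts follow d = p + p(p-1)/2 + pq", {
  expect_equal(effect_catalog(3, 1)$d, 9)
  expect_equal(effect_catalog(1000, 1)$d, 501500)
  cat22 <- effect_catalog(2, 2)
  expect_equal(c(cat22$d_main, cat22$d_epi, cat22$d_gt), c(2, 1, 4))
})

test_that("pair indexing is a lexicographic bijection", {
  p <- 7
  idx <- 0L
  for (i in 1:(p - 1)) for (j in (i + 1):p) {
    idx <- idx + 1L
    expect_equal(gblmm:::pair_index(i, j, p), idx)
    expect_equal(gblmm:::pair_from_index(idx, p), c(i, j))
  }
  expect_equal(idx, p * (p - 1) / 2)
})

test_that("design columns are elementwise products on raw additive codes", {
  G <- rbind(c(0, 0), c(1, 2), c(2, 2))
  Cov <- cbind(tstd = c(-1, 0, 1))
  subject <- 1:3
  terms <- data.frame(type = c("main", "epi", "gt"),
                      snp1 = c(1L, 1L, 1L), snp2 = c(NA, 2L, 1L))
  X <- design_columns(G, Cov, subject, terms)
  expect_equal(X[, 1], c(0, 1, 2))
  expect_equal(X[, 2], c(0, 2, 4))
  expect_equal(X[, 3], c(0, 0, 2))
  # empty active set -> zero columns
  expect_equal(ncol(design_columns(G, Cov, subject, NULL)), 0L)
})

test_that("marginal likelihood matches the fully assembled N-dimensional normal", {
  set.seed(7)
  g <- grid_spec(c(0, 1))
  times <- list(c(0.2, 0.9), c(0.1, 0.5), c(0.4, 0.8))
  im <- interp_matrix(times, g)
  subject <- im$subject
  N <- length(subject)
  delta <- c(0.7, 1.3); psi <- 0.4; sigma2 <- 0.6
  fixed <- rnorm(N); y <- rnorm(N, fixed, 1)
  ll <- marginal_loglik(y, fixed, im$A, subject, delta, psi, sigma2)
  # brute-force oracle: full N x N covariance P (I (x) D) P' + sigma2 I
  D <- reconstruct_D(delta, psi)
  Dbig <- kronecker(diag(3), D)
  S <- im$P %*% Dbig %*% t(im$P) + sigma2 * diag(N)
  r <- y - fixed
  ll_brute <- -0.5 * (N * log(2 * pi) + determinant(S)$modulus +
                        t(r) %*% solve(S, r))
  expect_equal(ll, as.numeric(ll_brute), tolerance = 1e-10)
})

test_that("degenerate limits of the likelihoods agree", {
  set.seed(8)
  # k = 1, delta = 0, one observation: plain univariate normal density
  A1 <- matrix(1, 1, 1)
  expect_equal(marginal_loglik(2.3, 1.1, A1, 1L, 0, numeric(0), 0.5),
               dnorm(2.3, 1.1, sqrt(0.5), log = TRUE))
  # conditional and marginal coincide when D = 0
  g <- grid_spec(c(0, 1))
  im <- interp_matrix(list(c(0.2, 0.8), c(0.3, 0.6, 0.9)), g)
  y <- rnorm(5); fixed <- rnorm(5)
  b <- matrix(rnorm(4), 2, 2)
  expect_equal(
    conditional_loglik(y, fixed, im$A, im$subject, c(0, 0), 0.3, b, 0.7),
    marginal_loglik(y, fixed, im$A, im$subject, c(0, 0), 0.3, 0.7),
    tolerance = 1e-10)
  # fully explained subject: -(n_i / 2) log(2 pi sigma2)
  expect_equal(conditional_loglik(fixed, fixed, im$A, im$subject, c(0, 0), 0.3,
                                  b * 0, 0.7),
               -5 / 2 * log(2 * pi * 0.7))
})

test_that("all-on-grid subjects with diagonal D give independent univariate terms", {
  g <- grid_spec(c(0, 0.5, 1))
  im <- interp_matrix(rep(list(c(0, 0.5, 1)), 2), g)
  delta <- c(0.5, 1, 1.5); psi <- rep(0, 3); sigma2 <- 0.4
  set.seed(9)
  y <- rnorm(6); fixed <- rep(0, 6)
  vars <- rep(delta^2, 2) + sigma2
  expect_equal(
    marginal_loglik(y, fixed, im$A, im$subject, delta, psi, sigma2),
    sum(dnorm(y, 0, sqrt(vars), log = TRUE)), tolerance = 1e-10)
})

test_that("marginal likelihood is invariant to subject ordering", {
  td <- make_tiny_data()
  base <- marginal_loglik(td$y, rep(td$mu, td$N), td$A, td$subject,
                          td$delta, td$psi, td$sigma2)
  perm <- c(4, 1, 6, 2, 3, 5)
  ord <- order(match(td$subject, perm))
  expect_equal(
    marginal_loglik(td$y[ord], rep(td$mu, td$N), td$A[ord, ], td$subject[ord],
                    td$delta, td$psi, td$sigma2),
    base, tolerance = 1e-10)
})

test_that("v_i = p_i Delta Psi satisfies v_i v_i' = p_i D p_i'", {
  set.seed(10)
  g <- grid_spec(c(0, 0.3, 0.7, 1))
  im <- interp_matrix(list(runif(4), runif(3)), g)
  delta <- runif(4); psi <- rnorm(6)
  L <- delta * psi_matrix(psi, 4)
  D <- reconstruct_D(delta, psi)
  for (p_i in im$blocks) {
    vi <- p_i %*% L
    expect_equal(vi %*% t(vi), p_i %*% D %*% t(p_i), tolerance = 1e-10)
  }
})

test_that("conditional Monte Carlo integration over b approximates the marginal", {
  td <- make_tiny_data(seed = 12, n = 2)
  fixed <- rep(td$mu, td$N)
  target <- marginal_loglik(td$y, fixed, td$A, td$subject, td$delta, td$psi,
                            td$sigma2)
  set.seed(13)
  M <- 4e5
  # log mean_b exp(conditional loglik) per subject, b ~ N(0, I_k)
  L <- td$delta * psi_matrix(td$psi, 2)
  total <- 0
  for (i in 1:2) {
    idx <- td$subject == i
    Zi <- td$A[idx, , drop = FALSE] %*% L
    B <- matrix(rnorm(2 * M), M, 2)
    resid <- matrix(td$y[idx] - fixed[idx], M, sum(idx), byrow = TRUE) -
      B %*% t(Zi)
    lls <- rowSums(dnorm(resid, 0, sqrt(td$sigma2), log = TRUE))
    total <- total + log(mean(exp(lls - max(lls)))) + max(lls)
  }
  # Monte Carlo tolerance on the log scale
  expect_equal(total, target, tolerance = 0.02)
})
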