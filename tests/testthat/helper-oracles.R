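# Shared fixtures and numerical-oracle helpers (built in code, no stored data).

# trapezoidal CDF on a grid of unnormalised density values
trap_cdf <- function(grid, dens) {
  h <- diff(grid)
  cdf <- c(0, cumsum(h * (utils::head(dens, -1) + utils::tail(dens, -1)) / 2))
  cdf / cdf[length(cdf)]
}

# Kolmogorov-Smirnov distance of samples against a gridded reference CDF
ks_dist <- function(x, cdf_grid, cdf_vals) {
  Fx <- stats::approx(cdf_grid, cdf_vals, xout = sort(x), rule = 2)$y
  n <- length(x)
  max(abs(Fx - seq_len(n) / n), abs(Fx - (seq_len(n) - 1) / n))
}

# tiny longitudinal dataset with known variance components (k = 2)
make_tiny_data <- function(seed = 5, n = 6, p = 3) {
  set.seed(seed)
  ni <- rep(3, n)
  subject <- rep(seq_len(n), ni)
  time <- as.numeric(replicate(n, sort(stats::runif(3))))
  G <- matrix(stats::rbinom(n * p, 2, 0.3), n, p)
  delta <- c(0.9, 1.1); psi <- 0.5; sigma2 <- 0.8; mu <- 1
  grid <- grid_spec(c(0, 1))
  A <- interp_matrix(split(time, subject), grid)$A
  L <- delta * psi_matrix(psi, 2)
  b <- matrix(stats::rnorm(n * 2), n, 2)
  y <- mu + rowSums((A %*% L) * b[subject, ]) + stats::rnorm(sum(ni), 0, sqrt(sigma2))
  list(ph = data.frame(subject = subject, time = time, y = y),
       G = G, A = A, subject = subject, time = time, y = y, grid = grid,
       delta = delta, psi = psi, sigma2 = sigma2, mu = mu, b = b, n = n, N = sum(ni))
}

# control with only the named update blocks enabled
frozen_control <- function(which_on, init, n_iter = 1e5, seed = 42,
                           store_b = FALSE, thin = 1, burn_in = 200, ...) {
  all_blocks <- c("gamma", "beta", "cov_beta", "b", "delta", "psi", "mu",
                  "sigma2", "sigma_beta2")
  upd <- as.list(stats::setNames(all_blocks %in% which_on, all_blocks))
  gblmm_control(n_iter = n_iter, burn_in = burn_in, thin = thin, seed = seed,
                update = upd, init = init, store_b = store_b, ...)
}

# highest true-positive rate at false-positive rate <= max_fpr
tpr_at <- function(scores, truth, max_fpr = 0.2) {
  roc <- roc_points(scores, truth)
  max(roc$tpr[roc$fpr <= max_fpr])
}
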