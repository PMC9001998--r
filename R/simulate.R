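#' Simulate Hardy-Weinberg genotypes with common minor alleles
#'
#' Each SNP column is drawn as `Binomial(2, maf_j)` with `maf_j ~
#' U(maf_range)`, the textbook stand-in for randomly selected common variants
#' after a minor-allele-frequency filter. Columns whose realised MAF falls
#' below half the lower bound (or that come out monomorphic) are redrawn.
#' No linkage disequilibrium is simulated.
#'
#' @param n Number of individuals.
#' @param p Number of SNPs.
#' @param maf_range Lower/upper bounds of the allele-frequency draw
#'   (default `c(0.05, 0.5)`, i.e. MAF >= 5%).
#' @return `n x p` integer matrix of additive codes, with the drawn
#'   frequencies in `attr(, "maf")`.
#' @export
sim_genotypes <- function(n, p, maf_range = c(0.05, 0.5)) {
  stopifnot(n >= 1, p >= 1, length(maf_range) == 2, maf_range[1] > 0,
            maf_range[2] <= 0.5, maf_range[1] <= maf_range[2])
  maf <- stats::runif(p, maf_range[1], maf_range[2])
  G <- matrix(stats::rbinom(n * p, 2L, rep(maf, each = n)), n, p)
  floor_maf <- 0.5 * maf_range[1]
  for (j in seq_len(p)) {
    reps <- 0L
    repeat {
      m <- mean(G[, j]) / 2
      if (min(m, 1 - m) >= floor_maf && stats::var(G[, j]) > 0) break
      G[, j] <- stats::rbinom(n, 2L, maf[j])
      reps <- reps + 1L
      if (reps > 1000L) stop("cannot realise requested MAF; increase n or maf_range")
    }
  }
  attr(G, "maf") <- maf
  G
}

#' Simulate per-subject observation schedules
#'
#' Per-subject counts are drawn uniformly from `ni_range` and then adjusted
#' by unit steps (staying in range) until they sum exactly to `N`. Raw times
#' are `U[0, 1]` draws; the standardised time covariate has mean 0 and
#' variance 1 over all `N` observations.
#'
#' @param n Number of subjects.
#' @param N Total number of observations (`3n <= N <= 7n` for the default
#'   range).
#' @param ni_range Admissible per-subject counts (default `3:7`).
#' @return List with `times` (per-subject list of raw times, each sorted),
#'   `ni`, `subject` (length `N`), `time` (raw, length `N`) and `tstd`
#'   (standardised, length `N`).
#' @export
sim_times <- function(n, N, ni_range = 3:7) {
  lo <- min(ni_range); hi <- max(ni_range)
  if (N < n * lo || N > n * hi) {
    stop(sprintf("N = %d infeasible for n = %d subjects with n_i in [%d, %d]", N, n, lo, hi))
  }
  ni <- sample(ni_range, n, replace = TRUE)
  while (sum(ni) != N) {
    if (sum(ni) > N) {
      i <- sample(which(ni > lo), 1L)
      ni[i] <- ni[i] - 1L
    } else {
      i <- sample(which(ni < hi), 1L)
      ni[i] <- ni[i] + 1L
    }
  }
  times <- lapply(ni, function(m) sort(stats::runif(m)))
  time <- unlist(times)
  list(
    times = times, ni = ni, subject = rep(seq_len(n), ni), time = time,
    tstd = as.numeric(scale(time))
  )
}

# Unscaled signal S (genetic terms + any time term inside the scaled bracket)
# for the six generative effect models. `causal` has length >= the model's
# requirement; tstd is the standardised time covariate at observation level.
signal_for_setup <- function(setup, genotypes, subject, tstd, causal) {
  Gc <- genotypes[subject, causal, drop = FALSE]
  m <- length(causal)
  need <- if (setup == 1) 1 else 10
  if (m < need) stop(sprintf("setup %d needs at least %d causal SNPs", setup, need))
  switch(as.character(setup),
    "1" = rowSums(Gc) + tstd,
    "2" = rowSums(Gc[, 1:6, drop = FALSE]) + Gc[, 7] * Gc[, 8] + Gc[, 9] * Gc[, 10] + tstd,
    "3" = Gc[, 1] * Gc[, 2] + Gc[, 3] * Gc[, 4] + Gc[, 5] * Gc[, 6] +
      Gc[, 7] * Gc[, 8] + Gc[, 9] * Gc[, 10] + tstd,
    "4" = rowSums(Gc[, 1:8, drop = FALSE]) + rowSums(Gc[, 9:10, drop = FALSE] * tstd),
    "5" = rowSums(Gc[, 1:5, drop = FALSE]) + rowSums(Gc[, 6:10, drop = FALSE] * tstd),
    "6" = rowSums(Gc * tstd),
    stop("setup must be 1..6")
  )
}

default_true_factors <- function(k) {
  delta_full <- c(1, 1.2, 0.8, 0.7)
  psi_full <- c(0.6, 0.4, 0.6, 0.2, 0.4, 0.6)
  if (k > 4) stop("built-in true factors available for k <= 4 only")
  list(delta = delta_full[seq_len(k)], psi = psi_full[seq_len(k * (k - 1) / 2)])
}

#' Heritability scale constant for a simulated design
#'
#' Solves `h2 = Var(c S) / (Var(c S) + V_re + sigma2)` for the scale `c`,
#' where `Var(S)` is the empirical variance of the unscaled signal over all
#' observations and `V_re` is the average random-effect variance
#' `mean(diag(p_i D p_i'))` over the realised interpolation rows:
#' `c = sqrt(h2 (V_re + sigma2) / ((1 - h2) Var(S)))`.
#'
#' @param h2 Target trait heritability in `[0, 1)`.
#' @param S Unscaled signal vector (length `N`).
#' @param A `N x k` interpolation weight matrix.
#' @param D Grid covariance matrix.
#' @param sigma2 Residual variance.
#' @return The scale constant `c_g`.
#' @export
calibrate_cg <- function(h2, S, A, D, sigma2) {
  stopifnot(h2 >= 0, h2 < 1)
  if (h2 == 0) return(0)
  vS <- stats::var(S)
  if (!is.finite(vS) || vS <= 0) stop("signal has zero variance; cannot calibrate heritability")
  v_re <- mean(rowSums((A %*% D) * A))
  sqrt(h2 * (v_re + sigma2) / ((1 - h2) * vS))
}

#' Simulate a longitudinal GWAS study
#'
#' Generates genotypes, irregular observation schedules and phenotypes from
#' one of six generative effect models: (1) ten main effects, (2) six mains +
#' two SNP-SNP interactions, (3) five SNP-SNP interactions, (4) eight mains +
#' two SNP-time interactions, (5) five mains + five SNP-time interactions,
#' (6) ten SNP-time interactions. The bracketed signal (genetic terms plus
#' the model's time term) is scaled by `c_g` to hit the target trait
#' heritability; subject random effects are `nu_i ~ N(0, D)` with `D`
#' rebuilt from its modified Cholesky factors on an equally spaced `k`-point
#' grid over `[0, 1]`, and residuals are `N(0, sigma2)`.
#'
#' Setup 1 accepts any causal count; setups 2-6 use the printed ten-SNP
#' structures and require exactly `round(causal_prop * p) >= 10`.
#'
#' @param setup Effect model, 1-6.
#' @param n,N,p Numbers of subjects, total observations, SNPs.
#' @param k Number of grid points (2-4 have built-in true factors).
#' @param causal_prop Proportion of causal SNPs (default 1%).
#' @param h2 Target trait heritability (default 0.4).
#' @param delta,psi True modified Cholesky factors (defaults: the reference
#'   values for the given `k`).
#' @param sigma2 Residual variance (default 1).
#' @param maf_range Allele-frequency bounds for [sim_genotypes()].
#' @param seed Optional seed for reproducibility.
#' @return Object of class `gblmm_sim`: `phenotypes` (long data frame with
#'   columns `subject`, `time`, `y`), `genotypes`, `grid`, and `truth`
#'   (causal indices, `c_g`, `delta`, `psi`, `sigma2`, `b`, realised
#'   heritability, seed).
#' @export
sim_study <- function(setup = 1, n = 400, N = 2000, p = 1000, k = 3,
                      causal_prop = 0.01, h2 = 0.4,
                      delta = NULL, psi = NULL, sigma2 = 1,
                      maf_range = c(0.05, 0.5), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(delta) || is.null(psi)) {
    tf <- default_true_factors(k)
    if (is.null(delta)) delta <- tf$delta
    if (is.null(psi)) psi <- tf$psi
  }
  stopifnot(length(delta) == k, length(psi) == k * (k - 1) / 2)
  m <- max(1L, round(causal_prop * p))
  if (m > p) stop("causal count exceeds p")
  G <- sim_genotypes(n, p, maf_range)
  tt <- sim_times(n, N)
  grid <- grid_spec(seq(0, 1, length.out = k))
  A <- interp_matrix(tt$times, grid)$A
  causal <- sort(sample.int(p, m))
  S <- signal_for_setup(setup, G, tt$subject, tt$tstd, causal)
  D <- reconstruct_D(delta, psi)
  c_g <- calibrate_cg(h2, S, A, D, sigma2)
  L <- delta * psi_matrix(psi, k)
  b <- matrix(stats::rnorm(n * k), n, k)
  re <- rowSums((A %*% L) * b[tt$subject, , drop = FALSE])
  e <- stats::rnorm(N, 0, sqrt(sigma2))
  y <- c_g * S + re + e
  v_re <- mean(rowSums((A %*% D) * A))
  structure(
    list(
      phenotypes = data.frame(subject = tt$subject, time = tt$time, y = y),
      genotypes = G, grid = grid,
      truth = list(
        setup = setup, causal = causal, c_g = c_g, delta = delta, psi = psi,
        sigma2 = sigma2, b = b, h2_target = h2,
        h2_realized = stats::var(c_g * S) / (stats::var(c_g * S) + v_re + sigma2),
        seed = seed
      )
    ),
    class = "gblmm_sim"
  )
}

#' @export
print.gblmm_sim <- function(x, ...) {
  tr <- x$truth
  cat(sprintf(
    "Simulated longitudinal study (setup %d): %d subjects, %d observations, %d SNPs\n",
    tr$setup, nrow(x$genotypes), nrow(x$phenotypes), ncol(x$genotypes)))
  cat(sprintf("  %d causal SNPs, c_g = %.4f, realised h2 = %.3f, k = %d grid points\n",
              length(tr$causal), tr$c_g, tr$h2_realized, x$grid$k))
  invisible(x)
}
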