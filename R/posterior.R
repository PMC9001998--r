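#' Posterior inclusion probability of a SNP position
#'
#' The fraction of retained MCMC samples in which any active effect (main,
#' epistatic or SNP-covariate) involves the given SNP position. Each sample
#' contributes an indicator, not a count, so the value is a probability in
#' `[0, 1]` even when a SNP enters through several terms at once.
#'
#' @param x A `gblmm` fit, or a data frame of active effects with columns
#'   `sample`, `type`, `snp1`, `snp2`.
#' @param snp SNP position (column index).
#' @param n_samples Total number of retained samples (required when `x` is a
#'   data frame).
#' @return Probability in `[0, 1]`.
#' @export
inclusion_prob <- function(x, snp, n_samples = NULL) {
  if (inherits(x, "gblmm")) {
    if (snp < 1 || snp > x$catalog$p) stop("unknown SNP position: ", snp)
    eff <- x$effects
    n_samples <- x$n_samples
  } else {
    eff <- x
    if (is.null(n_samples)) stop("n_samples required for a raw effects table")
  }
  hit <- eff$snp1 == snp | (!is.na(eff$snp2) & eff$type %in% c("epi", 1L) &
                              eff$snp2 == snp)
  length(unique(eff$sample[hit])) / n_samples
}

#' Bayes factor for SNP inclusion
#'
#' Posterior odds over prior odds: `BF = [P/(1-P)] / [p0/(1-p0)]` where `P`
#' is the posterior and `p0` the prior probability that any active effect
#' involves the SNP. A posterior of exactly 1 yields `Inf`.
#'
#' @param posterior Posterior inclusion probability in `[0, 1]`.
#' @param prior Prior inclusion probability in `(0, 1)`.
#' @return The Bayes factor (>= 0, possibly `Inf`).
#' @export
#' @examples
#' bayes_factor(0.5, 0.01)  # 99
bayes_factor <- function(posterior, prior) {
  if (any(prior <= 0 | prior >= 1)) stop("prior probability must lie strictly in (0, 1)")
  if (any(posterior < 0 | posterior > 1)) stop("posterior probability must lie in [0, 1]")
  (posterior / (1 - posterior)) / (prior / (1 - prior))
}

#' Support category from a Bayes factor
#'
#' Conventional evidence grades: weak for `BF` in (3, 10], moderate in
#' (10, 30], strong above 30, otherwise none.
#'
#' @param bf Numeric vector of Bayes factors.
#' @return Character vector of categories.
#' @export
bf_category <- function(bf) {
  cut(bf, breaks = c(-Inf, 3, 10, 30, Inf),
      labels = c("none", "weak", "moderate", "strong"), right = TRUE) |>
    as.character()
}

#' Genome-wide 2 log BF profile
#'
#' One row per SNP with the combined (any effect type) posterior inclusion
#' probability, Bayes factor, `2 log BF`, support category and the per-type
#' inclusion probabilities. Zero posterior counts are floored at `1/(2T)`
#' before forming the Bayes factor so that the log profile stays finite;
#' floored rows are flagged.
#'
#' @param x A `gblmm` fit or a raw effects data frame (columns `sample`,
#'   `type`, `snp1`, `snp2` with `type` in `main`/`epi`/`gt`).
#' @param n_samples,p Required when `x` is a data frame.
#' @param prior Scalar prior inclusion probability per SNP; defaults to the
#'   complement-rule prior stored in the fit. Supply e.g. an expected
#'   effects-per-position ratio to use a flat user-specified prior instead.
#' @return Data frame with columns `snp`, `prob`, `prob_main`, `prob_epi`,
#'   `prob_gt`, `bf`, `two_log_bf`, `category`, `floored`.
#' @export
genome_profile <- function(x, n_samples = NULL, p = NULL, prior = NULL) {
  if (inherits(x, "gblmm")) {
    eff <- x$effects
    n_samples <- x$n_samples
    p <- x$catalog$p
    if (is.null(prior)) prior <- x$prior_snp
  } else {
    eff <- x
    if (is.null(n_samples) || is.null(p) || is.null(prior)) {
      stop("n_samples, p and prior are required for a raw effects table")
    }
  }
  count_unique <- function(sub) {
    if (nrow(sub) == 0L) return(numeric(p))
    snps <- c(sub$snp1, sub$snp2[sub$type == "epi" & !is.na(sub$snp2)])
    samp <- c(sub$sample, sub$sample[sub$type == "epi" & !is.na(sub$snp2)])
    keep <- !duplicated(cbind(samp, snps))
    tabulate(snps[keep], nbins = p)
  }
  combined <- count_unique(eff)
  prob <- combined / n_samples
  floored <- prob == 0
  prob_bf <- pmax(prob, 1 / (2 * n_samples))
  bf <- bayes_factor(prob_bf, prior)
  data.frame(
    snp = seq_len(p), prob = prob,
    prob_main = count_unique(eff[eff$type == "main", , drop = FALSE]) / n_samples,
    prob_epi = count_unique(eff[eff$type == "epi", , drop = FALSE]) / n_samples,
    prob_gt = count_unique(eff[eff$type == "gt", , drop = FALSE]) / n_samples,
    bf = bf, two_log_bf = 2 * log(bf), category = bf_category(bf),
    floored = floored
  )
}

#' Highest posterior density interval
#'
#' Shortest interval containing the stated posterior mass, by the empirical
#' sorted-window method.
#'
#' @param x Numeric vector of posterior samples.
#' @param prob Target mass (default 0.95).
#' @return Length-2 numeric vector `(lower, upper)`.
#' @export
hpd <- function(x, prob = 0.95) {
  stopifnot(prob > 0, prob <= 1)
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n == 0) stop("no finite samples")
  m <- max(1L, ceiling(prob * n))
  if (m >= n) return(c(x[1L], x[n]))
  widths <- x[(m + 1):n] - x[1:(n - m)]
  i <- which.min(widths)
  c(x[i], x[i + m])
}

# spectral density at zero via an AIC-selected AR fit (used for Geweke's Z)
spectrum0_ar <- function(x) {
  x <- as.numeric(x)
  if (stats::var(x) == 0) return(0)
  fit <- stats::ar(x, aic = TRUE, order.max = min(30, floor(length(x) / 4)))
  fit$var.pred / (1 - sum(fit$ar))^2
}

#' Geweke's convergence Z-score
#'
#' Compares the means of the first `frac1` and last `frac2` portions of a
#' chain, standardised by their spectral-density-at-zero variance estimates.
#'
#' @param x Numeric chain.
#' @param frac1 Leading fraction (default 0.1).
#' @param frac2 Trailing fraction (default 0.5).
#' @return Z statistic (`NA` with a warning for a constant chain).
#' @export
geweke_z <- function(x, frac1 = 0.1, frac2 = 0.5) {
  n <- length(x)
  stopifnot(n >= 100, frac1 > 0, frac2 > 0, frac1 + frac2 <= 1)
  x1 <- x[seq_len(floor(frac1 * n))]
  x2 <- x[(n - floor(frac2 * n) + 1):n]
  if (stats::var(x) == 0) {
    warning("constant chain: Geweke Z undefined")
    return(NA_real_)
  }
  (mean(x1) - mean(x2)) /
    sqrt(spectrum0_ar(x1) / length(x1) + spectrum0_ar(x2) / length(x2))
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic between/within variance decomposition over parallel chains, with
#' the sampling-variability degrees-of-freedom correction.
#'
#' @param chains A list of (equal-length) numeric chains, or a matrix with
#'   one chain per column.
#' @return List with `psrf` (point estimate) and `upper` (97.5% upper limit).
#' @export
gelman_rubin <- function(chains, confidence = 0.975) {
  if (is.matrix(chains)) chains <- lapply(seq_len(ncol(chains)), function(j) chains[, j])
  m <- length(chains)
  stopifnot(m >= 2)
  n <- unique(lengths(chains))
  stopifnot(length(n) == 1, n >= 10)
  xbar <- vapply(chains, mean, numeric(1))
  S2 <- vapply(chains, stats::var, numeric(1))
  W <- mean(S2)
  B <- n * stats::var(xbar)
  if (W == 0) return(list(psrf = 1, upper = 1))
  muhat <- mean(xbar)
  Vhat <- (n - 1) / n * W + (1 + 1 / m) * B / n
  var_w <- stats::var(S2) / m
  var_b <- 2 * B^2 / (m - 1)
  cov_wb <- (n / m) * (stats::cov(S2, xbar^2) - 2 * muhat * stats::cov(S2, xbar))
  var_V <- ((n - 1) / n)^2 * var_w + ((m + 1) / (m * n))^2 * var_b +
    2 * ((m + 1) * (n - 1) / (m * n^2)) * cov_wb
  V_df <- 2 * Vhat^2 / max(var_V, .Machine$double.eps)
  df_adj <- (V_df + 3) / (V_df + 1)
  R2_fixed <- (n - 1) / n
  R2_random <- (1 + 1 / m) * B / (n * W)
  psrf <- sqrt(df_adj * (R2_fixed + R2_random))
  w_df <- 2 * W^2 / max(stats::var(S2), .Machine$double.eps)
  upper <- sqrt(df_adj * (R2_fixed + stats::qf(confidence, m - 1, w_df) * R2_random))
  list(psrf = psrf, upper = upper)
}

#' Empirical ROC curve from per-SNP scores
#'
#' Sweeps a threshold over the score (e.g. `2 log BF`) and reports
#' false/true positive rates against a binary causal truth.
#'
#' @param scores Numeric per-SNP scores (higher = more evidence).
#' @param truth Logical/0-1 vector of the same length marking causal SNPs.
#' @param max_fpr Optionally truncate the curve at this false positive rate.
#' @return Data frame with columns `threshold`, `fpr`, `tpr`, ordered by
#'   increasing `fpr`, always including the (0, 0) end point.
#' @export
roc_points <- function(scores, truth, max_fpr = 1) {
  truth <- as.logical(truth)
  stopifnot(length(scores) == length(truth))
  if (!any(truth)) stop("no causal SNPs in truth: ROC undefined")
  if (all(truth)) stop("no non-causal SNPs in truth: ROC undefined")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  fpr <- vapply(thr, function(t) mean(scores[!truth] >= t), numeric(1))
  tpr <- vapply(thr, function(t) mean(scores[truth] >= t), numeric(1))
  out <- data.frame(threshold = thr, fpr = fpr, tpr = tpr)
  out[out$fpr <= max_fpr + 1e-12, ]
}

#' Partial area under the ROC curve
#'
#' Trapezoidal area under [roc_points()] up to `max_fpr`, normalised by
#' `max_fpr` so a perfect classifier scores 1.
#'
#' @inheritParams roc_points
#' @return Normalised partial AUC in `[0, 1]`.
#' @export
partial_auc <- function(scores, truth, max_fpr = 0.2) {
  roc <- roc_points(scores, truth)
  f <- c(roc$fpr, 1); t <- c(roc$tpr, 1)
  keep <- f <= max_fpr
  f2 <- c(f[keep], max_fpr)
  t2 <- c(t[keep], stats::approx(f, t, xout = max_fpr, ties = max, rule = 2)$y)
  sum(diff(f2) * (utils::head(t2, -1) + utils::tail(t2, -1)) / 2) / max_fpr
}
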