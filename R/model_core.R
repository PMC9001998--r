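#' Catalog of candidate genetic effect terms
#'
#' With `p` SNPs and `q` observation-level covariates (time always included)
#' the candidate terms are `p` main effects, `p(p-1)/2` unordered SNP-SNP
#' (epistatic) products and `p*q` SNP-covariate products, for
#' `d = p + p(p-1)/2 + pq` terms in total. Terms are indexed canonically:
#' mains by SNP index, pairs lexicographically `(i < j)`, SNP-covariate by
#' SNP then covariate. The catalog is kept implicit (no `d`-row table is
#' materialised) so that large `p` is cheap.
#'
#' @param p Number of SNPs (>= 1).
#' @param q Number of observation-level covariates, including time (>= 1).
#' @return Object of class `effect_catalog` with counts per type and `d`.
#' @export
#' @examples
#' effect_catalog(3, 1)$d  # 9
effect_catalog <- function(p, q) {
  stopifnot(p >= 1, q >= 1)
  p <- as.integer(p); q <- as.integer(q)
  d_main <- p
  d_epi <- p * (p - 1) / 2
  d_gt <- p * q
  structure(
    list(p = p, q = q, d_main = d_main, d_epi = d_epi, d_gt = d_gt,
         d = d_main + d_epi + d_gt),
    class = "effect_catalog"
  )
}

#' @export
print.effect_catalog <- function(x, ...) {
  cat(sprintf("Effect catalog: p = %d SNPs, q = %d covariates\n", x$p, x$q))
  cat(sprintf("  main %d + epistatic %d + SNP-covariate %d = d = %.0f terms\n",
              x$d_main, x$d_epi, x$d_gt, x$d))
  invisible(x)
}

# lexicographic index <-> unordered SNP pair (i < j)
pair_index <- function(i, j, p) {
  stopifnot(i < j)
  (i - 1) * p - i * (i + 1) / 2 + j
}

pair_from_index <- function(idx, p) {
  i <- 1L
  while (idx > p - i) {
    idx <- idx - (p - i)
    i <- i + 1L
  }
  c(i, i + idx)
}

#' Materialise design columns for a set of effect terms
#'
#' Columns are expanded to observation level (each subject's genotype repeated
#' over its observations). Epistatic columns are elementwise products of the
#' two SNP columns; SNP-covariate columns are products of a SNP column and a
#' covariate column. Genotypes are used on the raw additive 0/1/2 coding.
#'
#' @param genotypes `n x p` matrix of additive codes (0/1/2 or dosages).
#' @param covariates `N x q` matrix of observation-level covariates
#'   (standardised time first).
#' @param subject Length-`N` integer vector mapping observations to rows of
#'   `genotypes`.
#' @param terms Data frame with columns `type` (`"main"`, `"epi"`, `"gt"`),
#'   `snp1`, `snp2` (second SNP for `epi`, covariate index for `gt`, `NA`
#'   otherwise).
#' @return `N x nrow(terms)` matrix of design columns (0 columns if no terms).
#' @export
design_columns <- function(genotypes, covariates, subject, terms) {
  N <- length(subject)
  if (is.null(terms) || nrow(terms) == 0L) return(matrix(0, N, 0))
  out <- matrix(0, N, nrow(terms))
  for (a in seq_len(nrow(terms))) {
    g1 <- genotypes[subject, terms$snp1[a]]
    out[, a] <- switch(as.character(terms$type[a]),
      main = g1,
      epi = g1 * genotypes[subject, terms$snp2[a]],
      gt = g1 * covariates[, terms$snp2[a]],
      stop("unknown effect type: ", terms$type[a])
    )
  }
  out
}

#' Marginal log-likelihood with random effects integrated out
#'
#' Per subject the marginal law is
#' `y_i ~ N(mu + x_i beta, p_i D p_i' + sigma^2 I_{n_i})`, summed over
#' subjects. When `sigma2 = 0` (the non-identifiability fix) the density is
#' evaluated with the pseudo-determinant of the possibly singular covariance;
#' residual mass outside its column space yields `-Inf`.
#'
#' @param y Length-`N` phenotype vector.
#' @param fixed Length-`N` fixed-effect mean (overall mean + covariate and
#'   genetic contributions).
#' @param A `N x k` interpolation weight matrix ([interp_matrix()] `$A`).
#' @param subject Length-`N` subject index.
#' @param delta,psi Modified Cholesky factors of the grid covariance.
#' @param sigma2 Residual variance (>= 0).
#' @return Total log-likelihood (scalar).
#' @export
marginal_loglik <- function(y, fixed, A, subject, delta, psi, sigma2) {
  stopifnot(length(y) == length(fixed), length(subject) == length(y), sigma2 >= 0)
  k <- length(delta)
  L <- delta * psi_matrix(psi, k)
  r <- y - fixed
  ll <- 0
  for (i in unique(subject)) {
    idx <- which(subject == i)
    Zi <- A[idx, , drop = FALSE] %*% L
    Si <- tcrossprod(Zi) + diag(sigma2, length(idx))
    ri <- r[idx]
    if (sigma2 > 0) {
      ch <- chol(Si)
      z <- backsolve(ch, ri, transpose = TRUE)
      ll <- ll - 0.5 * (length(idx) * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(z^2))
    } else {
      eg <- eigen(Si, symmetric = TRUE)
      pos <- eg$values > max(eg$values, 0) * 1e-10
      rk <- sum(pos)
      proj <- crossprod(eg$vectors[, pos, drop = FALSE], ri)
      resid_out <- ri - eg$vectors[, pos, drop = FALSE] %*% proj
      if (sqrt(sum(resid_out^2)) > 1e-8 * max(1, sqrt(sum(ri^2)))) return(-Inf)
      ll <- ll - 0.5 * (rk * log(2 * pi) + sum(log(eg$values[pos])) +
                          sum(proj^2 / eg$values[pos]))
    }
  }
  as.numeric(ll)
}

#' Conditional log-likelihood given the grid random effects
#'
#' `sum_ij log N(y_ij; mu + x_ij beta + v_ij b_i, sigma^2)` with
#' `v_i = p_i Delta Psi`. With `sigma2 = 0` the value is 0 when all residuals
#' vanish (exact fit) and `-Inf` otherwise.
#'
#' @inheritParams marginal_loglik
#' @param b `n x k` matrix of standardised random-effect coordinates.
#' @return Total log-likelihood (scalar).
#' @export
conditional_loglik <- function(y, fixed, A, subject, delta, psi, b, sigma2) {
  k <- length(delta)
  L <- delta * psi_matrix(psi, k)
  Z <- A %*% L
  re <- rowSums(Z * b[subject, , drop = FALSE])
  r <- y - fixed - re
  if (sigma2 > 0) {
    sum(stats::dnorm(r, 0, sqrt(sigma2), log = TRUE))
  } else {
    if (max(abs(r)) < 1e-8) 0 else -Inf
  }
}
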