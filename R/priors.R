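#' Prior specification for the grid-based Bayesian mixed model
#'
#' Inclusion probabilities default so that the expected numbers of active
#' main, epistatic and SNP-covariate effects are `expected_main`,
#' `expected_epi`, `expected_gt` (e.g. `w_main = expected_main / p`). The
#' per-effect slab variance prior is scaled inverse-chi-squared
#' `inv-chi2(nu_beta, s_beta2)` with `s_beta2` set from an expected per-effect
#' heritability: `s_beta2 = (nu_beta - 2) E(h) V / (nu_beta V_a)`, where `V`
#' is the total phenotypic variance and `V_a` the sample variance of the
#' term's design column (computed per term at proposal time). Grid-covariance
#' factors get independent half-normal `N+(m_delta0, s_delta02)` priors on
#' `delta` and independent `N(psi0, r0)` priors on the free elements of
#' `Psi`. The overall mean prior is `N(eta0, tau02)` with empirical defaults
#' (grand mean, sample variance of the trait), and the residual variance
#' prior is `inv-chi2(nu_sigma, s_sigma2)`.
#'
#' Data-dependent fields left `NULL` are filled when the model is fitted.
#'
#' @param w_main,w_epi,w_gt Per-type inclusion probabilities; if `NULL`,
#'   derived from the expected counts below.
#' @param expected_main,expected_epi,expected_gt Expected numbers of active
#'   effects per type used to derive default inclusion probabilities.
#' @param nu_beta Degrees of freedom of the slab-variance prior (default 6).
#' @param expected_h Expected per-effect heritability (default 0.1).
#' @param eta0,tau02 Overall-mean prior location/scale (defaults: trait mean
#'   and variance).
#' @param nu_sigma,s_sigma2 Residual-variance prior hyperparameters
#'   (defaults: 2 and the trait variance).
#' @param m_delta0,s_delta02 Half-normal location/scale for each `delta_l`
#'   (defaults 0 and 30).
#' @param psi0,r0 Normal prior mean/variance for each free `Psi` element
#'   (defaults 0 and 0.5).
#' @param cov_beta_var Prior variance of always-included covariate
#'   coefficients (default `100 * V`).
#' @return Object of class `gblmm_priors`.
#' @export
gblmm_priors <- function(w_main = NULL, w_epi = NULL, w_gt = NULL,
                         expected_main = 3, expected_epi = 1, expected_gt = 1,
                         nu_beta = 6, expected_h = 0.1,
                         eta0 = NULL, tau02 = NULL,
                         nu_sigma = 2, s_sigma2 = NULL,
                         m_delta0 = 0, s_delta02 = 30,
                         psi0 = 0, r0 = 0.5,
                         cov_beta_var = NULL) {
  stopifnot(nu_beta > 2, expected_h > 0, s_delta02 > 0, r0 > 0, nu_sigma > 0)
  structure(as.list(environment()), class = "gblmm_priors")
}

# Fill data-dependent hyperparameters from the trait and the effect catalog.
init_priors <- function(priors, y, catalog) {
  stopifnot(inherits(priors, "gblmm_priors"), inherits(catalog, "effect_catalog"))
  V <- stats::var(y)
  if (!is.finite(V) || V <= 0) stop("phenotype has zero variance; priors cannot be set")
  pr <- priors
  pr$V <- V
  if (is.null(pr$eta0)) pr$eta0 <- mean(y)
  if (is.null(pr$tau02)) pr$tau02 <- V
  if (is.null(pr$s_sigma2)) pr$s_sigma2 <- V
  if (is.null(pr$cov_beta_var)) pr$cov_beta_var <- 100 * V
  clip_w <- function(w) min(max(w, 1e-12), 0.5)
  if (is.null(pr$w_main)) pr$w_main <- clip_w(pr$expected_main / catalog$d_main)
  if (is.null(pr$w_epi)) {
    pr$w_epi <- if (catalog$d_epi > 0) clip_w(pr$expected_epi / catalog$d_epi) else 0
  }
  if (is.null(pr$w_gt)) {
    pr$w_gt <- if (catalog$d_gt > 0) clip_w(pr$expected_gt / catalog$d_gt) else 0
  }
  pr
}

#' Prior probability that any active effect involves a given SNP
#'
#' Under independent Bernoulli inclusion over the catalog and uniform
#' positions, one SNP is touched by 1 main term, `p - 1` epistatic terms and
#' `q` SNP-covariate terms, so by the complement rule
#' `P(kappa) = 1 - (1 - w_main)(1 - w_epi)^(p-1)(1 - w_gt)^q`.
#'
#' @param priors An initialised `gblmm_priors` (inclusion probabilities set).
#' @param catalog The [effect_catalog()].
#' @return Scalar prior inclusion probability per SNP position.
#' @export
prior_snp_inclusion <- function(priors, catalog) {
  w_epi <- if (catalog$p > 1) priors$w_epi else 0
  1 - (1 - priors$w_main) * (1 - w_epi)^(catalog$p - 1) * (1 - priors$w_gt)^catalog$q
}

#' MCMC control settings
#'
#' Defaults follow the reference analysis protocol: `4e5` sampling iterations
#' after `1000` burn-in sweeps, thinned every 40 draws (`1e4` retained
#' samples). Each sweep performs `mh_sweeps` Metropolis-Hastings model-space
#' moves (add / drop / swap-position / within-model refresh with
#' probabilities `move_probs`) followed by Gibbs updates of all continuous
#' blocks.
#'
#' @param n_iter Post-burn-in iterations.
#' @param burn_in Burn-in iterations (discarded).
#' @param thin Thinning interval; `floor(n_iter / thin)` samples retained.
#' @param seed Optional integer seed (`set.seed` is called when given).
#' @param mh_sweeps Model-space MH proposals per iteration.
#' @param move_probs Probabilities of the add / drop / swap / refresh moves.
#' @param effect_cap Maximum simultaneously active effects (default 3x the
#'   prior expected count).
#' @param update Named list of logical flags to disable individual update
#'   blocks (`gamma`, `beta`, `cov_beta`, `b`, `delta`, `psi`, `mu`,
#'   `sigma2`, `sigma_beta2`); missing entries default to `TRUE`.
#' @param init Named list of initial values (`mu`, `sigma2`, `delta`, `psi`,
#'   `b`); blocks that are not updated stay fixed at these values.
#' @param fix_sigma_beta2 Optional fixed slab variance shared by all active
#'   effects (disables the per-effect variance hierarchy; mainly for
#'   validation runs).
#' @param store_b If `TRUE`, retain the per-sample random-effect coordinates
#'   `b` (memory grows with `n * k * n_iter / thin`).
#' @return Object of class `gblmm_control`.
#' @export
gblmm_control <- function(n_iter = 4e5, burn_in = 1000, thin = 40, seed = NULL,
                          mh_sweeps = 5,
                          move_probs = c(add = 0.3, drop = 0.3, swap = 0.2, refresh = 0.2),
                          effect_cap = NULL, update = list(), init = list(),
                          fix_sigma_beta2 = NULL, store_b = FALSE) {
  stopifnot(n_iter >= 1, burn_in >= 0, thin >= 1, length(move_probs) == 4,
            all(move_probs >= 0), sum(move_probs) > 0)
  move_probs <- move_probs / sum(move_probs)
  structure(as.list(environment()), class = "gblmm_control")
}
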