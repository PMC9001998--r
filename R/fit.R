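#' Fit the grid-based Bayesian mixed model
#'
#' Jointly selects SNP main effects, SNP-SNP (epistatic) and SNP-covariate
#' interaction effects for a longitudinal trait, while modelling
#' within-subject dependence through random effects placed on `k` grid time
#' points and mapped to observation times by linear interpolation. The grid
#' covariance is factored as `D = Delta Psi Psi' Delta` (modified Cholesky)
#' so all variance components have conjugate normal / half-normal / scaled
#' inverse-chi-squared full conditionals; model-space indicators and SNP
#' positions are sampled by Metropolis-Hastings within Gibbs.
#'
#' @param phenotypes Long-format data frame with columns `subject`, `time`,
#'   `y` (one row per observation), plus optional extra covariate columns
#'   named in `covariates`.
#' @param genotypes `n x p` matrix of additive genotype codes (0/1/2 or
#'   dosages in `[0, 2]`); rows must correspond to the sorted unique subject
#'   ids. Missing genotypes are mean-imputed per SNP.
#' @param grid Either an integer number of grid points (equally spaced over
#'   the observed time range) or a [grid_spec()] / numeric vector of explicit
#'   grid times covering the observed range.
#' @param covariates Character vector of extra covariate columns in
#'   `phenotypes` (standardised time is always the first covariate).
#' @param priors A [gblmm_priors()] specification.
#' @param control A [gblmm_control()] specification.
#' @param random_effects If `FALSE`, fit the fixed-effect-only variable
#'   selection model (no grid random effects); used e.g. for single-time-point
#'   comparisons.
#' @param identifiability One of `"check"` (refuse non-identifiable
#'   designs), `"fix_sigma2"` (freeze `sigma^2` at 0 and model `D` directly)
#'   or `"ignore"`.
#' @return An object of class `gblmm`; see [summary.gblmm()],
#'   [genome_profile()], [compute_dic()].
#' @export
#' @examples
#' sim <- sim_study(setup = 1, n = 40, N = 200, p = 20, seed = 1)
#' fit <- gblmm(sim$phenotypes, sim$genotypes, grid = 3,
#'              control = gblmm_control(n_iter = 500, burn_in = 100,
#'                                      thin = 5, seed = 1))
#' fit
gblmm <- function(phenotypes, genotypes, grid = 3, covariates = NULL,
                  priors = gblmm_priors(), control = gblmm_control(),
                  random_effects = TRUE,
                  identifiability = c("check", "fix_sigma2", "ignore")) {
  identifiability <- match.arg(identifiability)
  stopifnot(is.data.frame(phenotypes),
            all(c("subject", "time", "y") %in% names(phenotypes)))
  if (!is.numeric(phenotypes$y)) stop("trait column 'y' must be numeric")
  if (anyNA(phenotypes$y) || anyNA(phenotypes$time)) stop("missing time/trait values")
  if (anyDuplicated(phenotypes[c("subject", "time")])) {
    stop("duplicate (subject, time) rows in phenotypes")
  }
  genotypes <- as.matrix(genotypes)
  subj_ids <- sort(unique(phenotypes$subject))
  n <- length(subj_ids)
  if (nrow(genotypes) != n) {
    stop(sprintf("genotypes has %d rows but phenotypes contain %d subjects",
                 nrow(genotypes), n))
  }
  if (anyNA(genotypes)) { # per-SNP mean imputation
    for (j in which(colSums(is.na(genotypes)) > 0)) {
      genotypes[is.na(genotypes[, j]), j] <- mean(genotypes[, j], na.rm = TRUE)
    }
  }
  ord <- order(match(phenotypes$subject, subj_ids), phenotypes$time)
  ph <- phenotypes[ord, , drop = FALSE]
  subject <- match(ph$subject, subj_ids)
  y <- as.numeric(ph$y)
  time <- as.numeric(ph$time)
  N <- length(y)

  if (!random_effects) {
    # grid is unused without random effects; any covering grid will do
    gs <- if (diff(range(time)) > 0) default_grid(time, 2) else grid_spec(time[1])
  } else if (inherits(grid, "grid_spec")) {
    gs <- grid
  } else if (length(grid) == 1L) {
    gs <- default_grid(time, grid)
  } else {
    gs <- grid_spec(grid)
  }
  k <- gs$k
  times_by_subj <- split(time, subject)
  im <- interp_matrix(times_by_subj, gs)

  ident <- identifiability_check(im$blocks)
  fix_sigma2 <- FALSE
  if (random_effects && identifiability != "ignore" && !ident$identifiable) {
    action <- resolve_nonidentifiable(ident, identifiability == "fix_sigma2")
    fix_sigma2 <- identical(action, "fix_sigma2")
  }

  tstd <- as.numeric(scale(time))
  Cov <- cbind(tstd = tstd)
  if (!is.null(covariates)) {
    miss <- setdiff(covariates, names(ph))
    if (length(miss)) stop("covariates not found in phenotypes: ",
                           paste(miss, collapse = ", "))
    Cov <- cbind(Cov, as.matrix(ph[covariates]))
  }
  catalog <- effect_catalog(ncol(genotypes), ncol(Cov))
  pr <- init_priors(priors, y, catalog)
  ctl <- control
  if (is.null(ctl$effect_cap)) {
    ctl$effect_cap <- max(3L, ceiling(3 * (pr$expected_main + pr$expected_epi +
                                             pr$expected_gt)))
  }
  if (!is.null(ctl$seed)) set.seed(ctl$seed)

  upd <- function(name, default = TRUE) {
    v <- ctl$update[[name]]
    if (is.null(v)) default else isTRUE(v)
  }
  init_of <- function(name, default) {
    v <- ctl$init[[name]]
    if (is.null(v)) default else v
  }
  npsi <- k * (k - 1) / 2
  sigma2_init <- init_of("sigma2", pr$V / 2)
  upd_sigma2 <- upd("sigma2")
  if (fix_sigma2) {
    sigma2_init <- 1e-8
    upd_sigma2 <- FALSE
  }
  re_on <- random_effects
  init_list <- list(
    mu = init_of("mu", mean(y)),
    sigma2 = sigma2_init,
    delta = init_of("delta", if (re_on) rep(sqrt(pr$V) / 2, k) else rep(0, k)),
    psi = init_of("psi", rep(0, npsi)),
    b = init_of("b", matrix(0, n, k)),
    cov_beta = rep(0, ncol(Cov)),
    active = data.frame(type = integer(), snp1 = integer(), snp2 = integer(),
                        beta = numeric(), sigb2 = numeric())
  )
  ctl_list <- list(
    n_iter = as.integer(ctl$n_iter), burn_in = as.integer(ctl$burn_in),
    thin = as.integer(ctl$thin), mh_sweeps = as.integer(ctl$mh_sweeps),
    move_probs = as.numeric(ctl$move_probs),
    effect_cap = as.integer(ctl$effect_cap),
    upd_gamma = upd("gamma"), upd_beta = upd("beta"),
    upd_cov_beta = upd("cov_beta"), upd_b = upd("b") && re_on,
    upd_delta = upd("delta") && re_on, upd_psi = upd("psi") && re_on,
    upd_mu = upd("mu"), upd_sigma2 = upd_sigma2,
    upd_sigma_beta2 = upd("sigma_beta2"),
    fix_sigma_beta2 = if (is.null(ctl$fix_sigma_beta2)) NaN else ctl$fix_sigma_beta2,
    store_b = isTRUE(ctl$store_b)
  )
  pr_list <- list(
    w = c(pr$w_main, pr$w_epi, pr$w_gt), nu_beta = pr$nu_beta,
    expected_h = pr$expected_h, V = pr$V, eta0 = pr$eta0, tau02 = pr$tau02,
    nu_sigma = pr$nu_sigma, s_sigma2 = pr$s_sigma2,
    m_delta0 = pr$m_delta0, s_delta02 = pr$s_delta02,
    psi0 = pr$psi0, r0 = pr$r0, cov_beta_var = pr$cov_beta_var
  )

  res <- mcmc_run(y, as.integer(subject - 1L), im$A, genotypes, Cov,
                  pr_list, ctl_list, init_list)

  eff <- res$effects
  eff$snp2[eff$type == 0L] <- NA_integer_
  eff$type <- factor(c("main", "epi", "gt")[eff$type + 1L],
                     levels = c("main", "epi", "gt"))
  if (fix_sigma2) res$sigma2[] <- 0

  colnames(res$delta) <- paste0("delta", seq_len(k))
  colnames(res$cov_beta) <- colnames(Cov)
  if (npsi > 0) {
    nm <- character(npsi); pos <- 1L
    for (m in 2:k) for (l in 1:(m - 1)) { nm[pos] <- paste0("psi", m, l); pos <- pos + 1L }
    colnames(res$psi) <- nm
  }

  structure(
    list(
      samples = list(mu = as.numeric(res$mu), sigma2 = as.numeric(res$sigma2),
                     delta = res$delta, psi = res$psi,
                     cov_beta = res$cov_beta, n_active = as.integer(res$n_active),
                     loglik_marg = as.numeric(res$loglik_marg),
                     loglik_cond = as.numeric(res$loglik_cond),
                     b = if (isTRUE(ctl$store_b)) res$b_samples),
      effects = eff, n_samples = res$n_samples,
      fit_mean = as.numeric(res$fit_mean), b_mean = res$b_mean,
      y = y, time = time, subject = subject, subj_ids = subj_ids,
      covariate_names = colnames(Cov),
      grid = gs, interp = im, catalog = catalog,
      priors = pr, control = ctl, identifiability = ident,
      fix_sigma2 = fix_sigma2, random_effects = re_on,
      prior_snp = prior_snp_inclusion(pr, catalog)
    ),
    class = "gblmm"
  )
}

#' @export
print.gblmm <- function(x, ...) {
  cat("Grid-based Bayesian longitudinal mixed model fit\n")
  cat(sprintf("  %d subjects, %d observations, %d SNPs, k = %d grid points\n",
              length(x$subj_ids), length(x$y), x$catalog$p, x$grid$k))
  cat(sprintf("  %d retained MCMC samples (thin %d after %d burn-in)\n",
              x$n_samples, x$control$thin, x$control$burn_in))
  if (x$fix_sigma2) cat("  sigma^2 fixed at 0 (non-identifiable design)\n")
  cat(sprintf("  posterior means: sigma2 = %.3f, mean active effects = %.2f\n",
              mean(x$samples$sigma2), mean(x$samples$n_active)))
  invisible(x)
}

#' Posterior summary of a fitted model
#'
#' Posterior mean, median, SD and 95% HPD interval for the residual variance,
#' overall mean, covariance factors and covariate effects, plus the top SNPs
#' ranked by Bayes factor.
#'
#' @param object A `gblmm` fit.
#' @param top Number of top SNPs to tabulate (default 10).
#' @param ... Unused.
#' @export
summary.gblmm <- function(object, top = 10, ...) {
  sm <- function(v) {
    h <- hpd(v)
    c(mean = mean(v), median = stats::median(v), sd = stats::sd(v),
      hpd_lower = h[1], hpd_upper = h[2])
  }
  pars <- cbind(
    mu = sm(object$samples$mu), sigma2 = sm(object$samples$sigma2),
    apply(object$samples$delta, 2, sm),
    if (ncol(object$samples$psi) > 0) apply(object$samples$psi, 2, sm),
    apply(object$samples$cov_beta, 2, sm)
  )
  colnames(pars)[seq_len(2)] <- c("mu", "sigma2")
  prof <- genome_profile(object)
  prof <- prof[order(-prof$bf), ]
  structure(list(parameters = t(pars), top_snps = utils::head(prof, top),
                 n_samples = object$n_samples, fix_sigma2 = object$fix_sigma2),
            class = "summary.gblmm")
}

#' @export
print.summary.gblmm <- function(x, ...) {
  cat("Posterior summaries (", x$n_samples, " samples)\n", sep = "")
  print(round(x$parameters, 3))
  cat("\nTop SNPs by Bayes factor:\n")
  print(x$top_snps, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Posterior-mean effect sizes of the selected genetic terms
#'
#' @param object A `gblmm` fit.
#' @param min_prob Report terms whose inclusion probability exceeds this
#'   threshold (default 0.01).
#' @param ... Unused.
#' @return Data frame of terms with inclusion probability and
#'   inclusion-conditional posterior mean effect size.
#' @export
coef.gblmm <- function(object, min_prob = 0.01, ...) {
  eff <- object$effects
  if (nrow(eff) == 0L) {
    return(data.frame(type = factor(character(), levels = c("main", "epi", "gt")),
                      snp1 = integer(), snp2 = integer(),
                      prob = numeric(), beta = numeric()))
  }
  key <- paste(eff$type, eff$snp1, eff$snp2, sep = ":")
  agg <- do.call(rbind, lapply(split(seq_len(nrow(eff)), key), function(i) {
    data.frame(type = eff$type[i[1]], snp1 = eff$snp1[i[1]], snp2 = eff$snp2[i[1]],
               prob = length(unique(eff$sample[i])) / object$n_samples,
               beta = mean(eff$beta[i]))
  }))
  agg <- agg[agg$prob >= min_prob, ]
  agg[order(-agg$prob), ]
}

#' @export
fitted.gblmm <- function(object, ...) {
  mean(object$samples$mu) + object$fit_mean +
    rowSums((object$interp$A %*%
               (colMeans(object$samples$delta) *
                  psi_matrix(colMeans(object$samples$psi), object$grid$k))) *
              object$b_mean[object$subject, , drop = FALSE])
}

#' @export
residuals.gblmm <- function(object, ...) {
  object$y - fitted(object)
}

#' Genome-wide evidence profile plot
#'
#' Plots `2 log BF` per SNP for the combined (any-effect) inclusion evidence,
#' with the conventional weak/moderate/strong support thresholds
#' (`BF` = 3, 10, 30) as horizontal lines.
#'
#' @param x A `gblmm` fit.
#' @param causal Optional integer vector of truly causal SNP indices to mark.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.gblmm <- function(x, causal = NULL, ...) {
  prof <- genome_profile(x)
  graphics::plot(prof$snp, prof$two_log_bf, type = "h",
                 xlab = "SNP index", ylab = "2 log BF", ...)
  graphics::abline(h = 2 * log(c(3, 10, 30)), lty = 3, col = "grey40")
  if (!is.null(causal)) graphics::abline(v = causal, col = "red", lty = 2)
  invisible(prof)
}
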