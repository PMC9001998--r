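#' Coefficient matrix of the covariance identifiability system
#'
#' The marginal covariance of the stacked phenotypes is `P D* P' + sigma^2 I`
#' with `D* = I_n (x) D`. Two parameterisations `(D, sigma^2)` are
#' observationally equivalent iff the homogeneous linear system `A X = 0` has
#' a nonzero solution, where `X` stacks the upper triangle of a symmetric
#' difference matrix and a scalar variance difference, and each row of `A`
#' encodes one upper-triangular element `(j, j')` of
#' `p_i D~ p_i' + sigma~^2 I = 0`. The coefficient of `d~_{r,s}` (`r <= s`)
#' in that row is `a_{ijr} a_{ij's} + [r != s] a_{ijs} a_{ij'r}`; the
#' coefficient of `sigma~^2` is 1 iff `j == j'`.
#'
#' Column order: `d~_{1,1}, d~_{1,2}, ..., d~_{1,k}, d~_{2,2}, ..., d~_{k,k},
#' sigma~^2`. Duplicate rows from identical subjects are retained, so the row
#' count is exactly `sum_i n_i (n_i + 1) / 2`.
#'
#' @param interp A list of per-subject `n_i x k` interpolation matrices (the
#'   `blocks` element of [interp_matrix()]).
#' @return Matrix with `sum n_i(n_i+1)/2` rows and `k(k+1)/2 + 1` columns.
#' @export
identifiability_matrix <- function(interp) {
  stopifnot(is.list(interp), length(interp) >= 1L)
  k <- ncol(interp[[1L]])
  if (!all(vapply(interp, ncol, integer(1)) == k)) {
    stop("all subjects must share the same grid dimension k")
  }
  ncolA <- k * (k + 1) / 2 + 1L
  # column index of d~_{r,s} for r <= s in row-major upper-triangle order
  colD <- function(r, s) (r - 1L) * (k + 1L) - r * (r - 1L) / 2 + (s - r + 1L)
  nrows <- sum(vapply(interp, function(m) nrow(m) * (nrow(m) + 1L) / 2, numeric(1)))
  A <- matrix(0, nrows, ncolA)
  rw <- 0L
  for (p_i in interp) {
    ni <- nrow(p_i)
    for (j in seq_len(ni)) {
      for (jp in j:ni) {
        rw <- rw + 1L
        for (r in seq_len(k)) {
          for (s in r:k) {
            v <- p_i[j, r] * p_i[jp, s]
            if (r != s) v <- v + p_i[j, s] * p_i[jp, r]
            A[rw, colD(r, s)] <- v
          }
        }
        if (j == jp) A[rw, ncolA] <- 1
      }
    }
  }
  A
}

#' Rank-based identifiability test for the grid covariance model
#'
#' The model's variance components `(D, sigma^2)` are identifiable from the
#' marginal covariance iff `rank(A) = k(k+1)/2 + 1`. Rank is computed from
#' singular values with tolerance `max(dim(A)) * eps * max(sv)`.
#'
#' @param interp A list of per-subject interpolation matrices, or the list
#'   returned by [interp_matrix()].
#' @return An object of class `gblmm_ident` with fields `rank`, `required`,
#'   `identifiable`, `n`, `k`, and `tol`.
#' @export
#' @examples
#' g <- grid_spec(c(0, 0.5, 1))
#' im <- interp_matrix(rep(list(c(0, 0.5, 1)), 4), g)
#' identifiability_check(im)          # rank 6 < 7: not identifiable
identifiability_check <- function(interp) {
  if (is.list(interp) && !is.null(interp$blocks)) interp <- interp$blocks
  k <- ncol(interp[[1L]])
  A <- identifiability_matrix(interp)
  sv <- svd(A, nu = 0, nv = 0)$d
  tol <- max(dim(A)) * .Machine$double.eps * max(sv, 0)
  rk <- sum(sv > tol)
  required <- as.integer(k * (k + 1) / 2 + 1)
  structure(
    list(
      rank = rk, required = required, identifiable = rk == required,
      n = length(interp), k = k, tol = tol
    ),
    class = "gblmm_ident"
  )
}

#' @export
print.gblmm_ident <- function(x, ...) {
  cat("Covariance identifiability check\n")
  cat(sprintf("  subjects: %d, grid points k: %d\n", x$n, x$k))
  cat(sprintf("  rank(A) = %d, required = k(k+1)/2 + 1 = %d\n", x$rank, x$required))
  cat(if (x$identifiable) "  model is identifiable\n" else
    sprintf("  NOT identifiable (rank deficit %d); consider fix_sigma2 = TRUE or an off-grid observation\n",
            x$required - x$rank))
  invisible(x)
}

#' Resolve a non-identifiable covariance design
#'
#' When every subject is observed exactly on the grid the marginal covariance
#' cannot separate `D` from `sigma^2`. The remedy is to fix `sigma^2 = 0` and
#' model `D` directly (skipping the residual-variance update); otherwise the
#' fit is refused with a diagnostic naming the rank deficit.
#'
#' @param check An object from [identifiability_check()].
#' @param fix_sigma2 Logical; if `TRUE` the returned action freezes
#'   `sigma^2` at 0 instead of raising an error.
#' @return Invisibly, one of `"none"` (already identifiable) or
#'   `"fix_sigma2"`.
#' @export
resolve_nonidentifiable <- function(check, fix_sigma2 = FALSE) {
  stopifnot(inherits(check, "gblmm_ident"))
  if (check$identifiable) return(invisible("none"))
  if (fix_sigma2) return(invisible("fix_sigma2"))
  stop(sprintf(
    paste0("model not identifiable: rank(A) = %d but %d is required ",
           "(rank deficit %d). Set fix_sigma2 = TRUE to model D directly with ",
           "sigma^2 = 0, or add off-grid observations."),
    check$rank, check$required, check$required - check$rank
  ))
}
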