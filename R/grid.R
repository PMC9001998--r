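#' Grid specification for random-effect time points
#'
#' A grid is an ordered set of `k` time values at which the subject-level
#' random effects live. Every observation time is mapped onto the grid by
#' linear interpolation between its two bracketing grid points, so the grid
#' must cover the full observed time range (no extrapolation is performed).
#'
#' @param points Numeric vector of strictly increasing time values.
#' @return An object of class `grid_spec` with elements `points` and `k`.
#' @seealso [default_grid()], [interp_weights()], [interp_matrix()]
#' @export
#' @examples
#' grid_spec(c(0, 0.5, 1))
grid_spec <- function(points) {
  points <- as.numeric(points)
  if (length(points) < 1L || anyNA(points)) {
    stop("grid must contain at least one finite time value")
  }
  if (length(points) > 1L && any(diff(points) <= 0)) {
    stop("grid points must be strictly increasing")
  }
  structure(list(points = points, k = length(points)), class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat("Time grid with", x$k, "points:", paste(signif(x$points, 6), collapse = ", "), "\n")
  invisible(x)
}

#' Equally spaced default grid over the observed time range
#'
#' @param times Numeric vector of all observed times (pooled across subjects).
#' @param k Number of grid points (>= 2 unless all times coincide).
#' @return A [grid_spec()] spanning `[min(times), max(times)]`.
#' @export
#' @examples
#' default_grid(c(0, 0.3, 1), 3)  # 0, 0.5, 1
default_grid <- function(times, k) {
  if (length(k) != 1L || is.na(k) || k < 1) stop("k must be a positive integer")
  k <- as.integer(k)
  rng <- range(times)
  if (k == 1L) {
    if (diff(rng) > 0) {
      stop("k = 1 only admissible when all observation times are identical")
    }
    return(grid_spec(rng[1L]))
  }
  grid_spec(seq(rng[1L], rng[2L], length.out = k))
}

#' Linear interpolation weights of one observation time onto the grid
#'
#' Returns the length-`k` weight vector placing mass `(t_{r+1}-t)/(t_{r+1}-t_r)`
#' and `(t-t_r)/(t_{r+1}-t_r)` on the two grid points bracketing `t`. A time
#' equal to a grid point yields that point's unit vector. Rows are
#' row-stochastic with at most two adjacent nonzero entries.
#'
#' @param t A single observation time within the grid span.
#' @param grid A [grid_spec()].
#' @return Numeric weight vector of length `grid$k`.
#' @export
#' @examples
#' interp_weights(0.25, grid_spec(c(0, 0.5, 1)))  # 0.5 0.5 0.0
interp_weights <- function(t, grid) {
  stopifnot(inherits(grid, "grid_spec"), length(t) == 1L, is.finite(t))
  pts <- grid$points
  k <- grid$k
  if (t < pts[1L] || t > pts[k]) {
    stop(sprintf(
      "observation time %g outside grid span [%g, %g]; extend the grid (no extrapolation)",
      t, pts[1L], pts[k]
    ))
  }
  w <- numeric(k)
  hit <- which(t == pts)
  if (length(hit)) {
    w[hit[1L]] <- 1
    return(w)
  }
  r <- findInterval(t, pts)
  h <- pts[r + 1L] - pts[r]
  w[r] <- (pts[r + 1L] - t) / h
  w[r + 1L] <- (t - pts[r]) / h
  w
}

#' Per-subject interpolation matrices and the block-diagonal P
#'
#' @param times A list with one numeric vector of observation times per
#'   subject (each nonempty).
#' @param grid A [grid_spec()].
#' @return A list with `blocks` (per-subject `n_i x k` matrices), `P` (the
#'   `N x nk` block-diagonal assembly), `A` (the `N x k` row-stack of all
#'   weights) and `subject` (subject index of each row of `A`).
#' @export
interp_matrix <- function(times, grid) {
  stopifnot(inherits(grid, "grid_spec"), is.list(times), length(times) >= 1L)
  k <- grid$k
  blocks <- lapply(times, function(tt) {
    if (length(tt) < 1L) stop("every subject needs at least one observation")
    m <- t(vapply(tt, interp_weights, numeric(k), grid = grid))
    dim(m) <- c(length(tt), k)
    m
  })
  n <- length(blocks)
  ni <- vapply(blocks, nrow, integer(1))
  N <- sum(ni)
  P <- matrix(0, N, n * k)
  row0 <- 0L
  for (i in seq_len(n)) {
    P[row0 + seq_len(ni[i]), (i - 1L) * k + seq_len(k)] <- blocks[[i]]
    row0 <- row0 + ni[i]
  }
  list(
    blocks = blocks, P = P,
    A = do.call(rbind, blocks),
    subject = rep(seq_len(n), ni)
  )
}

#' Unit-lower-triangular matrix from the packed psi vector
#'
#' The packed order is row-wise: (2,1), (3,1), (3,2), (4,1), (4,2), (4,3), ...
#'
#' @param psi Packed vector of length `k(k-1)/2`, or an already-formed
#'   unit-lower-triangular `k x k` matrix.
#' @param k Grid dimension.
#' @return A `k x k` unit-lower-triangular matrix.
#' @export
psi_matrix <- function(psi, k) {
  if (is.matrix(psi)) {
    stopifnot(nrow(psi) == k, ncol(psi) == k)
    if (any(abs(diag(psi) - 1) > 1e-12) || any(abs(psi[upper.tri(psi)]) > 1e-12)) {
      stop("psi matrix must be unit-lower-triangular")
    }
    return(psi)
  }
  npsi <- k * (k - 1) / 2
  if (length(psi) != npsi) {
    stop(sprintf("psi must have length k(k-1)/2 = %d", npsi))
  }
  Psi <- diag(1, k)
  if (k >= 2L) {
    pos <- 1L
    for (m in 2:k) {
      Psi[m, seq_len(m - 1L)] <- psi[pos:(pos + m - 2L)]
      pos <- pos + m - 1L
    }
  }
  Psi
}

#' Reconstruct the grid covariance from its modified Cholesky factors
#'
#' The grid covariance is factored as `D = Delta Psi Psi' Delta` with `Delta =
#' diag(delta)` nonnegative and `Psi` unit lower triangular, so `D = LL'` with
#' `L = Delta Psi`. This parameterisation allows conjugate half-normal priors
#' on `delta` and normal priors on the free elements of `Psi`.
#'
#' @param delta Nonnegative vector of length `k`.
#' @param psi Packed lower-triangle vector (length `k(k-1)/2`, row-wise) or a
#'   unit-lower-triangular matrix.
#' @return The `k x k` covariance matrix `D`.
#' @export
#' @examples
#' D <- reconstruct_D(c(1, 1.2, 0.8), c(0.6, 0.4, 0.6))
#' round(diag(D), 2)  # 1.00 1.96 0.97
reconstruct_D <- function(delta, psi) {
  delta <- as.numeric(delta)
  if (any(!is.finite(delta)) || any(delta < 0)) {
    stop("delta entries must be finite and nonnegative")
  }
  k <- length(delta)
  L <- delta * psi_matrix(psi, k)  # row-scaling = diag(delta) %*% Psi
  tcrossprod(L)
}
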