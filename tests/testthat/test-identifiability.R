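test_that("the all-on-grid k=3 design reproduces the printed coefficient system", {
  g <- grid_spec(c(0, 0.5, 1))
  im <- interp_matrix(rep(list(c(0, 0.5, 1)), 4), g)
  A <- identifiability_matrix(im$blocks)
  expect_equal(dim(A), c(4 * 6L, 7L))
  # rows for one subject, pairs (1,1), (1,2), (1,3), (2,2), (2,3), (3,3)
  A1 <- matrix(c(
    1, 0, 0, 0, 0, 0, 1,
    0, 1, 0, 0, 0, 0, 0,
    0, 0, 1, 0, 0, 0, 0,
    0, 0, 0, 1, 0, 0, 1,
    0, 0, 0, 0, 1, 0, 0,
    0, 0, 0, 0, 0, 1, 1
  ), 6, 7, byrow = TRUE)
  expect_equal(A[1:6, ], A1)
  chk <- identifiability_check(im)
  expect_equal(chk$rank, 6L)
  expect_equal(chk$required, 7L)
  expect_false(chk$identifiable)
})

test_that("one off-grid observation restores identifiability (rank 6 -> 7)", {
  g <- grid_spec(c(0, 0.5, 1))
  times <- c(rep(list(c(0, 0.5, 1)), 4), list(0.3))
  chk <- identifiability_check(interp_matrix(times, g))
  expect_equal(chk$rank, 7L)
  expect_true(chk$identifiable)
})

test_that("a k=1 subject with two on-grid observations is identifiable (rank 2)", {
  # rows: (1,1) -> d11 + s2, (1,2) -> d11; independent, rank 2 = 1*2/2 + 1
  blocks <- list(matrix(1, 2, 1))
  chk <- identifiability_check(blocks)
  expect_equal(chk$rank, 2L)
  expect_true(chk$identifiable)
})

test_that("A rows encode the stacked upper triangle of P D~ P' + s2~ I", {
  set.seed(4)
  g <- grid_spec(c(0, 0.4, 1))
  times <- list(c(0.1, 0.7), c(0, 0.55, 0.9), 0.25)
  im <- interp_matrix(times, g)
  A <- identifiability_matrix(im$blocks)
  k <- 3
  for (rep in 1:5) {
    Dt <- matrix(rnorm(k * k), k); Dt <- Dt + t(Dt)
    s2t <- rnorm(1)
    x <- c(Dt[1, 1], Dt[1, 2], Dt[1, 3], Dt[2, 2], Dt[2, 3], Dt[3, 3], s2t)
    lhs <- as.numeric(A %*% x)
    rhs <- unlist(lapply(im$blocks, function(p_i) {
      M <- p_i %*% Dt %*% t(p_i) + s2t * diag(nrow(p_i))
      out <- c()
      for (j in seq_len(nrow(M))) for (jp in j:nrow(M)) out <- c(out, M[j, jp])
      out
    }))
    expect_equal(lhs, as.numeric(rhs), tolerance = 1e-10)
  }
})

test_that("rank is invariant to subject reordering and duplication, monotone in data", {
  g <- grid_spec(c(0, 0.5, 1))
  times <- list(c(0, 0.5, 1), c(0.2, 0.8), 0.4)
  rk <- identifiability_check(interp_matrix(times, g))$rank
  expect_equal(identifiability_check(interp_matrix(rev(times), g))$rank, rk)
  expect_equal(identifiability_check(interp_matrix(c(times, times), g))$rank, rk)
  # adding an observation never decreases rank
  more <- list(c(0, 0.5, 1), c(0.2, 0.8, 0.65), 0.4)
  expect_gte(identifiability_check(interp_matrix(more, g))$rank, rk)
})

test_that("non-identifiable designs error unless the sigma2 = 0 fix is requested", {
  g <- grid_spec(c(0, 0.5, 1))
  chk_bad <- identifiability_check(interp_matrix(rep(list(c(0, 0.5, 1)), 3), g))
  expect_error(resolve_nonidentifiable(chk_bad), "rank deficit 1")
  expect_equal(resolve_nonidentifiable(chk_bad, fix_sigma2 = TRUE), "fix_sigma2")
  chk_ok <- identifiability_check(interp_matrix(list(c(0, 0.5, 1), 0.3), g))
  expect_equal(resolve_nonidentifiable(chk_ok), "none")
})

test_that("a non-identifiable fit completes with sigma2 frozen at zero", {
  set.seed(6)
  n <- 12
  times <- rep(list(c(0, 0.5, 1)), n)
  subject <- rep(1:n, each = 3)
  G <- matrix(rbinom(n * 2, 2, 0.4), n, 2)
  y <- rnorm(3 * n) + rep(rnorm(n), each = 3)
  ph <- data.frame(subject = subject, time = unlist(times), y = y)
  expect_error(
    gblmm(ph, G, grid = 3, control = gblmm_control(n_iter = 50, burn_in = 10,
                                                   thin = 1, seed = 1)),
    "not identifiable")
  fit <- gblmm(ph, G, grid = 3, identifiability = "fix_sigma2",
               control = gblmm_control(n_iter = 200, burn_in = 50, thin = 2, seed = 1))
  expect_true(fit$fix_sigma2)
  expect_true(all(fit$samples$sigma2 == 0))
  expect_true(all(is.finite(fit$samples$delta)))
})
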