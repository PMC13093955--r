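test_that("zero-order-hold discretization handles limits and matches RK4", {
  # A = 0 analytic limit
  dz <- discretize(0, 2.5, 0.3)
  expect_equal(dz$Abar, 1)
  expect_equal(dz$Bbar, 0.3 * 2.5)
  # delta -> 0 with A < 0
  dz <- discretize(-2, 1, 1e-9)
  expect_equal(dz$Abar, 1, tolerance = 1e-6)
  expect_equal(dz$Bbar, 0, tolerance = 1e-6)
  expect_error(discretize(-1, 1, 0), "positive")
  expect_error(discretize(-1, 1, -0.1), "positive")
  # one-step integration oracle: x(delta) from x0 with constant input
  set.seed(21)
  for (k in 1:20) {
    A <- -runif(1, 0.1, 5); B <- rnorm(1); u <- rnorm(1); x0 <- rnorm(1)
    dz <- discretize(A, B, 0.1)
    x_exact <- dz$Abar * x0 + dz$Bbar * u
    x_rk4 <- oracle_rk4_step(A, B, u, 0.1, x0)
    expect_equal(x_exact, x_rk4, tolerance = 1e-6)
  }
})

test_that("sequential scan matches closed forms and the dense operator", {
  set.seed(22)
  p <- ssm_params(3, d_state = 4)
  # zero input stays zero
  expect_equal(unclass(selective_scan(matrix(0, 5, 3), p))[1:15],
               rep(0, 15), ignore_attr = TRUE)
  # single step closed form
  u1 <- rnorm(3)
  y <- selective_scan(matrix(u1, 1, 3), p)
  delta <- log1p(exp(drop(u1 %*% p$W_delta) + p$b_delta))
  Bt <- drop(u1 %*% p$W_B); Ct <- drop(u1 %*% p$W_C)
  y_exp <- vapply(1:3, function(i) {
    s_terms <- vapply(1:4, function(s) {
      ab <- exp(delta[i] * p$A[s])
      Ct[s] * ((ab - 1) / p$A[s]) * Bt[s] * u1[i]
    }, numeric(1))
    sum(s_terms) + p$D[i] * u1[i]
  }, numeric(1))
  expect_equal(drop(unclass(y)), y_exp, tolerance = 1e-10,
               ignore_attr = TRUE)
  # dense T x T operator oracle at T = 8
  for (k in 1:5) {
    p <- ssm_params(3, d_state = 4)
    U <- matrix(rnorm(8 * 3), 8, 3)
    expect_equal(unclass(selective_scan(U, p))[, ],
                 oracle_selective_scan(U, p), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
  expect_error(selective_scan(matrix(0, 3, 5), p), "width")
  expect_error(selective_scan(matrix(NA_real_, 2, 3), p), "finite")
})

test_that("batched scan kernels agree with the sequential reference", {
  set.seed(23)
  worst <- 0
  for (k in 1:200) {
    di <- sample(2:5, 1); ns <- sample(2:6, 1); T_ <- sample(1:9, 1)
    p <- ssm_params(di, d_state = ns)
    U <- matrix(rnorm(T_ * di), T_, di)
    ref <- unclass(selective_scan(U, p))
    # rebuild the scan inputs the way the block does and call both batched
    # implementations
    Ub <- array(U, c(1, T_, di))
    delta <- array(log1p(exp(pmin(U %*% p$W_delta +
                                    rep(p$b_delta, each = T_), 30))),
                   c(1, T_, di))
    Bt <- array(U %*% p$W_B, c(1, T_, ns))
    Ct <- array(U %*% p$W_C, c(1, T_, ns))
    got_cpp <- ddimamba:::scan_batch_forward(Ub, delta, Bt, Ct, p$A, p$D)$Y
    got_r <- ddimamba:::scan_batch_forward_r(Ub, delta, Bt, Ct, p$A, p$D)$Y
    worst <- max(worst, max(abs(matrix(got_cpp, T_, di) - ref)),
                 max(abs(matrix(got_r, T_, di) - ref)))
  }
  expect_lt(worst, 1e-5)
})

test_that("batched scan gradient matches the pure-R reverse recurrence", {
  set.seed(24)
  for (k in 1:10) {
    B <- 3; T_ <- 5; di <- 4; ns <- 3
    U <- array(rnorm(B * T_ * di), c(B, T_, di))
    delta <- array(runif(B * T_ * di, 0.05, 1), c(B, T_, di))
    Bt <- array(rnorm(B * T_ * ns), c(B, T_, ns))
    Ct <- array(rnorm(B * T_ * ns), c(B, T_, ns))
    A <- -(1:ns); D <- rnorm(di)
    dY <- array(rnorm(B * T_ * di), c(B, T_, di))
    f_cpp <- ddimamba:::scan_batch_forward(U, delta, Bt, Ct, A, D)
    f_r <- ddimamba:::scan_batch_forward_r(U, delta, Bt, Ct, A, D)
    expect_equal(f_cpp$Y, f_r$Y, tolerance = 1e-10)
    g_cpp <- ddimamba:::scan_batch_backward(f_cpp, dY)
    g_r <- ddimamba:::scan_batch_backward_r(f_r, dY)
    for (nm in c("dU", "ddelta", "dB", "dC", "dD")) {
      expect_equal(g_cpp[[nm]], g_r[[nm]], tolerance = 1e-8)
    }
  }
})

test_that("the Mamba block is causal", {
  set.seed(25)
  p <- mamba_params(6, d_state = 4, dropout = 0)
  X <- matrix(rnorm(12 * 6), 12, 6)
  Y <- mamba_block(X, p)
  for (t in c(3, 7, 11)) {
    X2 <- X
    X2[(t + 1):12, ] <- rnorm((12 - t) * 6) * 5
    Y2 <- mamba_block(X2, p)
    expect_equal(Y2[1:t, ], Y[1:t, ], tolerance = 1e-12)
    expect_false(isTRUE(all.equal(Y2[(t + 1):12, ], Y[(t + 1):12, ])))
  }
  expect_error(mamba_block(matrix(NA_real_, 2, 6), p), "non-finite")
})

test_that("identity-wired block reduces to a gated passthrough", {
  d <- 4
  p <- mamba_params(d, d_state = 3, expand = 1, dropout = 0)
  p$in_proj$W <- cbind(diag(d), diag(d)); p$in_proj$b <- rep(0, 2 * d)
  p$conv$w[] <- 0; p$conv$w[1, ] <- 1; p$conv$b[] <- 0
  p$W_B[] <- 0; p$W_C[] <- 0
  p$D <- rep(1, d)
  p$out_proj$W <- diag(d); p$out_proj$b <- rep(0, d)
  set.seed(26)
  X <- matrix(rnorm(7 * d), 7, d)
  silu <- function(x) x / (1 + exp(-x))
  # u = z = X, conv taps only the current position, B = C = 0 so the scan
  # output is the skip D * silu(X); the gate multiplies by silu(X)
  expect_equal(mamba_block(X, p), X + silu(X) * silu(X), tolerance = 1e-10)
})

test_that("hidden state stays bounded over long sequences", {
  set.seed(27)
  p <- ssm_params(4, d_state = 6)
  U <- matrix(rnorm(1000 * 4), 1000, 4)  # bounded input
  Y <- selective_scan(U, p)
  expect_true(all(is.finite(Y)))
  expect_lt(max(abs(Y)), 1e4)
})

test_that("reference-scan arithmetic scales linearly in sequence length", {
  set.seed(28)
  p <- ssm_params(4, d_state = 5)
  U1 <- matrix(rnorm(16 * 4), 16, 4)
  U2 <- matrix(rnorm(32 * 4), 32, 4)
  ops1 <- attr(selective_scan(U1, p), "ops")
  ops2 <- attr(selective_scan(U2, p), "ops")
  expect_gte(ops2 / ops1, 1.8)
  expect_lte(ops2 / ops1, 2.2)
})
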