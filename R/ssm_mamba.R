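# Selective state-space (Mamba) block.
#
# The continuous system dx/dt = A x + B u, y = C x + D u is discretized per
# position with a zero-order hold at an input-dependent step size delta:
#   Abar = exp(delta * A)        (A diagonal)
#   Bbar = (exp(delta * A) - 1) / A * B     (limit delta*B as A -> 0)
# and the recurrence x_t = Abar_t x_{t-1} + Bbar_t u_t, y_t = C_t x_t + D u_t
# is scanned sequentially. delta, B and C are linear functions of the input
# (the "selective" part), delta made positive through a softplus. The state
# spectrum A is fixed at -(1..d_state), which keeps |Abar| < 1 for every
# positive step and bounds the hidden state for bounded input.

#' Zero-order-hold discretization of a diagonal SSM
#'
#' Computes `Abar = exp(delta * A)` and `Bbar = (exp(delta * A) - 1)/A * B`
#' elementwise, with the `A -> 0` limit handled analytically as
#' `Bbar = delta * B`.
#'
#' @param A Diagonal state-matrix entries (numeric vector).
#' @param B Input matrix entries, recycled against `A`.
#' @param delta Positive step size (scalar or recycled vector).
#' @return List with `Abar` and `Bbar`.
#' @export
discretize <- function(A, B, delta) {
  if (any(delta <= 0)) stop("discretize: delta must be positive")
  dA <- delta * A
  Abar <- exp(dA)
  phi <- ifelse(abs(A) < 1e-12, delta, expm1(dA) / A)
  list(Abar = Abar, Bbar = phi * B)
}

#' Parameters of a selective SSM
#'
#' Input-dependent projections for the step size, input and output matrices
#' of the selective scan, plus the fixed diagonal state spectrum and the
#' skip vector.
#'
#' @param d_inner Channel width the scan operates on.
#' @param d_state State width (default 16).
#' @param init_range Uniform init half-width for the projections.
#' @return An `ssm_params` list: `A` (fixed at `-(1..d_state)`), `W_delta`,
#'   `b_delta`, `W_B`, `W_C`, `D`.
#' @export
ssm_params <- function(d_inner, d_state = 16, init_range = 0.2) {
  u <- function(nr, nc) matrix(stats::runif(nr * nc, -init_range, init_range),
                               nr, nc)
  structure(list(
    A = -(seq_len(d_state)),
    W_delta = u(d_inner, d_inner),
    b_delta = stats::runif(d_inner, -init_range, init_range),
    W_B = u(d_inner, d_state),
    W_C = u(d_inner, d_state),
    D = rep(1, d_inner),
    d_inner = as.integer(d_inner),
    d_state = as.integer(d_state)
  ), class = "ssm_params")
}

#' Sequential reference selective scan
#'
#' The normative implementation of the selective scan: a plain sequential
#' recurrence over positions with explicit per-channel, per-state loops.
#' Any optimized implementation is bound to agree with this one. The number
#' of floating-point multiply/add operations performed in the recurrence is
#' attached as attribute `ops` (it scales linearly in the sequence length).
#'
#' @param U Input sequence, matrix `T x d_inner`.
#' @param params An [ssm_params()] list.
#' @return Output sequence `T x d_inner` with attribute `ops`.
#' @export
selective_scan <- function(U, params) {
  U <- as.matrix(U)
  if (!all(is.finite(U))) stop("selective_scan: non-finite input")
  d <- ncol(U)
  if (d != params$d_inner) stop("selective_scan: input width ", d,
                                " != d_inner ", params$d_inner)
  T_ <- nrow(U)
  ns <- params$d_state
  A <- params$A
  Y <- matrix(0, T_, d)
  x <- matrix(0, d, ns)
  ops <- 0
  for (t in seq_len(T_)) {
    u <- U[t, ]
    delta <- softplus_stable(drop(u %*% params$W_delta) + params$b_delta)
    Bt <- drop(u %*% params$W_B)
    Ct <- drop(u %*% params$W_C)
    ops <- ops + 2 * d * d + 4 * d * ns   # the three input projections
    for (i in seq_len(d)) {
      for (s in seq_len(ns)) {
        dz <- discretize(A[s], Bt[s], delta[i])
        x[i, s] <- dz$Abar * x[i, s] + dz$Bbar * u[i]
        Y[t, i] <- Y[t, i] + Ct[s] * x[i, s]
        ops <- ops + 6
      }
      Y[t, i] <- Y[t, i] + params$D[i] * u[i]
      ops <- ops + 2
    }
  }
  attr(Y, "ops") <- ops
  Y
}

## ---- batched scan (optimized; oracle-equivalent to selective_scan) ----

# U, delta: (B, T, di); Bt, Ct: (B, T, ns); A: (ns); D: (di)
# production path: compiled kernel; the pure-R versions below (_r suffix)
# are retained for cross-checking
scan_batch_forward <- function(U, delta, Bt, Ct, A, D) {
  Y <- .scan_forward_cpp(U, delta, Bt, Ct, as.numeric(A), as.numeric(D))
  list(Y = Y, U = U, delta = delta, Bt = Bt, Ct = Ct, A = A, D = D)
}

scan_batch_backward <- function(cache, dY) {
  .scan_backward_cpp(cache$U, cache$delta, cache$Bt, cache$Ct,
                     as.numeric(cache$A), as.numeric(cache$D), dY)
}

scan_batch_forward_r <- function(U, delta, Bt, Ct, A, D) {
  d <- dim(U); B <- d[1]; T_ <- d[2]; di <- d[3]
  ns <- length(A)
  n <- B * di
  grp <- rep(seq_len(B), di)
  Amat <- matrix(A, n, ns, byrow = TRUE)
  Dvec <- rep(D, each = B)
  Xhist <- array(0, c(n, ns, T_ + 1))
  Y <- array(0, d)
  x <- matrix(0, n, ns)
  for (t in seq_len(T_)) {
    dv <- c(delta[, t, ])
    uv <- c(U[, t, ])
    abar <- exp(outer(dv, A))
    phi <- expm1(outer(dv, A)) / Amat
    Bex <- matrix(Bt[, t, ], B, ns)[grp, , drop = FALSE]
    Cex <- matrix(Ct[, t, ], B, ns)[grp, , drop = FALSE]
    x <- abar * x + phi * Bex * uv
    Xhist[, , t + 1] <- x
    Y[, t, ] <- matrix(rowSums(x * Cex) + Dvec * uv, B, di)
  }
  list(Y = Y, U = U, delta = delta, Bt = Bt, Ct = Ct, A = A, D = D,
       Xhist = Xhist)
}

scan_batch_backward_r <- function(cache, dY) {
  U <- cache$U
  d <- dim(U); B <- d[1]; T_ <- d[2]; di <- d[3]
  A <- cache$A; ns <- length(A)
  n <- B * di
  grp <- rep(seq_len(B), di)
  Amat <- matrix(A, n, ns, byrow = TRUE)
  Dvec <- rep(cache$D, each = B)
  dU <- array(0, d)
  ddelta <- array(0, d)
  dB <- array(0, dim(cache$Bt))
  dC <- array(0, dim(cache$Ct))
  dD <- numeric(di)
  lam <- matrix(0, n, ns)
  for (t in rev(seq_len(T_))) {
    dv <- c(cache$delta[, t, ])
    uv <- c(U[, t, ])
    dyv <- c(dY[, t, ])
    abar <- exp(outer(dv, A))
    phi <- expm1(outer(dv, A)) / Amat
    Bex <- matrix(cache$Bt[, t, ], B, ns)[grp, , drop = FALSE]
    Cex <- matrix(cache$Ct[, t, ], B, ns)[grp, , drop = FALSE]
    xt <- cache$Xhist[, , t + 1]
    xprev <- cache$Xhist[, , t]
    dC[, t, ] <- rowsum(xt * dyv, grp)
    dD <- dD + colSums(matrix(uv * dyv, B, di))
    lam <- lam + Cex * dyv
    dU[, t, ] <- matrix(rowSums(lam * phi * Bex) + Dvec * dyv, B, di)
    dB[, t, ] <- rowsum(lam * phi * uv, grp)
    ddelta[, t, ] <- matrix(rowSums(lam * abar * (xprev * Amat + Bex * uv)),
                            B, di)
    lam <- lam * abar
  }
  list(dU = dU, ddelta = ddelta, dB = dB, dC = dC, dD = dD)
}

## ---- Mamba block ----

#' Parameters of a Mamba block
#'
#' Input projection to an expanded inner width (factor 2), depthwise causal
#' convolution (width 4), SiLU gate, selective SSM and output projection,
#' with a residual connection around the whole block and dropout on the
#' block output during training.
#'
#' @param d_model Channel width of the block input/output.
#' @param d_state SSM state width (default 16).
#' @param expand Inner-width expansion factor (default 2).
#' @param conv_width Depthwise causal convolution width (default 4).
#' @param dropout Dropout rate applied to the block output in training
#'   (default 0.2).
#' @param init_range Uniform init half-width.
#' @return A `mamba_params` list.
#' @export
mamba_params <- function(d_model, d_state = 16, expand = 2, conv_width = 4,
                         dropout = 0.2, init_range = 0.2) {
  stopifnot(d_model >= 1, dropout >= 0, dropout < 1)
  di <- expand * d_model
  p <- ssm_params(di, d_state, init_range)
  structure(list(
    in_proj = linear_params(d_model, 2 * di, init_range),
    conv = dwconv_params(di, conv_width, init_range),
    dt = linear_params(di, di, init_range),
    W_B = p$W_B, W_C = p$W_C, A = p$A, D = p$D,
    out_proj = linear_params(di, d_model, init_range),
    dropout = dropout,
    d_model = as.integer(d_model), d_inner = as.integer(di),
    d_state = as.integer(d_state)
  ), class = "mamba_params")
}

mamba_forward_batch <- function(X, p, training = FALSE) {
  d <- dim(X); B <- d[1]; T_ <- d[2]
  di <- p$d_inner
  lin1 <- linear_forward(X, p$in_proj)
  u <- lin1$out[, , seq_len(di), drop = FALSE]
  z <- lin1$out[, , di + seq_len(di), drop = FALSE]
  cv <- dwconv_forward(u, p$conv)
  sa <- silu_forward(cv$out)
  dtl <- linear_forward(sa$out, p$dt)
  dsig <- sigmoid(dtl$out)
  delta <- softplus_stable(dtl$out)
  ua_bt <- as_bt(sa$out)
  Bt <- from_bt(ua_bt %*% p$W_B, B, T_)
  Ct <- from_bt(ua_bt %*% p$W_C, B, T_)
  sc <- scan_batch_forward(sa$out, delta, Bt, Ct, p$A, p$D)
  gz <- silu_forward(z)
  yg <- sc$Y * gz$out
  lin2 <- linear_forward(yg, p$out_proj)
  dr <- dropout_forward(lin2$out, p$dropout, training)
  list(out = X + dr$out,
       cache = list(lin1 = lin1, cv = cv, sa = sa, dtl = dtl, dsig = dsig,
                    sc = sc, gz = gz, yg = yg, lin2 = lin2, dr = dr,
                    dims = d))
}

mamba_backward_batch <- function(p, cache, dOut) {
  di <- p$d_inner
  d <- cache$dims; B <- d[1]; T_ <- d[2]
  dO <- dropout_backward(cache$dr, dOut)
  lb2 <- linear_backward(p$out_proj, cache$lin2, dO)
  dyg <- lb2$dX
  dYsc <- dyg * cache$gz$out
  dgz <- dyg * cache$sc$Y
  dz <- silu_backward(cache$gz, dgz)
  sb <- scan_batch_backward(cache$sc, dYsc)
  ddpre <- sb$ddelta * cache$dsig
  dtb <- linear_backward(p$dt, cache$dtl, ddpre)
  dua_proj <- from_bt(as_bt(sb$dB) %*% t(p$W_B) +
                        as_bt(sb$dC) %*% t(p$W_C), B, T_)
  ua_bt <- as_bt(cache$sa$out)
  gW_B <- crossprod(ua_bt, as_bt(sb$dB))
  gW_C <- crossprod(ua_bt, as_bt(sb$dC))
  dua <- sb$dU + dtb$dX + dua_proj
  duc <- silu_backward(cache$sa, dua)
  cvb <- dwconv_backward(p$conv, cache$cv, duc)
  dP <- array(0, c(B, T_, 2 * di))
  dP[, , seq_len(di)] <- cvb$dX
  dP[, , di + seq_len(di)] <- dz
  lb1 <- linear_backward(p$in_proj, cache$lin1, dP)
  list(dX = dOut + lb1$dX,
       grads = list(in_proj = lb2_wrap(lb1$grads), conv = cvb$grads,
                    dt = lb2_wrap(dtb$grads), W_B = gW_B, W_C = gW_C,
                    D = sb$dD, out_proj = lb2_wrap(lb2$grads)))
}

# linear grads already come as list(W, b); identity kept for symmetry
lb2_wrap <- function(g) g

#' Apply a Mamba block to a sequence
#'
#' Causal: output position `t` depends only on input positions `1..t`.
#' The residual connection is included (`out = X + block(X)`).
#'
#' @param X Input sequence, matrix `T x d_model`; must be finite.
#' @param params A [mamba_params()] list.
#' @param training If `TRUE`, dropout is active (stochastic).
#' @return Matrix `T x d_model`.
#' @export
mamba_block <- function(X, params, training = FALSE) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("mamba_block: non-finite input")
  if (ncol(X) != params$d_model) {
    stop("mamba_block: input width ", ncol(X), " != d_model ",
         params$d_model)
  }
  fw <- mamba_forward_batch(array(X, c(1, nrow(X), ncol(X))), params,
                            training)
  matrix(fw$out, nrow(X), ncol(X))
}
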