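# Batched tensor primitives with hand-written backward passes.
#
# Sequence activations are stored as arrays of shape (B, T, C): batch,
# time, channel. Because R arrays are column-major, `matrix(X, B*T, C)`
# reinterprets such an array as a (B*T) x C matrix of per-position rows
# without copying semantics getting in the way, which lets position-wise
# linear maps run as a single BLAS call.

as_bt <- function(X) {
  d <- dim(X)
  matrix(X, d[1] * d[2], d[3])
}

from_bt <- function(M, B, T_) {
  array(M, c(B, T_, ncol(M)))
}

# out[, t, ] = X[, t + s, ], zero outside the range
shift_time <- function(X, s) {
  d <- dim(X); T_ <- d[2]
  if (s == 0) return(X)
  Y <- array(0, d)
  if (abs(s) >= T_) return(Y)
  if (s > 0) {
    Y[, 1:(T_ - s), ] <- X[, (1 + s):T_, ]
  } else {
    k <- -s
    Y[, (1 + k):T_, ] <- X[, 1:(T_ - k), ]
  }
  Y
}

## ---- linear (position-wise affine) ----

linear_params <- function(d_in, d_out, init_range = 0.2, bias = TRUE) {
  list(W = matrix(stats::runif(d_in * d_out, -init_range, init_range),
                  d_in, d_out),
       b = if (bias) stats::runif(d_out, -init_range, init_range) else NULL)
}

linear_forward <- function(X, p) {
  d <- dim(X)
  M <- as_bt(X) %*% p$W
  if (!is.null(p$b)) M <- M + rep(p$b, each = nrow(M))
  list(out = from_bt(M, d[1], d[2]), X = X)
}

linear_backward <- function(p, cache, dOut) {
  d <- dim(cache$X)
  dM <- as_bt(dOut)
  Xm <- as_bt(cache$X)
  list(dX = from_bt(dM %*% t(p$W), d[1], d[2]),
       grads = list(W = crossprod(Xm, dM),
                    b = if (!is.null(p$b)) colSums(dM) else NULL))
}

## ---- width-k same-padded 1-D convolution, full channel mixing ----

#' Parameters of a same-padded 1-D convolution
#'
#' Channel-mixing convolution over the time axis with odd width and zero
#' padding, as used by the SMILES encoder and the refinement stage.
#'
#' @param d_in,d_out Channel widths.
#' @param width Odd kernel width (default 3).
#' @param init_range Uniform init half-width.
#' @return List with `W` (list of `width` matrices `d_in x d_out`,
#'   offsets `-(width-1)/2 .. +(width-1)/2`) and bias `b`.
#' @export
conv1d_params <- function(d_in, d_out, width = 3, init_range = 0.2) {
  stopifnot(width %% 2 == 1)
  list(W = lapply(seq_len(width), function(j) {
    matrix(stats::runif(d_in * d_out, -init_range, init_range), d_in, d_out)
  }),
  b = stats::runif(d_out, -init_range, init_range),
  width = width)
}

conv1d_offsets <- function(p) seq_len(p$width) - (p$width + 1L) / 2L

conv1d_forward <- function(X, p) {
  d <- dim(X)
  offs <- conv1d_offsets(p)
  M <- matrix(rep(p$b, each = d[1] * d[2]), d[1] * d[2], length(p$b))
  for (j in seq_along(offs)) {
    M <- M + as_bt(shift_time(X, offs[j])) %*% p$W[[j]]
  }
  list(out = from_bt(M, d[1], d[2]), X = X)
}

conv1d_backward <- function(p, cache, dOut) {
  X <- cache$X
  d <- dim(X)
  offs <- conv1d_offsets(p)
  dM <- as_bt(dOut)
  dX <- array(0, d)
  gW <- vector("list", length(offs))
  for (j in seq_along(offs)) {
    Sx <- as_bt(shift_time(X, offs[j]))
    gW[[j]] <- crossprod(Sx, dM)
    dX <- dX + shift_time(from_bt(dM %*% t(p$W[[j]]), d[1], d[2]), -offs[j])
  }
  list(dX = dX, grads = list(W = gW, b = colSums(dM)))
}

## ---- depthwise causal convolution (Mamba local conv, width 4) ----

dwconv_params <- function(d, width = 4, init_range = 0.2) {
  list(w = matrix(stats::runif(width * d, -init_range, init_range), width, d),
       b = stats::runif(d, -init_range, init_range),
       width = width)
}

# out[, t, i] = b_i + sum_{j=0..width-1} w[j+1, i] * X[, t - j, i]
dwconv_forward <- function(X, p) {
  d <- dim(X)
  n <- d[1] * d[2]
  M <- matrix(rep(p$b, each = n), n, d[3])
  for (j in seq_len(p$width) - 1L) {
    M <- M + as_bt(shift_time(X, -j)) * rep(p$w[j + 1L, ], each = n)
  }
  list(out = from_bt(M, d[1], d[2]), X = X)
}

dwconv_backward <- function(p, cache, dOut) {
  X <- cache$X
  d <- dim(X)
  n <- d[1] * d[2]
  dM <- as_bt(dOut)
  dX <- array(0, d)
  gw <- matrix(0, p$width, d[3])
  for (j in seq_len(p$width) - 1L) {
    Sx <- as_bt(shift_time(X, -j))
    gw[j + 1L, ] <- colSums(Sx * dM)
    dX <- dX + shift_time(from_bt(dM * rep(p$w[j + 1L, ], each = n),
                                  d[1], d[2]), j)
  }
  list(dX = dX, grads = list(w = gw, b = colSums(dM)))
}

## ---- elementwise activations ----

sigmoid <- function(x) 1 / (1 + exp(-x))

silu_forward <- function(x) {
  s <- sigmoid(x)
  list(out = x * s, x = x, s = s)
}

silu_backward <- function(cache, dOut) {
  dOut * (cache$s * (1 + cache$x * (1 - cache$s)))
}

relu_forward <- function(x) list(out = pmax(x, 0), pos = x > 0)

relu_backward <- function(cache, dOut) dOut * cache$pos

softplus_stable <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))

## ---- dropout ----

dropout_forward <- function(X, rate, training) {
  if (!training || rate <= 0) return(list(out = X, mask = NULL))
  keep <- array(stats::rbinom(length(X), 1, 1 - rate), dim(X)) / (1 - rate)
  list(out = X * keep, mask = keep)
}

dropout_backward <- function(cache, dOut) {
  if (is.null(cache$mask)) dOut else dOut * cache$mask
}

## ---- scaled dot-product attention core (single head, one pair) ----

# Q: Tq x dk (already projected), K: Tk x dk, V: Tk x dv, key_len <= Tk:
# only the first key_len keys participate (prefix mask).
attn_core_forward <- function(Q, K, V, key_len = nrow(K)) {
  dk <- ncol(Q)
  S <- Q %*% t(K) / sqrt(dk)
  if (key_len < nrow(K)) S[, (key_len + 1):nrow(K)] <- -Inf
  S <- S - apply(S, 1, max)
  E <- exp(S)
  A <- E / rowSums(E)
  list(out = A %*% V, A = A, Q = Q, K = K, V = V, key_len = key_len)
}

attn_core_backward <- function(cache, dZ) {
  A <- cache$A
  dk <- ncol(cache$Q)
  dA <- dZ %*% t(cache$V)
  dV <- crossprod(A, dZ)
  dS <- A * (dA - rowSums(dA * A))
  if (cache$key_len < nrow(cache$K)) {
    dS[, (cache$key_len + 1):nrow(cache$K)] <- 0
  }
  dS <- dS / sqrt(dk)
  list(dQ = dS %*% cache$K, dK = crossprod(dS, cache$Q), dV = dV)
}

## ---- pooling over valid time prefix ----

# X: (B, T, C); len: integer vector of valid prefix lengths
maxpool_forward <- function(X, len) {
  d <- dim(X)
  out <- matrix(0, d[1], d[3])
  arg <- matrix(1L, d[1], d[3])
  for (b in seq_len(d[1])) {
    Xb <- matrix(X[b, seq_len(len[b]), ], len[b], d[3])
    arg[b, ] <- max.col(t(Xb), ties.method = "first")
    out[b, ] <- Xb[cbind(arg[b, ], seq_len(d[3]))]
  }
  list(out = out, arg = arg, dims = d)
}

maxpool_backward <- function(cache, dOut) {
  d <- cache$dims
  dX <- array(0, d)
  for (b in seq_len(d[1])) {
    dX[cbind(b, cache$arg[b, ], seq_len(d[3]))] <- dOut[b, ]
  }
  dX
}

# learned attention pooling: scores s_t = X[,t,] %*% w, alpha = softmax over
# the valid prefix, out = sum_t alpha_t X[,t,]
attnpool_forward <- function(X, w, len) {
  d <- dim(X)
  out <- matrix(0, d[1], d[3])
  alpha <- matrix(0, d[1], d[2])
  for (b in seq_len(d[1])) {
    L <- len[b]
    Xb <- matrix(X[b, seq_len(L), ], L, d[3])
    s <- drop(Xb %*% w)
    e <- exp(s - max(s)); a <- e / sum(e)
    alpha[b, seq_len(L)] <- a
    out[b, ] <- colSums(Xb * a)
  }
  list(out = out, alpha = alpha, X = X, w = w, len = len)
}

attnpool_backward <- function(cache, dOut) {
  X <- cache$X; d <- dim(X)
  dX <- array(0, d)
  dw <- numeric(d[3])
  for (b in seq_len(d[1])) {
    L <- cache$len[b]
    Xb <- matrix(X[b, seq_len(L), ], L, d[3])
    a <- cache$alpha[b, seq_len(L)]
    g <- dOut[b, ]
    # out = t(Xb) %*% a ; through both a and X
    da <- drop(Xb %*% g)
    ds <- a * (da - sum(da * a))
    dXb <- outer(a, g) + outer(ds, cache$w)
    dw <- dw + drop(crossprod(Xb, ds))
    dX[b, seq_len(L), ] <- dXb
  }
  list(dX = dX, dw = dw)
}

## ---- parameter-tree utilities (Adam etc.) ----

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- a
    for (nm in seq_along(a)) {
      if (!is.null(a[[nm]])) out[[nm]] <- tree_map2(f, a[[nm]], b[[nm]])
    }
    out
  } else if (is.null(a)) NULL else f(a, b)
}

tree_map <- function(f, a) {
  if (is.list(a)) {
    out <- a
    for (nm in seq_along(a)) {
      if (!is.null(a[[nm]])) out[[nm]] <- tree_map(f, a[[nm]])
    }
    out
  } else if (is.null(a)) NULL else f(a)
}

tree_zeros <- function(a) tree_map(function(x) x * 0, a)

tree_numel <- function(a) {
  if (is.list(a)) sum(vapply(a, tree_numel, numeric(1)))
  else if (is.null(a) || !is.numeric(a)) 0
  else length(a)
}

tree_add <- function(a, b) tree_map2(`+`, a, b)
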