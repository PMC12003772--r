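# Neural-network primitives (forward + hand-written backward).
#
# There is no autodiff here: every forward function returns the cache its
# paired backward function needs. Matrices are row-major batches of tokens
# (N x d). Gradient correctness is pinned by finite-difference tests.

# column-wise broadcast helpers (rep with a times-vector is C-fast)
add_bias <- function(Y, b) Y + rep(b, rep.int(nrow(Y), length(b)))
col_scale <- function(X, g) X * rep(g, rep.int(nrow(X), length(g)))

lin_fwd <- function(X, W, b) add_bias(X %*% W, b)

lin_bwd <- function(dY, X, W) {
  list(dX = tcrossprod(dY, W), dW = crossprod(X, dY), db = colSums(dY))
}

ln_fwd <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  inv <- 1 / sqrt(rowMeans(xc * xc) + eps)
  xhat <- xc * inv
  list(out = add_bias(col_scale(xhat, g), b), xhat = xhat, inv = inv)
}

ln_bwd <- function(dY, cache, g) {
  xhat <- cache$xhat
  dxhat <- col_scale(dY, g)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dX <- cache$inv * (dxhat - m1 - xhat * m2)
  list(dX = dX, dg = colSums(dY * xhat), db = colSums(dY))
}

relu_fwd <- function(X) {
  mask <- X > 0
  list(out = X * mask, mask = mask)
}

relu_bwd <- function(dY, mask) dY * mask

# GELU, tanh approximation (the standard transformer formulation); the
# forward caches tanh(inner) for the backward pass
gelu_fwd <- function(X) {
  x2 <- X * X
  th <- tanh(0.7978845608028654 * (X + 0.044715 * X * x2))
  list(out = 0.5 * X * (1 + th), th = th, x2 = x2)
}

gelu_bwd <- function(dY, X, g) {
  dY * (0.5 * (1 + g$th) +
          0.5 * X * (1 - g$th * g$th) *
            0.7978845608028654 * (1 + 0.134145 * g$x2))
}

dropout_fwd <- function(X, p, train) {
  if (!train || p <= 0) return(list(out = X, mask = NULL))
  mask <- (matrix(stats::runif(length(X)), nrow(X)) >= p) / (1 - p)
  list(out = X * mask, mask = mask)
}

dropout_bwd <- function(dY, mask) if (is.null(mask)) dY else dY * mask

# Naive scaled-dot-product attention for one head: the reference path that any
# optimized implementation must match. Q, K, V are n x d_k.
attention_naive <- function(Q, K, V) {
  A <- softmax_rows(Q %*% t(K) / sqrt(ncol(Q)))
  list(out = A %*% V, attn = A)
}

# ---- the two-layer expression encoder MLP (scalar input -> d) -----------
# Each layer is Dropout(ReLU(LayerNorm(Linear(.)))); dims 1 -> d -> d.

encmlp_init <- function(d, rng_sd = 0.02) {
  list(W1 = matrix(stats::rnorm(d, 0, rng_sd), 1, d), b1 = numeric(d),
       g1 = rep(1, d), c1 = numeric(d),
       W2 = matrix(stats::rnorm(d * d, 0, rng_sd), d, d), b2 = numeric(d),
       g2 = rep(1, d), c2 = numeric(d))
}

encmlp_fwd <- function(u, par, p_drop = 0.1, train = FALSE) {
  U <- matrix(u, ncol = 1L)
  Z1 <- lin_fwd(U, par$W1, par$b1)
  L1 <- ln_fwd(Z1, par$g1, par$c1)
  R1 <- relu_fwd(L1$out)
  D1 <- dropout_fwd(R1$out, p_drop, train)
  Z2 <- lin_fwd(D1$out, par$W2, par$b2)
  L2 <- ln_fwd(Z2, par$g2, par$c2)
  R2 <- relu_fwd(L2$out)
  D2 <- dropout_fwd(R2$out, p_drop, train)
  list(out = D2$out,
       cache = list(U = U, L1 = L1, R1 = R1, D1 = D1, H1 = D1$out,
                    L2 = L2, R2 = R2, D2 = D2))
}

encmlp_bwd <- function(dY, cache, par) {
  d2 <- dropout_bwd(dY, cache$D2$mask)
  r2 <- relu_bwd(d2, cache$R2$mask)
  l2 <- ln_bwd(r2, cache$L2, par$g2)
  lin2 <- lin_bwd(l2$dX, cache$H1, par$W2)
  d1 <- dropout_bwd(lin2$dX, cache$D1$mask)
  r1 <- relu_bwd(d1, cache$R1$mask)
  l1 <- ln_bwd(r1, cache$L1, par$g1)
  lin1 <- lin_bwd(l1$dX, cache$U, par$W1)
  list(grads = list(W1 = lin1$dW, b1 = lin1$db, g1 = l1$dg, c1 = l1$db,
                    W2 = lin2$dW, b2 = lin2$db, g2 = l2$dg, c2 = l2$db))
}

# ---- two-layer ReLU decoder MLP (d -> d -> k) ---------------------------

decmlp_init <- function(d, k, rng_sd = 0.02, final_w_mean = 0,
                        final_b = 0) {
  list(W1 = matrix(stats::rnorm(d * d, 0, rng_sd), d, d), b1 = numeric(d),
       W2 = matrix(stats::rnorm(d * k, final_w_mean, rng_sd), d, k),
       b2 = rep(final_b, k))
}

decmlp_fwd <- function(X, par) {
  Z1 <- lin_fwd(X, par$W1, par$b1)
  R1 <- relu_fwd(Z1)
  out <- lin_fwd(R1$out, par$W2, par$b2)
  list(out = out, cache = list(X = X, R1 = R1))
}

decmlp_bwd <- function(dY, cache, par) {
  lin2 <- lin_bwd(dY, cache$R1$out, par$W2)
  r1 <- relu_bwd(lin2$dX, cache$R1$mask)
  lin1 <- lin_bwd(r1, cache$X, par$W1)
  list(dX = lin1$dX,
       grads = list(W1 = lin1$dW, b1 = lin1$db,
                    W2 = lin2$dW, b2 = lin2$db))
}

# elementwise sum of two gradient lists with identical names
grads_add <- function(a, b) {
  if (is.null(a)) return(b)
  for (nm in names(b)) a[[nm]] <- if (is.null(a[[nm]])) b[[nm]] else a[[nm]] + b[[nm]]
  a
}

# prefix every name in a gradient list ("W1" -> "expr.W1")
grads_prefix <- function(g, prefix) {
  stats::setNames(g, paste0(prefix, ".", names(g)))
}
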