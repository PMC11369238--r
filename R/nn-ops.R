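# Layer primitives with hand-derived backward passes. Everything operates on
# L x K matrices (rows = positions). Parameters live in nested lists; the
# backward of each op returns gradients with the same shapes.

.LN_EPS <- 1e-5

ln_fwd <- function(x, g, b) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv_sd <- 1 / sqrt(v + .LN_EPS)
  xhat <- xc * inv_sd
  y <- sweep(sweep(xhat, 2, g, `*`), 2, b, `+`)
  list(y = y, cache = list(xhat = xhat, inv_sd = inv_sd, g = g))
}

ln_bwd <- function(dy, cache) {
  xhat <- cache$xhat
  dxhat <- sweep(dy, 2, cache$g, `*`)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- cache$inv_sd * (dxhat - m1 - xhat * m2)
  list(dx = dx, dg = colSums(dy * xhat), db = colSums(dy))
}

gelu_fwd <- function(x) x * stats::pnorm(x)

gelu_bwd <- function(dy, x) dy * (stats::pnorm(x) + x * stats::dnorm(x))

relu_fwd <- function(x) pmax(x, 0)

relu_bwd <- function(dy, x) dy * (x > 0)

# multi-head self attention; key_keep marks positions allowed as keys
# (softmax rows renormalize over kept keys only)
mha_fwd <- function(x, ap, H, key_keep) {
  K <- ncol(x)
  dh <- K %/% H
  Q <- sweep(x %*% ap$Wq, 2, ap$bq, `+`)
  Km <- sweep(x %*% ap$Wk, 2, ap$bk, `+`)
  V <- sweep(x %*% ap$Wv, 2, ap$bv, `+`)
  L <- nrow(x)
  ctx <- matrix(0, L, K)
  A_list <- vector("list", H)
  head_cache <- vector("list", H)
  for (h in seq_len(H)) {
    cols <- ((h - 1L) * dh + 1L):(h * dh)
    S <- tcrossprod(Q[, cols, drop = FALSE], Km[, cols, drop = FALSE]) /
      sqrt(dh)
    if (!all(key_keep)) S[, !key_keep] <- -1e30
    S <- S - apply(S, 1, max)
    E <- exp(S)
    A <- E / rowSums(E)
    ctx[, cols] <- A %*% V[, cols, drop = FALSE]
    A_list[[h]] <- A
    head_cache[[h]] <- A
  }
  y <- sweep(ctx %*% ap$Wo, 2, ap$bo, `+`)
  list(y = y, A = A_list,
       cache = list(x = x, Q = Q, Km = Km, V = V, ctx = ctx,
                    A = head_cache, H = H, dh = dh))
}

mha_bwd <- function(dy, ap, cache) {
  x <- cache$x
  H <- cache$H; dh <- cache$dh
  dWo <- crossprod(cache$ctx, dy)
  dbo <- colSums(dy)
  dctx <- dy %*% t(ap$Wo)
  dQ <- matrix(0, nrow(x), ncol(x))
  dK <- dQ; dV <- dQ
  for (h in seq_len(H)) {
    cols <- ((h - 1L) * dh + 1L):(h * dh)
    A <- cache$A[[h]]
    dctx_h <- dctx[, cols, drop = FALSE]
    dV[, cols] <- crossprod(A, dctx_h)
    dA <- tcrossprod(dctx_h, cache$V[, cols, drop = FALSE])
    dS <- A * (dA - rowSums(dA * A))
    dS <- dS / sqrt(dh)
    dQ[, cols] <- dS %*% cache$Km[, cols, drop = FALSE]
    dK[, cols] <- crossprod(dS, cache$Q[, cols, drop = FALSE])
  }
  dx <- dQ %*% t(ap$Wq) + dK %*% t(ap$Wk) + dV %*% t(ap$Wv)
  list(dx = dx,
       g = list(Wq = crossprod(x, dQ), bq = colSums(dQ),
                Wk = crossprod(x, dK), bk = colSums(dK),
                Wv = crossprod(x, dV), bv = colSums(dV),
                Wo = dWo, bo = dbo))
}

# pre-LN transformer block: x + MHA(LN(x)), then x + FFN(LN(x))
block_fwd <- function(x, bp, H, key_keep) {
  l1 <- ln_fwd(x, bp$ln1$g, bp$ln1$b)
  at <- mha_fwd(l1$y, bp$attn, H, key_keep)
  x1 <- x + at$y
  l2 <- ln_fwd(x1, bp$ln2$g, bp$ln2$b)
  u <- sweep(l2$y %*% bp$ffn$W1, 2, bp$ffn$b1, `+`)
  a <- gelu_fwd(u)
  f <- sweep(a %*% bp$ffn$W2, 2, bp$ffn$b2, `+`)
  x2 <- x1 + f
  list(x = x2, A = at$A,
       cache = list(l1 = l1$cache, at = at$cache, l2 = l2$cache,
                    h2 = l2$y, u = u, a = a))
}

block_bwd <- function(dx2, bp, cache) {
  # FFN branch
  da <- dx2 %*% t(bp$ffn$W2)
  dW2 <- crossprod(cache$a, dx2)
  db2 <- colSums(dx2)
  du <- gelu_bwd(da, cache$u)
  dW1 <- crossprod(cache$h2, du)
  db1 <- colSums(du)
  dh2 <- du %*% t(bp$ffn$W1)
  l2b <- ln_bwd(dh2, cache$l2)
  dx1 <- dx2 + l2b$dx
  # attention branch
  ab <- mha_bwd(dx1, bp$attn, cache$at)
  l1b <- ln_bwd(ab$dx, cache$l1)
  dx <- dx1 + l1b$dx
  list(dx = dx,
       g = list(ln1 = list(g = l1b$dg, b = l1b$db),
                attn = ab$g,
                ln2 = list(g = l2b$dg, b = l2b$db),
                ffn = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2)))
}

# parameter initializers
.init_mat <- function(nr, nc, sd = 0.02) matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)

.init_block <- function(K, ffK) {
  list(ln1 = list(g = rep(1, K), b = rep(0, K)),
       attn = list(Wq = .init_mat(K, K), bq = rep(0, K),
                   Wk = .init_mat(K, K), bk = rep(0, K),
                   Wv = .init_mat(K, K), bv = rep(0, K),
                   Wo = .init_mat(K, K), bo = rep(0, K)),
       ln2 = list(g = rep(1, K), b = rep(0, K)),
       ffn = list(W1 = .init_mat(K, ffK), b1 = rep(0, ffK),
                  W2 = .init_mat(ffK, K), b2 = rep(0, K)))
}
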