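# Neural-network primitives in base R: linear maps, layer normalization,
# multi-head self-attention, GRU cells, and their analytic backward passes.
# Parameters are nested lists of plain matrices/vectors; gradients mirror the
# parameter structure and are checked against finite differences in the tests.

rand_mat <- function(nr, nc, scale = NULL) {
  if (is.null(scale)) scale <- sqrt(2 / (nr + nc))
  matrix(stats::rnorm(nr * nc, sd = scale), nr, nc)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# ---- linear -----------------------------------------------------------------

linear_fwd <- function(x, W, b) {
  y <- x %*% W
  y <- sweep(y, 2L, b, "+")
  list(out = y, x = x)
}

linear_bwd <- function(cache, dy, W) {
  list(dx = dy %*% t(W), dW = crossprod(cache$x, dy), db = colSums(dy))
}

# ---- layer norm (per row, learned gain g and bias b) ------------------------

ln_fwd <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  y <- sweep(xhat * rep(1, nrow(x)) %o% g, 2L, b, "+")
  list(out = y, xhat = xhat, inv = inv)
}

ln_bwd <- function(cache, dy, g) {
  xhat <- cache$xhat
  inv <- cache$inv
  n <- ncol(xhat)
  dg <- colSums(dy * xhat)
  db <- colSums(dy)
  dxhat <- dy * rep(1, nrow(dy)) %o% g
  # dx = inv/n * (n*dxhat - rowSums(dxhat) - xhat*rowSums(dxhat*xhat))
  dx <- (inv / n) * (n * dxhat - rowSums(dxhat) - xhat * rowSums(dxhat * xhat))
  list(dx = dx, dg = dg, db = db)
}

# ---- softmax over rows ------------------------------------------------------

softmax_rows <- function(s) {
  m <- apply(s, 1L, max)
  e <- exp(s - m)
  e / rowSums(e)
}

# ---- multi-head self-attention (no projection biases) -----------------------

mha_init <- function(w, n_heads, scale = NULL) {
  list(Wq = rand_mat(w, w, scale), Wk = rand_mat(w, w, scale),
       Wv = rand_mat(w, w, scale), Wo = rand_mat(w, w, scale),
       n_heads = n_heads)
}

mha_fwd <- function(x, p) {
  w <- ncol(x)
  h <- p$n_heads
  dh <- w %/% h
  stopifnot(dh * h == w)
  Q <- x %*% p$Wq; K <- x %*% p$Wk; V <- x %*% p$Wv
  O <- matrix(0, nrow(x), w)
  A <- vector("list", h)
  for (k in seq_len(h)) {
    idx <- ((k - 1L) * dh + 1L):(k * dh)
    S <- tcrossprod(Q[, idx, drop = FALSE], K[, idx, drop = FALSE]) / sqrt(dh)
    A[[k]] <- softmax_rows(S)
    O[, idx] <- A[[k]] %*% V[, idx, drop = FALSE]
  }
  list(out = O %*% p$Wo, x = x, Q = Q, K = K, V = V, A = A, O = O, dh = dh)
}

mha_bwd <- function(cache, dy, p) {
  h <- p$n_heads
  dh <- cache$dh
  dO <- dy %*% t(p$Wo)
  dWo <- crossprod(cache$O, dy)
  dQ <- matrix(0, nrow(dy), ncol(cache$Q))
  dK <- dQ; dV <- dQ
  for (k in seq_len(h)) {
    idx <- ((k - 1L) * dh + 1L):(k * dh)
    A <- cache$A[[k]]
    dOh <- dO[, idx, drop = FALSE]
    Vh <- cache$V[, idx, drop = FALSE]
    dA <- tcrossprod(dOh, Vh)
    dV[, idx] <- crossprod(A, dOh)
    dS <- A * (dA - rowSums(dA * A))
    dQ[, idx] <- dS %*% cache$K[, idx, drop = FALSE] / sqrt(dh)
    dK[, idx] <- crossprod(dS, cache$Q[, idx, drop = FALSE]) / sqrt(dh)
  }
  x <- cache$x
  list(dx = dQ %*% t(p$Wq) + dK %*% t(p$Wk) + dV %*% t(p$Wv),
       dWq = crossprod(x, dQ), dWk = crossprod(x, dK),
       dWv = crossprod(x, dV), dWo = dWo)
}

# ---- transformer encoder block (pre-normalization) --------------------------

encoder_init <- function(w, n_heads, ffn_mult, scale = NULL) {
  list(ln1_g = rep(1, w), ln1_b = rep(0, w),
       mha = mha_init(w, n_heads, scale),
       ln2_g = rep(1, w), ln2_b = rep(0, w),
       W1 = rand_mat(w, ffn_mult * w, scale), b1 = rep(0, ffn_mult * w),
       W2 = rand_mat(ffn_mult * w, w, scale), b2 = rep(0, w))
}

encoder_fwd <- function(x, p) {
  l1 <- ln_fwd(x, p$ln1_g, p$ln1_b)
  at <- mha_fwd(l1$out, p$mha)
  y <- x + at$out
  l2 <- ln_fwd(y, p$ln2_g, p$ln2_b)
  f1 <- linear_fwd(l2$out, p$W1, p$b1)
  hrelu <- pmax(f1$out, 0)
  f2 <- linear_fwd(hrelu, p$W2, p$b2)
  list(out = y + f2$out, l1 = l1, at = at, l2 = l2, f1 = f1,
       hrelu = hrelu, f2 = f2)
}

encoder_bwd <- function(cache, dy, p) {
  g2 <- linear_bwd(list(x = cache$hrelu), dy, p$W2)
  dhr <- g2$dx * (cache$f1$out > 0)
  g1 <- linear_bwd(cache$f1, dhr, p$W1)
  l2g <- ln_bwd(cache$l2, g1$dx, p$ln2_g)
  dy1 <- dy + l2g$dx            # residual around FFN
  atg <- mha_bwd(cache$at, dy1, p$mha)
  l1g <- ln_bwd(cache$l1, atg$dx, p$ln1_g)
  dx <- dy1 + l1g$dx            # residual around attention
  grads <- list(ln1_g = l1g$dg, ln1_b = l1g$db,
                mha = list(Wq = atg$dWq, Wk = atg$dWk, Wv = atg$dWv,
                           Wo = atg$dWo, n_heads = 0),
                ln2_g = l2g$dg, ln2_b = l2g$db,
                W1 = g1$dW, b1 = g1$db, W2 = g2$dW, b2 = g2$db)
  list(dx = dx, grads = grads)
}

# ---- GRU over the length-3 structure sequence -------------------------------

gru_init <- function(w_in, w_hid, scale = NULL) {
  list(Wz = rand_mat(w_in, w_hid, scale), Uz = rand_mat(w_hid, w_hid, scale),
       bz = rep(0, w_hid),
       Wr = rand_mat(w_in, w_hid, scale), Ur = rand_mat(w_hid, w_hid, scale),
       br = rep(0, w_hid),
       Wh = rand_mat(w_in, w_hid, scale), Uh = rand_mat(w_hid, w_hid, scale),
       bh = rep(0, w_hid))
}

gru_cell_fwd <- function(x, hprev, p) {
  z <- sigmoid(sweep(x %*% p$Wz + hprev %*% p$Uz, 2L, p$bz, "+"))
  r <- sigmoid(sweep(x %*% p$Wr + hprev %*% p$Ur, 2L, p$br, "+"))
  rh <- r * hprev
  g <- tanh(sweep(x %*% p$Wh + rh %*% p$Uh, 2L, p$bh, "+"))
  h <- (1 - z) * hprev + z * g
  list(h = h, z = z, r = r, g = g, rh = rh, x = x, hprev = hprev)
}

gru_cell_bwd <- function(cache, dh, p, acc) {
  z <- cache$z; r <- cache$r; g <- cache$g
  hprev <- cache$hprev; x <- cache$x
  dz <- dh * (g - hprev)
  dg <- dh * z
  dhprev <- dh * (1 - z)
  da_g <- dg * (1 - g^2)
  acc$Wh <- acc$Wh + crossprod(x, da_g)
  acc$Uh <- acc$Uh + crossprod(cache$rh, da_g)
  acc$bh <- acc$bh + colSums(da_g)
  drh <- da_g %*% t(p$Uh)
  dr <- drh * hprev
  dhprev <- dhprev + drh * r
  da_z <- dz * z * (1 - z)
  da_r <- dr * r * (1 - r)
  acc$Wz <- acc$Wz + crossprod(x, da_z)
  acc$Uz <- acc$Uz + crossprod(hprev, da_z)
  acc$bz <- acc$bz + colSums(da_z)
  acc$Wr <- acc$Wr + crossprod(x, da_r)
  acc$Ur <- acc$Ur + crossprod(hprev, da_r)
  acc$br <- acc$br + colSums(da_r)
  dx <- da_z %*% t(p$Wz) + da_r %*% t(p$Wr) + da_g %*% t(p$Wh)
  dhprev <- dhprev + da_z %*% t(p$Uz) + da_r %*% t(p$Ur)
  list(dx = dx, dhprev = dhprev, acc = acc)
}

zero_like_gru <- function(p) lapply(p, function(m) m * 0)

# Run a (uni-directional) GRU over a list of T input matrices (n x w_in),
# h0 = 0. Returns hidden states at each step.
gru_seq_fwd <- function(xs, p) {
  n <- nrow(xs[[1]])
  h <- matrix(0, n, ncol(p$Uz))
  caches <- vector("list", length(xs))
  hs <- vector("list", length(xs))
  for (t in seq_along(xs)) {
    caches[[t]] <- gru_cell_fwd(xs[[t]], h, p)
    h <- caches[[t]]$h
    hs[[t]] <- h
  }
  list(hs = hs, caches = caches)
}

gru_seq_bwd <- function(cache, dhs, p) {
  Tn <- length(cache$caches)
  acc <- zero_like_gru(p)
  dxs <- vector("list", Tn)
  dh_next <- 0
  for (t in Tn:1) {
    dh <- dhs[[t]] + dh_next
    g <- gru_cell_bwd(cache$caches[[t]], dh, p, acc)
    acc <- g$acc
    dxs[[t]] <- g$dx
    dh_next <- g$dhprev
  }
  list(dxs = dxs, grads = acc)
}
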