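# Gated recurrent sequence scorer, implemented directly in vectorized R.
#
# The classifier contract calls for a gated recurrent cell (LSTM-class
# recurrence); this package uses a single-layer gated recurrent unit
# (GRU), which shares the LSTM's gated-memory mechanism with fewer
# parameters, trained by backpropagation through time with Adam. All
# state is plain R matrices, so models serialize as text and training is
# bit-reproducible for a fixed seed.

sigmoid <- function(x) 1 / (1 + exp(-x))

gru_init <- function(vocab_size, embedding_dim, hidden_dim, seed = 1) {
  set.seed(seed)
  r <- function(nr, nc) matrix(stats::runif(nr * nc, -0.08, 0.08), nr, nc)
  list(
    E  = r(vocab_size, embedding_dim),
    Wz = r(embedding_dim, hidden_dim), Uz = r(hidden_dim, hidden_dim),
    bz = rep(0, hidden_dim),
    Wr = r(embedding_dim, hidden_dim), Ur = r(hidden_dim, hidden_dim),
    br = rep(0, hidden_dim),
    Wh = r(embedding_dim, hidden_dim), Uh = r(hidden_dim, hidden_dim),
    bh = rep(0, hidden_dim),
    w_out = r(hidden_dim, 1), b_out = 0
  )
}

# ids: B x T integer matrix (pad positions hold 1); mask: B x T in {0,1}.
# Returns final hidden state and, if keep_cache, per-step caches for BPTT.
gru_forward <- function(par, ids, mask, keep_cache = FALSE) {
  B <- nrow(ids); T <- ncol(ids); H <- ncol(par$Uz)
  h <- matrix(0, B, H)
  cache <- if (keep_cache) vector("list", T) else NULL
  for (t in seq_len(T)) {
    x <- par$E[ids[, t], , drop = FALSE]
    z <- sigmoid(x %*% par$Wz + h %*% par$Uz +
                   matrix(par$bz, B, H, byrow = TRUE))
    r <- sigmoid(x %*% par$Wr + h %*% par$Ur +
                   matrix(par$br, B, H, byrow = TRUE))
    hb <- tanh(x %*% par$Wh + (r * h) %*% par$Uh +
                 matrix(par$bh, B, H, byrow = TRUE))
    m <- mask[, t]
    h_new <- (1 - z) * h + z * hb
    h_next <- m * h_new + (1 - m) * h
    if (keep_cache) cache[[t]] <- list(x = x, z = z, r = r, hb = hb,
                                       h_prev = h, m = m)
    h <- h_next
  }
  p <- sigmoid(as.numeric(h %*% par$w_out + par$b_out))
  list(h = h, p = p, cache = cache)
}

# BCE loss gradient through the whole unrolled network.
# y in {0,1}; sw: per-sample weights (mean-normalized by caller).
gru_backward <- function(par, fwd, ids, mask, y, sw) {
  B <- nrow(ids); T <- ncol(ids); H <- ncol(par$Uz)
  g <- lapply(par, function(p) if (is.matrix(p)) p * 0 else p * 0)
  dlogit <- sw * (fwd$p - y)                       # d(BCE)/d(logit)
  g$w_out <- crossprod(fwd$h, dlogit)
  g$b_out <- sum(dlogit)
  dh <- outer(dlogit, as.numeric(par$w_out))       # B x H
  dE_acc <- matrix(0, nrow(par$E), ncol(par$E))
  for (t in rev(seq_len(T))) {
    cc <- fwd$cache[[t]]
    m <- cc$m
    dh_new <- dh * m
    dh_prev <- dh * (1 - m)
    dz <- dh_new * (cc$hb - cc$h_prev)
    dhb <- dh_new * cc$z
    dh_prev <- dh_prev + dh_new * (1 - cc$z)
    da_h <- dhb * (1 - cc$hb^2)
    g$Wh <- g$Wh + crossprod(cc$x, da_h)
    g$Uh <- g$Uh + crossprod(cc$r * cc$h_prev, da_h)
    g$bh <- g$bh + colSums(da_h)
    dx <- da_h %*% t(par$Wh)
    drh <- da_h %*% t(par$Uh)
    dr <- drh * cc$h_prev
    dh_prev <- dh_prev + drh * cc$r
    da_z <- dz * cc$z * (1 - cc$z)
    g$Wz <- g$Wz + crossprod(cc$x, da_z)
    g$Uz <- g$Uz + crossprod(cc$h_prev, da_z)
    g$bz <- g$bz + colSums(da_z)
    dx <- dx + da_z %*% t(par$Wz)
    dh_prev <- dh_prev + da_z %*% t(par$Uz)
    da_r <- dr * cc$r * (1 - cc$r)
    g$Wr <- g$Wr + crossprod(cc$x, da_r)
    g$Ur <- g$Ur + crossprod(cc$h_prev, da_r)
    g$br <- g$br + colSums(da_r)
    dx <- dx + da_r %*% t(par$Wr)
    dh_prev <- dh_prev + da_r %*% t(par$Ur)
    # embeddings: masked rows have zero dx by construction of the gates'
    # gradients only when m == 0 zeroed dh_new; zero them explicitly.
    dx <- dx * m
    dE_acc <- dE_acc + rowsum_into(dx, ids[, t], nrow(par$E))
    dh <- dh_prev
  }
  g$E <- dE_acc
  g
}

# Accumulate rows of `m` into an nrow_out-row matrix by integer index.
rowsum_into <- function(m, idx, nrow_out) {
  rs <- rowsum(m, group = idx)
  out <- matrix(0, nrow_out, ncol(m))
  out[as.integer(rownames(rs)), ] <- rs
  out
}

adam_init <- function(par) {
  list(m = lapply(par, function(p) p * 0),
       v = lapply(par, function(p) p * 0), t = 0)
}

adam_step <- function(par, grad, st, lr = 3e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1
  for (k in names(par)) {
    st$m[[k]] <- beta1 * st$m[[k]] + (1 - beta1) * grad[[k]]
    st$v[[k]] <- beta2 * st$v[[k]] + (1 - beta2) * grad[[k]]^2
    mhat <- st$m[[k]] / (1 - beta1^st$t)
    vhat <- st$v[[k]] / (1 - beta2^st$t)
    par[[k]] <- par[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(par = par, st = st)
}
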