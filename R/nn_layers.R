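# Neural-network primitives.
#
# No deep-learning framework is used: every layer is written directly on
# BLAS-backed matrix operations with hand-derived backward passes, verified
# against central finite differences in the test suite.
#
# Tensor convention: a batch of N sequences of length L with C channels is a
# single ((N*L) x C) matrix, sequence-major (row (i-1)*L + t = residue t of
# sequence i), accompanied by a logical mask marking real residues. This
# keeps convolutions expressible as one im2col gather plus one GEMM.

# ---- convolution ------------------------------------------------------------

# Gather index for a same-padded stride-1 1-D convolution: for each kernel
# offset o (1..k) the block of N*L source rows, with out-of-sequence sources
# pointing at a sentinel zero row (N*L + 1).
conv_idx <- function(L, N, k) {
  pad <- (k - 1L) %/% 2L
  NL <- N * L
  base <- rep.int((seq_len(N) - 1L) * L, rep.int(L, N))
  t <- rep.int(seq_len(L), N)
  idx <- integer(NL * k)
  for (o in seq_len(k)) {
    src <- t + (o - pad - 1L)
    ii <- base + src
    ii[src < 1L | src > L] <- NL + 1L
    idx[((o - 1L) * NL + 1L):(o * NL)] <- ii
  }
  idx
}

# Weight layout: W is (k*Cin) x Cout with row (c-1)*k + o = (input channel c,
# kernel offset o). Returns the pre-activation and the im2col matrix needed
# by the backward pass.
conv1d_fwd <- function(A, W, b, k, L, N, idx = conv_idx(L, N, k)) {
  NL <- N * L
  A_pad <- rbind(A, 0)
  Col <- matrix(A_pad[idx, , drop = FALSE], nrow = NL)
  Z <- Col %*% W
  Z <- Z + rep(b, each = NL)
  list(Z = Z, Col = Col, idx = idx)
}

conv1d_bwd <- function(dZ, cache, W, k, L, N, Cin, need_dA = TRUE) {
  NL <- N * L
  dW <- crossprod(cache$Col, dZ)
  db <- colSums(dZ)
  dA <- NULL
  if (need_dA) {
    dCol <- tcrossprod(dZ, W)  # (NL) x (k*Cin)
    dA <- matrix(0, NL, Cin)
    for (o in seq_len(k)) {
      ii <- cache$idx[((o - 1L) * NL + 1L):(o * NL)]
      valid <- ii <= NL
      block <- dCol[, (seq_len(Cin) - 1L) * k + o, drop = FALSE]
      dA[ii[valid], ] <- dA[ii[valid], ] + block[valid, , drop = FALSE]
    }
  }
  list(dA = dA, dW = dW, db = db)
}

# ---- batch normalization ----------------------------------------------------

bn_fwd <- function(Z, gamma, beta, run_mean, run_var, train,
                   momentum = 0.1, eps = 1e-5) {
  NL <- nrow(Z)
  if (train) {
    m <- colMeans(Z)
    Zc <- Z - rep(m, each = NL)
    v <- colMeans(Zc * Zc)
    run_mean <- (1 - momentum) * run_mean + momentum * m
    run_var <- (1 - momentum) * run_var + momentum * v
  } else {
    m <- run_mean
    v <- run_var
    Zc <- Z - rep(m, each = NL)
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- Zc * rep(invstd, each = NL)
  out <- xhat * rep(gamma, each = NL) + rep(beta, each = NL)
  list(out = out, xhat = xhat, invstd = invstd, train = train,
       run_mean = run_mean, run_var = run_var)
}

bn_bwd <- function(dY, cache, gamma) {
  NL <- nrow(dY)
  dgamma <- colSums(dY * cache$xhat)
  dbeta <- colSums(dY)
  dxhat <- dY * rep(gamma, each = NL)
  if (cache$train) {
    s1 <- colSums(dxhat)
    s2 <- colSums(dxhat * cache$xhat)
    dZ <- (dxhat - rep(s1 / NL, each = NL) -
             cache$xhat * rep(s2 / NL, each = NL)) *
      rep(cache$invstd, each = NL)
  } else {
    dZ <- dxhat * rep(cache$invstd, each = NL)
  }
  list(dZ = dZ, dgamma = dgamma, dbeta = dbeta)
}

# ---- attention (1-D channel + spatial refinement) ---------------------------

# Masked per-sequence channel descriptors (used by the global max-pooling
# embedding): average and maximum over real positions, with argmax rows for
# the backward scatter.
masked_channel_pool <- function(A, mask, L, N) {
  C <- ncol(A)
  group <- rep.int(seq_len(N), rep.int(L, N))
  Am <- A
  Am[!mask, ] <- 0
  n_real <- as.numeric(rowsum(as.numeric(mask), group))
  s_avg <- rowsum(Am, group) / n_real
  Amax <- A
  Amax[!mask, ] <- -Inf
  M2 <- matrix(Amax, L, N * C)                 # column (c-1)*N + i
  am <- max.col(t(M2), ties.method = "first")  # argmax position within seq
  s_max <- matrix(M2[cbind(am, seq_len(N * C))], N, C)
  list(s_avg = s_avg, s_max = s_max, am = am, n_real = n_real, group = group)
}

# Channel refinement is POSITION-WISE (a two-layer bottleneck applied to each
# residue's channel vector), not pooled over the sequence: a sequence-global
# channel gate would carry class identity to every position, destroying the
# spatial fidelity that Grad-CAM interpretation depends on. The spatial stage
# is a small convolution over the channel-averaged and channel-maximum maps.
attn_fwd <- function(A, mask, L, N, p) {
  C <- ncol(A)
  NL <- N * L
  # channel gate per position
  H1 <- relu(A %*% p$ca_W1 + rep(p$ca_b1, each = NL))
  g <- sigmoid(H1 %*% p$ca_W2 + rep(p$ca_b2, each = NL))  # NL x C
  A1 <- A * g
  # spatial attention: conv over channel-avg and channel-max maps
  p_avg <- rowMeans(A1)
  am_s <- max.col(A1, ties.method = "first")
  p_max <- A1[cbind(seq_len(NL), am_s)]
  P <- cbind(p_avg, p_max)
  cv <- conv1d_fwd(P, p$sa_W, p$sa_b, p$sa_k, L, N)
  s <- sigmoid(cv$Z[, 1L])
  out <- A1 * s
  list(out = out, A = A, A1 = A1, g = g, s = s, H1 = H1,
       P = P, cv = cv, am_s = am_s)
}

attn_bwd <- function(dOut, cache, mask, L, N, p) {
  C <- ncol(dOut)
  NL <- N * L
  # spatial gate
  dA1 <- dOut * cache$s
  ds <- rowSums(dOut * cache$A1)
  dz <- ds * cache$s * (1 - cache$s)
  cb <- conv1d_bwd(matrix(dz, ncol = 1L), cache$cv, p$sa_W, p$sa_k, L, N, 2L)
  dP <- cb$dA
  dA1 <- dA1 + dP[, 1L] / C
  idx_max <- cbind(seq_len(NL), cache$am_s)
  dA1[idx_max] <- dA1[idx_max] + dP[, 2L]
  # position-wise channel gate
  dA <- dA1 * cache$g
  dg <- dA1 * cache$A
  dlogit <- dg * cache$g * (1 - cache$g)
  dH1 <- tcrossprod(dlogit, p$ca_W2) * (cache$H1 > 0)
  dW2 <- crossprod(cache$H1, dlogit)
  db2 <- colSums(dlogit)
  dW1 <- crossprod(cache$A, dH1)
  db1 <- colSums(dH1)
  dA <- dA + tcrossprod(dH1, p$ca_W1)
  list(dA = dA,
       grads = list(ca_W1 = dW1, ca_b1 = db1, ca_W2 = dW2, ca_b2 = db2,
                    sa_W = cb$dW, sa_b = cb$db))
}

# ---- pooling ----------------------------------------------------------------

# Masked local average pooling, window = stride = w (the bridge between the
# spatially resolved block and the downsampling block). Output positions
# with no real residue in their window are masked out.
avgpool_fwd <- function(A, mask, L, N, w) {
  L2 <- as.integer(ceiling(L / w))
  t <- rep.int(seq_len(L), N)
  pg <- (rep.int(seq_len(N), rep.int(L, N)) - 1L) * L2 + (t - 1L) %/% w + 1L
  Am <- A
  Am[!mask, ] <- 0
  cnt <- as.numeric(rowsum(as.numeric(mask), pg))
  out <- rowsum(Am, pg) / pmax(cnt, 1)
  list(out = out, mask2 = cnt > 0, cnt = cnt, pg = pg, L2 = L2)
}

avgpool_bwd <- function(dOut, cache, mask) {
  dA <- dOut[cache$pg, , drop = FALSE] / pmax(cache$cnt, 1)[cache$pg]
  dA[!mask, ] <- 0
  dA
}

# Masked local max pooling, window = stride = w. `pick` records the winning
# source row per (output row, channel) for the backward scatter.
maxpool_fwd <- function(A, mask, L, N, w) {
  C <- ncol(A)
  L2 <- as.integer(ceiling(L / w))
  NL2 <- N * L2
  Amax <- A
  Amax[!mask, ] <- -Inf
  out <- matrix(-Inf, NL2, C)
  pick <- matrix(NA_integer_, NL2, C)
  base2 <- rep.int((seq_len(N) - 1L) * L, rep.int(L2, N))
  t2 <- rep.int(seq_len(L2), N)
  for (o in seq_len(w)) {
    src_t <- (t2 - 1L) * w + o
    ok <- src_t <= L
    rows_src <- base2[ok] + src_t[ok]
    cand <- Amax[rows_src, , drop = FALSE]
    cur <- out[ok, , drop = FALSE]
    better <- cand > cur
    cur[better] <- cand[better]
    out[ok, ] <- cur
    pk <- pick[ok, , drop = FALSE]
    pk[better] <- rows_src[row(better)[better]]
    pick[ok, ] <- pk
  }
  mask2 <- is.finite(out[, 1L])
  out[!mask2, ] <- 0
  list(out = out, mask2 = mask2, pick = pick)
}

maxpool_bwd <- function(dOut, cache, NL, C) {
  dA <- matrix(0, NL, C)
  ok <- !is.na(cache$pick) & cache$mask2
  idx <- cbind(as.vector(cache$pick[ok]), col(cache$pick)[ok])
  dA[idx] <- dA[idx] + dOut[ok]
  dA
}

# Masked global max pooling over positions -> one vector per sequence.
# A sequence with no real position (fully padded input) pools to zero.
gmaxpool_fwd <- function(A, mask, L, N) {
  pool <- masked_channel_pool(A, mask, L, N)
  out <- pool$s_max
  out[!is.finite(out)] <- 0
  list(out = out, am = pool$am)
}

gmaxpool_bwd <- function(dOut, cache, L, N, C) {
  dA <- matrix(0, N * L, C)
  jj <- seq_len(N * C)
  cc <- (jj - 1L) %/% N + 1L
  ii <- (jj - 1L) %% N + 1L
  rowg <- (ii - 1L) * L + cache$am
  dA[cbind(rowg, cc)] <- dOut[cbind(ii, cc)]
  dA
}

# ---- instance normalization (autoencoder decoder) ---------------------------

# Normalizes each (sequence, channel) over its real positions; padding rows
# are zeroed so they cannot leak into subsequent convolutions.
in_fwd <- function(A, mask, L, N, gamma, beta, eps = 1e-5) {
  group <- rep.int(seq_len(N), rep.int(L, N))
  Am <- A
  Am[!mask, ] <- 0
  n_real <- as.numeric(rowsum(as.numeric(mask), group))
  m <- rowsum(Am, group) / n_real
  Zc <- A - m[group, , drop = FALSE]
  Zc[!mask, ] <- 0
  v <- rowsum(Zc * Zc, group) / n_real
  invstd <- 1 / sqrt(v + eps)
  xhat <- Zc * invstd[group, , drop = FALSE]
  NL <- N * L
  out <- xhat * rep(gamma, each = NL) + rep(beta, each = NL)
  out[!mask, ] <- 0
  list(out = out, xhat = xhat, invstd = invstd, group = group,
       n_real = n_real)
}

in_bwd <- function(dY, cache, mask, gamma) {
  NL <- nrow(dY)
  dY <- dY * mask  # padded rows were forced to zero in the forward pass
  dgamma <- colSums(dY * cache$xhat)
  dbeta <- colSums(dY * mask)
  dxhat <- dY * rep(gamma, each = NL)
  g <- cache$group
  s1 <- rowsum(dxhat, g) / cache$n_real
  s2 <- rowsum(dxhat * cache$xhat, g) / cache$n_real
  dZ <- (dxhat - s1[g, , drop = FALSE] -
           cache$xhat * s2[g, , drop = FALSE]) *
    cache$invstd[g, , drop = FALSE]
  dZ[!mask, ] <- 0
  list(dZ = dZ, dgamma = dgamma, dbeta = dbeta)
}

# ---- losses -----------------------------------------------------------------

# Softmax cross-entropy over rows; labels are integer class indices.
softmax_xent <- function(logits, labels) {
  P <- softmax_rows(logits)
  N <- nrow(logits)
  eps <- 1e-12
  loss <- -mean(log(P[cbind(seq_len(N), labels)] + eps))
  dlogits <- P
  dlogits[cbind(seq_len(N), labels)] <-
    dlogits[cbind(seq_len(N), labels)] - 1
  list(loss = loss, dlogits = dlogits / N, P = P)
}

# ---- parameter utilities ----------------------------------------------------

# He-scaled Gaussian initialization for a conv/dense weight matrix.
init_w <- function(n_in, n_out) {
  matrix(stats::rnorm(n_in * n_out, 0, sqrt(2 / n_in)), n_in, n_out)
}

# Adam with L2 weight decay folded into the gradient. `params` and `grads`
# are parallel flat named lists of numeric arrays.
adam_init <- function(params) {
  list(t = 0L,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))
}

adam_step <- function(params, grads, state, lr = 1e-4, weight_decay = 1e-5,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]] + weight_decay * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
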