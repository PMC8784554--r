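# Matrix-based neural-network primitives.
#
# Activations are stored as (N * P) x C matrices, where N is the batch size,
# P the number of spatial positions of the current level and C the channel
# count. Spatial structure enters only through precomputed gather-index
# tables, so 2D and 3D layers share one code path.

# Gather-index table for a strided window op on spatial shape S (length 2
# or 3): row = output position (column-major, first axis fastest), column =
# kernel offset; entries are 1-based linear input indices, 0 marks zero
# padding. Covers "same" convolution (kernel k, stride 1, pad (k-1)/2) and
# pooling (kernel 2, stride 2, pad 0).
build_gather_idx <- function(S, kernel, stride, pad) {
  d <- length(S)
  Tn <- (S + 2L * pad - kernel) %/% stride + 1L
  pos <- lapply(seq_len(d), function(j)
    (seq_len(Tn[j]) - 1L) * stride + 1L - pad)  # 1-based window origins
  offs <- as.matrix(do.call(expand.grid, rep(list(seq_len(kernel) - 1L), d)))
  P_out <- prod(Tn)
  idx <- matrix(0L, P_out, nrow(offs))
  rep_axis <- function(v, j) {
    inner <- if (j > 1) prod(Tn[seq_len(j - 1L)]) else 1L
    outer_ <- if (j < d) prod(Tn[(j + 1L):d]) else 1L
    rep(rep(v, each = inner), times = outer_)
  }
  for (g in seq_len(nrow(offs))) {
    lin <- rep(1L, P_out)
    ok <- rep(TRUE, P_out)
    mult <- 1L
    for (j in seq_len(d)) {
      src <- pos[[j]] + offs[g, j]          # 1-based source coord
      src_full <- rep_axis(src, j)
      ok <- ok & src_full >= 1L & src_full <= S[j]
      lin <- lin + (src_full - 1L) * mult
      mult <- mult * S[j]
    }
    lin[!ok] <- 0L
    idx[, g] <- lin
  }
  idx
}

# Output index table for a kernel-2 stride-2 transposed convolution:
# row = input position, column = kernel offset; entries are 1-based output
# positions on the doubled grid (each output voxel receives exactly one
# contribution).
build_scatter_idx <- function(S) {
  d <- length(S)
  Tn <- 2L * S
  pos <- lapply(seq_len(d), function(j) (seq_len(S[j]) - 1L) * 2L + 1L)
  offs <- as.matrix(do.call(expand.grid, rep(list(0:1), d)))
  P_in <- prod(S)
  idx <- matrix(0L, P_in, nrow(offs))
  rep_axis <- function(v, j) {
    inner <- if (j > 1) prod(S[seq_len(j - 1L)]) else 1L
    outer_ <- if (j < d) prod(S[(j + 1L):d]) else 1L
    rep(rep(v, each = inner), times = outer_)
  }
  for (g in seq_len(nrow(offs))) {
    lin <- rep(1L, P_in)
    mult <- 1L
    for (j in seq_len(d)) {
      out <- pos[[j]] + offs[g, j]
      lin <- lin + (rep_axis(out, j) - 1L) * mult
      mult <- mult * Tn[j]
    }
    idx[, g] <- lin
  }
  idx
}

# Extend a single-sample index table to a batch of N samples stacked
# row-wise (sample n occupies rows (n-1)*P + 1 .. n*P).
batch_idx <- function(idx, P, N) {
  if (N == 1L) return(idx)
  out <- matrix(0L, nrow(idx) * N, ncol(idx))
  nz <- idx > 0L
  for (n in seq_len(N)) {
    blk <- idx
    blk[nz] <- blk[nz] + (n - 1L) * P
    out[((n - 1L) * nrow(idx) + 1L):(n * nrow(idx)), ] <- blk
  }
  out
}

# im2col: gather the receptive fields of every output position.
# X: (N*P_in) x C; idxb: batched gather table (N*P_out x K).
# Returns (N*P_out) x (K*C) with column order offset-fastest per channel.
im2col <- function(X, idxb) {
  Xz <- rbind(0, X)                     # row 1 = zero padding sentinel
  R <- Xz[as.vector(idxb) + 1L, , drop = FALSE]
  dim(R) <- c(nrow(idxb), ncol(idxb) * ncol(X))
  R
}

conv_forward <- function(X, W, b, idxb) {
  B <- im2col(X, idxb)
  Z <- B %*% W
  Z <- sweep(Z, 2L, b, `+`)
  list(Z = Z, B = B)
}

# Scatter im2col gradients back onto the input grid. For a fixed kernel
# offset the output->input map is injective, so plain indexed addition per
# offset column is exact.
conv_backward <- function(dZ, B, W, idxb, n_in_rows, C_in) {
  dW <- crossprod(B, dZ)
  db <- colSums(dZ)
  dB <- dZ %*% t(W)                     # (N*P_out) x (K*C_in)
  K <- ncol(idxb)
  dim(dB) <- c(nrow(dB), K, C_in)
  dX <- matrix(0, n_in_rows, C_in)
  for (g in seq_len(K)) {
    rows <- idxb[, g]
    keep <- rows > 0L
    if (any(keep))
      dX[rows[keep], ] <- dX[rows[keep], ] + dB[keep, g, ]
  }
  list(dX = dX, dW = dW, db = db)
}

relu_forward <- function(Z) {
  A <- Z
  A[A < 0] <- 0
  A
}

maxpool_forward <- function(X, idxb) {
  K <- ncol(idxb)
  C <- ncol(X)
  cur <- X[idxb[, 1L], , drop = FALSE]
  arg <- matrix(1L, nrow(cur), C)
  for (g in 2:K) {
    cand <- X[idxb[, g], , drop = FALSE]
    better <- cand > cur
    cur[better] <- cand[better]
    arg[better] <- g
  }
  list(Y = cur, arg = arg)
}

maxpool_backward <- function(dY, arg, idxb, n_in_rows) {
  C <- ncol(dY)
  dX <- matrix(0, n_in_rows, C)
  for (g in seq_len(ncol(idxb))) {
    mask <- arg == g
    if (!any(mask)) next
    contrib <- dY * mask
    rows <- idxb[, g]
    dX[rows, ] <- dX[rows, ] + contrib
  }
  dX
}

bn_forward <- function(X, gamma, beta, run_mean, run_var, training,
                       eps = 1e-5, momentum = 0.9) {
  if (training) {
    mu <- colMeans(X)
    v <- colMeans(X^2) - mu^2
    v[v < 0] <- 0
    new_mean <- momentum * run_mean + (1 - momentum) * mu
    new_var <- momentum * run_var + (1 - momentum) * v
  } else {
    mu <- run_mean; v <- run_var
    new_mean <- run_mean; new_var <- run_var
  }
  ivar <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(X, 2L, mu, `-`), 2L, ivar, `*`)
  Y <- sweep(sweep(xhat, 2L, gamma, `*`), 2L, beta, `+`)
  list(Y = Y, xhat = xhat, ivar = ivar,
       new_mean = new_mean, new_var = new_var)
}

bn_backward <- function(dY, xhat, ivar, gamma, training) {
  dgamma <- colSums(dY * xhat)
  dbeta <- colSums(dY)
  if (training) {
    M <- nrow(dY)
    dxhat <- sweep(dY, 2L, gamma, `*`)
    t1 <- sweep(dxhat, 2L, colSums(dxhat) / M, `-`)
    t2 <- sweep(xhat, 2L, colSums(dxhat * xhat) / M, `*`)
    dX <- sweep(t1 - t2, 2L, ivar, `*`)
  } else {
    dX <- sweep(sweep(dY, 2L, gamma, `*`), 2L, ivar, `*`)
  }
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

upconv_forward <- function(X, W, b, sidxb, P_out_rows) {
  # W: array (2^d, C_in, C_out)
  K <- dim(W)[1]; C_out <- dim(W)[3]
  Y <- matrix(0, P_out_rows, C_out)
  for (g in seq_len(K)) {
    Y[sidxb[, g], ] <- X %*% W[g, , , drop = TRUE]
  }
  sweep(Y, 2L, b, `+`)
}

upconv_backward <- function(dY, X, W, sidxb) {
  K <- dim(W)[1]
  dW <- array(0, dim = dim(W))
  dX <- matrix(0, nrow(X), dim(W)[2])
  for (g in seq_len(K)) {
    dYg <- dY[sidxb[, g], , drop = FALSE]
    dW[g, , ] <- crossprod(X, dYg)
    dX <- dX + dYg %*% t(W[g, , , drop = TRUE])
  }
  list(dX = dX, dW = dW, db = colSums(dY))
}

sigmoid <- function(z) 1 / (1 + exp(-pmin(pmax(z, -30), 30)))

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

# Mean binary cross-entropy and its gradient w.r.t. the pre-sigmoid logits.
bce_loss_grad <- function(P, Y) {
  eps <- 1e-12
  loss <- -mean(Y * log(P + eps) + (1 - Y) * log(1 - P + eps))
  list(loss = loss, dZ = (P - Y) / length(Y))
}

# Mean categorical cross-entropy (per voxel) and its gradient w.r.t. the
# pre-softmax logits.
cce_loss_grad <- function(P, Y) {
  eps <- 1e-12
  loss <- -mean(rowSums(Y * log(P + eps)))
  list(loss = loss, dZ = (P - Y) / nrow(Y))
}

# Adam update; state holds first/second moments and the step counter.
adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(state$m[[nm]])) {
      state$m[[nm]] <- g * 0
      state$v[[nm]] <- g * 0
    }
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
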