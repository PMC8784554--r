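#' Configure a U-Net
#'
#' Describes an encoder-decoder segmentation network: `depth` encoding
#' blocks of two same-padded convolutions (kernel 3, ReLU) followed by batch
#' normalization, with 2x max-pooling between blocks and feature maps
#' doubling per level; a symmetric decoder of stride-2 transposed
#' convolutions whose outputs are concatenated with the skip features of the
#' corresponding encoding block; dropout (rate 0.2) on the last two encoding
#' blocks; and a kernel-1 output head with sigmoid (single-task, 1 channel)
#' or softmax (multitask, 4 channels) activation. The same configuration
#' drives 2D (slice-wise) and 3D (patch-wise) networks.
#'
#' @param dims 2 or 3.
#' @param input_shape spatial input shape (length `dims`); every axis must
#'   be divisible by `2^(depth - 1)` for pooling feasibility.
#' @param in_channels input channels (1 for windowed CT).
#' @param out_channels 1 (single-task) or 4 (multitask).
#' @param depth number of encoding blocks (the last is the bottleneck).
#' @param base_filters feature maps in the first block.
#' @param kernel convolution kernel size (odd; default 3).
#' @param dropout_rate dropout ratio on the last two encoding blocks.
#' @param final_activation `"sigmoid"` or `"softmax"`; defaults from
#'   `out_channels`.
#' @param preset `"desk"` sets depth 3 / base_filters 6, a size that trains
#'   in minutes on one CPU core. (Base 4 is representable but too narrow
#'   for reliable CSF convergence: whether the weak dark-side CSF/air
#'   contrast survives the first encoder block then depends on the luck of
#'   the weight draw.)
#' @return an object of class `unet_config`.
#' @export
unet_config <- function(dims = 2L, input_shape = c(64L, 64L),
                        in_channels = 1L, out_channels = 1L,
                        depth = 4L, base_filters = 16L, kernel = 3L,
                        dropout_rate = 0.2, final_activation = NULL,
                        preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, "desk")
    depth <- 3L; base_filters <- 6L
  }
  dims <- as.integer(dims)
  if (!dims %in% c(2L, 3L)) stopf("dims must be 2 or 3")
  input_shape <- as.integer(input_shape)
  if (length(input_shape) != dims) stopf("input_shape must have %d dims", dims)
  if (kernel %% 2L != 1L) stopf("kernel must be odd for same padding")
  div <- 2L^(as.integer(depth) - 1L)
  bad <- which(input_shape %% div != 0L)
  if (length(bad))
    stopf("input axis %d (size %d) is not divisible by 2^(depth-1) = %d",
          bad[1], input_shape[bad[1]], div)
  if (is.null(final_activation))
    final_activation <- if (out_channels == 1L) "sigmoid" else "softmax"
  final_activation <- match.arg(final_activation, c("sigmoid", "softmax"))
  structure(list(dims = dims, input_shape = input_shape,
                 in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 depth = as.integer(depth),
                 base_filters = as.integer(base_filters),
                 kernel = as.integer(kernel),
                 dropout_rate = dropout_rate,
                 final_activation = final_activation),
            class = "unet_config")
}

# Channel widths per level and per-block input channels.
unet_widths <- function(cfg) {
  f <- cfg$base_filters * 2L^(seq_len(cfg$depth) - 1L)
  enc_in <- c(cfg$in_channels, f[-cfg$depth])
  list(f = f, enc_in = enc_in)
}

#' Analytic trainable-parameter count of a U-Net configuration
#'
#' Sums kernel and bias counts per layer (convolutions, transposed
#' convolutions, batch-norm scale/shift, output head); running batch-norm
#' statistics are not trainable and are excluded. The built model must
#' report exactly this number for any configuration.
#'
#' @param cfg a [unet_config()].
#' @return integer parameter count.
#' @export
unet_param_count <- function(cfg) {
  K <- cfg$kernel^cfg$dims
  w <- unet_widths(cfg)
  total <- 0
  for (i in seq_len(cfg$depth)) {
    f <- w$f[i]
    total <- total + K * w$enc_in[i] * f + f   # conv1
    total <- total + K * f * f + f             # conv2
    total <- total + 2 * f                     # bn gamma/beta
  }
  for (j in seq_len(cfg$depth - 1L)) {
    f <- w$f[j]; up_in <- w$f[j + 1L]
    total <- total + 2L^cfg$dims * up_in * f + f  # transposed conv
    total <- total + K * (2 * f) * f + f          # conv1 on concat
    total <- total + K * f * f + f                # conv2
    total <- total + 2 * f                        # bn
  }
  as.integer(total + w$f[1] * cfg$out_channels + cfg$out_channels)  # 1x1 head
}

#' Build a U-Net model
#'
#' Instantiates the network described by a [unet_config()]: weights are
#' initialized from a normal distribution (mean 0, SD 0.01) and biases at
#' zero, batch-norm scale/shift at 1/0, all drawn reproducibly from `seed`.
#' Gather/scatter index tables for every resolution level are precomputed
#' here so that training and inference are pure matrix operations.
#'
#' @param cfg a [unet_config()].
#' @param seed integer controlling weight initialization.
#' @return an object of class `unet_model` with elements `cfg`, `params`
#'   (trainable tensors), `stats` (batch-norm running moments) and
#'   `n_params`.
#' @export
build_unet <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "unet_config"))
  D <- cfg$depth
  w <- unet_widths(cfg)
  shapes <- vector("list", D)
  shapes[[1]] <- cfg$input_shape
  for (i in 2:max(D, 2)) if (i <= D) shapes[[i]] <- shapes[[i - 1]] %/% 2L
  pad <- (cfg$kernel - 1L) %/% 2L
  conv_idx <- lapply(shapes, build_gather_idx,
                     kernel = cfg$kernel, stride = 1L, pad = pad)
  pool_idx <- lapply(seq_len(D - 1L), function(i)
    build_gather_idx(shapes[[i]], kernel = 2L, stride = 2L, pad = 0L))
  scat_idx <- lapply(seq_len(D - 1L), function(j)
    build_scatter_idx(shapes[[j + 1L]]))
  K <- cfg$kernel^cfg$dims
  params <- list()
  with_local_seed(seed, {
    new_w <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = 0.01), nr, nc)
    for (i in seq_len(D)) {
      f <- w$f[i]
      params[[sprintf("enc%d.c1.W", i)]] <- new_w(K * w$enc_in[i], f)
      params[[sprintf("enc%d.c1.b", i)]] <- numeric(f)
      params[[sprintf("enc%d.c2.W", i)]] <- new_w(K * f, f)
      params[[sprintf("enc%d.c2.b", i)]] <- numeric(f)
      params[[sprintf("enc%d.bn.g", i)]] <- rep(1, f)
      params[[sprintf("enc%d.bn.s", i)]] <- numeric(f)
    }
    for (j in seq_len(D - 1L)) {
      f <- w$f[j]; up_in <- w$f[j + 1L]
      params[[sprintf("dec%d.up.W", j)]] <-
        array(stats::rnorm(2L^cfg$dims * up_in * f, sd = 0.01),
              dim = c(2L^cfg$dims, up_in, f))
      params[[sprintf("dec%d.up.b", j)]] <- numeric(f)
      params[[sprintf("dec%d.c1.W", j)]] <- new_w(K * 2L * f, f)
      params[[sprintf("dec%d.c1.b", j)]] <- numeric(f)
      params[[sprintf("dec%d.c2.W", j)]] <- new_w(K * f, f)
      params[[sprintf("dec%d.c2.b", j)]] <- numeric(f)
      params[[sprintf("dec%d.bn.g", j)]] <- rep(1, f)
      params[[sprintf("dec%d.bn.s", j)]] <- numeric(f)
    }
    params[["out.W"]] <- new_w(w$f[1], cfg$out_channels)
    params[["out.b"]] <- numeric(cfg$out_channels)
  })
  stats <- list()
  for (i in seq_len(D)) {
    stats[[sprintf("enc%d.bn.mean", i)]] <- numeric(w$f[i])
    stats[[sprintf("enc%d.bn.var", i)]] <- rep(1, w$f[i])
  }
  for (j in seq_len(D - 1L)) {
    stats[[sprintf("dec%d.bn.mean", j)]] <- numeric(w$f[j])
    stats[[sprintf("dec%d.bn.var", j)]] <- rep(1, w$f[j])
  }
  model <- structure(list(cfg = cfg, params = params, stats = stats,
                          shapes = shapes, conv_idx = conv_idx,
                          pool_idx = pool_idx, scat_idx = scat_idx,
                          widths = w, cache_env = new.env(parent = emptyenv()),
                          n_params = sum(vapply(params, length, integer(1)))),
                     class = "unet_model")
  stopifnot(model$n_params == unet_param_count(cfg))
  model
}

#' @export
print.unet_model <- function(x, ...) {
  cat(sprintf("<unet_model> %dD, input %s, depth %d, base %d, %s head, %d parameters\n",
              x$cfg$dims, paste(x$cfg$input_shape, collapse = "x"),
              x$cfg$depth, x$cfg$base_filters, x$cfg$final_activation,
              x$n_params))
  invisible(x)
}

# Batched index tables, memoized per batch size.
model_idx <- function(model, kind, level, N) {
  key <- sprintf("%s_%d_%d", kind, level, N)
  env <- model$cache_env
  if (!is.null(env[[key]])) return(env[[key]])
  base <- switch(kind,
                 conv = model$conv_idx[[level]],
                 pool = model$pool_idx[[level]],
                 scat = model$scat_idx[[level]])
  P <- switch(kind,
              conv = prod(model$shapes[[level]]),
              pool = prod(model$shapes[[level]]),
              scat = prod(model$shapes[[level + 1L]]))
  P_target <- switch(kind,   # grid the (1-based) entries index into
                     conv = prod(model$shapes[[level]]),
                     pool = prod(model$shapes[[level]]),
                     scat = prod(model$shapes[[level]]))
  idxb <- batch_idx(base, P_target, N)
  env[[key]] <- idxb
  idxb
}

# Full forward pass. X: (N * prod(input_shape)) x in_channels.
# Returns head probabilities and (optionally) every cache needed for
# backpropagation plus updated batch-norm running stats.
unet_forward_pass <- function(model, X, N, training = FALSE,
                              keep_cache = FALSE) {
  cfg <- model$cfg
  D <- cfg$depth
  act <- X
  enc_cache <- vector("list", D)
  dec_cache <- vector("list", D - 1L)
  skips <- vector("list", D)
  new_stats <- list()
  drop_from <- max(1L, D - 1L)
  for (i in seq_len(D)) {
    idxb <- model_idx(model, "conv", i, N)
    cc <- list()
    for (cn in c("c1", "c2")) {
      W <- model$params[[sprintf("enc%d.%s.W", i, cn)]]
      b <- model$params[[sprintf("enc%d.%s.b", i, cn)]]
      cv <- conv_forward(act, W, b, idxb)
      A <- relu_forward(cv$Z)
      if (keep_cache)
        cc[[cn]] <- list(B = cv$B, pos = cv$Z > 0, n_in = nrow(act),
                         C_in = ncol(act))
      act <- A
    }
    bn <- bn_forward(act,
                     model$params[[sprintf("enc%d.bn.g", i)]],
                     model$params[[sprintf("enc%d.bn.s", i)]],
                     model$stats[[sprintf("enc%d.bn.mean", i)]],
                     model$stats[[sprintf("enc%d.bn.var", i)]],
                     training)
    if (training) {
      new_stats[[sprintf("enc%d.bn.mean", i)]] <- bn$new_mean
      new_stats[[sprintf("enc%d.bn.var", i)]] <- bn$new_var
    }
    act <- bn$Y
    if (keep_cache) cc$bn <- list(xhat = bn$xhat, ivar = bn$ivar)
    if (training && cfg$dropout_rate > 0 && i >= drop_from) {
      mask <- matrix(stats::rbinom(length(act), 1L, 1 - cfg$dropout_rate),
                     nrow(act), ncol(act)) / (1 - cfg$dropout_rate)
      act <- act * mask
      if (keep_cache) cc$drop <- mask
    }
    skips[[i]] <- act
    if (i < D) {
      pidxb <- model_idx(model, "pool", i, N)
      pl <- maxpool_forward(act, pidxb)
      if (keep_cache) cc$pool <- list(arg = pl$arg, n_in = nrow(act))
      act <- pl$Y
    }
    enc_cache[[i]] <- cc
  }
  for (j in rev(seq_len(D - 1L))) {
    sidxb <- model_idx(model, "scat", j, N)
    W_up <- model$params[[sprintf("dec%d.up.W", j)]]
    b_up <- model$params[[sprintf("dec%d.up.b", j)]]
    P_out_rows <- N * prod(model$shapes[[j]])
    up <- upconv_forward(act, W_up, b_up, sidxb, P_out_rows)
    cc <- list(up_in = if (keep_cache) act else NULL,
               up_ch = ncol(up))
    act <- cbind(up, skips[[j]])
    idxb <- model_idx(model, "conv", j, N)
    for (cn in c("c1", "c2")) {
      W <- model$params[[sprintf("dec%d.%s.W", j, cn)]]
      b <- model$params[[sprintf("dec%d.%s.b", j, cn)]]
      cv <- conv_forward(act, W, b, idxb)
      A <- relu_forward(cv$Z)
      if (keep_cache)
        cc[[cn]] <- list(B = cv$B, pos = cv$Z > 0, n_in = nrow(act),
                         C_in = ncol(act))
      act <- A
    }
    bn <- bn_forward(act,
                     model$params[[sprintf("dec%d.bn.g", j)]],
                     model$params[[sprintf("dec%d.bn.s", j)]],
                     model$stats[[sprintf("dec%d.bn.mean", j)]],
                     model$stats[[sprintf("dec%d.bn.var", j)]],
                     training)
    if (training) {
      new_stats[[sprintf("dec%d.bn.mean", j)]] <- bn$new_mean
      new_stats[[sprintf("dec%d.bn.var", j)]] <- bn$new_var
    }
    act <- bn$Y
    if (keep_cache) cc$bn <- list(xhat = bn$xhat, ivar = bn$ivar)
    dec_cache[[j]] <- cc
  }
  Z <- sweep(act %*% model$params[["out.W"]], 2L, model$params[["out.b"]], `+`)
  P <- if (cfg$final_activation == "sigmoid") sigmoid(Z) else softmax_rows(Z)
  list(P = P, head_in = if (keep_cache) act else NULL,
       enc_cache = enc_cache, dec_cache = dec_cache,
       new_stats = new_stats, N = N)
}

# Loss and parameter gradients for one mini-batch (training mode).
unet_loss_grads <- function(model, X, Y, N, training = TRUE) {
  cfg <- model$cfg
  fw <- unet_forward_pass(model, X, N, training = training, keep_cache = TRUE)
  lg <- if (cfg$final_activation == "sigmoid") bce_loss_grad(fw$P, Y)
        else cce_loss_grad(fw$P, Y)
  grads <- list()
  dZ <- lg$dZ
  grads[["out.W"]] <- crossprod(fw$head_in, dZ)
  grads[["out.b"]] <- colSums(dZ)
  dA <- dZ %*% t(model$params[["out.W"]])
  D <- cfg$depth
  d_skip <- vector("list", D)
  for (j in seq_len(D - 1L)) {            # reverse of forward decoder order
    cc <- fw$dec_cache[[j]]
    bnb <- bn_backward(dA, cc$bn$xhat, cc$bn$ivar,
                       model$params[[sprintf("dec%d.bn.g", j)]], TRUE)
    grads[[sprintf("dec%d.bn.g", j)]] <- bnb$dgamma
    grads[[sprintf("dec%d.bn.s", j)]] <- bnb$dbeta
    dA <- bnb$dX
    idxb <- model_idx(model, "conv", j, N)
    for (cn in c("c2", "c1")) {
      ci <- cc[[cn]]
      dZc <- dA * ci$pos
      cb <- conv_backward(dZc, ci$B,
                          model$params[[sprintf("dec%d.%s.W", j, cn)]],
                          idxb, ci$n_in, ci$C_in)
      grads[[sprintf("dec%d.%s.W", j, cn)]] <- cb$dW
      grads[[sprintf("dec%d.%s.b", j, cn)]] <- cb$db
      dA <- cb$dX
    }
    ch <- cc$up_ch
    dUp <- dA[, seq_len(ch), drop = FALSE]
    d_skip[[j]] <- dA[, (ch + 1L):ncol(dA), drop = FALSE]
    sidxb <- model_idx(model, "scat", j, N)
    ub <- upconv_backward(dUp, cc$up_in,
                          model$params[[sprintf("dec%d.up.W", j)]], sidxb)
    grads[[sprintf("dec%d.up.W", j)]] <- ub$dW
    grads[[sprintf("dec%d.up.b", j)]] <- ub$db
    dA <- ub$dX                           # gradient entering level j+1 output
  }
  # encoder backward, deepest level first; at the bottleneck the incoming
  # gradient is dA from the decoder chain; elsewhere it is the pooled-path
  # gradient plus the skip gradient.
  d_below <- dA
  for (i in rev(seq_len(D))) {
    cc <- fw$enc_cache[[i]]
    if (i < D) {
      pidxb <- model_idx(model, "pool", i, N)
      dA <- maxpool_backward(d_below, cc$pool$arg, pidxb, cc$pool$n_in)
      dA <- dA + d_skip[[i]]
    } else {
      dA <- d_below
    }
    if (!is.null(cc$drop)) dA <- dA * cc$drop
    bnb <- bn_backward(dA, cc$bn$xhat, cc$bn$ivar,
                       model$params[[sprintf("enc%d.bn.g", i)]], TRUE)
    grads[[sprintf("enc%d.bn.g", i)]] <- bnb$dgamma
    grads[[sprintf("enc%d.bn.s", i)]] <- bnb$dbeta
    dA <- bnb$dX
    idxb <- model_idx(model, "conv", i, N)
    for (cn in c("c2", "c1")) {
      ci <- cc[[cn]]
      dZc <- dA * ci$pos
      cb <- conv_backward(dZc, ci$B,
                          model$params[[sprintf("enc%d.%s.W", i, cn)]],
                          idxb, ci$n_in, ci$C_in)
      grads[[sprintf("enc%d.%s.W", i, cn)]] <- cb$dW
      grads[[sprintf("enc%d.%s.b", i, cn)]] <- cb$db
      dA <- cb$dX
    }
    d_below <- dA
  }
  list(loss = lg$loss, grads = grads, new_stats = fw$new_stats, P = fw$P)
}

# Flatten a sample array (spatial dims first, optional channel dim last)
# into the (P x C) activation layout.
sample_to_matrix <- function(arr, dims, in_channels = NULL) {
  d <- dim(arr) %||% length(arr)
  if (length(d) == dims) {
    matrix(as.vector(arr), ncol = 1L)
  } else if (length(d) == dims + 1L) {
    matrix(as.vector(arr), ncol = d[length(d)])
  } else stopf("sample has %d dims; expected %d or %d", length(d), dims,
               dims + 1L)
}

#' Configure a training run
#'
#' Defaults follow the published training recipe: Adam with an initial
#' learning rate of 1e-4, binary cross-entropy for single-task sigmoid
#' networks and categorical cross-entropy for multitask softmax networks,
#' batch size 16, up to 50 epochs with early stopping on validation loss
#' and learning-rate reduction on plateau.
#'
#' @param learning_rate initial Adam learning rate.
#' @param batch_size samples (slices or patches) per gradient step.
#' @param max_epochs upper bound on training epochs.
#' @param early_stopping_patience epochs without monitored-loss improvement
#'   before stopping; `Inf` disables.
#' @param lr_reduce_factor multiplicative learning-rate decay on plateau
#'   (1 disables).
#' @param lr_reduce_patience plateau epochs before each reduction.
#' @param min_lr lower bound for the reduced learning rate.
#' @param folds folds for [cv_train()] cross-validation.
#' @param shuffle reshuffle the sample order each epoch (seeded).
#' @param seed seed controlling shuffling and dropout.
#' @param verbose print per-epoch losses.
#' @return an object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 16L,
                         max_epochs = 50L, early_stopping_patience = 8L,
                         lr_reduce_factor = 0.5, lr_reduce_patience = 4L,
                         min_lr = 1e-6, folds = 3L, shuffle = TRUE,
                         seed = 1L, verbose = FALSE) {
  stopifnot(learning_rate > 0, batch_size >= 1, max_epochs >= 1,
            lr_reduce_factor > 0, lr_reduce_factor <= 1)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stopping_patience = early_stopping_patience,
                 lr_reduce_factor = lr_reduce_factor,
                 lr_reduce_patience = lr_reduce_patience,
                 min_lr = min_lr, folds = as.integer(folds),
                 shuffle = isTRUE(shuffle), seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

unet_eval_loss <- function(model, x, y, batch_size = 16L) {
  cfg <- model$cfg
  n <- length(x)
  tot <- 0; wt <- 0
  for (s in seq(1L, n, by = batch_size)) {
    ii <- s:min(s + batch_size - 1L, n)
    X <- do.call(rbind, lapply(x[ii], sample_to_matrix, dims = cfg$dims))
    Y <- do.call(rbind, lapply(y[ii], sample_to_matrix, dims = cfg$dims))
    fw <- unet_forward_pass(model, X, length(ii), training = FALSE)
    l <- if (cfg$final_activation == "sigmoid") bce_loss_grad(fw$P, Y)$loss
         else cce_loss_grad(fw$P, Y)$loss
    tot <- tot + l * length(ii); wt <- wt + length(ii)
  }
  tot / wt
}

#' Train a U-Net
#'
#' Mini-batch Adam training with per-epoch validation-loss monitoring,
#' early stopping and learning-rate reduction on plateau. Fully seeded
#' (sample order, dropout) so a rerun with the same seed reproduces the
#' loss trajectory exactly.
#'
#' @param model a [build_unet()] model.
#' @param x,y lists of training samples: arrays shaped like the model input
#'   (spatial dims, optional trailing channel dim) and their targets
#'   (binary masks for sigmoid heads, one-hot stacks for softmax heads).
#' @param tc a [train_config()].
#' @param val_x,val_y optional validation samples; when absent, early
#'   stopping monitors the training loss.
#' @return the model with trained parameters and a `history` data.frame
#'   (epoch, train_loss, val_loss, lr) attached.
#' @export
train_unet <- function(model, x, y, tc = train_config(),
                       val_x = NULL, val_y = NULL) {
  stopifnot(inherits(model, "unet_model"), inherits(tc, "train_config"))
  if (!length(x)) stopf("empty training set")
  if (length(x) != length(y)) stopf("x and y lengths differ")
  cfg <- model$cfg
  has_val <- !is.null(val_x) && length(val_x) > 0
  lr <- tc$learning_rate
  state <- list(t = 0L, m = list(), v = list())
  history <- vector("list", tc$max_epochs)
  best <- Inf; stall <- 0L; lr_stall <- 0L
  with_local_seed(tc$seed, {
    for (epoch in seq_len(tc$max_epochs)) {
      ord <- if (tc$shuffle) sample.int(length(x)) else seq_along(x)
      ep_loss <- 0; ep_n <- 0L
      for (s in seq(1L, length(ord), by = tc$batch_size)) {
        ii <- ord[s:min(s + tc$batch_size - 1L, length(ord))]
        X <- do.call(rbind, lapply(x[ii], sample_to_matrix, dims = cfg$dims))
        Y <- do.call(rbind, lapply(y[ii], sample_to_matrix, dims = cfg$dims))
        lg <- unet_loss_grads(model, X, Y, length(ii))
        if (!is.finite(lg$loss))
          stopf("non-finite loss at epoch %d (lr %.2g); training aborted",
                epoch, lr)
        upd <- adam_step(model$params, lg$grads, state, lr)
        model$params <- upd$params
        state <- upd$state
        model$stats[names(lg$new_stats)] <- lg$new_stats
        ep_loss <- ep_loss + lg$loss * length(ii)
        ep_n <- ep_n + length(ii)
      }
      train_loss <- ep_loss / ep_n
      val_loss <- if (has_val)
        unet_eval_loss(model, val_x, val_y, tc$batch_size) else NA_real_
      monitored <- if (has_val) val_loss else train_loss
      history[[epoch]] <- data.frame(epoch = epoch, train_loss = train_loss,
                                     val_loss = val_loss, lr = lr)
      if (tc$verbose)
        message(sprintf("epoch %3d  train %.5f  val %s  lr %.2g", epoch,
                        train_loss,
                        if (has_val) sprintf("%.5f", val_loss) else "-", lr))
      if (monitored < best - 1e-7) {
        best <- monitored; stall <- 0L; lr_stall <- 0L
      } else {
        stall <- stall + 1L; lr_stall <- lr_stall + 1L
        if (tc$lr_reduce_factor < 1 && lr_stall >= tc$lr_reduce_patience &&
            lr > tc$min_lr) {
          lr <- max(lr * tc$lr_reduce_factor, tc$min_lr)
          lr_stall <- 0L
        }
        if (stall >= tc$early_stopping_patience) break
      }
    }
  })
  model$history <- do.call(rbind, history[!vapply(history, is.null,
                                                  logical(1))])
  model
}

#' k-fold cross-validation training harness
#'
#' Splits the sample list into `tc$folds` contiguous folds, trains one
#' model per fold (fold f held out for validation) and pools the
#' validation histories.
#'
#' @inheritParams train_unet
#' @param cfg a [unet_config()] used to build each fold's model.
#' @return list with `models` (one per fold) and `history` (pooled, with a
#'   `fold` column).
#' @export
cv_train <- function(cfg, x, y, tc = train_config()) {
  k <- tc$folds
  if (length(x) < k) stopf("need at least %d samples for %d folds", k, k)
  fold_of <- rep(seq_len(k), length.out = length(x))
  models <- vector("list", k)
  hist <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- fold_of != f
    m <- build_unet(cfg, seed = tc$seed + f)
    m <- train_unet(m, x[tr], y[tr], tc, x[!tr], y[!tr])
    h <- m$history
    h$fold <- f
    models[[f]] <- m
    hist[[f]] <- h
  }
  list(models = models, history = do.call(rbind, hist))
}

#' Slice-wise 2D prediction for the three single-task networks
#'
#' Runs each tissue's 2D U-Net over every axial slice of the (windowed) CT
#' volume and stacks the slices back into 3D probability maps. Inference
#' uses batch-norm running statistics, so per-slice and batched inference
#' coincide exactly; the native z-depth is preserved.
#'
#' @param models named list with elements `gm`, `wm`, `csf` of trained 2D
#'   [unet_model]s.
#' @param ct a [ct_volume()] (already windowed to `[0, 1]`) or bare array.
#' @return named list of 3D probability arrays (`gm`, `wm`, `csf`), each
#'   the shape of `ct`.
#' @export
predict_2d <- function(models, ct) {
  if (!all(c("gm", "wm", "csf") %in% names(models)))
    stopf("models must be a named list with gm, wm and csf entries")
  x <- vol_data(ct)
  d <- dim(x)
  out <- list()
  for (nm in c("gm", "wm", "csf")) {
    m <- models[[nm]]
    stopifnot(inherits(m, "unet_model"))
    if (!all(m$cfg$input_shape == d[1:2]))
      stopf("model '%s' expects %s slices but volume is %s", nm,
            paste(m$cfg$input_shape, collapse = "x"),
            paste(d[1:2], collapse = "x"))
    X <- do.call(rbind, lapply(extract_slices(x), sample_to_matrix, dims = 2L))
    fw <- unet_forward_pass(m, X, d[3], training = FALSE)
    out[[nm]] <- array(fw$P[, 1L], dim = d)
  }
  out
}

#' Patch-based 3D prediction for the multitask network
#'
#' Plans the sliding-window grid, pads the volume if the grid would not
#' tile it, runs the multitask 3D U-Net over every patch and stitches the
#' four-channel softmax outputs back by voxel-wise averaging of
#' overlapping patches (which preserves the unit channel sum).
#'
#' @param model a trained multitask 3D [unet_model].
#' @param ct a [ct_volume()] (windowed to `[0, 1]`) or bare 3D array.
#' @param step per-axis sliding step; defaults to half the patch size in x
#'   and y and the full patch depth in z.
#' @param batch_patches patches evaluated per forward call.
#' @return 4D array (x, y, z, channel) with channel order (background, GM,
#'   WM, CSF); channels sum to 1 at every voxel up to numerical tolerance.
#' @export
predict_3d <- function(model, ct, step = NULL, batch_patches = 8L) {
  stopifnot(inherits(model, "unet_model"), model$cfg$dims == 3L)
  x <- vol_data(ct)
  d <- dim(x)
  patch <- model$cfg$input_shape
  if (any(d < patch))
    stopf("volume %s is smaller than the model patch %s; resize first",
          paste(d, collapse = "x"), paste(patch, collapse = "x"))
  if (is.null(step)) step <- c(patch[1] %/% 2L, patch[2] %/% 2L, patch[3])
  padded <- pad_to_grid(x, patch, step)
  grid <- plan_grid(dim(padded$data), patch, step)
  patches <- extract_patches(padded$data, grid)
  n_ch <- model$cfg$out_channels
  preds <- vector("list", grid$n_patches)
  for (s in seq(1L, grid$n_patches, by = batch_patches)) {
    ii <- s:min(s + batch_patches - 1L, grid$n_patches)
    X <- do.call(rbind, lapply(patches[ii], sample_to_matrix, dims = 3L))
    fw <- unet_forward_pass(model, X, length(ii), training = FALSE)
    Pp <- prod(patch)
    for (k in seq_along(ii))
      preds[[ii[k]]] <- array(fw$P[((k - 1L) * Pp + 1L):(k * Pp), ],
                              dim = c(patch, n_ch))
  }
  stitched <- stitch_patches(preds, grid)
  crop_to_shape(stitched, padded$offset, d)
}
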