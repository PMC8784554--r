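tiny2 <- unet_config(dims = 2, input_shape = c(16, 16), depth = 2,
                     base_filters = 2, dropout_rate = 0)
tiny3 <- unet_config(dims = 3, input_shape = c(8, 8, 4), depth = 2,
                     base_filters = 2, out_channels = 4, dropout_rate = 0)

rand_batch <- function(cfg, n, seed = 1) {
  set.seed(seed)
  P <- prod(cfg$input_shape)
  X <- matrix(runif(n * P * cfg$in_channels), n * P, cfg$in_channels)
  if (cfg$final_activation == "sigmoid") {
    Y <- matrix(rbinom(n * P, 1, 0.4), ncol = 1)
  } else {
    k <- sample(cfg$out_channels, n * P, TRUE)
    Y <- matrix(0, n * P, cfg$out_channels)
    Y[cbind(seq_len(n * P), k)] <- 1
  }
  list(X = X, Y = Y)
}

test_that("output heads respect their activation contracts", {
  m2 <- build_unet(tiny2, seed = 1)
  b <- rand_batch(tiny2, 2)
  fw <- ctsegbench:::unet_forward_pass(m2, b$X, 2L)
  expect_equal(dim(fw$P), c(2 * 16 * 16, 1))
  expect_true(all(fw$P >= 0 & fw$P <= 1))
  m3 <- build_unet(tiny3, seed = 1)
  b3 <- rand_batch(tiny3, 2)
  fw3 <- ctsegbench:::unet_forward_pass(m3, b3$X, 2L)
  expect_equal(ncol(fw3$P), 4)
  expect_equal(rowSums(fw3$P), rep(1, nrow(fw3$P)), tolerance = 1e-12)
})

test_that("analytic parameter count matches every built model", {
  cfgs <- list(
    tiny2, tiny3,
    unet_config(dims = 2, input_shape = c(64, 64), preset = "desk"),
    unet_config(dims = 3, input_shape = c(32, 32, 8), out_channels = 4,
                preset = "desk"),
    unet_config(dims = 2, input_shape = c(64, 64), depth = 4,
                base_filters = 8))
  for (cfg in cfgs) {
    m <- build_unet(cfg, seed = 2)
    expect_identical(m$n_params, unet_param_count(cfg))
    expect_identical(m$n_params,
                     sum(vapply(m$params, length, integer(1))))
  }
  # identical configs always report identical counts
  expect_identical(build_unet(tiny2, seed = 5)$n_params,
                   build_unet(tiny2, seed = 99)$n_params)
})

test_that("indivisible input dimensions are rejected naming the axis", {
  expect_error(unet_config(dims = 2, input_shape = c(30, 32), depth = 3),
               "axis 1")
  expect_error(unet_config(dims = 3, input_shape = c(32, 32, 6), depth = 3),
               "axis 3")
})

test_that("backpropagated gradients match finite differences", {
  for (cfg in list(tiny2, tiny3)) {
    m <- build_unet(cfg, seed = 3)
    # perturb weights away from the tiny init so the loss surface is
    # informative
    set.seed(30)
    m$params <- lapply(m$params, function(p)
      p + stats::rnorm(length(p), sd = 0.05))
    b <- rand_batch(cfg, 2, seed = 31)
    lg <- ctsegbench:::unet_loss_grads(m, b$X, b$Y, 2L)
    loss_at <- function(params) {
      m2 <- m; m2$params <- params
      fw <- ctsegbench:::unet_forward_pass(m2, b$X, 2L, training = TRUE)
      if (cfg$final_activation == "sigmoid")
        ctsegbench:::bce_loss_grad(fw$P, b$Y)$loss
      else ctsegbench:::cce_loss_grad(fw$P, b$Y)$loss
    }
    eps <- 1e-5
    set.seed(32)
    for (rep in 1:25) {
      nm <- sample(names(m$params), 1)
      i <- sample(length(m$params[[nm]]), 1)
      pp <- m$params; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- m$params; pm[[nm]][i] <- pm[[nm]][i] - eps
      num <- (loss_at(pp) - loss_at(pm)) / (2 * eps)
      ana <- lg$grads[[nm]][i]
      expect_lt(abs(num - ana) / max(abs(num), abs(ana), 1e-6), 5e-3)
    }
  }
})

test_that("training runs, descends on a learnable toy and is seeded", {
  # toy task: segment a bright square on a dark background
  set.seed(40)
  mk <- function() {
    x <- matrix(0.1 + runif(256, 0, 0.02), 16, 16)
    y <- matrix(0, 16, 16)
    o <- sample(4:8, 2, TRUE)
    x[o[1] + 1:6, o[2] + 1:6] <- 0.8
    y[o[1] + 1:6, o[2] + 1:6] <- 1
    list(x = x, y = y)
  }
  samples <- replicate(12, mk(), simplify = FALSE)
  xs <- lapply(samples, `[[`, "x"); ys <- lapply(samples, `[[`, "y")
  tc <- train_config(learning_rate = 1e-2, batch_size = 4, max_epochs = 1,
                     seed = 41)
  m1 <- train_unet(build_unet(tiny2, seed = 41), xs, ys, tc)
  expect_equal(nrow(m1$history), 1)
  expect_true(is.finite(m1$history$train_loss))
  # identical seeds give identical first-epoch losses; different seeds differ
  m1b <- train_unet(build_unet(tiny2, seed = 41), xs, ys, tc)
  expect_identical(m1$history$train_loss, m1b$history$train_loss)
  tc2 <- tc; tc2$seed <- 99L
  m1c <- train_unet(build_unet(tiny2, seed = 41), xs, ys, tc2)
  expect_false(identical(m1$history$train_loss, m1c$history$train_loss))
  # longer training descends
  tc30 <- train_config(learning_rate = 1e-2, batch_size = 4,
                       max_epochs = 30, early_stopping_patience = Inf,
                       seed = 41)
  m30 <- train_unet(build_unet(tiny2, seed = 41), xs, ys, tc30)
  expect_lt(utils::tail(m30$history$train_loss, 1),
            m30$history$train_loss[1] / 2)
  expect_error(train_unet(build_unet(tiny2), list(), list(), tc), "empty")
})

test_that("cross-validation yields one model per fold with pooled history", {
  set.seed(50)
  xs <- replicate(6, matrix(runif(256), 16, 16), simplify = FALSE)
  ys <- replicate(6, matrix(rbinom(256, 1, 0.3), 16, 16), simplify = FALSE)
  tc <- train_config(learning_rate = 1e-3, batch_size = 2, max_epochs = 2,
                     folds = 3, seed = 51)
  cvr <- cv_train(tiny2, xs, ys, tc)
  expect_length(cvr$models, 3)
  expect_setequal(unique(cvr$history$fold), 1:3)
  expect_true(all(is.finite(cvr$history$val_loss)))
})

test_that("slice-wise prediction equals per-slice inference and keeps shape", {
  sub <- make_subjects(1, desk_spec(seed = 61))[[1]]
  cfg <- unet_config(dims = 2, input_shape = c(64, 64), preset = "desk")
  m <- build_unet(cfg, seed = 6)
  models <- list(gm = m, wm = m, csf = m)
  p <- predict_2d(models, sub$ct)
  expect_equal(dim(p$gm), dim(sub$ct$data))
  expect_true(all(p$gm >= 0 & p$gm <= 1))
  # batched inference equals slice-at-a-time inference (running BN stats)
  k <- 3L
  one <- ctsegbench:::unet_forward_pass(
    m, matrix(as.vector(sub$ct$data[, , k]), ncol = 1), 1L)
  expect_equal(array(one$P[, 1], dim(sub$ct$data)[1:2]), p$gm[, , k],
               tolerance = 1e-12)
  # z-depth is arbitrary: a 3-slice volume works with the same models
  short <- ct_volume(sub$ct$data[, , 1:3], sub$ct$spacing_mm)
  expect_equal(dim(predict_2d(models, short)$wm), c(64, 64, 3))
  expect_error(predict_2d(models, array(0, c(32, 32, 4))), "expects")
})

test_that("patch-based 3D prediction stitches to normalized maps", {
  sub <- make_subjects(1, desk_spec(seed = 62))[[1]]
  cfg <- unet_config(dims = 3, input_shape = c(32, 32, 8), out_channels = 4,
                     preset = "desk")
  m <- build_unet(cfg, seed = 7)
  p4 <- predict_3d(m, sub$ct)
  expect_equal(dim(p4), c(64, 64, 8, 4))
  sums <- apply(p4, 1:3, sum)
  expect_true(all(abs(sums - 1) < 1e-5))
  # a volume of exactly one patch reduces to a direct model call
  patch <- sub$ct$data[1:32, 1:32, 1:8]
  direct <- ctsegbench:::unet_forward_pass(
    m, matrix(as.vector(patch), ncol = 1), 1L)
  via <- predict_3d(m, patch)
  expect_equal(array(direct$P, c(32, 32, 8, 4)), via, tolerance = 1e-12)
})
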