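test_that("Huber loss matches hand-worked values and the formula oracle", {
  expect_equal(huber_loss(c(1, 2, 3), c(1, 2, 3), 0.5), 0)
  expect_equal(huber_loss(0.3, 0, 0.5), 0.045) # quadratic branch: 0.5 * 0.09
  expect_equal(huber_loss(1, 0, 0.5), 0.375) # linear branch: 0.5 * (1 - 0.25)
  withr::local_seed(10)
  for (i in 1:100) {
    n <- sample(1:20, 1)
    y <- rnorm(n); yh <- rnorm(n); d <- runif(1, 0.05, 2)
    oracle <- mean(vapply(seq_len(n), function(j) {
      e <- abs(y[j] - yh[j])
      if (e <= d) 0.5 * e^2 else d * (e - 0.5 * d)
    }, 0))
    expect_equal(huber_loss(y, yh, d), oracle, tolerance = 1e-9)
  }
  expect_error(huber_loss(1:3, 1:2), "equal length")
})

test_that("event weights encode the glycemic categories", {
  expect_equal(event_weights(60), array(100, 1))
  expect_equal(event_weights(200), array(10, 1))
  expect_equal(event_weights(120), array(1, 1))
  # boundaries: 70 is not hypo; 180 is hyper
  expect_equal(as.vector(event_weights(c(69.999, 70, 179.999, 180))),
               c(100, 1, 1, 10))
  m <- matrix(c(50, 100, 190, 250), 2)
  expect_equal(event_weights(m), matrix(c(100, 1, 10, 10), 2))
})

test_that("weighted loss reduces to Huber and composes weights linearly", {
  cfg <- small_model_config()
  y <- matrix(runif(12), 4, 3)
  yh <- y + matrix(rnorm(12, 0, 0.3), 4, 3)
  y_mgdl <- matrix(runif(12, 80, 170), 4, 3)
  cfg1 <- small_model_config(lambda_hypo = 1, lambda_hyper = 1, lambda_normo = 1)
  expect_equal(weighted_sequence_loss(y, yh, y_mgdl, cfg1),
               huber_loss(y, yh, cfg1$delta), tolerance = 1e-12)
  # all-normo batch scales by lambda_normo
  cfg2 <- small_model_config(lambda_normo = 3.5)
  expect_equal(weighted_sequence_loss(y, yh, y_mgdl, cfg2),
               3.5 * huber_loss(y, yh, cfg2$delta), tolerance = 1e-12)
  # mixed two-element batch: (100 l + 1 l) / 2
  y2 <- matrix(c(0.2, 0.2), 1)
  yh2 <- matrix(c(0.3, 0.3), 1)
  ymg <- matrix(c(60, 120), 1)
  l <- 0.5 * 0.1^2
  expect_equal(weighted_sequence_loss(y2, yh2, ymg, small_model_config()),
               (100 * l + 1 * l) / 2, tolerance = 1e-9)
})

test_that("fusion is a masked weighted elementwise sum", {
  z <- matrix(rnorm(8), 2, 4)
  ones <- rep(1, 4); zero <- rep(0, 4)
  # selector
  expect_equal(fuse(list(z, z * 2, z * 3, z * 4), list(ones, zero, zero, zero)),
               z)
  # convex identity
  q <- rep(0.25, 4)
  expect_equal(fuse(list(z, z, z, z), list(q, q, q, q)), z)
  # elementwise product across the horizon
  y1 <- matrix(c(3, 4), 1)
  expect_equal(fuse(list(y1, y1, y1, y1), list(c(1, 2), c(0, 0), c(0, 0), c(0, 0))),
               matrix(c(3, 8), 1))
  # linear in each component with the others fixed
  withr::local_seed(11)
  W <- replicate(4, rnorm(4), simplify = FALSE)
  ys <- replicate(4, matrix(rnorm(12), 3, 4), simplify = FALSE)
  base <- fuse(ys, W)
  ys2 <- ys; ys2[[2]] <- ys[[2]] * 2
  delta <- fuse(ys2, W) - base
  expect_equal(delta, sweep(ys[[2]], 2, W[[2]], "*"), tolerance = 1e-12)
  expect_error(fuse(ys, W, mask = rep(FALSE, 4)), "masked off")
  # brute-force oracle
  for (i in 1:100) {
    Wr <- replicate(4, rnorm(3), simplify = FALSE)
    yr <- replicate(4, matrix(rnorm(6), 2, 3), simplify = FALSE)
    manual <- matrix(0, 2, 3)
    for (cc in 1:4) for (s in 1:2) for (j in 1:3) {
      manual[s, j] <- manual[s, j] + Wr[[cc]][j] * yr[[cc]][s, j]
    }
    expect_equal(fuse(yr, Wr), manual, tolerance = 1e-9)
  }
})

test_that("model construction obeys the configured shapes and seeding", {
  cfg <- model_config()
  m <- build_model(cfg, seed = 12)
  # component input channel counts (2,1,2,2); first encoder block projects
  expect_equal(ncol(m$params$comps$c1$enc[[1]]$c1$W[[1]]), 2)
  expect_equal(ncol(m$params$comps$c2$enc[[1]]$c1$W[[1]]), 1)
  expect_equal(ncol(m$params$comps$c3$enc[[1]]$c1$W[[1]]), 2)
  expect_equal(ncol(m$params$comps$c4$enc[[1]]$c1$W[[1]]), 2)
  expect_equal(dim(m$params$comps$c1$head$W), c(1L, 64L))
  expect_length(m$params$fusion$W1, 6)
  expect_true(all(unlist(m$params$fusion) == 0.25))
  m2 <- build_model(cfg, seed = 12)
  expect_identical(glucotcn:::flatten_params(m$params),
                   glucotcn:::flatten_params(m2$params))
  expect_error(model_config(component_mask = rep(FALSE, 4)), "component")
  expect_error(model_config(delta = 0), "delta")
})

test_that("masked-off components receive no gradient", {
  cfg <- small_model_config(component_mask = c(FALSE, TRUE, FALSE, FALSE))
  m <- build_model(cfg, seed = 13)
  w <- make_scaled_windows(n = 60)
  x_mats <- glucotcn:::windows_to_mats(w, 1:8)
  fw <- glucotcn:::model_forward(m, x_mats, 8L, training = FALSE, keep_cache = TRUE)
  d_yhat <- matrix(rnorm(24), 8, 3)
  gr <- glucotcn:::model_backward(m, fw, d_yhat, 8L)
  expect_true(all(glucotcn:::flatten_params(gr$comps$c1) == 0))
  expect_true(all(glucotcn:::flatten_params(gr$comps$c3) == 0))
  expect_true(all(glucotcn:::flatten_params(gr$comps$c4) == 0))
  expect_gt(sum(abs(glucotcn:::flatten_params(gr$comps$c2))), 0)
  expect_true(all(gr$fusion$W1 == 0) && any(gr$fusion$W2 != 0))
})

test_that("whole-model gradients match finite differences", {
  cfg <- small_model_config(tcn = small_tcn(spatial_dropout = 0))
  m <- build_model(cfg, seed = 14)
  w <- make_scaled_windows(n = 60)
  idx <- 1:6
  x_mats <- glucotcn:::windows_to_mats(w, idx)
  y <- w$y[idx, ]; y_mgdl <- w$y_mgdl[idx, ]
  loss_at <- function(theta) {
    mm <- m
    mm$params <- glucotcn:::unflatten_params(theta, m$params)
    fw <- glucotcn:::model_forward(mm, x_mats, length(idx), training = FALSE)
    weighted_sequence_loss(y, fw$y_hat, y_mgdl, cfg)
  }
  theta <- glucotcn:::flatten_params(m$params)
  fw <- glucotcn:::model_forward(m, x_mats, length(idx), training = FALSE,
                                 keep_cache = TRUE)
  d_yhat <- glucotcn:::weighted_loss_grad(y, fw$y_hat, y_mgdl, cfg)
  grads <- glucotcn:::flatten_params(
    glucotcn:::model_backward(m, fw, d_yhat, length(idx)))
  withr::local_seed(15)
  probe <- sample(length(theta), 25)
  eps <- 1e-6
  for (j in probe) {
    tp <- theta; tp[j] <- tp[j] + eps
    tm <- theta; tm[j] <- tm[j] - eps
    fd <- (loss_at(tp) - loss_at(tm)) / (2 * eps)
    expect_equal(grads[j], fd, tolerance = 1e-4)
  }
})

test_that("training minimizes the loss and stops as configured", {
  w <- make_scaled_windows(n = 260, stride = 1)
  cfg <- small_model_config(max_epochs = 12, learning_rate = 1e-3, seed = 16)
  m <- train_model(build_model(cfg), w)
  expect_true(m$trained)
  expect_lt(tail(m$history$train_loss, 1), 0.5 * m$history$train_loss[1])
  # identical seeds give identical trainings
  m2 <- train_model(build_model(cfg), w)
  expect_identical(glucotcn:::flatten_params(m$params),
                   glucotcn:::flatten_params(m2$params))
  # different loss weights change the trajectory
  cfg_flat <- small_model_config(max_epochs = 2, seed = 16, lambda_hypo = 1,
                                 lambda_hyper = 1)
  cfg_def <- small_model_config(max_epochs = 2, seed = 16)
  wa <- w
  wa$y_mgdl[1:50, ] <- 60 # make some targets hypoglycemic
  ma <- train_model(build_model(cfg_flat), wa)
  mb <- train_model(build_model(cfg_def), wa)
  expect_false(identical(glucotcn:::flatten_params(ma$params),
                         glucotcn:::flatten_params(mb$params)))
  # bookkeeping: patience 0 with a 1-epoch budget records exactly one epoch
  cfg1 <- small_model_config(max_epochs = 1, early_stop_patience = 0, seed = 17)
  m1 <- train_model(build_model(cfg1), w)
  expect_identical(nrow(m1$history), 1L)
  expect_error(train_model(build_model(cfg1), subset_windows(w, integer(0))),
               "empty")
})

test_that("prediction is deterministic, de-scaled and leakage-free", {
  w <- make_scaled_windows(n = 260)
  cfg <- small_model_config(max_epochs = 10, learning_rate = 1e-3, seed = 18)
  m <- train_model(build_model(cfg), w)
  fc1 <- predict(m, w)
  fc2 <- predict(m, w)
  expect_identical(fc1$y_pred, fc2$y_pred)
  expect_true(all(is.finite(fc1$y_pred)))
  expect_true(mean(fc1$y_pred) > 20 && mean(fc1$y_pred) < 600)
  # duplicated windows predict alike (BLAS may round differently per column)
  wd <- subset_windows(w, c(5, 5))
  pd <- predict(m, wd)$y_pred
  expect_equal(pd[1, ], pd[2, ], tolerance = 1e-10)
  # no leakage: the forecast depends only on data at or before the anchor
  seg <- make_segment(n = 260)
  sc <- w$scaler
  future_changed <- seg
  t_cut <- 200
  future_changed$cgm[(t_cut + 1):260] <- rev(future_changed$cgm[(t_cut + 1):260])
  w_a <- scale_windows(make_windows(seg, p = c(12, 6, 12, 12), f = 3), sc)
  w_b <- scale_windows(make_windows(future_changed, p = c(12, 6, 12, 12), f = 3), sc)
  keep <- which(w_a$anchors <= t_cut)
  pa <- predict(m, subset_windows(w_a, keep))$y_pred
  pb <- predict(m, subset_windows(w_b, keep))$y_pred
  expect_identical(pa, pb)
  # ablating a component at inference changes the forecast
  p_masked <- predict(m, w, mask = c(TRUE, FALSE, TRUE, TRUE))$y_pred
  expect_false(identical(fc1$y_pred, p_masked))
})

test_that("fusion contribution report has the right shape and start point", {
  cfg <- small_model_config()
  m <- build_model(cfg, seed = 19)
  rep <- report_fusion_contributions(m)
  expect_equal(nrow(rep), 4 * cfg$f)
  expect_true(all(rep$weight == 0.25))
  expect_equal(unname(attr(rep, "mean_abs_weight")), rep(0.25, 4))
})

test_that("checkpoints round-trip the model losslessly", {
  w <- make_scaled_windows(n = 200)
  cfg <- small_model_config(max_epochs = 2, seed = 20)
  m <- train_model(build_model(cfg), w)
  path <- withr::local_tempfile(fileext = ".json")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  expect_equal(glucotcn:::flatten_params(m2$params),
               glucotcn:::flatten_params(m$params), tolerance = 1e-9)
  expect_equal(m2$scaler$cgm, m$scaler$cgm, tolerance = 1e-9)
  expect_equal(predict(m2, w)$y_pred, predict(m, w)$y_pred, tolerance = 1e-9)
})

test_that("in-place Adam matches the reference update", {
  withr::local_seed(21)
  n <- 50
  theta_r <- rnorm(n); grad <- rnorm(n)
  st <- glucotcn:::adam_init(n)
  ref <- glucotcn:::adam_step(theta_r, grad, st, 1e-3)
  theta_c <- theta_r + 0
  m <- numeric(n); v <- numeric(n)
  glucotcn:::cpp_adam_step(theta_c, grad, m, v, 1e-3, 0.9, 0.999, 1e-8, 1L)
  expect_equal(theta_c, ref$theta, tolerance = 1e-12)
  expect_equal(m, ref$state$m, tolerance = 1e-12)
})
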