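# The four-component forecaster: each component is a TCN encoder-decoder
# over one input view -- (BG, meal) over p1 steps, recent BG over p2,
# (BG, basal) over p3, (BG, bolus) over p4 -- with a time-distributed linear
# head per horizon step; component forecasts are combined by a learnable
# parametric fusion layer, and training minimizes an event-weighted Huber
# loss with Adam.

#' Model configuration
#'
#' Defaults follow the published setup: histories `p1 = p3 = p4 = 36` and
#' `p2 = 6` five-minute steps, horizon `f = 6` (30 minutes), Adam with
#' learning rate 1e-4, batch size 32, Huber threshold `delta = 0.5` on
#' normalized glucose, and event weights 100/10/1 for
#' hypo-/hyper-/normoglycemic targets.
#'
#' @param p integer vector `c(p1, p2, p3, p4)` of input history lengths.
#' @param f prediction horizon in 5-minute steps.
#' @param tcn a [tcn_config()] shared by all encoders and decoders.
#' @param learning_rate Adam learning rate.
#' @param batch_size training batch size.
#' @param max_epochs maximum training epochs.
#' @param early_stop_patience epochs without validation improvement before
#'   stopping (best weights are restored).
#' @param val_frac chronological tail fraction of the training windows held
#'   out for validation when none is supplied.
#' @param delta Huber threshold, in normalized glucose units.
#' @param lambda_hypo,lambda_hyper,lambda_normo loss weights applied to
#'   elements whose true glucose is hypo- (< 70), hyper- (>= 180) or
#'   normoglycemic.
#' @param component_mask four logical flags enabling the components.
#' @param seed integer seed for initialization, shuffling and dropout.
#' @return a `model_config` object.
#' @export
model_config <- function(p = c(36L, 6L, 36L, 36L), f = 6L, tcn = tcn_config(),
                         learning_rate = 1e-4, batch_size = 32L,
                         max_epochs = 200L, early_stop_patience = 20L,
                         val_frac = 0.1, delta = 0.5, lambda_hypo = 100,
                         lambda_hyper = 10, lambda_normo = 1,
                         component_mask = rep(TRUE, 4), seed = 1L) {
  abort_if(length(p) != 4 || any(p < 1), "p must be four positive history lengths")
  abort_if(f < 1, "horizon f must be >= 1")
  abort_if(delta <= 0, "delta must be > 0")
  abort_if(any(c(lambda_hypo, lambda_hyper, lambda_normo) <= 0),
           "loss weights must be > 0")
  abort_if(length(component_mask) != 4, "component_mask must have 4 entries")
  abort_if(!any(component_mask), "at least one component must be enabled")
  structure(list(
    p = as.integer(p), f = as.integer(f), tcn = tcn,
    learning_rate = learning_rate, batch_size = as.integer(batch_size),
    max_epochs = as.integer(max_epochs),
    early_stop_patience = as.integer(early_stop_patience),
    val_frac = val_frac, delta = delta, lambda_hypo = lambda_hypo,
    lambda_hyper = lambda_hyper, lambda_normo = lambda_normo,
    component_mask = as.logical(component_mask), seed = as.integer(seed)
  ), class = "model_config")
}

COMP_CHANNELS <- c(2L, 1L, 2L, 2L)

#' Huber loss
#'
#' Mean over elements of the piecewise value: `0.5 * e^2` where
#' `|e| <= delta`, `delta * (|e| - delta / 2)` otherwise; continuous and once
#' differentiable at the threshold.
#'
#' @param y,y_hat numeric sequences of equal length (normalized glucose).
#' @param delta threshold between the quadratic and linear regimes.
#' @return scalar loss.
#' @export
huber_loss <- function(y, y_hat, delta = 0.5) {
  abort_if(length(y) != length(y_hat), "y and y_hat must have equal length")
  abort_if(delta <= 0, "delta must be > 0")
  e <- abs(y - y_hat)
  mean(ifelse(e <= delta, 0.5 * e^2, delta * (e - 0.5 * delta)))
}

#' Event weights for the loss
#'
#' Per-element weight decided by the true glucose in mg/dL: `lambda_hypo`
#' below 70, `lambda_hyper` at or above 180, `lambda_normo` otherwise.
#' Heavier weight on rare dangerous events counteracts their scarcity in
#' training data.
#'
#' @param y_true_mgdl true glucose values, mg/dL (de-scaled).
#' @param lambda_hypo,lambda_hyper,lambda_normo category weights.
#' @return numeric weights, same shape as the input.
#' @export
event_weights <- function(y_true_mgdl, lambda_hypo = 100, lambda_hyper = 10,
                          lambda_normo = 1) {
  w <- array(lambda_normo, dim = dim(y_true_mgdl) %||% length(y_true_mgdl))
  w[y_true_mgdl < HYPO_MGDL] <- lambda_hypo
  w[y_true_mgdl >= HYPER_MGDL] <- lambda_hyper
  w
}

#' Event-weighted sequence loss
#'
#' Mean over all sequence elements of
#' `weight(y_true_mgdl) * huber(y, y_hat, delta)`; the Huber error is taken
#' on normalized glucose while the event category is decided on the true
#' mg/dL values. Reduces to the plain Huber loss when all weights are 1.
#'
#' @param y,y_hat normalized true/predicted target matrices (samples x
#'   horizon).
#' @param y_true_mgdl matching true glucose in mg/dL.
#' @param config a [model_config()] supplying `delta` and the weights.
#' @return scalar loss.
#' @export
weighted_sequence_loss <- function(y, y_hat, y_true_mgdl, config) {
  abort_if(!all(dim(as.matrix(y)) == dim(as.matrix(y_hat))),
           "y and y_hat must have equal shape")
  w <- event_weights(y_true_mgdl, config$lambda_hypo, config$lambda_hyper,
                     config$lambda_normo)
  e <- abs(y - y_hat)
  d <- config$delta
  mean(w * ifelse(e <= d, 0.5 * e^2, d * (e - 0.5 * d)))
}

# Gradient of the weighted sequence loss with respect to y_hat.
weighted_loss_grad <- function(y, y_hat, y_true_mgdl, config) {
  w <- event_weights(y_true_mgdl, config$lambda_hypo, config$lambda_hyper,
                     config$lambda_normo)
  e <- y_hat - y
  d <- config$delta
  w * ifelse(abs(e) <= d, e, d * sign(e)) / length(e)
}

#' Parametric fusion of component forecasts
#'
#' `Y = sum_c mask_c * (W_c (*) Y_c)`, the elementwise product running over
#' the horizon dimension and broadcast over samples; `W_c` holds one
#' learnable weight per horizon step for component `c`.
#'
#' @param y_list list of four (samples x horizon) component forecasts.
#' @param W list of four numeric weight vectors of length `f`.
#' @param mask four logical flags; masked-off components contribute nothing.
#' @return fused (samples x horizon) forecast.
#' @export
fuse <- function(y_list, W, mask = rep(TRUE, 4)) {
  abort_if(length(y_list) != 4 || length(W) != 4, "four components expected")
  abort_if(!any(mask), "all components are masked off")
  out <- NULL
  for (c_i in 1:4) {
    if (!mask[c_i]) next
    contrib <- sweep(y_list[[c_i]], 2L, W[[c_i]], "*")
    out <- if (is.null(out)) contrib else out + contrib
  }
  out
}

# --- model construction ------------------------------------------------------

init_component <- function(c_in, f, cfg) {
  list(
    enc = init_stack(c_in, cfg),
    dec = init_stack(cfg$n_filters, cfg),
    head = list(W = matrix(rnorm(cfg$n_filters, sd = sqrt(1 / cfg$n_filters)),
                           1, cfg$n_filters),
                b = 0)
  )
}

#' Build an (untrained) forecasting model
#'
#' Four independent TCN encoder-decoder components with input channel counts
#' (2, 1, 2, 2) and history lengths `p1..p4`, each ending in a
#' time-distributed linear head (one scalar per horizon step); fusion
#' weights start at 0.25 per component and step.
#'
#' @param config a [model_config()].
#' @param seed integer seed for weight initialization (defaults to the
#'   config's seed).
#' @return a `bg_tcn_model` (untrained).
#' @export
build_model <- function(config, seed = config$seed) {
  abort_if(!inherits(config, "model_config"), "config must be a model_config")
  cfg <- config$tcn
  params <- with_seed(seed, list(
    comps = list(
      c1 = init_component(COMP_CHANNELS[1], config$f, cfg),
      c2 = init_component(COMP_CHANNELS[2], config$f, cfg),
      c3 = init_component(COMP_CHANNELS[3], config$f, cfg),
      c4 = init_component(COMP_CHANNELS[4], config$f, cfg)
    ),
    fusion = list(W1 = rep(0.25, config$f), W2 = rep(0.25, config$f),
                  W3 = rep(0.25, config$f), W4 = rep(0.25, config$f))
  ))
  structure(list(
    config = config, params = params,
    prune = lapply(config$p, encoder_prune_maps, cfg = cfg),
    scaler = NULL, patient_id = NULL, history = NULL, trained = FALSE
  ), class = "bg_tcn_model")
}

# Forward pass over a batch of windows (engine layout built here).
# x_mats: list of four (channels x p_c*B) matrices. Returns fused normalized
# forecasts plus per-component outputs and caches for backward.
model_forward <- function(model, x_mats, b_n, training, keep_cache = training,
                          mask = model$config$component_mask) {
  cfg <- model$config$tcn
  f <- model$config$f
  fast <- use_fast_path(cfg)
  comps <- model$params$comps
  y_list <- vector("list", 4)
  caches <- vector("list", 4)
  for (c_i in 1:4) {
    if (!mask[c_i]) {
      y_list[[c_i]] <- matrix(0, b_n, f)
      next
    }
    cp <- comps[[c_i]]
    p_c <- model$config$p[c_i]
    if (fast) {
      pm <- model$prune[[c_i]]
      xg <- gather_input_cols(x_mats[[c_i]], pm$input_cols, p_c, b_n)
      er <- cpp_penc_fwd(xg, cp$enc, pm$blocks, cfg$spatial_dropout, b_n,
                         training, keep_cache)
      latent <- er$latent
      xd <- repeat_latent(latent, f)
      dr <- cpp_dstack_fwd(xd, cp$dec, stack_dilations(cfg),
                           cfg$spatial_dropout, f, b_n, training, keep_cache)
      out_dec <- dr$out
    } else {
      sr <- stack_fwd(x_mats[[c_i]], cp$enc, cfg, p_c, b_n, training, keep_cache)
      latent <- take_last_step(sr$out, p_c, b_n)
      er <- sr
      xd <- repeat_latent(latent, f)
      dr <- stack_fwd(xd, cp$dec, cfg, f, b_n, training, keep_cache)
      out_dec <- dr$out
    }
    yh <- cp$head$W %*% out_dec + cp$head$b
    y_list[[c_i]] <- t(matrix(yh, f, b_n))
    if (keep_cache) {
      caches[[c_i]] <- if (fast) {
        list(enc = er$cache, dec = dr$cache, H = out_dec)
      } else {
        list(enc = er$caches, dec = dr$caches, H = out_dec)
      }
    }
  }
  y_hat <- fuse(y_list, model$params$fusion, mask)
  list(y_hat = y_hat, y_list = y_list, caches = caches)
}

# Backward pass; returns gradients with the same structure as model$params.
model_backward <- function(model, fw, d_yhat, b_n,
                           mask = model$config$component_mask) {
  cfg <- model$config$tcn
  f <- model$config$f
  fast <- use_fast_path(cfg)
  comps <- model$params$comps
  g_comps <- vector("list", 4)
  names(g_comps) <- names(comps)
  g_fusion <- model$params$fusion
  for (c_i in 1:4) {
    w_c <- model$params$fusion[[c_i]]
    if (!mask[c_i]) {
      g_comps[[c_i]] <- zero_like(comps[[c_i]])
      g_fusion[[c_i]] <- 0 * w_c
      next
    }
    g_fusion[[c_i]] <- colSums(fw$y_list[[c_i]] * d_yhat)
    d_yc <- sweep(d_yhat, 2L, w_c, "*")
    dyh <- matrix(t(d_yc), 1) # 1 x f*B, sample-major
    cache <- fw$caches[[c_i]]
    cp <- comps[[c_i]]
    g_head <- list(W = dyh %*% t(cache$H), b = sum(dyh))
    d_h <- crossprod(cp$head$W, dyh)
    p_c <- model$config$p[c_i]
    if (fast) {
      dec_b <- cpp_dstack_bwd(d_h, cp$dec, cache$dec, stack_dilations(cfg),
                              f, b_n, want_dX = TRUE)
      d_latent <- sum_latent_grad(dec_b$dX, f, b_n)
      enc_g <- cpp_penc_bwd(d_latent, cp$enc, cache$enc,
                            model$prune[[c_i]]$blocks, b_n)$grads
    } else {
      dec_b <- stack_bwd(d_h, cp$dec, cache$dec, cfg, f, b_n)
      d_latent <- sum_latent_grad(dec_b$dX, f, b_n)
      d_top <- scatter_last_step(d_latent, p_c, b_n)
      enc_g <- stack_bwd(d_top, cp$enc, cache$enc, cfg, p_c, b_n)$grads
    }
    g_comps[[c_i]] <- list(enc = enc_g, dec = dec_b$grads, head = g_head)
  }
  list(comps = g_comps, fusion = g_fusion)
}

zero_like <- function(x) {
  if (is.list(x)) lapply(x, zero_like) else x * 0
}

windows_to_mats <- function(windows, idx = NULL) {
  grab <- function(fld) {
    a <- windows[[fld]]
    if (!is.null(idx)) a <- a[idx, , , drop = FALSE]
    batch_to_mat(a)
  }
  list(grab("x1"), grab("x2"), grab("x3"), grab("x4"))
}

#' Train the model on scaled windows
#'
#' Minimizes the event-weighted Huber loss with Adam at the configured
#' learning rate and batch size. When no validation set is given, the
#' chronological tail of the training windows is held out; training stops
#' early once the validation loss has not improved for
#' `early_stop_patience` epochs, and the best-validation weights are
#' restored. Deterministic given the config seed (single-threaded BLAS).
#'
#' @param model a `bg_tcn_model` from [build_model()].
#' @param train_windows scaled `sample_windows`.
#' @param val_windows optional scaled `sample_windows` for validation.
#' @param verbose print per-epoch losses.
#' @return the trained model, with `history` (per-epoch train/validation
#'   loss) and the scaler attached.
#' @export
train_model <- function(model, train_windows, val_windows = NULL, verbose = FALSE) {
  abort_if(!inherits(model, "bg_tcn_model"), "model must be a bg_tcn_model")
  abort_if(n_windows(train_windows) == 0, "training set is empty")
  abort_if(!isTRUE(train_windows$scaled), "windows must be scaled (see scale_windows)")
  config <- model$config
  if (is.null(val_windows)) {
    n <- n_windows(train_windows)
    n_val <- max(1L, floor(config$val_frac * n))
    abort_if(n - n_val < 1, "too few windows to carve out validation data")
    val_windows <- subset_windows(train_windows, (n - n_val + 1L):n)
    train_windows <- subset_windows(train_windows, 1:(n - n_val))
  }
  n <- n_windows(train_windows)
  # warm-start: head biases at the mean scaled target, so the fused output
  # begins at the right level and epochs go into learning dynamics
  y_bar <- mean(train_windows$y)
  b0 <- y_bar / (0.25 * sum(config$component_mask))
  for (c_i in 1:4) {
    if (config$component_mask[c_i]) model$params$comps[[c_i]]$head$b <- b0
  }
  theta <- flatten_params(model$params)
  skeleton <- model$params
  adam_m <- numeric(length(theta))
  adam_v <- numeric(length(theta))
  adam_t <- 0L
  best <- list(loss = Inf, theta = theta + 0)
  wait <- 0L
  hist_train <- numeric(0)
  hist_val <- numeric(0)

  with_seed(config$seed, {
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n)
      batch_losses <- numeric(0)
      for (b0 in seq(1L, n, by = config$batch_size)) {
        idx <- ord[b0:min(b0 + config$batch_size - 1L, n)]
        b_n <- length(idx)
        x_mats <- windows_to_mats(train_windows, idx)
        y <- train_windows$y[idx, , drop = FALSE]
        y_mgdl <- train_windows$y_mgdl[idx, , drop = FALSE]
        fw <- model_forward(model, x_mats, b_n, training = TRUE)
        loss <- weighted_sequence_loss(y, fw$y_hat, y_mgdl, config)
        abort_if(!is.finite(loss),
                 sprintf("training failure: non-finite loss in epoch %d", epoch))
        batch_losses <- c(batch_losses, loss)
        d_yhat <- weighted_loss_grad(y, fw$y_hat, y_mgdl, config)
        grads <- model_backward(model, fw, d_yhat, b_n)
        adam_t <- adam_t + 1L
        cpp_adam_step(theta, flatten_params(grads), adam_m, adam_v,
                      config$learning_rate, 0.9, 0.999, 1e-8, adam_t)
        model$params <- unflatten_params(theta, skeleton)
      }
      val_loss <- evaluate_loss(model, val_windows)
      hist_train <- c(hist_train, mean(batch_losses))
      hist_val <- c(hist_val, val_loss)
      if (verbose) {
        message(sprintf("epoch %3d  train %.6f  val %.6f", epoch,
                        mean(batch_losses), val_loss))
      }
      if (val_loss < best$loss - 1e-12) {
        best <- list(loss = val_loss, theta = theta + 0) # + 0: snapshot copy
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait > config$early_stop_patience) break
      }
    }
  })
  model$params <- unflatten_params(best$theta, skeleton)
  model$history <- data.frame(epoch = seq_along(hist_train),
                              train_loss = hist_train, val_loss = hist_val)
  model$scaler <- train_windows$scaler
  model$patient_id <- train_windows$patient_id
  model$trained <- TRUE
  model
}

# Weighted loss over a window set in inference mode (chunked).
evaluate_loss <- function(model, windows, chunk = 1024L) {
  n <- n_windows(windows)
  total <- 0
  for (b0 in seq(1L, n, by = chunk)) {
    idx <- b0:min(b0 + chunk - 1L, n)
    fw <- model_forward(model, windows_to_mats(windows, idx), length(idx),
                        training = FALSE, keep_cache = FALSE)
    total <- total + length(idx) * weighted_sequence_loss(
      windows$y[idx, , drop = FALSE], fw$y_hat,
      windows$y_mgdl[idx, , drop = FALSE], model$config)
  }
  total / n
}

#' Subset a window set by window index
#' @param windows a `sample_windows`.
#' @param idx integer indices of the windows to keep.
#' @export
subset_windows <- function(windows, idx) {
  out <- windows
  for (fld in c("x1", "x2", "x3", "x4")) {
    out[[fld]] <- windows[[fld]][idx, , , drop = FALSE]
  }
  out$y <- windows$y[idx, , drop = FALSE]
  out$y_mgdl <- windows$y_mgdl[idx, , drop = FALSE]
  out$anchors <- windows$anchors[idx]
  out$anchor_bg <- windows$anchor_bg[idx]
  if (!is.null(out$segment_of)) out$segment_of <- windows$segment_of[idx]
  out
}

#' Predict multi-step glucose sequences
#'
#' Runs the fused model in inference mode (dropout off) and de-scales the
#' normalized outputs back to mg/dL with the model's glucose scaler.
#'
#' @param object a trained `bg_tcn_model`.
#' @param windows `sample_windows`; scaled with the model's scaler, or
#'   unscaled (then the model's scaler is applied).
#' @param mask optional component mask overriding the config (ablation).
#' @param ... unused.
#' @return a `forecast_batch`: anchors, `y_true` and `y_pred` (both
#'   samples x horizon, mg/dL).
#' @export
predict.bg_tcn_model <- function(object, windows, mask = NULL, ...) {
  abort_if(!object$trained, "model is not trained")
  if (!isTRUE(windows$scaled)) {
    abort_if(is.null(object$scaler), "windows are unscaled and model has no scaler")
    windows <- scale_windows(windows, object$scaler)
  }
  if (!is.null(object$patient_id) && !is.null(windows$patient_id) &&
        !identical(object$patient_id, windows$patient_id)) {
    warning(sprintf("predicting for patient '%s' with a model trained on '%s'",
                    windows$patient_id, object$patient_id))
  }
  mask <- mask %||% object$config$component_mask
  n <- n_windows(windows)
  y_pred <- matrix(0, n, object$config$f)
  chunk <- 1024L
  for (b0 in seq(1L, n, by = chunk)) {
    idx <- b0:min(b0 + chunk - 1L, n)
    fw <- model_forward(object, windows_to_mats(windows, idx), length(idx),
                        training = FALSE, keep_cache = FALSE, mask = mask)
    y_pred[idx, ] <- fw$y_hat
  }
  y_mgdl <- unscale_values(object$scaler %||% windows$scaler, y_pred, "cgm")
  structure(list(
    anchors = windows$anchors,
    y_true = windows$y_mgdl,
    # forecasts are glucose readings: clamp to the sensor range
    y_pred = pmin(pmax(y_mgdl, SENSOR_MIN_MGDL), SENSOR_MAX_MGDL),
    patient_id = windows$patient_id, f = object$config$f
  ), class = "forecast_batch")
}

#' Report the fusion-layer contributions
#'
#' @param model a `bg_tcn_model`.
#' @return data.frame with one row per component and horizon step (`weight`),
#'   plus a `mean_abs_weight` summary per component as an attribute.
#' @export
report_fusion_contributions <- function(model) {
  W <- model$params$fusion
  f <- model$config$f
  out <- data.frame(
    component = rep(1:4, each = f),
    step = rep(seq_len(f), 4),
    weight = unlist(W, use.names = FALSE)
  )
  attr(out, "mean_abs_weight") <- vapply(W, function(w) mean(abs(w)), 0)
  out
}

# --- checkpoints (self-describing JSON, lossless to ~1e-16) -----------------

#' Save a model checkpoint
#'
#' Writes configuration, scaler, flattened weights and training history as
#' JSON at full double precision; [load_checkpoint()] reconstructs the model
#' exactly.
#'
#' @param model a `bg_tcn_model`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
save_checkpoint <- function(model, path) {
  ck <- list(
    package = "glucotcn", format = 1L,
    config = unclass_deep(model$config),
    theta = flatten_params(model$params),
    scaler = if (!is.null(model$scaler)) unclass(model$scaler) else NULL,
    patient_id = model$patient_id,
    history = model$history,
    trained = model$trained
  )
  jsonlite::write_json(ck, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

#' Load a model checkpoint
#' @param path file written by [save_checkpoint()].
#' @return the reconstructed `bg_tcn_model`.
#' @export
load_checkpoint <- function(path) {
  ck <- jsonlite::read_json(path, simplifyVector = TRUE)
  abort_if(!identical(ck$package, "glucotcn"), "not a glucotcn checkpoint")
  cfg <- ck$config
  config <- model_config(
    p = cfg$p, f = cfg$f,
    tcn = tcn_config(cfg$tcn$kernel_size, cfg$tcn$n_filters, cfg$tcn$dilations,
                     cfg$tcn$spatial_dropout, cfg$tcn$use_normalization,
                     cfg$tcn$n_stacks),
    learning_rate = cfg$learning_rate, batch_size = cfg$batch_size,
    max_epochs = cfg$max_epochs, early_stop_patience = cfg$early_stop_patience,
    val_frac = cfg$val_frac, delta = cfg$delta, lambda_hypo = cfg$lambda_hypo,
    lambda_hyper = cfg$lambda_hyper, lambda_normo = cfg$lambda_normo,
    component_mask = cfg$component_mask, seed = cfg$seed
  )
  model <- build_model(config)
  model$params <- unflatten_params(as.numeric(ck$theta), model$params)
  if (!is.null(ck$scaler)) {
    model$scaler <- structure(lapply(ck$scaler, as.numeric), class = "minmax_scaler")
  }
  model$patient_id <- ck$patient_id
  model$history <- ck$history
  model$trained <- isTRUE(ck$trained)
  model
}

#' @export
print.bg_tcn_model <- function(x, ...) {
  cat(sprintf("<bg_tcn_model> p=(%s) f=%d filters=%d %s\n",
              paste(x$config$p, collapse = ","), x$config$f,
              x$config$tcn$n_filters,
              if (x$trained) sprintf("trained (%d epochs)", nrow(x$history))
              else "untrained"))
  invisible(x)
}
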