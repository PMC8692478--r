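# Reference predictors the forecaster is compared against: naive
# persistence, kernel ridge regression (linear/RBF), Gaussian-process
# regression with a fixed ARD-RBF kernel, and an ARX model fitted by least
# squares. All consume the same windows as the main model, so comparisons
# differ only in the predictor.

#' Feature layout for the kernel baselines
#'
#' 30 minutes of glucose history plus 3 hours of basal, bolus and meal
#' history, flattened into one feature vector per window.
#'
#' @param bg_history_steps,basal_history_steps,bolus_history_steps,meal_history_steps
#'   history lengths in 5-minute steps.
#' @return a `baseline_feature_spec`.
#' @export
baseline_feature_spec <- function(bg_history_steps = 6L, basal_history_steps = 36L,
                                  bolus_history_steps = 36L, meal_history_steps = 36L) {
  s <- list(bg = as.integer(bg_history_steps), basal = as.integer(basal_history_steps),
            bolus = as.integer(bolus_history_steps), meal = as.integer(meal_history_steps))
  abort_if(any(unlist(s) < 1), "history lengths must be positive")
  structure(s, class = "baseline_feature_spec")
}

# Flatten windows into the baseline feature matrix (uses the scaled views).
baseline_features <- function(windows, spec = baseline_feature_spec()) {
  tail_mat <- function(arr, chan, steps) {
    p <- dim(arr)[2]
    abort_if(steps > p, "requested history longer than the window provides")
    matrix(arr[, (p - steps + 1L):p, chan], nrow = dim(arr)[1])
  }
  cbind(
    tail_mat(windows$x2, 1L, spec$bg),
    tail_mat(windows$x3, 2L, spec$basal),
    tail_mat(windows$x4, 2L, spec$bolus),
    tail_mat(windows$x1, 2L, spec$meal)
  )
}

#' Naive persistence forecast
#'
#' Copies the last recorded glucose at the anchor to every horizon step.
#'
#' @param windows a `sample_windows` (scaled or not; anchor glucose is kept
#'   in mg/dL either way).
#' @return a `forecast_batch` over all `f` steps.
#' @export
naive_forecast <- function(windows) {
  n <- n_windows(windows)
  f <- windows$f
  structure(list(
    anchors = windows$anchors,
    y_true = windows$y_mgdl,
    y_pred = matrix(windows$anchor_bg, n, f),
    patient_id = windows$patient_id, f = f, steps = seq_len(f)
  ), class = "forecast_batch")
}

#' Kernel ridge regression baseline (single target step)
#'
#' Standard kernel ridge solution `(K + alpha I) c = y` on the flattened
#' feature vectors, predicting the glucose at the final horizon step only;
#' predictions are de-scaled to mg/dL.
#'
#' @param train_windows,test_windows scaled `sample_windows`.
#' @param kernel `"linear"` or `"rbf"` (`exp(-gamma * ||x - x'||^2)`).
#' @param alpha ridge regularization strength.
#' @param gamma RBF kernel width.
#' @param spec a [baseline_feature_spec()].
#' @param max_train optional cap on training points (evenly-spaced
#'   subsample) to bound the cubic solve.
#' @return a `forecast_batch` whose single column is horizon step `f`.
#' @export
krr_fit_predict <- function(train_windows, test_windows,
                            kernel = c("rbf", "linear"), alpha = 1.0,
                            gamma = 0.1, spec = baseline_feature_spec(),
                            max_train = 4000L) {
  kernel <- match.arg(kernel)
  abort_if(!isTRUE(train_windows$scaled) || !isTRUE(test_windows$scaled),
           "kernel baselines expect scaled windows")
  Xtr <- baseline_features(train_windows, spec)
  Xte <- baseline_features(test_windows, spec)
  abort_if(any(!is.finite(Xtr)) || any(!is.finite(Xte)), "non-finite features")
  f <- train_windows$f
  ytr <- train_windows$y[, f]
  if (nrow(Xtr) > max_train) {
    keep <- unique(round(seq(1L, nrow(Xtr), length.out = max_train)))
    Xtr <- Xtr[keep, , drop = FALSE]
    ytr <- ytr[keep]
  }
  kfun <- function(A, B) {
    if (kernel == "linear") {
      A %*% t(B)
    } else {
      d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
      exp(-gamma * pmax(d2, 0))
    }
  }
  K <- kfun(Xtr, Xtr)
  coefs <- solve(K + diag(alpha, nrow(K)), ytr)
  pred_scaled <- as.numeric(kfun(Xte, Xtr) %*% coefs)
  scaler <- test_windows$scaler
  structure(list(
    anchors = test_windows$anchors,
    y_true = test_windows$y_mgdl[, f, drop = FALSE],
    y_pred = matrix(unscale_values(scaler, pred_scaled, "cgm"), ncol = 1),
    patient_id = test_windows$patient_id, f = f, steps = f
  ), class = "forecast_batch")
}

#' Gaussian-process regression baseline (single target step)
#'
#' Posterior-mean prediction under an ARD-RBF kernel with all length scales
#' and the signal variance fixed at 1 (their initial values; no
#' marginal-likelihood optimization) plus a noise term. With tied length
#' scales this mean coincides with kernel ridge regression when
#' `noise_var = alpha` and `gamma = 1/(2 l^2)`.
#'
#' @inheritParams krr_fit_predict
#' @param length_scales per-feature ARD length scales (default all 1).
#' @param signal_var kernel signal variance.
#' @param noise_var observation noise variance added to the diagonal.
#' @return a `forecast_batch` whose single column is horizon step `f`.
#' @export
gp_fit_predict <- function(train_windows, test_windows, length_scales = NULL,
                           signal_var = 1.0, noise_var = 0.1,
                           spec = baseline_feature_spec(), max_train = 2000L) {
  abort_if(!isTRUE(train_windows$scaled) || !isTRUE(test_windows$scaled),
           "kernel baselines expect scaled windows")
  Xtr <- baseline_features(train_windows, spec)
  Xte <- baseline_features(test_windows, spec)
  f <- train_windows$f
  ytr <- train_windows$y[, f]
  if (nrow(Xtr) > max_train) {
    keep <- unique(round(seq(1L, nrow(Xtr), length.out = max_train)))
    Xtr <- Xtr[keep, , drop = FALSE]
    ytr <- ytr[keep]
  }
  ls <- length_scales %||% rep(1, ncol(Xtr))
  abort_if(length(ls) != ncol(Xtr) || any(ls <= 0), "bad length scales")
  As <- sweep(Xtr, 2L, ls, "/")
  Bs <- sweep(Xte, 2L, ls, "/")
  kfun <- function(A, B) {
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
    signal_var * exp(-0.5 * pmax(d2, 0))
  }
  K <- kfun(As, As)
  mu <- mean(ytr)
  alpha_vec <- tryCatch(
    solve(K + diag(noise_var, nrow(K)), ytr - mu),
    error = function(e) solve(K + diag(noise_var + 1e-8, nrow(K)), ytr - mu)
  )
  pred_scaled <- mu + as.numeric(kfun(Bs, As) %*% alpha_vec)
  structure(list(
    anchors = test_windows$anchors,
    y_true = test_windows$y_mgdl[, f, drop = FALSE],
    y_pred = matrix(unscale_values(test_windows$scaler, pred_scaled, "cgm"), ncol = 1),
    patient_id = test_windows$patient_id, f = f, steps = f
  ), class = "forecast_batch")
}

#' ARX model orders
#'
#' @param na autoregressive order (glucose lags).
#' @param nb exogenous orders for basal, bolus and meal inputs.
#' @param nk exogenous delays for the same inputs (0 = current value enters).
#' @return an `arx_config`.
#' @export
arx_config <- function(na = 6L, nb = c(36L, 36L, 36L), nk = c(0L, 0L, 0L)) {
  abort_if(na < 1, "na must be >= 1")
  abort_if(length(nb) != 3 || any(nb < 1), "nb must be three orders >= 1")
  abort_if(length(nk) != 3 || any(nk < 0), "nk must be three delays >= 0")
  structure(list(na = as.integer(na), nb = as.integer(nb), nk = as.integer(nk)),
            class = "arx_config")
}

ARX_EXOG <- c("basal", "bolus", "carbs")

#' Fit an ARX model by least squares
#'
#' One-step regression of glucose on `na` of its own lags and `nb[u]` lagged
#' values (delay `nk[u]`) of each exogenous input -- basal rate, bolus and
#' carbohydrate intake -- plus an intercept, pooled over the training
#' segments.
#'
#' @param train_segments list of gap-free `cgm_segment` objects.
#' @param config an [arx_config()].
#' @return an `arx_model` with the coefficient vector and orders.
#' @export
arx_fit <- function(train_segments, config = arx_config()) {
  abort_if(length(train_segments) == 0, "no training segments")
  na <- config$na; nb <- config$nb; nk <- config$nk
  burn <- max(na, max(nb + nk - 1L))
  rows <- list(); targets <- list()
  for (seg in train_segments) {
    L <- length(seg$cgm)
    if (L <= burn) next
    t_idx <- (burn + 1L):L
    reg <- matrix(0, length(t_idx), na + sum(nb))
    col <- 1L
    for (i in seq_len(na)) {
      reg[, col] <- seg$cgm[t_idx - i]
      col <- col + 1L
    }
    for (u in 1:3) {
      x <- seg[[ARX_EXOG[u]]]
      for (j in seq_len(nb[u]) - 1L) {
        reg[, col] <- x[t_idx - nk[u] - j]
        col <- col + 1L
      }
    }
    rows[[length(rows) + 1L]] <- reg
    targets[[length(targets) + 1L]] <- seg$cgm[t_idx]
  }
  abort_if(length(rows) == 0, "segments too short for the requested orders")
  X <- cbind(1, do.call(rbind, rows))
  y <- unlist(targets)
  fit <- stats::lm.fit(X, y)
  coefs <- fit$coefficients
  if (anyNA(coefs)) {
    warning("rank-deficient ARX design; falling back to a tiny ridge penalty")
    XtX <- crossprod(X)
    coefs <- solve(XtX + diag(1e-9 * mean(diag(XtX)), ncol(X)), crossprod(X, y))[, 1]
  }
  abort_if(any(!is.finite(coefs)), "ARX fit produced non-finite coefficients")
  structure(list(coef = as.numeric(coefs), config = config), class = "arx_model")
}

#' Multi-step ARX forecast by recursion
#'
#' Iterates the fitted one-step model over the horizon, feeding predictions
#' back as glucose lags while exogenous inputs are taken at their observed
#' values (pump and meal records are known over the horizon).
#'
#' @param model an [arx_fit()] result.
#' @param windows `sample_windows` carrying their source segments.
#' @param f horizon steps (defaults to the windows' horizon).
#' @return a `forecast_batch` over steps `1..f`, in mg/dL.
#' @export
arx_forecast <- function(model, windows, f = windows$f) {
  cfgo <- model$config
  na <- cfgo$na; nb <- cfgo$nb; nk <- cfgo$nk
  segs <- if (!is.null(windows$segment_of)) windows$segment else list(windows$segment)
  seg_of <- windows$segment_of %||% rep(1L, n_windows(windows))
  n <- n_windows(windows)
  y_pred <- matrix(NA_real_, n, f)
  for (w in seq_len(n)) {
    seg <- segs[[seg_of[w]]]
    t0 <- windows$anchors[w]
    abort_if(t0 < na, "anchor too early for the AR order")
    bg <- seg$cgm[(t0 - na + 1L):t0] # oldest..newest
    for (j in seq_len(f)) {
      reg <- c(1, rev(bg)[seq_len(na)])
      for (u in 1:3) {
        x <- seg[[ARX_EXOG[u]]]
        lag_idx <- t0 + j - nk[u] - (seq_len(nb[u]) - 1L)
        vals <- ifelse(lag_idx >= 1, x[pmax(lag_idx, 1L)], 0)
        reg <- c(reg, vals)
      }
      pred <- sum(model$coef * reg)
      y_pred[w, j] <- pred
      bg <- c(bg[-1L], pred)
    }
  }
  structure(list(
    anchors = windows$anchors,
    y_true = windows$y_mgdl[, seq_len(f), drop = FALSE],
    y_pred = y_pred,
    patient_id = windows$patient_id, f = f, steps = seq_len(f)
  ), class = "forecast_batch")
}
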