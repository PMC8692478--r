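# Quantitative evaluation: RMSE/MAE/MAPE/NRMSE overall and per glycemic
# category, event detection rates (TPR/FPR per category), error grids, and
# Welch model comparison, plus per-patient and cohort reporting.

#' Forecast accuracy metrics
#'
#' `RMSE = sqrt(mean((yhat - y)^2))`, `MAE = mean(|yhat - y|)`,
#' `MAPE = mean(|yhat - y| / y) * 100`, `NRMSE = RMSE / (max(y) - min(y))`,
#' with the min/max taken over the evaluated true values. Per-category
#' sub-reports (membership decided by the true value) are `NULL` with a
#' `"No test samples"` note when a category is empty.
#'
#' @param y_true true glucose values, mg/dL (> 0; the sensor floor of
#'   20 mg/dL guarantees this for CGM-derived targets).
#' @param y_pred predicted glucose values, mg/dL.
#' @return a `metrics_report`: `overall` plus `hypo`, `normo`, `hyper`
#'   sub-reports, each holding `rmse`, `mae`, `mape`, `nrmse` and `n`.
#' @export
compute_metrics <- function(y_true, y_pred) {
  y_true <- as.numeric(y_true); y_pred <- as.numeric(y_pred)
  abort_if(length(y_true) != length(y_pred), "inputs must have equal length")
  abort_if(length(y_true) == 0, "empty input")
  one <- function(yt, yp) {
    if (length(yt) == 0) return(NULL)
    rmse <- sqrt(mean((yp - yt)^2))
    rng <- diff(range(yt))
    list(rmse = rmse,
         mae = mean(abs(yp - yt)),
         mape = mean(abs(yp - yt) / yt) * 100,
         nrmse = if (rng > 0) rmse / rng else NA_real_,
         n = length(yt))
  }
  cat_of <- glycemic_category(y_true)
  structure(list(
    overall = one(y_true, y_pred),
    hypo = one(y_true[cat_of == "hypo"], y_pred[cat_of == "hypo"]),
    normo = one(y_true[cat_of == "normo"], y_pred[cat_of == "normo"]),
    hyper = one(y_true[cat_of == "hyper"], y_pred[cat_of == "hyper"])
  ), class = "metrics_report")
}

#' Event detection rates for one glycemic category
#'
#' True positives are pairs where predicted and actual glucose both fall in
#' the category; positives are actuals in the category. `TPR = TP/P`,
#' `FPR = FP/N`; a rate with an empty denominator is reported as `NA`
#' (no test samples), never as 0.
#'
#' @param y_true,y_pred paired glucose values, mg/dL.
#' @param category `"hypo"` (< 70), `"hyper"` (>= 180) or `"normo"`.
#' @return list with `tp`, `p`, `fp`, `n`, `tpr`, `fpr`.
#' @export
category_rates <- function(y_true, y_pred, category = c("hypo", "hyper", "normo")) {
  category <- match.arg(category)
  abort_if(length(y_true) != length(y_pred), "inputs must have equal length")
  in_cat <- function(x) glycemic_category(x) == category
  act <- in_cat(y_true)
  prd <- in_cat(y_pred)
  tp <- sum(act & prd); p <- sum(act)
  fp <- sum(!act & prd); n <- sum(!act)
  list(tp = tp, p = p, fp = fp, n = n,
       tpr = if (p > 0) tp / p else NA_real_,
       fpr = if (n > 0) fp / n else NA_real_)
}

#' Welch two-sample comparison of per-patient errors
#'
#' Two-sample t-test with unequal variances on per-patient metric values of
#' two models.
#'
#' @param errors_a,errors_b numeric vectors (>= 2 values each).
#' @return list with `statistic`, `df` and two-sided `p_value`.
#' @export
compare_models <- function(errors_a, errors_b) {
  abort_if(length(errors_a) < 2 || length(errors_b) < 2,
           "need at least 2 values per group")
  tt <- stats::t.test(errors_a, errors_b, var.equal = FALSE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value)
}

#' Extract one horizon step from a forecast batch
#'
#' @param batch a `forecast_batch`.
#' @param horizon_step which step ahead to pull (e.g. 6 for 30 minutes).
#' @return list with paired `y_true` and `y_pred` vectors, mg/dL.
#' @export
forecast_step <- function(batch, horizon_step) {
  steps <- batch$steps %||% seq_len(ncol(batch$y_pred))
  j <- match(horizon_step, steps)
  abort_if(is.na(j), sprintf("horizon step %d not present in the forecasts",
                             horizon_step))
  list(y_true = batch$y_true[, j], y_pred = batch$y_pred[, j])
}

#' Evaluate forecasts per patient and aggregate over the cohort
#'
#' For each patient's forecast batch, computes the accuracy metrics,
#' per-category detection rates and both error grids at the requested
#' horizon step, then aggregates metric means and sample (n-1) standard
#' deviations over patients.
#'
#' @param forecasts one `forecast_batch` or a list of them (one per patient).
#' @param horizon_step evaluation step (default: the final step, the
#'   prediction horizon).
#' @return an `evaluation_report`: `per_patient` (list) and `cohort`
#'   (data.frame of mean and sd per metric).
#' @export
evaluation_report <- function(forecasts, horizon_step = NULL) {
  if (inherits(forecasts, "forecast_batch")) forecasts <- list(forecasts)
  abort_if(length(forecasts) == 0, "no forecasts supplied")
  per <- lapply(forecasts, function(b) {
    hs <- horizon_step %||% b$f
    st <- forecast_step(b, hs)
    list(
      patient_id = b$patient_id,
      horizon_step = hs,
      metrics = compute_metrics(st$y_true, st$y_pred),
      rates = list(hypo = category_rates(st$y_true, st$y_pred, "hypo"),
                   hyper = category_rates(st$y_true, st$y_pred, "hyper"),
                   normo = category_rates(st$y_true, st$y_pred, "normo")),
      clarke = clarke_grid(st$y_true, st$y_pred),
      parkes = parkes_grid(st$y_true, st$y_pred)
    )
  })
  pull <- function(fn) vapply(per, fn, 0)
  vals <- list(
    rmse = pull(function(x) x$metrics$overall$rmse),
    mae = pull(function(x) x$metrics$overall$mae),
    mape = pull(function(x) x$metrics$overall$mape),
    nrmse = pull(function(x) x$metrics$overall$nrmse),
    clarke_zone_a_pct = pull(function(x) x$clarke$zone_percent[1]),
    parkes_zone_a_pct = pull(function(x) x$parkes$zone_percent[1])
  )
  cohort <- data.frame(
    metric = names(vals),
    mean = vapply(vals, mean, 0),
    sd = vapply(vals, function(v) if (length(v) > 1) sd(v) else NA_real_, 0),
    row.names = NULL
  )
  structure(list(per_patient = per, cohort = cohort,
                 n_patients = length(per)), class = "evaluation_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  fmt <- function(nm, m) {
    if (is.null(m)) {
      cat(sprintf("  %-7s No test samples\n", nm))
    } else {
      cat(sprintf("  %-7s RMSE %6.2f  MAE %6.2f  MAPE %6.2f%%  NRMSE %s  (n=%d)\n",
                  nm, m$rmse, m$mae, m$mape,
                  ifelse(is.na(m$nrmse), "NA", sprintf("%.3f", m$nrmse)), m$n))
    }
  }
  cat("<metrics_report>\n")
  fmt("overall", x$overall); fmt("hypo", x$hypo)
  fmt("normo", x$normo); fmt("hyper", x$hyper)
  invisible(x)
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %d patient(s)\n", x$n_patients))
  df <- x$cohort
  df$mean <- round(df$mean, 3); df$sd <- round(df$sd, 3)
  print(df)
  invisible(x)
}

#' Write forecasts to the interchange CSV
#'
#' Long format: `patient_id, anchor_index, step, y_true_mg_dl, y_pred_mg_dl`.
#'
#' @param forecasts one `forecast_batch` or a list of them.
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_forecasts <- function(forecasts, path) {
  if (inherits(forecasts, "forecast_batch")) forecasts <- list(forecasts)
  rows <- lapply(forecasts, function(b) {
    steps <- b$steps %||% seq_len(ncol(b$y_pred))
    data.table::data.table(
      patient_id = b$patient_id,
      anchor_index = rep(b$anchors, times = length(steps)),
      step = rep(steps, each = length(b$anchors)),
      y_true_mg_dl = as.vector(b$y_true),
      y_pred_mg_dl = as.vector(b$y_pred)
    )
  })
  data.table::fwrite(data.table::rbindlist(rows), path)
  invisible(path)
}

#' Read forecasts written by [write_forecasts()]
#' @param path CSV path.
#' @return list of `forecast_batch` objects, one per patient.
#' @export
read_forecasts <- function(path) {
  dt <- as.data.frame(data.table::fread(path))
  lapply(split(dt, dt$patient_id), function(d) {
    steps <- sort(unique(d$step))
    anchors <- unique(d$anchor_index)
    d <- d[order(d$step, d$anchor_index), , drop = FALSE]
    n <- length(anchors)
    structure(list(
      anchors = anchors,
      y_true = matrix(d$y_true_mg_dl, n, length(steps)),
      y_pred = matrix(d$y_pred_mg_dl, n, length(steps)),
      patient_id = d$patient_id[1], f = max(steps), steps = steps
    ), class = "forecast_batch")
  })
}
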