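# End-to-end orchestration: simulate (or read) a cohort, preprocess, train
# one model per patient and horizon, forecast, run baselines, evaluate, and
# aggregate -- every stage seeded and logged so a config reproduces its
# reports exactly.

#' Experiment configuration
#'
#' @param out_dir experiment output directory.
#' @param n_patients number of virtual patients to simulate.
#' @param n_days days of data per patient.
#' @param seed global seed; all stage seeds derive from it.
#' @param horizons prediction horizons in 5-minute steps (e.g. `c(6, 12)` for
#'   30 and 60 minutes).
#' @param max_epochs training epoch cap per model.
#' @param train_stride anchor spacing of training windows, in 5-minute steps
#'   (test windows always use stride 1).
#' @param test_frac chronological tail fraction held out for testing.
#' @param baselines subset of `c("naive", "krr-linear", "krr-rbf", "gp",
#'   "arx")` to run alongside the model.
#' @param tcn a [tcn_config()].
#' @param data_dir read patient CSVs from here instead of simulating.
#' @param qc a [qc_thresholds()]; ineligible patients are skipped (quality
#'   verdicts are reported but not enforced).
#' @param gap_spec,calibration_spec artifact injections handed to
#'   [inject_artifacts()] per patient (for pipeline robustness runs).
#' @return a `run_config`.
#' @export
run_config <- function(out_dir, n_patients = 3L, n_days = 21L, seed = 1L,
                       horizons = 6L, max_epochs = 60L, train_stride = 2L,
                       test_frac = 0.2, baselines = "naive",
                       tcn = tcn_config(), data_dir = NULL,
                       qc = qc_thresholds(), gap_spec = list(),
                       calibration_spec = list()) {
  abort_if(any(horizons < 1), "horizons must be positive step counts")
  known <- c("naive", "krr-linear", "krr-rbf", "gp", "arx")
  abort_if(!all(baselines %in% known),
           paste0("baselines must be among: ", paste(known, collapse = ", ")))
  structure(list(
    out_dir = out_dir, n_patients = as.integer(n_patients),
    n_days = as.integer(n_days), seed = as.integer(seed),
    horizons = as.integer(horizons), max_epochs = as.integer(max_epochs),
    train_stride = as.integer(train_stride), test_frac = test_frac,
    baselines = baselines, tcn = tcn, data_dir = data_dir, qc = qc,
    gap_spec = gap_spec, calibration_spec = calibration_spec
  ), class = "run_config")
}

# Preprocess one series into scaled train/test windows for one horizon.
prepare_patient <- function(series, f, train_stride, test_frac,
                            p = c(36L, 6L, 36L, 36L)) {
  filled <- fill_short_gaps(series)
  segments <- split_and_reject(filled)
  abort_if(length(segments) == 0, paste0("no usable segments for ", series$patient_id))
  sp <- split_segments(segments, test_frac)
  abort_if(length(sp$train) == 0 || length(sp$test) == 0,
           paste0("degenerate train/test split for ", series$patient_id))
  scaler <- fit_scaler(sp$train)
  mk <- function(segs, stride) {
    ws <- lapply(segs, make_windows, p = p, f = f, stride = stride)
    ws <- ws[vapply(ws, n_windows, 0L) > 0]
    abort_if(length(ws) == 0, "no windows after preprocessing")
    scale_windows(bind_windows(ws), scaler)
  }
  list(train = mk(sp$train, train_stride), test = mk(sp$test, 1L),
       scaler = scaler, segments = sp,
       fill_report = attr(filled, "fill_report"),
       segment_report = attr(segments, "segment_report"))
}

run_baselines <- function(which, prep, f) {
  out <- list()
  for (b in which) {
    out[[b]] <- switch(b,
      "naive" = naive_forecast(prep$test),
      "krr-linear" = krr_fit_predict(prep$train, prep$test, kernel = "linear"),
      "krr-rbf" = krr_fit_predict(prep$train, prep$test, kernel = "rbf"),
      "gp" = gp_fit_predict(prep$train, prep$test),
      "arx" = arx_forecast(arx_fit(prep$segments$train), prep$test, f)
    )
  }
  out
}

#' Run a full experiment
#'
#' Simulates (or loads) the cohort, preprocesses each record, trains one
#' model per patient and horizon, forecasts the held-out tail, runs the
#' requested baselines, and writes per-patient checkpoints, forecasts,
#' metrics and error-grid plots plus a cohort summary under `out_dir`.
#' Re-running with the same config reproduces every report.
#'
#' @param config a [run_config()].
#' @return invisibly, a summary list: per-horizon evaluation reports for the
#'   model and each baseline, plus artifact paths.
#' @export
run_experiment <- function(config) {
  abort_if(!inherits(config, "run_config"), "config must be a run_config")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_plain <- rapply(unclass(config), identity, how = "replace")
  yaml::write_yaml(cfg_plain, file.path(config$out_dir, "config.yaml"))
  # the run id identifies the scientific configuration, not where it is stored
  run_id <- rlang::hash(cfg_plain[setdiff(names(cfg_plain), c("out_dir", "data_dir"))])

  series_list <- if (is.null(config$data_dir)) {
    cohort <- sample_cohort(config$n_patients, config$seed)
    data_dir <- file.path(config$out_dir, "data")
    lapply(cohort, function(pp) {
      s <- simulate_patient(pp, config$n_days)
      if (length(config$gap_spec) || length(config$calibration_spec)) {
        s <- inject_artifacts(s, config$gap_spec, config$calibration_spec)
      }
      write_patient(s, data_dir)
      s
    })
  } else {
    paths <- list.files(config$data_dir, pattern = "\\.csv$", full.names = TRUE)
    paths <- paths[!grepl("_truth\\.csv$", paths)]
    abort_if(length(paths) == 0, "no patient CSVs in data_dir")
    lapply(paths, read_patient)
  }

  qc_reports <- lapply(series_list, apply_qc, thresholds = config$qc)
  eligible <- vapply(qc_reports, `[[`, TRUE, "eligible")
  message(sprintf("[%s] %d/%d patients eligible", run_id,
                  sum(eligible), length(eligible)))
  series_list <- series_list[eligible]

  summary <- list(run_id = run_id, qc = qc_reports, horizons = list())
  for (f in config$horizons) {
    t_h <- Sys.time()
    model_batches <- list()
    baseline_batches <- list()
    for (i in seq_along(series_list)) {
      s <- series_list[[i]]
      prep <- prepare_patient(s, f, config$train_stride, config$test_frac)
      mcfg <- model_config(f = f, tcn = config$tcn,
                           max_epochs = config$max_epochs,
                           seed = config$seed * 1000L + i * 10L + f)
      model <- build_model(mcfg)
      model <- train_model(model, prep$train)
      fc <- predict(model, prep$test)
      pdir <- file.path(config$out_dir, sprintf("h%02d", f), s$patient_id)
      dir.create(pdir, recursive = TRUE, showWarnings = FALSE)
      save_checkpoint(model, file.path(pdir, "model.ckpt.json"))
      write_forecasts(fc, file.path(pdir, "forecasts.csv"))
      bl <- run_baselines(config$baselines, prep, f)
      for (b in names(bl)) {
        write_forecasts(bl[[b]], file.path(pdir, paste0("forecasts_", b, ".csv")))
        baseline_batches[[b]][[s$patient_id]] <- bl[[b]]
      }
      st <- forecast_step(fc, f)
      for (g in c("clarke", "parkes")) {
        ggplot2::ggsave(file.path(pdir, paste0(g, "_grid.png")),
                        plot_error_grid(st$y_true, st$y_pred, g),
                        width = 5, height = 5, dpi = 120)
      }
      model_batches[[s$patient_id]] <- fc
      message(sprintf("[%s] h=%d %s: %d train / %d test windows, %d epochs",
                      run_id, f, s$patient_id, n_windows(prep$train),
                      n_windows(prep$test), nrow(model$history)))
    }
    reports <- list(model = evaluation_report(model_batches, f))
    for (b in names(baseline_batches)) {
      reports[[b]] <- evaluation_report(baseline_batches[[b]], f)
    }
    cohort <- lapply(reports, function(r) r$cohort)
    jsonlite::write_json(
      list(run_id = run_id, seed = config$seed, horizon = f, cohort = cohort),
      file.path(config$out_dir, sprintf("metrics_h%02d.json", f)),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
    summary$horizons[[as.character(f)]] <- reports
    message(sprintf("[%s] horizon %d done in %.1f min", run_id, f,
                    as.numeric(Sys.time() - t_h, units = "mins")))
  }
  invisible(summary)
}

#' Component / history ablation study
#'
#' Trains one model per variant -- a component on/off mask and optionally
#' overridden history lengths -- on identical data and seeds, and tabulates
#' test RMSE at the final horizon step.
#'
#' @param config a [run_config()] (first horizon is used).
#' @param variants list of variants; each is a list with `mask` (4 logicals)
#'   and optionally `p` (history lengths) and `label`.
#' @return data.frame with one row per variant.
#' @export
ablation_run <- function(config, variants) {
  abort_if(length(variants) == 0, "variants must be a non-empty list")
  for (v in variants) {
    abort_if(is.null(v$mask) || length(v$mask) != 4, "each variant needs a 4-flag mask")
    abort_if(!any(v$mask), "all-off component mask is invalid")
  }
  f <- config$horizons[1]
  cohort <- sample_cohort(config$n_patients, config$seed)
  rows <- list()
  for (v_i in seq_along(variants)) {
    v <- variants[[v_i]]
    p <- as.integer(v$p %||% c(36L, 6L, 36L, 36L))
    rmses <- numeric(0)
    for (i in seq_along(cohort)) {
      s <- simulate_patient(cohort[[i]], config$n_days)
      prep <- prepare_patient(s, f, config$train_stride, config$test_frac, p = p)
      mcfg <- model_config(p = p, f = f, tcn = config$tcn,
                           max_epochs = config$max_epochs,
                           component_mask = v$mask,
                           seed = config$seed * 1000L + i * 10L + f)
      model <- train_model(build_model(mcfg), prep$train)
      st <- forecast_step(predict(model, prep$test), f)
      rmses <- c(rmses, compute_metrics(st$y_true, st$y_pred)$overall$rmse)
    }
    rows[[v_i]] <- data.frame(
      variant = v$label %||% paste0("mask=", paste(as.integer(v$mask), collapse = "")),
      p1 = p[1], p2 = p[2], p3 = p[3], p4 = p[4],
      mean_rmse = mean(rmses), sd_rmse = if (length(rmses) > 1) sd(rmses) else NA_real_
    )
  }
  do.call(rbind, rows)
}
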