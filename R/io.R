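# CSV interchange for per-patient records. One row per 5-minute grid point:
# timestamp_iso8601, cgm_mg_dl, basal_u_per_hr, bolus_u, carbs_g,
# calibration_mg_dl (empty = absent), plus a companion *_meta.json and, for
# simulated patients, a *_truth.csv with the noise-free glucose trace.

TS_FORMAT <- "%Y-%m-%dT%H:%M:%SZ"

#' Write a patient series to CSV (+ metadata JSON, + truth trace)
#'
#' @param series a `patient_series`.
#' @param dir output directory (created if needed).
#' @return invisibly, the path of the main CSV file.
#' @export
write_patient <- function(series, dir) {
  abort_if(!inherits(series, "patient_series"), "series must be a patient_series")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(series$cgm)
  cal <- rep(NA_real_, n)
  if (nrow(series$calibrations)) cal[series$calibrations$index] <- series$calibrations$value
  dt <- data.table::data.table(
    timestamp_iso8601 = format(series$timestamps, TS_FORMAT, tz = "UTC"),
    cgm_mg_dl = series$cgm,
    basal_u_per_hr = series$basal,
    bolus_u = series$bolus,
    carbs_g = series$carbs,
    calibration_mg_dl = cal
  )
  path <- file.path(dir, paste0(series$patient_id, ".csv"))
  data.table::fwrite(dt, path, na = "")
  meta <- c(list(patient_id = series$patient_id), series$metadata,
            list(seed = if (!is.null(series$params)) series$params$seed else NA))
  jsonlite::write_json(meta, file.path(dir, paste0(series$patient_id, "_meta.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(series$truth)) {
    data.table::fwrite(
      data.table::data.table(timestamp_iso8601 = dt$timestamp_iso8601,
                             bg_mg_dl = series$truth),
      file.path(dir, paste0(series$patient_id, "_truth.csv"))
    )
  }
  invisible(path)
}

#' Read and validate a patient series from CSV
#'
#' Enforces the grid contract: strictly increasing timestamps with exact
#' 5-minute spacing, CGM (where present) within the 20-600 mg/dL sensor
#' range, non-negative doses and carbohydrates. Violations raise a schema
#' error naming the first offending row.
#'
#' @param path path to a patient CSV written by [write_patient()].
#' @return a `patient_series`.
#' @export
read_patient <- function(path) {
  abort_if(!file.exists(path), paste0("no such file: ", path))
  dt <- data.table::fread(path, na.strings = "", colClasses = list(character = 1))
  req <- c("timestamp_iso8601", "cgm_mg_dl", "basal_u_per_hr", "bolus_u",
           "carbs_g", "calibration_mg_dl")
  missing_cols <- setdiff(req, names(dt))
  abort_if(length(missing_cols) > 0,
           paste0("schema error: missing columns ", paste(missing_cols, collapse = ", ")))
  ts <- as.POSIXct(dt$timestamp_iso8601, format = TS_FORMAT, tz = "UTC")
  bad <- which(is.na(ts))
  abort_if(length(bad) > 0, sprintf("schema error: unparseable timestamp at row %d", bad[1]))
  d <- diff(as.numeric(ts))
  bad <- which(d <= 0)
  abort_if(length(bad) > 0,
           sprintf("schema error: non-monotone timestamps at row %d", bad[1] + 1L))
  bad <- which(d != STEP_MIN * 60)
  abort_if(length(bad) > 0,
           sprintf("schema error: spacing is not 5 minutes at row %d", bad[1] + 1L))
  check_nonneg <- function(x, nm) {
    bad <- which(!is.na(x) & x < 0)
    abort_if(length(bad) > 0, sprintf("schema error: negative %s at row %d", nm, bad[1]))
  }
  check_nonneg(dt$basal_u_per_hr, "basal rate")
  check_nonneg(dt$bolus_u, "bolus")
  check_nonneg(dt$carbs_g, "carbs")
  bad <- which(!is.na(dt$cgm_mg_dl) &
                 (dt$cgm_mg_dl < SENSOR_MIN_MGDL | dt$cgm_mg_dl > SENSOR_MAX_MGDL))
  abort_if(length(bad) > 0,
           sprintf("schema error: CGM outside sensor range at row %d", bad[1]))

  cal_idx <- which(!is.na(dt$calibration_mg_dl))
  pid <- sub("\\.csv$", "", basename(path))
  meta_path <- file.path(dirname(path), paste0(pid, "_meta.json"))
  metadata <- NULL
  if (file.exists(meta_path)) {
    m <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    pid <- m$patient_id %||% pid
    metadata <- m[intersect(names(m), c("age", "diabetes_type", "years_since_diagnosis"))]
  }
  truth_path <- file.path(dirname(path), paste0(pid, "_truth.csv"))
  truth <- if (file.exists(truth_path)) data.table::fread(truth_path)$bg_mg_dl else NULL

  structure(list(
    patient_id = pid,
    timestamps = ts,
    cgm = as.numeric(dt$cgm_mg_dl),
    basal = as.numeric(ifelse(is.na(dt$basal_u_per_hr), 0, dt$basal_u_per_hr)),
    bolus = as.numeric(ifelse(is.na(dt$bolus_u), 0, dt$bolus_u)),
    carbs = as.numeric(ifelse(is.na(dt$carbs_g), 0, dt$carbs_g)),
    calibrations = data.frame(index = cal_idx,
                              value = as.numeric(dt$calibration_mg_dl[cal_idx])),
    metadata = metadata, truth = truth, params = NULL
  ), class = "patient_series")
}
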