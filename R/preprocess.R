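# Preprocessing: the cleaning rules applied to raw CGM records before
# windowing. Short sensor dropouts are interpolated, long ones split the
# record into contiguous segments, segments containing a discordant
# fingerstick calibration are dismissed, and surviving segments are min-max
# scaled and cut into multi-view training windows.

#' Fill short CGM gaps by shape-preserving piecewise-cubic interpolation
#'
#' Runs of up to `max_gap_steps` consecutive missing CGM values (30 minutes
#' at the 5-minute sampling interval) are interpolated through the
#' surrounding non-missing readings with a monotone piecewise-cubic Hermite
#' spline, which cannot overshoot into spurious hypo- or hyperglycemia.
#' Longer runs, and runs touching the series boundary, are left untouched.
#' Non-CGM channels are never modified.
#'
#' @param series a `patient_series`.
#' @param max_gap_steps largest fillable run length, in 5-minute steps.
#' @return the series with fillable gaps interpolated; a `fill_report`
#'   attribute lists every missing run and whether it was filled.
#' @export
fill_short_gaps <- function(series, max_gap_steps = 6L) {
  abort_if(!inherits(series, "patient_series"), "series must be a patient_series")
  cgm <- series$cgm
  r <- rle(is.na(cgm))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  report <- data.frame(start = integer(0), length = integer(0), filled = logical(0))
  known <- which(!is.na(cgm))
  for (k in which(r$values)) {
    s <- starts[k]; e <- ends[k]; len <- e - s + 1L
    interior <- s > 1L && e < length(cgm)
    fill <- len <= max_gap_steps && interior
    if (fill) {
      cgm[s:e] <- pracma::pchip(known, series$cgm[known], s:e)
    }
    report <- rbind(report, data.frame(start = s, length = len, filled = fill))
  }
  out <- series
  out$cgm <- cgm
  attr(out, "fill_report") <- report
  out
}

#' Split a series at remaining gaps and dismiss calibration-discordant segments
#'
#' Missing runs that survived [fill_short_gaps()] split the record into
#' gap-free contiguous segments. Any segment containing a fingerstick
#' calibration that differs from the simultaneous CGM reading by more than
#' `calib_discrepancy` is dismissed, since such a calibration produces a step
#' discontinuity that does not reflect the true glucose time course.
#'
#' @param series a `patient_series` (after gap filling).
#' @param calib_discrepancy rejection threshold, mg/dL; the segment is kept
#'   when the absolute difference is exactly at the threshold.
#' @return ordered list of `cgm_segment` objects; a `segment_report`
#'   attribute records every candidate segment and its fate.
#' @export
split_and_reject <- function(series, calib_discrepancy = 50) {
  abort_if(!inherits(series, "patient_series"), "series must be a patient_series")
  n <- length(series$cgm)
  r <- rle(is.na(series$cgm))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  report <- data.frame(start = integer(0), end = integer(0), dismissed = logical(0))
  for (k in which(!r$values)) {
    s <- starts[k]; e <- ends[k]
    seg <- extract_segment(series, s, e)
    drop <- FALSE
    if (nrow(seg$calibrations)) {
      simul <- seg$cgm[seg$calibrations$index]
      drop <- any(!is.na(simul) &
                    abs(seg$calibrations$value - simul) > calib_discrepancy)
    }
    report <- rbind(report, data.frame(start = s, end = e, dismissed = drop))
    if (!drop) out[[length(out) + 1L]] <- seg
  }
  attr(out, "segment_report") <- report
  out
}

# Cut a gap-free sub-range [from, to] (parent indices) out of a series.
extract_segment <- function(series, from, to) {
  idx <- from:to
  cal <- series$calibrations
  cal <- cal[cal$index >= from & cal$index <= to, , drop = FALSE]
  cal$index <- cal$index - from + 1L
  structure(list(
    parent_id = series$patient_id,
    start_index = as.integer(from),
    timestamps = series$timestamps[idx],
    cgm = series$cgm[idx],
    basal = series$basal[idx],
    bolus = series$bolus[idx],
    carbs = series$carbs[idx],
    calibrations = cal,
    metadata = series$metadata
  ), class = "cgm_segment")
}

#' Eligibility and data-quality thresholds
#'
#' Eligibility mirrors the clinical inclusion criteria (confirmed type-1
#' diabetes, age over 18 years, more than 2 years since diagnosis); the
#' quality trio selects records whose meal annotations are likely reliable:
#' time in range (70-180 mg/dL) above 70%, more than 3.5 logged meals per
#' day, and under 2% of time in hypoglycemia.
#'
#' @param min_age years (exclusive bound).
#' @param min_years_diagnosed years (exclusive bound).
#' @param min_time_in_range_frac fraction of readings in 70-180 mg/dL.
#' @param min_meals_per_day logged meal inputs per day.
#' @param max_time_hypo_frac fraction of readings below 70 mg/dL.
#' @return a `qc_thresholds` object.
#' @export
qc_thresholds <- function(min_age = 18, min_years_diagnosed = 2,
                          min_time_in_range_frac = 0.70,
                          min_meals_per_day = 3.5,
                          max_time_hypo_frac = 0.02) {
  fr <- c(min_time_in_range_frac, max_time_hypo_frac)
  abort_if(any(fr < 0 | fr > 1), "fractions must lie in [0, 1]")
  structure(list(min_age = min_age, min_years_diagnosed = min_years_diagnosed,
                 min_time_in_range_frac = min_time_in_range_frac,
                 min_meals_per_day = min_meals_per_day,
                 max_time_hypo_frac = max_time_hypo_frac),
            class = "qc_thresholds")
}

#' Apply eligibility and quality criteria to a patient record
#'
#' @param series a `patient_series` with metadata.
#' @param thresholds a [qc_thresholds()].
#' @return list with per-criterion pass flags (`ec1` type-1 diabetes, `ec2`
#'   age, `ec3` diabetes duration; `q_tir`, `q_meals`, `q_hypo`), the
#'   computed statistics, and overall `eligible` / `quality_ok` verdicts.
#' @export
apply_qc <- function(series, thresholds = qc_thresholds()) {
  abort_if(!inherits(series, "patient_series"), "series must be a patient_series")
  m <- series$metadata
  for (f in c("age", "diabetes_type", "years_since_diagnosis")) {
    abort_if(is.null(m[[f]]), paste0("qc error: missing metadata field ", f))
  }
  cgm <- series$cgm[!is.na(series$cgm)]
  abort_if(length(cgm) == 0, "qc error: no CGM readings")
  days <- length(series$cgm) * STEP_MIN / 1440
  stats <- list(
    time_in_range_frac = mean(cgm >= HYPO_MGDL & cgm < HYPER_MGDL),
    meals_per_day = sum(series$carbs > 0) / days,
    time_hypo_frac = mean(cgm < HYPO_MGDL)
  )
  checks <- list(
    ec1 = identical(m$diabetes_type, "type1"),
    ec2 = m$age > thresholds$min_age,
    ec3 = m$years_since_diagnosis > thresholds$min_years_diagnosed,
    q_tir = stats$time_in_range_frac > thresholds$min_time_in_range_frac,
    q_meals = stats$meals_per_day > thresholds$min_meals_per_day,
    q_hypo = stats$time_hypo_frac < thresholds$max_time_hypo_frac
  )
  c(checks, stats,
    list(eligible = checks$ec1 && checks$ec2 && checks$ec3,
         quality_ok = checks$q_tir && checks$q_meals && checks$q_hypo))
}

#' Fit a per-variable min-max scaler on training segments
#'
#' Maps each variable's training minimum to 0 and maximum to 1. The scaler is
#' fitted on training data only; test values outside the training range are
#' scaled beyond `[0, 1]` without clipping.
#'
#' @param train_segments list of `cgm_segment` objects (training split only).
#' @return a `minmax_scaler` with `(min, max)` per variable.
#' @export
fit_scaler <- function(train_segments) {
  abort_if(length(train_segments) == 0, "no training segments to fit on")
  vars <- c("cgm", "basal", "bolus", "carbs")
  rng <- lapply(vars, function(v) {
    x <- unlist(lapply(train_segments, `[[`, v))
    r <- range(x, na.rm = TRUE)
    abort_if(!is.finite(diff(r)) || diff(r) <= 0,
             paste0("cannot fit scaler: variable '", v, "' is constant"))
    r
  })
  names(rng) <- vars
  structure(rng, class = "minmax_scaler")
}

#' Scale values to the unit interval of the fitted training range
#' @param scaler a [fit_scaler()] result.
#' @param x numeric values in native units.
#' @param var one of `"cgm"`, `"basal"`, `"bolus"`, `"carbs"`.
#' @return scaled values.
#' @export
scale_values <- function(scaler, x, var) {
  r <- scaler[[var]]
  abort_if(is.null(r), paste0("unknown variable ", var))
  (x - r[1]) / (r[2] - r[1])
}

#' Invert the min-max scaling back to native units
#' @inheritParams scale_values
#' @param x scaled values.
#' @export
unscale_values <- function(scaler, x, var) {
  r <- scaler[[var]]
  abort_if(is.null(r), paste0("unknown variable ", var))
  x * (r[2] - r[1]) + r[1]
}

#' Cut multi-view forecasting windows from a gap-free segment
#'
#' Each window holds the four component input views ending at a shared
#' anchor `t` -- (BG, meal) over `p1` steps, recent BG over `p2` steps,
#' (BG, basal) over `p3`, (BG, bolus) over `p4`, each view being exactly `p`
#' samples ending at and including `t` -- and the target sequence
#' `BG[t+1 .. t+f]`. Anchors run from `max(p)` to `L - f`; with stride 1 a
#' segment of length `L` yields `L - max(p) - f + 1` windows (none when
#' shorter).
#'
#' @param segment a `cgm_segment`.
#' @param p integer vector `c(p1, p2, p3, p4)` of history lengths, in 5-min
#'   steps.
#' @param f prediction horizon in 5-min steps.
#' @param stride anchor step between consecutive windows.
#' @return a `sample_windows` object (columnar: arrays `x1..x4`, matrix `y`),
#'   carrying the anchor glucose and the source segment for baseline use.
#' @export
make_windows <- function(segment, p = c(36L, 6L, 36L, 36L), f = 6L, stride = 1L) {
  abort_if(!inherits(segment, "cgm_segment"), "segment must be a cgm_segment")
  abort_if(length(p) != 4 || any(p < 1), "p must be four positive history lengths")
  abort_if(f < 1, "horizon f must be >= 1")
  abort_if(anyNA(segment$cgm), "segment must be gap-free")
  L <- length(segment$cgm)
  p_max <- max(p)
  anchors <- if (L >= p_max + f) seq.int(p_max, L - f, by = stride) else integer(0)
  n <- length(anchors)
  view <- function(chans, steps) {
    a <- array(0, dim = c(n, steps, length(chans)))
    if (n > 0) {
      idx <- outer(anchors, (steps - 1L):0, "-") # n x steps, ending at t
      for (j in seq_along(chans)) {
        a[, , j] <- segment[[chans[j]]][idx]
      }
    }
    a
  }
  y <- matrix(0, n, f)
  if (n > 0) y[] <- segment$cgm[outer(anchors, 1:f, "+")]
  structure(list(
    x1 = view(c("cgm", "carbs"), p[1]),
    x2 = view("cgm", p[2]),
    x3 = view(c("cgm", "basal"), p[3]),
    x4 = view(c("cgm", "bolus"), p[4]),
    y = y,
    anchors = anchors,
    anchor_bg = if (n > 0) segment$cgm[anchors] else numeric(0),
    p = as.integer(p), f = as.integer(f),
    patient_id = segment$parent_id,
    segment_start = segment$start_index,
    segment = segment,
    scaled = FALSE, scaler = NULL, y_mgdl = y
  ), class = "sample_windows")
}

#' Number of windows in a `sample_windows` object
#' @param windows a `sample_windows`.
#' @export
n_windows <- function(windows) length(windows$anchors)

#' Concatenate window sets (e.g. across a patient's segments)
#' @param ... `sample_windows` objects with identical `p`, `f` and scaling.
#' @return one pooled `sample_windows`; the `segment` field is a list of the
#'   source segments with per-window provenance in `segment_of`.
#' @export
bind_windows <- function(...) {
  ws <- list(...)
  if (length(ws) == 1 && is.list(ws[[1]]) && !inherits(ws[[1]], "sample_windows")) {
    ws <- ws[[1]]
  }
  abort_if(length(ws) == 0, "nothing to bind")
  w0 <- ws[[1]]
  for (w in ws[-1]) {
    abort_if(!identical(w$p, w0$p) || !identical(w$f, w0$f) ||
               !identical(w$scaled, w0$scaled),
             "window sets differ in p, f or scaling")
  }
  bind3 <- function(field) {
    arrs <- lapply(ws, `[[`, field)
    out <- array(0, dim = c(sum(vapply(arrs, function(a) dim(a)[1], 0)),
                            dim(arrs[[1]])[2], dim(arrs[[1]])[3]))
    at <- 1L
    for (a in arrs) {
      if (dim(a)[1] > 0) out[at:(at + dim(a)[1] - 1L), , ] <- a
      at <- at + dim(a)[1]
    }
    out
  }
  out <- w0
  for (fld in c("x1", "x2", "x3", "x4")) out[[fld]] <- bind3(fld)
  out$y <- do.call(rbind, lapply(ws, `[[`, "y"))
  out$y_mgdl <- do.call(rbind, lapply(ws, `[[`, "y_mgdl"))
  out$anchors <- unlist(lapply(ws, `[[`, "anchors"))
  out$anchor_bg <- unlist(lapply(ws, `[[`, "anchor_bg"))
  out$segment <- lapply(ws, `[[`, "segment")
  out$segment_of <- rep(seq_along(ws), vapply(ws, n_windows, 0L))
  out
}

#' Scale a window set with a fitted scaler
#'
#' Applies the per-variable min-max transform to every input view and to the
#' target; the unscaled targets and anchor glucose are retained (`y_mgdl`,
#' `anchor_bg`) for loss weighting and evaluation.
#'
#' @param windows an unscaled `sample_windows`.
#' @param scaler a [fit_scaler()] result.
#' @return the scaled `sample_windows`.
#' @export
scale_windows <- function(windows, scaler) {
  abort_if(windows$scaled, "windows are already scaled")
  vars <- list(x1 = c("cgm", "carbs"), x2 = "cgm", x3 = c("cgm", "basal"),
               x4 = c("cgm", "bolus"))
  out <- windows
  for (fld in names(vars)) {
    for (j in seq_along(vars[[fld]])) {
      out[[fld]][, , j] <- scale_values(scaler, windows[[fld]][, , j], vars[[fld]][j])
    }
  }
  out$y <- scale_values(scaler, windows$y, "cgm")
  out$scaled <- TRUE
  out$scaler <- scaler
  out
}

#' Chronological train/test split of a patient's segments
#'
#' Splits at the parent-series index corresponding to the requested test
#' fraction of the overall record; a segment straddling the cut point is
#' divided in two, so no window ever mixes the eras.
#'
#' @param segments list of `cgm_segment` objects from one patient.
#' @param test_frac fraction of the record (by time) reserved for testing.
#' @return list with `train` and `test` segment lists.
#' @export
split_segments <- function(segments, test_frac = 0.2) {
  abort_if(length(segments) == 0, "no segments to split")
  ends <- vapply(segments, function(s) s$start_index + length(s$cgm) - 1L, 0L)
  cut <- as.integer(floor((1 - test_frac) * max(ends)))
  train <- list(); test <- list()
  for (s in segments) {
    s_end <- s$start_index + length(s$cgm) - 1L
    if (s_end <= cut) {
      train[[length(train) + 1L]] <- s
    } else if (s$start_index > cut) {
      test[[length(test) + 1L]] <- s
    } else {
      k <- cut - s$start_index + 1L
      tr <- extract_local(s, 1L, k)
      te <- extract_local(s, k + 1L, length(s$cgm))
      train[[length(train) + 1L]] <- tr
      test[[length(test) + 1L]] <- te
    }
  }
  list(train = train, test = test)
}

# Subset a segment by local indices, keeping parent bookkeeping consistent.
extract_local <- function(seg, from, to) {
  idx <- from:to
  cal <- seg$calibrations
  cal <- cal[cal$index >= from & cal$index <= to, , drop = FALSE]
  cal$index <- cal$index - from + 1L
  out <- seg
  out$start_index <- seg$start_index + from - 1L
  out$timestamps <- seg$timestamps[idx]
  out$cgm <- seg$cgm[idx]
  out$basal <- seg$basal[idx]
  out$bolus <- seg$bolus[idx]
  out$carbs <- seg$carbs[idx]
  out$calibrations <- cal
  out
}
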