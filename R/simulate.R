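# Virtual type-1-diabetes patients: a Bergman-minimal-model glucose-insulin
# core with a two-compartment gut, driven by a pump-style basal profile,
# carbohydrate meals and meal/correction boluses, observed through a CGM
# noise model. The generator exists so the whole forecasting pipeline can be
# exercised end-to-end on data with the statistical structure the model
# assumes: 5-minute sampling, 3-5 meals per day with boluses, circadian basal
# modulation, AR(1)-correlated sensor noise, and genuine hypo-/hyper-glycemic
# excursions.

#' Virtual patient parameters
#'
#' Physiological and sensor parameters of one simulated patient. Rate
#' constants are per minute; `insulin_sensitivity` converts plasma-insulin
#' excess (U/L) into extra fractional glucose clearance (1/min per U/L).
#'
#' @param basal_glucose fasting equilibrium glucose, mg/dL (80-160).
#' @param insulin_sensitivity steady-state gain from insulin excess to remote
#'   insulin action, 1/(U/L * min).
#' @param glucose_effectiveness insulin-independent fractional glucose
#'   clearance, 1/min.
#' @param insulin_action_rate rate constant of the remote insulin-action
#'   compartment, 1/min.
#' @param insulin_clearance plasma insulin elimination rate, 1/min.
#' @param carb_bioavailability fraction of ingested carbohydrate reaching
#'   plasma, in (0, 1].
#' @param gut_absorption_rate two-compartment gut transfer rate, 1/min.
#' @param body_weight kg; sets glucose (1.6 dL/kg) and insulin (0.12 L/kg)
#'   distribution volumes.
#' @param carb_ratio insulin-to-carb dosing ratio, g/U.
#' @param correction_factor expected glucose drop per unit insulin, mg/dL/U.
#' @param basal_rate_profile 24 hourly basal rates, U/h.
#' @param sensor_noise_sd CGM AR(1) innovation standard deviation, mg/dL.
#' @param sensor_ar_coeff CGM noise autocorrelation, in [0, 1).
#' @param seed integer seed driving meals, dosing errors and sensor noise.
#' @param patient_id identifier used in file names and reports.
#' @param metadata list with `age`, `diabetes_type`, `years_since_diagnosis`.
#' @return an object of class `virtual_patient_params`.
#' @export
virtual_patient_params <- function(basal_glucose = 120,
                                   insulin_sensitivity = 0.12,
                                   glucose_effectiveness = 0.013,
                                   insulin_action_rate = 0.03,
                                   insulin_clearance = 0.016,
                                   carb_bioavailability = 0.875,
                                   gut_absorption_rate = 0.035,
                                   body_weight = 75,
                                   carb_ratio = 12,
                                   correction_factor = 90,
                                   basal_rate_profile = rep(1, 24),
                                   sensor_noise_sd = 4,
                                   sensor_ar_coeff = 0.7,
                                   seed = 1L,
                                   patient_id = "vp001",
                                   metadata = list(age = 35, diabetes_type = "type1",
                                                   years_since_diagnosis = 10)) {
  p <- list(
    basal_glucose = basal_glucose, insulin_sensitivity = insulin_sensitivity,
    glucose_effectiveness = glucose_effectiveness,
    insulin_action_rate = insulin_action_rate,
    insulin_clearance = insulin_clearance,
    carb_bioavailability = carb_bioavailability,
    gut_absorption_rate = gut_absorption_rate, body_weight = body_weight,
    carb_ratio = carb_ratio, correction_factor = correction_factor,
    basal_rate_profile = basal_rate_profile, sensor_noise_sd = sensor_noise_sd,
    sensor_ar_coeff = sensor_ar_coeff, seed = as.integer(seed),
    patient_id = patient_id, metadata = metadata
  )
  rates <- c("insulin_sensitivity", "glucose_effectiveness",
             "insulin_action_rate", "insulin_clearance", "gut_absorption_rate")
  abort_if(any(unlist(p[rates]) <= 0), "all rate constants must be strictly positive")
  abort_if(basal_glucose < 80 || basal_glucose > 160,
           "basal_glucose must lie in [80, 160] mg/dL")
  abort_if(sensor_ar_coeff < 0 || sensor_ar_coeff >= 1,
           "sensor_ar_coeff must be in [0, 1)")
  abort_if(carb_bioavailability <= 0 || carb_bioavailability > 1,
           "carb_bioavailability must be in (0, 1]")
  abort_if(length(basal_rate_profile) != 24 || any(basal_rate_profile < 0),
           "basal_rate_profile must be 24 non-negative hourly rates")
  structure(p, class = "virtual_patient_params")
}

#' Draw a cohort of virtual patients
#'
#' Parameters are sampled from documented physiological ranges; the dosing
#' parameters (carb ratio, correction factor) are derived from each patient's
#' insulin kinetics so that boluses approximately cover meals, then perturbed,
#' which is what makes simulated traces visit hypo- and hyperglycemia.
#'
#' @param n_patients number of patients, `>= 1`.
#' @param seed integer seed; the draw is deterministic given the seed.
#' @return list of [virtual_patient_params()] objects.
#' @export
sample_cohort <- function(n_patients, seed = 1L) {
  abort_if(!is.numeric(n_patients) || n_patients < 1, "n_patients must be >= 1")
  n <- as.integer(n_patients)
  with_seed(seed, {
    seeds <- sample.int(.Machine$integer.max - 1L, n)
    lapply(seq_len(n), function(i) {
      si <- runif(1, 0.08, 0.16)
      ke <- runif(1, 0.012, 0.020)
      fbio <- runif(1, 0.80, 0.95)
      bw <- runif(1, 55, 95)
      r0 <- runif(1, 0.6, 1.4)
      hours <- 0:23
      profile <- r0 * (1 + 0.3 * cos(2 * pi * (hours - 3) / 24))
      # balanced dosing implied by the kinetics (see vignette), then perturbed
      icr <- 1.6 * si / (fbio * ke)
      cf <- 120 * si / (0.12 * bw * ke)
      virtual_patient_params(
        basal_glucose = runif(1, 100, 140),
        insulin_sensitivity = si,
        glucose_effectiveness = runif(1, 0.010, 0.016),
        insulin_action_rate = runif(1, 0.02, 0.04),
        insulin_clearance = ke,
        carb_bioavailability = fbio,
        gut_absorption_rate = runif(1, 0.025, 0.045),
        body_weight = bw,
        carb_ratio = icr * runif(1, 0.85, 1.15),
        correction_factor = cf * runif(1, 0.8, 1.2),
        basal_rate_profile = profile,
        sensor_noise_sd = 4, sensor_ar_coeff = 0.7,
        seed = seeds[i],
        patient_id = sprintf("vp%03d", i),
        metadata = list(age = round(runif(1, 19, 65)), diabetes_type = "type1",
                        years_since_diagnosis = round(runif(1, 3, 30), 1))
      )
    })
  })
}

# Meal/bolus schedule for one day (minutes of day on the 5-min grid).
sample_day_schedule <- function(params) {
  anchors <- c(breakfast = 450, lunch = 750, dinner = 1110)
  snacks <- c(630, 930, 1290)
  n_extra <- sample(0:2, 1)
  times <- round(anchors / 5 + rnorm(3, 0, 6)) * 5
  carbs <- runif(3, 40, 90)
  if (n_extra > 0) {
    st <- sample(snacks, n_extra)
    times <- c(times, round(st / 5 + rnorm(n_extra, 0, 4)) * 5)
    carbs <- c(carbs, runif(n_extra, 10, 30))
  }
  ok <- times >= 0 & times <= 1435
  o <- order(times[ok])
  list(times = times[ok][o], carbs = carbs[ok][o])
}

#' Simulate one virtual patient
#'
#' Integrates the five-state glucose-insulin-gut system (plasma glucose,
#' remote insulin action, plasma insulin, two gut compartments) with
#' fixed-step RK4 on a 1-minute grid, applying basal infusion continuously
#' and meals/boluses as impulses on 5-minute grid points. Meal boluses are
#' `carbs / carb_ratio` with a multiplicative dosing error, plus a correction
#' `(BG - 100) / correction_factor` (with its own per-event dosing error)
#' whenever glucose exceeds 170 mg/dL at dosing time -- including at the
#' correction checks two hours after each meal; occasionally a bolus is
#' missed entirely. The noise-free glucose is
#' sampled every 5 minutes (clamped to the 20-600 mg/dL sensor range) and
#' AR(1)-plus-white sensor noise is added to produce the CGM channel.
#'
#' @param params a [virtual_patient_params()].
#' @param n_days number of simulated days, `>= 1`.
#' @param start start timestamp (UTC) of the record.
#' @param events optional explicit event table overriding the meal/dosing
#'   policy: a data.frame with columns `time_min` (minutes from start, on the
#'   5-min grid), `carbs` (g) and `bolus` (U), applied exactly as given (no
#'   corrections, no dosing noise). `events = NULL` uses the stochastic daily
#'   schedule; an empty data.frame simulates unfed steady state.
#' @return an object of class `patient_series` with 5-minute-grid channels
#'   `cgm`, `basal`, `bolus`, `carbs`, sparse `calibrations`, `metadata`, and
#'   the noise-free `truth` trace for oracle use.
#' @export
simulate_patient <- function(params, n_days,
                             start = as.POSIXct("2024-01-01 00:00:00", tz = "UTC"),
                             events = NULL) {
  abort_if(!inherits(params, "virtual_patient_params"), "params must be virtual_patient_params")
  abort_if(!is.numeric(n_days) || n_days < 1, "n_days must be >= 1")
  n_days <- as.integer(n_days)
  n_min <- n_days * 1440L
  v_g <- 1.6 * params$body_weight # glucose distribution volume, dL
  v_i <- 0.12 * params$body_weight # insulin distribution volume, L
  ke <- params$insulin_clearance
  i_b <- mean(params$basal_rate_profile) / 60 / (ke * v_i) # reference insulin, U/L
  prof <- params$basal_rate_profile

  deriv <- function(t, y, parms) {
    u <- prof[(floor(t / 60) %% 24) + 1] / 60 # U/min
    g <- y[1]; x <- y[2]; i <- y[3]; q1 <- y[4]; q2 <- y[5]
    dg <- -(params$glucose_effectiveness + x) * g +
      params$glucose_effectiveness * params$basal_glucose +
      params$gut_absorption_rate * q2 / v_g
    dx <- -params$insulin_action_rate * (x - params$insulin_sensitivity * (i - i_b))
    di <- -ke * i + u / v_i
    dq1 <- -params$gut_absorption_rate * q1
    dq2 <- params$gut_absorption_rate * (q1 - q2)
    list(c(dg, dx, di, dq1, dq2))
  }

  with_seed(params$seed, {
    # meal events plus correction-check events 2 h after each meal; the
    # latter dose only if glucose is still high, stacking insulin action the
    # way real corrections do (the main source of simulated hypoglycemia)
    ev_time <- numeric(0); ev_carbs <- numeric(0); ev_bolus_frac <- numeric(0)
    ev_cf_err <- numeric(0); ev_fixed_dose <- numeric(0)
    if (is.null(events)) {
      for (d in seq_len(n_days)) {
        sc <- sample_day_schedule(params)
        nm <- length(sc$times)
        dose_err <- exp(rnorm(nm, 0, 0.3))
        dose_err[runif(nm) < 0.08] <- 0 # missed bolus
        corr_on <- as.numeric(runif(nm) < 0.85) # corrections usually, not always
        cf_err <- exp(rnorm(2 * nm, 0, 0.25)) # per-event correction-dose error
        ev_time <- c(ev_time, (d - 1L) * 1440 + c(sc$times, sc$times + 120))
        ev_carbs <- c(ev_carbs, sc$carbs, rep(0, nm))
        ev_bolus_frac <- c(ev_bolus_frac, dose_err, corr_on)
        ev_cf_err <- c(ev_cf_err, cf_err)
      }
      ev_fixed_dose <- rep(NA_real_, length(ev_time))
    } else if (nrow(events) > 0) {
      ev_time <- events$time_min
      ev_carbs <- events$carbs
      ev_fixed_dose <- events$bolus
      ev_bolus_frac <- rep(1, nrow(events))
      ev_cf_err <- rep(1, nrow(events))
    }
    o <- order(ev_time)
    ev_time <- ev_time[o]; ev_carbs <- ev_carbs[o]
    ev_bolus_frac <- ev_bolus_frac[o]; ev_cf_err <- ev_cf_err[o]
    ev_fixed_dose <- ev_fixed_dose[o]
    keep <- ev_time < n_min
    ev_time <- ev_time[keep]; ev_carbs <- ev_carbs[keep]
    ev_bolus_frac <- ev_bolus_frac[keep]; ev_cf_err <- ev_cf_err[keep]
    ev_fixed_dose <- ev_fixed_dose[keep]

    y <- c(G = params$basal_glucose, X = 0, I = i_b, Q1 = 0, Q2 = 0)
    minute_bg <- numeric(n_min + 1L)
    bolus_amt <- numeric(length(ev_time))
    seg_start <- 0
    record <- function(sol) {
      idx <- sol[, 1] + 1L
      minute_bg[idx] <<- sol[, 2]
    }
    for (j in seq_along(ev_time)) {
      tj <- ev_time[j]
      if (tj > seg_start) {
        sol <- deSolve::ode(y, seq(seg_start, tj), deriv, NULL, method = "rk4")
        record(sol)
        y <- sol[nrow(sol), -1]
        seg_start <- tj
      }
      abort_if(any(!is.finite(y)),
               sprintf("simulation diverged (non-finite state) at t = %g min", tj))
      # impulses: carbs into gut; bolus (meal and/or correction) into plasma
      bg_now <- y[1]
      if (!is.na(ev_fixed_dose[j])) {
        dose <- ev_fixed_dose[j]
      } else {
        dose <- if (ev_carbs[j] > 0) ev_carbs[j] / params$carb_ratio * ev_bolus_frac[j] else 0
        if (bg_now > 170 && ev_bolus_frac[j] > 0) {
          dose <- dose + (bg_now - 100) / (params$correction_factor * ev_cf_err[j])
        }
      }
      bolus_amt[j] <- dose
      y[4] <- y[4] + ev_carbs[j] * 1000 * params$carb_bioavailability
      y[3] <- y[3] + dose / v_i
      names(y) <- c("G", "X", "I", "Q1", "Q2")
    }
    if (seg_start < n_min) {
      sol <- deSolve::ode(y, seq(seg_start, n_min), deriv, NULL, method = "rk4")
      record(sol)
      y <- sol[nrow(sol), -1]
    }
    abort_if(any(!is.finite(y)),
             sprintf("simulation diverged (non-finite state) at t = %d min", n_min))

    n_samp <- n_days * 288L
    samp_min <- (seq_len(n_samp) - 1L) * 5L
    truth <- pmin(pmax(minute_bg[samp_min + 1L], SENSOR_MIN_MGDL), SENSOR_MAX_MGDL)
    ar <- params$sensor_ar_coeff
    innov <- rnorm(n_samp, 0, params$sensor_noise_sd)
    noise <- as.numeric(stats::filter(innov, ar, method = "recursive",
                                      init = rnorm(1, 0, params$sensor_noise_sd / sqrt(1 - ar^2))))
    cgm <- pmin(pmax(truth + noise, SENSOR_MIN_MGDL), SENSOR_MAX_MGDL)

    basal <- prof[(floor(samp_min / 60) %% 24) + 1]
    bolus <- numeric(n_samp); carbs <- numeric(n_samp)
    slot <- ev_time / 5 + 1L
    keep <- slot >= 1 & slot <= n_samp
    bolus[slot[keep]] <- bolus[slot[keep]] + bolus_amt[keep]
    carbs[slot[keep]] <- carbs[slot[keep]] + ev_carbs[keep]

    structure(list(
      patient_id = params$patient_id,
      timestamps = start + samp_min * 60,
      cgm = cgm, basal = basal, bolus = bolus, carbs = carbs,
      calibrations = data.frame(index = integer(0), value = numeric(0)),
      metadata = params$metadata, truth = truth, params = params
    ), class = "patient_series")
  })
}

#' Inject sensor artifacts into a simulated series
#'
#' Creates CGM dropouts and discordant fingerstick calibrations of the kind
#' the preprocessing stage must handle. Gaps set the CGM channel to missing;
#' calibration records equal the simultaneous CGM reading plus a stated
#' offset. The input series is not modified.
#'
#' @param series a `patient_series`.
#' @param gap_spec list of `c(start_index, length)` pairs (1-based).
#' @param calibration_spec list of `c(index, offset_mg_dl)` pairs.
#' @return a new `patient_series` with artifacts applied.
#' @export
inject_artifacts <- function(series, gap_spec = list(), calibration_spec = list()) {
  abort_if(!inherits(series, "patient_series"), "series must be a patient_series")
  n <- length(series$cgm)
  gap_idx <- integer(0)
  for (g in gap_spec) {
    abort_if(length(g) != 2 || g[2] < 1, "gap spec entries are c(start_index, length)")
    idx <- seq.int(g[1], length.out = g[2])
    abort_if(any(idx < 1 | idx > n), "gap outside series")
    gap_idx <- c(gap_idx, idx)
  }
  cal_idx <- vapply(calibration_spec, `[`, numeric(1), 1)
  abort_if(any(cal_idx < 1 | cal_idx > n), "calibration index outside series")
  abort_if(length(intersect(gap_idx, as.integer(cal_idx))) > 0,
           "a calibration cannot coincide with a CGM gap at the same index")
  out <- series
  out$cgm[gap_idx] <- NA_real_
  if (length(calibration_spec)) {
    cal <- data.frame(
      index = as.integer(cal_idx),
      value = vapply(calibration_spec, function(cc) series$cgm[cc[1]] + cc[2], numeric(1))
    )
    out$calibrations <- rbind(out$calibrations, cal)
    out$calibrations <- out$calibrations[order(out$calibrations$index), , drop = FALSE]
  }
  out
}

#' @export
print.patient_series <- function(x, ...) {
  n <- length(x$cgm)
  cat(sprintf("<patient_series> %s: %d samples (%.1f days), %d missing CGM, %d calibrations\n",
              x$patient_id, n, n / 288, sum(is.na(x$cgm)), nrow(x$calibrations)))
  invisible(x)
}
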