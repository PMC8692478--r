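# Shared fixtures: small deterministic objects built in code.

fixture_start <- as.POSIXct("2024-01-01 00:00:00", tz = "UTC")

# A smooth synthetic CGM record (sine around 120 mg/dL) with pump channels;
# cheap stand-in for a simulated patient where ODE realism is irrelevant.
make_series <- function(n = 600, period_steps = 48, amplitude = 40,
                        pid = "fix01", seed = 1) {
  withr::local_seed(seed)
  i <- seq_len(n) - 1
  bg <- 120 + amplitude * sin(2 * pi * i / period_steps)
  carbs <- numeric(n)
  bolus <- numeric(n)
  if (n >= 130) {
    meal_at <- seq(60, n - 60, by = 90)
    carbs[meal_at] <- round(runif(length(meal_at), 30, 80))
    bolus[meal_at] <- carbs[meal_at] / 10
  } else {
    carbs[pmin(10L, n)] <- 40
    bolus[pmin(10L, n)] <- 4
  }
  structure(list(
    patient_id = pid,
    timestamps = fixture_start + i * 300,
    cgm = bg,
    basal = rep(c(0.8, 1.0, 1.2, 1.0), length.out = n),
    bolus = bolus,
    carbs = carbs,
    calibrations = data.frame(index = integer(0), value = numeric(0)),
    metadata = list(age = 30, diabetes_type = "type1", years_since_diagnosis = 10),
    truth = bg, params = NULL
  ), class = "patient_series")
}

# Gap-free segment cut from a fixture series.
make_segment <- function(n = 200, ...) {
  s <- make_series(n = n, ...)
  glucotcn::split_and_reject(s)[[1]]
}

# A tiny TCN config that keeps unit tests fast.
small_tcn <- function(...) {
  glucotcn::tcn_config(n_filters = 8L, dilations = c(1L, 2L), ...)
}

small_model_config <- function(tcn = small_tcn(), ...) {
  glucotcn::model_config(p = c(12L, 6L, 12L, 12L), f = 3L, tcn = tcn, ...)
}

# Scaled windows from a fixture series (single segment).
make_scaled_windows <- function(n = 300, p = c(12L, 6L, 12L, 12L), f = 3L,
                                stride = 1L, ...) {
  seg <- make_segment(n = n, ...)
  sc <- glucotcn::fit_scaler(list(seg))
  glucotcn::scale_windows(glucotcn::make_windows(seg, p = p, f = f, stride = stride), sc)
}

# Even-odd ray-casting point-in-polygon, independent of the package's
# boundary-interpolation classifier.
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    cross <- (vy[i] > py) != (vy[j] > py)
    if (any(cross)) {
      xint <- (vx[j] - vx[i]) * (py[cross] - vy[i]) / (vy[j] - vy[i]) + vx[i]
      inside[cross] <- xor(inside[cross], px[cross] < xint)
    }
    j <- i
  }
  inside
}

# Closed zone rings of the type-1 consensus grid, assembled from the same
# published vertex table the package uses (domain square 0-550).
parkes_zone_polygons <- function() {
  list(
    A = list(x = c(0, 50, 50, 170, 385, 550, 550, 430, 280, 140, 30, 0),
             y = c(0, 0, 30, 145, 300, 450, 550, 550, 380, 170, 50, 50)),
    B_up = list(x = c(0, 30, 140, 280, 430, 260, 70, 50, 30, 0),
                y = c(50, 50, 170, 380, 550, 550, 110, 80, 60, 60)),
    B_lo = list(x = c(50, 120, 120, 260, 550, 550, 385, 170, 50),
                y = c(0, 0, 30, 130, 250, 450, 300, 145, 30)),
    C_up = list(x = c(0, 30, 50, 70, 260, 125, 80, 50, 25, 0),
                y = c(60, 60, 80, 110, 550, 550, 215, 125, 100, 100)),
    C_lo = list(x = c(120, 250, 250, 550, 550, 260, 120),
                y = c(0, 0, 40, 150, 250, 130, 30)),
    D_up = list(x = c(0, 25, 50, 80, 125, 50, 35, 0),
                y = c(100, 100, 125, 215, 550, 550, 155, 150)),
    D_lo = list(x = c(250, 250, 550, 550), y = c(0, 40, 150, 0)),
    E = list(x = c(0, 35, 50, 0), y = c(150, 155, 550, 550))
  )
}

parkes_zone_oracle <- function(ref, pred) {
  polys <- parkes_zone_polygons()
  z <- rep(NA_character_, length(ref))
  for (nm in names(polys)) {
    zone <- substr(nm, 1, 1)
    hit <- is.na(z) & point_in_polygon(ref, pred, polys[[nm]]$x, polys[[nm]]$y)
    z[hit] <- zone
  }
  z[is.na(z)] <- "E"
  z
}
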