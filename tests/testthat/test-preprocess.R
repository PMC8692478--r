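test_that("patient CSV round-trips through write/read", {
  p <- sample_cohort(1, seed = 4)[[1]]
  s <- inject_artifacts(simulate_patient(p, 2), gap_spec = list(c(50, 3)),
                        calibration_spec = list(c(200, 20)))
  dir <- withr::local_tempdir()
  path <- write_patient(s, dir)
  r <- read_patient(path)
  expect_equal(r$cgm, s$cgm, tolerance = 1e-9)
  expect_equal(r$basal, s$basal, tolerance = 1e-9)
  expect_equal(r$bolus, s$bolus, tolerance = 1e-9)
  expect_equal(r$carbs, s$carbs, tolerance = 1e-9)
  expect_equal(r$calibrations, s$calibrations, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(r$truth, s$truth, tolerance = 1e-9)
  expect_identical(r$timestamps, s$timestamps)
  expect_equal(r$metadata$age, s$metadata$age)
})

test_that("schema violations are rejected with the offending row", {
  s <- make_series(n = 50)
  dir <- withr::local_tempdir()
  path <- write_patient(s, dir)

  dt <- as.data.frame(data.table::fread(path, colClasses = list(character = 1)))
  dt$bolus_u[10] <- -1
  bad <- file.path(dir, "bad.csv")
  data.table::fwrite(dt, bad, na = "")
  expect_error(read_patient(bad), "negative bolus at row 10")

  dt2 <- as.data.frame(data.table::fread(path, colClasses = list(character = 1)))
  shuffled <- dt2[c(2, 1, 3:nrow(dt2)), , drop = FALSE]
  data.table::fwrite(shuffled, bad, na = "")
  expect_error(read_patient(bad), "non-monotone")

  dt3 <- as.data.frame(data.table::fread(path, colClasses = list(character = 1)))
  dt3 <- dt3[-5, , drop = FALSE]
  data.table::fwrite(dt3, bad, na = "")
  expect_error(read_patient(bad), "spacing")
})

test_that("short gaps are filled, long gaps and boundary gaps are not", {
  s <- make_series(n = 400)
  s$cgm[c(101:105, 201:207)] <- NA # 5-step and 7-step runs
  s$cgm[1:2] <- NA # boundary
  filled <- fill_short_gaps(s, max_gap_steps = 6)
  expect_false(anyNA(filled$cgm[101:105]))
  expect_true(all(is.na(filled$cgm[201:207])))
  expect_true(all(is.na(filled$cgm[1:2])))
  rep <- attr(filled, "fill_report")
  expect_equal(rep$filled, c(FALSE, TRUE, FALSE))
  # non-missing values never change
  ok <- !is.na(s$cgm)
  expect_identical(filled$cgm[ok], s$cgm[ok])
})

test_that("gap interpolation tracks a smooth trace closely", {
  s <- make_series(n = 400, period_steps = 48, amplitude = 40)
  truth <- s$cgm
  gap <- 150:154
  s$cgm[gap] <- NA
  filled <- fill_short_gaps(s)
  expect_lt(max(abs(filled$cgm[gap] - truth[gap])), 5)
})

test_that("splitting and calibration rejection follow the thresholds", {
  s <- make_series(n = 600)
  s <- inject_artifacts(s, gap_spec = list(c(300, 7)),
                        calibration_spec = list(c(100, 60), c(450, 40)))
  segs <- split_and_reject(fill_short_gaps(s))
  # 7-step gap splits in two; the +60 mg/dL calibration kills segment 1,
  # the +40 one is within tolerance
  rep <- attr(segs, "segment_report")
  expect_equal(nrow(rep), 2)
  expect_equal(rep$dismissed, c(TRUE, FALSE))
  expect_length(segs, 1)
  expect_equal(segs[[1]]$start_index, 307L)
  # segments plus gaps tile the parent record exactly
  expect_equal(rep$start[1], 1L)
  expect_equal(rep$end[1], 299L)
  expect_equal(rep$end[2], 600L)
})

test_that("boundary case: offset exactly at the threshold is retained", {
  s <- make_series(n = 200)
  s <- inject_artifacts(s, calibration_spec = list(c(100, 50)))
  expect_length(split_and_reject(s), 1)
  s2 <- make_series(n = 200)
  s2 <- inject_artifacts(s2, calibration_spec = list(c(100, 50.5)))
  expect_length(split_and_reject(s2), 0)
})

test_that("eligibility and quality criteria evaluate the record", {
  s <- make_series(n = 288 * 3) # all-normo sine (80..160)
  qc <- apply_qc(s)
  expect_true(qc$ec1 && qc$ec2 && qc$ec3 && qc$eligible)
  expect_equal(qc$time_in_range_frac, 1.0)

  s$metadata$age <- 17
  expect_false(apply_qc(s)$ec2)

  s2 <- make_series(n = 1000)
  s2$cgm[1:100] <- 60 # 10% hypo
  qc2 <- apply_qc(s2)
  expect_equal(qc2$time_hypo_frac, 0.1)
  expect_false(qc2$q_hypo)

  s3 <- make_series(n = 100)
  s3$metadata$years_since_diagnosis <- NULL
  expect_error(apply_qc(s3), "years_since_diagnosis")
})

test_that("min-max scaling maps the training range to [0,1] and inverts", {
  seg <- make_segment(n = 300)
  sc <- fit_scaler(list(seg))
  r <- range(seg$cgm)
  expect_equal(scale_values(sc, r, "cgm"), c(0, 1))
  x <- c(70, 120, 250, 431.7)
  expect_equal(unscale_values(sc, scale_values(sc, x, "cgm"), "cgm"), x,
               tolerance = 1e-9)
  # out-of-range test values scale beyond [0,1] without clipping
  expect_gt(scale_values(sc, r[2] + 60, "cgm"), 1)
  # hand value: train range {70,190} puts 250 at 1.5
  sc2 <- structure(list(cgm = c(70, 190)), class = "minmax_scaler")
  expect_equal(scale_values(sc2, 250, "cgm"), 1.5)
  # constant channel cannot be scaled
  seg2 <- seg
  seg2$basal[] <- 1
  expect_error(fit_scaler(list(seg2)), "constant")
})

test_that("scaler is fitted on training data only", {
  seg <- make_segment(n = 300)
  sc <- fit_scaler(list(seg))
  perturbed_test <- make_segment(n = 300, seed = 99)
  perturbed_test$cgm <- perturbed_test$cgm * 2
  expect_identical(fit_scaler(list(seg)), sc)
  w <- scale_windows(make_windows(perturbed_test, p = c(12, 6, 12, 12), f = 3), sc)
  expect_identical(w$scaler, sc)
})

test_that("window cutting matches the counting rule and the data", {
  seg <- make_segment(n = 100)
  w <- make_windows(seg, p = c(36, 6, 36, 36), f = 6)
  expect_equal(n_windows(w), 100 - 36 - 6 + 1)
  short <- make_segment(n = 41)
  expect_equal(n_windows(make_windows(short, p = c(36, 6, 36, 36), f = 6)), 0)

  # brute-force count check over random shapes
  withr::local_seed(42)
  for (i in 1:50) {
    L <- sample(20:150, 1)
    pm <- sample(5:40, 1)
    f <- sample(1:12, 1)
    seg_i <- make_segment(n = L)
    got <- n_windows(make_windows(seg_i, p = c(pm, min(pm, 3), pm, pm), f = f))
    manual <- sum(vapply(seq_len(L), function(t) t >= pm && t + f <= L, TRUE))
    expect_identical(got, as.integer(manual))
  }

  # content: y is the next f values; views end at the anchor; the last p2
  # glucose values of every view agree with x2 (shared source)
  t0 <- w$anchors[5]
  expect_equal(w$y[5, ], seg$cgm[(t0 + 1):(t0 + 6)])
  expect_equal(w$x1[5, , 1], seg$cgm[(t0 - 35):t0])
  expect_equal(w$x1[5, 31:36, 1], w$x2[5, , 1])
  expect_equal(w$x3[5, 31:36, 1], w$x2[5, , 1])
  expect_equal(w$x4[5, , 2], seg$bolus[(t0 - 35):t0])
  expect_equal(w$anchor_bg[5], seg$cgm[t0])
})

test_that("chronological split keeps eras apart", {
  s <- make_series(n = 500)
  s$cgm[c(200:206)] <- NA
  segs <- split_and_reject(fill_short_gaps(s))
  sp <- split_segments(segs, test_frac = 0.2)
  train_end <- max(vapply(sp$train, function(x) x$start_index + length(x$cgm) - 1L, 0L))
  test_start <- min(vapply(sp$test, `[[`, 0L, "start_index"))
  expect_lt(train_end, test_start)
  total <- sum(vapply(c(sp$train, sp$test), function(x) length(x$cgm), 0L))
  expect_equal(total, sum(vapply(segs, function(x) length(x$cgm), 0L)))
})
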