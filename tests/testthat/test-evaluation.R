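test_that("accuracy metrics match hand calculations and the formula oracle", {
  m0 <- compute_metrics(c(100, 150), c(100, 150))
  expect_equal(unlist(m0$overall[c("rmse", "mae", "mape")]),
               c(rmse = 0, mae = 0, mape = 0))
  m <- compute_metrics(c(100, 200), c(110, 190))$overall
  expect_equal(m$mae, 10)
  expect_equal(m$rmse, 10)
  expect_equal(m$mape, 7.5)
  expect_equal(m$nrmse, 0.1)
  withr::local_seed(25)
  for (i in 1:100) {
    n <- sample(2:30, 1)
    yt <- runif(n, 40, 400)
    yp <- yt + rnorm(n, 0, 25)
    got <- compute_metrics(yt, yp)$overall
    expect_equal(got$rmse, sqrt(sum((yp - yt)^2) / n), tolerance = 1e-9)
    expect_equal(got$mae, sum(abs(yp - yt)) / n, tolerance = 1e-9)
    expect_equal(got$mape, sum(abs(yp - yt) / yt) / n * 100, tolerance = 1e-9)
    expect_equal(got$nrmse, got$rmse / (max(yt) - min(yt)), tolerance = 1e-9)
    expect_gte(got$rmse, got$mae) # power-mean inequality
  }
  expect_error(compute_metrics(numeric(0), numeric(0)), "empty")
})

test_that("per-category sub-reports partition by the true value", {
  r <- compute_metrics(c(60, 100, 200), c(65, 95, 210))
  expect_equal(r$hypo$n, 1)
  expect_equal(r$normo$n, 1)
  expect_equal(r$hyper$n, 1)
  # an absent category reports no numbers
  r2 <- compute_metrics(c(100, 150), c(90, 160))
  expect_null(r2$hypo)
  expect_null(r2$hyper)
  expect_output(print(r2), "No test samples")
})

test_that("category detection rates follow the TP/P and FP/N definitions", {
  yt <- c(60, 65, 100, 200)
  yp <- c(65, 80, 90, 210)
  hy <- category_rates(yt, yp, "hypo")
  expect_equal(hy[c("p", "tp", "fp", "n")], list(p = 2L, tp = 1L, fp = 0L, n = 2L))
  expect_equal(hy$tpr, 0.5)
  expect_equal(hy$fpr, 0)
  hr <- category_rates(yt, yp, "hyper")
  expect_equal(hr$tpr, 1.0)
  expect_equal(hr$fp, 0L)
  # a perfect forecast has TPR 1 and FPR 0 in every represented category
  for (categ in c("hypo", "hyper", "normo")) {
    pr <- category_rates(yt, yt, categ)
    expect_equal(pr$tpr, 1)
    expect_equal(pr$fpr, 0)
  }
  # empty denominators are reported missing, never zero
  expect_true(is.na(category_rates(c(100, 120), c(60, 60), "hypo")$tpr))
  # exhaustive random cross-check of the counting
  withr::local_seed(26)
  for (i in 1:50) {
    yt <- runif(30, 40, 300)
    yp <- runif(30, 40, 300)
    cr <- category_rates(yt, yp, "hyper")
    expect_equal(cr$p, sum(yt >= 180))
    expect_equal(cr$tp, sum(yt >= 180 & yp >= 180))
    expect_equal(cr$fp, sum(yt < 180 & yp >= 180))
    expect_lte(cr$tp, cr$p)
    expect_lte(cr$fp, cr$n)
  }
})

test_that("model comparison reproduces the Welch formula", {
  a <- c(1, 1, 1, 1)
  expect_equal(compare_models(a, a + c(1e-9, -1e-9, 0, 0))$statistic, 0,
               tolerance = 1e-6)
  jit <- c(0.001, -0.001, 0.0005, -0.0005)
  r <- compare_models(c(0, 0, 0, 0) + jit, c(1, 1, 1, 1) + jit)
  expect_lt(r$p_value, 0.001)
  # antisymmetry
  expect_equal(compare_models(1:5, 6:10)$statistic,
               -compare_models(6:10, 1:5)$statistic)
  expect_error(compare_models(1, 1:3), "at least 2")
  # textbook Welch oracle
  withr::local_seed(27)
  for (i in 1:100) {
    x <- rnorm(sample(3:20, 1), sd = runif(1, 0.5, 3))
    y <- rnorm(sample(3:20, 1), mean = runif(1, -1, 1))
    got <- compare_models(x, y)
    se2 <- var(x) / length(x) + var(y) / length(y)
    tstat <- (mean(x) - mean(y)) / sqrt(se2)
    df <- se2^2 / (var(x)^2 / (length(x)^2 * (length(x) - 1)) +
                     var(y)^2 / (length(y)^2 * (length(y) - 1)))
    pval <- 2 * pt(-abs(tstat), df)
    expect_equal(got$statistic, tstat, tolerance = 1e-10)
    expect_equal(got$df, df, tolerance = 1e-10)
    expect_equal(got$p_value, pval, tolerance = 1e-10)
  }
})

test_that("Clarke zones match the published rule set on canonical points", {
  expect_equal(clarke_zone(100, 100), "A")
  expect_equal(clarke_zone(60, 200), "E")
  expect_equal(clarke_zone(200, 150), "B")
  expect_equal(clarke_zone(50, 50), "A") # joint hypo branch of zone A
  expect_equal(clarke_zone(200, 350), "C") # pred >= ref + 110
  expect_equal(clarke_zone(150, 25), "C") # lower C wedge
  expect_equal(clarke_zone(300, 120), "D") # high ref read as in-range
  expect_equal(clarke_zone(40, 120), "D") # hypo read as in-range
  expect_equal(clarke_zone(70, 56), "A") # exactly 20% off -> still A
  expect_error(clarke_zone(-5, 100), "non-negative")
})

test_that("Parkes type-1 zones match canonical points and stay a partition", {
  expect_equal(parkes_zone_type1(100, 100), "A")
  expect_equal(parkes_zone_type1(550, 550), "A")
  expect_equal(parkes_zone_type1(0, 0), "A")
  expect_equal(parkes_zone_type1(100, 170), "B")
  expect_equal(parkes_zone_type1(100, 250), "C")
  expect_equal(parkes_zone_type1(50, 300), "D")
  expect_equal(parkes_zone_type1(30, 400), "E")
  expect_equal(parkes_zone_type1(400, 50), "D") # severe under-read, lower right
  expect_warning(parkes_zone_type1(560, 100), "clamped")
})

test_that("grid tabulation sums counts and percentages consistently", {
  withr::local_seed(28)
  ref <- runif(500, 20, 540)
  pred <- pmin(pmax(20, ref + rnorm(500, 0, 40)), 550)
  for (g in c("clarke", "parkes")) {
    r <- error_grid(ref, pred, g)
    expect_equal(sum(r$zone_counts), 500)
    expect_equal(sum(r$zone_percent), 100, tolerance = 1e-9)
  }
})

test_that("evaluation reports aggregate patients with sample sd", {
  mk_batch <- function(pid, rmse_target) {
    yt <- rep(c(100, 150), 50)
    structure(list(anchors = 1:100, y_true = matrix(yt, 100, 1),
                   y_pred = matrix(yt + rmse_target, 100, 1),
                   patient_id = pid, f = 1, steps = 1),
              class = "forecast_batch")
  }
  rep <- evaluation_report(list(mk_batch("a", 10), mk_batch("b", 20)), 1)
  co <- rep$cohort
  expect_equal(co$mean[co$metric == "rmse"], 15)
  expect_equal(co$sd[co$metric == "rmse"], sd(c(10, 20)))
  # perfect forecasts: zone A 100%, RMSE 0
  perfect <- evaluation_report(mk_batch("c", 0), 1)
  expect_equal(perfect$per_patient[[1]]$metrics$overall$rmse, 0)
  expect_equal(perfect$per_patient[[1]]$clarke$zone_percent[1], 100)
  expect_equal(perfect$per_patient[[1]]$parkes$zone_percent[1], 100)
})

test_that("forecast CSVs round-trip", {
  w <- make_scaled_windows(n = 150)
  fc <- naive_forecast(w)
  path <- withr::local_tempfile(fileext = ".csv")
  write_forecasts(fc, path)
  back <- read_forecasts(path)[[1]]
  expect_equal(back$y_pred, fc$y_pred, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(back$y_true, fc$y_true, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(back$anchors, fc$anchors)
})

test_that("error-grid plots build without evaluation", {
  p <- plot_error_grid(c(100, 200, 300), c(110, 150, 280), "clarke")
  expect_s3_class(p, "ggplot")
  p2 <- plot_error_grid(c(100, 200, 300), c(110, 150, 280), "parkes")
  expect_s3_class(p2, "ggplot")
})
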