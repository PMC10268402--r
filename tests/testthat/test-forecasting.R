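test_that("Holt smoothing is exact on affine series for any weights", {
  x <- c(3, 5, 7, 9)
  for (a in seq(0.1, 0.9, by = 0.2)) {
    for (b in seq(0.1, 0.9, by = 0.2)) {
      st <- holt_fit(x, alpha = a, beta = b)
      expect_equal(st$level_path, x, tolerance = 1e-12)
      expect_equal(st$trend_path, rep(2, 4), tolerance = 1e-12)
      expect_equal(st$sse, 0, tolerance = 1e-20)
      expect_equal(holt_forecast(st, 3), c(11, 13, 15), tolerance = 1e-12)
    }
  }
  const <- holt_fit(rep(4.2, 6), alpha = 0.3, beta = 0.3)
  expect_equal(const$level, 4.2)
  expect_equal(const$trend, 0)
  expect_equal(holt_forecast(const, 4), rep(4.2, 4))
})

test_that("one hand-stepped update matches the recursion", {
  # series 9, 10, 12: after i = 2 the state is (s, t) = (10, 1);
  # the i = 3 update with alpha = beta = 0.5 and x = 12 gives
  # s = 11.5, t = 1.25, one-step prediction 12.75
  st <- holt_fit(c(9, 10, 12), alpha = 0.5, beta = 0.5)
  expect_equal(st$level, 11.5)
  expect_equal(st$trend, 1.25)
  expect_equal(st$fitted[3], 12.75)
  expect_equal(holt_forecast(st, 2), c(12.75, 14.0))
})

test_that("weight optimisation is deterministic and respects bounds", {
  set.seed(2)
  x <- cumsum(stats::rnorm(20, 0.5))
  f1 <- holt_fit(x)
  f2 <- holt_fit(x)
  expect_identical(f1, f2)
  expect_true(f1$alpha > 0 && f1$alpha < 1 && f1$beta > 0 && f1$beta < 1)
  expect_lte(f1$sse, holt_fit(x, 0.5, 0.5)$sse)
  expect_error(holt_fit(c(1, 2)), "length >= 3")
  expect_error(holt_fit(c(1, NA, 3)), "non-finite")
  expect_error(holt_forecast(f1, 0), ">= 1")
})

test_that("sliding windows enumerate (window, next value) pairs", {
  ds <- make_windows(c(1, 2, 3, 4), w = 2)
  expect_equal(unname(ds$inputs), rbind(c(1, 2), c(2, 3)))
  expect_equal(ds$targets, c(3, 4))

  many <- make_windows(replicate(31, stats::rnorm(8), simplify = FALSE), 3)
  expect_equal(nrow(many$inputs), 31 * 5)
  expect_equal(length(many$targets), 155)
  expect_equal(length(unique(many$series_id)), 31)

  expect_error(make_windows(c(1, 2, 3, 4), 4), "smaller than series length")

  # width-1 windows keep one row per sample
  ds1 <- make_windows(c(5, 6, 7, 8), 1)
  expect_equal(dim(ds1$inputs), c(3, 1))
  expect_equal(ds1$targets, c(6, 7, 8))
})

test_that("the residual network learns degenerate and periodic patterns", {
  zero_ds <- make_windows(replicate(4, rep(0, 8), simplify = FALSE), 3)
  dnn0 <- fit_residual_dnn(zero_ds, epochs = 300, seed = 5)
  expect_lt(max(abs(predict(dnn0, zero_ds$inputs))), 1e-3)

  c_amp <- 0.8
  alt <- rep(c(c_amp, -c_amp), 10)
  ds <- make_windows(list(a = alt[1:14], b = -alt[1:14]), 2)
  dnn <- fit_residual_dnn(ds, epochs = 500, seed = 5)
  test_x <- rbind(c(c_amp, -c_amp), c(-c_amp, c_amp))
  test_y <- c(c_amp, -c_amp)
  mse <- mean((predict(dnn, test_x) - test_y)^2)
  expect_lt(mse, c_amp^2 / 10)

  dnn_b <- fit_residual_dnn(ds, epochs = 500, seed = 5)
  expect_identical(predict(dnn, ds$inputs), predict(dnn_b, ds$inputs))

  expect_error(fit_residual_dnn(make_windows(rep(c(1, -1), 3), 2)),
               "too few")
})

test_that("recursive residual prediction feeds outputs back as inputs", {
  ds <- make_windows(list(a = rep(c(1, -1), 7)), 2)
  dnn <- fit_residual_dnn(ds, epochs = 400, seed = 3)
  rec <- predict_residuals(dnn, c(1, -1), horizon = 4)
  manual <- numeric(4); window <- c(1, -1)
  for (h in 1:4) {
    manual[h] <- predict(dnn, matrix(window, 1))
    window <- c(window[2], manual[h])
  }
  expect_identical(rec, manual)
})

test_that("the metric harness reproduces hand-computed values and invariances", {
  m <- evaluate_forecast(c(1, 2, 4), c(1, 2, 2))
  expect_equal(m$mse, 4 / 3, tolerance = 1e-12)
  expect_equal(m$mae, 2 / 3, tolerance = 1e-12)
  expect_equal(m$rmse, 2 / sqrt(3), tolerance = 1e-12)
  expect_equal(m$mape, 100 * 0.5 / 3, tolerance = 1e-12)
  expect_equal(m$r2, 1 / 7, tolerance = 1e-12)

  perfect <- evaluate_forecast(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unlist(perfect[c("mse", "mae", "rmse", "mape")]),
               c(mse = 0, mae = 0, rmse = 0, mape = 0))
  expect_equal(perfect$r2, 1)

  y <- c(2, 4, 9)
  expect_equal(evaluate_forecast(y, rep(mean(y), 3))$r2, 0, tolerance = 1e-12)

  set.seed(6)
  yt <- stats::rlnorm(10); yp <- yt + stats::rnorm(10, 0, 0.2)
  m0 <- evaluate_forecast(yt, yp)
  expect_equal(m0$rmse^2, m0$mse, tolerance = 1e-12)
  shifted <- evaluate_forecast(yt + 5, yp + 5)
  expect_equal(shifted$r2, m0$r2, tolerance = 1e-12)
  scaled <- evaluate_forecast(3 * yt, 3 * yp)
  expect_equal(scaled$mape, m0$mape, tolerance = 1e-12)

  expect_error(evaluate_forecast(c(0, 1, 2), c(1, 1, 1)), "index 1")
  expect_error(evaluate_forecast(rep(2, 3), c(1, 2, 3)), "zero variance")
  expect_error(evaluate_forecast(1:3, 1:4), "length")
})

test_that("a purely linear panel is forecast exactly by the smoother alone", {
  years <- 2011:2020
  series <- list(a = 3 + 2 * (0:9), b = 10 - 0.5 * (0:9), c = 1 + 0.25 * (0:9))
  fc <- ets_dnn_forecast(series, years, train_end = 2018, test_end = 2020,
                         horizon = 3, w = 3, seed = 2)
  for (id in names(series)) {
    ps <- fc$per_series[[id]]
    expect_equal(ps$ets_test, ps$test_actual, tolerance = 1e-9)
    expect_lt(max(abs(ps$residual_pred)), 1e-3)
  }
  expect_lt(fc$metrics$ets$rmse, 1e-9)
})

test_that("hybrid forecasts decompose exactly into smoother plus residual model", {
  set.seed(4)
  years <- 2011:2020
  series <- lapply(stats::setNames(1:6, paste0("s", 1:6)), function(i)
    5 + 0.3 * (0:9) + stats::rnorm(10, 0, 0.3))
  fc <- ets_dnn_forecast(series, years, train_end = 2018, test_end = 2020,
                         horizon = 4, w = 3, seed = 9)
  for (ps in fc$per_series) {
    expect_equal(c(ps$hybrid_test, ps$hybrid_future) -
                   c(ps$ets_test, ps$ets_future),
                 ps$residual_pred, tolerance = 1e-12)
    expect_true(all(is.finite(ps$hybrid_future)))
    expect_equal(length(ps$hybrid_future), 4)
  }
  fc2 <- ets_dnn_forecast(series, years, train_end = 2018, test_end = 2020,
                          horizon = 4, w = 3, seed = 9)
  expect_identical(fc$per_series, fc2$per_series)
  expect_error(ets_dnn_forecast(series, years, 2020, 2020), "test span")
})
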