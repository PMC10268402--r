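#' Holt linear-trend exponential smoothing
#'
#' Double exponential smoothing with separate level and trend recursions:
#' \deqn{s_i = \alpha x_i + (1-\alpha)(s_{i-1} + t_{i-1})}
#' \deqn{t_i = \beta (s_i - s_{i-1}) + (1-\beta) t_{i-1}}
#' \deqn{\hat x_i = s_i + t_i}
#' initialised with `s_1 = x_1`, `t_1 = x_2 - x_1`, so an exactly affine
#' series is fitted with zero one-step error for any smoothing weights.
#' `"optimize"` selects the weights by a deterministic grid search
#' (0.05 to 0.95 in steps of 0.05) over the in-sample one-step squared
#' error, refined by Nelder-Mead.
#'
#' @param series numeric vector, length >= 3, no missing values
#' @param alpha level smoothing weight in (0, 1), or `"optimize"`
#' @param beta trend smoothing weight in (0, 1), or `"optimize"`
#' @return an `ets_state` list: `level`, `trend` (final values), `alpha`,
#'   `beta`, `fitted` (one-step-ahead predictions `hat x_i = s_i + t_i`,
#'   aligned so `fitted[i]` predicts `series[i + 1]`), `residuals`
#'   (`series[i] - fitted[i - 1]`, `NA` for i = 1), `sse` (in-sample
#'   one-step sum of squares), and the level/trend paths
#' @export
holt_fit <- function(series, alpha = "optimize", beta = "optimize") {
  series <- as.numeric(series)
  if (length(series) < 3L) stop("series must have length >= 3", call. = FALSE)
  if (any(!is.finite(series))) stop("series contains non-finite values",
                                    call. = FALSE)
  optimize_weights <- identical(alpha, "optimize") || identical(beta, "optimize")
  if (!optimize_weights) {
    stopifnot(is.numeric(alpha), alpha > 0, alpha < 1,
              is.numeric(beta), beta > 0, beta < 1)
    return(.holt_run(series, alpha, beta))
  }
  grid <- seq(0.05, 0.95, by = 0.05)
  best <- c(0.5, 0.5); best_sse <- Inf
  for (a in grid) {
    for (b in grid) {
      sse <- .holt_sse(series, a, b)
      if (sse < best_sse) { best_sse <- sse; best <- c(a, b) }
    }
  }
  refined <- stats::optim(best, function(p) {
    if (any(p <= 1e-6) || any(p >= 1 - 1e-6)) return(Inf)
    .holt_sse(series, p[1], p[2])
  }, method = "Nelder-Mead")
  if (refined$value < best_sse) best <- refined$par
  .holt_run(series, best[1], best[2])
}

.holt_run <- function(x, alpha, beta) {
  m <- length(x)
  s <- t <- fitted <- numeric(m)
  s[1] <- x[1]; t[1] <- x[2] - x[1]
  fitted[1] <- s[1] + t[1]
  for (i in 2:m) {
    s[i] <- alpha * x[i] + (1 - alpha) * (s[i - 1] + t[i - 1])
    t[i] <- beta * (s[i] - s[i - 1]) + (1 - beta) * t[i - 1]
    fitted[i] <- s[i] + t[i]
  }
  residuals <- c(NA_real_, x[-1] - fitted[-m])
  structure(list(level = s[m], trend = t[m], alpha = alpha, beta = beta,
                 fitted = fitted, residuals = residuals,
                 sse = sum(residuals[-1]^2),
                 level_path = s, trend_path = t, n = m),
            class = "ets_state")
}

.holt_sse <- function(x, alpha, beta) .holt_run(x, alpha, beta)$sse

#' Forecast from a fitted Holt state
#'
#' Linear extrapolation of the final level and trend: the lead-m forecast is
#' `level + m * trend` (the one-step form `hat x = s + t` extended to the
#' only extrapolation consistent with a level-plus-trend model).
#'
#' @param state an `ets_state` from [holt_fit()]
#' @param horizon number of steps ahead, h >= 1
#' @return numeric vector of h forecasts
#' @export
holt_forecast <- function(state, horizon) {
  stopifnot(inherits(state, "ets_state"))
  if (!is.numeric(horizon) || horizon < 1) {
    stop("horizon must be >= 1", call. = FALSE)
  }
  state$level + seq_len(horizon) * state$trend
}

#' Build sliding-window supervised samples from series
#'
#' Converts each series into (window, next value) pairs: for window length
#' w, sample i is `(x[i-w+1], ..., x[i]) -> x[i+1]`, giving `L - w` samples
#' from a series of length L. Multiple series (a named list, or a matrix
#' with one row per region) are pooled with provenance retained.
#'
#' @param series numeric vector, named list of vectors, or matrix with one
#'   series per row
#' @param w window length, `1 <= w < length(series)`
#' @return a `window_dataset` list: `inputs` (samples x w matrix), `targets`
#'   (numeric vector), `series_id` and `t_index` (provenance: the target's
#'   position within its series)
#' @export
make_windows <- function(series, w) {
  if (is.matrix(series)) {
    ids <- rownames(series)
    if (is.null(ids)) ids <- as.character(seq_len(nrow(series)))
    series <- stats::setNames(lapply(seq_len(nrow(series)),
                                     function(i) series[i, ]), ids)
  }
  if (!is.list(series)) series <- list(series = as.numeric(series))
  if (is.null(names(series))) names(series) <- as.character(seq_along(series))
  w <- as.integer(w)
  if (w < 1L) stop("window length must be >= 1", call. = FALSE)
  inputs <- NULL; targets <- numeric(0)
  series_id <- character(0); t_index <- integer(0)
  for (id in names(series)) {
    x <- as.numeric(series[[id]])
    if (w >= length(x)) {
      stop("window length ", w, " must be smaller than series length ",
           length(x), " (series '", id, "')", call. = FALSE)
    }
    n_samp <- length(x) - w
    idx <- outer(seq_len(n_samp), 0:(w - 1L), "+")   # n_samp x w positions
    m <- matrix(x[idx], n_samp, w)
    inputs <- rbind(inputs, m)
    targets <- c(targets, x[(w + 1L):length(x)])
    series_id <- c(series_id, rep(id, n_samp))
    t_index <- c(t_index, (w + 1L):length(x))
  }
  structure(list(inputs = inputs, targets = targets, series_id = series_id,
                 t_index = t_index, w = w),
            class = "window_dataset")
}

## ---- minimal fully-connected network with Adam, seeded and deterministic ----

.mlp_init <- function(sizes, seed) {
  withr_seed(seed, {
    layers <- vector("list", length(sizes) - 1L)
    for (l in seq_along(layers)) {
      fan_in <- sizes[l]
      layers[[l]] <- list(
        W = matrix(stats::rnorm(sizes[l] * sizes[l + 1L], 0,
                                sqrt(2 / fan_in)),
                   sizes[l], sizes[l + 1L]),
        b = rep(0, sizes[l + 1L]))
    }
    layers
  })
}

.mlp_forward <- function(layers, x) {
  acts <- list(x)
  n_l <- length(layers)
  for (l in seq_len(n_l)) {
    z <- sweep(acts[[l]] %*% layers[[l]]$W, 2L, layers[[l]]$b, "+")
    acts[[l + 1L]] <- if (l < n_l) pmax(z, 0) else z  # ReLU hidden, linear out
  }
  acts
}

.mlp_train <- function(x, y, hidden, epochs, lr, seed) {
  sizes <- c(ncol(x), hidden, 1L)
  layers <- .mlp_init(sizes, seed)
  n <- nrow(x)
  adam <- lapply(layers, function(l) list(mW = l$W * 0, vW = l$W * 0,
                                          mb = l$b * 0, vb = l$b * 0))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; step <- 0
  n_l <- length(layers)
  for (epoch in seq_len(epochs)) {
    acts <- .mlp_forward(layers, x)
    pred <- acts[[n_l + 1L]]
    grad_out <- 2 * (pred - y) / n          # d(MSE)/d(pred)
    delta <- grad_out
    step <- step + 1
    for (l in rev(seq_len(n_l))) {
      gW <- crossprod(acts[[l]], delta)
      gb <- colSums(delta)
      if (l > 1L) {
        delta <- (delta %*% t(layers[[l]]$W)) * (acts[[l]] > 0)
      }
      adam[[l]]$mW <- b1 * adam[[l]]$mW + (1 - b1) * gW
      adam[[l]]$vW <- b2 * adam[[l]]$vW + (1 - b2) * gW^2
      adam[[l]]$mb <- b1 * adam[[l]]$mb + (1 - b1) * gb
      adam[[l]]$vb <- b2 * adam[[l]]$vb + (1 - b2) * gb^2
      mW_hat <- adam[[l]]$mW / (1 - b1^step)
      vW_hat <- adam[[l]]$vW / (1 - b2^step)
      mb_hat <- adam[[l]]$mb / (1 - b1^step)
      vb_hat <- adam[[l]]$vb / (1 - b2^step)
      layers[[l]]$W <- layers[[l]]$W - lr * mW_hat / (sqrt(vW_hat) + eps)
      layers[[l]]$b <- layers[[l]]$b - lr * mb_hat / (sqrt(vb_hat) + eps)
    }
  }
  layers
}

#' Train the residual-correcting neural network
#'
#' A small fully-connected network (default two hidden layers of 32 ReLU
#' units, trained full-batch with Adam) mapping a window of recent
#' one-step residuals of the linear smoother to the next residual -- the
#' nonlinear half of the hybrid forecaster. Inputs and targets are
#' standardised by the training-set mean and standard deviation; training
#' is bit-reproducible under a fixed seed.
#'
#' @param windows a `window_dataset` built from smoothing residuals
#' @param hidden integer vector of hidden layer widths (default `c(32, 32)`)
#' @param epochs training epochs (default 500)
#' @param learning_rate Adam step size (default 0.01)
#' @param seed integer seed for weight initialisation
#' @return a `residual_dnn` object with a `predict` method; recursive
#'   multi-step prediction is available through [predict_residuals()]
#' @export
fit_residual_dnn <- function(windows, hidden = c(32L, 32L), epochs = 500L,
                             learning_rate = 0.01, seed = 1L) {
  stopifnot(inherits(windows, "window_dataset"))
  x <- windows$inputs; y <- windows$targets
  if (nrow(x) < 10L) {
    stop("too few training samples (", nrow(x),
         "); use a smaller window or pool more series", call. = FALSE)
  }
  x_mean <- colMeans(x); x_sd <- apply(x, 2L, stats::sd)
  x_sd[x_sd == 0] <- 1
  y_mean <- mean(y); y_sd <- stats::sd(y)
  if (y_sd == 0) y_sd <- 1
  xs <- sweep(sweep(x, 2L, x_mean), 2L, x_sd, "/")
  ys <- (y - y_mean) / y_sd
  layers <- .mlp_train(xs, matrix(ys, ncol = 1L), hidden,
                       epochs = epochs, lr = learning_rate, seed = seed)
  structure(list(layers = layers, x_mean = x_mean, x_sd = x_sd,
                 y_mean = y_mean, y_sd = y_sd, w = windows$w,
                 hidden = hidden, epochs = epochs,
                 learning_rate = learning_rate, seed = seed),
            class = "residual_dnn")
}

#' @export
predict.residual_dnn <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  if (ncol(x) != object$w) stop("window width mismatch", call. = FALSE)
  xs <- sweep(sweep(x, 2L, object$x_mean), 2L, object$x_sd, "/")
  pred <- .mlp_forward(object$layers, xs)[[length(object$layers) + 1L]]
  as.vector(pred) * object$y_sd + object$y_mean
}

#' Recursive multi-step residual prediction
#'
#' Predicts `horizon` future residuals from the last observed window,
#' feeding each prediction back into the window for the next step.
#'
#' @param model a `residual_dnn`
#' @param last_window numeric vector of the w most recent residuals
#' @param horizon steps ahead
#' @return numeric vector of length `horizon`
#' @export
predict_residuals <- function(model, last_window, horizon) {
  stopifnot(inherits(model, "residual_dnn"),
            length(last_window) == model$w, horizon >= 1)
  window <- as.numeric(last_window)
  out <- numeric(horizon)
  for (h in seq_len(horizon)) {
    out[h] <- predict(model, matrix(window, nrow = 1L))
    window <- c(window[-1L], out[h])
  }
  out
}

#' Regression evaluation metrics
#'
#' The five-metric harness used to compare forecasters: mean squared error,
#' mean absolute error, root mean squared error, mean absolute percentage
#' error (in percent; requires nonzero true values) and R-squared
#' (`1 - SSres/SStot`; requires nonconstant true values).
#'
#' @param y_true,y_pred numeric vectors of equal length >= 2
#' @return a `regression_metrics` named list: `mse`, `mae`, `rmse`, `mape`,
#'   `r2`
#' @export
evaluate_forecast <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred differ in length", call. = FALSE)
  }
  if (length(y_true) < 2L) stop("need at least 2 observations", call. = FALSE)
  if (any(!is.finite(y_true)) || any(!is.finite(y_pred))) {
    stop("non-finite values in inputs", call. = FALSE)
  }
  zero <- which(y_true == 0)
  if (length(zero) > 0L) {
    stop("MAPE undefined: y_true is zero at index ",
         paste(zero, collapse = ", "), call. = FALSE)
  }
  if (stats::var(y_true) == 0) {
    stop("R-squared undefined: y_true has zero variance", call. = FALSE)
  }
  err <- y_true - y_pred
  mse <- mean(err^2)
  structure(list(mse = mse, mae = mean(abs(err)), rmse = sqrt(mse),
                 mape = 100 * mean(abs(err / y_true)),
                 r2 = 1 - sum(err^2) / sum((y_true - mean(y_true))^2)),
            class = "regression_metrics")
}

#' @export
print.regression_metrics <- function(x, ...) {
  cat(sprintf("MSE %.4f | MAE %.4f | RMSE %.4f | MAPE %.4f%% | R2 %.4f\n",
              x$mse, x$mae, x$rmse, x$mape, x$r2))
  invisible(x)
}

#' Hybrid linear + neural forecast of panel series
#'
#' The hybrid forecaster treats each series as the sum of a linear and a
#' nonlinear component. Per series: (1) Holt smoothing is fitted on the
#' training span and extrapolated over the test span and future horizon;
#' (2) the actual training values concatenated with the extrapolation are
#' smoothed again, manufacturing additional one-step predictions ("new
#' samples") beyond the short observed record; (3) one-step residuals
#' (actual minus smoothed prediction) on the training span are pooled
#' across all series into sliding windows and a residual network is trained
#' on them; (4) the hybrid forecast is the Holt forecast plus the
#' recursively predicted residual at every lead. Metrics for the smoother
#' alone and for the hybrid are computed on the held-out test span, pooled
#' across series (per-series metrics are also returned where the test span
#' has at least 2 points).
#'
#' @param series named list of numeric vectors (or single vector, or matrix
#'   with one series per row), all observed over `years`
#' @param years integer vector of calendar years labelling the columns of
#'   every series
#' @param train_end last year of the training span
#' @param test_end last year of the test span (`train_end < test_end <=
#'   max(years)`)
#' @param horizon years to forecast beyond the last observed year
#' @param w residual window length (default 3)
#' @param alpha,beta Holt weights, or `"optimize"` (default)
#' @param dnn_config list overriding [fit_residual_dnn()] defaults
#'   (`hidden`, `epochs`, `learning_rate`)
#' @param seed seed controlling network initialisation
#' @return a `forecast_result` list: per-method (`ets`, `ets_dnn`) test
#'   predictions and future forecasts per series, pooled
#'   [evaluate_forecast()] metrics on the test span, per-series Holt
#'   states, the residual model, and metadata recording the sample
#'   augmentation reading used in step (2)
#' @export
ets_dnn_forecast <- function(series, years, train_end, test_end,
                             horizon = 0L, w = 3L, alpha = "optimize",
                             beta = "optimize", dnn_config = list(),
                             seed = 1L) {
  if (is.matrix(series)) {
    ids <- rownames(series)
    if (is.null(ids)) ids <- as.character(seq_len(nrow(series)))
    series <- stats::setNames(lapply(seq_len(nrow(series)),
                                     function(i) series[i, ]), ids)
  }
  if (!is.list(series)) series <- list(series = as.numeric(series))
  if (is.null(names(series))) names(series) <- as.character(seq_along(series))
  years <- as.integer(years)
  stopifnot(all(vapply(series, length, integer(1)) == length(years)))
  if (!train_end %in% years) stop("train_end outside panel years", call. = FALSE)
  if (test_end <= train_end || !test_end %in% years) {
    stop("test span is empty: need train_end < test_end within the panel",
         call. = FALSE)
  }
  train_idx <- which(years <= train_end)
  test_idx <- which(years > train_end & years <= test_end)
  if (length(train_idx) < 3L) stop("training span too short", call. = FALSE)
  n_test <- length(test_idx)
  total_ahead <- n_test + horizon

  states <- list(); ets_ahead <- list(); resid_series <- list()
  last_windows <- list()
  for (id in names(series)) {
    x <- series[[id]]
    state <- holt_fit(x[train_idx], alpha = alpha, beta = beta)
    ahead <- holt_forecast(state, total_ahead)
    # step (2): smooth actual train values + projection to manufacture
    # one-step predictions over the extended record
    extended <- c(x[train_idx], ahead)
    ext_state <- .holt_run(extended, state$alpha, state$beta)
    resid <- extended - c(NA_real_, ext_state$fitted[-length(extended)])
    resid <- resid[-1L]                     # residual at positions 2..end
    states[[id]] <- state
    ets_ahead[[id]] <- ahead
    resid_series[[id]] <- resid[seq_len(length(train_idx) - 1L)]
    last_windows[[id]] <- utils::tail(resid_series[[id]], w)
  }

  windows <- make_windows(resid_series, w)
  cfg <- utils::modifyList(list(hidden = c(32L, 32L), epochs = 500L,
                                learning_rate = 0.01), dnn_config)
  dnn <- fit_residual_dnn(windows, hidden = cfg$hidden, epochs = cfg$epochs,
                          learning_rate = cfg$learning_rate, seed = seed)

  future_years <- if (horizon > 0) seq(test_end + 1L, by = 1L,
                                       length.out = horizon) else integer(0)
  per_series <- list()
  y_true_all <- y_ets_all <- y_hyb_all <- numeric(0)
  for (id in names(series)) {
    resid_pred <- predict_residuals(dnn, last_windows[[id]], total_ahead)
    ets_fc <- ets_ahead[[id]]
    hyb_fc <- ets_fc + resid_pred
    truth <- series[[id]][test_idx]
    per_series[[id]] <- list(
      test_years = years[test_idx], test_actual = truth,
      ets_test = ets_fc[seq_len(n_test)], hybrid_test = hyb_fc[seq_len(n_test)],
      future_years = future_years,
      ets_future = if (horizon > 0) ets_fc[n_test + seq_len(horizon)] else numeric(0),
      hybrid_future = if (horizon > 0) hyb_fc[n_test + seq_len(horizon)] else numeric(0),
      residual_pred = resid_pred,
      metrics = if (n_test >= 2L && stats::var(truth) > 0 && all(truth != 0)) {
        list(ets = evaluate_forecast(truth, ets_fc[seq_len(n_test)]),
             ets_dnn = evaluate_forecast(truth, hyb_fc[seq_len(n_test)]))
      } else NULL)
    y_true_all <- c(y_true_all, truth)
    y_ets_all <- c(y_ets_all, ets_fc[seq_len(n_test)])
    y_hyb_all <- c(y_hyb_all, hyb_fc[seq_len(n_test)])
  }

  metrics <- list(ets = evaluate_forecast(y_true_all, y_ets_all),
                  ets_dnn = evaluate_forecast(y_true_all, y_hyb_all))
  structure(list(per_series = per_series, metrics = metrics,
                 states = states, residual_model = dnn,
                 train_end = train_end, test_end = test_end,
                 horizon = horizon, w = w, seed = seed,
                 metadata = list(
                   sample_augmentation = paste(
                     "one-step residuals taken from Holt smoothing of the",
                     "concatenated actual-plus-projected series"))),
            class = "forecast_result")
}

#' @export
print.forecast_result <- function(x, ...) {
  cat(sprintf("forecast_result: %d series, train to %d, test to %d, horizon %d\n",
              length(x$per_series), x$train_end, x$test_end, x$horizon))
  cat("test metrics (pooled):\n")
  for (m in names(x$metrics)) {
    cat(sprintf("  %-8s", m)); print(x$metrics[[m]])
  }
  invisible(x)
}
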