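#' Fit a NARX grip-force decoder
#'
#' The central modelling function of the package: fits the nonlinear
#' autoregressive model with exogenous inputs
#' \deqn{y(t) = f(u(t), u(t-1), \ldots, u(t-D),\; y(t-1), \ldots, y(t-D))}
#' where `u(t)` is the multi-channel preprocessed sEMG envelope, `y(t)` the
#' measured grip force, `D` the shared delay order, and `f` a feed-forward
#' network with tanh hidden layers and a linear output. Training is
#' teacher-forced (series-parallel): the delay line holds measured force,
#' and the mean squared one-step error is minimized by the chosen method.
#'
#' @param data A [grip_dataset()], a `"grip_sim"` (preprocessed with
#'   defaults), or a data frame with a `force` column.
#' @param delay Delay order `D` applied to both input and output taps.
#' @param hidden Hidden-layer widths; a single number gives one hidden
#'   layer (the usual configuration), `integer(0)` a linear model.
#' @param method Training algorithm: `"cg"` (nonlinear conjugate gradient,
#'   the default -- fast and resistant to overfitting), `"lm"`
#'   (Levenberg--Marquardt, aggressive on the training loss), or `"brsgd"`
#'   (Bayesian-regularized stochastic gradient descent).
#' @param control A [narx_control()].
#' @param include_current Include the current input `u(t)` in the
#'   regressor.
#' @param init_scale Weight-initialization scale.
#' @param scale_data Standardize inputs and target (z-score, computed on
#'   the training data) before training and invert the scaling on
#'   prediction. Strongly recommended: grip force is O(100 N) while the
#'   EMG envelope is O(1), and training on raw units conditions the
#'   problem badly. All reported fits and metrics are on the original
#'   newton scale.
#' @param seed Seed for the weight initialization.
#' @return An object of class `"narx"` with components `network`,
#'   `training` (a `"narx_training"`), `data`, `scaling`, `fitted`
#'   (full-length open-loop fit, `NA` over the first `D` samples),
#'   `residuals`, and `train_metrics`.
#' @seealso [predict.narx()], [compute_metrics()], [run_sweep()],
#'   [compare_trainers()]
#' @examples
#' sim <- simulate_grip(seed = 1)
#' ds <- preprocess_pipeline(sim$emg, sim$force)
#' sp <- split_dataset(ds, test_fraction = 0.3)
#' fit <- narx(sp$train, delay = 5, hidden = 10,
#'             control = narx_control(max_epochs = 50))
#' fit
#' compute_metrics(predict(fit, sp$test), sp$test$force[-(1:5)])
#' @export
narx <- function(data, delay = 5, hidden = 10,
                 method = c("cg", "lm", "brsgd"),
                 control = narx_control(), include_current = TRUE,
                 init_scale = 0.5, scale_data = TRUE, seed = 1) {
  method <- match.arg(method)
  data <- as_grip_dataset(data)
  scaling <- fit_scaling(data, scale_data)
  scaled <- apply_scaling(data, scaling)
  net0 <- narx_network(ncol(data$emg), delay, hidden,
                       include_current = include_current,
                       init_scale = init_scale, seed = seed)
  reg <- build_regressors(scaled, delay, include_current)
  training <- train_network(net0, reg$x, reg$y, method, control)
  pred <- narx_forward(training$network, reg$x) * scaling$y_scale +
    scaling$y_center
  fitted_full <- rep(NA_real_, dataset_length(data))
  fitted_full[reg$t] <- pred
  structure(
    list(network = training$network, training = training, method = method,
         control = control, data = data, scaling = scaling,
         fitted = fitted_full, residuals = fitted_full - data$force,
         train_metrics = compute_metrics(pred, data$force[reg$t]),
         call = match.call()),
    class = "narx"
  )
}

# Training-data standardization shared by fitting and prediction.
fit_scaling <- function(data, scale_data) {
  if (!scale_data) {
    return(list(u_center = rep(0, ncol(data$emg)),
                u_scale = rep(1, ncol(data$emg)),
                y_center = 0, y_scale = 1))
  }
  u_scale <- apply(data$emg, 2, stats::sd)
  u_scale[u_scale == 0] <- 1
  y_scale <- stats::sd(data$force)
  list(u_center = colMeans(data$emg), u_scale = u_scale,
       y_center = mean(data$force),
       y_scale = if (y_scale == 0) 1 else y_scale)
}

apply_scaling <- function(data, s) {
  grip_dataset(sweep(sweep(data$emg, 2, s$u_center), 2, s$u_scale, "/"),
               (data$force - s$y_center) / s$y_scale, data$rate,
               phase = data$phase)
}

#' @export
print.narx <- function(x, ...) {
  cat("NARX grip-force model\n")
  cat(sprintf("  delay %d, hidden [%s], %d parameters, trained by %s\n",
              x$network$delay, paste(x$network$hidden, collapse = ", "),
              narx_n_params(x$network), toupper(x$method)))
  cat(sprintf("  %d epoch(s) (%s); training MSE %.4g, R %.4f\n",
              x$training$epochs, x$training$stop_reason,
              x$train_metrics$mse, x$train_metrics$r))
  invisible(x)
}

#' @export
summary.narx <- function(object, ...) {
  structure(list(fit = object), class = "summary.narx")
}

#' @export
print.summary.narx <- function(x, ...) {
  f <- x$fit
  print(f)
  m <- f$train_metrics
  cat(sprintf("  training metrics: MSE %.4g N^2, RMSE %.4g N, MAE %.4g N, R %.4f (n = %d)\n",
              m$mse, m$rmse, m$mae, m$r, m$n))
  tr <- f$training$loss_trace
  cat(sprintf("  loss trace: %.4g -> %.4g over %d recorded epochs\n",
              tr[1], tr[length(tr)], length(tr) - 1L))
  if (!is.null(f$training$objective_terms)) {
    ot <- f$training$objective_terms
    cat(sprintf("  evidence terms: alpha %.4g, beta %.4g, E_D %.4g, E_W %.4g\n",
                ot$alpha, ot$beta, ot$E_D, ot$E_W))
  }
  invisible(x)
}

#' @export
coef.narx <- function(object, ...) {
  w <- flatten_params(object$network)
  names(w) <- paste0("w", seq_along(w))
  w
}

#' @export
fitted.narx <- function(object, ...) object$fitted

#' @export
residuals.narx <- function(object, ...) object$residuals

#' Predict grip force from a fitted NARX model
#'
#' @param object A fitted `"narx"` model.
#' @param newdata A [grip_dataset()]; defaults to the training data.
#' @param mode `"open"` for one-step-ahead prediction with measured force
#'   in the delay line (the evaluation convention), `"closed"` to feed
#'   predictions back (deployment simulation).
#' @param init Closed-loop initial force history of length `delay`;
#'   defaults to the first `delay` measured force samples of `newdata`.
#' @param ... Unused.
#' @return Numeric vector of predictions for `t = D+1, ..., N`.
#' @export
predict.narx <- function(object, newdata = NULL, mode = c("open", "closed"),
                         init = NULL, ...) {
  mode <- match.arg(mode)
  data <- if (is.null(newdata)) object$data else as_grip_dataset(newdata)
  s <- object$scaling
  scaled <- apply_scaling(data, s)
  if (mode == "open")
    return(predict_open_loop(object$network, scaled) * s$y_scale + s$y_center)
  d <- object$network$delay
  if (is.null(init)) init <- data$force[seq_len(d)]
  pred <- predict_closed_loop(object$network, scaled$emg,
                              (init - s$y_center) / s$y_scale)
  pred * s$y_scale + s$y_center
}

#' Simulate closed-loop force trajectories from a fitted model
#'
#' Runs the model in parallel (closed-loop) mode over the exogenous EMG of
#' `newdata`, optionally adding Gaussian innovations to each fed-back
#' prediction, giving `nsim` stochastic force trajectories.
#'
#' @param object A fitted `"narx"` model.
#' @param nsim Number of trajectories.
#' @param seed Optional seed.
#' @param newdata A [grip_dataset()]; defaults to the training data.
#' @param innovation_sd Standard deviation of the per-step innovations
#'   (0 gives `nsim` identical deterministic trajectories).
#' @param ... Unused.
#' @return A data frame with `nsim` columns of length `N - D`.
#' @export
simulate.narx <- function(object, nsim = 1, seed = NULL, newdata = NULL,
                          innovation_sd = 0, ...) {
  data <- if (is.null(newdata)) object$data else as_grip_dataset(newdata)
  sc <- object$scaling
  scaled <- apply_scaling(data, sc)
  d <- object$network$delay
  n <- dataset_length(data)
  init <- scaled$force[seq_len(d)]
  runs <- with_seed(seed %||% 1L, {
    lapply(seq_len(nsim), function(s) {
      y_scaled <- if (innovation_sd == 0) {
        predict_closed_loop(object$network, scaled$emg, init)
      } else {
        y <- c(init, numeric(n - d))
        u_lags <- if (object$network$include_current) 0:d else 1:d
        sd_scaled <- innovation_sd / sc$y_scale
        for (t in (d + 1L):n) {
          reg <- c(t(scaled$emg[t - u_lags, , drop = FALSE]), y[t - (1:d)])
          y[t] <- narx_forward(object$network, reg) +
            stats::rnorm(1, 0, sd_scaled)
        }
        y[(d + 1L):n]
      }
      y_scaled * sc$y_scale + sc$y_center
    })
  })
  out <- as.data.frame(runs, col.names = paste0("sim_", seq_len(nsim)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Plot a fitted NARX grip-force model
#'
#' Two panels: measured versus fitted force over time, and the one-step
#' residuals.
#'
#' @param x A fitted `"narx"` model.
#' @param newdata Optional [grip_dataset()] to plot instead of the
#'   training data.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.narx <- function(x, newdata = NULL, ...) {
  data <- if (is.null(newdata)) x$data else as_grip_dataset(newdata)
  pred <- predict(x, newdata = data)
  d <- x$network$delay
  tt <- (seq_len(dataset_length(data)) - 1L) / data$rate
  old <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  graphics::plot(tt, data$force, type = "l", xlab = "time (s)",
                 ylab = "force (N)", main = "Measured vs fitted", ...)
  graphics::lines(tt[-seq_len(d)], pred, col = "red")
  graphics::legend("topright", legend = c("measured", "fitted"),
                   col = c("black", "red"), lty = 1, bty = "n")
  graphics::plot(tt[-seq_len(d)], pred - data$force[-seq_len(d)],
                 type = "h", xlab = "time (s)", ylab = "residual (N)",
                 main = "One-step residuals")
  graphics::abline(h = 0, col = "grey")
  invisible(x)
}
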