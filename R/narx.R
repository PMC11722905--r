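# NARX network core: tapped-delay regressors, feed-forward evaluation,
# backpropagated gradients and per-sample Jacobians.
#
# The model is y(t) = f(u(t), u(t-1), ..., u(t-D), y(t-1), ..., y(t-D))
# with u(t) the multi-channel EMG envelope, y(t) the grip force, and f a
# fully-connected network with tanh hidden layers and a linear output.
# The regressor layout [u lags 0..D, y lags 1..D] is the single source of
# truth shared by training, open-loop and closed-loop prediction.

#' Initialize a NARX network
#'
#' Builds the network weights for a given delay order and hidden topology.
#' Weights and biases of each layer are drawn from a seeded uniform
#' distribution on `(-s, s)` with `s = init_scale / sqrt(fan_in)`, keeping
#' initial tanh units in their linear range.
#'
#' @param input_dim Number of exogenous input channels.
#' @param delay Delay order `D` (>= 1); the same order is applied to the
#'   input and the fed-back output.
#' @param hidden Integer vector of hidden-layer widths; `integer(0)` gives a
#'   purely linear (affine) model.
#' @param include_current Include the current input `u(t)` in the regressor
#'   (default `TRUE`).
#' @param init_scale Scale of the initialization; 0 gives all-zero weights.
#' @param seed Integer seed; identical seeds give identical weights.
#' @return An object of class `"narx_network"`.
#' @export
narx_network <- function(input_dim, delay, hidden = 10,
                         include_current = TRUE, init_scale = 0.5, seed = 1) {
  if (!is_count(input_dim)) stopf("input_dim must be a positive integer")
  if (!is_count(delay)) stopf("delay must be a positive integer")
  hidden <- as.integer(hidden)
  if (any(hidden < 1)) stopf("hidden layer widths must be >= 1")
  p0 <- input_dim * (delay + as.integer(include_current)) + delay
  dims <- c(p0, hidden, 1L)
  layers <- with_seed(seed, {
    lapply(seq_len(length(dims) - 1L), function(l) {
      fan_in <- dims[l]
      s <- init_scale / sqrt(fan_in)
      list(W = matrix(stats::runif(dims[l + 1L] * fan_in, -s, s),
                      dims[l + 1L], fan_in),
           b = stats::runif(dims[l + 1L], -s, s))
    })
  })
  structure(
    list(input_dim = as.integer(input_dim), delay = as.integer(delay),
         hidden = hidden, include_current = isTRUE(include_current),
         init_scale = init_scale, seed = as.integer(seed),
         regressor_dim = p0, layers = layers),
    class = "narx_network"
  )
}

#' @export
print.narx_network <- function(x, ...) {
  arch <- paste(c(x$regressor_dim, x$hidden, 1), collapse = "-")
  cat(sprintf(
    "<narx_network> %d input channel(s), delay %d, architecture %s (%d parameters)\n",
    x$input_dim, x$delay, arch, narx_n_params(x)))
  invisible(x)
}

#' Number of trainable parameters
#' @param network A `"narx_network"`.
#' @return Integer parameter count.
#' @export
narx_n_params <- function(network) {
  sum(vapply(network$layers, function(l) length(l$W) + length(l$b), 0))
}

# Flatten weights into a single parameter vector (column-major per layer,
# weights before biases) and back. The flat layout is the optimizer currency.
flatten_params <- function(network) {
  unlist(lapply(network$layers, function(l) c(as.vector(l$W), l$b)),
         use.names = FALSE)
}

unflatten_params <- function(network, w) {
  pos <- 0L
  for (l in seq_along(network$layers)) {
    nw <- length(network$layers[[l]]$W)
    nb <- length(network$layers[[l]]$b)
    network$layers[[l]]$W[] <- w[pos + seq_len(nw)]
    network$layers[[l]]$b <- w[pos + nw + seq_len(nb)]
    pos <- pos + nw + nb
  }
  network
}

#' Build teacher-forced regressor/target pairs from an aligned dataset
#'
#' For every time `t` past the delay order, concatenates the current and
#' lagged inputs with the lagged *measured* outputs (series-parallel /
#' teacher-forced form) and pairs the result with the measured target
#' `y(t)`.
#'
#' @param data A [grip_dataset()] (or anything [as_grip_dataset()] accepts).
#' @param delay Delay order `D`.
#' @param include_current Include `u(t)` itself.
#' @return A list with matrix `x` (`N - D` rows), target vector `y`, and
#'   `t` the original sample indices of the targets.
#' @export
build_regressors <- function(data, delay, include_current = TRUE) {
  data <- as_grip_dataset(data)
  n <- dataset_length(data)
  if (n <= delay)
    stopf("dataset length (%d) must exceed the delay order (%d)", n, delay)
  rows <- (delay + 1L):n
  u_lags <- if (include_current) 0:delay else 1:delay
  blocks <- lapply(u_lags, function(l) data$emg[rows - l, , drop = FALSE])
  yblocks <- lapply(1:delay, function(l) data$force[rows - l])
  x <- cbind(do.call(cbind, blocks), do.call(cbind, yblocks))
  m <- ncol(data$emg)
  colnames(x) <- c(
    unlist(lapply(u_lags, function(l) sprintf("u%d.lag%d", seq_len(m), l))),
    sprintf("y.lag%d", 1:delay))
  list(x = x, y = data$force[rows], t = rows)
}

# Forward pass keeping all layer activations (for backprop). `x` is a
# matrix of regressors, one per row.
forward_pass <- function(network, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != network$regressor_dim)
    stopf("regressor has %d columns; network expects %d",
          ncol(x), network$regressor_dim)
  acts <- vector("list", length(network$layers) + 1L)
  acts[[1L]] <- x
  nl <- length(network$layers)
  for (l in seq_len(nl)) {
    lay <- network$layers[[l]]
    z <- tcrossprod(acts[[l]], lay$W)
    z <- sweep(z, 2L, lay$b, "+")
    acts[[l + 1L]] <- if (l < nl) tanh(z) else z # linear output
  }
  acts
}

#' Evaluate the network on regressors
#'
#' @param network A `"narx_network"`.
#' @param x Regressor vector or matrix (one regressor per row).
#' @return Numeric vector of predictions, one per regressor.
#' @export
narx_forward <- function(network, x) {
  acts <- forward_pass(network, x)
  as.numeric(acts[[length(acts)]])
}

#' One-step-ahead (open-loop, series-parallel) prediction
#'
#' Predicts `y(t)` for every `t` past the delay order using the *measured*
#' force history in the feedback taps -- the mode used for training and for
#' the reported fit metrics.
#'
#' @param network A `"narx_network"`.
#' @param data A [grip_dataset()].
#' @return Numeric vector of length `N - D`.
#' @export
predict_open_loop <- function(network, data) {
  reg <- build_regressors(data, network$delay, network$include_current)
  narx_forward(network, reg$x)
}

#' Closed-loop (parallel) simulation
#'
#' Feeds the network's own predictions back into the output delay line,
#' simulating deployment where the true force is not measured. Requires an
#' initial force history of length `D`.
#'
#' @param network A `"narx_network"`.
#' @param exog Numeric matrix of exogenous inputs (one column per channel).
#' @param init Numeric vector of length `delay`: the force history for the
#'   first prediction (most recent last). Defaults to zeros.
#' @return Numeric vector of length `nrow(exog) - D` (predictions for
#'   `t = D+1, ..., N`).
#' @export
predict_closed_loop <- function(network, exog, init = NULL) {
  if (is.null(dim(exog))) exog <- matrix(exog, ncol = 1L)
  d <- network$delay
  n <- nrow(exog)
  if (n <= d) stopf("exogenous series must be longer than the delay order")
  if (is.null(init)) init <- numeric(d)
  if (length(init) != d) stopf("init must have length %d", d)
  y <- c(init, numeric(n - d))
  u_lags <- if (network$include_current) 0:d else 1:d
  for (t in (d + 1L):n) {
    reg <- c(t(exog[t - u_lags, , drop = FALSE]), y[t - (1:d)])
    y[t] <- narx_forward(network, reg)
  }
  y[(d + 1L):n]
}

# Backpropagation through the layer stack. `dout` is dL/d(output) per
# sample (length n). Returns the flat gradient.
backprop <- function(network, acts, dout) {
  nl <- length(network$layers)
  grads <- vector("list", nl)
  delta <- matrix(dout, ncol = 1L)
  for (l in rev(seq_len(nl))) {
    a_prev <- acts[[l]]
    grads[[l]] <- c(as.vector(crossprod(delta, a_prev)), colSums(delta))
    if (l > 1L) {
      delta <- (delta %*% network$layers[[l]]$W) * (1 - acts[[l]]^2)
    }
  }
  unlist(grads, use.names = FALSE)
}

#' Mean-squared-error loss over teacher-forced pairs
#' @param network A `"narx_network"`.
#' @param x Regressor matrix.
#' @param y Target vector.
#' @return Scalar MSE.
#' @export
narx_loss <- function(network, x, y) {
  mean((narx_forward(network, x) - y)^2)
}

#' Exact gradient of the MSE loss
#'
#' Backpropagates the mean-squared one-step prediction error through the
#' network, returning the exact gradient with respect to every weight and
#' bias in the flat parameter layout.
#'
#' @param network A `"narx_network"`.
#' @param x Regressor matrix (from [build_regressors()]).
#' @param y Target vector.
#' @return Numeric gradient vector with attribute `"loss"` (the MSE).
#' @export
narx_gradient <- function(network, x, y) {
  acts <- forward_pass(network, x)
  pred <- as.numeric(acts[[length(acts)]])
  e <- pred - y
  g <- backprop(network, acts, 2 * e / length(y))
  attr(g, "loss") <- mean(e^2)
  g
}

#' Per-sample residual Jacobian
#'
#' Computes the matrix `J` with `J[i, j] = d e_i / d w_j` for residuals
#' `e_i = yhat_i - y_i`, the quantity Levenberg--Marquardt and the
#' Gauss--Newton Hessian are built from. By the chain rule
#' `2 J' e / n` equals [narx_gradient()].
#'
#' @param network A `"narx_network"`.
#' @param x Regressor matrix.
#' @param y Target vector.
#' @return A list with `jacobian` (`n x n_params`) and `residuals`.
#' @export
narx_jacobian <- function(network, x, y) {
  acts <- forward_pass(network, x)
  pred <- as.numeric(acts[[length(acts)]])
  n <- length(pred)
  nl <- length(network$layers)
  blocks <- vector("list", nl)
  delta <- matrix(1, n, 1L) # d yhat / d (output pre-activation)
  for (l in rev(seq_len(nl))) {
    a_prev <- acts[[l]]
    q <- ncol(delta)
    p <- ncol(a_prev)
    # column-major W layout: entry (j, k) sits at position j + (k-1) q
    jw <- delta[, rep(seq_len(q), times = p), drop = FALSE] *
      a_prev[, rep(seq_len(p), each = q), drop = FALSE]
    blocks[[l]] <- cbind(jw, delta)
    if (l > 1L) {
      delta <- (delta %*% network$layers[[l]]$W) * (1 - acts[[l]]^2)
    }
  }
  list(jacobian = do.call(cbind, blocks), residuals = pred - y)
}

#' Write a NARX network to a plain-text model file
#'
#' Serializes the configuration and all weights with 17 significant digits
#' so that [read_narx()] reproduces the network bit-exactly.
#'
#' @param network A `"narx_network"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_narx <- function(network, path) {
  lines <- c(
    "narxgrip-model 1",
    sprintf("input_dim %d", network$input_dim),
    sprintf("delay %d", network$delay),
    sprintf("hidden %s", paste(network$hidden, collapse = " ")),
    sprintf("include_current %d", as.integer(network$include_current)),
    sprintf("init_scale %.17g", network$init_scale),
    sprintf("seed %d", network$seed),
    sprintf("params %s", paste(sprintf("%.17g", flatten_params(network)),
                               collapse = " "))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a NARX network from a model file written by [write_narx()]
#' @param path Model file path.
#' @return A `"narx_network"`.
#' @export
read_narx <- function(path) {
  lines <- readLines(path)
  if (!identical(lines[1], "narxgrip-model 1"))
    stopf("'%s' is not a narxgrip model file", path)
  fields <- list()
  for (ln in lines[-1]) {
    parts <- strsplit(ln, " ", fixed = TRUE)[[1]]
    fields[[parts[1]]] <- parts[-1]
  }
  hidden <- as.integer(fields$hidden[nzchar(fields$hidden)])
  net <- narx_network(as.integer(fields$input_dim),
                      as.integer(fields$delay), hidden,
                      include_current = as.integer(fields$include_current) == 1L,
                      init_scale = as.numeric(fields$init_scale),
                      seed = as.integer(fields$seed))
  unflatten_params(net, as.numeric(fields$params))
}
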