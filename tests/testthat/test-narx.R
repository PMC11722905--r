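test_that("network initialization is seeded and correctly shaped", {
  net <- narx_network(3, delay = 5, hidden = 5, seed = 4)
  expect_equal(dim(net$layers[[1]]$W), c(5, 23)) # 3 * 6 + 5 regressors
  expect_equal(dim(net$layers[[2]]$W), c(1, 5))
  expect_identical(narxgrip:::flatten_params(net),
                   narxgrip:::flatten_params(narx_network(3, 5, 5, seed = 4)))
  expect_false(identical(
    narxgrip:::flatten_params(net),
    narxgrip:::flatten_params(narx_network(3, 5, 5, seed = 5))))

  # zero init scale: output equals the (zero) output bias everywhere
  z <- narx_network(3, 5, 5, init_scale = 0, seed = 1)
  expect_equal(narx_forward(z, matrix(stats::rnorm(46), 2, 23)), c(0, 0))

  # flatten/unflatten round trip
  w <- narxgrip:::flatten_params(net)
  expect_equal(length(w), narx_n_params(net))
  net2 <- narxgrip:::unflatten_params(net, w + 1)
  expect_equal(narxgrip:::flatten_params(net2), w + 1)
})

test_that("regressor construction follows the tapped-delay layout", {
  ds <- toy_dataset(n = 100)
  reg <- build_regressors(ds, delay = 5)
  expect_equal(nrow(reg$x), 95)
  expect_equal(ncol(reg$x), 2 * 6 + 5)
  expect_equal(reg$y, ds$force[6:100])
  # spot-check one row: u lags then y lags
  t <- 10
  expect_equal(unname(reg$x[t - 5, ]),
               c(as.vector(t(ds$emg[t - 0:5, ])), ds$force[t - 1:5]))

  # boundary: D = N - 1 leaves exactly one pair
  reg1 <- build_regressors(ds, delay = 99)
  expect_equal(nrow(reg1$x), 1)
  expect_error(build_regressors(ds, delay = 100), "must exceed")

  # constant series give identical regressors
  const <- grip_dataset(matrix(2, 20, 1), rep(3, 20), 10)
  regc <- build_regressors(const, delay = 4)
  expect_true(all(apply(regc$x, 2, function(col) all(col == col[1]))))
})

test_that("forward pass matches an independent brute-force evaluation", {
  for (hidden in list(4L, c(5L, 3L), c(4L, 3L, 2L))) {
    net <- narx_network(3, delay = 2, hidden = hidden, seed = 8)
    reg <- with_seed_(9, stats::rnorm(net$regressor_dim))
    expect_equal(narx_forward(net, reg), brute_force_narx(net, reg),
                 tolerance = 1e-12)
  }
  # all-zero weights with a set bias: prediction equals the bias
  net <- narx_network(1, 1, 2, init_scale = 0, seed = 1)
  net$layers[[2]]$b <- 0.7
  expect_equal(narx_forward(net, c(0.3, -1, 2)), 0.7)
  expect_error(narx_forward(net, c(1, 2)), "regressor")
})

test_that("a linear bypass network can route an input straight through", {
  net <- narx_network(1, delay = 1, hidden = integer(0), init_scale = 0,
                      seed = 1)
  # regressor is [u(t), u(t-1), y(t-1)]; pick out u(t-1)
  net$layers[[1]]$W[1, ] <- c(0, 1, 0)
  expect_equal(narx_forward(net, c(0.3, -2.5, 7)), -2.5)
})

test_that("analytic gradients match central finite differences", {
  ds <- toy_dataset(n = 60)
  for (hidden in list(3L, c(4L, 3L), c(3L, 3L, 2L))) {
    for (d in c(1L, 5L, 20L)) {
      net <- narx_network(2, delay = d, hidden = hidden, seed = d + 1L)
      reg <- build_regressors(ds, d)
      g <- as.numeric(narx_gradient(net, reg$x, reg$y))
      fd <- fd_gradient(net, reg$x, reg$y)
      expect_lt(max(abs(g - fd)) / max(abs(fd)), 1e-5)
    }
  }
})

test_that("gradient properties hold at special points", {
  ds <- toy_dataset(n = 40)
  d <- 2L
  reg <- build_regressors(ds, d)
  # perfect fit: force the target to equal the network output
  net <- narx_network(2, d, 3, seed = 2)
  yhat <- narx_forward(net, reg$x)
  g0 <- narx_gradient(net, reg$x, yhat)
  expect_lt(sqrt(sum(g0^2)), 1e-12)
  # at a zero-weight point predictions are constant, so the output-layer
  # gradient is linear in the targets
  z <- narx_network(2, d, 3, init_scale = 0, seed = 1)
  g1 <- as.numeric(narx_gradient(z, reg$x, reg$y))
  g2 <- as.numeric(narx_gradient(z, reg$x, 2 * reg$y))
  nb <- narx_n_params(z)
  expect_equal(g2[nb], 2 * g1[nb], tolerance = 1e-12) # output bias entry
})

test_that("the Jacobian is consistent with the gradient and with finite
          differences", {
  ds <- toy_dataset(n = 50)
  net <- narx_network(2, 3, c(4, 2), seed = 6)
  reg <- build_regressors(ds, 3)
  jac <- narx_jacobian(net, reg$x, reg$y)
  n <- length(reg$y)
  g_from_j <- 2 * crossprod(jac$jacobian, jac$residuals) / n
  expect_equal(as.numeric(g_from_j), as.numeric(narx_gradient(net, reg$x,
                                                              reg$y)),
               tolerance = 1e-10)
  # single-sample row equals the finite difference of that residual
  x1 <- reg$x[1, , drop = FALSE]
  y1 <- reg$y[1]
  j1 <- narx_jacobian(net, x1, y1)$jacobian[1, ]
  fd <- fd_gradient(net, x1, y1) # d/dw of (e^2) = 2 e de/dw
  e1 <- narx_forward(net, x1) - y1
  expect_equal(as.numeric(j1), fd / (2 * e1), tolerance = 1e-5)
  # zero residuals: J'e vanishes
  jz <- narx_jacobian(net, reg$x, narx_forward(net, reg$x))
  expect_lt(max(abs(crossprod(jz$jacobian, jz$residuals))), 1e-10)
})

test_that("open-loop prediction is causal and definitionally consistent", {
  ds <- toy_dataset(n = 80)
  net <- narx_network(2, 4, 5, seed = 3)
  pred <- predict_open_loop(net, ds)
  reg <- build_regressors(ds, 4)
  expect_equal(pred, narx_forward(net, reg$x), tolerance = 1e-14)
  # causality: predictions up to time t do not change if later samples do
  trunc <- narxgrip:::subset_dataset(ds, 1:50)
  pred_trunc <- predict_open_loop(net, trunc)
  expect_equal(pred_trunc, pred[1:(50 - 4)], tolerance = 1e-14)
})

test_that("closed-loop prediction feeds back its own outputs", {
  # zero-weight network with output bias b: constant b from the first step
  net <- narx_network(2, 3, 4, init_scale = 0, seed = 1)
  net$layers[[2]]$b <- 1.5
  exog <- matrix(stats::rnorm(40), 20, 2)
  cl <- predict_closed_loop(net, exog, init = rep(0, 3))
  expect_equal(cl, rep(1.5, 17))

  # self-consistency: on data the network itself generated closed-loop,
  # open-loop prediction reproduces the same trajectory
  net2 <- narx_network(2, 3, 4, init_scale = 0.3, seed = 9)
  y_cl <- predict_closed_loop(net2, exog, init = rep(0.1, 3))
  ds <- grip_dataset(exog, c(rep(0.1, 3), y_cl), 10)
  expect_equal(predict_open_loop(net2, ds), y_cl, tolerance = 1e-12)

  # bounded weights keep a long closed-loop run finite (tanh squashing)
  long_exog <- matrix(stats::rnorm(2e4), 1e4, 2)
  y_long <- predict_closed_loop(net2, long_exog, init = rep(0, 3))
  expect_true(all(is.finite(y_long)))
})

test_that("model files round-trip bit-exactly", {
  net <- narx_network(3, 5, c(7, 4), init_scale = 0.4, seed = 13)
  path <- tempfile(fileext = ".txt")
  write_narx(net, path)
  back <- read_narx(path)
  expect_identical(narxgrip:::flatten_params(back),
                   narxgrip:::flatten_params(net))
  expect_identical(back$hidden, net$hidden)
  expect_identical(back$delay, net$delay)
  # linear model (no hidden layer) round-trips too
  lin <- narx_network(2, 2, integer(0), seed = 1)
  write_narx(lin, path)
  expect_identical(narxgrip:::flatten_params(read_narx(path)),
                   narxgrip:::flatten_params(lin))
  unlink(path)
})
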