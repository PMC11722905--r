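# A small linear identification problem with a known closed-form solution:
# y(t) = a u(t-1) + b y(t-1) + c. With a linear network (no hidden layer,
# current input excluded) the MSE is an exact quadratic in its 3 parameters
# and ordinary least squares is the oracle.
linear_problem <- function(n = 80, seed = 31) {
  u <- with_seed_(seed, stats::runif(n))
  y <- numeric(n)
  for (t in 2:n) y[t] <- 0.7 * u[t - 1] + 0.4 * y[t - 1] + 0.2
  ds <- grip_dataset(matrix(u, ncol = 1), y, 10)
  reg <- build_regressors(ds, delay = 1, include_current = FALSE)
  ols <- stats::lm(reg$y ~ reg$x)
  w_star <- unname(c(stats::coef(ols)[-1], stats::coef(ols)[1]))
  list(ds = ds, reg = reg, w_star = w_star)
}

lin_net <- function(seed = 1, scale = 0.5) {
  narx_network(1, delay = 1, hidden = integer(0),
               include_current = FALSE, init_scale = scale, seed = seed)
}

test_that("CG solves a quadratic problem exactly in at most n_params steps", {
  lp <- linear_problem()
  net <- lin_net(seed = 2)
  res <- train_cg(net, lp$reg$x, lp$reg$y,
                  narx_control(max_epochs = 3, grad_tol = 0))
  w <- narxgrip:::flatten_params(res$network)
  expect_lt(max(abs(w - lp$w_star)), 1e-8)
  expect_lte(res$epochs, 3)
})

test_that("CG stops immediately at an optimum and its trace never rises", {
  lp <- linear_problem()
  opt <- narxgrip:::unflatten_params(lin_net(), lp$w_star)
  res <- train_cg(opt, lp$reg$x, lp$reg$y,
                  narx_control(max_epochs = 50, grad_tol = 1e-8))
  expect_equal(res$stop_reason, "gradient_tolerance")
  expect_lte(res$epochs, 1)

  # nonlinear fixture: Wolfe steps keep the loss non-increasing
  ds <- toy_dataset(n = 80)
  reg <- build_regressors(ds, 3)
  net <- narx_network(2, 3, 5, seed = 11)
  out <- train_cg(net, reg$x, reg$y, narx_control(max_epochs = 60))
  expect_true(all(diff(out$loss_trace) <= 1e-12))
  expect_lt(out$loss_trace[length(out$loss_trace)], out$loss_trace[1])
})

test_that("both CG variants descend on a nonlinear fixture", {
  ds <- toy_dataset(n = 60)
  reg <- build_regressors(ds, 2)
  for (v in c("polak_ribiere_restart", "fletcher_reeves")) {
    net <- narx_network(2, 2, 4, seed = 5)
    out <- train_cg(net, reg$x, reg$y,
                    narx_control(max_epochs = 40, cg_variant = v))
    expect_lt(out$loss_trace[length(out$loss_trace)],
              0.5 * out$loss_trace[1])
  }
})

test_that("LM reaches the least-squares solution of a linear problem", {
  lp <- linear_problem()
  net <- lin_net(seed = 3)
  res <- train_lm(net, lp$reg$x, lp$reg$y,
                  narx_control(max_epochs = 50, grad_tol = 1e-12))
  w <- narxgrip:::flatten_params(res$network)
  expect_lt(max(abs(w - lp$w_star)), 1e-8)
  # accepted steps only (loss strictly decreased) are few on a quadratic
  accepted <- sum(diff(res$loss_trace) < 0)
  expect_lte(accepted, 5)
})

test_that("LM stops at a zero-residual start and overflows lambda on a
          hopeless problem", {
  lp <- linear_problem()
  opt <- narxgrip:::unflatten_params(lin_net(), lp$w_star)
  res <- train_lm(opt, lp$reg$x, lp$reg$y,
                  narx_control(max_epochs = 20, grad_tol = 1e-8))
  expect_equal(res$stop_reason, "gradient_tolerance")
  expect_equal(res$epochs, 0)

  # at an exact local minimum with nonzero residuals, no step can improve:
  # lambda climbs to overflow
  res2 <- train_lm(opt, lp$reg$x, lp$reg$y,
                   narx_control(max_epochs = 200, grad_tol = 0,
                                lambda_max = 1e6))
  expect_equal(res2$stop_reason, "lambda_overflow")
})

test_that("a heavily damped LM step is a scaled steepest-descent step", {
  ds <- toy_dataset(n = 50)
  reg <- build_regressors(ds, 2)
  net <- narx_network(2, 2, 3, seed = 7)
  jac <- narx_jacobian(net, reg$x, reg$y)
  p <- ncol(jac$jacobian)
  A <- crossprod(jac$jacobian)
  diag(A) <- diag(A) + 1e8
  delta <- solve(A, -crossprod(jac$jacobian, jac$residuals))
  sd_dir <- -crossprod(jac$jacobian, jac$residuals)
  cosine <- sum(delta * sd_dir) /
    sqrt(sum(delta^2) * sum(sd_dir^2))
  expect_gt(cosine, 1 - 1e-6)
})

test_that("full-batch unregularized BRSGD is plain gradient descent", {
  ds <- toy_dataset(n = 40)
  reg <- build_regressors(ds, 2)
  net <- narx_network(2, 2, 3, seed = 19)
  lr <- 1e-4
  epochs <- 25
  res <- train_brsgd(net, reg$x, reg$y,
                     narx_control(max_epochs = epochs, learning_rate = lr,
                                  batch_size = Inf, regularization = "none",
                                  grad_tol = 0, max_step = Inf))
  # hand-rolled deterministic gradient descent on the sum of squared errors
  w <- narxgrip:::flatten_params(net)
  n <- length(reg$y)
  for (k in seq_len(epochs)) {
    g <- narx_gradient(narxgrip:::unflatten_params(net, w), reg$x, reg$y)
    w <- w - lr * n * as.numeric(g)
  }
  expect_lt(max(abs(narxgrip:::flatten_params(res$network) - w)), 1e-10)
})

test_that("BRSGD descends, and evidence-updated hyperparameters stay
          positive", {
  ds <- quick_dataset(seed = 61)
  scaled <- narxgrip:::apply_scaling(ds, narxgrip:::fit_scaling(ds, TRUE))
  reg <- build_regressors(scaled, 3)
  for (ep in c(2L, 10L)) {
    net <- narx_network(3, 3, 5, seed = 23)
    res <- train_brsgd(net, reg$x, reg$y,
                       narx_control(max_epochs = ep,
                                    regularization = "bayesian_evidence"))
    expect_gt(res$objective_terms$alpha, 0)
    expect_gt(res$objective_terms$beta, 0)
    expect_true(all(is.finite(res$loss_trace)))
  }
  net <- narx_network(3, 3, 5, seed = 23)
  res <- train_brsgd(net, reg$x, reg$y,
                     narx_control(max_epochs = 40,
                                  regularization = "bayesian_evidence"))
  expect_lt(res$loss_trace[length(res$loss_trace)], res$loss_trace[1])
})

test_that("a dominant weight penalty shrinks the weights", {
  ds <- toy_dataset(n = 40)
  reg <- build_regressors(ds, 2)
  net <- narx_network(2, 2, 4, seed = 3)
  w0 <- sqrt(sum(narxgrip:::flatten_params(net)^2))
  res <- train_brsgd(net, reg$x, reg$y,
                     narx_control(max_epochs = 50, learning_rate = 1e-4,
                                  regularization = "fixed_l2",
                                  l2_lambda = 1e4, grad_tol = 0))
  w1 <- sqrt(sum(narxgrip:::flatten_params(res$network)^2))
  expect_lt(w1, w0)
})

test_that("Bayesian regularization does not hurt test error relative to
          unregularized SGD", {
  # noisy force sensor and generous capacity: the regime where the weight
  # penalty is supposed to pay off
  res <- sapply(1:10, function(s) {
    sim <- simulate_grip(protocol = quick_protocol(), force_noise_sd = 8,
                         seed = 500 + s)
    ds <- preprocess_pipeline(sim$emg, sim$force)
    scaled <- narxgrip:::apply_scaling(ds, narxgrip:::fit_scaling(ds, TRUE))
    sp <- split_dataset(scaled, test_fraction = 0.3)
    regtr <- build_regressors(sp$train, 3)
    regte <- build_regressors(sp$test, 3)
    net <- narx_network(3, 3, 20, seed = s)
    args <- list(max_epochs = 200, learning_rate = 1e-3, batch_size = 16,
                 seed = s)
    plain <- train_brsgd(net, regtr$x, regtr$y,
                         do.call(narx_control,
                                 c(args, regularization = "none")))
    bayes <- train_brsgd(net, regtr$x, regtr$y,
                         do.call(narx_control,
                                 c(args,
                                   regularization = "bayesian_evidence")))
    mse <- function(r) mean((narx_forward(r$network, regte$x) - regte$y)^2)
    c(plain = mse(plain), bayes = mse(bayes))
  })
  expect_lte(stats::median(res["bayes", ]), stats::median(res["plain", ]))
})

test_that("all trainers reduce the training MSE on the standard fixture", {
  ds <- quick_dataset(seed = 71)
  scaled <- narxgrip:::apply_scaling(ds, narxgrip:::fit_scaling(ds, TRUE))
  reg <- build_regressors(scaled, 3)
  for (m in c("cg", "lm", "brsgd")) {
    net <- narx_network(3, 3, 5, seed = 2)
    res <- narxgrip:::train_network(net, reg$x, reg$y, m,
                                    narx_control(max_epochs = 30))
    expect_lt(res$loss_trace[length(res$loss_trace)], res$loss_trace[1])
  }
})

test_that("compare_trainers reports a reproducible side-by-side table", {
  ds <- quick_dataset(seed = 81)
  sp <- split_dataset(ds, test_fraction = 0.3)
  ctrl <- narx_control(max_epochs = 20)
  tab <- compare_trainers(sp$train, sp$test, delay = 3, hidden = 5,
                          default_control = ctrl, seed = 1)
  expect_equal(tab$method, c("cg", "lm", "brsgd"))
  expect_true(all(c("train_mse", "train_rmse", "train_mae", "train_r",
                    "test_mse", "test_rmse", "test_mae", "test_r",
                    "time_s", "epochs", "stop_reason") %in% names(tab)))
  tab2 <- compare_trainers(sp$train, sp$test, delay = 3, hidden = 5,
                           default_control = ctrl, seed = 1)
  expect_identical(tab$test_mse, tab2$test_mse)
  # LM is at least as aggressive as CG on the training set
  expect_lte(tab$train_mse[tab$method == "lm"],
             tab$train_mse[tab$method == "cg"])
})
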