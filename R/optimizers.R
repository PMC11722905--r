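# The three training strategies behind narx(): nonlinear conjugate gradient
# with a strong-Wolfe line search, Levenberg-Marquardt, and
# Bayesian-regularized stochastic gradient descent with evidence
# re-estimation of the data/penalty weights.

#' Training control parameters
#'
#' Collects every tunable of the three trainers. Only the fields relevant
#' to the chosen method are used.
#'
#' @param max_epochs Epoch / iteration budget (default 1000).
#' @param grad_tol Stop when the gradient 2-norm falls below this.
#' @param learning_rate BRSGD step size. The objective is a *sum* of
#'   squared errors, so its gradient grows with the sample count; the
#'   default is sized for a few hundred standardized samples.
#' @param batch_size BRSGD mini-batch size (`Inf` for full batch).
#' @param max_step Norm clip on a single BRSGD parameter update (`Inf`
#'   disables clipping).
#' @param lambda_init,lambda_factor,lambda_max Levenberg--Marquardt damping
#'   schedule: initial lambda, multiplicative factor, overflow bound.
#' @param cg_variant `"polak_ribiere_restart"` (PR+ with periodic and
#'   non-descent restarts) or `"fletcher_reeves"`.
#' @param wolfe_c1,wolfe_c2 Strong-Wolfe line-search constants.
#' @param regularization BRSGD penalty mode: `"none"`,
#'   `"bayesian_evidence"` (alpha/beta re-estimated each epoch) or
#'   `"fixed_l2"`.
#' @param l2_lambda Fixed penalty weight when `regularization = "fixed_l2"`
#'   (used as alpha with beta frozen at 1).
#' @param alpha_init,beta_init Initial penalty / data weights for BRSGD.
#' @param alpha_max Clamp for alpha when the weight norm collapses.
#' @param evidence_warmup Epochs of plain descent before the first
#'   evidence update. Re-estimating immediately is counter-productive:
#'   while the weights are still near their small initialization,
#'   `E_W` is tiny and `alpha = gamma / (2 E_W)` explodes, freezing the
#'   network before it has fit anything.
#' @param seed Seed for the BRSGD shuffling stream.
#' @return An object of class `"narx_control"`.
#' @export
narx_control <- function(max_epochs = 1000, grad_tol = 1e-6,
                         learning_rate = 1e-5, batch_size = 32,
                         max_step = 1,
                         lambda_init = 1e-3, lambda_factor = 10,
                         lambda_max = 1e10,
                         cg_variant = c("polak_ribiere_restart",
                                        "fletcher_reeves"),
                         wolfe_c1 = 1e-4, wolfe_c2 = 0.1,
                         regularization = c("none", "bayesian_evidence",
                                            "fixed_l2"),
                         l2_lambda = 1e-3, alpha_init = 1e-3, beta_init = 1,
                         alpha_max = 1e6, evidence_warmup = 10, seed = 1) {
  if (!is_count(max_epochs)) stopf("max_epochs must be a positive integer")
  if (!is_number(learning_rate) || learning_rate <= 0)
    stopf("learning_rate must be > 0")
  if (!is_number(lambda_init) || lambda_init <= 0)
    stopf("lambda_init must be > 0")
  structure(
    list(max_epochs = as.integer(max_epochs), grad_tol = grad_tol,
         learning_rate = learning_rate, batch_size = batch_size,
         max_step = max_step,
         lambda_init = lambda_init, lambda_factor = lambda_factor,
         lambda_max = lambda_max, cg_variant = match.arg(cg_variant),
         wolfe_c1 = wolfe_c1, wolfe_c2 = wolfe_c2,
         regularization = match.arg(regularization), l2_lambda = l2_lambda,
         alpha_init = alpha_init, beta_init = beta_init,
         alpha_max = alpha_max, evidence_warmup = evidence_warmup,
         seed = as.integer(seed)),
    class = "narx_control"
  )
}

training_result <- function(network, loss_trace, stop_reason, epochs,
                            extra = list()) {
  structure(c(list(network = network, loss_trace = loss_trace,
                   stop_reason = stop_reason, epochs = epochs), extra),
            class = "narx_training")
}

#' @export
print.narx_training <- function(x, ...) {
  cat(sprintf(
    "<narx_training> %d epoch(s), stop: %s, MSE %.6g -> %.6g\n",
    x$epochs, x$stop_reason, x$loss_trace[1],
    x$loss_trace[length(x$loss_trace)]))
  invisible(x)
}

# Strong-Wolfe line search (bracket + zoom with quadratic interpolation,
# Nocedal & Wright Alg. 3.5/3.6). `fg` maps a parameter vector to
# list(f, g). Exact on quadratics: the first interpolation lands on the
# one-dimensional minimizer, where the curvature condition holds trivially.
wolfe_line_search <- function(fg, w, d, f0, g0, c1 = 1e-4, c2 = 0.1,
                              a_init = 1, max_iter = 30) {
  dphi0 <- sum(g0 * d)
  if (dphi0 >= 0) return(list(ok = FALSE))
  phi <- function(a) {
    r <- fg(w + a * d)
    list(a = a, f = r$f, df = sum(r$g * d), g = r$g)
  }
  quad_min <- function(a_lo, f_lo, df_lo, a_hi, f_hi) {
    denom <- 2 * (f_hi - f_lo - df_lo * (a_hi - a_lo))
    if (denom == 0) return((a_lo + a_hi) / 2)
    a_lo - df_lo * (a_hi - a_lo)^2 / denom
  }
  zoom <- function(lo, hi) {
    for (i in seq_len(max_iter)) {
      a <- quad_min(lo$a, lo$f, lo$df, hi$a, hi$f)
      span <- abs(hi$a - lo$a)
      if (!is.finite(a) || a <= min(lo$a, hi$a) + 1e-12 * span ||
          a >= max(lo$a, hi$a) - 1e-12 * span)
        a <- (lo$a + hi$a) / 2
      e <- phi(a)
      if (e$f > f0 + c1 * a * dphi0 || e$f >= lo$f) {
        hi <- e
      } else {
        if (abs(e$df) <= -c2 * dphi0)
          return(list(ok = TRUE, a = a, f = e$f, g = e$g))
        if (e$df * (hi$a - lo$a) >= 0) hi <- lo
        lo <- e
      }
      if (abs(hi$a - lo$a) < 1e-16) break
    }
    if (lo$f < f0) return(list(ok = TRUE, a = lo$a, f = lo$f, g = lo$g))
    list(ok = FALSE)
  }
  prev <- list(a = 0, f = f0, df = dphi0, g = g0)
  a <- a_init
  for (i in seq_len(max_iter)) {
    e <- phi(a)
    if (e$f > f0 + c1 * a * dphi0 || (i > 1 && e$f >= prev$f))
      return(zoom(prev, e))
    if (abs(e$df) <= -c2 * dphi0)
      return(list(ok = TRUE, a = a, f = e$f, g = e$g))
    if (e$df >= 0) return(zoom(e, prev))
    prev <- e
    a <- 2.5 * a
  }
  list(ok = FALSE)
}

#' Train by nonlinear conjugate gradient
#'
#' Full-batch nonlinear CG on the teacher-forced MSE. Directions use
#' Polak--Ribiere+ (non-negative beta) with a restart to steepest descent
#' every `n_params` iterations or whenever the new direction fails to be a
#' descent direction; Fletcher--Reeves is available via the control. Step
#' lengths satisfy the strong Wolfe conditions, so the loss trace is
#' non-increasing. On a quadratic objective (linear network) the
#' interpolating line search is exact and the method reduces to linear CG,
#' converging in at most `n_params` iterations.
#'
#' @param network Initial `"narx_network"`.
#' @param x,y Regressor matrix and target vector ([build_regressors()]).
#' @param control A [narx_control()].
#' @return A `"narx_training"` result: trained network, per-epoch loss
#'   trace (element 1 is the pre-training loss), stop reason, epoch count.
#' @export
train_cg <- function(network, x, y, control = narx_control()) {
  fg <- function(w) {
    net <- unflatten_params(network, w)
    g <- narx_gradient(net, x, y)
    list(f = attr(g, "loss"), g = as.numeric(g))
  }
  w <- flatten_params(network)
  np <- length(w)
  cur <- fg(w)
  f <- cur$f
  g <- cur$g
  if (!is.finite(f)) stopf("non-finite loss at the initial point")
  trace <- f
  d <- -g
  stop_reason <- "max_epochs"
  epochs <- 0L
  a_prev <- NULL
  for (k in seq_len(control$max_epochs)) {
    gn <- sqrt(sum(g^2))
    if (gn <= control$grad_tol) {
      stop_reason <- "gradient_tolerance"
      break
    }
    a_init <- if (is.null(a_prev)) min(1, 1 / gn) else a_prev
    ls <- wolfe_line_search(fg, w, d, f, g, control$wolfe_c1,
                            control$wolfe_c2, a_init = a_init)
    if (!ls$ok && !identical(d, -g)) { # fall back to steepest descent
      d <- -g
      ls <- wolfe_line_search(fg, w, d, f, g, control$wolfe_c1,
                              control$wolfe_c2, a_init = min(1, 1 / gn))
    }
    if (!ls$ok) {
      stop_reason <- "line_search_failure"
      break
    }
    w <- w + ls$a * d
    g_new <- ls$g
    if (!is.finite(ls$f)) stopf("non-finite loss during CG training")
    beta <- switch(control$cg_variant,
      polak_ribiere_restart = max(0, sum(g_new * (g_new - g)) / sum(g * g)),
      fletcher_reeves = sum(g_new^2) / sum(g^2))
    d_new <- -g_new + beta * d
    if (k %% np == 0 || sum(d_new * g_new) >= 0) d_new <- -g_new
    # scale the next initial step to keep the directional slope comparable
    a_prev <- ls$a * sum(g * d) / sum(g_new * d_new)
    if (!is.finite(a_prev) || a_prev <= 0) a_prev <- NULL
    f <- ls$f
    g <- g_new
    d <- d_new
    trace <- c(trace, f)
    epochs <- k
  }
  training_result(unflatten_params(network, w), trace, stop_reason, epochs,
                  list(gradient_norm = sqrt(sum(g^2))))
}

#' Train by Levenberg--Marquardt
#'
#' Damped Gauss--Newton on the residual vector: each iteration solves
#' `(J'J + lambda I) delta = -J'e` and accepts the step only if the MSE
#' decreases, dividing the damping by `lambda_factor` on acceptance and
#' multiplying on rejection. Large damping turns the step into scaled
#' steepest descent; small damping recovers Gauss--Newton. Stops on the
#' gradient tolerance, the epoch budget, or damping overflow.
#'
#' @inheritParams train_cg
#' @return A `"narx_training"` result (stop reason one of
#'   `"gradient_tolerance"`, `"max_epochs"`, `"lambda_overflow"`).
#' @export
train_lm <- function(network, x, y, control = narx_control()) {
  w <- flatten_params(network)
  np <- length(w)
  n <- length(y)
  jac <- narx_jacobian(unflatten_params(network, w), x, y)
  e <- jac$residuals
  J <- jac$jacobian
  f <- mean(e^2)
  if (!is.finite(f)) stopf("non-finite loss at the initial point")
  g <- 2 * crossprod(J, e) / n
  lambda <- control$lambda_init
  trace <- f
  stop_reason <- "max_epochs"
  epochs <- 0L
  for (k in seq_len(control$max_epochs)) {
    if (sqrt(sum(g^2)) <= control$grad_tol) {
      stop_reason <- "gradient_tolerance"
      break
    }
    A <- crossprod(J)
    diag(A) <- diag(A) + lambda
    delta <- tryCatch(solve(A, -crossprod(J, e)),
                      error = function(err) NULL)
    f_new <- if (is.null(delta)) Inf else
      narx_loss(unflatten_params(network, w + as.numeric(delta)), x, y)
    if (is.finite(f_new) && f_new < f) {
      w <- w + as.numeric(delta)
      jac <- narx_jacobian(unflatten_params(network, w), x, y)
      e <- jac$residuals
      J <- jac$jacobian
      f <- f_new
      g <- 2 * crossprod(J, e) / n
      lambda <- lambda / control$lambda_factor
    } else {
      lambda <- lambda * control$lambda_factor
      if (lambda > control$lambda_max) {
        stop_reason <- "lambda_overflow"
        epochs <- k
        trace <- c(trace, f)
        break
      }
    }
    trace <- c(trace, f)
    epochs <- k
  }
  training_result(unflatten_params(network, w), trace, stop_reason, epochs,
                  list(lambda = lambda, gradient_norm = sqrt(sum(g^2))))
}

#' Train by Bayesian-regularized stochastic gradient descent
#'
#' Mini-batch SGD on the regularized objective
#' `beta * E_D + alpha * E_W` with `E_D` the sum of squared one-step errors
#' and `E_W = ||w||^2 / 2`. With `regularization = "bayesian_evidence"` the
#' hyperparameters are re-estimated after every epoch by the evidence
#' approximation: the effective number of parameters
#' `gamma = n_params - alpha * tr((beta H + alpha I)^{-1})` (with `H` the
#' Gauss--Newton Hessian of `E_D`) sets `alpha = gamma / (2 E_W)` and
#' `beta = (n - gamma) / (2 E_D)`. With `"fixed_l2"` the weights are
#' penalized at a frozen `l2_lambda`; with `"none"` the method reduces to
#' plain (mini-batch) gradient descent on the sum of squared errors.
#' Shuffling is seeded; indices within a batch are kept sorted so a
#' full-batch run is floating-point identical to deterministic gradient
#' descent.
#'
#' @inheritParams train_cg
#' @return A `"narx_training"` result; the extra field `objective_terms`
#'   holds the final `alpha`, `beta`, `E_D` and `E_W`.
#' @export
train_brsgd <- function(network, x, y, control = narx_control()) {
  w <- flatten_params(network)
  np <- length(w)
  n <- length(y)
  mode <- control$regularization
  alpha <- switch(mode, none = 0, fixed_l2 = control$l2_lambda,
                  bayesian_evidence = control$alpha_init)
  beta <- switch(mode, none = 1, fixed_l2 = 1,
                 bayesian_evidence = control$beta_init)
  bsize <- min(control$batch_size, n)
  trace <- narx_loss(unflatten_params(network, w), x, y)
  stop_reason <- "max_epochs"
  epochs <- 0L
  e_d <- NA_real_
  e_w <- NA_real_
  with_seed(control$seed, {
    for (epoch in seq_len(control$max_epochs)) {
      net <- unflatten_params(network, w)
      g_full <- narx_gradient(net, x, y) # MSE gradient
      # n * MSE gradient = SSE gradient
      gobj <- beta * n * as.numeric(g_full) + alpha * w
      if (sqrt(sum(gobj^2)) <= control$grad_tol) {
        stop_reason <- "gradient_tolerance"
        break
      }
      idx <- if (bsize >= n) seq_len(n) else sample.int(n)
      starts <- seq(1L, n, by = bsize)
      for (s in starts) {
        b <- sort(idx[s:min(s + bsize - 1L, n)])
        net <- unflatten_params(network, w)
        gb <- narx_gradient(net, x[b, , drop = FALSE], y[b])
        # (n/|b|) * |b| * MSE-batch-grad = full-data SSE gradient estimate
        g_d <- n * as.numeric(gb)
        # step on the scale-invariant form E_D + (alpha/beta) E_W: same
        # minimizer as beta E_D + alpha E_W, but the step size does not
        # blow up when the evidence update rescales beta
        step <- control$learning_rate * (g_d + (alpha / beta) * w)
        if (!all(is.finite(step)))
          stopf("non-finite gradient during BRSGD training")
        sn <- sqrt(sum(step^2))
        if (sn > control$max_step) step <- step * (control$max_step / sn)
        w <- w - step
      }
      net <- unflatten_params(network, w)
      if (mode == "bayesian_evidence" && epoch > control$evidence_warmup) {
        jac <- narx_jacobian(net, x, y)
        e_d <- sum(jac$residuals^2)
        e_w <- sum(w^2) / 2
        H <- 2 * crossprod(jac$jacobian)
        M <- beta * H
        diag(M) <- diag(M) + alpha
        tr_inv <- tryCatch(sum(diag(solve(M))), error = function(err) NA)
        if (is.finite(tr_inv)) {
          gamma <- np - alpha * tr_inv
          alpha <- if (e_w <= 1e-300) control$alpha_max
                   else min(max(gamma / (2 * e_w), 1e-12), control$alpha_max)
          beta <- min(max((n - gamma) / (2 * max(e_d, 1e-300)), 1e-12), 1e12)
        }
      } else {
        e_d <- sum((narx_forward(net, x) - y)^2)
        e_w <- sum(w^2) / 2
      }
      trace <- c(trace, e_d / n)
      epochs <- epoch
    }
  })
  training_result(unflatten_params(network, w), trace, stop_reason, epochs,
                  list(objective_terms = list(alpha = alpha, beta = beta,
                                              E_D = e_d, E_W = e_w)))
}

train_network <- function(network, x, y, method, control) {
  switch(method,
    cg = train_cg(network, x, y, control),
    lm = train_lm(network, x, y, control),
    brsgd = train_brsgd(network, x, y, control),
    stopf("unknown training method '%s'", method)
  )
}
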