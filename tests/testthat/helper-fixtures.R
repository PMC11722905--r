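# Shared fixtures and independent oracles for the test suite.

# Small, quick simulated session: shorter holds than the default protocol
# so unit tests stay fast, same structure.
quick_protocol <- function() {
  grip_protocol(hold = 3, rest = 2, repetitions = 2, ramp = 0.5,
                initial_rest = 1)
}

quick_sim <- function(seed = 1, noise = noise_config()) {
  simulate_grip(protocol = quick_protocol(), noise = noise, seed = seed)
}

quick_dataset <- function(seed = 1) {
  sim <- quick_sim(seed)
  preprocess_pipeline(sim$emg, sim$force, phase = sim$activation$phase)
}

# A tiny aligned dataset from raw numbers (no preprocessing involved).
toy_dataset <- function(n = 60, seed = 42, m = 2) {
  u <- matrix(with_seed_(seed, stats::runif(n * m)), n, m)
  f <- as.numeric(stats::filter(0.6 * u[, 1] + 0.3 * u[, m], 0.5,
                                method = "recursive", init = 0))
  grip_dataset(u, f, rate = 10)
}

with_seed_ <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# Independent brute-force NARX evaluation: plain R loops over layers and
# units, no matrix algebra shared with the package implementation.
brute_force_narx <- function(network, reg) {
  a <- as.numeric(reg)
  nl <- length(network$layers)
  for (l in seq_len(nl)) {
    W <- network$layers[[l]]$W
    b <- network$layers[[l]]$b
    z <- numeric(nrow(W))
    for (j in seq_len(nrow(W))) {
      acc <- b[j]
      for (k in seq_len(ncol(W))) acc <- acc + W[j, k] * a[k]
      z[j] <- acc
    }
    a <- if (l < nl) tanh(z) else z
  }
  a[1]
}

# Central finite-difference gradient of the MSE loss.
fd_gradient <- function(network, x, y, h = 1e-6) {
  w <- narxgrip:::flatten_params(network)
  g <- numeric(length(w))
  for (i in seq_along(w)) {
    wp <- w; wp[i] <- w[i] + h
    wm <- w; wm[i] <- w[i] - h
    fp <- narx_loss(narxgrip:::unflatten_params(network, wp), x, y)
    fm <- narx_loss(narxgrip:::unflatten_params(network, wm), x, y)
    g[i] <- (fp - fm) / (2 * h)
  }
  g
}

# Amplitude of a sinusoid at frequency f in a signal, estimated by
# least-squares regression on sin/cos over the middle 60% of the samples
# (avoids zero-phase filter edge transients).
sine_amplitude <- function(x, f, rate) {
  n <- length(x)
  keep <- seq(floor(0.2 * n) + 1, ceiling(0.8 * n))
  tt <- (keep - 1) / rate
  fit <- stats::lm(x[keep] ~ sin(2 * pi * f * tt) + cos(2 * pi * f * tt))
  sqrt(sum(stats::coef(fit)[2:3]^2))
}

# Fraction of spectral power in a frequency band, via the raw periodogram.
band_power_fraction <- function(x, rate, lo, hi) {
  n <- length(x)
  p <- Mod(stats::fft(x - mean(x)))^2
  half <- 2:(floor(n / 2)) # drop DC; one-sided
  freqs <- (half - 1) * rate / n
  sum(p[half][freqs >= lo & freqs <= hi]) / sum(p[half])
}
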