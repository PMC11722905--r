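# Orthogonal discrete wavelet transform (periodized) and threshold denoising.
#
# The decomposition uses circular convolution on a signal reflected out to a
# multiple of 2^level, which makes the analysis/synthesis pair an exact
# orthogonal transform for any input length: reconstruction with untouched
# coefficients returns the input to machine precision.

# Daubechies scaling filters, normalized so sum(h) = sqrt(2), sum(h^2) = 1.
wavelet_filter <- function(family) {
  switch(family,
    haar = c(1, 1) / sqrt(2),
    db2 = c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2)),
    db4 = c(0.23037781330885523, 0.71484657055254153,
            0.63088076792959036, -0.02798376941698385,
            -0.18703481171888114, 0.03084138183598697,
            0.03288301166698295, -0.01059740178499728),
    stopf("unknown wavelet family '%s' (available: haar, db2, db4)", family)
  )
}

# Quadrature-mirror wavelet filter g[k] = (-1)^k h[L-1-k] (k zero-based).
wavelet_qmf <- function(h) {
  L <- length(h)
  rev(h) * (-1)^(0:(L - 1))
}

# One analysis step on an even-length signal (circular convolution).
dwt_step <- function(x, h, g) {
  n <- length(x)
  n2 <- n %/% 2L
  a <- numeric(n2)
  d <- numeric(n2)
  base <- 2L * (0:(n2 - 1L))
  for (k in seq_along(h)) {
    idx <- (base + (k - 1L)) %% n + 1L
    a <- a + h[k] * x[idx]
    d <- d + g[k] * x[idx]
  }
  list(a = a, d = d)
}

# One synthesis step (transpose of the analysis step; exact inverse).
idwt_step <- function(a, d, h, g) {
  n <- 2L * length(a)
  x <- numeric(n)
  base <- 2L * (0:(length(a) - 1L))
  for (k in seq_along(h)) {
    idx <- (base + (k - 1L)) %% n + 1L
    x[idx] <- x[idx] + h[k] * a + g[k] * d
  }
  x
}

# Multi-level decomposition. Details are stored finest scale first.
wavelet_decompose <- function(x, family = "db4", level = 4) {
  if (!is_count(level)) stopf("wavelet level must be a positive integer")
  h <- wavelet_filter(family)
  g <- wavelet_qmf(h)
  n <- length(x)
  block <- 2^level
  m <- ceiling(n / block) * block
  if (m / 2^(level - 1) < length(h))
    stopf("signal too short (%d samples) for %s at level %d", n, family, level)
  pad <- m - n
  if (pad > 0) {
    if (pad > n) stopf("signal too short to pad for level %d", level)
    x <- c(x, x[n - seq_len(pad) + 1L]) # reflect the tail
  }
  details <- vector("list", level)
  a <- x
  for (l in seq_len(level)) {
    st <- dwt_step(a, h, g)
    a <- st$a
    details[[l]] <- st$d
  }
  list(approx = a, details = details, family = family, level = level,
       n = n, pad = pad)
}

wavelet_reconstruct <- function(dec) {
  h <- wavelet_filter(dec$family)
  g <- wavelet_qmf(h)
  a <- dec$approx
  for (l in rev(seq_len(dec$level))) a <- idwt_step(a, dec$details[[l]], h, g)
  a[seq_len(dec$n)]
}

# Stein's unbiased risk estimate threshold for unit-variance coefficients.
sure_threshold <- function(d) {
  n <- length(d)
  ad <- sort(abs(d))
  cum <- cumsum(ad^2)
  # risk of thresholding at t = ad[i]: n - 2*i + cum[i] + (n - i) * ad[i]^2
  risk <- n - 2 * seq_len(n) + cum + (n - seq_len(n)) * ad^2
  ad[which.min(risk)]
}

shrink <- function(d, tau, mode) {
  switch(mode,
    soft = sign(d) * pmax(abs(d) - tau, 0),
    hard = d * (abs(d) > tau),
    stopf("unknown threshold mode '%s'", mode)
  )
}

#' Wavelet-threshold denoising
#'
#' Multi-level orthogonal wavelet decomposition of each channel, shrinkage
#' of the detail coefficients (noise spreads thinly across the wavelet
#' domain while signal energy concentrates in few large coefficients),
#' and reconstruction. The noise scale is estimated robustly from the
#' finest-level details as `median(|d1|) / 0.6745`; the `"universal"` rule
#' applies the threshold `sigma * sqrt(2 * log(N))` at every detail level,
#' while `"sure"` picks a per-level threshold minimizing Stein's unbiased
#' risk estimate (capped at the universal level). Approximation
#' coefficients are never touched.
#'
#' @param x A `"signal_record"`.
#' @param family Wavelet family: `"haar"`, `"db2"` or `"db4"` (default; the
#'   usual choice for surface EMG).
#' @param level Decomposition depth.
#' @param rule Threshold selection rule, `"universal"` or `"sure"`.
#' @param mode `"soft"` (shrink) or `"hard"` (keep-or-kill) thresholding.
#' @param threshold Optional fixed threshold overriding `rule`; `0` returns
#'   the input (perfect reconstruction).
#' @return The denoised `"signal_record"` (same length, rate, channels).
#' @export
wavelet_denoise <- function(x, family = "db4", level = 4,
                            rule = c("universal", "sure"),
                            mode = c("soft", "hard"), threshold = NULL) {
  rule <- match.arg(rule)
  mode <- match.arg(mode)
  map_channels(x, function(ch) {
    dec <- wavelet_decompose(ch, family, level)
    sigma <- stats::median(abs(dec$details[[1]])) / 0.6745
    n <- length(ch)
    univ <- sigma * sqrt(2 * log(n))
    for (l in seq_len(dec$level)) {
      tau <- if (!is.null(threshold)) threshold
      else if (rule == "universal") univ
      else if (sigma <= 0) 0
      else min(univ, sigma * sure_threshold(dec$details[[l]] / sigma))
      dec$details[[l]] <- shrink(dec$details[[l]], tau, mode)
    }
    wavelet_reconstruct(dec)
  })
}
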