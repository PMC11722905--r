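#' Robust outlier removal by thresholding on the scaled MAD
#'
#' Flags, per channel, every sample farther than `k` robust standard
#' deviations (`1.4826 * MAD`) from the channel median -- the signature of
#' impulsive motion artifacts -- and replaces flagged samples by linear
#' interpolation between the nearest valid neighbours (endpoints take the
#' nearest valid value). Signal length is unchanged.
#'
#' @param x A `"signal_record"`.
#' @param k Threshold in multiples of the robust scale (> 0); default 5.
#' @return The cleaned record, with attribute `"n_replaced"` giving the
#'   per-channel count of interpolated samples.
#' @export
remove_outliers <- function(x, k = 5) {
  if (!is_number(k) || k <= 0) stopf("k must be > 0")
  n_replaced <- integer(ncol(x$data))
  out <- x
  for (j in seq_len(ncol(x$data))) {
    ch <- x$data[, j]
    med <- stats::median(ch)
    bound <- k * stats::mad(ch) # mad() already applies the 1.4826 scale
    bad <- abs(ch - med) > bound
    if (all(bad))
      stopf("channel %s: every sample flagged as outlier (degenerate signal)",
            x$channels[j])
    n_replaced[j] <- sum(bad)
    out$data[, j] <- interp_over(ch, bad)
  }
  attr(out, "n_replaced") <- stats::setNames(n_replaced, x$channels)
  out
}

#' Zero-phase Butterworth band-pass filter
#'
#' Designs a Butterworth band-pass and applies it forward--backward
#' (`signal::filtfilt`), so the passband magnitude is squared and the phase
#' response is zero: the filtered EMG stays time-aligned with the force
#' channel. Default band 10--200 Hz removes baseline wander below and
#' out-of-band noise above the useful surface-EMG spectrum.
#'
#' @param x A `"signal_record"`.
#' @param low,high Band edges in Hz; `0 < low < high < rate/2`.
#' @param order Filter order (the zero-phase pass doubles it effectively).
#' @return The filtered record (length and rate unchanged).
#' @export
bandpass_filter <- function(x, low = 10, high = 200, order = 4) {
  nyq <- x$rate / 2
  if (!is_number(low) || !is_number(high) || low <= 0 || low >= high ||
      high >= nyq)
    stopf("invalid band [%g, %g] Hz for a %g Hz signal", low, high, x$rate)
  filt <- signal::butter(order, c(low, high) / nyq, type = "pass")
  map_channels(x, function(ch) signal::filtfilt(filt, ch))
}

#' Zero-phase IIR notch filter
#'
#' Second-order IIR notch (constrained biquad design) applied forward and
#' backward, removing a narrow band around `freq` -- by default the 50 Hz
#' powerline interference -- with unit gain at DC and elsewhere.
#'
#' @param x A `"signal_record"`.
#' @param freq Notch centre frequency, Hz; `0 < freq < rate/2`.
#' @param q Quality factor; the -3 dB notch width is `freq / q`.
#' @return The filtered record.
#' @export
notch_filter <- function(x, freq = 50, q = 30) {
  nyq <- x$rate / 2
  if (!is_number(freq) || freq <= 0 || freq >= nyq)
    stopf("notch frequency %g Hz outside (0, %g)", freq, nyq)
  if (!is_number(q) || q <= 0) stopf("q must be > 0")
  w0 <- 2 * pi * freq / x$rate
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  filt <- signal::Arma(b = b, a = a)
  map_channels(x, function(ch) signal::filtfilt(filt, ch))
}

#' Polynomial baseline-drift removal by least squares
#'
#' Fits, per channel, an ordinary least-squares polynomial of the given
#' order over time and subtracts it, removing the very-low-frequency trend
#' (baseline drift) that rides on biosignals. By construction the output is
#' orthogonal to the polynomial basis; order 0 is mean removal.
#'
#' @param x A `"signal_record"`.
#' @param poly_order Polynomial order (>= 0 and < signal length).
#' @return The detrended record.
#' @export
remove_baseline <- function(x, poly_order = 3) {
  n <- n_samples(x)
  if (!is.numeric(poly_order) || poly_order < 0 || poly_order >= n)
    stopf("poly_order must be in [0, %d)", n)
  poly_order <- as.integer(round(poly_order))
  if (poly_order == 0) return(map_channels(x, function(ch) ch - mean(ch)))
  basis <- cbind(1, stats::poly(seq_len(n), poly_order))
  qrb <- qr(basis)
  out <- x
  out$data <- qr.resid(qrb, x$data)
  colnames(out$data) <- x$channels
  out
}

#' Downsample a signal to a lower rate
#'
#' Two methods are offered. `"block_rms"` (the default for EMG) computes the
#' root-mean-square of each contiguous block of `rate / target_rate`
#' samples -- an amplitude-envelope estimate, which is the quantity that
#' actually tracks muscle effort once the EMG has been band-passed far above
#' the target Nyquist frequency. `"decimate"` applies an anti-aliasing
#' low-pass at `0.8 * target_rate / 2` and keeps every
#' `rate / target_rate`-th sample (literal rate reduction).
#'
#' @param x A `"signal_record"`.
#' @param target_rate Target rate in Hz; must divide the input rate.
#' @param method `"block_rms"` or `"decimate"`.
#' @return A `"signal_record"` at `target_rate` with
#'   `floor(n * target_rate / rate)` samples.
#' @export
downsample_signal <- function(x, target_rate = 10,
                              method = c("block_rms", "decimate")) {
  method <- match.arg(method)
  ratio <- x$rate / target_rate
  if (abs(ratio - round(ratio)) > 1e-9)
    stopf("target rate %g Hz does not divide the input rate %g Hz",
          target_rate, x$rate)
  m <- as.integer(round(ratio))
  n_out <- n_samples(x) %/% m
  if (n_out < 1) stopf("signal shorter than one output sample")
  out <- x
  if (method == "block_rms") {
    out$data <- apply(x$data, 2, function(ch) {
      blocks <- matrix(ch[seq_len(n_out * m)]^2, nrow = m)
      sqrt(colMeans(blocks))
    })
  } else {
    lp <- signal::butter(4, (0.8 * target_rate / 2) / (x$rate / 2),
                         type = "low")
    out$data <- apply(x$data, 2, function(ch) {
      signal::filtfilt(lp, ch)[seq(1, n_out * m, by = m)]
    })
  }
  out$data <- matrix(out$data, ncol = ncol(x$data),
                     dimnames = list(NULL, x$channels))
  out$rate <- target_rate
  out
}

#' Preprocessing configuration
#'
#' Bundles the tunable parameters of the full sEMG conditioning chain.
#' Defaults: outlier threshold 5 robust SDs, Butterworth order 4 band-pass
#' 10--200 Hz, 50 Hz notch with Q = 30, db4 level-4 soft universal wavelet
#' denoising, cubic polynomial baseline removal, and block-RMS envelope
#' downsampling to 10 Hz.
#'
#' @param outlier_k Outlier threshold in robust SDs.
#' @param bandpass_low,bandpass_high Band edges, Hz.
#' @param butterworth_order Band-pass filter order.
#' @param notch_freq,notch_q Notch centre frequency (Hz) and quality factor.
#' @param wavelet_family,wavelet_level,wavelet_threshold_rule,wavelet_threshold_mode
#'   Wavelet denoising parameters, see [wavelet_denoise()].
#' @param baseline_poly_order Baseline polynomial order.
#' @param target_rate Output rate, Hz (the force-channel rate).
#' @param downsample_method `"block_rms"` or `"decimate"`.
#' @return An object of class `"preprocess_config"`.
#' @export
preprocess_config <- function(outlier_k = 5, bandpass_low = 10,
                              bandpass_high = 200, butterworth_order = 4,
                              notch_freq = 50, notch_q = 30,
                              wavelet_family = "db4", wavelet_level = 4,
                              wavelet_threshold_rule = "universal",
                              wavelet_threshold_mode = "soft",
                              baseline_poly_order = 3, target_rate = 10,
                              downsample_method = "block_rms") {
  structure(
    list(outlier_k = outlier_k, bandpass_low = bandpass_low,
         bandpass_high = bandpass_high,
         butterworth_order = butterworth_order, notch_freq = notch_freq,
         notch_q = notch_q, wavelet_family = wavelet_family,
         wavelet_level = wavelet_level,
         wavelet_threshold_rule = wavelet_threshold_rule,
         wavelet_threshold_mode = wavelet_threshold_mode,
         baseline_poly_order = baseline_poly_order,
         target_rate = target_rate, downsample_method = downsample_method),
    class = "preprocess_config"
  )
}

#' Aligned predictor / response dataset
#'
#' Pairs the preprocessed multi-channel EMG envelope `E(t)` with the grip
#' force `F(t)` on a common clock -- the input expected by [narx()].
#'
#' @param emg Numeric matrix, one column per EMG channel.
#' @param force Numeric vector of grip force, same number of samples.
#' @param rate Common sampling rate, Hz.
#' @param phase Optional per-sample grip-phase factor (from simulation
#'   ground truth), carried along for phase-resolved error summaries.
#' @return An object of class `"grip_dataset"`.
#' @export
grip_dataset <- function(emg, force, rate = 10, phase = NULL) {
  if (is.null(dim(emg))) emg <- matrix(as.numeric(emg), ncol = 1L)
  emg <- as.matrix(emg)
  storage.mode(emg) <- "double"
  force <- as.numeric(force)
  if (nrow(emg) != length(force))
    stopf("EMG (%d samples) and force (%d) lengths differ",
          nrow(emg), length(force))
  if (anyNA(emg) || anyNA(force)) stopf("dataset contains NA values")
  if (!is.null(phase) && length(phase) != length(force))
    stopf("phase labels must match the number of samples")
  if (is.null(colnames(emg))) colnames(emg) <- paste0("ch", seq_len(ncol(emg)))
  structure(list(emg = emg, force = force, rate = rate, phase = phase),
            class = "grip_dataset")
}

#' @export
print.grip_dataset <- function(x, ...) {
  cat(sprintf("<grip_dataset> %d samples @ %g Hz, %d EMG channel(s)\n",
              length(x$force), x$rate, ncol(x$emg)))
  invisible(x)
}

#' Number of samples in a grip dataset
#' @param x A `"grip_dataset"`.
#' @return Integer sample count.
#' @export
dataset_length <- function(x) length(x$force)

subset_dataset <- function(x, idx) {
  grip_dataset(x$emg[idx, , drop = FALSE], x$force[idx], x$rate,
               phase = if (!is.null(x$phase)) x$phase[idx])
}

#' Coerce to a grip dataset
#'
#' @param x A `"grip_dataset"` (returned as is), a `"grip_sim"` (run through
#'   [preprocess_pipeline()] with default configuration), or a data frame
#'   with a `force` column and one column per EMG channel.
#' @param rate Sampling rate for the data-frame method.
#' @return A `"grip_dataset"`.
#' @export
as_grip_dataset <- function(x, rate = 10) {
  if (inherits(x, "grip_dataset")) return(x)
  if (inherits(x, "grip_sim"))
    return(preprocess_pipeline(x$emg, x$force, phase = x$activation$phase))
  if (is.data.frame(x)) {
    if (!"force" %in% names(x)) stopf("data frame must have a 'force' column")
    emg <- as.matrix(x[setdiff(names(x), c("force", "time"))])
    return(grip_dataset(emg, x$force, rate))
  }
  stopf("cannot coerce object of class '%s' to grip_dataset", class(x)[1])
}

#' Full sEMG conditioning pipeline
#'
#' Applies the complete chain to a raw EMG record -- outlier removal,
#' zero-phase Butterworth band-pass, notch, wavelet denoising, polynomial
#' baseline removal, downsampling to the force rate -- and aligns the result
#' with the force channel (both truncated to the shorter; durations more
#' than 1 s apart raise an error).
#'
#' @param emg Raw EMG `"signal_record"` (e.g. 3 channels at 1000 Hz).
#' @param force Force `"signal_record"` at the target rate.
#' @param config A [preprocess_config()].
#' @param phase Optional per-sample phase labels at the force rate.
#' @return A [grip_dataset()] with attribute `"stage_log"`, a list of
#'   per-stage summaries (per-channel RMS after each stage, outlier counts).
#' @export
preprocess_pipeline <- function(emg, force, config = preprocess_config(),
                                phase = NULL) {
  if (!inherits(emg, "signal_record") || !inherits(force, "signal_record"))
    stopf("emg and force must be signal_record objects")
  dur_e <- n_samples(emg) / emg$rate
  dur_f <- n_samples(force) / force$rate
  if (abs(dur_e - dur_f) > 1)
    stopf("EMG (%.2f s) and force (%.2f s) durations differ by more than 1 s",
          dur_e, dur_f)
  log <- list()
  note <- function(stage, x, extra = NULL) {
    log[[stage]] <<- c(list(rms = apply(x$data, 2, function(v)
      sqrt(mean(v^2)))), extra)
  }
  x <- remove_outliers(emg, config$outlier_k)
  note("outliers", x, list(n_replaced = attr(x, "n_replaced")))
  x <- bandpass_filter(x, config$bandpass_low, config$bandpass_high,
                       config$butterworth_order)
  note("bandpass", x)
  x <- notch_filter(x, config$notch_freq, config$notch_q)
  note("notch", x)
  x <- wavelet_denoise(x, config$wavelet_family, config$wavelet_level,
                       config$wavelet_threshold_rule,
                       config$wavelet_threshold_mode)
  note("wavelet", x)
  x <- remove_baseline(x, config$baseline_poly_order)
  note("baseline", x)
  x <- downsample_signal(x, config$target_rate, config$downsample_method)
  note("downsample", x)
  n <- min(n_samples(x), n_samples(force))
  ds <- grip_dataset(x$data[seq_len(n), , drop = FALSE],
                     force$data[seq_len(n), 1], config$target_rate,
                     phase = if (!is.null(phase)) phase[seq_len(n)])
  attr(ds, "stage_log") <- log
  ds
}
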