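#' Uniformly sampled multi-channel signal
#'
#' The common container for every stage of the pipeline: a numeric matrix of
#' samples (one column per channel) together with its sampling rate. Raw sEMG
#' is held at 1000 Hz, grip force at 10 Hz.
#'
#' @param data Numeric vector (one channel) or matrix with one column per
#'   channel and one row per sample.
#' @param rate Sampling rate in Hz; must be positive.
#' @param channels Optional character vector of channel names; defaults to
#'   `"ch1"`, `"ch2"`, ... or the column names of `data`.
#' @param start_time Time of the first sample in seconds.
#' @return An object of class `"signal_record"` with fields `data`, `rate`,
#'   `channels` and `start_time`.
#' @examples
#' x <- signal_record(sin(2 * pi * 5 * (0:99) / 100), rate = 100)
#' x
#' @export
signal_record <- function(data, rate, channels = NULL, start_time = 0) {
  if (is.null(dim(data))) data <- matrix(as.numeric(data), ncol = 1L)
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (nrow(data) < 1L) stopf("signal must contain at least one sample")
  if (!is_number(rate) || rate <= 0) stopf("sampling rate must be positive")
  if (is.null(channels)) {
    channels <- colnames(data) %||% paste0("ch", seq_len(ncol(data)))
  }
  if (length(channels) != ncol(data))
    stopf("got %d channel names for %d channels", length(channels), ncol(data))
  colnames(data) <- channels
  structure(
    list(data = data, rate = rate, channels = channels,
         start_time = start_time),
    class = "signal_record"
  )
}

#' @export
print.signal_record <- function(x, ...) {
  cat(sprintf("<signal_record> %d samples x %d channel(s) @ %g Hz (%.2f s)\n",
              nrow(x$data), ncol(x$data), x$rate, n_samples(x) / x$rate))
  cat("channels:", paste(x$channels, collapse = ", "), "\n")
  invisible(x)
}

#' Number of samples per channel
#' @param x A `signal_record`.
#' @return Integer sample count.
#' @export
n_samples <- function(x) nrow(x$data)

#' Sample times of a signal record
#' @param x A `signal_record`.
#' @return Numeric vector of sample times in seconds.
#' @export
signal_time <- function(x) x$start_time + (seq_len(n_samples(x)) - 1L) / x$rate

#' @export
as.data.frame.signal_record <- function(x, ...) {
  data.frame(time = signal_time(x), x$data, check.names = FALSE)
}

# Apply a vector->vector function to every channel, preserving metadata.
map_channels <- function(x, f, ...) {
  out <- x
  for (j in seq_len(ncol(x$data))) out$data[, j] <- f(x$data[, j], ...)
  out
}
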