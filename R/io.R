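#' Read a delimited-text signal file
#'
#' Expects a comma-separated file with a header row whose first column is
#' time in seconds at uniform spacing; the remaining columns are channels.
#' The sampling rate is inferred from the median time step, and any step
#' deviating from it by more than 1% is rejected with the offending row
#' named.
#'
#' @param path File path.
#' @return A `"signal_record"`.
#' @export
read_signal_file <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- tryCatch(utils::read.csv(path, check.names = FALSE),
                 error = function(e) stopf("cannot parse '%s': %s", path,
                                           conditionMessage(e)))
  if (nrow(df) < 2L) stopf("'%s': need at least two samples", path)
  if (ncol(df) < 2L) stopf("'%s': need a time column plus channels", path)
  for (j in seq_along(df)) {
    if (!is.numeric(df[[j]]))
      stopf("'%s': non-numeric values in column '%s'", path, names(df)[j])
    bad <- which(!is.finite(df[[j]]))
    if (length(bad))
      stopf("'%s': non-finite value at data row %d, column '%s'", path,
            bad[1], names(df)[j])
  }
  tt <- df[[1]]
  dt <- diff(tt)
  med <- stats::median(dt)
  if (med <= 0) stopf("'%s': time column is not increasing", path)
  off <- which(abs(dt - med) > 0.01 * med)
  if (length(off))
    stopf("'%s': non-uniform sampling at data row %d (step %.6g s, expected %.6g s)",
          path, off[1] + 1L, dt[off[1]], med)
  signal_record(as.matrix(df[-1]), rate = 1 / med,
                channels = names(df)[-1], start_time = tt[1])
}

#' Write a signal record to a delimited-text file
#'
#' Comma-separated with a header row (`time,ch1,...`), time printed with
#' six decimals and samples with twelve significant digits. Output bytes
#' are deterministic for identical input, so reruns are diffable.
#'
#' @param x A `"signal_record"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signal_file <- function(x, path) {
  if (!inherits(x, "signal_record")) stopf("x must be a signal_record")
  if (n_samples(x) < 1L || ncol(x$data) < 1L)
    stopf("refusing to write a zero-length signal")
  header <- paste(c("time", x$channels), collapse = ",")
  tt <- sprintf("%.6f", signal_time(x))
  vals <- apply(x$data, 1, function(row)
    paste(sprintf("%.12g", row), collapse = ","))
  writeLines(c(header, paste(tt, vals, sep = ",")), path)
  invisible(path)
}
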