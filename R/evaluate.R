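#' Fit-quality metrics for force prediction
#'
#' Mean squared error (N^2), root mean squared error (N), mean absolute
#' error (N) and the regression value R -- the Pearson correlation between
#' prediction and target, the toolbox convention for reporting time-series
#' fits.
#'
#' @param pred,target Equal-length numeric vectors.
#' @return An object of class `"narx_metrics"`: `mse`, `rmse`, `mae`, `r`,
#'   `n`, and a `degenerate` flag that is `TRUE` when either series has
#'   zero variance (R is then `NA` rather than propagating `NaN`).
#' @examples
#' compute_metrics(c(1, 2, 3), c(1, 2, 3))
#' @export
compute_metrics <- function(pred, target) {
  if (length(pred) != length(target) || length(pred) == 0)
    stopf("pred and target must be equal-length, non-empty vectors")
  e <- pred - target
  degenerate <- stats::sd(pred) == 0 || stats::sd(target) == 0
  structure(
    list(mse = mean(e^2), rmse = sqrt(mean(e^2)), mae = mean(abs(e)),
         r = if (degenerate) NA_real_ else stats::cor(pred, target),
         n = length(pred), degenerate = degenerate),
    class = "narx_metrics"
  )
}

#' @export
print.narx_metrics <- function(x, ...) {
  cat(sprintf("MSE %.6g N^2 | RMSE %.6g N | MAE %.6g N | R %s | n = %d\n",
              x$mse, x$rmse, x$mae,
              if (is.na(x$r)) "NA (degenerate)" else sprintf("%.4f", x$r),
              x$n))
  invisible(x)
}

#' Temporal train/test split of an aligned dataset
#'
#' `"last_fraction"` (default) holds out the final contiguous fraction of
#' the recording, preserving temporal causality through the delay lines.
#' `"by_repetition"` holds out whole grip cycles at the end of the session
#' (each held-out cycle spans the rest preceding a grip plus the grip
#' itself), mimicking cycle-level generalization; it requires the
#' [grip_protocol()] that produced the recording.
#'
#' @param data A [grip_dataset()].
#' @param strategy `"last_fraction"` or `"by_repetition"`.
#' @param test_fraction Fraction held out under `"last_fraction"`.
#' @param protocol The [grip_protocol()], required for `"by_repetition"`.
#' @param n_test_reps Number of final grip cycles held out.
#' @return A list with `"grip_dataset"` elements `train` and `test`, and
#'   the index vectors `train_idx`, `test_idx` (a disjoint partition).
#' @export
split_dataset <- function(data, strategy = c("last_fraction",
                                             "by_repetition"),
                          test_fraction = 0.3, protocol = NULL,
                          n_test_reps = 1) {
  strategy <- match.arg(strategy)
  data <- as_grip_dataset(data)
  n <- dataset_length(data)
  if (strategy == "last_fraction") {
    if (!is_number(test_fraction) || test_fraction <= 0 || test_fraction >= 1)
      stopf("test_fraction must lie in (0, 1)")
    n_test <- floor(n * test_fraction)
    if (n_test < 1 || n_test >= n) stopf("split leaves an empty part")
    cut <- n - n_test
  } else {
    if (is.null(protocol)) stopf("by_repetition requires the grip protocol")
    seg <- protocol_segments(protocol)
    counts <- round(seg$duration * data$rate)
    first_rep <- protocol$repetitions - n_test_reps + 1L
    if (first_rep < 2L) stopf("cannot hold out every repetition")
    start <- sum(counts[seg$repetition < first_rep])
    cut <- min(start, n)
  }
  train_idx <- seq_len(cut)
  test_idx <- (cut + 1L):n
  list(train = subset_dataset(data, train_idx),
       test = subset_dataset(data, test_idx),
       train_idx = train_idx, test_idx = test_idx)
}

# Train/evaluate one configuration; shared by run_sweep and
# compare_trainers. Returns metrics on both splits.
fit_and_score <- function(train, test, delay, hidden, method, control,
                          n_restarts = 1, seed = 1, include_current = TRUE,
                          init_scale = 0.5) {
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- narx(train, delay = delay, hidden = hidden, method = method,
                control = control, include_current = include_current,
                init_scale = init_scale, seed = seed + r - 1L)
    if (is.null(best) || fit$train_metrics$mse < best$train_metrics$mse)
      best <- fit
  }
  test_pred <- predict(best, newdata = test)
  test_y <- test$force[-seq_len(delay)]
  list(fit = best, train = best$train_metrics,
       test = compute_metrics(test_pred, test_y))
}

#' Sweep hidden size and delay order
#'
#' Trains one model per (hidden size, delay) cell on the training split --
#' keeping the best of `n_restarts` seeded initializations by training
#' MSE -- and reports test metrics for every cell, plus per-hidden-size
#' averages over delays. A failed cell is recorded with an error flag and
#' the sweep continues.
#'
#' @param train,test [grip_dataset()] splits (see [split_dataset()]).
#' @param hidden_sizes Integer vector of hidden-layer widths.
#' @param delays Integer vector of delay orders.
#' @param method Training method (default `"cg"`).
#' @param control A [narx_control()].
#' @param n_restarts Random restarts per cell.
#' @param seed Base seed; cell restarts draw deterministic sub-seeds.
#' @return An object of class `"narx_sweep"`: `table` (one row per cell
#'   with train/test metrics, epochs and the winning seed), `averages`
#'   (per hidden size, averaged over delays), and the grids swept.
#' @export
run_sweep <- function(train, test, hidden_sizes = c(5, 10, 20, 30),
                      delays = c(5, 10, 20, 30, 40), method = "cg",
                      control = narx_control(), n_restarts = 3, seed = 1) {
  grid <- expand.grid(delay = delays, hidden = hidden_sizes,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    d <- grid$delay[i]
    h <- grid$hidden[i]
    cell_seed <- seed + 1000L * i
    res <- tryCatch(
      fit_and_score(train, test, d, h, method, control,
                    n_restarts = n_restarts, seed = cell_seed),
      error = function(err) err)
    rows[[i]] <- if (inherits(res, "error")) {
      data.frame(hidden = h, delay = d, failed = TRUE,
                 error = conditionMessage(res), train_mse = NA, test_mse = NA,
                 test_rmse = NA, test_mae = NA, test_r = NA, epochs = NA,
                 seed = cell_seed)
    } else {
      data.frame(hidden = h, delay = d, failed = FALSE, error = "",
                 train_mse = res$train$mse, test_mse = res$test$mse,
                 test_rmse = res$test$rmse, test_mae = res$test$mae,
                 test_r = res$test$r, epochs = res$fit$training$epochs,
                 seed = cell_seed)
    }
  }
  table <- do.call(rbind, rows)
  ok <- !table$failed
  averages <- do.call(rbind, lapply(hidden_sizes, function(h) {
    sub <- table[table$hidden == h & ok, , drop = FALSE]
    data.frame(hidden = h, test_mse = mean(sub$test_mse),
               test_mae = mean(sub$test_mae), test_r = mean(sub$test_r))
  }))
  structure(list(table = table, averages = averages,
                 hidden_sizes = hidden_sizes, delays = delays,
                 method = method, seed = seed),
            class = "narx_sweep")
}

#' @export
print.narx_sweep <- function(x, ...) {
  cat(sprintf("NARX sweep (%s): hidden size x delay grid, MSE/MAE shown x 10^-1\n",
              toupper(x$method)))
  header <- c("Delay", unlist(lapply(x$hidden_sizes, function(h)
    sprintf(c("MSE[%d]", "MAE[%d]", "R[%d]"), h))))
  fmt_row <- function(label, cells) {
    cat(sprintf("%-8s", label))
    cat(sprintf("%10s", cells), sep = "")
    cat("\n")
  }
  fmt_row("", header[-1])
  for (d in x$delays) {
    cells <- unlist(lapply(x$hidden_sizes, function(h) {
      row <- x$table[x$table$hidden == h & x$table$delay == d, ]
      if (nrow(row) == 0 || row$failed) return(rep("--", 3))
      sprintf(c("%.2f", "%.2f", "%.4f"),
              c(row$test_mse * 10, row$test_mae * 10, row$test_r))
    }))
    fmt_row(sprintf("%d", d), cells)
  }
  cells <- unlist(lapply(x$hidden_sizes, function(h) {
    row <- x$averages[x$averages$hidden == h, ]
    sprintf(c("%.2f", "%.2f", "%.4f"),
            c(row$test_mse * 10, row$test_mae * 10, row$test_r))
  }))
  fmt_row("Average", cells)
  invisible(x)
}

#' Compare the three training strategies on a common split
#'
#' Fits one model per method from the same initialization and reports
#' train/test MSE, RMSE, MAE and R, the wall time and the epoch count --
#' the standard side-by-side view of CG's speed, LM's training-set
#' aggressiveness and BRSGD's regularized compromise.
#'
#' @param train,test [grip_dataset()] splits.
#' @param delay,hidden Model architecture shared by all methods.
#' @param methods Character vector of methods to run.
#' @param controls Named list of [narx_control()] objects per method;
#'   missing entries fall back to `default_control`.
#' @param default_control Fallback control.
#' @param seed Initialization seed shared by all methods.
#' @return A `"trainer_comparison"`: a data frame with one row per method.
#' @export
compare_trainers <- function(train, test, delay = 5, hidden = 10,
                             methods = c("cg", "lm", "brsgd"),
                             controls = list(),
                             default_control = narx_control(), seed = 1) {
  rows <- lapply(methods, function(m) {
    ctrl <- controls[[m]] %||% default_control
    elapsed <- system.time(
      res <- fit_and_score(train, test, delay, hidden, m, ctrl, seed = seed)
    )[["elapsed"]]
    data.frame(method = m,
               train_mse = res$train$mse, train_rmse = res$train$rmse,
               train_mae = res$train$mae, train_r = res$train$r,
               test_mse = res$test$mse, test_rmse = res$test$rmse,
               test_mae = res$test$mae, test_r = res$test$r,
               time_s = elapsed, epochs = res$fit$training$epochs,
               stop_reason = res$fit$training$stop_reason)
  })
  structure(do.call(rbind, rows), class = c("trainer_comparison",
                                            "data.frame"))
}

#' @export
print.trainer_comparison <- function(x, ...) {
  cat("Training-method comparison (one-step metrics)\n")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], signif, 4)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Phase-resolved residual summaries
#'
#' Splits the prediction residuals by grip phase (rest, ramp-up, hold,
#' ramp-down) and returns the box-plot statistics of each phase: Tukey
#' hinges, median, whiskers at the most extreme points within 1.5 IQR of
#' the hinges, and the outliers beyond them. Used to locate where in the
#' grip cycle the decoder errs (typically the onsets of grip hold and
#' release).
#'
#' @param pred,target Equal-length prediction and target vectors.
#' @param phase Factor (or character) of grip-phase labels per sample;
#'   must partition the samples.
#' @return An object of class `"phase_error_summary"`: a `summary` data
#'   frame (one row per non-empty phase: n, lower whisker, lower hinge,
#'   median, upper hinge, upper whisker, IQR) and a named `outliers` list.
#'   Empty phases are omitted with a warning.
#' @export
error_distribution <- function(pred, target, phase) {
  if (length(pred) != length(target) || length(pred) != length(phase))
    stopf("pred, target and phase must have equal lengths")
  phase <- as.factor(phase)
  resid <- pred - target
  levs <- levels(phase)
  present <- levs[levs %in% unique(as.character(phase))]
  if (length(present) < length(levs))
    warning(sprintf("empty phase(s) omitted: %s",
                    paste(setdiff(levs, present), collapse = ", ")),
            call. = FALSE)
  rows <- list()
  outliers <- list()
  for (lv in present) {
    r <- resid[phase == lv]
    bs <- grDevices::boxplot.stats(r)
    rows[[lv]] <- data.frame(
      phase = lv, n = length(r), whisker_low = bs$stats[1],
      q1 = bs$stats[2], median = bs$stats[3], q3 = bs$stats[4],
      whisker_high = bs$stats[5], iqr = bs$stats[4] - bs$stats[2],
      n_outliers = length(bs$out))
    outliers[[lv]] <- bs$out
  }
  structure(list(summary = do.call(rbind, c(rows, make.row.names = FALSE)),
                 outliers = outliers),
            class = "phase_error_summary")
}

#' @export
print.phase_error_summary <- function(x, ...) {
  cat("Residual distribution by grip phase (N)\n")
  df <- x$summary
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], signif, 4)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
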