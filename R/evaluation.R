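# Batch-wise data splitting and the regression metrics used throughout:
# R2, RMSE, and mean/variance summaries over repeated model runs.

#' Split a dataset by whole culture batches
#'
#' The first `n_cal_batches` batches (in order of first appearance) form the
#' calibration set; the remaining batches form the validation set.  The split
#' never separates samples of the same batch, so validation batches are truly
#' independent cultures.
#'
#' @param data data.frame with a `batch_id` column (e.g. from
#'   [generate_dataset()]).
#' @param n_cal_batches number of calibration batches (default 6 of 8).
#' @return list of class `split_dataset` with data.frames `calibration` and
#'   `validation` and the value `n_cal_batches`.
#' @export
#' @examples
#' d <- generate_dataset(n_batches = 3, seed = 1)
#' s <- split_by_batch(d, n_cal_batches = 2)
#' nrow(s$calibration); nrow(s$validation)
split_by_batch <- function(data, n_cal_batches = 6) {
  if (!"batch_id" %in% names(data)) stop("'data' must have a 'batch_id' column")
  batches <- unique(data$batch_id)
  if (n_cal_batches >= length(batches))
    stop("'n_cal_batches' must be smaller than the number of batches")
  cal_b <- batches[seq_len(n_cal_batches)]
  structure(list(calibration = data[data$batch_id %in% cal_b, , drop = FALSE],
                 validation = data[!data$batch_id %in% cal_b, , drop = FALSE],
                 n_cal_batches = n_cal_batches),
            class = "split_dataset")
}

#' Coefficient of determination
#'
#' `R2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`.
#'
#' @param y observed values.
#' @param yhat predicted values.
#' @return scalar R2 (at most 1; can be negative for poor fits).
#' @export
r2 <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("'y' and 'yhat' must have equal length")
  if (length(y) < 2L) stop("need at least 2 observations")
  sst <- sum((y - mean(y))^2)
  if (sst == 0) stop("'y' is constant; R2 is undefined")
  1 - sum((y - yhat)^2) / sst
}

#' Root mean square error
#'
#' @inheritParams r2
#' @return scalar `sqrt(mean((y - yhat)^2))`.
#' @export
rmse <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("'y' and 'yhat' must have equal length")
  if (length(y) == 0L) stop("empty input")
  sqrt(mean((y - yhat)^2))
}

#' Summarize a metric over repeated runs
#'
#' Repeated model fits are reported as mean plus a spread statistic; both the
#' sample variance (n - 1 denominator) and the standard deviation are given.
#'
#' @param values numeric vector of per-run metric values (length >= 2).
#' @return list of class `metric_summary` with `mean`, `variance`, `sd`,
#'   `n_runs`.
#' @export
#' @examples
#' summarize_runs(c(1, 3))
summarize_runs <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("need at least 2 values")
  structure(list(mean = mean(values), variance = var(values),
                 sd = sd(values), n_runs = length(values)),
            class = "metric_summary")
}

#' @export
print.metric_summary <- function(x, ...) {
  cat(sprintf("%.4f +/- %.4f (sd; variance %.4f; n = %d)\n",
              x$mean, x$sd, x$variance, x$n_runs))
  invisible(x)
}

# Rc2/RMSECV on calibration and Rp2/RMSEP on validation for one fitted model.
model_metrics <- function(fit, split, feature_cols, response = "od_measured") {
  Xc <- as.matrix(split$calibration[, feature_cols, drop = FALSE])
  Xv <- as.matrix(split$validation[, feature_cols, drop = FALSE])
  yc <- split$calibration[[response]]
  yv <- split$validation[[response]]
  pc <- predict(fit, Xc)
  pv <- predict(fit, Xv)
  c(Rc2 = r2(yc, pc), RMSECV = rmse(yc, pc),
    Rp2 = r2(yv, pv), RMSEP = rmse(yv, pv))
}
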