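#' Regression error metrics
#'
#' `MSE = mean((y - yhat)^2)`, `RMSE = sqrt(MSE)`,
#' `MAE = mean(|y - yhat|)`, `MAPE = 100 * mean(|y - yhat| / y)`, and the
#' coefficient of determination `R2 = 1 - SSE/SST` with the total sum of
#' squares about `mean(y)` (ranging from `-Inf` to 1). When any target is
#' zero, MAPE is undefined and returned as `NA` with a `reason` attribute;
#' the other metrics are still computed.
#'
#' @param y actual values (length >= 2).
#' @param yhat predicted values, same length.
#' @return named list with `mse`, `rmse`, `mae`, `mape`, `r2`.
#' @export
bp_metrics <- function(y, yhat) {
  stopifnot(is.numeric(y), is.numeric(yhat))
  if (length(y) != length(yhat)) stop("y and yhat must have equal length")
  if (length(y) < 2) stop("need at least 2 observations")
  err <- y - yhat
  mse <- mean(err^2)
  mae <- mean(abs(err))
  if (any(y == 0)) {
    mape <- NA_real_
    attr(mape, "reason") <- "undefined: zero value(s) in y"
  } else {
    mape <- 100 * mean(abs(err / y))
  }
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sum(err^2) / sst else NA_real_
  list(mse = mse, rmse = sqrt(mse), mae = mae, mape = mape, r2 = r2)
}

#' Pearson correlation between actual and predicted values
#'
#' @param y,yhat equal-length numeric vectors (length >= 3).
#' @return correlation coefficient, or `NA` with a `reason` attribute when
#'   either input has zero variance.
#' @export
pearson_r <- function(y, yhat) {
  stopifnot(length(y) == length(yhat), length(y) >= 3)
  if (stats::sd(y) == 0 || stats::sd(yhat) == 0) {
    out <- NA_real_
    attr(out, "reason") <- "undefined: zero-variance input"
    return(out)
  }
  stats::cor(y, yhat)
}

#' Bland-Altman agreement statistics
#'
#' Differences are `yhat - y` (predicted minus actual); limits of agreement
#' are `mean_diff +/- 1.96 * sd_diff` with the n-1 SD denominator. The
#' per-point `(mean, diff)` pairs are returned for plotting.
#'
#' @param y actual values (length >= 3).
#' @param yhat predicted values, same length.
#' @return list of class `bland_altman`: `mean_diff`, `sd_diff`, `loa_low`,
#'   `loa_high`, and a `points` data.frame with columns `mean` and `diff`.
#' @export
bland_altman <- function(y, yhat) {
  stopifnot(is.numeric(y), is.numeric(yhat))
  if (length(y) != length(yhat)) stop("y and yhat must have equal length")
  if (length(y) < 3) stop("need at least 3 observations")
  d <- yhat - y
  m <- (yhat + y) / 2
  md <- mean(d)
  sd_d <- stats::sd(d)
  structure(list(mean_diff = md, sd_diff = sd_d,
                 loa_low = md - 1.96 * sd_d, loa_high = md + 1.96 * sd_d,
                 points = data.frame(mean = m, diff = d)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: mean diff %.3f mmHg, LoA [%.3f, %.3f]\n",
              x$mean_diff, x$loa_low, x$loa_high))
  invisible(x)
}

#' K-fold cross-validation of one model on a feature table
#'
#' Rows are shuffled into `k` balanced folds from the stated seed; each fold
#' is predicted by a model trained on the remaining folds, so every row is
#' predicted exactly once out-of-fold. Headline metrics are computed on the
#' pooled out-of-fold predictions; per-fold metrics are retained for
#' dispersion.
#'
#' @param table a [feature_table()].
#' @param spec a [model_spec()].
#' @param target `"sbp"` or `"dbp"`.
#' @param k number of folds (>= 2, <= number of rows).
#' @param seed integer seed controlling the shuffle.
#' @return list of class `bp_cv_report`: `model`, `target`, `k`, `seed`,
#'   `n`, `metrics` (pooled, from [bp_metrics()]), `fold_metrics`
#'   (data.frame), `predictions` (data.frame with `row`, `fold`, `actual`,
#'   `predicted`).
#' @export
cross_validate <- function(table, spec, target = c("sbp", "dbp"),
                           k = 10, seed = 17) {
  target <- match.arg(target)
  table <- feature_table(as.data.frame(table))
  n <- nrow(table)
  if (k < 2) stop("k must be >= 2")
  if (n < k) stop("need at least k rows")
  X <- as.matrix(table[, ppg_feature_names(), drop = FALSE])
  y <- table[[target]]

  fold <- with_private_seed(seed, rep_len(seq_len(k), n)[sample.int(n)])
  pred <- numeric(n)
  for (f in seq_len(k)) {
    test <- which(fold == f)
    model <- fit_bp_model(spec, X[-test, , drop = FALSE], y[-test])
    pred[test] <- predict(model, X[test, , drop = FALSE])
  }
  fold_metrics <- do.call(rbind, lapply(seq_len(k), function(f) {
    idx <- which(fold == f)
    if (length(idx) < 2) {
      return(data.frame(fold = f, n = length(idx), mse = NA, rmse = NA,
                        mae = abs(y[idx] - pred[idx]), mape = NA, r2 = NA))
    }
    m <- bp_metrics(y[idx], pred[idx])
    data.frame(fold = f, n = length(idx), mse = m$mse, rmse = m$rmse,
               mae = m$mae, mape = as.numeric(m$mape), r2 = m$r2)
  }))
  structure(list(model = spec$name, target = target, k = k, seed = seed,
                 n = n, metrics = bp_metrics(y, pred),
                 fold_metrics = fold_metrics,
                 predictions = data.frame(row = seq_len(n), fold = fold,
                                          actual = y, predicted = pred)),
            class = "bp_cv_report")
}

#' @export
print.bp_cv_report <- function(x, ...) {
  cat(sprintf("<%d-fold CV> %s on %s (n = %d): RMSE %.3f, MAE %.3f, R2 %.3f\n",
              x$k, x$model, toupper(x$target), x$n,
              x$metrics$rmse, x$metrics$mae, x$metrics$r2))
  invisible(x)
}

#' Classify a blood-pressure reading into British Hypertension Society grades
#'
#' Categories: Optimal (SBP < 120 and DBP < 80), Normal (< 130 / < 85),
#' High normal (130-139 or 85-89), Grade 1 (140-159 or 90-99), Grade 2
#' (160-179 or 100-109), Grade 3 (>= 180 or >= 110); when SBP and DBP fall
#' in different categories the higher-severity one wins. Readings with
#' SBP >= 140 and DBP < 90 are isolated systolic hypertension: ISH Grade 1
#' for SBP 140-159, ISH Grade 2 for SBP >= 160.
#'
#' @param sbp,dbp systolic and diastolic pressure in mmHg (vectorised;
#'   requires `sbp > dbp > 0` elementwise).
#' @return character vector of category labels.
#' @export
classify_bp_grade <- function(sbp, dbp) {
  stopifnot(length(sbp) == length(dbp))
  if (any(!is.finite(sbp) | !is.finite(dbp) | dbp <= 0 | sbp <= dbp)) {
    stop("require finite sbp > dbp > 0")
  }
  sev_s <- findInterval(sbp, c(120, 130, 140, 160, 180)) + 1L
  sev_d <- findInterval(dbp, c(80, 85, 90, 100, 110)) + 1L
  sev <- pmax(sev_s, sev_d)
  labels <- c("Optimal", "Normal", "High normal",
              "Grade 1", "Grade 2", "Grade 3")
  out <- labels[sev]
  ish <- sbp >= 140 & dbp < 90
  out[ish & sbp < 160] <- "ISH Grade 1"
  out[ish & sbp >= 160] <- "ISH Grade 2"
  out
}

#' Export an evaluation report to CSV files
#'
#' Writes, under `out_dir`:
#' * `metrics.csv` — one row per model x target with columns
#'   `target`, `regression_method`, `RMSE`, `R2`, `MSE`, `MAE`, `MAPE`.
#' * per target, for the model with the lowest pooled RMSE:
#'   `overlay_<target>.csv` (`index`, `actual`, `predicted` — the
#'   time-series overlay data), `bland_altman_<target>.csv` (`mean`, `diff`
#'   pairs plus the limits in comment-free extra columns), and
#'   `correlation_<target>.csv` (the Pearson r).
#'
#' Output is deterministic: re-exporting the same reports is byte-identical.
#'
#' @param reports list of `bp_cv_report` objects (typically 7 models x 2
#'   targets).
#' @param out_dir output directory, created if needed.
#' @return invisibly, the metrics data.frame.
#' @export
export_report <- function(reports, out_dir) {
  if (inherits(reports, "bp_cv_report")) reports <- list(reports)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop(sprintf("cannot create directory '%s'", out_dir))
  metrics <- do.call(rbind, lapply(reports, function(r) {
    data.frame(target = toupper(r$target), regression_method = r$model,
               RMSE = r$metrics$rmse, R2 = r$metrics$r2,
               MSE = r$metrics$mse, MAE = r$metrics$mae,
               MAPE = as.numeric(r$metrics$mape))
  }))
  write_csv_plain(metrics, file.path(out_dir, "metrics.csv"))
  for (tg in unique(vapply(reports, `[[`, "", "target"))) {
    sub <- reports[vapply(reports, `[[`, "", "target") == tg]
    best <- sub[[which.min(vapply(sub, function(r) r$metrics$rmse, 1))]]
    ov <- data.frame(index = best$predictions$row,
                     actual = best$predictions$actual,
                     predicted = best$predictions$predicted)
    write_csv_plain(ov, file.path(out_dir, sprintf("overlay_%s.csv", tg)))
    ba <- bland_altman(best$predictions$actual, best$predictions$predicted)
    badf <- ba$points
    badf$mean_diff <- ba$mean_diff
    badf$loa_low <- ba$loa_low
    badf$loa_high <- ba$loa_high
    write_csv_plain(badf, file.path(out_dir, sprintf("bland_altman_%s.csv", tg)))
    r <- pearson_r(best$predictions$actual, best$predictions$predicted)
    write_csv_plain(data.frame(model = best$model, pearson_r = as.numeric(r)),
                    file.path(out_dir, sprintf("correlation_%s.csv", tg)))
  }
  invisible(metrics)
}

write_csv_plain <- function(df, path) {
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop(sprintf("I/O error writing '%s': %s", path, conditionMessage(ok)))
  }
  invisible(path)
}
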