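#' End-to-end estimation pipeline
#'
#' Preprocesses each record (baseline removal, low-pass, segmentation,
#' SBP/DBP reference extraction), extracts the 24-feature table, then
#' cross-validates the requested regression models per target and optionally
#' exports the report files.
#'
#' @param records a [waveform_record()] or list of them; each needs `PPG`
#'   and `ABP` channels.
#' @param preprocess a [preprocess_config()].
#' @param features a [feature_params()].
#' @param models `"all"` or a character vector of [bp_model_names()].
#' @param targets subset of `c("sbp", "dbp")`.
#' @param k cross-validation folds.
#' @param seed integer seed for the fold shuffle.
#' @param out_dir optional directory for [export_report()] output.
#' @param quiet suppress per-stage progress messages.
#' @return list with `feature_table`, `reports` (list of `bp_cv_report`),
#'   and `summary` (the metrics data.frame).
#' @export
run_bp_pipeline <- function(records,
                            preprocess = preprocess_config(),
                            features = feature_params(),
                            models = "all",
                            targets = c("sbp", "dbp"),
                            k = 10, seed = 17,
                            out_dir = NULL, quiet = FALSE) {
  if (inherits(records, "waveform_record")) records <- list(records)
  targets <- match.arg(targets, several.ok = TRUE)
  if (identical(models, "all")) models <- bp_model_names()
  bad <- setdiff(models, bp_model_names())
  if (length(bad)) stop(sprintf("unknown model(s): %s", paste(bad, collapse = ", ")))

  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- proc.time()[["elapsed"]]
  segs <- list()
  n_excluded <- 0L
  for (rec in records) {
    s <- preprocess_pipeline(rec, preprocess)
    n_excluded <- n_excluded + (attr(s, "n_excluded") %||% 0L)
    segs <- c(segs, s)
  }
  say("preprocess: %d segments (%d excluded) in %.1f s",
      length(segs), n_excluded, proc.time()[["elapsed"]] - t0)

  t0 <- proc.time()[["elapsed"]]
  tab <- extract_feature_table(segs, features)
  say("features: %d x %d table in %.1f s", nrow(tab), ncol(tab),
      proc.time()[["elapsed"]] - t0)

  reports <- list()
  for (tg in targets) {
    for (mn in models) {
      t0 <- proc.time()[["elapsed"]]
      rep_ <- cross_validate(tab, model_spec(mn), target = tg, k = k,
                             seed = seed)
      say("cv: %s/%s RMSE %.3f in %.1f s", mn, tg, rep_$metrics$rmse,
          proc.time()[["elapsed"]] - t0)
      reports[[paste(tg, mn, sep = ".")]] <- rep_
    }
  }
  summary_df <- if (!is.null(out_dir)) {
    export_report(reports, out_dir)
  } else {
    do.call(rbind, lapply(reports, function(r) {
      data.frame(target = toupper(r$target), regression_method = r$model,
                 RMSE = r$metrics$rmse, R2 = r$metrics$r2,
                 MSE = r$metrics$mse, MAE = r$metrics$mae,
                 MAPE = as.numeric(r$metrics$mape))
    }))
  }
  rownames(summary_df) <- NULL
  list(feature_table = tab, reports = reports, summary = summary_df)
}
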