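# Synthetic feature tables with a known linear feature -> pressure map:
# 3 informative columns, the remaining 21 pure noise, additive Gaussian
# target noise. Used for the model parameter-recovery checks.

make_linear_feature_table <- function(n, seed, noise_sd = 2) {
  set.seed(seed)
  p <- length(ppg_feature_names())
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, ppg_feature_names()))
  sbp <- 120 + 8 * X[, 1] + 5 * X[, 2] - 6 * X[, 3] + rnorm(n, 0, noise_sd)
  dbp <- 80 + 4 * X[, 1] + 3 * X[, 2] - 3 * X[, 3] + rnorm(n, 0, noise_sd)
  stopifnot(all(sbp > dbp))
  feature_table(data.frame(X, sbp = sbp, dbp = dbp))
}

linear_truth_coeffs <- function(target = "sbp") {
  b <- numeric(length(ppg_feature_names()))
  if (target == "sbp") b[1:3] <- c(8, 5, -6) else b[1:3] <- c(4, 3, -3)
  b
}
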