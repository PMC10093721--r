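test_that("OLS recovers an exact linear map without noise", {
  tab <- make_linear_feature_table(120, seed = 1, noise_sd = 0)
  X <- as.matrix(tab[, ppg_feature_names()])
  fit <- fit_bp_model(model_spec("linear"), X, tab$sbp)
  pred <- predict(fit, X)
  expect_lt(sqrt(mean((pred - tab$sbp)^2)), 1e-8)
  beta_hat <- fit$fit$coef[-1] / fit$feature_sd
  expect_equal(unname(beta_hat), linear_truth_coeffs("sbp"), tolerance = 1e-8)
})

test_that("robust regression shrugs off a gross outlier that breaks OLS", {
  set.seed(13)
  tab <- make_linear_feature_table(200, seed = 13, noise_sd = 1)
  X <- as.matrix(tab[, ppg_feature_names()])
  y <- tab$sbp
  truth <- linear_truth_coeffs("sbp")
  coef_err <- function(fit) {
    sqrt(sum((fit$fit$coef[-1] / fit$feature_sd - truth)^2))
  }
  base_err <- coef_err(fit_bp_model(model_spec("linear"), X, y))
  y_out <- y
  y_out[50] <- y_out[50] + 1000
  ols_err <- coef_err(fit_bp_model(model_spec("linear"), X, y_out))
  rob_err <- coef_err(fit_bp_model(model_spec("robust_linear"), X, y_out))
  expect_lt(rob_err, 10 * base_err)
  expect_gt(ols_err, rob_err)
})

test_that("GPR with floored noise interpolates noise-free smooth data", {
  set.seed(21)
  X <- matrix(runif(80 * 3, -2, 2), 80, 3)
  y <- sin(X[, 1]) + 0.5 * X[, 2]^2 - X[, 3]
  for (m in c("gpr_se", "gpr_matern52", "gpr_rq")) {
    fit <- fit_bp_model(
      model_spec(m, hyperparams = list(sigma_f = sd(y), ell = 1.5,
                                       sigma_n = 1e-3, alpha = 2,
                                       optimize = FALSE)),
      X, y)
    expect_lt(max(abs(predict(fit, X) - y)), 1e-3)
  }
})

test_that("rational quadratic GPR converges to squared exponential as alpha grows", {
  set.seed(11)
  n <- 200
  X <- matrix(rnorm(n * 24), n, 24, dimnames = list(NULL, ppg_feature_names()))
  y <- 100 + 6 * X[, 1] - 4 * X[, 2] + sin(X[, 3]) + rnorm(n, 0, 1)
  se <- fit_bp_model(model_spec("gpr_se"), X, y)
  hp <- exp(se$fit$par)
  rq <- fit_bp_model(
    model_spec("gpr_rq", hyperparams = list(
      sigma_f = unname(hp[["log_sigma_f"]]), ell = unname(hp[["log_ell"]]),
      sigma_n = unname(hp[["log_sigma_n"]]), alpha = 1e6, optimize = FALSE)),
    X, y)
  expect_lt(sqrt(mean((predict(se, X) - predict(rq, X))^2)), 1e-4)
})

test_that("SE-GPR posterior mean matches the kernlab reference", {
  skip_if_not_installed("kernlab")
  set.seed(11)
  X <- matrix(rnorm(120 * 5), 120, 5)
  y <- 2 * X[, 1] - X[, 2] + rnorm(120, 0, 0.5)
  ells <- 2
  sn <- 0.7
  mine <- fit_bp_model(
    model_spec("gpr_se", hyperparams = list(sigma_f = 1, ell = ells,
                                            sigma_n = sn, optimize = FALSE)),
    X, y)
  Xs <- sweep(sweep(X, 2, colMeans(X), "-"), 2, apply(X, 2, sd), "/")
  gp <- kernlab::gausspr(Xs, y - mean(y), kernel = "rbfdot",
                         kpar = list(sigma = 1 / (2 * ells^2)),
                         var = sn^2, scaled = FALSE)
  ref <- as.numeric(kernlab::predict(gp, Xs)) + mean(y)
  expect_equal(predict(mine, X), ref, tolerance = 1e-7)
})

test_that("GPR kernels give symmetric positive semidefinite Gram matrices", {
  set.seed(31)
  X <- matrix(rnorm(40 * 6), 40, 6)
  D2 <- ppg2bp:::sq_dist(X, X)
  for (kern in c("se", "rq", "matern52", "matern32")) {
    par <- c(log_sigma_f = log(1.3), log_ell = log(0.8), log_alpha = log(2))
    K <- ppg2bp:::gpr_kernel_eval(kern, D2, par)$K
    expect_equal(K, t(K))
    expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
               -1e-8)
  }
})

test_that("predictions are row-independent and reject malformed inputs", {
  tab <- make_linear_feature_table(100, seed = 3)
  X <- as.matrix(tab[, ppg_feature_names()])
  for (m in c("linear", "gpr_matern52", "svm_gaussian")) {
    fit <- fit_bp_model(model_spec(m), X, tab$sbp)
    pred <- predict(fit, X)
    perm <- sample(nrow(X))
    expect_equal(predict(fit, X[perm, ]), pred[perm])
    expect_equal(predict(fit, X[c(1, 1), ]), rep(pred[1], 2))
    expect_error(predict(fit, X[, 1:10]), "columns")
  }
  expect_error(fit_bp_model(model_spec("linear"), X, c(1, 2)), "length")
  expect_error(fit_bp_model(model_spec("linear"), X * NA, tab$sbp), "finite")
  expect_error(model_spec("deep_net"), "arg")
  expect_error(model_spec("gpr_se", hyperparams = list(ell = -1)), "> 0")
})

test_that("predictions are invariant to affine rescaling of feature columns", {
  tab <- make_linear_feature_table(150, seed = 17)
  X <- as.matrix(tab[, ppg_feature_names()])
  X2 <- X
  X2[, 1] <- 100 * X2[, 1] + 55   # absorbed by internal standardization
  X2[, 7] <- -0.01 * X2[, 7]
  for (m in bp_model_names()) {
    f1 <- fit_bp_model(model_spec(m), X, tab$sbp)
    f2 <- fit_bp_model(model_spec(m), X2, tab$sbp)
    expect_equal(predict(f1, X), predict(f2, X2), tolerance = 1e-6)
  }
})

test_that("rank-deficient designs fall back to the pseudo-inverse with a warning", {
  tab <- make_linear_feature_table(60, seed = 5)
  X <- as.matrix(tab[, ppg_feature_names()])
  X[, 2] <- X[, 1]   # duplicate column (same z-scores after standardization)
  expect_warning(fit <- fit_bp_model(model_spec("linear"), X, tab$sbp),
                 "rank-deficient")
  expect_true(all(is.finite(predict(fit, X))))
})
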