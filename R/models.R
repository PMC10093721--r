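#' Specify one of the seven blood-pressure regression models
#'
#' The closed model set comprises ordinary least squares (`linear`),
#' Huber-loss iteratively reweighted least squares (`robust_linear`), exact
#' Gaussian process regression with the rational quadratic (`gpr_rq`),
#' squared exponential (`gpr_se`) or Matern 5/2 (`gpr_matern52`) kernel, and
#' epsilon-insensitive support vector regression with a linear
#' (`svm_linear`) or Gaussian (`svm_gaussian`) kernel.
#'
#' Recognised hyperparameters:
#' * GPR models: `sigma_f` (signal SD), `ell` (kernel length scale on
#'   standardised features), `sigma_n` (noise SD), `alpha` (RQ shape),
#'   `optimize` (logical; `FALSE` fixes the supplied values instead of
#'   maximising the marginal likelihood), `as_printed` (logical, Matern
#'   only: selects the sqrt(3) Matern 3/2 form instead of the true 5/2
#'   kernel).
#' * SVM models: `cost` (box constraint, default `IQR(y)/1.349`), `epsilon`
#'   (insensitive-tube half width, default `IQR(y)/13.49`), `sigma`
#'   (Gaussian kernel scale, default `sqrt(p)` for `p` features, the
#'   "medium Gaussian" convention).
#'
#' All positivity-constrained hyperparameters must be > 0.
#'
#' @param name one of the seven model names above.
#' @param hyperparams named list of hyperparameter overrides.
#' @return a list of class `bp_model_spec`.
#' @export
model_spec <- function(name = c("linear", "robust_linear", "gpr_rq", "gpr_se",
                                "gpr_matern52", "svm_linear", "svm_gaussian"),
                       hyperparams = list()) {
  name <- match.arg(name)
  pos <- c("sigma_f", "ell", "sigma_n", "alpha", "cost", "epsilon", "sigma")
  for (k in intersect(names(hyperparams), pos)) {
    if (!is.numeric(hyperparams[[k]]) || hyperparams[[k]] <= 0) {
      stop(sprintf("hyperparameter '%s' must be > 0", k))
    }
  }
  structure(list(name = name, hyperparams = hyperparams),
            class = "bp_model_spec")
}

#' Names of the seven regression models
#' @return character vector.
#' @export
bp_model_names <- function() {
  c("linear", "robust_linear", "gpr_rq", "gpr_se", "gpr_matern52",
    "svm_linear", "svm_gaussian")
}

#' Fit a blood-pressure regression model
#'
#' Features are z-scored inside the fit (constants stored on the model), so
#' predictions are invariant to affine rescaling of any feature column.
#' Rank-deficient designs for the linear models are resolved through the
#' pseudo-inverse with a warning.
#'
#' @param spec a [model_spec()].
#' @param X numeric feature matrix (n rows, one column per feature).
#' @param y numeric target vector (mmHg), same length as `nrow(X)`.
#' @return an object of class `bp_model` supporting [predict()].
#' @export
fit_bp_model <- function(spec, X, y) {
  stopifnot(inherits(spec, "bp_model_spec"))
  X <- as.matrix(X)
  if (!is.numeric(X) || !all(is.finite(X))) stop("X must be finite numeric")
  if (!is.numeric(y) || !all(is.finite(y))) stop("y must be finite numeric")
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)")
  if (nrow(X) < 3) stop("need at least 3 training rows")

  mu <- colMeans(X)
  sd_ <- apply(X, 2, stats::sd)
  sd_[!is.finite(sd_) | sd_ == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu, "-"), 2, sd_, "/")
  hp <- spec$hyperparams

  fit <- switch(spec$name,
    linear = fit_linear(Xs, y, robust = FALSE),
    robust_linear = fit_linear(Xs, y, robust = TRUE),
    gpr_rq = gpr_fit(Xs, y, "rq", hyperparams = hp,
                     optimize = hp$optimize %||% TRUE),
    gpr_se = gpr_fit(Xs, y, "se", hyperparams = hp,
                     optimize = hp$optimize %||% TRUE),
    gpr_matern52 = gpr_fit(Xs, y,
                           if (isTRUE(hp$as_printed)) "matern32" else "matern52",
                           hyperparams = hp,
                           optimize = hp$optimize %||% TRUE),
    svm_linear = fit_svr(Xs, y, kernel = "linear", hp = hp),
    svm_gaussian = fit_svr(Xs, y, kernel = "radial", hp = hp)
  )

  structure(list(spec = spec, fit = fit, feature_mean = mu, feature_sd = sd_,
                 n_features = ncol(X), feature_names = colnames(X)),
            class = "bp_model")
}

fit_linear <- function(Xs, y, robust) {
  A <- cbind(`(Intercept)` = 1, Xs)
  qf <- qr(A)
  if (robust) {
    keep <- sort(qf$pivot[seq_len(qf$rank)])
    if (length(keep) < ncol(A)) {
      warning("rank-deficient design: dependent columns dropped from robust fit")
    }
    rf <- MASS::rlm(A[, keep, drop = FALSE], y, psi = MASS::psi.huber,
                    k = 1.345, maxit = 100)
    coef <- numeric(ncol(A))
    coef[keep] <- stats::coef(rf)
    return(list(type = "linear", coef = coef))
  }
  if (qf$rank < ncol(A)) {
    warning("rank-deficient design: coefficients via pseudo-inverse")
    coef <- MASS::ginv(A) %*% y
  } else {
    coef <- qr.coef(qf, y)
  }
  list(type = "linear", coef = unname(as.numeric(coef)))
}

fit_svr <- function(Xs, y, kernel, hp) {
  iqr_y <- stats::IQR(y)
  if (!is.finite(iqr_y) || iqr_y <= 0) iqr_y <- max(stats::sd(y), 1)
  cost <- hp$cost %||% (iqr_y / 1.349)
  epsilon <- hp$epsilon %||% (iqr_y / 13.49)
  sigma <- hp$sigma %||% sqrt(ncol(Xs))
  m <- e1071::svm(Xs, y, type = "eps-regression", kernel = kernel,
                  cost = cost, epsilon = epsilon,
                  gamma = 1 / (2 * sigma^2), scale = FALSE)
  list(type = "svr", model = m)
}

#' Predict blood pressure from a fitted model
#'
#' @param object a `bp_model` from [fit_bp_model()].
#' @param newdata numeric matrix with the same number of feature columns the
#'   model was trained on.
#' @param ... unused.
#' @return numeric vector of predictions (mmHg).
#' @export
predict.bp_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != object$n_features) {
    stop(sprintf("newdata has %d columns; model expects %d",
                 ncol(X), object$n_features))
  }
  if (!all(is.finite(X))) stop("newdata must be finite")
  Xs <- sweep(sweep(X, 2, object$feature_mean, "-"), 2, object$feature_sd, "/")
  f <- object$fit
  out <- switch(f$type %||% object$spec$name,
    linear = as.numeric(cbind(1, Xs) %*% f$coef),
    svr = as.numeric(stats::predict(f$model, Xs)),
    gpr_predict(f, Xs)
  )
  out
}

#' @export
print.bp_model <- function(x, ...) {
  cat(sprintf("<bp_model '%s'> trained on %d features\n",
              x$spec$name, x$n_features))
  invisible(x)
}
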