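#' Time-domain waveform features
#'
#' Computes the 17 time-domain features used by the blood-pressure pipeline
#' from one preprocessed PPG window `x` of length `L`:
#'
#' * `emav`, `ewl` — enhanced mean absolute value / enhanced wavelength,
#'   `mean(|x_i|^P)` and `sum(|x_i - x_{i-1}|^P)` with the position-dependent
#'   exponent `P = 0.75` for the central half of the window
#'   (`0.25 L <= i <= 0.75 L`) and `P = 0.5` elsewhere.
#' * `mav` — mean absolute value `mean(|x|)`.
#' * `wl` — wavelength (waveform length) `sum(|diff(x)|)`.
#' * `zc` — zero crossings: adjacent pairs of opposite sign whose amplitude
#'   gap reaches `zc_threshold`.
#' * `ssc` — slope sign changes: interior points where
#'   `(x_i - x_{i-1}) (x_i - x_{i+1})` exceeds `ssc_threshold`.
#' * `rms` — root mean square.
#' * `aac` — average amplitude change `wl / L`.
#' * `dasdv` — `sqrt(sum(diff(x)^2) / (L - 1))`.
#' * `log_detector` — `exp(mean(log |x|))`, the geometric mean of `|x|`
#'   (exact zeros are floored at 1e-12 to keep the value finite).
#' * `mmav1`, `mmav2` — modified mean absolute values, `mean(w_i |x_i|)` with
#'   weights 1 in the central half and, respectively, 0.5 outside, or the
#'   ramp `4i/L` (rising edge) and `4(L - i)/L` (falling edge).
#' * `myop` — myopulse percentage rate: fraction of `|x_i| >= ` threshold.
#' * `ssi` — simple square integral `sum(x^2)`.
#' * `var` — `sum(x^2) / (L - 1)` (no mean subtraction: segments are
#'   near-zero-mean after baseline removal, where this coincides with the
#'   usual variance).
#' * `wamp` — Willison amplitude: successive differences exceeding threshold.
#' * `mfl` — maximum fractal length `log10(sqrt(sum(diff(x)^2)))`.
#'
#' Thresholds for `zc`/`ssc` default to 0; `wamp`/`myop` thresholds default to
#' `0.5 * sd(x)` so the counts are invariant to the PPG gain.
#'
#' @param x numeric vector, length >= 2, all finite.
#' @param params a [feature_params()].
#' @return named numeric vector of the 17 features, in canonical order.
#' @export
time_features <- function(x, params = feature_params()) {
  if (!is.numeric(x) || length(x) < 2) stop("x must be numeric with length >= 2")
  if (!all(is.finite(x))) stop("time_features: non-finite samples in x")
  L <- length(x)
  i <- seq_len(L)
  ax <- abs(x)
  dx <- diff(x)
  adx <- abs(dx)
  sdx <- stats::sd(x)

  central <- i >= 0.25 * L & i <= 0.75 * L
  P <- ifelse(central, 0.75, 0.5)
  emav <- mean(ax^P)
  ewl <- sum(adx^P[-1])

  mav <- mean(ax)
  wl <- sum(adx)
  aac <- wl / L
  rms <- sqrt(mean(x^2))
  ssi <- sum(x^2)
  var_ <- ssi / (L - 1)
  dasdv <- sqrt(sum(dx^2) / (L - 1))
  ld <- exp(mean(log(pmax(ax, 1e-12))))

  zc_thr <- params$zc_threshold
  zc <- sum(x[-L] * x[-1] < 0 & adx >= zc_thr)
  if (L >= 3) {
    prod_slope <- (x[2:(L - 1)] - x[1:(L - 2)]) * (x[2:(L - 1)] - x[3:L])
    ssc <- sum(prod_slope > params$ssc_threshold)
  } else {
    ssc <- 0
  }
  wamp_thr <- resolve_threshold(params$wamp_threshold, sdx)
  wamp <- sum(adx > wamp_thr)
  myop_thr <- resolve_threshold(params$myop_threshold, sdx)
  myop <- mean(ax >= myop_thr)

  w1 <- ifelse(central, 1, 0.5)
  mmav1 <- mean(w1 * ax)
  w2 <- ifelse(central, 1, ifelse(i < 0.25 * L, 4 * i / L, 4 * (L - i) / L))
  mmav2 <- mean(w2 * ax)

  mfl <- log10(sqrt(sum(dx^2)))

  c(emav = emav, ewl = ewl, mav = mav, wl = wl, zc = as.numeric(zc),
    ssc = as.numeric(ssc), rms = rms, aac = aac, dasdv = dasdv,
    log_detector = ld, mmav1 = mmav1, mmav2 = mmav2, myop = myop,
    ssi = ssi, var = var_, wamp = as.numeric(wamp), mfl = mfl)
}

# Thresholds given as list(rel = f) mean f * sd(x); plain numbers are absolute.
resolve_threshold <- function(thr, sdx) {
  if (is.list(thr) && !is.null(thr$rel)) thr$rel * sdx else thr
}
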