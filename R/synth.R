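#' Configuration for the synthetic PPG + ABP generator
#'
#' The generator emulates the statistical structure the estimation pipeline
#' relies on: a quasi-periodic PPG made of per-beat systolic and dicrotic
#' pulses, slow baseline wander, additive white noise, and an arterial
#' pressure (ABP) channel whose per-beat maximum/minimum equal a systolic and
#' diastolic pressure that are exact linear functions of the per-beat
#' morphology parameters (pulse amplitude, pulse width, heart period). That
#' linear map is what makes feature-to-pressure recovery testable.
#'
#' @param fs sampling frequency, Hz (>= 25).
#' @param duration record length, seconds.
#' @param hr_mean,hr_sd per-beat heart rate mean and SD, beats/min.
#' @param pulse_amp_mean,pulse_amp_sd per-beat PPG systolic amplitude mean and
#'   stationary SD, arbitrary units. Amplitudes evolve as a stationary AR(1)
#'   across beats (see `amp_drift_phi`), emulating slow vasomotor drift.
#' @param amp_drift_phi lag-1 autocorrelation of the per-beat amplitude
#'   process, in `[0, 1)`. High values concentrate amplitude variation at
#'   low frequencies, so segment-mean amplitudes — and with them the
#'   segment-level SBP/DBP references — differ between analysis windows.
#' @param width_mean,width_sd per-beat systolic pulse width (Gaussian sigma)
#'   mean and SD, seconds.
#' @param dicrotic_ratio dicrotic pulse amplitude as a fraction of the
#'   systolic amplitude, in `[0, 1)`.
#' @param baseline_amp,baseline_freq baseline-wander sinusoid amplitude
#'   (units) and frequency (Hz, must stay below 0.5 so preprocessing can be
#'   validated against it).
#' @param noise_sd additive white-noise SD on the PPG channel, units (>= 0).
#' @param sbp_coeffs,dbp_coeffs length-4 coefficient vectors
#'   `(intercept, amplitude, width, period)` of the linear map from per-beat
#'   morphology to SBP/DBP in mmHg. The defaults give SBP around 112 mmHg and
#'   DBP around 74 mmHg with negative amplitude loading, mirroring the
#'   inverse PPG-pressure relationship seen in intensive-care waveforms.
#' @param bp_noise_sd SD of the additive Gaussian noise on the per-beat
#'   SBP/DBP truth values, mmHg.
#' @param seed integer seed; the generator is fully deterministic given it.
#' @return a validated list of class `synth_config`.
#' @export
synth_config <- function(fs = 125, duration = 60,
                         hr_mean = 75, hr_sd = 3,
                         pulse_amp_mean = 1, pulse_amp_sd = 0.1,
                         amp_drift_phi = 0.95,
                         width_mean = 0.12, width_sd = 0.01,
                         dicrotic_ratio = 0.35,
                         baseline_amp = 0.3, baseline_freq = 0.2,
                         noise_sd = 0.02,
                         sbp_coeffs = c(intercept = 140, amp = -15,
                                        width = -40, period = -10),
                         dbp_coeffs = c(intercept = 90, amp = -10,
                                        width = -20, period = -5),
                         bp_noise_sd = 1, seed = 1L) {
  cfg <- list(fs = fs, duration = duration, hr_mean = hr_mean, hr_sd = hr_sd,
              pulse_amp_mean = pulse_amp_mean, pulse_amp_sd = pulse_amp_sd,
              amp_drift_phi = amp_drift_phi,
              width_mean = width_mean, width_sd = width_sd,
              dicrotic_ratio = dicrotic_ratio,
              baseline_amp = baseline_amp, baseline_freq = baseline_freq,
              noise_sd = noise_sd,
              sbp_coeffs = unname(sbp_coeffs), dbp_coeffs = unname(dbp_coeffs),
              bp_noise_sd = bp_noise_sd, seed = as.integer(seed))
  if (!is.finite(fs) || fs < 25) stop("fs must be >= 25 Hz")
  if (!is.finite(duration) || duration <= 0) stop("duration must be > 0")
  if (!is.finite(hr_mean) || hr_mean <= 0) stop("hr_mean must be > 0")
  if (hr_sd < 0 || pulse_amp_sd < 0 || width_sd < 0) stop("SDs must be >= 0")
  if (noise_sd < 0 || bp_noise_sd < 0) stop("noise SDs must be >= 0")
  if (dicrotic_ratio < 0 || dicrotic_ratio >= 1) {
    stop("dicrotic_ratio must lie in [0, 1)")
  }
  if (baseline_freq >= 0.5) stop("baseline_freq must stay below 0.5 Hz")
  if (amp_drift_phi < 0 || amp_drift_phi >= 1) {
    stop("amp_drift_phi must lie in [0, 1)")
  }
  if (length(cfg$sbp_coeffs) != 4 || length(cfg$dbp_coeffs) != 4) {
    stop("sbp_coeffs and dbp_coeffs must have length 4")
  }
  class(cfg) <- "synth_config"
  cfg
}

# Evaluate the generator's own RNG stream without touching the caller's.
with_private_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Generate one synthetic PPG + ABP record with per-beat ground truth
#'
#' The PPG channel is a sum over beats of a systolic Gaussian pulse (centred
#' at 0.70 of the beat period, emulating pulse transit delay relative to the
#' pressure upstroke; this late placement also reproduces the negative
#' instantaneous PPG-ABP correlation seen in intensive-care recordings) and
#' a smaller delayed dicrotic Gaussian, plus a sub-0.5 Hz
#' baseline sinusoid and white noise. The ABP channel is a piecewise pulse
#' per beat whose sampled maximum equals the truth-table SBP and sampled
#' minimum (at the beat onset) equals the truth-table DBP, exactly.
#'
#' @param cfg a [synth_config()].
#' @return a list with elements `record` (a [waveform_record()] with channels
#'   `PPG` and `ABP`) and `truth` (a data.frame with one row per rendered
#'   beat: `beat`, `onset_sample`, `peak_sample` (0-based), `onset_time`,
#'   `amp`, `width`, `period`, `sbp`, `dbp`, `complete`).
#' @export
generate_record <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  with_private_seed(cfg$seed, generate_record_impl(cfg))
}

generate_record_impl <- function(cfg) {
  fs <- cfg$fs
  n <- round(cfg$duration * fs)
  t <- (seq_len(n) - 1) / fs

  # draw beats until they cover the record, then one spare
  onsets <- 0
  periods <- numeric(0)
  while (sum(periods) < cfg$duration + 2) {
    hr <- min(200, max(30, stats::rnorm(1, cfg$hr_mean, cfg$hr_sd)))
    periods <- c(periods, 60 / hr)
    onsets <- c(onsets, sum(periods))
  }
  nb <- length(periods)
  onsets <- onsets[seq_len(nb)]
  # pulse amplitude follows a stationary AR(1) across beats (slow vasomotor
  # drift): keeps per-beat SD at pulse_amp_sd while giving segments distinct
  # mean amplitudes, so the feature -> pressure map survives within-segment
  # averaging
  e <- numeric(nb)
  e[1] <- stats::rnorm(1)
  phi <- cfg$amp_drift_phi
  if (nb > 1) {
    innov <- stats::rnorm(nb - 1, 0, sqrt(1 - phi^2))
    for (k in 2:nb) e[k] <- phi * e[k - 1] + innov[k - 1]
  }
  amp <- pmax(0.1, cfg$pulse_amp_mean + cfg$pulse_amp_sd * e)
  width <- pmin(0.4, pmax(0.04, stats::rnorm(nb, cfg$width_mean, cfg$width_sd)))
  sbp <- cfg$sbp_coeffs[1] + cfg$sbp_coeffs[2] * amp +
    cfg$sbp_coeffs[3] * width + cfg$sbp_coeffs[4] * periods +
    stats::rnorm(nb, 0, cfg$bp_noise_sd)
  dbp <- cfg$dbp_coeffs[1] + cfg$dbp_coeffs[2] * amp +
    cfg$dbp_coeffs[3] * width + cfg$dbp_coeffs[4] * periods +
    stats::rnorm(nb, 0, cfg$bp_noise_sd)
  if (any(sbp <= dbp)) {
    stop("synth_config rejected: generated SBP <= DBP for at least one beat; ",
         "adjust sbp_coeffs/dbp_coeffs or bp_noise_sd")
  }

  # PPG: systolic pulse late in the beat (transit delay), dicrotic after it
  ppg <- numeric(n)
  for (k in seq_len(nb)) {
    c_sys <- onsets[k] + 0.70 * periods[k]
    c_dic <- onsets[k] + 0.95 * periods[k]
    w_sys <- width[k]
    w_dic <- 0.8 * width[k]
    lo <- max(1L, 1L + floor((c_sys - 5 * w_sys) * fs))
    hi <- min(n, 1L + ceiling((c_dic + 5 * w_dic) * fs))
    if (lo > n || hi < 1L) next
    idx <- lo:hi
    tt <- t[idx]
    ppg[idx] <- ppg[idx] +
      amp[k] * exp(-0.5 * ((tt - c_sys) / w_sys)^2) +
      cfg$dicrotic_ratio * amp[k] * exp(-0.5 * ((tt - c_dic) / w_dic)^2)
  }
  ppg <- ppg + cfg$baseline_amp * sin(2 * pi * cfg$baseline_freq * t)
  if (cfg$noise_sd > 0) ppg <- ppg + stats::rnorm(n, 0, cfg$noise_sd)

  # ABP: per-beat pulse with exact sampled extrema (rise to SBP, decay to the
  # next onset's DBP); the onset sample itself carries DBP exactly
  abp <- numeric(n)
  onset_s <- round(onsets * fs)          # 0-based sample indices
  peak_s <- rep(NA_integer_, nb)
  for (k in seq_len(nb)) {
    s0 <- onset_s[k]
    s1 <- if (k < nb) onset_s[k + 1] else n
    nk <- s1 - s0
    if (nk < 4 || s0 >= n) next
    rise <- max(2L, as.integer(round(0.3 * nk)))
    j <- 0:(nk - 1L)
    shape <- ifelse(j <= rise,
                    0.5 - 0.5 * cos(pi * j / rise),
                    0.5 + 0.5 * cos(pi * (j - rise) / (nk - rise)))
    vals <- dbp[k] + (sbp[k] - dbp[k]) * shape
    idx <- (s0 + 1L) + j
    keep <- idx <= n
    abp[idx[keep]] <- vals[keep]
    if (s0 + rise < n) peak_s[k] <- s0 + rise
  }

  truth <- data.frame(
    beat = seq_len(nb), onset_sample = onset_s, peak_sample = peak_s,
    onset_time = onsets, amp = amp, width = width, period = periods,
    sbp = sbp, dbp = dbp,
    complete = c(onset_s[-1], n + 1L) <= n & !is.na(peak_s)
  )
  truth <- truth[!is.na(truth$peak_sample) & truth$onset_sample < n, , drop = FALSE]
  rownames(truth) <- NULL

  rec <- waveform_record(list(PPG = ppg, ABP = abp), fs = fs,
                         record_id = sprintf("synth-seed%d", cfg$seed))
  list(record = rec, truth = truth)
}

#' Generate a dataset of independent synthetic records
#'
#' Record `k` uses its own seed derived deterministically from `cfg$seed`
#' (seed-splitting by record index), so records are independent but the whole
#' dataset is reproducible.
#'
#' @param cfg a [synth_config()].
#' @param n_records number of records (>= 1).
#' @return list with `records` (list of [waveform_record()]) and `truth`
#'   (pooled truth data.frame with a `record_id` column).
#' @export
generate_dataset <- function(cfg, n_records) {
  stopifnot(inherits(cfg, "synth_config"))
  if (!is.numeric(n_records) || n_records < 1) {
    stop("n_records must be >= 1")
  }
  n_records <- as.integer(n_records)
  out <- vector("list", n_records)
  for (k in seq_len(n_records)) {
    cfg_k <- cfg
    cfg_k$seed <- (cfg$seed + 7919L * k) %% .Machine$integer.max
    gen <- generate_record(cfg_k)
    gen$record$record_id <- sprintf("synth-%03d", k)
    gen$truth$record_id <- gen$record$record_id
    out[[k]] <- gen
  }
  list(records = lapply(out, `[[`, "record"),
       truth = do.call(rbind, lapply(out, `[[`, "truth")))
}
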