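#' Remove baseline wander with a running-median filter
#'
#' Estimates the slow baseline by (by default two) passes of a running median
#' and subtracts it. Median filtering is the standard baseline-correction
#' choice for PPG because it tracks sub-Hz drift without distorting pulse
#' morphology. For the median to track a drift component its window must be
#' short relative to the drift period; the 0.6 s / 1.2 s default pair removes
#' drift below roughly 0.5 Hz while leaving beat-rate content (about 1 Hz and
#' up) intact.
#'
#' @param x numeric signal.
#' @param fs sampling frequency, Hz.
#' @param window_s numeric vector of median window lengths in seconds, applied
#'   in sequence to form the baseline estimate. Each window must span at
#'   least 3 samples and no more than the signal.
#' @return `x` minus the estimated baseline.
#' @export
remove_baseline <- function(x, fs, window_s = c(0.6, 1.2)) {
  stopifnot(is.numeric(x), length(x) >= 3, is.finite(fs), fs > 0)
  baseline <- x
  for (w_s in window_s) {
    w <- as.integer(round(w_s * fs))
    if (w < 3L) stop("median window must span at least 3 samples")
    if (w > length(x)) stop("median window longer than the signal")
    if (w %% 2L == 0L) w <- w + 1L
    baseline <- as.numeric(stats::runmed(baseline, k = w, endrule = "median"))
  }
  x - baseline
}

#' Zero-phase Butterworth low-pass filter
#'
#' Forward-backward (zero-phase) application of a Butterworth low-pass, so
#' pulse timing is preserved for the derivative-based features. The default
#' 5 Hz cutoff removes high-frequency noise from PPG while keeping the pulse
#' and dicrotic components.
#'
#' @param x numeric signal.
#' @param fs sampling frequency, Hz.
#' @param cutoff_hz cutoff frequency, Hz; must satisfy `0 < cutoff_hz < fs/2`.
#' @param order Butterworth order of the one-way filter (effective order is
#'   doubled by the forward-backward pass).
#' @return filtered signal, same length as `x`.
#' @export
lowpass_filter <- function(x, fs, cutoff_hz = 5, order = 4) {
  stopifnot(is.numeric(x), is.finite(fs), fs > 0)
  if (!is.finite(cutoff_hz) || cutoff_hz <= 0 || cutoff_hz >= fs / 2) {
    stop("cutoff_hz must lie strictly between 0 and the Nyquist frequency")
  }
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  as.numeric(signal::filtfilt(bf, x))
}

#' Split a signal into fixed-length analysis windows
#'
#' Left-aligned, half-open windows `[start, start + L)` with 0-based start
#' indices; a trailing partial window is dropped. For a signal of `N >= L`
#' samples the segment count is `floor((N - L) / step) + 1`.
#'
#' @param x preprocessed PPG samples.
#' @param fs sampling frequency, Hz.
#' @param window_s window length in seconds; `window_s * fs` must be >= 16
#'   samples.
#' @param overlap fraction of overlap between consecutive windows, in
#'   `[0, 1)`.
#' @return list of `ppg_segment` objects (fields `x`, `start_index`, `fs`,
#'   `sbp_ref`, `dbp_ref`); empty list when the signal is shorter than one
#'   window.
#' @export
segment_signal <- function(x, fs, window_s = 8, overlap = 0) {
  stopifnot(is.numeric(x), is.finite(fs), fs > 0)
  L <- as.integer(round(window_s * fs))
  if (L < 16L) stop("window must span at least 16 samples")
  if (overlap < 0 || overlap >= 1) stop("overlap must lie in [0, 1)")
  n <- length(x)
  if (n < L) return(list())
  step <- max(1L, as.integer(round(L * (1 - overlap))))
  starts <- seq.int(0L, n - L, by = step)
  lapply(starts, function(s) {
    structure(list(x = x[(s + 1L):(s + L)], start_index = s, fs = fs,
                   sbp_ref = NA_real_, dbp_ref = NA_real_),
              class = "ppg_segment")
  })
}

#' Detect pulse peaks
#'
#' Strict local maxima above the given amplitude percentile of the window,
#' thinned greedily (largest first) so no two kept peaks are closer than the
#' refractory distance. Deterministic and threshold-simple by design.
#'
#' @param x numeric signal (one analysis window).
#' @param fs sampling frequency, Hz.
#' @param min_distance_s refractory period between peaks, seconds.
#' @param percentile amplitude percentile (0-1) a peak must exceed.
#' @return integer vector of peak sample indices (1-based, sorted).
#' @export
find_pulse_peaks <- function(x, fs, min_distance_s = 0.33, percentile = 0.6) {
  n <- length(x)
  if (n < 3) return(integer(0))
  thr <- stats::quantile(x, percentile, names = FALSE)
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  cand <- cand[x[cand] > thr]
  if (!length(cand)) return(integer(0))
  min_gap <- round(min_distance_s * fs)
  ord <- cand[order(-x[cand], cand)]
  kept <- integer(0)
  for (i in ord) {
    if (!length(kept) || all(abs(kept - i) >= min_gap)) kept <- c(kept, i)
  }
  sort(kept)
}

#' Fill per-segment SBP/DBP references from the ABP channel
#'
#' Within each segment's sample range, beats are located on the raw ABP
#' waveform by [find_pulse_peaks()]; the systolic reference is the mean of
#' per-beat maxima (peak values) and the diastolic reference the mean of
#' per-beat minima (the troughs between consecutive peaks; with a single
#' detected beat, the window minimum). Segments in which no beat is detected
#' are excluded, and the exclusion count is reported via `message()` and the
#' `n_excluded` attribute.
#'
#' @param abp ABP channel samples (mmHg), covering every segment's range.
#' @param fs sampling frequency, Hz.
#' @param segments list of `ppg_segment` objects from [segment_signal()].
#' @param min_distance_s,percentile peak-detection parameters, see
#'   [find_pulse_peaks()].
#' @return the retained segments with `sbp_ref`/`dbp_ref` filled, with
#'   attribute `n_excluded`.
#' @export
extract_bp_refs <- function(abp, fs, segments,
                            min_distance_s = 0.33, percentile = 0.6) {
  stopifnot(is.numeric(abp))
  out <- list()
  excluded <- 0L
  for (seg in segments) {
    s <- seg$start_index
    L <- length(seg$x)
    if (s + L > length(abp)) {
      stop("ABP channel does not cover segment sample range")
    }
    w <- abp[(s + 1L):(s + L)]
    pk <- find_pulse_peaks(w, fs, min_distance_s, percentile)
    if (!length(pk)) {
      excluded <- excluded + 1L
      next
    }
    seg$sbp_ref <- mean(w[pk])
    if (length(pk) >= 2L) {
      troughs <- vapply(seq_len(length(pk) - 1L), function(i) {
        span <- (pk[i] + 1L):(pk[i + 1L] - 1L)
        min(w[span])
      }, numeric(1))
      seg$dbp_ref <- mean(troughs)
    } else {
      seg$dbp_ref <- min(w)
    }
    if (seg$sbp_ref <= seg$dbp_ref) {
      excluded <- excluded + 1L
      next
    }
    out[[length(out) + 1L]] <- seg
  }
  if (excluded > 0L) {
    message(sprintf("extract_bp_refs: excluded %d segment(s) with no usable beats",
                    excluded))
  }
  attr(out, "n_excluded") <- excluded
  out
}

#' Preprocessing configuration
#'
#' Defaults: two-stage median baseline (0.6 s, 1.2 s), 5 Hz 4th-order
#' zero-phase Butterworth low-pass, 8 s non-overlapping windows (at least six
#' beats at 50 beats/min, enough support for the entropy estimates), beat
#' detection with a 0.33 s refractory period above the 60th amplitude
#' percentile.
#'
#' @param baseline_window_s median window lengths, seconds.
#' @param lowpass_cutoff_hz,lowpass_order low-pass parameters.
#' @param segment_window_s,segment_overlap segmentation parameters.
#' @param peaks_min_distance_s,peaks_percentile beat-detection parameters.
#' @return a list of class `preprocess_config`.
#' @export
preprocess_config <- function(baseline_window_s = c(0.6, 1.2),
                              lowpass_cutoff_hz = 5, lowpass_order = 4,
                              segment_window_s = 8, segment_overlap = 0,
                              peaks_min_distance_s = 0.33,
                              peaks_percentile = 0.6) {
  structure(list(baseline_window_s = baseline_window_s,
                 lowpass_cutoff_hz = lowpass_cutoff_hz,
                 lowpass_order = lowpass_order,
                 segment_window_s = segment_window_s,
                 segment_overlap = segment_overlap,
                 peaks_min_distance_s = peaks_min_distance_s,
                 peaks_percentile = peaks_percentile),
            class = "preprocess_config")
}

#' Full preprocessing pipeline for one record
#'
#' Fixed stage order: baseline removal, low-pass filtering, segmentation,
#' and (when the record has an ABP channel) SBP/DBP reference extraction on
#' the raw pressure waveform over the same sample windows.
#'
#' @param record a [waveform_record()] with a `PPG` channel.
#' @param config a [preprocess_config()].
#' @return list of `ppg_segment` objects; references filled when ABP is
#'   present, with the `n_excluded` attribute from [extract_bp_refs()].
#' @export
preprocess_pipeline <- function(record, config = preprocess_config()) {
  stopifnot(inherits(record, "waveform_record"),
            inherits(config, "preprocess_config"))
  ppg <- channel(record, "PPG")
  ppg <- remove_baseline(ppg, record$fs, config$baseline_window_s)
  ppg <- lowpass_filter(ppg, record$fs, config$lowpass_cutoff_hz,
                        config$lowpass_order)
  segs <- segment_signal(ppg, record$fs, config$segment_window_s,
                         config$segment_overlap)
  if (has_channel(record, "ABP") && length(segs)) {
    segs <- extract_bp_refs(channel(record, "ABP"), record$fs, segs,
                            config$peaks_min_distance_s,
                            config$peaks_percentile)
  }
  segs
}
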