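test_that("median baseline correction removes slow drift, keeps pulses", {
  fs <- 125
  t <- seq(0, 30, by = 1 / fs)
  expect_equal(remove_baseline(rep(3.7, 1000), fs), rep(0, 1000))

  drift <- sin(2 * pi * 0.2 * t)   # pure sub-Hz drift
  resid <- remove_baseline(drift, fs)
  core <- seq(2 * fs, length(t) - 2 * fs)  # ignore filter edges
  expect_lt(max(abs(resid[core])), 0.1)    # >= 90% attenuation

  # pulse train riding on realistic-amplitude drift: correcting the drifty
  # signal agrees with correcting the drift-free one at the window-mean level
  pulses <- rowSums(sapply(seq(0.4, 29.6, by = 0.8), function(ck) {
    exp(-0.5 * ((t - ck) / 0.1)^2)
  }))
  clean <- remove_baseline(pulses, fs)
  drifty <- remove_baseline(pulses + 0.3 * drift, fs)
  wmean <- function(z) {
    vapply(split(z[core], (seq_along(core) - 1) %/% (2 * fs)), mean, 0)
  }
  expect_lt(max(abs(wmean(drifty) - wmean(clean))), 0.1)

  expect_error(remove_baseline(rnorm(100), fs, window_s = 2), "longer")
  expect_error(remove_baseline(rnorm(1000), fs, window_s = 0.01), "at least 3")
})

test_that("zero-phase low-pass has unit DC gain, flat passband, sharp stopband", {
  fs <- 125
  t <- seq(0, 10, by = 1 / fs)
  dc <- lowpass_filter(rep(2, 500), fs, 5)
  expect_equal(dc[100:400], rep(2, 301), tolerance = 1e-6)  # unit gain at DC
  core <- seq(2 * fs, length(t) - 2 * fs)
  amp_of <- function(f_hz) {
    y <- lowpass_filter(sin(2 * pi * f_hz * t), fs, cutoff_hz = 5)
    max(abs(y[core]))
  }
  expect_equal(amp_of(1), 1, tolerance = 0.01)   # passband preserved
  expect_lt(amp_of(20), 0.1)                     # >= 90% attenuation
  expect_error(lowpass_filter(rnorm(100), fs, cutoff_hz = 70), "Nyquist")
})

test_that("segmentation produces left-aligned fixed windows, partials dropped", {
  fs <- 10
  s1 <- segment_signal(rnorm(100), fs, window_s = 2, overlap = 0)
  expect_length(s1, 5)
  expect_identical(vapply(s1, `[[`, 0L, "start_index") * 1L,
                   as.integer(seq(0, 80, by = 20)))
  s2 <- segment_signal(rnorm(100), fs, window_s = 4, overlap = 0.5)
  expect_length(s2, 4)
  expect_identical(vapply(s2, function(s) s$start_index, 0L),
                   c(0L, 20L, 40L, 60L))
  expect_identical(segment_signal(rnorm(10), fs, window_s = 2), list())

  # count formula floor((N - L)/step) + 1 over random shapes
  set.seed(41)
  for (i in 1:20) {
    N <- sample(200:2000, 1)
    L_s <- sample(2:8, 1)
    ov <- sample(c(0, 0.25, 0.5), 1)
    segs <- segment_signal(rnorm(N), fs, L_s, ov)
    L <- L_s * fs
    step <- round(L * (1 - ov))
    expect_length(segs, if (N >= L) floor((N - L) / step) + 1 else 0)
    starts <- vapply(segs, `[[`, 0L, "start_index")
    expect_true(all(diff(starts) > 0))
  }
})

test_that("SBP/DBP references from a noise-free record match truth exactly", {
  cfg <- synth_config(noise_sd = 0, baseline_amp = 0, bp_noise_sd = 0,
                      hr_sd = 0, pulse_amp_sd = 0, width_sd = 0,
                      duration = 40, seed = 2)
  gen <- generate_record(cfg)
  segs <- segment_signal(channel(gen$record, "PPG"), cfg$fs, 8, 0)
  segs <- extract_bp_refs(channel(gen$record, "ABP"), cfg$fs, segs)
  expect_gt(length(segs), 0)
  tr <- gen$truth
  for (s in segs) {
    expect_equal(s$sbp_ref, tr$sbp[1], tolerance = 1e-9)
    expect_equal(s$dbp_ref, tr$dbp[1], tolerance = 1e-9)
  }
})

test_that("beat-free windows are excluded with a count", {
  segs <- segment_signal(rnorm(2000), 125, 8, 0)
  expect_message(
    kept <- extract_bp_refs(rep(100, 2000), 125, segs),
    "excluded"
  )
  expect_length(kept, 0)
  expect_identical(attr(kept, "n_excluded"), 2L)
})

test_that("a single full beat yields its own max as the systolic reference", {
  fs <- 125
  w <- rep(80, 8 * fs)
  j <- 0:99
  w[301:400] <- 80 + 40 * sin(pi * j / 99)^2   # one smooth beat, peak 120
  segs <- segment_signal(rnorm(8 * fs), fs, 8, 0)
  out <- extract_bp_refs(w, fs, segs)
  expect_length(out, 1)
  expect_identical(out[[1]]$sbp_ref, max(w))
})

test_that("the full preprocessing pipeline composes per the fixed stage order", {
  cfg <- synth_config(seed = 12, duration = 40, noise_sd = 0)
  gen <- generate_record(cfg)
  segs <- preprocess_pipeline(gen$record)
  expect_gt(length(segs), 3)
  expect_true(all(vapply(segs, function(s) s$sbp_ref > s$dbp_ref, TRUE)))
  tr <- gen$truth
  for (s in segs) {
    in_win <- tr$peak_sample >= s$start_index &
      tr$peak_sample < s$start_index + length(s$x)
    expect_equal(s$sbp_ref, mean(tr$sbp[in_win]), tolerance = 0.5)
  }
})

test_that("reapplying the filters leaves output baseline-free with stable pulse timing", {
  cfg <- synth_config(seed = 12, duration = 40, noise_sd = 0)
  gen <- generate_record(cfg)
  fs <- cfg$fs
  x <- lowpass_filter(remove_baseline(channel(gen$record, "PPG"), fs), fs)
  y <- lowpass_filter(remove_baseline(x, fs), fs)
  core <- seq(2 * fs, length(x) - 2 * fs)
  # waveform shape is preserved up to a gain: high correlation, every pulse
  # peak recovered within 2 samples (16 ms)
  expect_gt(cor(x[core], y[core]), 0.99)
  px <- find_pulse_peaks(x[core], fs)
  py <- find_pulse_peaks(y[core], fs)
  expect_equal(length(px), length(py))
  expect_lte(max(abs(px - py)), 2)
})
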