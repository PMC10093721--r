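#' Feature-extraction parameters
#'
#' Defaults follow established practice for waveform feature extraction:
#' zero thresholds for the crossing counts, amplitude-relative thresholds
#' (`0.5 * sd`) for Willison amplitude and myopulse rate so the counts do not
#' depend on PPG gain, `m = 2` and `r = 0.2 * sd` for the template entropies,
#' 16 equal-width histogram bins for Shannon entropy, ordinal patterns of
#' order 3 at delay 1 for permutation entropy, and `kmax = 10` Higuchi
#' scales. `fuzzyen_r`/`fuzzyen_n` are retained for forward compatibility
#' with template-based fuzzy entropy but are unused by the membership-based
#' statistic computed here (see [fuzzy_entropy()]).
#'
#' @param zc_threshold,ssc_threshold absolute thresholds (signal units).
#' @param wamp_threshold,myop_threshold absolute numbers, or
#'   `list(rel = f)` for `f * sd(x)`.
#' @param sampen_m,apen_m embedding dimensions (>= 1).
#' @param sampen_r,apen_r,fuzzyen_r tolerances as fractions of `sd(x)` (> 0).
#' @param fuzzyen_n fuzzy gradient exponent (unused by the membership form).
#' @param shannon_bins histogram bins (>= 2).
#' @param permen_order,permen_delay ordinal-pattern parameters.
#' @param higuchi_kmax largest Higuchi scale (>= 2).
#' @return a validated list of class `feature_params`.
#' @export
feature_params <- function(zc_threshold = 0, ssc_threshold = 0,
                           wamp_threshold = list(rel = 0.5),
                           myop_threshold = list(rel = 0.5),
                           sampen_m = 2, sampen_r = 0.2,
                           apen_m = 2, apen_r = 0.2,
                           fuzzyen_r = 0.2, fuzzyen_n = 2,
                           shannon_bins = 16,
                           permen_order = 3, permen_delay = 1,
                           higuchi_kmax = 10) {
  p <- list(zc_threshold = zc_threshold, ssc_threshold = ssc_threshold,
            wamp_threshold = wamp_threshold, myop_threshold = myop_threshold,
            sampen_m = sampen_m, sampen_r = sampen_r,
            apen_m = apen_m, apen_r = apen_r,
            fuzzyen_r = fuzzyen_r, fuzzyen_n = fuzzyen_n,
            shannon_bins = shannon_bins,
            permen_order = permen_order, permen_delay = permen_delay,
            higuchi_kmax = higuchi_kmax)
  if (p$sampen_m < 1 || p$apen_m < 1) stop("embedding dimensions must be >= 1")
  if (p$sampen_r <= 0 || p$apen_r <= 0 || p$fuzzyen_r <= 0) {
    stop("tolerances must be > 0")
  }
  if (p$shannon_bins < 2) stop("shannon_bins must be >= 2")
  if (p$permen_order < 2) stop("permen_order must be >= 2")
  if (p$higuchi_kmax < 2) stop("higuchi_kmax must be >= 2")
  class(p) <- "feature_params"
  p
}

#' Extract all 24 features from one segment
#'
#' Concatenates [time_features()] with the 7 chaotic features (sample,
#' approximate, fuzzy, Shannon and permutation entropy; Higuchi and Katz
#' fractal dimension), in the canonical [ppg_feature_names()] order.
#'
#' @param segment a `ppg_segment` from [segment_signal()], or a bare numeric
#'   vector of preprocessed PPG samples.
#' @param params a [feature_params()].
#' @return named numeric vector of length 24, all values finite.
#' @export
extract_features <- function(segment, params = feature_params()) {
  x <- if (inherits(segment, "ppg_segment")) segment$x else segment
  if (!is.numeric(x) || length(x) < 2) stop("segment must hold >= 2 samples")
  if (!all(is.finite(x))) stop("segment contains non-finite samples")
  wrap <- function(name, f) {
    tryCatch(f(), error = function(e) {
      stop(sprintf("feature '%s': %s", name, conditionMessage(e)))
    })
  }
  tf <- wrap("time_features", function() time_features(x, params))
  out <- c(
    tf,
    sampen = wrap("sampen", function()
      sample_entropy(x, params$sampen_m, params$sampen_r)),
    apen = wrap("apen", function()
      approximate_entropy(x, params$apen_m, params$apen_r)),
    fuzzyen = wrap("fuzzyen", function() fuzzy_entropy(x)),
    shannon = wrap("shannon", function()
      shannon_entropy(x, params$shannon_bins)),
    permen = wrap("permen", function()
      permutation_entropy(x, params$permen_order, params$permen_delay)),
    higuchi_fd = wrap("higuchi_fd", function()
      higuchi_fd(x, params$higuchi_kmax)),
    katz_fd = wrap("katz_fd", function() katz_fd(x))
  )
  stopifnot(identical(names(out), ppg_feature_names()))
  out
}

#' Build a feature table from preprocessed segments
#'
#' Runs [extract_features()] on every segment and pairs the result with the
#' segment's SBP/DBP references. Segments without references are rejected
#' (run [extract_bp_refs()] first, or use [extract_features()] directly for
#' inference-only work).
#'
#' @param segments list of `ppg_segment` objects with references filled.
#' @param params a [feature_params()].
#' @return a [feature_table()].
#' @export
extract_feature_table <- function(segments, params = feature_params()) {
  if (!length(segments)) {
    empty <- as.data.frame(matrix(numeric(0), ncol = 26,
                                  dimnames = list(NULL, c(ppg_feature_names(),
                                                          "sbp", "dbp"))))
    return(feature_table(empty))
  }
  rows <- lapply(segments, function(seg) {
    if (!inherits(seg, "ppg_segment")) stop("segments must be ppg_segment objects")
    if (is.na(seg$sbp_ref) || is.na(seg$dbp_ref)) {
      stop("segment lacks SBP/DBP references; run extract_bp_refs() first")
    }
    c(extract_features(seg, params), sbp = seg$sbp_ref, dbp = seg$dbp_ref)
  })
  feature_table(as.data.frame(do.call(rbind, rows)))
}
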