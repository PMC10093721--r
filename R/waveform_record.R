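#' Multichannel waveform record
#'
#' Container for a sampled physiological recording: one or more equal-length
#' channels, a sampling frequency, and an identifier. The estimation pipeline
#' expects a `"PPG"` channel (arbitrary units); training workflows additionally
#' need an `"ABP"` channel in mmHg from which systolic/diastolic references are
#' taken.
#'
#' @param samples named list of numeric vectors (or a data.frame/matrix with
#'   column names), one element per channel, all of equal length (at least 2
#'   samples). Stored internally as double precision.
#' @param fs sampling frequency in Hz (finite, > 0).
#' @param record_id identifier string.
#'
#' @return An object of class `waveform_record` with elements `samples`
#'   (named list of doubles), `fs`, `channel_names` and `record_id`.
#' @examples
#' rec <- waveform_record(list(PPG = sin(seq(0, 10, by = 0.008))), fs = 125)
#' rec
#' @export
waveform_record <- function(samples, fs, record_id = "record") {
  if (is.matrix(samples) || is.data.frame(samples)) {
    samples <- as.list(as.data.frame(samples))
  }
  if (!is.list(samples) || length(samples) == 0) {
    stop("`samples` must be a non-empty named list of numeric vectors")
  }
  nms <- names(samples)
  if (is.null(nms) || any(!nzchar(nms))) {
    stop("every channel must be named")
  }
  if (anyDuplicated(nms)) {
    stop("channel names must be unique")
  }
  lens <- vapply(samples, length, integer(1))
  if (length(unique(lens)) != 1L) {
    stop("all channels must have equal length (ragged channels)")
  }
  if (lens[[1]] < 2L) {
    stop("channels must contain at least 2 samples")
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("`fs` must be a single positive finite number (Hz)")
  }
  samples <- lapply(samples, function(x) {
    if (!is.numeric(x)) stop("channel samples must be numeric")
    as.double(x)
  })
  structure(
    list(samples = samples, fs = as.double(fs),
         channel_names = nms, record_id = as.character(record_id)),
    class = "waveform_record"
  )
}

#' @export
print.waveform_record <- function(x, ...) {
  n <- length(x$samples[[1]])
  cat(sprintf("<waveform_record '%s'>\n", x$record_id))
  cat(sprintf("  channels: %s\n", paste(x$channel_names, collapse = ", ")))
  cat(sprintf("  fs: %g Hz, %d samples (%.1f s)\n", x$fs, n, n / x$fs))
  invisible(x)
}

#' Number of samples per channel of a waveform record
#' @param record a `waveform_record`.
#' @return integer sample count.
#' @export
n_samples <- function(record) {
  stopifnot(inherits(record, "waveform_record"))
  length(record$samples[[1]])
}

#' Extract one channel of a waveform record
#'
#' @param record a `waveform_record`.
#' @param name channel name (after aliasing, e.g. `"PPG"`, `"ABP"`).
#' @return numeric vector of samples.
#' @export
channel <- function(record, name) {
  stopifnot(inherits(record, "waveform_record"))
  if (!name %in% record$channel_names) {
    stop(sprintf("record '%s' has no channel '%s' (channels: %s)",
                 record$record_id, name,
                 paste(record$channel_names, collapse = ", ")))
  }
  record$samples[[name]]
}

#' Has a record a given channel?
#' @inheritParams channel
#' @return logical.
#' @export
has_channel <- function(record, name) {
  inherits(record, "waveform_record") && name %in% record$channel_names
}

# Map common waveform-database signal names onto the canonical channel labels
# used by the pipeline. Case-insensitive; unknown names pass through unchanged.
canonical_channel_name <- function(name) {
  alias <- c(PLETH = "PPG", PPG = "PPG", ABP = "ABP", ART = "ABP")
  up <- toupper(trimws(name))
  out <- unname(alias[up])
  ifelse(is.na(out), name, out)
}
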