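#' Read a waveform record from disk
#'
#' Two on-disk formats are supported:
#'
#' * `"csv"` — comma-separated values with a mandatory header row naming the
#'   channels and a `# fs=<value>` comment line carrying the sampling
#'   frequency (an optional `# record_id=<id>` line names the record). This is
#'   the fixture format written by [write_record()].
#' * `"wfdb"` — a WFDB-style record: a text header (`<record>.hea`) plus one
#'   16-bit little-endian signal file, the layout used by physiological
#'   waveform databases. `path` may point at the header with or without the
#'   `.hea` extension. Only format 16 is supported.
#'
#' Channel names are passed through an alias map (`PLETH` -> `PPG`,
#' `ART`/`ABP` -> `ABP`, case-insensitive) so records exported from common
#' waveform databases load unchanged.
#'
#' @param path file path (for `"wfdb"`, the header file).
#' @param format `"csv"` or `"wfdb"`.
#' @return a [waveform_record()].
#' @export
read_record <- function(path, format = c("csv", "wfdb")) {
  format <- match.arg(format)
  switch(format,
    csv  = read_record_csv(path),
    wfdb = read_record_wfdb(path)
  )
}

read_record_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  head_lines <- readLines(path, n = 50L, warn = FALSE)
  meta <- grep("^#", head_lines, value = TRUE)
  fs_line <- grep("^#\\s*fs\\s*=", meta, value = TRUE)
  if (length(fs_line) == 0) {
    stop(sprintf("format error in '%s': missing '# fs=<value>' line", path))
  }
  fs <- as.numeric(sub("^#\\s*fs\\s*=\\s*", "", fs_line[[1]]))
  if (!is.finite(fs)) {
    stop(sprintf("format error in '%s': unparsable fs", path))
  }
  id_line <- grep("^#\\s*record_id\\s*=", meta, value = TRUE)
  record_id <- if (length(id_line)) {
    trimws(sub("^#\\s*record_id\\s*=\\s*", "", id_line[[1]]))
  } else {
    sub("\\.[^.]*$", "", basename(path))
  }
  df <- tryCatch(
    utils::read.csv(path, comment.char = "#", check.names = FALSE,
                    colClasses = "numeric"),
    error = function(e) stop(sprintf("format error in '%s': %s",
                                     path, conditionMessage(e)))
  )
  if (anyNA(df)) {
    stop(sprintf("format error in '%s': ragged or non-numeric columns", path))
  }
  names(df) <- canonical_channel_name(names(df))
  waveform_record(df, fs = fs, record_id = record_id)
}

# Minimal WFDB header+signal reader: record line "<name> <nsig> <fs> <nsamp>",
# one line per signal "<file> <fmt> <gain>(<baseline>)/<units> ... <description>",
# samples interleaved across signals in a single int16 little-endian file.
read_record_wfdb <- function(path) {
  hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea)) stop(sprintf("file not found: %s", hea))
  lines <- readLines(hea, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) < 2) stop(sprintf("format error in '%s': truncated header", hea))
  rec_tok <- strsplit(lines[[1]], "\\s+")[[1]]
  if (length(rec_tok) < 4) {
    stop(sprintf("format error in '%s': record line needs name/nsig/fs/nsamp", hea))
  }
  record_name <- sub("/.*$", "", rec_tok[[1]])
  nsig <- as.integer(rec_tok[[2]])
  fs <- as.numeric(rec_tok[[3]])
  nsamp <- as.integer(rec_tok[[4]])
  if (!is.finite(fs)) stop(sprintf("format error in '%s': missing fs", hea))
  if (length(lines) < 1 + nsig) {
    stop(sprintf("format error in '%s': %d signal lines expected", hea, nsig))
  }
  sig <- lapply(lines[2:(1 + nsig)], parse_wfdb_signal_line, hea = hea)
  files <- unique(vapply(sig, `[[`, "", "file"))
  if (length(files) != 1) {
    stop(sprintf("format error in '%s': multi-file records not supported", hea))
  }
  dat <- file.path(dirname(hea), files)
  if (!file.exists(dat)) stop(sprintf("file not found: %s", dat))
  raw <- readBin(dat, what = "integer", n = nsig * nsamp, size = 2L,
                 signed = TRUE, endian = "little")
  if (length(raw) < nsig * nsamp) {
    stop(sprintf("format error in '%s': signal file shorter than header claims", dat))
  }
  mat <- matrix(as.double(raw[seq_len(nsig * nsamp)]), ncol = nsig, byrow = TRUE)
  chans <- lapply(seq_len(nsig), function(i) {
    (mat[, i] - sig[[i]]$baseline) / sig[[i]]$gain
  })
  names(chans) <- canonical_channel_name(vapply(sig, `[[`, "", "name"))
  waveform_record(chans, fs = fs, record_id = record_name)
}

parse_wfdb_signal_line <- function(line, hea) {
  tok <- strsplit(line, "\\s+")[[1]]
  if (length(tok) < 3) {
    stop(sprintf("format error in '%s': bad signal line '%s'", hea, line))
  }
  fmt <- sub("x\\d+$", "", sub(":\\d+$", "", tok[[2]]))
  if (fmt != "16") {
    stop(sprintf("unsupported WFDB signal format '%s' in '%s' (only 16)", fmt, hea))
  }
  gain_tok <- tok[[3]]
  gain_num <- sub("/.*$", "", gain_tok)            # strip "/units"
  baseline <- 0
  if (grepl("\\(", gain_num)) {
    baseline <- as.numeric(sub("^.*\\(", "", sub("\\).*$", "", gain_num)))
    gain_num <- sub("\\(.*$", "", gain_num)
  }
  gain <- as.numeric(gain_num)
  if (!is.finite(gain) || gain == 0) gain <- 200   # WFDB default gain
  name <- if (length(tok) >= 9) paste(tok[9:length(tok)], collapse = " ") else tok[[1]]
  list(file = tok[[1]], gain = gain, baseline = baseline, name = name)
}

#' Write a waveform record as self-contained CSV
#'
#' Samples are written with 17 significant digits so a write/read round trip
#' reproduces doubles exactly. The sampling frequency and record id travel in
#' `#`-comment lines, keeping the fixture a single file.
#'
#' @param record a [waveform_record()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_record <- function(record, path) {
  stopifnot(inherits(record, "waveform_record"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# fs=%s", format(record$fs, digits = 17)), con)
  writeLines(sprintf("# record_id=%s", record$record_id), con)
  writeLines(paste(record$channel_names, collapse = ","), con)
  cols <- lapply(record$samples, function(x) sprintf("%.17g", x))
  writeLines(do.call(paste, c(cols, sep = ",")), con)
  invisible(path)
}

#' Feature table: per-segment features plus blood-pressure references
#'
#' A data.frame with one row per analysed segment: the 24 features in the
#' canonical column order given by [ppg_feature_names()], followed by `sbp`
#' and `dbp` reference columns in mmHg. Validated on construction: feature
#' columns must be complete (no missing values) and every row must satisfy
#' `sbp > dbp`.
#'
#' @param df data.frame with the 26 columns described above (extra columns are
#'   rejected; order is normalised to canonical).
#' @return the validated data.frame with class `feature_table`.
#' @export
feature_table <- function(df) {
  want <- c(ppg_feature_names(), "sbp", "dbp")
  if (!is.data.frame(df)) stop("`df` must be a data.frame")
  missing_cols <- setdiff(want, names(df))
  if (length(missing_cols)) {
    stop(sprintf("feature table missing columns: %s",
                 paste(missing_cols, collapse = ", ")))
  }
  extra <- setdiff(names(df), want)
  if (length(extra)) {
    stop(sprintf("unexpected feature table columns: %s",
                 paste(extra, collapse = ", ")))
  }
  df <- df[, want, drop = FALSE]
  feat <- df[, ppg_feature_names(), drop = FALSE]
  if (nrow(df) > 0) {
    if (anyNA(feat) || !all(vapply(feat, function(x) all(is.finite(x)), TRUE))) {
      stop("feature columns must be finite with no missing values")
    }
    if (!all(df$sbp > df$dbp)) {
      stop("invariant violation: sbp must exceed dbp in every row")
    }
  }
  class(df) <- c("feature_table", "data.frame")
  df
}

#' Canonical feature column order
#'
#' The 17 time-domain feature names followed by the 7 chaotic feature names,
#' in the order used throughout the package.
#' @return character vector of length 24.
#' @export
ppg_feature_names <- function() {
  c("emav", "ewl", "mav", "wl", "zc", "ssc", "rms", "aac", "dasdv",
    "log_detector", "mmav1", "mmav2", "myop", "ssi", "var", "wamp", "mfl",
    "sampen", "apen", "fuzzyen", "shannon", "permen", "higuchi_fd", "katz_fd")
}

#' Write / read a feature table
#'
#' Full-precision text (17 significant digits) so the round trip is
#' value-exact for doubles. Reading re-validates the table invariants.
#'
#' @param table a [feature_table()].
#' @param path CSV file path.
#' @return `write_feature_table`: `path` invisibly; `read_feature_table`: a
#'   validated [feature_table()].
#' @export
write_feature_table <- function(table, path) {
  table <- feature_table(as.data.frame(table))
  con <- tryCatch(file(path, open = "wt"),
                  error = function(e) stop(sprintf("cannot write '%s': %s",
                                                   path, conditionMessage(e))))
  on.exit(close(con))
  writeLines(paste(names(table), collapse = ","), con)
  if (nrow(table) > 0) {
    cols <- lapply(table, function(x) sprintf("%.17g", x))
    writeLines(do.call(paste, c(cols, sep = ",")), con)
  }
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, check.names = FALSE)
  df[] <- lapply(df, as.double)
  feature_table(df)
}
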