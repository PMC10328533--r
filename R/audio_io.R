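# Minimal RIFF/WAVE PCM reader and writer (16-bit integer). Only what
# is needed to move mono story audio in and out of the pipeline.

#' Read a 16-bit PCM WAV file
#'
#' @param path Path to a RIFF/WAVE file with 16-bit integer PCM data.
#' @return List with `samples` (numeric matrix, channels x frames,
#'   scaled to `[-1, 1]`) and `rate` (Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF"))
    stop_speechTRF("not a RIFF file", "bad_audio_file")
  readBin(con, "integer", 1, size = 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE"))
    stop_speechTRF("not a WAVE file", "bad_audio_file")
  fmt <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || !nzchar(id))
      stop_speechTRF("no data chunk found", "bad_audio_file")
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw_fmt <- readBin(con, "raw", size)
      fmt <- list(
        format = readBin(raw_fmt[1:2], "integer", 1, 2, endian = "little"),
        channels = readBin(raw_fmt[3:4], "integer", 1, 2, endian = "little"),
        rate = readBin(raw_fmt[5:8], "integer", 1, 4, endian = "little"),
        bits = readBin(raw_fmt[15:16], "integer", 1, 2, endian = "little"))
    } else if (identical(id, "data")) {
      if (is.null(fmt))
        stop_speechTRF("data chunk before fmt chunk", "bad_audio_file")
      if (fmt$format != 1L || fmt$bits != 16L)
        stop_speechTRF("only 16-bit integer PCM is supported",
                       "bad_audio_file")
      n <- size %/% 2L
      x <- readBin(con, "integer", n, size = 2, signed = TRUE,
                   endian = "little") / 32768
      samples <- matrix(x, nrow = fmt$channels)
      return(list(samples = samples, rate = fmt$rate))
    } else {
      readBin(con, "raw", size + size %% 2L)
    }
  }
}

#' Write a 16-bit PCM WAV file
#'
#' @param samples Numeric vector (mono) or channels-x-frames matrix
#'   with values in `[-1, 1]` (clipped otherwise).
#' @param rate Sampling rate in Hz.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, rate, path) {
  if (!is.matrix(samples)) samples <- matrix(samples, nrow = 1L)
  x <- as.integer(pmin(pmax(round(as.vector(samples) * 32767), -32768),
                       32767))
  n_bytes <- length(x) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  wint <- function(v, size) writeBin(as.integer(v), con, size = size,
                                     endian = "little")
  writeChar("RIFF", con, eos = NULL); wint(36L + n_bytes, 4)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL); wint(16L, 4)
  wint(1L, 2); wint(nrow(samples), 2); wint(rate, 4)
  wint(rate * nrow(samples) * 2L, 4); wint(nrow(samples) * 2L, 2)
  wint(16L, 2)
  writeChar("data", con, eos = NULL); wint(n_bytes, 4)
  wint(x, 2)
  invisible(path)
}

#' Read interval tiers from a Praat TextGrid
#'
#' Parses the long ("full") TextGrid text format and returns the
#' labelled intervals of the requested interval tiers, as produced by
#' forced-alignment tools for phoneme and word tiers.
#'
#' @param path Path to a TextGrid file (UTF-8).
#' @param tiers Optional character vector of tier names to keep.
#' @param drop_empty Drop intervals with empty labels (default `TRUE`).
#' @return Data frame with columns `tier`, `label`, `onset`, `offset`
#'   (seconds).
#' @export
read_textgrid <- function(path, tiers = NULL, drop_empty = TRUE) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(lines)
  get_num <- function(line) as.numeric(sub(".*=\\s*", "", line))
  get_str <- function(line) {
    m <- regmatches(line, regexpr('"[^"]*"', line))
    if (length(m) == 0L) "" else substr(m, 2, nchar(m) - 1L)
  }
  out <- list()
  tier_name <- NA_character_
  tier_is_interval <- FALSE
  xmin <- xmax <- NA_real_
  for (line in lines) {
    if (grepl("^class\\s*=", line)) {
      tier_is_interval <- identical(get_str(line), "IntervalTier")
    } else if (grepl("^name\\s*=", line)) {
      tier_name <- get_str(line)
    } else if (grepl("^xmin\\s*=", line)) {
      xmin <- get_num(line)
    } else if (grepl("^xmax\\s*=", line)) {
      xmax <- get_num(line)
    } else if (grepl("^text\\s*=", line) && tier_is_interval) {
      out[[length(out) + 1L]] <- data.frame(
        tier = tier_name, label = get_str(line),
        onset = xmin, offset = xmax, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    stop_speechTRF("no interval tiers found in TextGrid",
                   "bad_textgrid")
  df <- do.call(rbind, out)
  if (!is.null(tiers)) df <- df[df$tier %in% tiers, , drop = FALSE]
  if (drop_empty) df <- df[nzchar(df$label), , drop = FALSE]
  rownames(df) <- NULL
  df
}
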