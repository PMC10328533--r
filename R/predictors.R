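# Predictor assembly: named channels on a common time grid, impulse or
# continuous, optionally duplicated into high/low word-entropy
# conditions, plus the nested model ladder.

#' Predictor matrix container
#'
#' Stores named predictor channels (columns) sampled on a common time
#' grid, with per-channel kind (`"impulse"` or `"continuous"`) and
#' entropy-condition tag (`"all"`, `"high"`, `"low"`).
#'
#' @param channels Numeric matrix (time samples x channels) with column
#'   names, or a named list of equal-length numeric vectors.
#' @param sample_rate Sampling rate in Hz.
#' @param kind Character vector of channel kinds, recycled if length 1.
#' @param condition Character vector of condition tags, recycled if
#'   length 1.
#' @return An object of class `predictor_matrix`.
#' @export
predictor_matrix <- function(channels, sample_rate,
                             kind = "continuous", condition = "all") {
  if (is.list(channels) && !is.data.frame(channels))
    channels <- do.call(cbind, channels)
  stopifnot(is.matrix(channels), !is.null(colnames(channels)),
            all(nzchar(colnames(channels))), sample_rate > 0)
  if (anyDuplicated(colnames(channels)))
    stop_speechTRF("duplicate channel names", "bad_predictors")
  nc <- ncol(channels)
  kind <- rep_len(kind, nc)
  condition <- rep_len(condition, nc)
  stopifnot(all(kind %in% c("impulse", "continuous")),
            all(condition %in% c("all", "high", "low")))
  structure(list(channels = channels, sample_rate = sample_rate,
                 kind = setNames(kind, colnames(channels)),
                 condition = setNames(condition, colnames(channels))),
            class = "predictor_matrix")
}

#' @export
print.predictor_matrix <- function(x, ...) {
  cat(sprintf("predictor_matrix: %d channels x %d samples at %g Hz (%.1f s)\n",
              ncol(x$channels), nrow(x$channels), x$sample_rate,
              nrow(x$channels) / x$sample_rate))
  cat(" channels:", paste(colnames(x$channels), collapse = ", "), "\n")
  invisible(x)
}

n_samples <- function(pm) nrow(pm$channels)

#' Subset channels of a predictor matrix
#'
#' @param pm A [predictor_matrix()].
#' @param names Channel names to keep (order preserved).
#' @return A [predictor_matrix()] with those channels.
#' @export
subset_channels <- function(pm, names) {
  stopifnot(inherits(pm, "predictor_matrix"))
  missing <- setdiff(names, colnames(pm$channels))
  if (length(missing) > 0L)
    stop_speechTRF(paste("unknown channels:",
                         paste(missing, collapse = ", ")),
                   "bad_predictors")
  predictor_matrix(pm$channels[, names, drop = FALSE], pm$sample_rate,
                   pm$kind[names], pm$condition[names])
}

#' Channels matching a set of base feature names
#'
#' Matches channel names either exactly or up to a trailing `"_high"` /
#' `"_low"` condition suffix, so model specifications written in terms
#' of base features also select condition-split predictor matrices.
#'
#' @param pm A [predictor_matrix()].
#' @param base Character vector of base channel names.
#' @param condition Optional filter: `"all"`, `"high"` or `"low"`.
#' @return Character vector of matching channel names.
#' @export
matching_channels <- function(pm, base, condition = NULL) {
  nm <- colnames(pm$channels)
  stripped <- sub("_(high|low)$", "", nm)
  keep <- nm %in% base | stripped %in% base
  if (!is.null(condition)) keep <- keep & pm$condition[nm] %in% condition
  nm[keep]
}

#' Sample an impulse channel from timed events
#'
#' Produces a zero time series with each event's value added at the
#' sample nearest its time (round half up); events falling in the same
#' sample bin sum. Event times must lie in `[0, duration)`.
#'
#' @param times Event times in seconds.
#' @param values Event values (recycled; default 1, the phoneme-onset
#'   convention).
#' @param sample_rate Sampling rate in Hz.
#' @param duration Series duration in seconds.
#' @return Numeric vector of `round(duration * sample_rate)` samples.
#' @export
impulse_channel <- function(times, values = 1, sample_rate, duration) {
  n <- round(duration * sample_rate)
  if (any(times < 0 | times >= duration))
    stop_speechTRF("event times must lie in [0, duration)", "bad_events")
  values <- rep_len(values, length(times))
  out <- numeric(n)
  if (length(times) > 0L) {
    idx <- pmin(floor(times * sample_rate + 0.5) + 1L, n)
    for (i in seq_along(idx)) out[idx[i]] <- out[idx[i]] + values[i]
  }
  out
}

#' Normalize channels to unit mean absolute value
#'
#' Divides each channel by its mean absolute value, matching how
#' predictors and responses are scaled before estimation. Idempotent;
#' an all-zero channel is an error naming the channel.
#'
#' @param pm A [predictor_matrix()].
#' @return A [predictor_matrix()] with `mean(abs(x)) == 1` per channel;
#'   the applied scales are stored in the `"scales"` attribute.
#' @export
normalize_channels <- function(pm) {
  stopifnot(inherits(pm, "predictor_matrix"))
  scales <- colMeans(abs(pm$channels))
  zero <- scales == 0
  if (any(zero))
    stop_speechTRF(paste("all-zero channel(s):",
                         paste(colnames(pm$channels)[zero], collapse = ", ")),
                   "zero_channel")
  out <- predictor_matrix(sweep(pm$channels, 2, scales, "/"),
                          pm$sample_rate, pm$kind, pm$condition)
  attr(out, "scales") <- scales
  out
}

#' Duplicate channels into high/low word-entropy conditions
#'
#' Replaces every channel by a `"_high"` and a `"_low"` copy. Samples
#' within a word's `[onset, offset)` interval go to that word's
#' condition channel and are zero in the other. Samples not covered by
#' any word (pauses, the tail after the last offset) inherit the
#' condition of the most recent word (the first word's condition before
#' any word), so the two copies sum to the original channel exactly.
#'
#' @param pm A [predictor_matrix()].
#' @param word_events Word events with `onset`, `offset` and an
#'   assigned `condition` column (see [split_by_entropy()]).
#' @return A [predictor_matrix()] with twice the channels.
#' @export
condition_duplicate <- function(pm, word_events) {
  stopifnot(inherits(pm, "predictor_matrix"),
            all(c("onset", "offset", "condition") %in% names(word_events)))
  if (anyNA(word_events$condition))
    stop_speechTRF("word conditions must be assigned before duplication",
                   "missing_condition")
  we <- word_events[order(word_events$onset), , drop = FALSE]
  n <- n_samples(pm)
  t <- (seq_len(n) - 1) / pm$sample_rate
  # condition label per sample: covering word, else most recent word
  idx <- findInterval(t, we$onset)          # 0 before first word
  idx[idx == 0L] <- 1L
  lab <- we$condition[idx]
  is_high <- lab == "high"
  ch <- pm$channels
  high <- ch * is_high
  low <- ch * !is_high
  colnames(high) <- paste0(colnames(ch), "_high")
  colnames(low) <- paste0(colnames(ch), "_low")
  ord <- as.vector(rbind(seq_len(ncol(ch)), ncol(ch) + seq_len(ncol(ch))))
  both <- cbind(high, low)[, ord, drop = FALSE]
  predictor_matrix(both, pm$sample_rate,
                   rep(pm$kind, each = 2L),
                   rep(c("high", "low"), ncol(ch)))
}

#' Canonical channel names for the standard feature set
#'
#' @param n_bands Number of acoustic bands (default 8).
#' @return Named list of character vectors: `spectrogram`, `edge`,
#'   `phoneme_onset`, `phoneme_surprisal`, `phoneme_entropy`,
#'   `word_frequency`.
#' @export
feature_channel_names <- function(n_bands = 8L) {
  list(spectrogram = paste0("spec_", seq_len(n_bands)),
       edge = paste0("edge_", seq_len(n_bands)),
       phoneme_onset = "phoneme_onset",
       phoneme_surprisal = "phoneme_surprisal",
       phoneme_entropy = "phoneme_entropy",
       word_frequency = "word_frequency")
}

#' The nested encoding-model ladder
#'
#' Returns the strictly nested model sequence used for incremental
#' accuracy comparison: an acoustic base model (gammatone spectrogram
#' plus acoustic edges), then adding phoneme onset, phoneme surprisal,
#' phoneme entropy, and word frequency, one feature at a time.
#'
#' @param n_bands Number of acoustic bands (default 8).
#' @return List of `model_spec` objects (`name`, `channels`), length 5.
#' @export
model_ladder <- function(n_bands = 8L) {
  fc <- feature_channel_names(n_bands)
  acoustic <- c(fc$spectrogram, fc$edge)
  specs <- list(
    list(name = "Acoustic", channels = acoustic),
    list(name = "PhonemeOnset",
         channels = c(acoustic, fc$phoneme_onset)),
    list(name = "PhonemeSurprisal",
         channels = c(acoustic, fc$phoneme_onset, fc$phoneme_surprisal)),
    list(name = "PhonemeEntropy",
         channels = c(acoustic, fc$phoneme_onset, fc$phoneme_surprisal,
                      fc$phoneme_entropy)),
    list(name = "WordFrequency",
         channels = c(acoustic, fc$phoneme_onset, fc$phoneme_surprisal,
                      fc$phoneme_entropy, fc$word_frequency)))
  lapply(specs, function(s) structure(s, class = "model_spec"))
}

#' Build a custom nested model ladder
#'
#' @param base_channels Channels of the first (base) model.
#' @param additions Named list; each element adds one feature group on
#'   top of the previous model.
#' @param base_name Name of the base model.
#' @return List of `model_spec` objects.
#' @export
custom_ladder <- function(base_channels, additions,
                          base_name = "Base") {
  stopifnot(length(additions) == 0L || !is.null(names(additions)))
  specs <- list(structure(list(name = base_name,
                               channels = base_channels),
                          class = "model_spec"))
  cur <- base_channels
  for (nm in names(additions)) {
    cur <- c(cur, additions[[nm]])
    specs[[length(specs) + 1L]] <-
      structure(list(name = nm, channels = cur), class = "model_spec")
  }
  specs
}

#' Serialize / read a predictor matrix as tab-separated text
#'
#' The file stores one column per channel with `#`-prefixed metadata
#' lines (`sample_rate`, `kind`, `condition`) before the header.
#'
#' @param pm A [predictor_matrix()].
#' @param path Output (or input) path.
#' @return `write_predictors()` returns `path` invisibly;
#'   `read_predictors()` returns a [predictor_matrix()].
#' @export
write_predictors <- function(pm, path) {
  stopifnot(inherits(pm, "predictor_matrix"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(sprintf("# sample_rate\t%.10g", pm$sample_rate),
               paste0("# kind\t", paste(pm$kind, collapse = "\t")),
               paste0("# condition\t", paste(pm$condition, collapse = "\t"))),
             con)
  write.table(pm$channels, con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_predictors
#' @export
read_predictors <- function(path) {
  meta <- readLines(path, n = 3L)
  parts <- strsplit(sub("^# ", "", meta), "\t")
  rate <- as.numeric(parts[[1]][2])
  kind <- parts[[2]][-1]
  condition <- parts[[3]][-1]
  m <- as.matrix(read.delim(path, skip = 3L, sep = "\t",
                            check.names = FALSE))
  predictor_matrix(m, rate, kind, condition)
}
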