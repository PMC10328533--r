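#' Read a pronunciation lexicon
#'
#' Reads a tab-separated lexicon with one header line and three columns:
#' `word` (orthographic form), `frequency` (occurrences per million words)
#' and `phonemes` (space-separated phoneme symbols). This is the layout
#' that SUBTLEX-style frequency tables export once a phonemic
#' transcription column is added.
#'
#' @param path Path to a UTF-8 tab-separated file.
#' @return A data frame with columns `word`, `phonemes`, `frequency`.
#' @seealso [prepare_lexicon()], [build_cohort_index()]
#' @export
read_lexicon <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                   stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("word", "frequency", "phonemes")
  if (!all(need %in% names(df)))
    stop_speechTRF(sprintf("lexicon file must have columns %s",
                           paste(need, collapse = ", ")),
                   "bad_lexicon_file")
  data.frame(word = as.character(df$word),
             phonemes = as.character(df$phonemes),
             frequency = as.numeric(df$frequency),
             stringsAsFactors = FALSE)
}

#' Prepare a raw lexicon for cohort computations
#'
#' Removes entries whose orthographic form contains non-alphabetic
#' characters, drops zero/negative frequencies and empty pronunciations,
#' and (optionally) keeps only the most frequent entries. The result is
#' deterministically ordered by decreasing frequency with ties broken
#' lexicographically on the word.
#'
#' @param entries Data frame with columns `word`, `phonemes`,
#'   `frequency` (per million words).
#' @param max_words Keep only this many of the most frequent entries
#'   (`NULL` keeps all).
#' @return Filtered, ordered data frame of the same shape.
#' @examples
#' lex <- data.frame(word = c("cat", "a1", "dog"),
#'                   phonemes = c("k a t", "a one", "d o g"),
#'                   frequency = c(10, 5, 60))
#' prepare_lexicon(lex)
#' @export
prepare_lexicon <- function(entries, max_words = NULL) {
  stopifnot(is.data.frame(entries),
            all(c("word", "phonemes", "frequency") %in% names(entries)))
  if (nrow(entries) == 0L)
    stop_speechTRF("empty lexicon", "empty_lexicon")
  word <- as.character(entries$word)
  keep <- grepl("^[[:alpha:]]+$", word) &
    is.finite(entries$frequency) & entries$frequency > 0 &
    nzchar(trimws(entries$phonemes))
  out <- entries[keep, , drop = FALSE]
  if (nrow(out) == 0L)
    stop_speechTRF("no usable entries after filtering", "empty_lexicon")
  ord <- order(-out$frequency, out$word, method = "radix")
  out <- out[ord, , drop = FALSE]
  if (!is.null(max_words)) {
    stopifnot(max_words >= 1)
    out <- head(out, max_words)
  }
  rownames(out) <- NULL
  out
}

#' Log word-frequency predictor value
#'
#' Converts an occurrence frequency per million words into the negative
#' log2 of the relative frequency: `-log2(frequency / 1e6)`. A word
#' occurring once per hundred thousand words (10 per million) scores
#' about 16.6 bits; a hypothetical word filling the whole corpus scores
#' 0 bits.
#'
#' @param frequency_per_million Positive occurrence rate per million
#'   words (vectorised).
#' @return Nonnegative predictor value(s) in bits.
#' @export
word_frequency_value <- function(frequency_per_million) {
  if (any(!is.finite(frequency_per_million)) ||
      any(frequency_per_million <= 0))
    stop_speechTRF("frequency must be positive and finite",
                   "bad_frequency")
  -log2(frequency_per_million / 1e6)
}
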