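# Contextual word entropy and the equal-duration entropy split.
#
# Word entropy operationalizes sentence/discourse constraint: the
# Shannon entropy of the next-word distribution given up to `window`
# preceding words. The probability provider abstracts the language
# model; in tests and simulations it is a word-level bigram table whose
# row entropies are available in closed form.

#' Shannon entropy of a probability distribution in bits
#'
#' @param dist Numeric vector of nonnegative probabilities summing to 1
#'   within `tol`.
#' @param tol Normalization tolerance (default `1e-8`).
#' @return Entropy in bits: 0 for a point mass, `log2(length(dist))`
#'   for a uniform distribution.
#' @export
word_entropy <- function(dist, tol = 1e-8) {
  if (any(!is.finite(dist)) || any(dist < 0))
    stop_speechTRF("distribution must be finite and nonnegative",
                   "bad_distribution")
  if (abs(sum(dist) - 1) > tol)
    stop_speechTRF(sprintf("distribution sums to %.10f, not 1", sum(dist)),
                   "bad_distribution")
  -sum(dist * log2_safe(dist))
}

#' Construct a next-word probability provider
#'
#' A provider bundles a vocabulary with a deterministic `query(context)`
#' function returning a probability distribution over the vocabulary
#' given up to 30 preceding words. This is the contract a neural
#' language model would fulfil; [bigram_provider()] is the table-backed
#' implementation used in tests and simulations.
#'
#' @param query Function taking a character vector of context words and
#'   returning a named probability vector over `vocabulary`.
#' @param vocabulary Character vector of tokens.
#' @return An object of class `probability_provider`.
#' @export
probability_provider <- function(query, vocabulary) {
  stopifnot(is.function(query), is.character(vocabulary),
            length(vocabulary) >= 1L)
  structure(list(query = query, vocabulary = vocabulary),
            class = "probability_provider")
}

#' Bigram (word-level Markov) probability provider
#'
#' Wraps a row-stochastic transition matrix as a probability provider:
#' the distribution over the next word depends only on the last context
#' word. With an empty context the `initial` distribution is returned
#' (uniform by default). Because the provider is Markov, word entropies
#' computed from it equal the row entropies of the matrix exactly.
#'
#' @param transition Square numeric matrix with identical row/column
#'   names (the vocabulary); every row must sum to 1 within `1e-9`.
#' @param initial Optional named initial distribution; default uniform.
#' @return A [probability_provider()].
#' @export
bigram_provider <- function(transition, initial = NULL) {
  stopifnot(is.matrix(transition), nrow(transition) == ncol(transition),
            !is.null(rownames(transition)))
  vocab <- rownames(transition)
  if (!identical(vocab, colnames(transition)))
    stop_speechTRF("transition row and column names must match",
                   "bad_transition")
  if (any(abs(rowSums(transition) - 1) > 1e-9))
    stop_speechTRF("transition rows must sum to 1", "bad_transition")
  if (is.null(initial)) {
    initial <- setNames(rep(1 / length(vocab), length(vocab)), vocab)
  } else {
    stopifnot(identical(sort(names(initial)), sort(vocab)))
    initial <- initial[vocab]
  }
  query <- function(context) {
    if (length(context) == 0L) return(initial)
    last <- context[[length(context)]]
    if (!last %in% vocab)
      stop_speechTRF(sprintf("context word '%s' not in vocabulary", last),
                     "provider_vocabulary")
    transition[last, ]
  }
  probability_provider(query, vocab)
}

#' Read a table-backed transition provider
#'
#' Reads a tab-separated table with columns `context`, `token`,
#' `probability` (one row per transition) and returns the corresponding
#' [bigram_provider()]. Missing transitions are zero.
#'
#' @param path Path to a UTF-8 TSV file with a header line.
#' @return A [probability_provider()].
#' @export
read_transition_table <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   fileEncoding = "UTF-8")
  stopifnot(all(c("context", "token", "probability") %in% names(df)))
  vocab <- sort(unique(c(df$context, df$token)))
  tm <- matrix(0, length(vocab), length(vocab),
               dimnames = list(vocab, vocab))
  tm[cbind(match(df$context, vocab), match(df$token, vocab))] <-
    df$probability
  bigram_provider(tm)
}

#' Annotate word events with contextual entropy
#'
#' For each word event, queries the provider with up to `window`
#' preceding words *of the same story part* (the first word of a part
#' uses the empty context) and stores the Shannon entropy of the
#' returned distribution. Context never crosses story-part boundaries
#' because parts were presented separately.
#'
#' @param events Data frame of word events with columns `story_part`,
#'   `word`, `onset`, `offset`, ordered by onset within each part.
#' @param provider A [probability_provider()].
#' @param window Maximum number of preceding context words (default 30).
#' @return `events` with an `entropy` column (bits).
#' @export
annotate_word_entropy <- function(events, provider, window = 30L) {
  stopifnot(inherits(provider, "probability_provider"),
            all(c("story_part", "word", "onset", "offset") %in%
                  names(events)),
            window >= 1L)
  events$entropy <- NA_real_
  for (part in unique(events$story_part)) {
    rows <- which(events$story_part == part)
    if (is.unsorted(events$onset[rows]))
      stop_speechTRF("events must be ordered by onset within story part",
                     "unsorted_events")
    words <- events$word[rows]
    for (i in seq_along(rows)) {
      context <- tail(words[seq_len(i - 1L)], window)
      dist <- tryCatch(
        provider$query(context),
        speechTRF_error = function(e) {
          stop_speechTRF(sprintf("provider failed at word %d ('%s'): %s",
                                 rows[i], words[i], conditionMessage(e)),
                         "provider_vocabulary")
        })
      events$entropy[rows[i]] <- word_entropy(dist)
    }
  }
  events
}

#' Split words into equal-duration high/low entropy conditions
#'
#' Within each story part, words are ordered by entropy (ties broken by
#' onset order) and a single threshold position is chosen, over all
#' possible positions with both sides non-empty, that minimizes the
#' absolute difference between the summed durations of the two sides.
#' Every entropy in the high set is `>=` every entropy in the low set,
#' and the duration imbalance is at most the duration of the single
#' word adjacent to the threshold.
#'
#' @param events Word events with `entropy` annotated (see
#'   [annotate_word_entropy()]) and positive durations.
#' @return `events` with a `condition` column (`"low"` / `"high"`).
#' @export
split_by_entropy <- function(events) {
  if (!"entropy" %in% names(events) || anyNA(events$entropy))
    stop_speechTRF("entropies must be annotated before splitting",
                   "missing_entropy")
  dur <- events$offset - events$onset
  if (any(dur <= 0))
    stop_speechTRF("word durations must be positive", "bad_events")
  events$condition <- NA_character_
  for (part in unique(events$story_part)) {
    rows <- which(events$story_part == part)
    n <- length(rows)
    if (n < 2L)
      stop_speechTRF(sprintf("story part '%s' has fewer than 2 words", part),
                     "too_few_words")
    ord <- rows[order(events$entropy[rows], events$onset[rows],
                      method = "radix")]
    d <- dur[ord]
    total <- sum(d)
    cum <- cumsum(d)
    k <- seq_len(n - 1L)
    imbalance <- abs(2 * cum[k] - total)
    k_best <- k[which.min(imbalance)]
    events$condition[ord[seq_len(k_best)]] <- "low"
    events$condition[ord[(k_best + 1L):n]] <- "high"
  }
  events
}
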