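# Cohort model: prefix-indexed frequency-weighted lexicon.
#
# The cohort at a phoneme prefix is the set of lexicon words whose
# pronunciation starts with that prefix; its mass is the summed
# occurrence frequency of those words. The conditional probability of
# the next phoneme is the ratio of the continuation cohort's mass to the
# current cohort's mass. Words that terminate exactly at a prefix stay
# in the denominator but contribute to no continuation, so continuation
# probabilities plus the termination mass sum to one.

ckey <- function(prefix) paste0("k:", paste(prefix, collapse = " "))

split_phonemes <- function(x) {
  if (length(x) == 1L && grepl("[[:space:]]", x))
    x <- strsplit(trimws(x), "[[:space:]]+")[[1]]
  as.character(x)
}

#' Build a prefix index over a pronunciation lexicon
#'
#' Indexes every phoneme prefix of every word, recording the cohort
#' member set, its summed frequency, the mass of words terminating
#' exactly at the prefix, and the frequency mass of each possible next
#' phoneme. All cohort-model quantities ([phoneme_probability()],
#' [phoneme_entropy()], [word_surprisal_profile()]) are computed from
#' this index.
#'
#' @param entries Prepared lexicon (see [prepare_lexicon()]).
#' @return An object of class `cohort_index`.
#' @examples
#' lex <- data.frame(word = c("cat", "cap", "dog"),
#'                   phonemes = c("k a t", "k a p", "d o g"),
#'                   frequency = c(10, 30, 60))
#' idx <- build_cohort_index(lex)
#' cohort_frequency(idx, c("k", "a"))  # 40
#' @export
build_cohort_index <- function(entries) {
  stopifnot(is.data.frame(entries),
            all(c("word", "phonemes", "frequency") %in% names(entries)))
  if (nrow(entries) == 0L)
    stop_speechTRF("empty lexicon", "empty_lexicon")
  phon <- strsplit(trimws(entries$phonemes), "[[:space:]]+")
  if (any(lengths(phon) == 0L))
    stop_speechTRF("entry with empty pronunciation", "bad_entry")
  if (anyDuplicated(paste(entries$word, entries$phonemes)))
    stop_speechTRF("duplicate (word, phonemes) pairs", "duplicate_entries")
  nodes <- new.env(parent = emptyenv(), hash = TRUE)
  for (i in seq_along(phon)) {
    ph <- phon[[i]]
    f <- entries$frequency[i]
    for (j in 0:length(ph)) {
      k <- ckey(ph[seq_len(j)])
      node <- nodes[[k]] %||%
        list(freq = 0, members = integer(), term_freq = 0,
             next_freq = numeric())
      node$freq <- node$freq + f
      node$members <- c(node$members, i)
      if (j < length(ph)) {
        nx <- ph[[j + 1L]]
        cur <- if (nx %in% names(node$next_freq)) node$next_freq[[nx]] else 0
        node$next_freq[[nx]] <- cur + f
      } else {
        node$term_freq <- node$term_freq + f
      }
      nodes[[k]] <- node
    }
  }
  structure(list(nodes = nodes,
                 inventory = sort(unique(unlist(phon))),
                 total_frequency = sum(entries$frequency),
                 entries = entries),
            class = "cohort_index")
}

#' @export
print.cohort_index <- function(x, ...) {
  cat(sprintf(
    "cohort_index: %d words, %d phoneme symbols, total frequency %.6g\n",
    nrow(x$entries), length(x$inventory), x$total_frequency))
  invisible(x)
}

cohort_node <- function(index, prefix) {
  stopifnot(inherits(index, "cohort_index"))
  node <- index$nodes[[ckey(split_phonemes(prefix))]]
  if (is.null(node))
    stop_speechTRF(sprintf("unattested prefix '%s'",
                           paste(split_phonemes(prefix), collapse = " ")),
                   "unattested_prefix")
  node
}

#' Summed frequency of the cohort at a prefix
#'
#' @param index A [build_cohort_index()] object.
#' @param prefix Phoneme prefix (character vector of symbols, or a
#'   single space-separated string; empty vector = whole lexicon).
#' @return Summed occurrence frequency of the cohort members.
#' @export
cohort_frequency <- function(index, prefix = character()) {
  cohort_node(index, prefix)$freq
}

#' Words in the cohort at a prefix
#'
#' @inheritParams cohort_frequency
#' @return Character vector of orthographic words.
#' @export
cohort_members <- function(index, prefix = character()) {
  index$entries$word[cohort_node(index, prefix)$members]
}

#' Cohort-model conditional phoneme probability
#'
#' Probability of hearing phoneme `next` after the phoneme prefix
#' `prefix`, defined as the ratio of the summed frequencies of the words
#' still compatible after `next` to the summed frequencies of the words
#' compatible with `prefix`. An attested prefix with an unattested
#' continuation yields probability 0; an unattested prefix is an error.
#'
#' @inheritParams cohort_frequency
#' @param next_phoneme Single phoneme symbol.
#' @return Probability in `[0, 1]`.
#' @export
phoneme_probability <- function(index, prefix, next_phoneme) {
  stopifnot(length(next_phoneme) == 1L)
  node <- cohort_node(index, prefix)
  num <- if (next_phoneme %in% names(node$next_freq))
    node$next_freq[[next_phoneme]] else 0
  num / node$freq
}

#' Phoneme surprisal in bits
#'
#' `-log2(p)` for a probability in `(0, 1]`. Zero iff the phoneme was
#' certain; strictly decreasing in `p`.
#'
#' @param p Probability (vectorised), each in `(0, 1]`.
#' @return Surprisal in bits.
#' @export
phoneme_surprisal <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop_speechTRF("probability must lie in (0, 1]", "bad_probability")
  -log2(p)
}

#' Cohort-model phoneme entropy in bits
#'
#' Shannon entropy of the next-phoneme distribution at a prefix:
#' the expected surprisal over all possible continuations, where each
#' continuation's probability is its cohort-frequency ratio. Words that
#' terminate exactly at the prefix keep their mass in the denominator
#' but are not a phoneme continuation, so they contribute no entropy
#' term.
#'
#' @inheritParams cohort_frequency
#' @return Entropy in bits, in `[0, log2(inventory size)]`.
#' @export
phoneme_entropy <- function(index, prefix = character()) {
  node <- cohort_node(index, prefix)
  if (length(node$next_freq) == 0L) return(0)
  p <- node$next_freq / node$freq
  -sum(p * log2_safe(p))
}

#' Per-position cohort statistics for one word
#'
#' Walks a word's pronunciation through the cohort index and returns,
#' for each phoneme position, the conditional probability of that
#' phoneme, its surprisal, and the entropy of the next-phoneme
#' distribution *before* the phoneme is heard (the same conditioning
#' cohort as the surprisal). Summed surprisal telescopes to
#' `-log2(final cohort frequency / total lexicon frequency)`.
#'
#' @inheritParams cohort_frequency
#' @param phonemes The word's pronunciation (vector of symbols or
#'   space-separated string).
#' @return Data frame with columns `position`, `phoneme`,
#'   `probability`, `surprisal`, `entropy`.
#' @export
word_surprisal_profile <- function(index, phonemes) {
  ph <- split_phonemes(phonemes)
  n <- length(ph)
  prob <- surp <- ent <- numeric(n)
  for (i in seq_len(n)) {
    prefix <- ph[seq_len(i - 1L)]
    ent[i] <- phoneme_entropy(index, prefix)
    prob[i] <- phoneme_probability(index, prefix, ph[[i]])
    if (prob[i] <= 0)
      stop_speechTRF(sprintf("phoneme sequence '%s' not in lexicon",
                             paste(ph, collapse = " ")),
                     "unattested_prefix")
    surp[i] <- -log2(prob[i])
  }
  data.frame(position = seq_len(n), phoneme = ph, probability = prob,
             surprisal = surp, entropy = ent, stringsAsFactors = FALSE)
}

#' Attach cohort statistics to phoneme events
#'
#' Computes [word_surprisal_profile()] for each word instance of a
#' phoneme event track and attaches `probability`, `surprisal` and
#' `entropy` columns. Out-of-lexicon words (pronunciations that cannot
#' be walked through the index) receive `NA` statistics under the
#' default policy and their count is recorded in the `"n_oov"`
#' attribute; with `oov = "error"` they abort.
#'
#' @param events Data frame of phoneme events with columns `word_index`
#'   (instance identifier), `phoneme`, and an ordering column `onset`.
#' @param index A [build_cohort_index()] object.
#' @param oov Out-of-lexicon policy: `"na"` (default) or `"error"`.
#' @return `events` with three added columns; attribute `n_oov` gives
#'   the number of skipped word instances.
#' @export
annotate_phoneme_events <- function(events, index, oov = c("na", "error")) {
  oov <- match.arg(oov)
  stopifnot(all(c("word_index", "phoneme", "onset") %in% names(events)))
  events <- events[order(events$word_index, events$onset), , drop = FALSE]
  events$probability <- events$surprisal <- events$entropy <- NA_real_
  cache <- new.env(parent = emptyenv())
  n_oov <- 0L
  for (wi in unique(events$word_index)) {
    rows <- which(events$word_index == wi)
    ph <- events$phoneme[rows]
    key <- ckey(ph)
    prof <- cache[[key]]
    if (is.null(prof)) {
      prof <- tryCatch(word_surprisal_profile(index, ph),
                       unattested_prefix = function(e) NULL)
      cache[[key]] <- if (is.null(prof)) list(oov = TRUE) else prof
    }
    if (is.list(prof) && !is.data.frame(prof)) prof <- NULL
    if (is.null(prof)) {
      if (oov == "error")
        stop_speechTRF(sprintf("word instance %s ('%s') not in lexicon",
                               wi, paste(ph, collapse = " ")),
                       "oov_word")
      n_oov <- n_oov + 1L
      next
    }
    events$probability[rows] <- prof$probability
    events$surprisal[rows] <- prof$surprisal
    events$entropy[rows] <- prof$entropy
  }
  attr(events, "n_oov") <- n_oov
  events
}
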