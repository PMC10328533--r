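# Synthetic study generator: Zipfian toy lexica, bigram-language
# stories with phoneme alignments and exact word entropies,
# ground-truth Gabor-bump kernels, and simulated multichannel
# responses. Everything the pipeline consumes can be generated here
# with known ground truth, which is what the oracle and
# parameter-recovery tests rely on.

#' Generate a Zipfian toy pronunciation lexicon
#'
#' Draws `n_words` unique words as random phoneme strings over a small
#' inventory (single letters, so orthography stays alphabetic) and
#' assigns rank-`r` frequency proportional to `r^-zipf_exponent`,
#' scaled so the most frequent word has 10,000 occurrences per million.
#'
#' @param n_words Number of words (>= 2).
#' @param inventory_size Number of phoneme symbols (default 10,
#'   maximum 26).
#' @param zipf_exponent Zipf exponent (default 1).
#' @param word_length_range Inclusive range of word lengths in phonemes
#'   (default `c(2, 5)`).
#' @param seed Integer seed; identical seeds give identical lexica.
#' @return A prepared lexicon data frame (`word`, `phonemes`,
#'   `frequency`), frequency-descending.
#' @export
make_toy_lexicon <- function(n_words, inventory_size = 10L,
                             zipf_exponent = 1,
                             word_length_range = c(2L, 5L),
                             seed = 1L) {
  stopifnot(n_words >= 2L, inventory_size >= 2L, inventory_size <= 26L,
            word_length_range[1L] >= 1L,
            word_length_range[2L] >= word_length_range[1L])
  n_possible <- sum(inventory_size^
                      (word_length_range[1L]:word_length_range[2L]))
  if (n_possible < n_words)
    stop_speechTRF("inventory too small for that many unique words",
                   "inventory_too_small")
  inv <- letters[seq_len(inventory_size)]
  set.seed(seed)
  words <- character(0)
  tries <- 0L
  while (length(words) < n_words) {
    tries <- tries + 1L
    if (tries > 1000L * n_words)
      stop_speechTRF("failed to draw enough unique words",
                     "inventory_too_small")
    len <- sample(word_length_range[1L]:word_length_range[2L], 1L)
    w <- paste(sample(inv, len, replace = TRUE), collapse = "")
    if (!w %in% words) words <- c(words, w)
  }
  freq <- 1e4 * seq_len(n_words)^(-zipf_exponent)
  lex <- data.frame(
    word = words,
    phonemes = vapply(strsplit(words, ""), paste, "", collapse = " "),
    frequency = freq, stringsAsFactors = FALSE)
  prepare_lexicon(lex)
}

#' Random row-stochastic word transition matrix
#'
#' Dirichlet-distributed rows over the lexicon vocabulary, the bigram
#' language model behind synthetic stories.
#'
#' @param lexicon A lexicon data frame (`word` column used).
#' @param concentration Dirichlet concentration (small values give
#'   peaky, low-entropy rows; default 0.5).
#' @param seed Integer seed.
#' @return Row-stochastic matrix with word dimnames.
#' @export
random_transition_matrix <- function(lexicon, concentration = 0.5,
                                     seed = 1L) {
  words <- lexicon$word
  set.seed(seed)
  m <- matrix(rgamma(length(words)^2, shape = concentration, rate = 1),
              length(words), length(words),
              dimnames = list(words, words))
  m[m < .Machine$double.eps] <- .Machine$double.eps
  m / rowSums(m)
}

#' Simulate a phoneme-aligned story from a bigram language model
#'
#' Samples a word sequence from the bigram chain, assigns each phoneme
#' an independent uniform duration, and lays words out back-to-back
#' from time zero. The returned provider reports the true transition
#' row, so contextual word entropies computed from it equal the row
#' entropies of the matrix exactly.
#'
#' @param lexicon A prepared lexicon.
#' @param transition Row-stochastic matrix over the lexicon words (see
#'   [random_transition_matrix()]).
#' @param n_words Number of story words.
#' @param phoneme_duration_range Uniform phoneme duration range in
#'   seconds (default `c(0.05, 0.15)`, a typical phone-duration band).
#' @param seed Integer seed.
#' @param story_part Story-part identifier (default `"part1"`).
#' @return List with `words` (data frame: `story_part`, `word_index`,
#'   `word`, `onset`, `offset`), `phonemes` (data frame: `story_part`,
#'   `word_index`, `word`, `position`, `phoneme`, `onset`, `offset`),
#'   `provider` (a [bigram_provider()]), `duration` (seconds) and
#'   `transition`.
#' @export
make_story <- function(lexicon, transition, n_words,
                       phoneme_duration_range = c(0.05, 0.15),
                       seed = 1L, story_part = "part1") {
  stopifnot(n_words >= 2L,
            phoneme_duration_range[1L] > 0,
            phoneme_duration_range[2L] >= phoneme_duration_range[1L])
  words_vocab <- lexicon$word
  if (!identical(sort(rownames(transition)), sort(words_vocab)))
    stop_speechTRF("transition matrix must cover the lexicon words",
                   "bad_transition")
  if (any(rowSums(transition) == 0))
    stop_speechTRF("absorbing state with zero out-probability",
                   "bad_transition")
  phon <- strsplit(lexicon$phonemes, " ")
  names(phon) <- words_vocab
  set.seed(seed)
  seq_words <- character(n_words)
  seq_words[1L] <- sample(words_vocab, 1L)
  for (i in 2:n_words)
    seq_words[i] <- sample(colnames(transition), 1L,
                           prob = transition[seq_words[i - 1L], ])
  ph_rows <- list()
  w_onset <- w_offset <- numeric(n_words)
  t_cur <- 0
  for (i in seq_len(n_words)) {
    ph <- phon[[seq_words[i]]]
    durs <- runif(length(ph), phoneme_duration_range[1L],
                  phoneme_duration_range[2L])
    onsets <- t_cur + cumsum(c(0, durs[-length(durs)]))
    ph_rows[[i]] <- data.frame(
      story_part = story_part, word_index = i, word = seq_words[i],
      position = seq_along(ph), phoneme = ph,
      onset = onsets, offset = onsets + durs,
      stringsAsFactors = FALSE)
    w_onset[i] <- t_cur
    t_cur <- t_cur + sum(durs)
    w_offset[i] <- t_cur
  }
  words_df <- data.frame(
    story_part = story_part, word_index = seq_len(n_words),
    word = seq_words, onset = w_onset, offset = w_offset,
    stringsAsFactors = FALSE)
  list(words = words_df, phonemes = do.call(rbind, ph_rows),
       provider = bigram_provider(transition), duration = t_cur,
       transition = transition)
}

gabor_bump <- function(lags, center, width, amplitude, freq = 0,
                       phase = 0) {
  amplitude * exp(-(lags - center)^2 / (2 * width^2)) *
    cos(2 * pi * freq * (lags - center) + phase)
}

#' Ground-truth TRF kernels from Gabor-like bumps
#'
#' Builds smooth per-channel, per-feature kernels as sums of Gaussian
#' or Gabor bumps with known centers, widths and amplitudes. The
#' default shape has an early bump near 80 ms and a broader late bump
#' near 400 ms, echoing the early/late response morphology of speech
#' TRFs; bump amplitudes are jittered per channel and feature under the
#' seed.
#'
#' @param features Character vector of feature (channel) names.
#' @param axis A [lag_axis()].
#' @param n_channels Number of response channels.
#' @param bumps List of bump specifications, each a list with `center`
#'   (s), `width` (s), `amplitude`, optional `freq` (Hz) and `phase`;
#'   `NULL` gives the default two-bump shape.
#' @param amplitude_jitter SD of the multiplicative log-normal jitter
#'   applied per (feature, channel) (default 0.3; 0 disables).
#' @param seed Integer seed.
#' @return Array features x lags x channels with dimnames, class
#'   `true_kernels`; the lag axis is attached as the `"axis"`
#'   attribute.
#' @export
make_true_kernels <- function(features, axis, n_channels,
                              bumps = NULL, amplitude_jitter = 0.3,
                              seed = 1L) {
  stopifnot(inherits(axis, "lag_axis"), n_channels >= 1L)
  bumps <- bumps %||% list(
    list(center = 0.08, width = 0.02, amplitude = 1),
    list(center = 0.40, width = 0.08, amplitude = -0.6))
  for (b in bumps) {
    if (b$center < axis$tmin || b$center > axis$tmax)
      stop_speechTRF("bump center outside the lag range", "bad_bumps")
  }
  set.seed(seed)
  nf <- length(features)
  nl <- length(axis$lags)
  out <- array(0, c(nf, nl, n_channels),
               dimnames = list(features, NULL,
                               paste0("ch", seq_len(n_channels))))
  for (ch in seq_len(n_channels)) {
    for (f in seq_len(nf)) {
      scale <- if (amplitude_jitter > 0)
        exp(rnorm(1, 0, amplitude_jitter)) else 1
      sgn <- sample(c(-1, 1), 1L)
      k <- numeric(nl)
      for (b in bumps)
        k <- k + gabor_bump(axis$lags, b$center, b$width, b$amplitude,
                            b$freq %||% 0, b$phase %||% 0)
      out[f, , ch] <- sgn * scale * k
    }
  }
  structure(out, axis = axis, class = "true_kernels")
}

#' Simulate multichannel responses from ground-truth kernels
#'
#' For each channel, convolves the true kernel with the predictors
#' ([forward_predict()]) and adds Gaussian noise of standard deviation
#' `noise_sd` (optionally AR(1)-correlated). `noise_sd` may also be the
#' string `"snr0"`: per channel, noise SD equal to the SD of the clean
#' signal, i.e. a 0 dB signal-to-noise ratio.
#'
#' @param true_kernels A [make_true_kernels()] array.
#' @param pm A [predictor_matrix()] whose channels match the kernel
#'   features.
#' @param noise_sd Noise standard deviation (scalar, or `"snr0"`).
#' @param seed Integer seed.
#' @param ar Optional AR(1) coefficient for temporally correlated
#'   noise (default 0 = white); the innovation SD is scaled so the
#'   marginal noise SD stays `noise_sd`.
#' @return List with `response` (samples x channels), `signal` (clean
#'   part) and `noise_sd` (per-channel vector actually used).
#' @export
simulate_response <- function(true_kernels, pm, noise_sd, seed = 1L,
                              ar = 0) {
  stopifnot(inherits(true_kernels, "true_kernels"))
  axis <- attr(true_kernels, "axis")
  n_ch <- dim(true_kernels)[3L]
  n <- n_samples(pm)
  signal <- matrix(0, n, n_ch,
                   dimnames = list(NULL, dimnames(true_kernels)[[3L]]))
  for (ch in seq_len(n_ch)) {
    beta <- true_kernels[, , ch, drop = TRUE]
    if (!is.matrix(beta)) beta <- matrix(beta, nrow = dim(true_kernels)[1L])
    rownames(beta) <- dimnames(true_kernels)[[1L]]
    signal[, ch] <- forward_predict(trf_kernel(beta, axis), pm)
  }
  sds <- if (identical(noise_sd, "snr0")) apply(signal, 2L, sd)
  else rep_len(noise_sd, n_ch)
  set.seed(seed)
  noise <- matrix(rnorm(n * n_ch), n, n_ch)
  if (ar != 0) {
    stopifnot(abs(ar) < 1)
    noise <- apply(noise, 2L, function(e)
      as.vector(filter(e, ar, method = "recursive")) * sqrt(1 - ar^2))
  }
  response <- signal + sweep(noise, 2L, sds, "*")
  colnames(response) <- colnames(signal)
  list(response = response, signal = signal, noise_sd = sds)
}

#' Build standard predictor channels for a synthetic story
#'
#' Assembles the pipeline's predictor channels for a simulated story:
#' impulse channels for phoneme onset, cohort surprisal and entropy
#' (from [annotate_phoneme_events()] against the story's own lexicon)
#' and log word frequency at word onsets, plus `n_acoustic` continuous
#' envelope-like channels (low-pass-smoothed rectified noise) standing
#' in for gammatone bands when no audio exists.
#'
#' @param story A [make_story()] result.
#' @param index [build_cohort_index()] of the story's lexicon.
#' @param lexicon The lexicon data frame (for word frequencies).
#' @param sample_rate Analysis rate in Hz (default 100).
#' @param n_acoustic Number of synthetic continuous channels
#'   (default 2).
#' @param seed Seed for the continuous channels.
#' @return A [predictor_matrix()].
#' @export
story_predictors <- function(story, index, lexicon, sample_rate = 100,
                             n_acoustic = 2L, seed = 1L) {
  dur <- story$duration + 1e-9
  ph <- annotate_phoneme_events(story$phonemes, index)
  freq_by_word <- setNames(lexicon$frequency, lexicon$word)
  wf <- word_frequency_value(freq_by_word[story$words$word])
  chans <- list()
  kinds <- character(0)
  set.seed(seed)
  if (n_acoustic > 0L) {
    n <- round(dur * sample_rate)
    # light smoothing only: 100 Hz band envelopes of speech keep
    # modulation energy across the band, which is also what makes the
    # kernel identifiable from a continuous predictor
    bw <- signal::butter(2, 0.6, type = "low")
    for (i in seq_len(n_acoustic)) {
      x <- pmax(signal::filtfilt(bw, abs(rnorm(n))), 0)
      chans[[paste0("spec_", i)]] <- x
      kinds <- c(kinds, "continuous")
    }
  }
  chans$phoneme_onset <-
    impulse_channel(ph$onset, 1, sample_rate, dur)
  chans$phoneme_surprisal <-
    impulse_channel(ph$onset, ph$surprisal, sample_rate, dur)
  chans$phoneme_entropy <-
    impulse_channel(ph$onset, ph$entropy, sample_rate, dur)
  chans$word_frequency <-
    impulse_channel(story$words$onset, wf, sample_rate, dur)
  kinds <- c(kinds, rep("impulse", 4L))
  predictor_matrix(chans, sample_rate, kind = kinds)
}

#' Predictor set for parameter-recovery simulations
#'
#' Three normalized predictor channels emulating the pipeline's mix:
#' a phoneme-like impulse train (`ph`, about `phoneme_rate` events/s
#' with positive jittered values), a sparser word-like impulse train
#' (`wd`), and a continuous envelope-like channel (`env`, lightly
#' smoothed rectified noise with broadband modulation content).
#'
#' @param duration Duration in seconds (default 300, i.e. a 5-minute
#'   story part).
#' @param sample_rate Analysis rate in Hz (default 100).
#' @param phoneme_rate,word_rate Mean event rates per second
#'   (defaults 5 and 2).
#' @param seed Integer seed.
#' @return A normalized [predictor_matrix()] with channels `ph`, `wd`,
#'   `env`.
#' @export
make_recovery_predictors <- function(duration = 300, sample_rate = 100,
                                     phoneme_rate = 5, word_rate = 2,
                                     seed = 1L) {
  set.seed(seed)
  n <- round(duration * sample_rate)
  ph <- numeric(n)
  ph[sample(n, round(phoneme_rate * duration))] <- abs(rnorm(
    round(phoneme_rate * duration), 1, 0.3))
  wd <- numeric(n)
  wd[sample(n, round(word_rate * duration))] <- abs(rnorm(
    round(word_rate * duration), 1, 0.5))
  env <- pmax(as.vector(signal::filtfilt(signal::butter(2, 0.6),
                                         abs(rnorm(n)))), 0)
  normalize_channels(predictor_matrix(
    list(ph = ph, wd = wd, env = env), sample_rate,
    kind = c("impulse", "impulse", "continuous")))
}

#' Simulate a complete synthetic study
#'
#' One call that generates a lexicon, a bigram story, predictors, true
#' kernels, simulated responses, and a grid channel layout with
#' pseudo-hemisphere group labels, reproducible from the seed. This is
#' the ground-truth harness behind parameter-recovery and calibration
#' tests.
#'
#' @param n_words_lexicon Lexicon size (default 50).
#' @param n_words_story Story length in words (default 300).
#' @param n_channels Number of response channels (default 4; laid out
#'   on a 2-row grid).
#' @param noise_sd Noise level passed to [simulate_response()]
#'   (default `"snr0"`).
#' @param sample_rate Analysis rate in Hz (default 100).
#' @param concentration Bigram Dirichlet concentration (default 0.5).
#' @param axis [lag_axis()] for the ground-truth kernels (default
#'   -100 to 800 ms).
#' @param bumps Bump specification passed to [make_true_kernels()].
#' @param null_features Character vector of predictor channels whose
#'   true kernels are zeroed, giving features with no causal role
#'   (useful for gain-calibration studies).
#' @param seed Integer master seed.
#' @return List with `lexicon`, `index`, `story`, `predictors`
#'   (normalized), `true_kernels`, `response`, `signal`, `adjacency`,
#'   `coords`, `channel_groups`, `axis`, `seed`.
#' @export
simulate_study <- function(n_words_lexicon = 50L, n_words_story = 300L,
                           n_channels = 4L, noise_sd = "snr0",
                           sample_rate = 100, concentration = 0.5,
                           axis = NULL, bumps = NULL,
                           null_features = character(), seed = 1L) {
  lexicon <- make_toy_lexicon(n_words_lexicon, seed = seed)
  index <- build_cohort_index(lexicon)
  tm <- random_transition_matrix(lexicon, concentration, seed = seed + 1L)
  story <- make_story(lexicon, tm, n_words_story, seed = seed + 2L)
  pm <- story_predictors(story, index, lexicon, sample_rate,
                         seed = seed + 3L)
  pm <- normalize_channels(pm)
  axis <- axis %||% lag_axis(-0.1, 0.8, sample_rate)
  kernels <- make_true_kernels(colnames(pm$channels), axis, n_channels,
                               bumps = bumps, seed = seed + 4L)
  if (length(null_features) > 0L) {
    missing <- setdiff(null_features, colnames(pm$channels))
    if (length(missing) > 0L)
      stop_speechTRF(paste("unknown null features:",
                           paste(missing, collapse = ", ")),
                     "bad_predictors")
    kernels[null_features, , ] <- 0
  }
  sim <- simulate_response(kernels, pm, noise_sd, seed = seed + 5L)
  grid <- grid_adjacency(ceiling(n_channels / 2L), 2L)
  coords <- grid$coords[seq_len(n_channels), , drop = FALSE]
  groups <- setNames(rep(c("A", "B"), length.out = n_channels),
                     colnames(sim$response))
  list(lexicon = lexicon, index = index, story = story,
       predictors = pm, true_kernels = kernels,
       response = sim$response, signal = sim$signal,
       adjacency = grid$adjacency[seq_len(n_channels),
                                  seq_len(n_channels), drop = FALSE],
       coords = coords, channel_groups = groups, axis = axis,
       seed = seed)
}

#' Write / read word or phoneme event tables
#'
#' Tab-separated, UTF-8, one header line; the standard exchange format
#' for event tracks.
#'
#' @param events Event data frame.
#' @param path File path.
#' @return `write_events()` returns `path` invisibly; `read_events()`
#'   returns a data frame.
#' @export
write_events <- function(events, path) {
  write.table(events, path, sep = "\t", quote = FALSE,
              row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE,
             fileEncoding = "UTF-8")
}
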