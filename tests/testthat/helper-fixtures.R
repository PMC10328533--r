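# Shared fixtures, all generated in code.

toy_lexicon <- function() {
  data.frame(word = c("cat", "cap", "dog"),
             phonemes = c("k a t", "k a p", "d o g"),
             frequency = c(10, 30, 60),
             stringsAsFactors = FALSE)
}

toy_index <- function() build_cohort_index(toy_lexicon())

# Brute-force cohort oracle: enumerate the lexicon instead of using
# the prefix index.
brute_cohort_freq <- function(lexicon, prefix) {
  phon <- strsplit(lexicon$phonemes, " ")
  ok <- vapply(phon, function(p)
    length(p) >= length(prefix) &&
      identical(p[seq_along(prefix)], prefix), logical(1))
  sum(lexicon$frequency[ok])
}

brute_phoneme_probability <- function(lexicon, prefix, nxt) {
  brute_cohort_freq(lexicon, c(prefix, nxt)) /
    brute_cohort_freq(lexicon, prefix)
}

brute_phoneme_entropy <- function(lexicon, prefix) {
  phon <- strsplit(lexicon$phonemes, " ")
  denom <- brute_cohort_freq(lexicon, prefix)
  nxt <- unique(vapply(
    phon[vapply(phon, function(p)
      length(p) > length(prefix) &&
        identical(p[seq_along(prefix)], prefix), logical(1))],
    function(p) p[[length(prefix) + 1L]], character(1)))
  if (length(nxt) == 0L) return(0)
  p <- vapply(nxt, function(s)
    brute_cohort_freq(lexicon, c(prefix, s)), numeric(1)) / denom
  -sum(p * log2(p))
}

# Independent convolution oracle: explicit nested loops.
oracle_forward <- function(beta, x, lag_samples) {
  n <- nrow(x)
  y <- numeric(n)
  for (t in seq_len(n))
    for (f in seq_len(ncol(x)))
      for (k in seq_along(lag_samples)) {
        s <- t - lag_samples[k]
        if (s >= 1 && s <= n) y[t] <- y[t] + beta[f, k] * x[s, f]
      }
  y
}

# Small simulated response + predictors for boosting tests.
small_sim <- function(seed = 1, n = 6000, noise = "snr0",
                      axis = lag_axis(0, 0.35, 100)) {
  pm <- make_recovery_predictors(duration = n / 100, seed = seed)
  tk <- make_true_kernels(colnames(pm$channels), axis, 1,
                          bumps = list(
                            list(center = 0.08, width = 0.02,
                                 amplitude = 1),
                            list(center = 0.20, width = 0.05,
                                 amplitude = -0.6)),
                          seed = seed + 1)
  sim <- simulate_response(tk, pm, noise, seed = seed + 2)
  list(pm = pm, kernels = tk, response = sim$response,
       signal = sim$signal, axis = axis)
}
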