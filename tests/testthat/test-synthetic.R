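test_that("toy lexica are Zipfian, unique and reproducible", {
  lex <- make_toy_lexicon(40, seed = 3)
  expect_equal(nrow(lex), 40)
  expect_false(anyDuplicated(lex$word) > 0)
  # rank-frequency slope on log-log axes equals -exponent
  fit <- lm(log(frequency) ~ log(seq_len(40)), data = lex)
  expect_equal(unname(coef(fit)[2]), -1, tolerance = 1e-9)
  lex2 <- make_toy_lexicon(40, zipf_exponent = 1.5, seed = 3)
  fit2 <- lm(log(frequency) ~ log(seq_len(40)), data = lex2)
  expect_equal(unname(coef(fit2)[2]), -1.5, tolerance = 1e-9)
  expect_identical(make_toy_lexicon(40, seed = 3), lex)
  expect_equal(nrow(make_toy_lexicon(2, seed = 1)), 2)
  expect_error(make_toy_lexicon(100, inventory_size = 2,
                                word_length_range = c(1L, 2L)),
               class = "inventory_too_small")
})

test_that("stories tile time and expose exact word entropies", {
  lex <- make_toy_lexicon(12, seed = 4)
  tm <- random_transition_matrix(lex, seed = 5)
  story <- make_story(lex, tm, 40, seed = 6)
  # duration is the sum of all phoneme durations; words tile [0, dur]
  expect_equal(story$duration,
               sum(story$phonemes$offset - story$phonemes$onset))
  expect_equal(story$words$onset[-1],
               story$words$offset[-nrow(story$words)])
  expect_true(all(story$phonemes$word %in% lex$word))
  # annotation with the story's own provider returns row entropies
  ann <- annotate_word_entropy(story$words, story$provider)
  row_h <- apply(tm, 1, function(p) -sum(p[p > 0] * log2(p[p > 0])))
  expect_equal(ann$entropy[-1],
               unname(row_h[story$words$word[-nrow(ann)]]))
  # deterministic chain: all entropies zero
  perm <- diag(nrow(lex))[c(2:nrow(lex), 1), ]
  dimnames(perm) <- list(lex$word, lex$word)
  det_story <- make_story(lex, perm, 20, seed = 7)
  det_ann <- annotate_word_entropy(det_story$words, det_story$provider)
  expect_true(all(det_ann$entropy[-1] == 0))
  expect_identical(make_story(lex, tm, 40, seed = 6)$words, story$words)
})

test_that("true kernels honour the bump specification", {
  ax <- lag_axis(-0.1, 0.8, 100)
  tk <- make_true_kernels("f", ax, 1,
                          bumps = list(list(center = 0.08, width = 0.02,
                                            amplitude = 1)),
                          amplitude_jitter = 0, seed = 8)
  expect_equal(which.max(abs(tk[1, , 1])), which.min(abs(ax$lags - 0.08)))
  zero <- make_true_kernels("f", ax, 1,
                            bumps = list(list(center = 0.1, width = 0.05,
                                              amplitude = 0)),
                            seed = 8)
  expect_true(all(zero == 0))
  # dual-peak shape: two local maxima of |kernel|
  two <- make_true_kernels("f", ax, 1, amplitude_jitter = 0, seed = 8)
  mag <- abs(two[1, , 1])
  peaks <- which(diff(sign(diff(mag))) == -2) + 1
  big <- peaks[mag[peaks] > 0.1 * max(mag)]
  expect_equal(length(big), 2)
  expect_error(make_true_kernels("f", ax, 1,
                                 bumps = list(list(center = 2, width = 0.1,
                                                   amplitude = 1))),
               class = "bad_bumps")
})

test_that("simulated responses are kernel convolution plus scaled noise", {
  sim0 <- small_sim(seed = 31, n = 2000, noise = 0)
  expect_equal(sim0$response, sim0$signal)
  sim_a <- small_sim(seed = 31, n = 2000, noise = "snr0")
  sim_b <- small_sim(seed = 31, n = 2000, noise = "snr0")
  expect_identical(sim_a$response, sim_b$response)
  # doubling the noise sd doubles the residual sd
  pm <- make_recovery_predictors(duration = 20, seed = 32)
  tk <- make_true_kernels(colnames(pm$channels), lag_axis(0, 0.3, 100),
                          1, bumps = list(list(center = 0.1,
                                               width = 0.03,
                                               amplitude = 1)),
                          seed = 33)
  r1 <- vapply(1:25, function(s)
    sd(simulate_response(tk, pm, 1, seed = s)$response -
         simulate_response(tk, pm, 0, seed = s)$signal), numeric(1))
  r2 <- vapply(1:25, function(s)
    sd(simulate_response(tk, pm, 2, seed = s)$response -
         simulate_response(tk, pm, 0, seed = s)$signal), numeric(1))
  expect_equal(mean(r2) / mean(r1), 2, tolerance = 0.01)
  # AR(1) noise keeps the marginal sd but adds autocorrelation
  ar <- simulate_response(tk, pm, 1, seed = 34, ar = 0.7)
  eps <- ar$response - ar$signal
  expect_equal(sd(eps), 1, tolerance = 0.1)
  expect_gt(cor(eps[-1, 1], eps[-nrow(eps), 1]), 0.5)
})

test_that("simulate_study wires all pieces together reproducibly", {
  study <- simulate_study(n_words_story = 50, n_channels = 2, seed = 9)
  expect_equal(ncol(study$response), 2)
  expect_equal(nrow(study$response), nrow(study$predictors$channels))
  expect_equal(colMeans(abs(study$predictors$channels)),
               setNames(rep(1, ncol(study$predictors$channels)),
                        colnames(study$predictors$channels)))
  expect_setequal(unique(study$channel_groups), c("A", "B"))
  study2 <- simulate_study(n_words_story = 50, n_channels = 2, seed = 9)
  expect_identical(study$response, study2$response)
  # null features have exactly zero true kernels
  study3 <- simulate_study(n_words_story = 50, n_channels = 1,
                           null_features = "word_frequency", seed = 9)
  expect_true(all(study3$true_kernels["word_frequency", , ] == 0))
})

test_that("event tables round-trip through TSV", {
  lex <- make_toy_lexicon(8, seed = 10)
  tm <- random_transition_matrix(lex, seed = 10)
  story <- make_story(lex, tm, 10, seed = 10)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_events(story$words, path)
  back <- read_events(path)
  expect_equal(back$word, story$words$word)
  expect_equal(back$onset, story$words$onset, tolerance = 1e-9)
})
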