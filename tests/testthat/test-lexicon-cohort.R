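test_that("lexicon preparation filters, ranks and truncates", {
  raw <- data.frame(
    word = c("a1", "cat", "dog", "bee", "ape", "nul"),
    phonemes = c("a one", "k a t", "d o g", "b i", "e p", "n u l"),
    frequency = c(5, 10, 60, 10, 25, 0))
  prep <- prepare_lexicon(raw)
  expect_false("a1" %in% prep$word)   # nonalphabetic dropped
  expect_false("nul" %in% prep$word)  # zero frequency dropped
  # frequency descending, frequency ties broken lexicographically
  expect_identical(prep$word, c("dog", "ape", "bee", "cat"))
  expect_identical(prepare_lexicon(raw, max_words = 2)$word,
                   c("dog", "ape"))
  expect_error(prepare_lexicon(raw[1, ]), class = "empty_lexicon")
})

test_that("tie-breaking matches the rule under full enumeration", {
  # 4 entries, two tied pairs: enumerate expected order by the rule
  raw <- data.frame(word = c("dd", "cc", "bb", "aa"),
                    phonemes = c("d d", "c c", "b b", "a a"),
                    frequency = c(7, 7, 3, 3))
  expect_identical(prepare_lexicon(raw)$word, c("cc", "dd", "aa", "bb"))
})

test_that("cohort index matches brute-force enumeration on the toy lexicon", {
  idx <- toy_index()
  expect_setequal(cohort_members(idx, c("k", "a")), c("cat", "cap"))
  expect_equal(cohort_frequency(idx, c("k", "a")), 40)
  expect_equal(cohort_frequency(idx), 100)
  # single-word lexicon: chain trie with constant frequency
  one <- build_cohort_index(data.frame(word = "zo", phonemes = "z o",
                                       frequency = 4))
  expect_equal(cohort_frequency(one, "z"), 4)
  expect_equal(cohort_frequency(one, c("z", "o")), 4)
  expect_error(build_cohort_index(rbind(toy_lexicon(), toy_lexicon()[1, ])),
               class = "duplicate_entries")
})

test_that("phoneme probability follows the cohort frequency ratio", {
  idx <- toy_index()
  expect_equal(phoneme_probability(idx, "k", "a"), 1.0)
  expect_equal(phoneme_probability(idx, c("k", "a"), "t"), 0.25)
  expect_equal(phoneme_probability(idx, character(), "k"), 0.4)
  # attested prefix + unattested continuation: probability 0, no error
  expect_equal(phoneme_probability(idx, "k", "z"), 0)
  # unattested prefix: distinct error
  expect_error(phoneme_probability(idx, "x", "a"),
               class = "unattested_prefix")
})

test_that("surprisal is -log2(p) with domain checks", {
  expect_equal(phoneme_surprisal(1), 0)
  expect_equal(phoneme_surprisal(0.25), 2)
  expect_error(phoneme_surprisal(0), class = "bad_probability")
  expect_error(phoneme_surprisal(1.2), class = "bad_probability")
  # a frequent word's continuation is less surprising than a rare one's
  lex <- data.frame(word = c("internet", "interval"),
                    phonemes = c("i n t e r n", "i n t e r v"),
                    frequency = c(80, 20))
  idx <- build_cohort_index(lex)
  pre <- c("i", "n", "t", "e", "r")
  s_n <- phoneme_surprisal(phoneme_probability(idx, pre, "n"))
  s_v <- phoneme_surprisal(phoneme_probability(idx, pre, "v"))
  expect_lt(s_n, s_v)
})

test_that("phoneme entropy matches closed forms", {
  idx <- toy_index()
  expect_equal(phoneme_entropy(idx, c("k", "a")),
               -(0.25 * log2(0.25) + 0.75 * log2(0.75)))
  expect_equal(phoneme_entropy(idx, "k"), 0)  # single continuation
  uni <- build_cohort_index(data.frame(
    word = c("aa", "ab", "ac", "ad"),
    phonemes = c("a a", "a b", "a c", "a d"),
    frequency = rep(5, 4)))
  expect_equal(phoneme_entropy(uni, "a"), 2)  # 4 equiprobable
})

test_that("word profiles telescope and flag out-of-lexicon words", {
  idx <- toy_index()
  prof <- word_surprisal_profile(idx, "k a t")
  expect_equal(nrow(prof), 3)
  expect_equal(sum(prof$surprisal), -log2(10 / 100))
  expect_true(all(prof$surprisal >= 0))
  # unique from the first phoneme: zero surprisal and entropy after it
  prof_d <- word_surprisal_profile(idx, "d o g")
  expect_equal(prof_d$surprisal[2:3], c(0, 0))
  expect_equal(prof_d$entropy[2:3], c(0, 0))
  expect_error(word_surprisal_profile(idx, "k a z"),
               class = "unattested_prefix")
})

test_that("event annotation applies the OOV policy", {
  idx <- toy_index()
  ev <- data.frame(word_index = c(1, 1, 1, 2, 2),
                   phoneme = c("k", "a", "t", "x", "y"),
                   onset = c(0, 0.1, 0.2, 0.3, 0.4))
  ann <- annotate_phoneme_events(ev, idx)
  expect_equal(attr(ann, "n_oov"), 1L)
  expect_true(all(is.na(ann$surprisal[ann$word_index == 2])))
  expect_equal(ann$surprisal[1], -log2(0.4))
  expect_error(annotate_phoneme_events(ev, idx, oov = "error"),
               class = "oov_word")
})

test_that("word frequency predictor is -log2 relative frequency", {
  expect_equal(word_frequency_value(1e6), 0)
  expect_equal(word_frequency_value(5e5), 1)
  expect_equal(word_frequency_value(10), -log2(1e-5))
  expect_error(word_frequency_value(0), class = "bad_frequency")
})

test_that("cohort invariants hold on random lexica vs the brute-force oracle", {
  set.seed(42)
  for (rep in 1:30) {
    lex <- make_toy_lexicon(n_words = sample(5:25, 1),
                            inventory_size = sample(3:6, 1),
                            word_length_range = c(1L, 4L),
                            seed = rep)
    idx <- build_cohort_index(lex)
    phon <- strsplit(lex$phonemes, " ")
    for (k in 1:10) {
      w <- phon[[sample(length(phon), 1)]]
      cut <- sample(0:length(w), 1)
      prefix <- w[seq_len(cut)]
      node_freq <- cohort_frequency(idx, prefix)
      expect_equal(node_freq, brute_cohort_freq(lex, prefix),
                   tolerance = 1e-12)
      # normalization: continuations + termination mass = 1
      inv <- unique(unlist(phon))
      p_cont <- vapply(inv, function(s)
        phoneme_probability(idx, prefix, s), numeric(1))
      term <- sum(lex$frequency[vapply(phon, function(p)
        identical(p, prefix), logical(1))]) / node_freq
      expect_equal(sum(p_cont) + term, 1, tolerance = 1e-12)
      # monotone cohort along the path
      if (cut >= 1)
        expect_lte(node_freq, cohort_frequency(idx, w[seq_len(cut - 1)]))
      # entropy bound and oracle equivalence
      h <- phoneme_entropy(idx, prefix)
      expect_gte(h, 0)
      expect_lte(h, log2(length(inv)) + 1e-12)
      expect_equal(h, brute_phoneme_entropy(lex, prefix),
                   tolerance = 1e-12)
      # entropy equals expected surprisal over the continuation mass
      pos <- p_cont[p_cont > 0]
      if (length(pos) > 0)
        expect_equal(h, sum(pos * -log2(pos)), tolerance = 1e-12)
    }
    # telescoping identity for every word
    for (i in seq_len(nrow(lex))) {
      prof <- word_surprisal_profile(idx, phon[[i]])
      expect_equal(sum(prof$surprisal),
                   -log2(brute_cohort_freq(lex, phon[[i]]) /
                           sum(lex$frequency)),
                   tolerance = 1e-10)
    }
  }
})

test_that("lexicon round-trips through the TSV reader", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("word\tfrequency\tphonemes",
               "cat\t10\tk a t",
               "dog\t60\td o g"), path)
  lex <- read_lexicon(path)
  expect_equal(lex$word, c("cat", "dog"))
  expect_equal(lex$frequency, c(10, 60))
  expect_equal(lex$phonemes[1], "k a t")
})
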