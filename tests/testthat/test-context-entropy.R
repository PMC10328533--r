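make_events <- function(onsets, offsets, entropy = NULL,
                        part = "p1", words = NULL) {
  df <- data.frame(story_part = part,
                   word = words %||% paste0("w", seq_along(onsets)),
                   onset = onsets, offset = offsets,
                   stringsAsFactors = FALSE)
  if (!is.null(entropy)) df$entropy <- entropy
  df
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("word entropy matches closed forms and checks normalization", {
  expect_equal(word_entropy(rep(1 / 8, 8)), 3)
  expect_equal(word_entropy(c(1, 0, 0)), 0)
  expect_equal(word_entropy(c(0.5, 0.25, 0.25)), 1.5)
  expect_error(word_entropy(c(0.5, 0.4)), class = "bad_distribution")
  expect_error(word_entropy(c(0.5, -0.1, 0.6)),
               class = "bad_distribution")
})

test_that("bigram provider annotation equals closed-form row entropies", {
  tm <- matrix(c(0.5, 0.5, 0,
                 0.1, 0.2, 0.7,
                 1 / 3, 1 / 3, 1 / 3), 3, 3, byrow = TRUE,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  prov <- bigram_provider(tm)
  row_h <- apply(tm, 1, function(p) -sum(p[p > 0] * log2(p[p > 0])))
  words <- c("a", "b", "c", "b", "a")
  ev <- make_events(0:4, 1:5, words = words)
  ann <- annotate_word_entropy(ev, prov)
  # first word: uniform initial context
  expect_equal(ann$entropy[1], log2(3))
  expect_equal(ann$entropy[-1], unname(row_h[words[-length(words)]]))
  # Markov provider: window size is irrelevant
  ann1 <- annotate_word_entropy(ev, prov, window = 1)
  expect_equal(ann1$entropy, ann$entropy)
  # uniform provider: all entropies identical
  uni <- probability_provider(function(ctx)
    setNames(rep(0.25, 4), letters[1:4]), letters[1:4])
  annu <- annotate_word_entropy(ev, uni)
  expect_true(all(annu$entropy == 2))
  # unknown context word surfaces as a provider error with the index
  ev_bad <- make_events(0:1, 1:2, words = c("a", "zz"))
  ev_bad2 <- make_events(0:1, 1:2, words = c("zz", "a"))
  expect_error(annotate_word_entropy(ev_bad2, prov),
               class = "provider_vocabulary")
})

test_that("context never crosses story-part boundaries", {
  tm <- matrix(c(0, 1, 1, 0), 2, 2, byrow = TRUE,
               dimnames = list(c("a", "b"), c("a", "b")))
  prov <- bigram_provider(tm)
  ev <- rbind(make_events(0:1, 1:2, part = "p1", words = c("a", "b")),
              make_events(0:1, 1:2, part = "p2", words = c("b", "a")))
  ann <- annotate_word_entropy(ev, prov)
  # first word of each part gets the empty-context (uniform) entropy
  expect_equal(ann$entropy[c(1, 3)], c(1, 1))
  expect_equal(ann$entropy[c(2, 4)], c(0, 0))
})

test_that("entropy split balances durations via an exhaustive threshold", {
  ev <- make_events(c(0, 2, 4, 7), c(2, 4, 7, 10),
                    entropy = c(0.1, 0.9, 0.2, 0.8))
  sp <- split_by_entropy(ev)
  expect_equal(sp$condition, c("low", "high", "low", "high"))
  # equal entropies: tie-break by onset order balances durations
  ev2 <- make_events(c(0, 1, 2, 3), c(1, 2, 3, 4), entropy = rep(1, 4))
  sp2 <- split_by_entropy(ev2)
  expect_equal(sp2$condition, c("low", "low", "high", "high"))
  expect_error(split_by_entropy(make_events(0, 1, entropy = 0.5)),
               class = "too_few_words")
  expect_error(split_by_entropy(make_events(0:1, 1:2)),
               class = "missing_entropy")
})

test_that("split selects the duration-optimal threshold (oracle search)", {
  set.seed(7)
  for (rep in 1:25) {
    n <- sample(3:12, 1)
    dur <- runif(n, 0.1, 2)
    onsets <- cumsum(c(0, dur[-n]))
    ev <- make_events(onsets, onsets + dur, entropy = runif(n))
    sp <- split_by_entropy(ev)
    # every word labelled, both conditions present
    expect_false(anyNA(sp$condition))
    expect_setequal(unique(sp$condition), c("low", "high"))
    # threshold property: all high entropies >= all low entropies
    expect_gte(min(sp$entropy[sp$condition == "high"]),
               max(sp$entropy[sp$condition == "low"]))
    # imbalance equals the exhaustive minimum over thresholds
    ord <- order(sp$entropy, sp$onset)
    d <- (sp$offset - sp$onset)[ord]
    all_imb <- abs(2 * cumsum(d)[1:(n - 1)] - sum(d))
    got <- abs(sum((sp$offset - sp$onset)[sp$condition == "high"]) -
                 sum((sp$offset - sp$onset)[sp$condition == "low"]))
    expect_equal(got, min(all_imb), tolerance = 1e-12)
    # bound: imbalance <= duration of the threshold-adjacent word
    k <- sum(sp$condition == "low")
    expect_lte(got, max(d[k], d[k + 1]) + 1e-12)
  }
})

test_that("an outlier forms a singleton set only when duration-optimal", {
  # outlier entropy but tiny duration: balance favours a larger high set
  ev <- make_events(c(0, 1, 2, 3), c(1, 2, 3, 3.1),
                    entropy = c(0.1, 0.2, 0.3, 9))
  sp <- split_by_entropy(ev)
  expect_equal(sum(sp$condition == "high"), 2)
  # outlier with half the total duration: singleton high set is optimal
  ev2 <- make_events(c(0, 1, 2, 3), c(1, 2, 3, 6),
                     entropy = c(0.1, 0.2, 0.3, 9))
  sp2 <- split_by_entropy(ev2)
  expect_equal(which(sp2$condition == "high"), 4L)
})

test_that("table-backed providers read from TSV", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("context\ttoken\tprobability",
               "a\ta\t0.25", "a\tb\t0.75",
               "b\ta\t1.0"), path)
  prov <- read_transition_table(path)
  expect_equal(unname(prov$query("a")),
               c(0.25, 0.75))
  expect_equal(word_entropy(prov$query("a")),
               -(0.25 * log2(0.25) + 0.75 * log2(0.75)))
})
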