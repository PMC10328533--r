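test_that("lag axes have the expected geometry", {
  ax <- lag_axis(-0.1, 0.8, 100)
  expect_length(ax$lags, 90)
  expect_equal(ax$lags[1], -0.1)
  expect_length(lag_axis(0, 0.1, 100)$lags, 10)
  expect_length(lag_axis(-0.1, 0.8, 200)$lags, 180)
  expect_error(lag_axis(0.5, 0.5), class = "bad_lag_axis")
})

test_that("sliding windows tile the lag range", {
  w <- sliding_window_models()
  expect_length(w, 17)
  expect_equal(attr(w[[1]], "center"), -0.05)
  expect_equal(attr(w[[17]], "center"), 0.75)
  expect_length(sliding_window_models(width = 0.9), 1)
  w2 <- sliding_window_models(0, 0.4, width = 0.1, step = 0.1)
  expect_length(w2, 4)  # non-overlapping tiling: span / width
  expect_error(sliding_window_models(0, 0.05, width = 0.1),
               class = "bad_lag_axis")
})

test_that("forward prediction matches the nested-loop oracle", {
  set.seed(8)
  pm <- predictor_matrix(list(a = rnorm(50), b = rnorm(50)), 100)
  ax <- lag_axis(-0.02, 0.03, 100)
  zero <- trf_kernel(matrix(0, 2, 5,
                            dimnames = list(c("a", "b"), NULL)), ax)
  expect_equal(forward_predict(zero, pm), numeric(50))
  # single impulse: output is the kernel copied from the event
  imp <- predictor_matrix(list(a = impulse_channel(0.1, 1, 100, 0.5)),
                          100)
  ax2 <- lag_axis(0, 0.05, 100)
  h <- matrix(rnorm(5), 1, 5, dimnames = list("a", NULL))
  y <- forward_predict(trf_kernel(h, ax2), imp)
  expect_equal(y[11:15], as.vector(h))
  expect_equal(sum(y != 0), sum(h != 0))
  # random instances vs oracle
  for (rep in 1:10) {
    x <- matrix(rnorm(100), 50, 2, dimnames = list(NULL, c("a", "b")))
    pmr <- predictor_matrix(x, 100)
    axr <- lag_axis(-0.02, 0.03, 100)
    beta <- matrix(rnorm(10), 2, 5, dimnames = list(c("a", "b"), NULL))
    expect_equal(forward_predict(trf_kernel(beta, axr), pmr),
                 oracle_forward(beta, x, axr$lag_samples),
                 tolerance = 1e-12)
  }
  wrong <- trf_kernel(matrix(0, 2, 5,
                             dimnames = list(c("a", "zz"), NULL)), ax)
  expect_error(forward_predict(wrong, pm), class = "channel_mismatch")
})

test_that("boosting returns a zero kernel for a zero response", {
  set.seed(9)
  pm <- normalize_channels(predictor_matrix(list(a = rnorm(1000)), 100))
  fit <- boosting_fit(numeric(1000), pm, lag_axis(0, 0.1, 100))
  expect_true(all(fit$kernel$beta == 0))
  expect_equal(fit$n_steps, 0L)
})

test_that("boosting recovers a known kernel from clean data", {
  sim <- small_sim(seed = 11, noise = 0)
  fit <- boosting_fit(sim$response[, 1], sim$pm, sim$axis)
  expect_gt(cor(as.vector(fit$kernel$beta), as.vector(sim$kernels[, , 1])),
            0.99)
  # training error is non-increasing, exactly
  expect_true(all(diff(fit$train_curve) <= 0))
  # validation minimum at or before the stopping step
  expect_lte(fit$best_step, fit$n_steps)
  expect_equal(which.min(fit$val_curve), fit$best_step)
})

test_that("training error never increases across random fits", {
  for (seed in 1:3) {
    sim <- small_sim(seed = seed, n = 3000)
    fit <- boosting_fit(sim$response[, 1], sim$pm, sim$axis,
                        fit_config(max_steps = 300))
    expect_true(all(diff(fit$train_curve) <= 1e-10))
  }
})

test_that("degenerate inputs are rejected", {
  pm <- normalize_channels(predictor_matrix(list(a = rnorm(500)), 100))
  expect_error(boosting_fit(rep(2, 500), pm, lag_axis(0, 0.1, 100)),
               class = "degenerate_response")
  expect_error(boosting_fit(c(rep(1, 499), NA), pm,
                            lag_axis(0, 0.1, 100)),
               class = "nonfinite_input")
  expect_error(fit_config(n_folds = 2), class = "bad_config")
})

test_that("reconstruction accuracy behaves like explained variance", {
  set.seed(12)
  y <- rnorm(500)
  expect_equal(reconstruction_accuracy(y, y), 1)
  expect_equal(reconstruction_accuracy(y, rep(mean(y), 500)), 0,
               tolerance = 1e-12)
  # independent noise predictions: non-positive in expectation
  accs <- replicate(50, reconstruction_accuracy(rnorm(200), rnorm(200)))
  expect_lt(mean(accs), 0.02)
  expect_error(reconstruction_accuracy(rep(1, 5), rnorm(5)),
               class = "degenerate_response")
})

test_that("cross-validation partitions samples and scores held-out data", {
  sim <- small_sim(seed = 13, n = 4000)
  cv <- cross_validate(sim$response, sim$pm, sim$axis)
  # every sample in exactly one test fold, all predicted
  expect_equal(sort(unique(cv$folds)), 1:5)
  expect_equal(length(cv$folds), 4000)
  expect_false(anyNA(cv$predictions))
  expect_lte(max(cv$accuracy), 1)
  # generative predictors beat time-shuffled ones on the same data
  set.seed(14)
  shuf <- sim$pm
  shuf$channels <- shuf$channels[sample(nrow(shuf$channels)), ,
                                 drop = FALSE]
  cv_shuf <- cross_validate(sim$response, shuf, sim$axis)
  expect_lt(cv_shuf$accuracy[1], 0.02)  # chance level
  expect_gt(cv$accuracy[1], cv_shuf$accuracy[1])
  expect_error(cross_validate(sim$response[1:100, , drop = FALSE],
                              subset_channels(sim$pm, "ph"),
                              sim$axis),
               class = "length_mismatch")
  expect_error(cross_validate(rnorm(200),
                              predictor_matrix(list(a = rnorm(200)), 100),
                              sim$axis),
               class = "too_short")
})
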