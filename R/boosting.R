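# TRF estimation by coordinate-wise boosting with a Hamming-window
# update basis, L1 loss, early stopping on a validation fold, and
# cross-validated reconstruction accuracy.

#' Lag axis for a temporal response function
#'
#' Builds the left-inclusive lag grid `tmin, tmin + 1/rate, ...` with
#' `T = round((tmax - tmin) * sample_rate)` points (`tmax` itself is
#' excluded). The default -100 to 800 ms at 100 Hz yields 90 lags.
#'
#' @param tmin,tmax Lag range in seconds (defaults -0.1 and 0.8).
#' @param sample_rate Sampling rate in Hz (default 100).
#' @return An object of class `lag_axis` with elements `tmin`, `tmax`,
#'   `sample_rate`, `lags` (seconds) and `lag_samples` (integer).
#' @export
lag_axis <- function(tmin = -0.1, tmax = 0.8, sample_rate = 100) {
  if (!(tmax > tmin))
    stop_speechTRF("need tmin < tmax", "bad_lag_axis")
  n_lags <- round((tmax - tmin) * sample_rate)
  if (n_lags < 1L)
    stop_speechTRF("lag span shorter than one sample", "bad_lag_axis")
  lag_samples <- round(tmin * sample_rate) + seq_len(n_lags) - 1L
  structure(list(tmin = tmin, tmax = tmax, sample_rate = sample_rate,
                 lags = lag_samples / sample_rate,
                 lag_samples = as.integer(lag_samples)),
            class = "lag_axis")
}

#' @export
print.lag_axis <- function(x, ...) {
  cat(sprintf("lag_axis: %d lags, %g to %g s at %g Hz\n",
              length(x$lags), x$tmin, x$tmax, x$sample_rate))
  invisible(x)
}

#' Sliding lag-window axes
#'
#' Generates the lag windows used for time-resolved model comparison:
#' `[tmin + j*step, tmin + j*step + width]` for every `j` with the
#' window end at most `tmax`. The defaults (100 ms windows stepped by
#' 50 ms over -100 to 800 ms) yield 17 windows. Each window is labelled
#' by its center time.
#'
#' @param tmin,tmax Overall lag range in seconds.
#' @param width Window width in seconds (default 0.1).
#' @param step Window step in seconds (default 0.05).
#' @param sample_rate Sampling rate in Hz (default 100).
#' @return List of [lag_axis()] objects; each carries a `"center"`
#'   attribute in seconds.
#' @export
sliding_window_models <- function(tmin = -0.1, tmax = 0.8, width = 0.1,
                                  step = 0.05, sample_rate = 100) {
  if (width > tmax - tmin + 1e-12)
    stop_speechTRF("window wider than the lag span", "bad_lag_axis")
  stopifnot(step > 0)
  starts <- seq(tmin, tmax - width + 1e-9, by = step)
  lapply(starts, function(s) {
    ax <- lag_axis(s, s + width, sample_rate)
    attr(ax, "center") <- round(s + width / 2, 9)
    ax
  })
}

#' Fit configuration for boosting
#'
#' @param n_folds Number of contiguous cross-validation folds (>= 3 so
#'   that train, validation and test are distinct; default 5).
#' @param step_fraction Coordinate step size as a fraction of the mean
#'   absolute response on the training set (default 0.005).
#' @param patience Number of boosting steps without a new validation
#'   minimum before stopping (default 10).
#' @param max_steps Hard cap on boosting steps (default 4000).
#' @param basis_width Width in seconds of the Hamming-window update
#'   basis (default 0.05).
#' @param min_fold_samples Minimum samples per fold (default 50).
#' @param anneal_halvings How many times the step size may be halved
#'   once no update of the current size reduces the training error
#'   (default 5); 0 keeps the step size fixed.
#' @param selective_stopping Undo any applied update that increases
#'   the validation error and freeze that coordinate (default `TRUE`),
#'   so coordinates that only fit training noise are retired early;
#'   frozen coordinates are released when the step size anneals.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(n_folds = 5L, step_fraction = 0.005,
                       patience = 10L, max_steps = 4000L,
                       basis_width = 0.05, min_fold_samples = 50L,
                       anneal_halvings = 5L, selective_stopping = TRUE) {
  if (n_folds < 3L)
    stop_speechTRF("n_folds must be >= 3 (train/validation/test)",
                   "bad_config")
  stopifnot(step_fraction > 0, patience >= 1L, max_steps >= 1L,
            basis_width >= 0, anneal_halvings >= 0L)
  structure(list(n_folds = as.integer(n_folds),
                 step_fraction = step_fraction,
                 patience = as.integer(patience),
                 max_steps = as.integer(max_steps),
                 basis_width = basis_width,
                 min_fold_samples = as.integer(min_fold_samples),
                 anneal_halvings = as.integer(anneal_halvings),
                 selective_stopping = isTRUE(selective_stopping),
                 loss = "l1"),
            class = "fit_config")
}

hamming_window <- function(m) {
  if (m == 1L) return(1)
  0.54 - 0.46 * cos(2 * pi * (0:(m - 1)) / (m - 1))
}

# Time-lagged design matrix: column (f-1)*T + k holds x_f(t - tau_k),
# zero-padded outside the recording.
lagged_design <- function(pm, axis) {
  x <- pm$channels
  n <- nrow(x)
  nf <- ncol(x)
  nl <- length(axis$lag_samples)
  out <- matrix(0, n, nf * nl)
  for (f in seq_len(nf)) {
    for (k in seq_len(nl)) {
      s <- axis$lag_samples[k]
      col <- (f - 1L) * nl + k
      if (s >= 0L) {
        if (s < n) out[(s + 1L):n, col] <- x[seq_len(n - s), f]
      } else {
        if (-s < n) out[seq_len(n + s), col] <- x[(1L - s):n, f]
      }
    }
  }
  out
}

# Smooth a lagged design (or expand basis coefficients) with the
# Hamming update basis along the lag axis, per feature.
basis_smooth_cols <- function(D, n_features, n_lags, w) {
  m <- length(w)
  if (m == 1L) return(D * w)
  center <- (m + 1L) %/% 2L
  out <- matrix(0, nrow(D), ncol(D))
  for (j in seq_len(m)) {
    off <- j - center
    ks <- seq_len(n_lags)
    src <- ks + off
    ok <- src >= 1L & src <= n_lags
    for (f in seq_len(n_features)) {
      base <- (f - 1L) * n_lags
      out[, base + ks[ok]] <- out[, base + ks[ok]] +
        w[j] * D[, base + src[ok], drop = FALSE]
    }
  }
  out
}

expand_basis <- function(gamma_mat, w) {
  # gamma_mat: features x lag-centers; returns kernel features x lags
  m <- length(w)
  if (m == 1L) return(gamma_mat * w)
  center <- (m + 1L) %/% 2L
  nl <- ncol(gamma_mat)
  out <- matrix(0, nrow(gamma_mat), nl)
  for (j in seq_len(m)) {
    off <- j - center
    ks <- seq_len(nl)
    dst <- ks + off
    ok <- dst >= 1L & dst <= nl
    out[, dst[ok]] <- out[, dst[ok]] + w[j] * gamma_mat[, ks[ok],
                                                        drop = FALSE]
  }
  out
}

#' TRF kernel container
#'
#' @param beta Coefficient matrix, features x lags, with feature row
#'   names.
#' @param axis The [lag_axis()] of the columns.
#' @param basis_width Hamming basis width in seconds used in fitting.
#' @return An object of class `trf_kernel`.
#' @export
trf_kernel <- function(beta, axis, basis_width = 0.05) {
  stopifnot(is.matrix(beta), inherits(axis, "lag_axis"),
            ncol(beta) == length(axis$lags), all(is.finite(beta)))
  structure(list(beta = beta, axis = axis, basis_width = basis_width),
            class = "trf_kernel")
}

#' @export
print.trf_kernel <- function(x, ...) {
  cat(sprintf("trf_kernel: %d features x %d lags (%g to %g s)\n",
              nrow(x$beta), ncol(x$beta), x$axis$tmin, x$axis$tmax))
  invisible(x)
}

#' Predict a response by convolving a TRF with predictors
#'
#' Computes `y(t) = sum_f sum_k beta[f, k] * x_f(t - tau_k)`, with
#' samples outside the recording treated as zero.
#'
#' @param kernel A [trf_kernel()] whose feature rows match the channel
#'   names of `pm` (order and names).
#' @param pm A [predictor_matrix()].
#' @return Numeric vector of predicted samples, same length as the
#'   predictors.
#' @export
forward_predict <- function(kernel, pm) {
  stopifnot(inherits(kernel, "trf_kernel"),
            inherits(pm, "predictor_matrix"))
  if (!identical(rownames(kernel$beta), colnames(pm$channels)))
    stop_speechTRF("kernel features do not match predictor channels",
                   "channel_mismatch")
  x <- pm$channels
  n <- nrow(x)
  y <- numeric(n)
  for (k in seq_along(kernel$axis$lag_samples)) {
    s <- kernel$axis$lag_samples[k]
    b <- kernel$beta[, k]
    if (all(b == 0)) next
    contrib <- as.vector(x %*% b)
    if (s >= 0L) {
      if (s < n) y[(s + 1L):n] <- y[(s + 1L):n] + contrib[seq_len(n - s)]
    } else {
      if (-s < n) y[seq_len(n + s)] <- y[seq_len(n + s)] + contrib[(1L - s):n]
    }
  }
  y
}

#' Fit a TRF to one response channel by boosting
#'
#' Starting from an all-zero kernel, repeatedly applies the single
#' `(feature, lag)` coordinate update (a +/- delta-scaled Hamming
#' window of `basis_width` seconds centered on the lag, truncated at
#' the lag-axis edges) that most reduces the training L1 error, and
#' stops once the L1 error on a held-out validation segment has not
#' reached a new minimum for `patience` steps. The kernel at the
#' validation minimum is returned. The step size delta is
#' `step_fraction * mean(abs(response[train]))`.
#'
#' @param response Numeric response vector, same length and rate as the
#'   predictors.
#' @param pm A [predictor_matrix()].
#' @param axis A [lag_axis()].
#' @param cfg A [fit_config()].
#' @param train_idx,val_idx Integer sample indices for training and
#'   validation; by default the last `1/n_folds` of the samples
#'   validate and the rest train.
#' @return List with `kernel` (a [trf_kernel()]), `train_curve`,
#'   `val_curve`, `n_steps`, `best_step`, `delta`.
#' @export
boosting_fit <- function(response, pm, axis, cfg = fit_config(),
                         train_idx = NULL, val_idx = NULL) {
  stopifnot(inherits(pm, "predictor_matrix"),
            inherits(axis, "lag_axis"), inherits(cfg, "fit_config"))
  n <- n_samples(pm)
  if (length(response) != n)
    stop_speechTRF("response and predictors must share length",
                   "length_mismatch")
  if (any(!is.finite(response)) || any(!is.finite(pm$channels)))
    stop_speechTRF("non-finite values in response or predictors",
                   "nonfinite_input")
  if (is.null(train_idx) || is.null(val_idx)) {
    cut <- floor(n * (cfg$n_folds - 1) / cfg$n_folds)
    train_idx <- seq_len(cut)
    val_idx <- (cut + 1L):n
  }
  if (all(response == 0)) {
    # nothing to explain: no coordinate update can reduce the L1 error
    beta <- matrix(0, ncol(pm$channels), length(axis$lag_samples),
                   dimnames = list(colnames(pm$channels), NULL))
    return(list(kernel = trf_kernel(beta, axis, cfg$basis_width),
                train_curve = numeric(0), val_curve = numeric(0),
                n_steps = 0L, best_step = 0L, delta = 0))
  }
  if (var(response[train_idx]) == 0)
    stop_speechTRF("constant response on the training set",
                   "degenerate_response")
  D <- lagged_design(pm, axis)
  nf <- ncol(pm$channels)
  nl <- length(axis$lag_samples)
  m <- max(1L, round(cfg$basis_width * axis$sample_rate))
  w <- hamming_window(m)
  Z <- basis_smooth_cols(D, nf, nl, w)
  delta <- cfg$step_fraction * mean(abs(response[train_idx]))
  if (delta <= 0)
    stop_speechTRF("zero step size (flat response)", "degenerate_response")
  fit <- boost_fit_cpp(Z[train_idx, , drop = FALSE],
                       Z[val_idx, , drop = FALSE],
                       response[train_idx], response[val_idx],
                       delta, cfg$patience, cfg$max_steps,
                       cfg$anneal_halvings, cfg$selective_stopping)
  gamma <- matrix(fit$gamma, nrow = nf, ncol = nl, byrow = TRUE)
  beta <- expand_basis(gamma, w)
  rownames(beta) <- colnames(pm$channels)
  list(kernel = trf_kernel(beta, axis, cfg$basis_width),
       train_curve = fit$train_curve, val_curve = fit$val_curve,
       n_steps = fit$n_steps, best_step = fit$best_step, delta = delta)
}

#' Proportion of explained variance
#'
#' `1 - var(y - yhat) / var(y)`; equals 1 for a perfect prediction, 0
#' for predicting the mean, and may be negative for predictions worse
#' than the mean.
#'
#' @param y Observed response.
#' @param yhat Predicted response of the same length.
#' @return Proportion of explained variance (at most 1).
#' @export
reconstruction_accuracy <- function(y, yhat) {
  stopifnot(length(y) == length(yhat))
  vy <- var(y)
  if (!is.finite(vy) || vy == 0)
    stop_speechTRF("response variance is zero", "degenerate_response")
  1 - var(y - yhat) / vy
}

fold_assignment <- function(n, n_folds) {
  bounds <- floor(seq(0, n, length.out = n_folds + 1L))
  rep(seq_len(n_folds), times = diff(bounds))
}

#' Cross-validated TRF estimation
#'
#' Splits the time axis into `n_folds` contiguous folds. For each test
#' fold, the cyclically following fold is the validation segment (early
#' stopping) and the remaining folds train; the boosted kernel predicts
#' the held-out test fold. Held-out predictions are concatenated and
#' accuracy is the proportion of held-out variance they explain, per
#' response channel.
#'
#' @param response Numeric vector or samples-x-channels matrix.
#' @param pm A [predictor_matrix()].
#' @param axis A [lag_axis()].
#' @param cfg A [fit_config()].
#' @return An object of class `trf_fit`: `accuracy` (named per
#'   channel), `kernels` (per channel, fold-averaged [trf_kernel()]),
#'   `fold_kernels`, `predictions` (held-out, same shape as
#'   `response`), `folds`, `axis`, `cfg`.
#' @export
cross_validate <- function(response, pm, axis, cfg = fit_config()) {
  if (!is.matrix(response)) response <- matrix(response, ncol = 1L)
  n <- n_samples(pm)
  if (nrow(response) != n)
    stop_speechTRF("response and predictors must share length",
                   "length_mismatch")
  if (is.null(colnames(response)))
    colnames(response) <- paste0("ch", seq_len(ncol(response)))
  folds <- fold_assignment(n, cfg$n_folds)
  if (min(tabulate(folds, cfg$n_folds)) < cfg$min_fold_samples)
    stop_speechTRF("recording too short for the requested folds",
                   "too_short")
  nf <- ncol(pm$channels)
  nl <- length(axis$lag_samples)
  m <- max(1L, round(cfg$basis_width * axis$sample_rate))
  w <- hamming_window(m)
  D <- lagged_design(pm, axis)
  Z <- basis_smooth_cols(D, nf, nl, w)
  n_ch <- ncol(response)
  predictions <- matrix(NA_real_, n, n_ch,
                        dimnames = list(NULL, colnames(response)))
  fold_kernels <- vector("list", n_ch)
  kernels <- vector("list", n_ch)
  curves <- vector("list", n_ch)
  for (ch in seq_len(n_ch)) {
    y <- response[, ch]
    fks <- vector("list", cfg$n_folds)
    crv <- vector("list", cfg$n_folds)
    beta_sum <- matrix(0, nf, nl)
    for (test_fold in seq_len(cfg$n_folds)) {
      val_fold <- test_fold %% cfg$n_folds + 1L
      train_idx <- which(!(folds %in% c(test_fold, val_fold)))
      val_idx <- which(folds == val_fold)
      test_idx <- which(folds == test_fold)
      delta <- cfg$step_fraction * mean(abs(y[train_idx]))
      if (delta <= 0 || var(y[train_idx]) == 0)
        stop_speechTRF("constant response on a training set",
                       "degenerate_response")
      fit <- boost_fit_cpp(Z[train_idx, , drop = FALSE],
                           Z[val_idx, , drop = FALSE],
                           y[train_idx], y[val_idx],
                           delta, cfg$patience, cfg$max_steps,
                           cfg$anneal_halvings, cfg$selective_stopping)
      gamma <- matrix(fit$gamma, nrow = nf, ncol = nl, byrow = TRUE)
      beta <- expand_basis(gamma, w)
      rownames(beta) <- colnames(pm$channels)
      fks[[test_fold]] <- trf_kernel(beta, axis, cfg$basis_width)
      crv[[test_fold]] <- list(train = fit$train_curve,
                               val = fit$val_curve,
                               best_step = fit$best_step)
      beta_sum <- beta_sum + beta
      predictions[test_idx, ch] <-
        as.vector(D[test_idx, , drop = FALSE] %*% as.vector(t(beta)))
    }
    beta_avg <- beta_sum / cfg$n_folds
    rownames(beta_avg) <- colnames(pm$channels)
    kernels[[ch]] <- trf_kernel(beta_avg, axis, cfg$basis_width)
    fold_kernels[[ch]] <- fks
    curves[[ch]] <- crv
  }
  accuracy <- vapply(seq_len(n_ch), function(ch)
    reconstruction_accuracy(response[, ch], predictions[, ch]),
    numeric(1))
  names(accuracy) <- colnames(response)
  names(kernels) <- names(fold_kernels) <- names(curves) <-
    colnames(response)
  structure(list(accuracy = accuracy, kernels = kernels,
                 fold_kernels = fold_kernels, predictions = predictions,
                 curves = curves, folds = folds, axis = axis, cfg = cfg),
            class = "trf_fit")
}

#' @export
print.trf_fit <- function(x, ...) {
  cat(sprintf("trf_fit: %d response channel(s), %d folds\n",
              length(x$accuracy), x$cfg$n_folds))
  cat(" held-out accuracy:",
      paste(sprintf("%s=%.4f", names(x$accuracy), x$accuracy),
            collapse = ", "), "\n")
  invisible(x)
}
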