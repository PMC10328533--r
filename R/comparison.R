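# Nested model ladders, feature-exclusion contrasts, and sliding
# lag-window comparisons. All models in a comparison are fitted with
# identical fold boundaries so accuracy differences are meaningful.

fit_models_shared <- function(response, pm, specs, axis, cfg) {
  if (!is.matrix(response)) response <- matrix(response, ncol = 1L)
  if (is.null(colnames(response)))
    colnames(response) <- paste0("ch", seq_len(ncol(response)))
  fits <- vector("list", length(specs))
  folds_ref <- NULL
  for (i in seq_along(specs)) {
    chans <- matching_channels(pm, specs[[i]]$channels)
    if (length(chans) == 0L)
      stop_speechTRF(sprintf("model '%s' selects no channels",
                             specs[[i]]$name), "bad_model_spec")
    fit <- cross_validate(response, subset_channels(pm, chans), axis, cfg)
    if (is.null(folds_ref)) folds_ref <- fit$folds
    else if (!identical(folds_ref, fit$folds))
      stop_speechTRF("fold assignment differs across models",
                     "fold_mismatch")
    fits[[i]] <- fit
  }
  names(fits) <- vapply(specs, `[[`, "", "name")
  fits
}

#' Incremental reconstruction-accuracy gains along a model ladder
#'
#' Fits every model of a strictly nested ladder on identical folds and
#' data and reports, per response channel, each model's held-out
#' accuracy and its gain over the previous model. The base model's
#' accuracy is reported with `NA` gain.
#'
#' @param response Numeric vector or samples-x-channels matrix.
#' @param pm A [predictor_matrix()]; model channel specifications are
#'   matched with [matching_channels()], so condition-split matrices
#'   work transparently.
#' @param ladder List of `model_spec` objects (see [model_ladder()] or
#'   [custom_ladder()]), nested in order.
#' @param axis A [lag_axis()].
#' @param cfg A [fit_config()].
#' @return A tidy data frame (`channel`, `model`, `condition`,
#'   `accuracy`, `gain`) with the underlying fits in the `"fits"`
#'   attribute.
#' @export
incremental_gains <- function(response, pm, ladder, axis = lag_axis(),
                              cfg = fit_config()) {
  for (i in seq_along(ladder)[-1]) {
    if (!all(ladder[[i - 1]]$channels %in% ladder[[i]]$channels))
      stop_speechTRF("ladder models must be nested", "bad_model_spec")
  }
  fits <- fit_models_shared(response, pm, ladder, axis, cfg)
  acc <- do.call(rbind, lapply(fits, `[[`, "accuracy"))
  n_models <- nrow(acc)
  gain <- rbind(NA_real_, acc[-1L, , drop = FALSE] -
                  acc[-n_models, , drop = FALSE])
  out <- data.frame(
    channel = rep(colnames(acc), each = n_models),
    model = rep(rownames(acc), times = ncol(acc)),
    condition = "all",
    accuracy = as.vector(acc),
    gain = as.vector(gain),
    stringsAsFactors = FALSE)
  attr(out, "fits") <- fits
  out
}

#' Feature-exclusion accuracy gain
#'
#' Quantifies a feature group's contribution as the accuracy of the
#' full model minus the accuracy of the model with that group removed,
#' fitted on identical folds. With a condition-split predictor matrix,
#' passing `condition` drops only that condition's copies, giving the
#' entropy-conditioned contrast.
#'
#' @param response Numeric vector or samples-x-channels matrix.
#' @param pm The full-model [predictor_matrix()].
#' @param drop Base channel names of the group to exclude.
#' @param axis A [lag_axis()].
#' @param cfg A [fit_config()].
#' @param condition Optional condition filter for the dropped copies
#'   (`"high"` or `"low"`).
#' @param contrast Name for the contrast (default from `drop`).
#' @return Tidy data frame (`channel`, `contrast`, `condition`,
#'   `accuracy_full`, `accuracy_reduced`, `gain`).
#' @export
exclusion_gain <- function(response, pm, drop, axis = lag_axis(),
                           cfg = fit_config(), condition = NULL,
                           contrast = NULL) {
  if (length(drop) == 0L)
    stop_speechTRF("empty drop set", "bad_model_spec")
  full_chans <- colnames(pm$channels)
  drop_chans <- matching_channels(pm, drop, condition = condition)
  if (length(drop_chans) == 0L)
    stop_speechTRF("drop set selects no channels", "bad_model_spec")
  kept <- setdiff(full_chans, drop_chans)
  specs <- list(structure(list(name = "full", channels = full_chans),
                          class = "model_spec"))
  if (length(kept) > 0L)
    specs <- c(list(structure(list(name = "reduced", channels = kept),
                              class = "model_spec")), specs)
  fits <- fit_models_shared(response, pm, specs, axis, cfg)
  # dropping everything leaves the null model, which predicts zero and
  # explains none of the variance
  acc_reduced <- if (length(kept) > 0L) as.vector(fits$reduced$accuracy)
  else rep(0, length(fits$full$accuracy))
  data.frame(
    channel = names(fits$full$accuracy),
    contrast = contrast %||% paste(drop, collapse = "+"),
    condition = if (is.null(condition)) "all" else condition,
    accuracy_full = as.vector(fits$full$accuracy),
    accuracy_reduced = acc_reduced,
    gain = as.vector(fits$full$accuracy) - acc_reduced,
    stringsAsFactors = FALSE)
}

#' Incremental gains across sliding lag windows
#'
#' Runs [incremental_gains()] once per sliding lag window and stacks
#' the results, labelling each window by its center time.
#'
#' @inheritParams incremental_gains
#' @param windows List of [lag_axis()] objects from
#'   [sliding_window_models()].
#' @return Tidy data frame with an additional `window_center` column
#'   (seconds).
#' @export
windowed_gains <- function(response, pm, ladder, windows,
                           cfg = fit_config()) {
  stopifnot(length(windows) >= 1L)
  out <- lapply(windows, function(wax) {
    g <- incremental_gains(response, pm, ladder, wax, cfg)
    attr(g, "fits") <- NULL
    g$window_center <- attr(wax, "center") %||%
      mean(c(wax$tmin, wax$tmax))
    g
  })
  do.call(rbind, out)
}

#' Average a gain table over channel groups
#'
#' Averages accuracies and gains over channels sharing a group label
#' (e.g. pseudo-hemisphere labels of the synthetic module).
#'
#' @param gains A tidy gain table with a `channel` column.
#' @param groups Named character vector mapping channel name to group.
#' @return Data frame aggregated by group and the remaining id columns.
#' @export
summarize_gains <- function(gains, groups) {
  stopifnot("channel" %in% names(gains), !is.null(names(groups)))
  gains$group <- unname(groups[gains$channel])
  num <- intersect(c("accuracy", "gain", "accuracy_full",
                     "accuracy_reduced"), names(gains))
  ids <- setdiff(names(gains), c(num, "channel"))
  aggregate(gains[num], by = gains[ids], FUN = mean, na.rm = TRUE)
}

#' Write a tidy gain table as tab-separated text
#'
#' @param gains A gain table from [incremental_gains()],
#'   [exclusion_gain()] or [windowed_gains()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gain_table <- function(gains, path) {
  write.table(gains, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
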