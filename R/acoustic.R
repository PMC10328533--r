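# Acoustic predictors: ERB-spaced gammatone band envelopes and the
# half-wave-rectified acoustic-edge (onset) spectrogram.

#' ERB-number scale (Glasberg & Moore)
#'
#' `erb_number()` maps frequency in Hz to ERB number
#' (`21.4 * log10(1 + 0.00437 f)`); `erb_number_inverse()` is its
#' inverse; `erb_bandwidth()` is the equivalent rectangular bandwidth
#' `24.7 * (4.37 f / 1000 + 1)` in Hz.
#'
#' @param f Frequency in Hz.
#' @param e ERB number.
#' @return Numeric vector.
#' @export
erb_number <- function(f) 21.4 * log10(1 + 0.00437 * f)

#' @rdname erb_number
#' @export
erb_number_inverse <- function(e) (10^(e / 21.4) - 1) / 0.00437

#' @rdname erb_number
#' @export
erb_bandwidth <- function(f) 24.7 * (4.37 * f / 1000 + 1)

#' Filterbank center frequencies equally spaced on the ERB scale
#'
#' Returns `n_bands` center frequencies between `f_lo` and `f_hi`
#' inclusive, equally spaced on the ERB-number scale. With a single
#' band the ERB-scale midpoint is returned.
#'
#' @param n_bands Number of bands (default 8).
#' @param f_lo,f_hi Frequency range in Hz (defaults 20 and 5000).
#' @return Ascending numeric vector of center frequencies in Hz.
#' @export
erb_centers <- function(n_bands = 8L, f_lo = 20, f_hi = 5000) {
  stopifnot(n_bands >= 1L)
  if (!(f_lo > 0 && f_hi > f_lo))
    stop_speechTRF("need 0 < f_lo < f_hi", "bad_range")
  e <- if (n_bands == 1L) mean(erb_number(c(f_lo, f_hi)))
  else seq(erb_number(f_lo), erb_number(f_hi), length.out = n_bands)
  erb_number_inverse(e)
}

#' Band envelope container
#'
#' @param values Nonnegative matrix, bands x time samples.
#' @param band_centers Ascending center frequencies in Hz.
#' @param sample_rate Analysis sampling rate in Hz.
#' @return An object of class `band_envelopes`.
#' @export
band_envelopes <- function(values, band_centers, sample_rate) {
  stopifnot(is.matrix(values), nrow(values) == length(band_centers),
            !is.unsorted(band_centers, strictly = TRUE), sample_rate > 0)
  structure(list(values = values, band_centers = band_centers,
                 sample_rate = sample_rate), class = "band_envelopes")
}

#' @export
print.band_envelopes <- function(x, ...) {
  cat(sprintf("band_envelopes: %d bands x %d samples at %g Hz (%.1f-%.1f Hz)\n",
              nrow(x$values), ncol(x$values), x$sample_rate,
              min(x$band_centers), max(x$band_centers)))
  invisible(x)
}

gammatone_fir <- function(fc, fs, order = 4L, dur = 0.128) {
  t <- seq(0, dur, by = 1 / fs)
  b <- 1.019 * erb_bandwidth(fc)
  h <- t^(order - 1) * exp(-2 * pi * b * t) * cos(2 * pi * fc * t)
  # unit gain at the center frequency
  gain <- Mod(sum(h * exp(-2i * pi * fc * t)))
  h / gain
}

#' Gammatone band-envelope spectrogram
#'
#' Filters a mono waveform through a 4th-order gammatone filterbank
#' with [erb_centers()] spacing, takes the magnitude of each band
#' output, low-pass smooths it (zero-phase Butterworth), and samples the
#' result on the analysis time grid. This is the auditory spectrogram
#' used as the acoustic base predictor.
#'
#' @param waveform Numeric vector of mono PCM samples.
#' @param audio_rate Audio sampling rate in Hz; must be at least
#'   `2 * f_hi`.
#' @param n_bands,f_lo,f_hi Filterbank geometry (defaults 8 bands,
#'   20-5000 Hz).
#' @param analysis_rate Output sampling rate in Hz (default 100).
#' @param smoothing_cutoff Envelope low-pass cutoff in Hz; default
#'   `0.4 * analysis_rate`.
#' @return A [band_envelopes()] object with
#'   `floor(length(waveform) / audio_rate * analysis_rate)` samples.
#' @export
gammatone_spectrogram <- function(waveform, audio_rate, n_bands = 8L,
                                  f_lo = 20, f_hi = 5000,
                                  analysis_rate = 100,
                                  smoothing_cutoff = NULL) {
  if (is.matrix(waveform)) {
    if (ncol(waveform) != 1L)
      stop_speechTRF("waveform must be mono", "bad_audio")
    waveform <- as.vector(waveform)
  }
  stopifnot(is.numeric(waveform), length(waveform) > 1L)
  if (audio_rate < 2 * f_hi)
    stop_speechTRF("audio_rate must be at least 2 * f_hi", "bad_audio")
  smoothing_cutoff <- smoothing_cutoff %||% (0.4 * analysis_rate)
  centers <- erb_centers(n_bands, f_lo, f_hi)
  n <- length(waveform)
  n_out <- max(1L, floor(n / audio_rate * analysis_rate))
  t_audio <- (seq_len(n) - 1) / audio_rate
  t_out <- (seq_len(n_out) - 1) / analysis_rate
  bw <- signal::butter(4, min(0.99, smoothing_cutoff / (audio_rate / 2)),
                       type = "low")
  vals <- matrix(0, n_bands, n_out)
  for (bi in seq_len(n_bands)) {
    h <- gammatone_fir(centers[bi], audio_rate)
    y <- convolve(waveform, rev(h), type = "open")[seq_len(n)]
    env <- signal::filtfilt(bw, abs(y))
    env <- pmax(env, 0)
    vals[bi, ] <- approx(t_audio, env, xout = t_out, rule = 2)$y
  }
  band_envelopes(vals, centers, analysis_rate)
}

#' Acoustic-edge (onset) spectrogram
#'
#' Per band, the half-wave-rectified first temporal difference of the
#' log-compressed envelope `log(1 + env / eps)`, with
#' `eps = compression * max(env)`. Zero wherever the envelope is
#' locally non-increasing; the first sample is zero. This is a declared,
#' reproducible operator for "positive change in the band envelope";
#' it does not emulate any particular auditory edge-detection model.
#'
#' @param env A [band_envelopes()] object.
#' @param compression Relative log-compression constant (default
#'   `1e-8` of the envelope maximum).
#' @return A [band_envelopes()] object of identical shape.
#' @export
acoustic_edges <- function(env, compression = 1e-8) {
  stopifnot(inherits(env, "band_envelopes"))
  v <- env$values
  mx <- max(v)
  if (mx <= 0) return(band_envelopes(v * 0, env$band_centers,
                                     env$sample_rate))
  lg <- log1p(v / (compression * mx))
  d <- cbind(0, lg[, -1L, drop = FALSE] - lg[, -ncol(lg), drop = FALSE])
  band_envelopes(pmax(d, 0), env$band_centers, env$sample_rate)
}
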