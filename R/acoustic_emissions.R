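# Acoustic emission (AE) scoring from passive cavitation detector traces.
#
# The chain is: raw voltage trace -> magnitude spectrum (FFT, un-normalized,
# non-negative half-spectrum, no window) -> band-averaged linear magnitudes
# -> dB metrics against the median noise floor -> per-sonication subharmonic
# classification and per-treatment harmonic-increase summary.

#' One passive-cavitation-detector pulse record
#'
#' @param samples Numeric vector of voltages for one burst.
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @param pulse_index 1-based pulse number within the treatment.
#' @param time_offset Seconds from sonication start.
#' @param is_baseline `TRUE` for pre-injection (baseline) pulses.
#' @return An object of class `pulse_trace`.
#' @export
pulse_trace <- function(samples, sampling_rate, pulse_index = 1L,
                        time_offset = 0, is_baseline = FALSE) {
  if (!is.numeric(samples) || length(samples) == 0L)
    stop("samples must be a non-empty numeric vector")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      !is.finite(sampling_rate) || sampling_rate <= 0)
    stop("sampling_rate must be a single positive number")
  structure(
    list(samples = as.numeric(samples),
         sampling_rate = as.numeric(sampling_rate),
         pulse_index = as.integer(pulse_index),
         time_offset = as.numeric(time_offset),
         is_baseline = isTRUE(is_baseline)),
    class = "pulse_trace")
}

#' @export
print.pulse_trace <- function(x, ...) {
  cat(sprintf("<pulse_trace> pulse %d, %d samples @ %.4g MHz, t = %.1f s%s\n",
              x$pulse_index, length(x$samples), x$sampling_rate / 1e6,
              x$time_offset, if (x$is_baseline) " (baseline)" else ""))
  invisible(x)
}

#' Magnitude spectrum of a pulse trace
#'
#' Un-normalized forward FFT, retaining only the non-negative half-spectrum
#' (`floor(N/2) + 1` bins for `N` samples).  No window function is applied;
#' the burst is treated as rectangular-windowed.  A bin-centered sinusoid of
#' amplitude `a` therefore produces a single peak of magnitude `a * N / 2`.
#'
#' @param trace A [pulse_trace()], or a numeric vector (then `sampling_rate`
#'   must be given).
#' @param sampling_rate Sampling rate in Hz when `trace` is a bare vector.
#' @return An object of class `magnitude_spectrum` with fields `frequencies`
#'   (Hz, strictly increasing from 0) and `magnitudes` (linear, >= 0).
#' @export
magnitude_spectrum <- function(trace, sampling_rate = NULL) {
  if (inherits(trace, "pulse_trace")) {
    x <- trace$samples
    fs <- trace$sampling_rate
  } else {
    if (is.null(sampling_rate))
      stop("sampling_rate required when trace is a plain vector")
    x <- as.numeric(trace)
    fs <- sampling_rate
  }
  n <- length(x)
  if (n == 0L) stop("empty trace")
  nh <- n %/% 2L + 1L
  mag <- Mod(stats::fft(x))[seq_len(nh)]
  structure(
    list(frequencies = (seq_len(nh) - 1) * fs / n,
         magnitudes = mag,
         n_samples = n,
         sampling_rate = fs),
    class = "magnitude_spectrum")
}

#' @export
print.magnitude_spectrum <- function(x, ...) {
  cat(sprintf("<magnitude_spectrum> %d bins, 0 - %.4g MHz, df = %.4g Hz\n",
              length(x$frequencies), max(x$frequencies) / 1e6,
              x$frequencies[2] - x$frequencies[1]))
  invisible(x)
}

#' Frequency band definition
#'
#' A band is the closed interval `center +/- half_width`; optionally a
#' closed inner interval `center +/- exclusion_half_width` is excluded from
#' it (used for the subharmonic band, where the tonal line at the band
#' center is excluded).  Both interval memberships are endpoint-inclusive.
#'
#' @param center Band center, Hz.
#' @param half_width Band half-width, Hz (> 0).
#' @param exclusion_half_width Excluded inner half-width, Hz; 0 disables the
#'   exclusion.  Must be < `half_width`.
#' @return An object of class `band_def`.
#' @export
band_def <- function(center, half_width, exclusion_half_width = 0) {
  stopifnot(is.numeric(center), center > 0,
            is.numeric(half_width), half_width > 0)
  if (exclusion_half_width < 0 ||
      (exclusion_half_width != 0 && exclusion_half_width >= half_width))
    stop("exclusion_half_width must be 0 or in (0, half_width)")
  structure(list(center = center, half_width = half_width,
                 exclusion_half_width = exclusion_half_width),
            class = "band_def")
}

band_mask <- function(frequencies, band) {
  inside <- frequencies >= band$center - band$half_width &
    frequencies <= band$center + band$half_width
  if (band$exclusion_half_width > 0) {
    excl <- frequencies >= band$center - band$exclusion_half_width &
      frequencies <= band$center + band$exclusion_half_width
    inside <- inside & !excl
  }
  inside
}

#' Average linear magnitude over a band
#'
#' Arithmetic mean of the *linear* magnitudes at bins whose center frequency
#' lies inside the band (and outside its exclusion zone).  Averaging is done
#' in linear units; any dB conversion happens afterwards.
#'
#' @param spectrum A [magnitude_spectrum()].
#' @param band A [band_def()].
#' @return List with `mean` (linear magnitude) and `n_bins` (number of
#'   contributing bins).
#' @export
band_average <- function(spectrum, band) {
  stopifnot(inherits(spectrum, "magnitude_spectrum"), inherits(band, "band_def"))
  mask <- band_mask(spectrum$frequencies, band)
  n <- sum(mask)
  if (n == 0L)
    stop("band contains no spectrum bins (band outside spectrum support?)")
  list(mean = mean(spectrum$magnitudes[mask]), n_bins = n)
}

#' Spectral noise floor
#'
#' The noise floor is the median of the linear magnitudes over the entire
#' (half-)spectrum, converted to dB.
#'
#' @param spectrum A [magnitude_spectrum()].
#' @return Noise floor in dB.
#' @export
noise_floor <- function(spectrum) {
  stopifnot(inherits(spectrum, "magnitude_spectrum"))
  if (length(spectrum$magnitudes) == 0L) stop("empty spectrum")
  db(stats::median(spectrum$magnitudes))
}

#' Classify a sonication for subharmonic emissions
#'
#' A sonication is subharmonic-positive when the band-averaged subharmonic
#' magnitude, in dB, exceeds the median noise floor by at least
#' `threshold_db` (boundary inclusive).
#'
#' @param spectrum A [magnitude_spectrum()].
#' @param band Subharmonic [band_def()]; default 325 kHz +/- 2 kHz excluding
#'   +/- 100 Hz.
#' @param threshold_db Detection threshold in dB above the noise floor
#'   (default 7).
#' @return List with `subharmonic_level` (dB), `noise_floor` (dB),
#'   `subharmonic_excess` (dB), `subharmonic_positive` (logical), and
#'   `n_band_bins`.
#' @export
classify_subharmonic <- function(spectrum,
                                 band = band_def(325e3, 2e3, 100),
                                 threshold_db = 7) {
  avg <- band_average(spectrum, band)
  level <- db(avg$mean)
  floor_db <- noise_floor(spectrum)
  excess <- level - floor_db
  list(subharmonic_level = level,
       noise_floor = floor_db,
       subharmonic_excess = excess,
       subharmonic_positive = excess >= threshold_db,
       n_band_bins = avg$n_bins)
}

#' Harmonic increase over the pre-injection baseline
#'
#' The harmonic baseline is the mean of the first `n_baseline` harmonic
#' levels (dB); the increase series is each post-baseline level minus that
#' baseline, and the maximum of the series is recorded.
#'
#' @param harmonic_db Per-pulse harmonic band levels in dB, baseline pulses
#'   first.
#' @param n_baseline Number of pre-injection baseline pulses (default 5).
#' @return An object of class `treatment_ae_summary` with
#'   `harmonic_baseline`, `harmonic_increase_series`, and
#'   `max_harmonic_increase` (all dB).
#' @export
harmonic_increase_series <- function(harmonic_db, n_baseline = 5L) {
  harmonic_db <- as.numeric(harmonic_db)
  n_baseline <- as.integer(n_baseline)
  if (n_baseline < 1L) stop("n_baseline must be >= 1")
  if (length(harmonic_db) < n_baseline)
    stop(sprintf("need at least %d baseline pulses, got %d",
                 n_baseline, length(harmonic_db)))
  baseline <- mean(harmonic_db[seq_len(n_baseline)])
  post <- harmonic_db[-seq_len(n_baseline)]
  series <- post - baseline
  structure(
    list(harmonic_baseline = baseline,
         harmonic_increase_series = series,
         max_harmonic_increase = if (length(series)) max(series) else NA_real_,
         n_baseline = n_baseline,
         n_post = length(series)),
    class = "treatment_ae_summary")
}

#' AE analysis configuration
#'
#' Bands and thresholds of the AE chain for a 650 kHz excitation: the
#' subharmonic band is `f0/2 +/- 2 kHz` excluding `+/- 100 Hz` (the tonal
#' line at the band center), the harmonic band is `2 f0 +/- 300 Hz`, a
#' sonication is subharmonic-positive at >= 7 dB over the median noise
#' floor, and the harmonic baseline averages the first five pre-injection
#' pulses.
#'
#' @param f0 Fundamental (transmit) frequency, Hz.
#' @param subharmonic_band,harmonic_band [band_def()] overrides.
#' @param threshold_db Subharmonic detection threshold, dB.
#' @param n_baseline Number of baseline pulses averaged.
#' @param exclude_subharmonic_peak If `FALSE`, drop the +/- 100 Hz exclusion
#'   zone from the subharmonic band.
#' @return A list of class `ae_config`.
#' @export
ae_config <- function(f0 = 650e3,
                      subharmonic_band = NULL,
                      harmonic_band = NULL,
                      threshold_db = 7,
                      n_baseline = 5L,
                      exclude_subharmonic_peak = TRUE) {
  if (is.null(subharmonic_band))
    subharmonic_band <- band_def(f0 / 2, 2e3,
                                 if (exclude_subharmonic_peak) 100 else 0)
  if (is.null(harmonic_band))
    harmonic_band <- band_def(2 * f0, 300, 0)
  structure(list(f0 = f0,
                 subharmonic_band = subharmonic_band,
                 harmonic_band = harmonic_band,
                 threshold_db = threshold_db,
                 n_baseline = as.integer(n_baseline)),
            class = "ae_config")
}

#' Score a full pulse train and summarize the treatment
#'
#' Applies spectrum computation, band metrics, and subharmonic
#' classification to every pulse, then aggregates: the harmonic baseline and
#' increase series from the baseline-flagged pulses, and the count of
#' subharmonic-positive post-injection pulses.  Baseline pulses do not count
#' toward `n_subharmonic_positive`.
#'
#' @param pulses List of [pulse_trace()] objects (equal length and sampling
#'   rate; baseline pulses flagged and ordered first).
#' @param config An [ae_config()].
#' @return A `treatment_ae_summary` additionally carrying `pulse_table`
#'   (one row per pulse with levels, excess, and classification),
#'   `n_subharmonic_positive`, and `any_subharmonic`.
#' @export
summarize_treatment <- function(pulses, config = ae_config()) {
  stopifnot(inherits(config, "ae_config"))
  if (!length(pulses)) stop_bbb("ae", "empty pulse train")
  if (!all(vapply(pulses, inherits, logical(1), "pulse_trace")))
    stop_bbb("ae", "pulses must be pulse_trace objects")
  ns <- vapply(pulses, function(p) length(p$samples), integer(1))
  fs <- vapply(pulses, function(p) p$sampling_rate, numeric(1))
  if (length(unique(ns)) != 1L || length(unique(fs)) != 1L)
    stop_bbb("ae", "all pulses must share length and sampling rate")
  is_baseline <- vapply(pulses, function(p) p$is_baseline, logical(1))
  if (sum(is_baseline) < config$n_baseline)
    stop_bbb("ae", sprintf("need %d baseline pulses, found %d",
                           config$n_baseline, sum(is_baseline)))

  n <- ns[1]
  nh <- n %/% 2L + 1L
  X <- matrix(unlist(lapply(pulses, `[[`, "samples"), use.names = FALSE), n)
  mags <- Mod(stats::mvfft(X))[seq_len(nh), , drop = FALSE]
  freqs <- (seq_len(nh) - 1) * fs[1] / n

  sub_mask <- band_mask(freqs, config$subharmonic_band)
  harm_mask <- band_mask(freqs, config$harmonic_band)
  if (!any(sub_mask) || !any(harm_mask))
    stop_bbb("ae", "AE band contains no spectrum bins at this resolution")

  sub_level <- db(colMeans(mags[sub_mask, , drop = FALSE]))
  harm_level <- db(colMeans(mags[harm_mask, , drop = FALSE]))
  floor_db <- db(apply(mags, 2, stats::median))
  excess <- sub_level - floor_db
  positive <- excess >= config$threshold_db

  tab <- data.frame(
    pulse_index = vapply(pulses, function(p) p$pulse_index, integer(1)),
    time_offset = vapply(pulses, function(p) p$time_offset, numeric(1)),
    is_baseline = is_baseline,
    subharmonic_level = sub_level,
    noise_floor = floor_db,
    subharmonic_excess = excess,
    subharmonic_positive = positive,
    harmonic_level = harm_level)

  # baseline = first n_baseline baseline-flagged pulses; post = all others
  base_idx <- which(is_baseline)[seq_len(config$n_baseline)]
  post_idx <- which(!is_baseline)
  out <- harmonic_increase_series(
    c(harm_level[base_idx], harm_level[post_idx]), config$n_baseline)
  out$pulse_table <- tab
  out$n_subharmonic_positive <- sum(positive[post_idx])
  out$any_subharmonic <- out$n_subharmonic_positive > 0L
  out
}

#' @export
print.treatment_ae_summary <- function(x, ...) {
  cat(sprintf(
    "<treatment_ae_summary> baseline %.2f dB, max harmonic increase %.2f dB",
    x$harmonic_baseline, x$max_harmonic_increase))
  if (!is.null(x$n_subharmonic_positive))
    cat(sprintf(", %d subharmonic-positive pulse(s)", x$n_subharmonic_positive))
  cat("\n")
  invisible(x)
}
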