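# Spectrum computation, band metrics, noise floor, and the subharmonic /
# harmonic scoring chain.

test_that("magnitude spectrum matches the brute-force DFT oracle", {
  # silent trace
  z <- magnitude_spectrum(pulse_trace(rep(0, 64), 1e6))
  expect_true(all(z$magnitudes == 0))
  expect_length(z$magnitudes, 33)

  # bin-centered sinusoid: single non-zero bin of magnitude a * N / 2
  n <- 256; fs <- 1e4; a <- 0.7; k <- 17
  x <- a * sin(2 * pi * k * fs / n * (0:(n - 1)) / fs)
  sp <- magnitude_spectrum(pulse_trace(x, fs))
  ora <- oracle_dft_magnitudes(x)
  expect_equal(sp$magnitudes, ora, tolerance = 1e-9)
  expect_equal(sp$magnitudes[k + 1], a * n / 2, tolerance = 1e-9)
  others <- sp$magnitudes[-(k + 1)]
  expect_lt(max(others), 1e-8 * a * n)

  # random trace: half-spectrum equals the oracle, energy is consistent
  # with the time domain (Parseval, un-normalized convention)
  set.seed(11)
  x <- rnorm(128)
  sp <- magnitude_spectrum(pulse_trace(x, 1e6))
  expect_equal(sp$magnitudes, oracle_dft_magnitudes(x), tolerance = 1e-9)
  full <- Mod(fft(x))
  expect_equal(sum(full^2), length(x) * sum(x^2), tolerance = 1e-9)

  expect_error(magnitude_spectrum(pulse_trace(numeric(0), 1e6)))
  expect_error(pulse_trace(1:10, -1))
})

test_that("dB convention is 20 log10 with ~6.0206 dB per doubling", {
  expect_equal(db(10), 20)
  expect_equal(db(2) - db(1), 20 * log10(2), tolerance = 1e-6)
  expect_equal(db(2 * 0.37) - db(0.37), 6.0206, tolerance = 1e-4)
})

test_that("band averages agree with manual bin enumeration", {
  freqs <- seq(0, 5e5, by = 100)
  mags <- rep(2.5, length(freqs))
  sp <- make_spectrum(freqs, mags)

  # constant spectrum -> the constant, for any band
  b <- band_def(325e3, 2e3, 100)
  expect_equal(band_average(sp, b)$mean, 2.5)
  expect_equal(band_average(sp, band_def(1e5, 500))$mean, 2.5)

  # elevated bin inside the exclusion zone is ignored
  mags2 <- mags
  mags2[freqs == 325e3] <- 1e4
  sp2 <- make_spectrum(freqs, mags2)
  expect_equal(band_average(sp2, b)$mean, 2.5)
  expect_equal(band_average(sp2, b)$mean,
               oracle_band_mean(freqs, mags2, 325e3, 2e3, 100))

  # elevated bin inside the band, outside the exclusion
  mags3 <- mags
  mags3[freqs == 326e3] <- 100
  sp3 <- make_spectrum(freqs, mags3)
  expect_equal(band_average(sp3, b)$mean,
               oracle_band_mean(freqs, mags3, 325e3, 2e3, 100))
  # 41 bins in ±2 kHz at 100 Hz spacing, minus 3 excluded
  expect_identical(band_average(sp3, b)$n_bins, 38L)

  # no contributing bins is an explicit error, distinct from zero
  expect_error(band_average(sp, band_def(5e6, 100)), "no spectrum bins")
  expect_error(band_def(325e3, 2e3, 2e3))
})

test_that("noise floor is the median magnitude in dB", {
  sp <- make_spectrum(0:4 * 100, c(1, 2, 3, 4, 100))
  expect_equal(noise_floor(sp), db(3))
  expect_equal(noise_floor(sp), oracle_noise_floor_db(c(1, 2, 3, 4, 100)))
  # constant spectrum
  expect_equal(noise_floor(make_spectrum(0:9, rep(2.5, 10))), db(2.5))
  # scaling all magnitudes by 10 raises the floor by exactly 20 dB
  sp10 <- make_spectrum(0:4 * 100, 10 * c(1, 2, 3, 4, 100))
  expect_equal(noise_floor(sp10) - noise_floor(sp), 20, tolerance = 1e-12)
})

# Spectrum with a controlled subharmonic excess: flat background 1 with
# the in-band (non-excluded) bins raised so the linear band mean is
# 10^(excess_db / 20) while the median stays 1.
spectrum_with_excess <- function(excess_db) {
  freqs <- seq(0, 1e6, by = 100)
  mags <- rep(1, length(freqs))
  band <- freqs >= 323e3 & freqs <= 327e3 &
    !(freqs >= 324.9e3 & freqs <= 325.1e3)
  mags[band] <- 10^(excess_db / 20)
  make_spectrum(freqs, mags)
}

test_that("subharmonic classification uses an inclusive 7 dB boundary", {
  b <- band_def(325e3, 2e3, 100)
  flat <- make_spectrum(seq(0, 1e6, by = 100), rep(1, 10001))
  r <- classify_subharmonic(flat, b)
  expect_equal(r$subharmonic_excess, 0)
  expect_false(r$subharmonic_positive)

  r7 <- classify_subharmonic(spectrum_with_excess(7), b)
  expect_equal(r7$subharmonic_excess, 7, tolerance = 1e-9)
  expect_true(r7$subharmonic_positive)

  # 6.99 dB excess: mean = 10^(6.99/20) = 2.2361..., median 1, so the
  # hand-computed excess is 6.99 dB and the call is negative
  r699 <- classify_subharmonic(spectrum_with_excess(6.99), b)
  expect_equal(r699$subharmonic_excess, 6.99, tolerance = 1e-9)
  expect_false(r699$subharmonic_positive)
  # invariant: excess = level - floor
  expect_equal(r699$subharmonic_excess,
               r699$subharmonic_level - r699$noise_floor)
})

test_that("harmonic increase series is computed against a 5-pulse baseline", {
  s <- harmonic_increase_series(c(10, 10, 10, 10, 10, 10, 17, 12))
  expect_equal(s$harmonic_baseline, 10)
  expect_equal(s$harmonic_increase_series, c(0, 7, 2))
  expect_equal(s$max_harmonic_increase, 7)
  expect_identical(s$n_baseline, 5L)

  # all pulses identical -> all increases zero
  s0 <- harmonic_increase_series(rep(3.3, 12))
  expect_true(all(s0$harmonic_increase_series == 0))
  expect_equal(s0$max_harmonic_increase, 0)

  expect_error(harmonic_increase_series(c(10, 11, 12)),
               "at least 5 baseline")
})

# Half the production sampling rate: keeps the 100 Hz bin spacing and both
# AE bands below Nyquist while making test FFTs cheap.
small_schedule <- function(n_post = 12)
  pulse_schedule(sampling_rate = 3.29e6, burst_length = 0.01,
                 n_baseline = 5, n_post = n_post)

test_that("treatment summary composes the per-pulse chain", {
  # noise-free train without subharmonic energy is never positive
  tr <- simulate_pulse_train(emission_truth(noise_sd = 0), small_schedule(),
                             seed = 1)
  s <- summarize_treatment(tr)
  expect_false(s$any_subharmonic)
  expect_identical(s$n_subharmonic_positive, 0L)
  expect_equal(s$max_harmonic_increase,
               max(s$harmonic_increase_series))

  # injected subharmonic: every post pulse positive, no baseline pulse
  # counted; band mean validated against the DFT oracle on one pulse
  tr2 <- simulate_pulse_train(emission_truth(subharmonic_amp = 0.05,
                                             noise_sd = 0),
                              small_schedule(), seed = 1)
  s2 <- summarize_treatment(tr2)
  expect_identical(s2$n_subharmonic_positive, 12L)
  expect_true(all(!s2$pulse_table$subharmonic_positive[1:5]))
  sp6 <- magnitude_spectrum(tr2[[6]])
  cfg <- ae_config()
  expect_equal(
    band_average(sp6, cfg$subharmonic_band)$mean,
    oracle_band_mean(sp6$frequencies, sp6$magnitudes, 325e3, 2e3, 100),
    tolerance = 1e-12)

  # deterministic on a fixed input
  s2b <- summarize_treatment(simulate_pulse_train(
    emission_truth(subharmonic_amp = 0.05, noise_sd = 0),
    small_schedule(), seed = 1))
  expect_identical(s2$pulse_table, s2b$pulse_table)
})

test_that("raising the subharmonic amplitude never flips positive to negative", {
  sch <- small_schedule(4)
  was_positive <- FALSE
  for (amp in c(0, 0.001, 0.005, 0.02, 0.1, 0.5)) {
    tr <- simulate_pulse_train(emission_truth(subharmonic_amp = amp,
                                              noise_sd = 1e-3),
                               sch, seed = 99)
    pos <- summarize_treatment(tr)$any_subharmonic
    if (was_positive) expect_true(pos)
    was_positive <- was_positive || pos
  }
  expect_true(was_positive)
})

test_that("white-noise false-positive rate at 7 dB is stable across seeds", {
  sch <- pulse_schedule(sampling_rate = 3.29e6, burst_length = 0.01,
                        n_baseline = 5, n_post = 250)
  rate <- function(seed) {
    tr <- simulate_pulse_train(emission_truth(
      fundamental_amp = 0, harmonic_amps = c(0, 0), noise_sd = 0.01),
      sch, seed = seed)
    tab <- summarize_treatment(tr)$pulse_table
    mean(tab$subharmonic_positive[!tab$is_baseline])
  }
  r1 <- rate(1); r2 <- rate(2)
  # binomial agreement between seeds: |p1 - p2| within 3 * SE of the
  # pooled rate (plus a floor for rates near zero)
  pool <- (r1 + r2) / 2
  se <- sqrt(2 * pool * (1 - pool) / 250)
  expect_lt(abs(r1 - r2), 3 * se + 0.02)
  expect_lt(pool, 0.2)  # a 7 dB excess is rare under pure noise
})
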