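# Seeded generators: trace trains, image pairs, histology, full cohorts.

sch <- pulse_schedule(sampling_rate = 3.29e6, burst_length = 0.002,
                      n_baseline = 2, n_post = 4)

test_that("pulse trains are silent, seeded, and baseline-clean", {
  # all amplitudes and noise zero -> all-zero traces
  tr <- simulate_pulse_train(emission_truth(0, c(0, 0), 0, 0, 0), sch, 1)
  expect_length(tr, 6)
  expect_true(all(vapply(tr, function(p) all(p$samples == 0), logical(1))))

  # same (truth, schedule, seed) -> bitwise identical
  t1 <- simulate_pulse_train(emission_truth(subharmonic_amp = 0.01), sch, 5)
  t2 <- simulate_pulse_train(emission_truth(subharmonic_amp = 0.01), sch, 5)
  expect_identical(lapply(t1, `[[`, "samples"), lapply(t2, `[[`, "samples"))

  # baseline pulses carry no subharmonic energy: their spectra are flat
  # (to roundoff) in the subharmonic band while post pulses are not
  t3 <- simulate_pulse_train(emission_truth(subharmonic_amp = 0.05,
                                            noise_sd = 0), sch, 5)
  band <- band_def(325e3, 2e3, 100)
  base_e <- band_average(magnitude_spectrum(t3[[1]]), band)$mean
  post_e <- band_average(magnitude_spectrum(t3[[3]]), band)$mean
  expect_lt(base_e, 1e-6)
  expect_gt(post_e, 1)

  expect_error(pulse_schedule(sampling_rate = -1))
  expect_error(pulse_schedule(burst_length = 0))
})

test_that("the band-pass receiver option attenuates out-of-band components", {
  sch2 <- pulse_schedule(3.29e6, 0.01, 1, 1, 2)
  truth <- emission_truth(subharmonic_amp = 0.05, noise_sd = 0)
  flat <- simulate_pulse_train(truth, sch2, 3)
  bp <- simulate_pulse_train(truth, sch2, 3, receiver = "bandpass")
  band <- band_def(325e3, 2e3, 100)
  m_flat <- band_average(magnitude_spectrum(flat[[2]]), band)$mean
  m_bp <- band_average(magnitude_spectrum(bp[[2]]), band)$mean
  # 325 kHz sits ~1.6 MHz below the 1.95 MHz receiver center: strong loss
  expect_lt(m_bp, 0.01 * m_flat)
})

test_that("a sufficient subharmonic amplitude is detected downstream", {
  # the amplitude-to-excess relation was computed with the DFT oracle on a
  # generated noise-free pulse: an 0.05 V/line comb gives an excess far
  # above 7 dB over the noise floor of a noisy trace at noise_sd = 1e-3
  tr <- simulate_pulse_train(emission_truth(subharmonic_amp = 0.05,
                                            noise_sd = 1e-3),
                             pulse_schedule(3.29e6, 0.01, 1, 5, 5), 7)
  s <- summarize_treatment(tr)
  expect_true(s$any_subharmonic)
  expect_identical(s$n_subharmonic_positive, 5L)
})

test_that("MRI pairs plant the requested enhancement ratio", {
  geo <- image_geometry()
  # ratio 1, no noise -> identical images
  p1 <- simulate_mri_pair(outcome_truth(true_enhancement_ratio = 1), geo, 3)
  expect_equal(p1$pre$intensities, p1$post$intensities)

  # planted 1.4, noise-free: direct pixel-average oracle at the planted
  # focus reproduces the ratio
  p <- simulate_mri_pair(outcome_truth(true_enhancement_ratio = 1.4), geo, 3)
  f <- p$foci[[1]]
  img <- p$post$intensities
  son <- img[(f[1] - 2):(f[1] + 2), (f[2] - 2):(f[2] + 2)]
  mc <- round(2 * geo$midline_col - f[2])
  con <- img[(f[1] - 2):(f[1] + 2), (mc - 2):(mc + 2)]
  expect_equal(mean(son) / mean(con), 1.4, tolerance = 1e-6)

  # identical seeds -> identical pairs (with noise on)
  a <- simulate_mri_pair(outcome_truth(true_enhancement_ratio = 1.3), geo, 9,
                         noise_sd = 1)
  b <- simulate_mri_pair(outcome_truth(true_enhancement_ratio = 1.3), geo, 9,
                         noise_sd = 1)
  expect_identical(a$post$intensities, b$post$intensities)

  expect_error(image_geometry(midline_col = 500), "midline")
})

test_that("simulated histology is self-consistent with its true grade", {
  # minimum severity -> empty annotation grading to 0
  h0 <- simulate_histology(outcome_truth(true_grade = 0), 1)
  expect_identical(h0$lesions$n_microhemorrhages, 0L)
  expect_identical(h0$lesions$edema_severity, "none")
  expect_identical(grade_section(h0$lesions)$grade, 0L)

  # every grade maps back to itself through grade_section
  for (g in 0:5) for (seed in 1:5) {
    h <- simulate_histology(outcome_truth(true_grade = g), seed)
    expect_identical(grade_section(h$lesions)$grade, as.integer(g))
  }

  # zero rates -> all counts zero, all deltas zero
  hz <- simulate_histology(outcome_truth(activation_rate_sonicated = 0,
                                         activation_rate_control = 0),
                           2, nonactivated_rate = 0)
  expect_true(all(hz$counts$activated == 0))
  expect_true(all(hemisphere_deltas(hz$counts)$delta_density == 0))
})

test_that("activation deltas match the closed-form Poisson mean", {
  # sonicated 50/mm^2 vs control 10/mm^2: per-ROI-pair delta has mean 40
  # and variance 60/area; the grand mean over 200 animals x 6 pairs must
  # sit within 3 standard errors of 40
  truth <- outcome_truth(activation_rate_sonicated = 50,
                         activation_rate_control = 10)
  deltas <- unlist(lapply(1:200, function(s)
    hemisphere_deltas(simulate_histology(truth, s)$counts)$delta_density))
  se <- sqrt(60 / default_roi_area / length(deltas))
  expect_lt(abs(mean(deltas) - 40), 3 * se)
})

test_that("cohort simulation follows the design grid and master seed", {
  d1 <- cohort_design(dose_levels = 10,
                      pnp_levels_per_dose = list("10" = 0.3),
                      n_per_group = 1, control_pfus_only = FALSE,
                      control_untreated = FALSE, seed = 4)
  c1 <- simulate_cohort(d1)
  expect_identical(nrow(c1$animals), 1L)

  # full design: 12 groups (10 microbubble + 2 control) x 5 = 60 animals
  cfull <- simulate_cohort(cohort_design(seed = 8))
  expect_identical(nrow(cfull$animals), 60L)
  expect_identical(sum(!cfull$animals$is_control), 50L)
  expect_identical(length(unique(cfull$animals$group)), 12L)

  # same seed -> identical cohort summaries
  cfull2 <- simulate_cohort(cohort_design(seed = 8))
  expect_identical(cfull$animals, cfull2$animals)

  # raw bundles materialize one bundle per animal
  craw <- simulate_cohort(
    cohort_design(dose_levels = 10,
                  pnp_levels_per_dose = list("10" = c(0.15, 0.45)),
                  n_per_group = 2, control_pfus_only = FALSE,
                  control_untreated = FALSE, seed = 5),
    raw = TRUE, schedule = sch)
  expect_length(craw$bundles, 4)
  expect_named(craw$bundles[[1]], c("animal_id", "traces", "images",
                                    "histology"))

  expect_error(cohort_design(dose_levels = c(10, 10)))
  expect_error(cohort_design(n_per_group = 0))
  expect_error(cohort_design(dose_levels = numeric(0)))
})

test_that("mean planted enhancement is non-decreasing in PNP at fixed dose", {
  d <- cohort_design(n_per_group = 200, control_pfus_only = FALSE,
                     control_untreated = FALSE, seed = 12)
  co <- simulate_cohort(d)
  for (dose in c(10, 250)) {
    sub <- co$animals[co$animals$dose == dose, ]
    m <- tapply(sub$true_enhancement_ratio, sub$pnp, mean)
    m <- m[order(as.numeric(names(m)))]
    # allow Monte Carlo jitter well below the group SE (sd 0.05, n 200)
    expect_true(all(diff(m) > -3 * 0.05 / sqrt(200)))
  }
})

test_that("cohort designs load from key-value config files", {
  dir <- withr::local_tempdir()
  fy <- file.path(dir, "design.yaml")
  writeLines(c("dose_levels: [10, 250]",
               "pnp_levels_per_dose:",
               "  '10': [0.15, 0.45]",
               "  '250': [0.10, 0.35]",
               "n_per_group: 3",
               "control_untreated: false",
               "seed: 99"), fy)
  d <- cohort_design_from_file(fy)
  expect_identical(d$n_per_group, 3L)
  expect_identical(d$seed, 99L)
  expect_equal(d$pnp_levels_per_dose[["250"]], c(0.10, 0.35))
  expect_false(d$control_untreated)
  expect_identical(nrow(simulate_cohort(d)$animals), 15L)  # 4x3 + 3 pfus-only
})

test_that("trace and image containers round-trip through files", {
  dir <- withr::local_tempdir()
  tr <- simulate_pulse_train(emission_truth(subharmonic_amp = 0.01), sch, 2)
  f <- file.path(dir, "traces.f32")
  write_pulse_traces(tr, f)
  back <- read_pulse_traces(f)
  expect_length(back, length(tr))
  expect_equal(back[[3]]$samples, tr[[3]]$samples, tolerance = 1e-6)
  expect_identical(back[[1]]$is_baseline, TRUE)
  expect_identical(back[[6]]$is_baseline, FALSE)

  img <- simulate_mri_pair(outcome_truth(true_enhancement_ratio = 1.5),
                           image_geometry(), 3)$post
  fn <- file.path(dir, "post.nii.gz")
  write_brain_image(img, fn)
  img2 <- read_brain_image(fn)
  expect_equal(img2$intensities, img$intensities, tolerance = 1e-5)
  expect_identical(img2$sonicated_side, img$sonicated_side)

  h <- simulate_histology(outcome_truth(true_grade = 3), 4, animal_id = "m1")
  write_histology_csv(
    data.frame(animal_id = "m1",
               n_microhemorrhages = h$lesions$n_microhemorrhages,
               edema_severity = h$lesions$edema_severity),
    h$counts, dir)
  back <- read_histology_csv(dir)
  expect_identical(back$counts$activated, h$counts$activated)
  expect_identical(back$lesions$n_microhemorrhages,
                   h$lesions$n_microhemorrhages)
})
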