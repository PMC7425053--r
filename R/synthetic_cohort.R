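# Seeded synthetic data generator: per-pulse PCD voltage traces, pre/post
# contrast image pairs, and histology annotations, linked to per-animal
# ground truth so every downstream stage of the pipeline can be tested
# against known answers.

#' Pulse schedule of a sonication
#'
#' Defaults follow a 1 Hz pulse repetition frequency with 10 ms bursts
#' sampled at 6.58 MHz, five pre-injection baseline pulses, and 120 s of
#' post-injection treatment (125 pulses in total).  At these defaults the
#' spectral resolution is exactly 100 Hz.
#'
#' @param sampling_rate Sampling rate, Hz (> 0).
#' @param burst_length Burst duration, s (> 0).
#' @param prf Pulse repetition frequency, Hz.
#' @param n_baseline Number of pre-injection baseline pulses.
#' @param n_post Number of post-injection pulses.
#' @return An object of class `pulse_schedule`.
#' @export
pulse_schedule <- function(sampling_rate = 6.58e6, burst_length = 0.010,
                           prf = 1, n_baseline = 5L, n_post = 120L) {
  if (sampling_rate <= 0) stop("sampling_rate must be > 0")
  if (burst_length <= 0) stop("burst_length must be > 0")
  if (prf <= 0) stop("prf must be > 0")
  n_baseline <- as.integer(n_baseline); n_post <- as.integer(n_post)
  if (n_baseline < 0 || n_post < 0 || n_baseline + n_post < 1)
    stop("schedule must contain at least one pulse")
  structure(list(sampling_rate = sampling_rate, burst_length = burst_length,
                 prf = prf, n_baseline = n_baseline, n_post = n_post,
                 n_total = n_baseline + n_post,
                 n_samples = as.integer(round(sampling_rate * burst_length))),
            class = "pulse_schedule")
}

#' Ground-truth emission amplitudes for the trace simulator
#'
#' Amplitudes are linear volts.  `harmonic_amps` holds the second and third
#' harmonic (2 f0, 3 f0).  The subharmonic and ultraharmonic components are
#' simulated as finite-bandwidth combs of spectral lines spaced at the
#' burst's natural frequency resolution (see [simulate_pulse_train()]);
#' their amplitudes are per line.
#'
#' @param fundamental_amp,subharmonic_amp,ultraharmonic_amp Amplitudes, V.
#' @param harmonic_amps Length-2 numeric `(2 f0, 3 f0)` amplitudes, V.
#' @param noise_sd Additive white Gaussian noise SD, V.
#' @param f0 Fundamental frequency, Hz.
#' @return An object of class `emission_truth`.
#' @export
emission_truth <- function(fundamental_amp = 0.5,
                           harmonic_amps = c(0.05, 0.02),
                           subharmonic_amp = 0,
                           ultraharmonic_amp = 0,
                           noise_sd = 2e-3,
                           f0 = 650e3) {
  amps <- c(fundamental_amp, harmonic_amps, subharmonic_amp,
            ultraharmonic_amp)
  if (any(amps < 0)) stop("amplitudes must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (f0 <= 0) stop("f0 must be > 0")
  structure(list(fundamental_amp = fundamental_amp,
                 harmonic_amps = rep_len(as.numeric(harmonic_amps), 2L),
                 subharmonic_amp = subharmonic_amp,
                 ultraharmonic_amp = ultraharmonic_amp,
                 noise_sd = noise_sd, f0 = f0),
            class = "emission_truth")
}

#' Simulate a seeded train of PCD pulse traces
#'
#' Each trace is a sum of sinusoids at the fundamental `f0`, harmonics
#' `2 f0` and `3 f0`, and (post-injection only) subharmonic `f0/2` and
#' ultraharmonic `3 f0/2` components, plus white Gaussian noise.  The
#' sub/ultraharmonic components are combs of lines spaced at the burst's
#' frequency resolution within `+/- comb_bandwidth` of the center, since a
#' single on-bin tone at `f0/2` would fall entirely inside the detector's
#' spectral exclusion zone.  Harmonic amplitudes post-injection follow a
#' microbubble bolus envelope rising to a peak `bolus_peak_time` seconds
#' after injection and then decaying (`env(t) = (t/tp) exp(1 - t/tp)`),
#' scaled by `harmonic_boost`.  Component frequencies are snapped to DFT
#' bin centers by default so spectral peak values are closed-form.
#'
#' @param truth An [emission_truth()].
#' @param schedule A [pulse_schedule()].
#' @param seed Integer seed; identical (truth, schedule, seed) give
#'   bitwise-identical traces.
#' @param snap_to_bins Snap component frequencies to DFT bin centers
#'   (default `TRUE`).
#' @param bolus_peak_time Seconds to peak harmonic emission post injection.
#' @param harmonic_boost Peak fractional increase of harmonic amplitudes.
#' @param comb_bandwidth Half-bandwidth of the sub/ultraharmonic combs, Hz.
#' @param receiver `"flat"` (default) or `"bandpass"`: with `"bandpass"`,
#'   component amplitudes are shaped by a Gaussian receiver response of
#'   the stated PCD (1.95 MHz center, 51% fractional bandwidth at FWHM).
#' @param receiver_center,receiver_fractional_bw Band-pass response
#'   parameters (Hz; dimensionless fraction).
#' @return List of [pulse_trace()] objects of length `schedule$n_total`;
#'   the first `n_baseline` are flagged baseline and contain no
#'   subharmonic or ultraharmonic energy.
#' @export
simulate_pulse_train <- function(truth, schedule, seed,
                                 snap_to_bins = TRUE,
                                 bolus_peak_time = 25,
                                 harmonic_boost = 1,
                                 comb_bandwidth = 1e3,
                                 receiver = c("flat", "bandpass"),
                                 receiver_center = 1.95e6,
                                 receiver_fractional_bw = 0.51) {
  receiver <- match.arg(receiver)
  stopifnot(inherits(truth, "emission_truth"),
            inherits(schedule, "pulse_schedule"))
  n <- schedule$n_samples
  if (n < 2L) stop("burst too short for the sampling rate")
  fs <- schedule$sampling_rate
  df <- fs / n
  snap <- function(f) if (snap_to_bins) round(f / df) * df else f
  f0 <- truth$f0

  k <- seq(-floor(comb_bandwidth / df), floor(comb_bandwidth / df))
  comb_sub <- snap(f0 / 2) + k * df
  comb_ultra <- snap(1.5 * f0) + k * df
  comb_sub <- comb_sub[comb_sub > 0 & comb_sub < fs / 2]
  comb_ultra <- comb_ultra[comb_ultra > 0 & comb_ultra < fs / 2]

  freqs <- c(snap(f0), snap(2 * f0), snap(3 * f0), comb_sub, comb_ultra)
  gain <- if (receiver == "bandpass") {
    sigma <- receiver_fractional_bw * receiver_center / 2.355  # FWHM -> sd
    exp(-((freqs - receiver_center)^2) / (2 * sigma^2))
  } else rep(1, length(freqs))
  tt <- (0:(n - 1)) / fs
  W <- vapply(freqs, function(f) sin(2 * pi * f * tt), numeric(n))
  W <- sweep(W, 2, gain, `*`)

  idx_harm <- 2:3
  idx_sub <- 3 + seq_along(comb_sub)
  idx_ultra <- 3 + length(comb_sub) + seq_along(comb_ultra)

  env <- function(t_post) {
    tp <- bolus_peak_time
    ifelse(t_post <= 0, 0, (t_post / tp) * exp(1 - t_post / tp))
  }

  np <- schedule$n_total
  A <- matrix(0, np, ncol(W))
  A[, 1] <- truth$fundamental_amp
  A[, idx_harm[1]] <- truth$harmonic_amps[1]
  A[, idx_harm[2]] <- truth$harmonic_amps[2]
  post <- seq_len(np) > schedule$n_baseline
  t_post <- (seq_len(np) - schedule$n_baseline - 1) / schedule$prf + 1 / schedule$prf
  if (any(post)) {
    e <- env(t_post[post])
    A[post, idx_harm[1]] <- truth$harmonic_amps[1] * (1 + harmonic_boost * e)
    A[post, idx_harm[2]] <- truth$harmonic_amps[2] * (1 + harmonic_boost * e)
    A[post, idx_sub] <- truth$subharmonic_amp
    A[post, idx_ultra] <- truth$ultraharmonic_amp
  }

  set.seed(seed)
  X <- tcrossprod(W, A)
  if (truth$noise_sd > 0)
    X <- X + matrix(stats::rnorm(n * np, sd = truth$noise_sd), n, np)

  lapply(seq_len(np), function(i)
    pulse_trace(X[, i], fs, pulse_index = i,
                time_offset = (i - 1) / schedule$prf,
                is_baseline = !post[i]))
}

#' Image geometry for the MRI simulator
#'
#' @param n_row,n_col Image size in pixels.
#' @param pixel_spacing mm per pixel (row, col).
#' @param midline_col Midline column index (inside image).
#' @param sonicated_side `"left"` or `"right"`.
#' @return An object of class `image_geometry`.
#' @export
image_geometry <- function(n_row = 128L, n_col = 128L,
                           pixel_spacing = c(0.1, 0.1),
                           midline_col = 64.5,
                           sonicated_side = "left") {
  if (midline_col < 1 || midline_col > n_col) stop("midline outside image")
  structure(list(n_row = as.integer(n_row), n_col = as.integer(n_col),
                 pixel_spacing = rep_len(as.numeric(pixel_spacing), 2L),
                 midline_col = midline_col,
                 sonicated_side = match.arg(sonicated_side, c("left", "right"))),
            class = "image_geometry")
}

#' Ground-truth outcome bundle for one animal
#'
#' @param true_enhancement_ratio Planted CE-MRI ROI ratio (>= 0).
#' @param latent_severity Latent lesion severity driving the grade.
#' @param true_grade Integer histopathology grade 0..5.
#' @param activation_rate_sonicated,activation_rate_control Activated cells
#'   per mm^2 in the sonicated / contralateral ROIs.
#' @param subharmonic_amp Per-line subharmonic amplitude for the trace
#'   simulator (non-zero only above the severity threshold).
#' @return An object of class `outcome_truth`.
#' @export
outcome_truth <- function(true_enhancement_ratio = 1,
                          latent_severity = 0,
                          true_grade = 0L,
                          activation_rate_sonicated = 10,
                          activation_rate_control = 10,
                          subharmonic_amp = 0) {
  true_grade <- as.integer(true_grade)
  if (!true_grade %in% 0:5) stop("true_grade must be in 0..5")
  if (true_enhancement_ratio < 0) stop("enhancement ratio must be >= 0")
  if (activation_rate_sonicated < 0 || activation_rate_control < 0)
    stop("activation rates must be >= 0")
  structure(list(true_enhancement_ratio = true_enhancement_ratio,
                 latent_severity = latent_severity,
                 true_grade = true_grade,
                 activation_rate_sonicated = activation_rate_sonicated,
                 activation_rate_control = activation_rate_control,
                 subharmonic_amp = subharmonic_amp),
            class = "outcome_truth")
}

#' Simulate a pre/post contrast image pair with a planted enhancement ratio
#'
#' The pre-contrast image is a constant base intensity plus seeded white
#' noise; the post-contrast image adds a smooth Gaussian focal enhancement
#' in the sonicated hemisphere whose amplitude is scaled so that, in the
#' noise-free case, the mean-intensity ratio between the 0.5 x 0.5 mm ROI
#' centered on the focus and its mirrored contralateral ROI equals
#' `truth$true_enhancement_ratio` exactly.
#'
#' @param truth An [outcome_truth()] (only the enhancement ratio is used).
#' @param geometry An [image_geometry()].
#' @param seed Integer seed.
#' @param foci List of `(row, col)` focal centers; the default plants two
#'   enhancing regions (the cortical and thalamic ROIs of the analysis) in
#'   the sonicated hemisphere, 3 mm apart.
#' @param focus_sigma_mm Gaussian focal spot sigma, mm.
#' @param base_intensity Pre-contrast tissue intensity.
#' @param noise_sd Additive Gaussian noise SD (applied independently to
#'   both images).
#' @param roi_size_mm ROI size used for the planting contract.
#' @return List with `pre`, `post` (both [brain_image()]), and `foci`.
#' @export
simulate_mri_pair <- function(truth, geometry = image_geometry(), seed = 1L,
                              foci = NULL, focus_sigma_mm = 0.4,
                              base_intensity = 100, noise_sd = 0,
                              roi_size_mm = c(0.5, 0.5)) {
  stopifnot(inherits(truth, "outcome_truth"),
            inherits(geometry, "image_geometry"))
  g <- geometry
  if (is.null(foci)) {
    fc <- if (g$sonicated_side == "left") round(g$midline_col / 2)
          else round((g$midline_col + g$n_col) / 2)
    dr <- round(1.5 / g$pixel_spacing[1])
    foci <- list(c(round(g$n_row / 2) - dr, fc),
                 c(round(g$n_row / 2) + dr, fc))
  }
  if (!is.list(foci)) foci <- list(foci)
  foci <- lapply(foci, function(f) as.integer(round(f)))

  half <- as.integer(round(rep_len(roi_size_mm, 2L) / 2 / g$pixel_spacing))
  enh <- matrix(0, g$n_row, g$n_col)
  for (f in foci) {
    rows <- matrix((seq_len(g$n_row) - f[1]) * g$pixel_spacing[1],
                   g$n_row, g$n_col)
    cols <- matrix((seq_len(g$n_col) - f[2]) * g$pixel_spacing[2],
                   g$n_row, g$n_col, byrow = TRUE)
    blob <- exp(-(rows^2 + cols^2) / (2 * focus_sigma_mm^2))
    rr <- (f[1] - half[1]):(f[1] + half[1])
    cc <- (f[2] - half[2]):(f[2] + half[2])
    if (min(rr) < 1 || max(rr) > g$n_row || min(cc) < 1 || max(cc) > g$n_col)
      stop("focal ROI does not fit inside the image")
    # scale each focus so the ROI-mean ratio at that focus equals the
    # planted ratio exactly in the noise-free case
    amp <- base_intensity * (truth$true_enhancement_ratio - 1) /
      mean(blob[rr, cc])
    enh <- enh + amp * blob
  }

  set.seed(seed)
  noise1 <- if (noise_sd > 0)
    matrix(stats::rnorm(g$n_row * g$n_col, sd = noise_sd), g$n_row) else 0
  noise2 <- if (noise_sd > 0)
    matrix(stats::rnorm(g$n_row * g$n_col, sd = noise_sd), g$n_row) else 0
  pre_mat <- base_intensity + noise1
  if (!is.matrix(pre_mat)) pre_mat <- matrix(pre_mat, g$n_row, g$n_col)
  post_mat <- pre_mat + enh + noise2

  mk <- function(m) brain_image(m, g$pixel_spacing, g$midline_col,
                                g$sonicated_side)
  list(pre = mk(pre_mat), post = mk(post_mat), foci = foci)
}

# Draw a lesion annotation consistent with a true grade: the annotation is
# sampled from the set of (count, edema) combinations that grade back to
# exactly that grade.
annotation_for_grade <- function(grade) {
  counts <- switch(as.character(grade),
                   "0" = 0L, "1" = sample(1:3, 1), "2" = sample(4:10, 1),
                   "3" = sample(4:10, 1), "4" = sample(11:20, 1),
                   "5" = sample(11:25, 1))
  edema <- c("none", "minimal", "mild", "moderate", "marked",
             "severe_regional")[grade + 1L]
  lesion_annotation(counts, edema)
}

#' Simulate histology for one animal
#'
#' The lesion annotation is drawn from the combinations that map back to
#' `truth$true_grade` under [grade_section()] (self-consistency by
#' construction).  Activated-cell counts are Poisson with mean
#' `rate * roi_area` at the sonicated rate in sonicated ROIs and the
#' control rate contralaterally, for each stain and region (four ROIs per
#' stain).  Non-activated cells are Poisson at `nonactivated_rate`.
#'
#' @param truth An [outcome_truth()].
#' @param seed Integer seed.
#' @param animal_id Identifier copied into the counts table.
#' @param roi_area ROI area in mm^2 (default [default_roi_area]).
#' @param nonactivated_rate Non-activated cell density per mm^2.
#' @return List with `lesions` (a [lesion_annotation()]) and `counts`
#'   (a [cell_counts()] table).
#' @export
simulate_histology <- function(truth, seed = 1L, animal_id = "a1",
                               roi_area = default_roi_area,
                               nonactivated_rate = 100) {
  stopifnot(inherits(truth, "outcome_truth"))
  set.seed(seed)
  lesions <- annotation_for_grade(truth$true_grade)
  grid <- expand.grid(stain = c("Iba1", "TMEM119", "GFAP"),
                      region = c("cortex", "thalamus"),
                      hemisphere = c("sonicated", "contralateral"),
                      stringsAsFactors = FALSE)
  rate <- ifelse(grid$hemisphere == "sonicated",
                 truth$activation_rate_sonicated,
                 truth$activation_rate_control)
  activated <- stats::rpois(nrow(grid), rate * roi_area)
  total <- activated + stats::rpois(nrow(grid), nonactivated_rate * roi_area)
  counts <- cell_counts(animal_id, grid$stain, grid$region, grid$hemisphere,
                        activated, total, roi_area)
  list(lesions = lesions, counts = counts)
}

#' Cohort design grid
#'
#' Defaults reproduce the study design: a 10 uL/kg microbubble dose at
#' peak negative pressures 0.15/0.25/0.35/0.45 MPa and a 250 uL/kg dose at
#' 0.10-0.35 MPa, five animals per group (12 treatment groups, 60
#' animals), plus ultrasound-only (0.35 MPa, saline) and untreated
#' control groups.
#'
#' @param dose_levels Microbubble doses, uL/kg (distinct).
#' @param pnp_levels_per_dose Named list mapping dose to PNPs in MPa (> 0).
#' @param n_per_group Animals per group (>= 1).
#' @param control_pfus_only,control_untreated Include control groups?
#' @param control_pnp PNP for the ultrasound-only control, MPa.
#' @param seed Master seed for the whole cohort.
#' @return An object of class `cohort_design`.
#' @export
cohort_design <- function(dose_levels = c(10, 250),
                          pnp_levels_per_dose = list(
                            "10" = c(0.15, 0.25, 0.35, 0.45),
                            "250" = c(0.10, 0.15, 0.20, 0.25, 0.30, 0.35)),
                          n_per_group = 5L,
                          control_pfus_only = TRUE,
                          control_untreated = TRUE,
                          control_pnp = 0.35,
                          seed = 1L) {
  if (anyDuplicated(dose_levels)) stop("doses must be distinct")
  if (n_per_group < 1L) stop("n_per_group must be >= 1")
  if (!length(dose_levels) || is.null(pnp_levels_per_dose))
    stop("empty design")
  if (!all(as.character(dose_levels) %in% names(pnp_levels_per_dose)))
    stop("every dose needs PNP levels")
  pnps <- unlist(pnp_levels_per_dose)
  if (!length(pnps) || any(pnps <= 0)) stop("all PNPs must be > 0")
  structure(list(dose_levels = dose_levels,
                 pnp_levels_per_dose = pnp_levels_per_dose,
                 n_per_group = as.integer(n_per_group),
                 control_pfus_only = isTRUE(control_pfus_only),
                 control_untreated = isTRUE(control_untreated),
                 control_pnp = control_pnp,
                 seed = as.integer(seed)),
            class = "cohort_design")
}

# Monotone severity link: latent severity rises linearly in PNP and
# logarithmically in dose; fixed thresholds map it to grades 0..5.
# Enhancement follows a Gompertz curve of PNP whose inflection pressure
# decreases with dose.  Subharmonic emission is non-zero only above the
# grade >= +4 severity threshold.
severity_link_params <- function() {
  list(alpha = 18, beta = 1.2, sigma = 0.5,
       thresholds = c(4.3, 5.0, 5.7, 6.3, 6.9),
       gomp_A = 1.2, gomp_k = 15, gomp_p0_ref = 0.28, gomp_p0_slope = 0.057,
       ratio_sd = 0.05,
       rate_control = 10, rate_slope = 7,
       sub_amp = 0.02)
}

outcome_truth_for <- function(pnp, dose, is_control, link = severity_link_params()) {
  if (is_control) {
    return(outcome_truth(1, -Inf, 0L, link$rate_control, link$rate_control, 0))
  }
  latent <- link$alpha * pnp + link$beta * log10(dose / 10) +
    stats::rnorm(1, sd = link$sigma)
  grade <- sum(latent >= link$thresholds)
  p0 <- link$gomp_p0_ref - link$gomp_p0_slope * log10(dose / 10)
  ratio <- 1 + link$gomp_A * exp(-exp(-link$gomp_k * (pnp - p0))) +
    stats::rnorm(1, sd = link$ratio_sd)
  ratio <- max(ratio, 0.5)
  outcome_truth(
    true_enhancement_ratio = ratio,
    latent_severity = latent,
    true_grade = grade,
    activation_rate_sonicated = link$rate_control +
      link$rate_slope * max(latent, 0),
    activation_rate_control = link$rate_control,
    subharmonic_amp = if (latent >= link$thresholds[4]) link$sub_amp else 0)
}

#' Read a cohort design from a YAML/JSON config file
#'
#' The file is a key-value tree mirroring the [cohort_design()] arguments,
#' e.g. `dose_levels`, `pnp_levels_per_dose` (a map from dose to PNP
#' list), `n_per_group`, `control_pfus_only`, `control_untreated`, `seed`.
#' Keys that are absent keep the defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [cohort_design()].
#' @export
cohort_design_from_file <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  keep <- intersect(names(cfg), names(formals(cohort_design)))
  cfg <- cfg[keep]
  if (!is.null(cfg$pnp_levels_per_dose))
    cfg$pnp_levels_per_dose <- lapply(cfg$pnp_levels_per_dose, as.numeric)
  do.call(cohort_design, cfg)
}

#' Simulate a full cohort
#'
#' Generates the per-animal ground truths for every (dose, PNP) group of
#' the design plus configured controls, all randomness derived from
#' `design$seed`.  With `raw = TRUE`, raw data bundles (pulse traces,
#' image pair, histology) are materialized for every animal; with
#' `raw = FALSE` only the truth table is built and bundles can be
#' generated per animal with [simulate_animal()] (the pipeline does this
#' to bound memory).
#'
#' @param design A [cohort_design()].
#' @param raw Materialize raw per-animal bundles?
#' @param schedule [pulse_schedule()] for the trace simulator.
#' @param geometry [image_geometry()] for the image simulator.
#' @return An object of class `bbb_cohort`: list with `design`, `animals`
#'   (one row per animal: id, group, dose, PNP, control flags, seed, and
#'   truth columns), and `bundles` (list, `NULL` unless `raw`).
#' @export
simulate_cohort <- function(design, raw = FALSE,
                            schedule = pulse_schedule(),
                            geometry = image_geometry()) {
  stopifnot(inherits(design, "cohort_design"))
  groups <- do.call(rbind, lapply(design$dose_levels, function(d) {
    data.frame(dose = d, pnp = design$pnp_levels_per_dose[[as.character(d)]])
  }))
  groups$group <- sprintf("d%g_p%.2f", groups$dose, groups$pnp)
  groups$control_type <- "treatment"
  if (design$control_pfus_only)
    groups <- rbind(groups, data.frame(dose = 0, pnp = design$control_pnp,
                                       group = "pfus_only",
                                       control_type = "pfus_only"))
  if (design$control_untreated)
    groups <- rbind(groups, data.frame(dose = 0, pnp = 0,
                                       group = "untreated",
                                       control_type = "untreated"))

  animals <- groups[rep(seq_len(nrow(groups)), each = design$n_per_group), ]
  animals$animal_id <- sprintf("m%03d", seq_len(nrow(animals)))
  animals$is_control <- animals$control_type != "treatment"
  animals$seed <- vapply(seq_len(nrow(animals)),
                         function(i) derive_seed(design$seed, i), integer(1))
  rownames(animals) <- NULL

  truths <- vector("list", nrow(animals))
  for (i in seq_len(nrow(animals))) {
    set.seed(derive_seed(animals$seed[i], 0L))
    truths[[i]] <- outcome_truth_for(animals$pnp[i], animals$dose[i],
                                     animals$is_control[i])
  }
  animals$true_enhancement_ratio <-
    vapply(truths, `[[`, numeric(1), "true_enhancement_ratio")
  animals$latent_severity <- vapply(truths, `[[`, numeric(1), "latent_severity")
  animals$true_grade <- vapply(truths, `[[`, integer(1), "true_grade")
  animals$activation_rate_sonicated <-
    vapply(truths, `[[`, numeric(1), "activation_rate_sonicated")
  animals$activation_rate_control <-
    vapply(truths, `[[`, numeric(1), "activation_rate_control")
  animals$subharmonic_amp <- vapply(truths, `[[`, numeric(1), "subharmonic_amp")

  cohort <- structure(list(design = design, animals = animals,
                           truths = truths, schedule = schedule,
                           geometry = geometry, bundles = NULL),
                      class = "bbb_cohort")
  if (raw)
    cohort$bundles <- lapply(seq_len(nrow(animals)),
                             function(i) simulate_animal(cohort, i))
  cohort
}

#' Simulate the raw data bundle for one cohort animal
#'
#' @param cohort A [simulate_cohort()] result.
#' @param i Animal row index.
#' @return List with `animal_id`, `traces`, `images`, and `histology`.
#' @export
simulate_animal <- function(cohort, i) {
  stopifnot(inherits(cohort, "bbb_cohort"))
  a <- cohort$animals[i, ]
  truth <- cohort$truths[[i]]
  # ultrasound is on in every sonicated group; untreated controls have no
  # acoustic signal beyond noise
  sonicated <- a$control_type != "untreated"
  em <- emission_truth(
    fundamental_amp = if (sonicated) 0.5 * a$pnp / 0.35 else 0,
    harmonic_amps = if (sonicated) c(0.05, 0.02) * a$pnp / 0.35 else c(0, 0),
    subharmonic_amp = truth$subharmonic_amp,
    ultraharmonic_amp = truth$subharmonic_amp / 2,
    noise_sd = 2e-3)
  traces <- simulate_pulse_train(
    em, cohort$schedule, seed = derive_seed(a$seed, 1L),
    harmonic_boost = if (a$is_control) 0 else 1 + 2 * a$pnp)
  images <- simulate_mri_pair(truth, cohort$geometry,
                              seed = derive_seed(a$seed, 2L),
                              noise_sd = 0.5)
  histology <- simulate_histology(truth, seed = derive_seed(a$seed, 3L),
                                  animal_id = a$animal_id)
  list(animal_id = a$animal_id, traces = traces, images = images,
       histology = histology)
}

#' @export
print.bbb_cohort <- function(x, ...) {
  cat(sprintf("<bbb_cohort> %d animals (%d groups), seed %d%s\n",
              nrow(x$animals), length(unique(x$animals$group)),
              x$design$seed,
              if (!is.null(x$bundles)) ", raw bundles materialized" else ""))
  invisible(x)
}
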