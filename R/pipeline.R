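# End-to-end orchestration: simulate -> AE scoring -> MRI enhancement ->
# histology grading -> statistics, with a consolidated, reproducible
# report.  A single master seed (the design seed) deterministically derives
# every per-animal and per-test seed, so identical configs give identical
# reports.

#' Pipeline run configuration
#'
#' @param design A [cohort_design()]; its seed is the master seed.
#' @param schedule A [pulse_schedule()].
#' @param geometry An [image_geometry()].
#' @param ae An [ae_config()].
#' @param n_rois ROIs per animal on CE-MRI (default 2).
#' @param roi_size_mm CE-MRI ROI size, mm.
#' @param smooth_sigma Peak-search smoothing sigma, pixels.
#' @param min_separation_mm Minimum ROI center separation, mm.
#' @param opening_threshold Enhancement-ratio threshold for calling opening.
#' @param fisher_B,jt_B Monte Carlo draws for the large-table Fisher and
#'   large-n Jonckheere-Terpstra paths.
#' @return An object of class `run_config`.
#' @export
run_config <- function(design = cohort_design(),
                       schedule = pulse_schedule(),
                       geometry = image_geometry(),
                       ae = ae_config(),
                       n_rois = 2L,
                       roi_size_mm = c(0.5, 0.5),
                       smooth_sigma = 1,
                       min_separation_mm = 1,
                       opening_threshold = 1.10,
                       fisher_B = 1e4,
                       jt_B = 1e4) {
  stopifnot(inherits(design, "cohort_design"),
            inherits(schedule, "pulse_schedule"),
            inherits(geometry, "image_geometry"),
            inherits(ae, "ae_config"))
  structure(list(design = design, schedule = schedule, geometry = geometry,
                 ae = ae, n_rois = as.integer(n_rois),
                 roi_size_mm = rep_len(roi_size_mm, 2L),
                 smooth_sigma = smooth_sigma,
                 min_separation_mm = min_separation_mm,
                 opening_threshold = opening_threshold,
                 fisher_B = fisher_B, jt_B = jt_B,
                 seed = design$seed),
            class = "run_config")
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Simulates the cohort animal by animal (traces are scored and discarded
#' to bound memory), scores acoustic emissions, quantifies CE-MRI
#' enhancement, grades histology, computes activation deltas, and runs the
#' statistical layer: per-dose Gompertz fits of enhancement vs PNP,
#' Kendall tau and Fisher tests of PNP vs grade, Wilcoxon-Pratt tests of
#' the hemisphere deltas per stain, Jonckheere-Terpstra trend of deltas
#' across grades, and linear regressions of deltas on enhancement and on
#' maximum harmonic increase.
#'
#' @param config A [run_config()].
#' @return An object of class `cohort_report`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  cohort <- simulate_cohort(config$design, raw = FALSE,
                            schedule = config$schedule,
                            geometry = config$geometry)
  an <- cohort$animals
  n <- nrow(an)

  roi_rows <- list()
  delta_rows <- list()
  rec <- vector("list", n)
  for (i in seq_len(n)) {
    bundle <- simulate_animal(cohort, i)
    aes <- summarize_treatment(bundle$traces, config$ae)

    post <- bundle$images$post
    rois <- find_enhancement_rois(post, config$n_rois,
                                  roi_size_mm = config$roi_size_mm,
                                  smooth_sigma = config$smooth_sigma,
                                  min_separation_mm = config$min_separation_mm)
    enh <- lapply(rois, function(r) relative_enhancement(post, r))
    ratios <- vapply(enh, `[[`, numeric(1), "ratio")
    roi_rows[[i]] <- data.frame(
      animal_id = an$animal_id[i],
      roi = seq_along(enh),
      center_row = vapply(enh, function(e) e$roi$center[1], integer(1)),
      center_col = vapply(enh, function(e) e$roi$center[2], integer(1)),
      mean_sonicated = vapply(enh, `[[`, numeric(1), "mean_sonicated"),
      mean_contralateral = vapply(enh, `[[`, numeric(1), "mean_contralateral"),
      ratio = ratios)

    grade <- grade_section(bundle$histology$lesions)
    deltas <- hemisphere_deltas(bundle$histology$counts)
    delta_rows[[i]] <- deltas

    rec[[i]] <- data.frame(
      animal_id = an$animal_id[i], group = an$group[i],
      dose = an$dose[i], pnp = an$pnp[i],
      is_control = an$is_control[i], control_type = an$control_type[i],
      enhancement_ratio = mean(ratios),
      bbb_opening = call_bbb_opening(mean(ratios), config$opening_threshold),
      grade = grade$grade, grade_label = grade$label,
      n_microhemorrhages = bundle$histology$lesions$n_microhemorrhages,
      edema_severity = bundle$histology$lesions$edema_severity,
      harmonic_baseline = aes$harmonic_baseline,
      max_harmonic_increase = aes$max_harmonic_increase,
      n_subharmonic_positive = aes$n_subharmonic_positive,
      any_subharmonic = aes$any_subharmonic,
      true_grade = an$true_grade[i],
      true_enhancement_ratio = an$true_enhancement_ratio[i])
  }
  animals <- do.call(rbind, rec)
  rois <- do.call(rbind, roi_rows)
  deltas <- do.call(rbind, delta_rows)
  deltas <- merge(deltas, animals[, c("animal_id", "dose", "pnp", "grade",
                                      "is_control", "enhancement_ratio",
                                      "max_harmonic_increase")],
                  by = "animal_id", sort = FALSE)
  deltas <- deltas[order(deltas$animal_id, deltas$stain, deltas$region), ]
  rownames(deltas) <- NULL

  group_summaries <- do.call(rbind, lapply(split(animals, animals$group),
    function(gdf) data.frame(
      group = gdf$group[1], dose = gdf$dose[1], pnp = gdf$pnp[1],
      n = nrow(gdf),
      mean_enhancement = mean(gdf$enhancement_ratio),
      sd_enhancement = stats::sd(gdf$enhancement_ratio),
      n_opened = sum(gdf$bbb_opening),
      mean_grade = mean(gdf$grade),
      n_subharmonic = sum(gdf$any_subharmonic))))
  group_summaries <-
    group_summaries[order(group_summaries$dose, group_summaries$pnp), ]
  rownames(group_summaries) <- NULL

  tests <- run_cohort_stats(animals, deltas, config)

  structure(list(config = config, animals = animals, rois = rois,
                 deltas = deltas, group_summaries = group_summaries,
                 tests = tests,
                 provenance = list(
                   seed = config$seed,
                   package = "bbbopen",
                   version = as.character(utils::packageVersion("bbbopen")),
                   n_animals = nrow(animals))),
            class = "cohort_report")
}

run_cohort_stats <- function(animals, deltas, config) {
  treat <- animals[!animals$is_control, ]
  out <- list(gompertz = list(), kendall = list(), fisher = list(),
              wilcoxon = list(), jonckheere = list(),
              regressions = list())
  for (d in unique(treat$dose)) {
    sub <- treat[treat$dose == d, ]
    key <- paste0("dose_", d)
    # degenerate reduced designs (too few pressures, all grades tied)
    # simply skip the tests whose preconditions they cannot meet
    out$gompertz[[key]] <- if (nrow(sub) >= 5 && length(unique(sub$pnp)) >= 3)
      fit_gompertz(sub$pnp, sub$enhancement_ratio) else NULL
    out$kendall[[key]] <- if (nrow(sub) >= 3 &&
                              length(unique(sub$grade)) > 1 &&
                              length(unique(sub$pnp)) > 1)
      kendall_tau(sub$pnp, sub$grade) else NULL
    tab <- table(factor(sub$pnp), factor(sub$grade, levels = 0:5))
    tab <- tab[, colSums(tab) > 0, drop = FALSE]
    out$fisher[[key]] <- if (ncol(tab) >= 2)
      fisher_exact(unclass(tab), B = config$fisher_B,
                   seed = derive_seed(config$seed, 101L)) else NULL
  }
  dtr <- deltas[!deltas$is_control, ]
  for (st in unique(dtr$stain)) {
    sub <- dtr[dtr$stain == st, ]
    out$wilcoxon[[st]] <- wilcoxon_pratt(sub$delta_density)
    grp <- split(sub$delta_density, factor(sub$grade, levels = sort(unique(sub$grade))))
    out$jonckheere[[st]] <- if (length(grp) >= 2)
      jonckheere_terpstra(grp, alternative = "increasing",
                          method = if (sum(lengths(grp)) <= 12) "auto" else "normal",
                          B = config$jt_B,
                          seed = derive_seed(config$seed, 102L)) else NULL
    out$regressions[[paste0(st, "_vs_enhancement")]] <-
      linfit_r2(sub$enhancement_ratio, sub$delta_density)
    out$regressions[[paste0(st, "_vs_harmonic")]] <-
      linfit_r2(sub$max_harmonic_increase, sub$delta_density)
  }
  out
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("<cohort_report> %d animals, %d groups, seed %d\n",
              nrow(x$animals), nrow(x$group_summaries), x$provenance$seed))
  print(x$group_summaries, digits = 3)
  invisible(x)
}

tests_to_table <- function(tests) {
  rows <- list()
  add <- function(family, name, t) {
    if (is.null(t)) return()
    if (inherits(t, "bbb_test"))
      rows[[length(rows) + 1L]] <<- data.frame(
        family = family, name = name, method = t$method,
        statistic = t$statistic, p_value = t$p_value, n = t$n,
        exact = t$exact)
    else if (inherits(t, "gompertz_fit"))
      rows[[length(rows) + 1L]] <<- data.frame(
        family = family, name = name, method = "gompertz_nls",
        statistic = t$mape, p_value = NA_real_, n = length(t$fitted),
        exact = FALSE)
    else if (!is.null(t$r_squared))
      rows[[length(rows) + 1L]] <<- data.frame(
        family = family, name = name, method = "ols",
        statistic = t$r_squared, p_value = NA_real_, n = t$n,
        exact = FALSE)
  }
  for (fam in names(tests))
    for (nm in names(tests[[fam]])) add(fam, nm, tests[[fam]][[nm]])
  do.call(rbind, rows)
}

#' Write a cohort report to disk
#'
#' Persists a JSON master report plus per-stage CSV tables (animals, ROIs,
#' activation deltas, group summaries, test results) and, optionally,
#' diagnostic figures (enhancement vs PNP, deltas vs PNP, grade vs
#' enhancement).
#'
#' @param report A [run_pipeline()] result.
#' @param directory Output directory (created if missing).
#' @param figures Also write PDF figures?
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, directory, figures = FALSE) {
  stopifnot(inherits(report, "cohort_report"))
  if (is.null(report$animals) || nrow(report$animals) == 0L)
    stop("empty report")
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wcsv <- function(df, name) {
    p <- file.path(directory, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wcsv(report$animals, "animals.csv")
  wcsv(report$rois, "rois.csv")
  wcsv(report$deltas, "activation_deltas.csv")
  wcsv(report$group_summaries, "group_summaries.csv")
  test_tab <- tests_to_table(report$tests)
  wcsv(test_tab, "tests.csv")

  master <- list(
    provenance = report$provenance,
    design = list(
      dose_levels = report$config$design$dose_levels,
      pnp_levels_per_dose = report$config$design$pnp_levels_per_dose,
      n_per_group = report$config$design$n_per_group,
      seed = report$config$design$seed),
    settings = list(
      n_rois = report$config$n_rois,
      opening_threshold = report$config$opening_threshold,
      subharmonic_threshold_db = report$config$ae$threshold_db,
      n_baseline = report$config$ae$n_baseline),
    group_summaries = report$group_summaries,
    tests = test_tab)
  pjson <- file.path(directory, "report.json")
  jsonlite::write_json(master, pjson, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  paths <- c(paths, pjson)

  if (figures) {
    pfig <- file.path(directory, "figures.pdf")
    grDevices::pdf(pfig, width = 7, height = 5)
    on.exit(grDevices::dev.off(), add = TRUE)
    tr <- report$animals[!report$animals$is_control, ]
    for (d in unique(tr$dose)) {
      sub <- tr[tr$dose == d, ]
      graphics::plot(sub$pnp, sub$enhancement_ratio,
                     xlab = "PNP (MPa)", ylab = "relative enhancement",
                     main = sprintf("Enhancement vs PNP, %g uL/kg", d))
      gf <- report$tests$gompertz[[paste0("dose_", d)]]
      if (!is.null(gf) && gf$converged) {
        pp <- seq(min(sub$pnp), max(sub$pnp), length.out = 100)
        graphics::lines(pp, gompertz_curve(
          pp, gf$parameters["c"], gf$parameters["A"],
          gf$parameters["k"], gf$parameters["p0"]), lty = 2)
      }
    }
    graphics::boxplot(enhancement_ratio ~ grade, data = tr,
                      xlab = "histopathology grade",
                      ylab = "relative enhancement")
    dtr <- report$deltas[!report$deltas$is_control, ]
    graphics::plot(dtr$pnp, dtr$delta_density, col = factor(dtr$stain),
                   xlab = "PNP (MPa)",
                   ylab = "activated cells / mm^2 (sonicated - control)")
    paths <- c(paths, pfig)
  }
  invisible(paths)
}

#' Read back the master JSON report
#'
#' @param directory Directory written by [write_report()].
#' @return Parsed report list.
#' @export
read_report <- function(directory) {
  jsonlite::read_json(file.path(directory, "report.json"),
                      simplifyVector = TRUE)
}
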