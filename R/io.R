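# File interchange: pulse-trace containers (little-endian float32 binary
# plus a JSON sidecar), NIfTI brain images, and CSV histology tables.

#' Write a pulse train to a float32 container with a JSON sidecar
#'
#' Traces are concatenated in pulse order as IEEE-754 little-endian
#' float32; the sidecar records sampling rate, pulse schedule, baseline
#' count, and per-pulse metadata needed to reconstruct the train.
#'
#' @param traces List of [pulse_trace()] (equal lengths).
#' @param file Binary container path; the sidecar is `<file>.json`.
#' @return Invisibly, `c(file, sidecar)`.
#' @export
write_pulse_traces <- function(traces, file) {
  stopifnot(length(traces) > 0,
            all(vapply(traces, inherits, logical(1), "pulse_trace")))
  ns <- vapply(traces, function(t) length(t$samples), integer(1))
  if (length(unique(ns)) != 1L) stop("traces must have equal length")
  con <- file(file, "wb")
  on.exit(close(con))
  for (tr in traces)
    writeBin(tr$samples, con, size = 4L, endian = "little")
  sidecar <- paste0(file, ".json")
  jsonlite::write_json(list(
    sampling_rate = traces[[1]]$sampling_rate,
    n_pulses = length(traces),
    samples_per_pulse = ns[1],
    n_baseline = sum(vapply(traces, `[[`, logical(1), "is_baseline")),
    pulse_index = vapply(traces, `[[`, integer(1), "pulse_index"),
    time_offset = vapply(traces, `[[`, numeric(1), "time_offset"),
    is_baseline = vapply(traces, `[[`, logical(1), "is_baseline")),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(c(file, sidecar))
}

#' Read a pulse train container written by [write_pulse_traces()]
#'
#' @param file Binary container path (sidecar `<file>.json` must exist).
#' @return List of [pulse_trace()] (float32 precision).
#' @export
read_pulse_traces <- function(file) {
  meta <- jsonlite::read_json(paste0(file, ".json"), simplifyVector = TRUE)
  con <- file(file, "rb")
  on.exit(close(con))
  n <- meta$n_pulses * meta$samples_per_pulse
  x <- readBin(con, numeric(), n = n, size = 4L, endian = "little")
  lapply(seq_len(meta$n_pulses), function(i) {
    s <- x[((i - 1) * meta$samples_per_pulse + 1):(i * meta$samples_per_pulse)]
    pulse_trace(s, meta$sampling_rate,
                pulse_index = meta$pulse_index[i],
                time_offset = meta$time_offset[i],
                is_baseline = meta$is_baseline[i])
  })
}

#' Write a brain image as NIfTI with a JSON geometry sidecar
#'
#' Pixel spacing (mm) is stored in the NIfTI header; midline column and
#' sonicated side, which NIfTI cannot carry, go to `<file>.json`.
#'
#' @param image A [brain_image()].
#' @param file Output path (`.nii` or `.nii.gz`).
#' @return Invisibly, the paths written.
#' @export
write_brain_image <- function(image, file) {
  stopifnot(inherits(image, "brain_image"))
  nii <- RNifti::asNifti(image$intensities,
                         pixdim = c(image$pixel_spacing, 1))
  RNifti::writeNifti(nii, file)
  sidecar <- paste0(file, ".json")
  jsonlite::write_json(list(midline_col = image$midline_col,
                            sonicated_side = image$sonicated_side,
                            pixel_spacing = image$pixel_spacing),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(c(file, sidecar))
}

#' Read a brain image written by [write_brain_image()]
#'
#' @param file NIfTI path (sidecar `<file>.json` must exist).
#' @return A [brain_image()].
#' @export
read_brain_image <- function(file) {
  nii <- RNifti::readNifti(file)
  meta <- jsonlite::read_json(paste0(file, ".json"), simplifyVector = TRUE)
  brain_image(matrix(as.numeric(nii), dim(nii)[1], dim(nii)[2]),
              pixel_spacing = meta$pixel_spacing,
              midline_col = meta$midline_col,
              sonicated_side = meta$sonicated_side)
}

#' Write histology tables (lesions and counts) as CSV
#'
#' @param lesions `data.frame` with one row per animal (`animal_id`,
#'   `n_microhemorrhages`, `edema_severity`).
#' @param counts A [cell_counts()] table.
#' @param directory Output directory.
#' @return Invisibly, the paths written.
#' @export
write_histology_csv <- function(lesions, counts, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  pl <- file.path(directory, "lesions.csv")
  pc <- file.path(directory, "cell_counts.csv")
  utils::write.csv(lesions, pl, row.names = FALSE)
  utils::write.csv(as.data.frame(counts), pc, row.names = FALSE)
  invisible(c(pl, pc))
}

#' Read histology tables written by [write_histology_csv()]
#'
#' @param directory Directory holding `lesions.csv` and `cell_counts.csv`.
#' @return List with `lesions` and `counts` (a [cell_counts()] table).
#' @export
read_histology_csv <- function(directory) {
  lesions <- utils::read.csv(file.path(directory, "lesions.csv"))
  cc <- utils::read.csv(file.path(directory, "cell_counts.csv"))
  list(lesions = lesions,
       counts = cell_counts(cc$animal_id, cc$stain, cc$region,
                            cc$hemisphere, cc$activated, cc$total,
                            cc$roi_area))
}
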