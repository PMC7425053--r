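# Semiquantitative histopathology grading and glial activation bookkeeping.
#
# Lesion grading maps a pathologist's annotation (microhemorrhage count,
# ordinal edema severity) to a 0..+5 grade.  Activated-cell counts from
# rectangular IHC ROIs are converted to densities per mm^2 and paired
# across hemispheres into sonicated-minus-contralateral deltas.

#' Ordinal edema severity levels, least to most severe
#' @export
edema_levels <- c("none", "minimal", "mild", "moderate", "marked",
                  "severe_regional")

#' Grade labels for grades 0..+5
#' @export
grade_labels <- c("None", "Minimal", "Mild", "Moderate", "Marked", "Severe")

#' Lesion annotation for one H&E section
#'
#' @param n_microhemorrhages Non-negative integer count of microhemorrhages.
#' @param edema_severity One of [edema_levels].
#' @return An object of class `lesion_annotation`.
#' @export
lesion_annotation <- function(n_microhemorrhages, edema_severity) {
  n <- as.integer(n_microhemorrhages)
  if (is.na(n) || n < 0) stop("n_microhemorrhages must be a count >= 0")
  edema_severity <- match.arg(edema_severity, edema_levels)
  structure(list(n_microhemorrhages = n, edema_severity = edema_severity),
            class = "lesion_annotation")
}

#' Semiquantitative histopathology grade of a section
#'
#' Grading rules:
#' \describe{
#'   \item{0 (None)}{no microhemorrhages, no edema}
#'   \item{+1 (Minimal)}{1-3 microhemorrhages with minimal edema}
#'   \item{+2 (Mild)}{4-10 microhemorrhages with mild edema}
#'   \item{+3 (Moderate)}{4-10 microhemorrhages with moderate edema}
#'   \item{+4 (Marked)}{more than ten microhemorrhages with marked edema}
#'   \item{+5 (Severe)}{more than ten microhemorrhages with severe,
#'     regionally extensive edema}
#' }
#' Combinations outside these rows (e.g. no microhemorrhages with severe
#' edema, or 4-10 microhemorrhages with minimal edema) have no defined
#' grade and are returned as explicitly ungradable rather than coerced.
#'
#' @param annotation A [lesion_annotation()].
#' @return An object of class `histo_grade` with fields `grade` (integer
#'   0..5, or `NA` when ungradable), `label`, `gradable` (logical), and
#'   `reason` (why a combination is ungradable).
#' @export
grade_section <- function(annotation) {
  stopifnot(inherits(annotation, "lesion_annotation"))
  n <- annotation$n_microhemorrhages
  e <- annotation$edema_severity
  g <- if (n == 0 && e == "none") 0L
  else if (n >= 1 && n <= 3 && e == "minimal") 1L
  else if (n >= 4 && n <= 10 && e == "mild") 2L
  else if (n >= 4 && n <= 10 && e == "moderate") 3L
  else if (n >= 11 && e == "marked") 4L
  else if (n >= 11 && e == "severe_regional") 5L
  else NA_integer_
  structure(
    list(grade = g,
         label = if (is.na(g)) NA_character_ else grade_labels[g + 1L],
         gradable = !is.na(g),
         reason = if (is.na(g))
           sprintf("no grading row for %d microhemorrhage(s) with %s edema",
                   n, e) else NULL),
    class = "histo_grade")
}

#' @export
print.histo_grade <- function(x, ...) {
  if (x$gradable)
    cat(sprintf("<histo_grade> %s%d (%s)\n", if (x$grade > 0) "+" else "",
                x$grade, x$label))
  else cat(sprintf("<histo_grade> ungradable: %s\n", x$reason))
  invisible(x)
}

#' Default IHC ROI area: 1.32 mm x 0.72 mm
#' @export
default_roi_area <- 1.32 * 0.72

#' Activated-cell counts table constructor/validator
#'
#' One row per (animal, stain, region, hemisphere) ROI.
#'
#' @param animal_id,stain,region,hemisphere,activated,total Vectors of equal
#'   length; `stain` in Iba1/TMEM119/GFAP, `region` in cortex/thalamus,
#'   `hemisphere` in sonicated/contralateral.
#' @param roi_area ROI area in mm^2 (default [default_roi_area]).
#' @return A validated `data.frame` of class `cell_counts`.
#' @export
cell_counts <- function(animal_id, stain, region, hemisphere,
                        activated, total = NA_integer_,
                        roi_area = default_roi_area) {
  df <- data.frame(animal_id = animal_id,
                   stain = as.character(stain),
                   region = as.character(region),
                   hemisphere = as.character(hemisphere),
                   activated = as.integer(activated),
                   total = as.integer(total),
                   roi_area = as.numeric(roi_area))
  if (!all(df$stain %in% c("Iba1", "TMEM119", "GFAP")))
    stop("stain must be one of Iba1, TMEM119, GFAP")
  if (!all(df$region %in% c("cortex", "thalamus")))
    stop("region must be cortex or thalamus")
  if (!all(df$hemisphere %in% c("sonicated", "contralateral")))
    stop("hemisphere must be sonicated or contralateral")
  if (any(df$activated < 0)) stop("activated counts must be >= 0")
  bad <- !is.na(df$total) & df$total < df$activated
  if (any(bad)) stop("total must be >= activated")
  if (any(df$roi_area <= 0)) stop("roi_area must be > 0")
  class(df) <- c("cell_counts", "data.frame")
  df
}

#' Activated-cell density per mm^2
#'
#' @param activated Activated-cell count(s), or a `cell_counts` table.
#' @param roi_area ROI area(s) in mm^2 (ignored when a table is given).
#' @return Density in activated cells per mm^2.
#' @export
activation_density <- function(activated, roi_area = default_roi_area) {
  if (inherits(activated, "cell_counts"))
    return(activated$activated / activated$roi_area)
  if (any(roi_area <= 0)) stop("roi_area must be > 0")
  if (any(activated < 0)) stop("activated counts must be >= 0")
  activated / roi_area
}

#' Sonicated-minus-contralateral activation deltas
#'
#' Pairs each sonicated ROI with the contralateral ROI of the same animal,
#' stain, and region, and returns the difference in activated-cell density
#' (per mm^2).  ROIs without a partner are an error listing the offending
#' combinations rather than being dropped silently.
#'
#' @param counts A [cell_counts()] table.
#' @return `data.frame` with one row per (animal, stain, region) and column
#'   `delta_density`.
#' @export
hemisphere_deltas <- function(counts) {
  stopifnot(inherits(counts, "data.frame"))
  key <- interaction(counts$animal_id, counts$stain, counts$region,
                     drop = TRUE)
  out <- lapply(split(seq_len(nrow(counts)), key), function(idx) {
    rows <- counts[idx, ]
    son <- rows[rows$hemisphere == "sonicated", ]
    con <- rows[rows$hemisphere == "contralateral", ]
    if (nrow(son) != 1L || nrow(con) != 1L) return(rows[1, 1:3])
    data.frame(animal_id = rows$animal_id[1], stain = rows$stain[1],
               region = rows$region[1],
               delta_density = son$activated / son$roi_area -
                 con$activated / con$roi_area)
  })
  unmatched <- vapply(out, function(d) is.null(d$delta_density), logical(1))
  if (any(unmatched)) {
    bad <- do.call(rbind, out[unmatched])
    stop("unmatched hemisphere ROI pairs: ",
         paste(sprintf("%s/%s/%s", bad$animal_id, bad$stain, bad$region),
               collapse = ", "))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Normalize per-animal metrics by a global maximum
#'
#' In mode `"per-metric"` (default) each metric is divided by its own global
#' maximum across all values, so the largest value maps to 1.  In mode
#' `"by-enhancement"` every metric is divided by the global maximum relative
#' signal enhancement supplied via `enhancement`.
#'
#' @param values Numeric vector, or data.frame of numeric metric columns.
#' @param mode `"per-metric"` or `"by-enhancement"`.
#' @param enhancement Relative-enhancement values whose maximum is the
#'   divisor in `"by-enhancement"` mode.
#' @return Normalized values with the shape of the input.
#' @export
normalize_metrics <- function(values, mode = c("per-metric", "by-enhancement"),
                              enhancement = NULL) {
  mode <- match.arg(mode)
  norm1 <- function(v, divisor) {
    if (!is.finite(divisor) || divisor <= 0)
      stop("normalization divisor must be a positive finite maximum")
    v / divisor
  }
  if (mode == "by-enhancement") {
    if (is.null(enhancement)) stop("enhancement values required")
    divisor <- max(enhancement, na.rm = TRUE)
    if (is.data.frame(values)) return(as.data.frame(lapply(values, norm1, divisor)))
    return(norm1(values, divisor))
  }
  if (is.data.frame(values))
    return(as.data.frame(lapply(values, function(v) norm1(v, max(v, na.rm = TRUE)))))
  norm1(values, max(values, na.rm = TRUE))
}
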