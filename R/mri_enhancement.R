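# Contrast-enhanced MRI quantification of BBB opening: peak-seeded ROIs in
# the sonicated hemisphere, mirrored contralateral ROIs, and the relative
# signal enhancement ratio between their mean intensities.
#
# Coordinates are 1-based (row, col) with origin at the top-left, matching
# R matrix indexing; the hemisphere midline is a column index.

#' A 2-D brain image with hemisphere geometry
#'
#' @param intensities Numeric matrix of signal intensities.
#' @param pixel_spacing Length-2 numeric, mm per pixel (row, col).
#' @param midline_col Column index of the sagittal midline (inside image).
#' @param sonicated_side `"left"` (columns < midline) or `"right"`.
#' @return An object of class `brain_image`.
#' @export
brain_image <- function(intensities, pixel_spacing = c(0.1, 0.1),
                        midline_col = (ncol(intensities) + 1) / 2,
                        sonicated_side = c("left", "right")) {
  if (!is.matrix(intensities) || !is.numeric(intensities))
    stop("intensities must be a numeric matrix")
  pixel_spacing <- rep_len(as.numeric(pixel_spacing), 2L)
  if (any(pixel_spacing <= 0)) stop("pixel spacing must be > 0")
  if (midline_col < 1 || midline_col > ncol(intensities))
    stop("midline outside image")
  structure(list(intensities = intensities,
                 pixel_spacing = pixel_spacing,
                 midline_col = as.numeric(midline_col),
                 sonicated_side = match.arg(sonicated_side)),
            class = "brain_image")
}

#' @export
print.brain_image <- function(x, ...) {
  cat(sprintf("<brain_image> %d x %d px @ %.3g x %.3g mm, midline col %.1f, sonicated %s\n",
              nrow(x$intensities), ncol(x$intensities),
              x$pixel_spacing[1], x$pixel_spacing[2], x$midline_col,
              x$sonicated_side))
  invisible(x)
}

#' Rectangular ROI centered on a pixel
#'
#' The ROI half-extent along each axis is `round(size_mm / 2 / spacing)`
#' pixels, so ROIs always have odd pixel dimensions centered on the peak;
#' at 0.1 mm spacing a 0.5 x 0.5 mm ROI covers exactly 5 x 5 pixels.
#'
#' @param center Length-2 integer `(row, col)` pixel center.
#' @param size_mm Length-2 numeric ROI size in mm (height, width); default
#'   0.5 x 0.5 mm.
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(center, size_mm = c(0.5, 0.5)) {
  center <- as.integer(round(center))
  size_mm <- rep_len(as.numeric(size_mm), 2L)
  stopifnot(length(center) == 2L, all(size_mm > 0))
  structure(list(center = center, size_mm = size_mm), class = "roi_spec")
}

roi_half_px <- function(roi, image) {
  as.integer(round(roi$size_mm / 2 / image$pixel_spacing))
}

roi_extent <- function(roi, image) {
  h <- roi_half_px(roi, image)
  list(rows = (roi$center[1] - h[1]):(roi$center[1] + h[1]),
       cols = (roi$center[2] - h[2]):(roi$center[2] + h[2]))
}

roi_in_image <- function(roi, image) {
  e <- roi_extent(roi, image)
  min(e$rows) >= 1 && max(e$rows) <= nrow(image$intensities) &&
    min(e$cols) >= 1 && max(e$cols) <= ncol(image$intensities)
}

roi_mean <- function(roi, image) {
  e <- roi_extent(roi, image)
  mean(image$intensities[e$rows, e$cols])
}

# Separable Gaussian smoothing with edge replication; sigma in pixels.
gaussian_smooth <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  conv1 <- function(v) {
    pad <- c(rep(v[1], r), v, rep(v[length(v)], r))
    stats::convolve(pad, rev(k), type = "filter")
  }
  t(apply(apply(mat, 2, conv1), 1, conv1))
}

sonicated_cols <- function(image) {
  if (image$sonicated_side == "left")
    seq_len(floor(image$midline_col - 1e-9))
  else seq(ceiling(image$midline_col + 1e-9), ncol(image$intensities))
}

#' Locate enhancement ROIs at intensity peaks in the sonicated hemisphere
#'
#' The image is Gaussian-smoothed (`smooth_sigma` pixels), and local maxima
#' (>= all 8 neighbours) are searched within the sonicated hemisphere,
#' restricted to centers whose ROI and mirrored ROI fit inside the image.
#' Candidates are ranked by smoothed intensity, ties broken by (row, col)
#' lexicographic order, and selected greedily subject to a minimum
#' separation between centers.  A constant image is not an error: the
#' tie-break makes the selection deterministic.
#'
#' @param post_image Post-contrast [brain_image()].
#' @param n_rois Number of ROIs to return (default 2).
#' @param roi_size_mm ROI size in mm (default 0.5 x 0.5).
#' @param smooth_sigma Smoothing sigma in pixels (default 1).
#' @param min_separation_mm Minimum distance between ROI centers (default 1 mm).
#' @return List of [roi_spec()] of length `n_rois` (fewer only if the
#'   hemisphere cannot hold that many separated peaks).
#' @export
find_enhancement_rois <- function(post_image, n_rois = 2L,
                                  roi_size_mm = c(0.5, 0.5),
                                  smooth_sigma = 1,
                                  min_separation_mm = 1) {
  stopifnot(inherits(post_image, "brain_image"), n_rois >= 1L)
  img <- post_image$intensities
  h <- as.integer(round(rep_len(roi_size_mm, 2L) / 2 / post_image$pixel_spacing))
  cols_hemi <- sonicated_cols(post_image)
  if (length(cols_hemi) < 2 * h[2] + 1 || nrow(img) < 2 * h[1] + 1)
    stop_bbb("mri", "sonicated hemisphere smaller than the ROI")

  sm <- gaussian_smooth(img, smooth_sigma)
  rows_ok <- (1 + h[1]):(nrow(img) - h[1])
  cols_ok <- intersect(cols_hemi, (1 + h[2]):(ncol(img) - h[2]))
  # mirrored center must also fit
  cols_ok <- cols_ok[vapply(cols_ok, function(cc) {
    mc <- round(2 * post_image$midline_col - cc)
    mc - h[2] >= 1 && mc + h[2] <= ncol(img)
  }, logical(1))]
  if (!length(cols_ok) || !length(rows_ok))
    stop_bbb("mri", "no admissible ROI centers in the sonicated hemisphere")

  is_peak <- function(r, cc) {
    v <- sm[r, cc]
    nb <- sm[max(1, r - 1):min(nrow(sm), r + 1),
             max(1, cc - 1):min(ncol(sm), cc + 1)]
    v >= max(nb)
  }
  cand <- expand.grid(row = rows_ok, col = cols_ok)
  keep <- mapply(is_peak, cand$row, cand$col)
  cand <- cand[keep, , drop = FALSE]
  if (!nrow(cand))  # plateau inside a slope: fall back to the global max
    cand <- expand.grid(row = rows_ok, col = cols_ok)
  vals <- sm[cbind(cand$row, cand$col)]
  ord <- order(-vals, cand$row, cand$col)
  cand <- cand[ord, , drop = FALSE]

  sp <- post_image$pixel_spacing
  sel <- list()
  for (i in seq_len(nrow(cand))) {
    p <- c(cand$row[i], cand$col[i])
    far <- all(vapply(sel, function(q)
      sqrt(sum(((p - q$center) * sp)^2)) >= min_separation_mm, logical(1)))
    if (far) sel[[length(sel) + 1L]] <- roi_spec(p, rep_len(roi_size_mm, 2L))
    if (length(sel) == n_rois) break
  }
  sel
}

#' Mirror an ROI across the hemisphere midline
#'
#' The mirrored center column is `2 * midline_col - col`; size is
#' preserved.  The reflection is an involution: mirroring twice returns the
#' original ROI.
#'
#' @param roi [roi_spec()] inside the sonicated hemisphere.
#' @param image [brain_image()] providing midline and bounds.
#' @return The mirrored [roi_spec()].
#' @export
mirror_roi <- function(roi, image) {
  stopifnot(inherits(roi, "roi_spec"), inherits(image, "brain_image"))
  m <- roi_spec(c(roi$center[1], round(2 * image$midline_col - roi$center[2])),
                roi$size_mm)
  if (!roi_in_image(m, image))
    stop_bbb("mri", "mirrored ROI falls outside the image")
  m
}

#' Relative signal enhancement of an ROI
#'
#' Ratio of the mean intensity inside the ROI (sonicated hemisphere) to the
#' mean intensity inside the mirrored contralateral ROI.  The ratio is
#' invariant under global intensity scaling.
#'
#' @param post_image Post-contrast [brain_image()].
#' @param roi [roi_spec()] in the sonicated hemisphere.
#' @return An object of class `enhancement_result` with `roi`,
#'   `mirrored_roi`, `mean_sonicated`, `mean_contralateral`, and `ratio`.
#' @export
relative_enhancement <- function(post_image, roi) {
  stopifnot(inherits(post_image, "brain_image"), inherits(roi, "roi_spec"))
  if (!roi_in_image(roi, post_image))
    stop_bbb("mri", "ROI falls outside the image")
  mir <- mirror_roi(roi, post_image)
  ms <- roi_mean(roi, post_image)
  mc <- roi_mean(mir, post_image)
  if (!is.finite(mc) || mc <= 0)
    stop_bbb("mri", "contralateral mean intensity is not positive; ",
             "ratio undefined")
  structure(list(roi = roi, mirrored_roi = mir,
                 mean_sonicated = ms, mean_contralateral = mc,
                 ratio = ms / mc),
            class = "enhancement_result")
}

#' @export
print.enhancement_result <- function(x, ...) {
  cat(sprintf("<enhancement_result> ratio %.4f (%.2f / %.2f), ROI at (%d, %d)\n",
              x$ratio, x$mean_sonicated, x$mean_contralateral,
              x$roi$center[1], x$roi$center[2]))
  invisible(x)
}

#' Call BBB opening from an enhancement ratio
#'
#' Declares BBB opening when the relative enhancement ratio meets or
#' exceeds a threshold.  The threshold is a package convention (default
#' 1.10), not a community standard; the boundary is inclusive.
#'
#' @param result An [relative_enhancement()] result, or a bare ratio.
#' @param threshold Ratio threshold (> 1; default 1.10).
#' @return Logical: opening called?
#' @export
call_bbb_opening <- function(result, threshold = 1.10) {
  if (!is.numeric(threshold) || threshold <= 1)
    stop("threshold must be > 1")
  ratio <- if (inherits(result, "enhancement_result")) result$ratio else result
  ratio >= threshold
}
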