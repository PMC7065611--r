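#' Binary stain mask
#'
#' Per-pixel stain/background partition; every pixel is classified.
#'
#' @param mask Logical matrix, `TRUE` = stain.
#' @param source Free-text provenance (method + channel).
#' @return An object of class `stain_mask`.
#' @export
stain_mask <- function(mask, source = "") {
  if (!is.matrix(mask) || !is.logical(mask) || anyNA(mask)) {
    stop("mask must be a logical matrix with no missing values",
         call. = FALSE)
  }
  structure(list(mask = mask, source = source), class = "stain_mask")
}

#' @export
print.stain_mask <- function(x, ...) {
  cat(sprintf("stain mask: %d / %d px flagged (%s)\n",
              sum(x$mask), length(x$mask), x$source))
  invisible(x)
}

as_frame_matrix <- function(frame) {
  if (is.list(frame) && !is.null(frame$frame)) frame$frame else frame
}

#' Absolute-intensity threshold map
#'
#' Flags pixels whose intensity strictly exceeds the threshold as candidate
#' stain ("orange"); everything at or below is background ("black"). A pixel
#' exactly at the threshold is background. Fluorescent soil is brighter than
#' background in its emission channel, so the stain polarity is
#' above-threshold.
#'
#' @param frame Numeric matrix in \[0, 1\], or a [select_channel()] result.
#' @param threshold Intensity threshold in \[0, 1\]; the worked armrest
#'   example uses 0.35.
#' @return A [stain_mask()].
#' @export
threshold_map <- function(frame, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold < 0 || threshold > 1) {
    stop("parameter error: threshold must be a single value in [0, 1]",
         call. = FALSE)
  }
  m <- as_frame_matrix(frame)
  src <- sprintf("threshold_map > %g", threshold)
  if (is.list(frame) && !is.null(frame$meta)) {
    src <- sprintf("%s on %s/%g nm", src, frame$meta$light,
                   frame$meta$filter_nm)
  }
  stain_mask(m > threshold, source = src)
}

#' Dirty-vs-clean differential stain map
#'
#' Flags pixels above threshold in the dirty frame but not in the clean frame
#' of the same channel: `threshold_map(dirty) AND NOT threshold_map(clean)`.
#' Bright fixed features of the surface itself, above threshold in both
#' images, are thereby excluded; only soil removed by cleaning remains.
#'
#' @param dirty_frame,clean_frame Matrices or [select_channel()] results of
#'   the same channel and dimensions.
#' @param threshold Intensity threshold in \[0, 1\].
#' @return A [stain_mask()].
#' @export
differential_mask <- function(dirty_frame, clean_frame, threshold) {
  md <- if (is.list(dirty_frame)) dirty_frame$meta else NULL
  mc <- if (is.list(clean_frame)) clean_frame$meta else NULL
  if (!is.null(md) && !is.null(mc) &&
      !(md$light == mc$light && md$filter_nm == mc$filter_nm &&
        md$i_rel == mc$i_rel)) {
    stop("comparison error: dirty and clean frames are different channels",
         call. = FALSE)
  }
  d <- as_frame_matrix(dirty_frame)
  c_ <- as_frame_matrix(clean_frame)
  if (!all(dim(d) == dim(c_))) {
    stop("comparison error: dirty and clean frames differ in size",
         call. = FALSE)
  }
  td <- threshold_map(d, threshold)
  tc <- threshold_map(c_, threshold)
  src <- sprintf("differential_mask > %g", threshold)
  if (!is.null(md)) src <- sprintf("%s on %s/%g nm", src, md$light,
                                   md$filter_nm)
  stain_mask(td$mask & !tc$mask, source = src)
}

#' Summarize a stain mask
#'
#' @param mask A [stain_mask()] or logical matrix.
#' @param pixel_scale mm/px, for the area conversion.
#' @return List with `pixel_count`, `area_mm2` (= count x scale^2) and
#'   `bbox` (`x0, y0, width, height` in px, 0-based; `NULL` when empty).
#' @export
mask_summary <- function(mask, pixel_scale = 0.05) {
  m <- if (inherits(mask, "stain_mask")) mask$mask else mask
  n <- sum(m)
  bbox <- NULL
  if (n > 0) {
    idx <- which(m, arr.ind = TRUE)
    bbox <- list(x0 = min(idx[, 2]) - 1L, y0 = min(idx[, 1]) - 1L,
                 width = diff(range(idx[, 2])) + 1L,
                 height = diff(range(idx[, 1])) + 1L)
  }
  list(pixel_count = n, area_mm2 = n * pixel_scale^2, bbox = bbox)
}

#' Jaccard index between two masks
#'
#' |A intersect B| / |A union B|; the recovery metric between a detected and
#' a planted stain mask. Two empty masks score 1.
#'
#' @param a,b [stain_mask()]s or logical matrices of identical size.
#' @return Numeric in \[0, 1\].
#' @export
jaccard <- function(a, b) {
  ma <- if (inherits(a, "stain_mask")) a$mask else a
  mb <- if (inherits(b, "stain_mask")) b$mask else b
  stopifnot(all(dim(ma) == dim(mb)))
  un <- sum(ma | mb)
  if (un == 0) return(1)
  sum(ma & mb) / un
}
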