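#' Registered multispectral image stack
#'
#' A cube of co-registered single-channel frames plus channel metadata.
#' Intensities live in \[0, 1\]; 8-bit files are mapped by v/255 on read (an
#' absolute scale, not per-image min-max, so one intensity threshold is
#' comparable across images and channels).
#'
#' @param frames List of numeric matrices, identical dimensions, values in
#'   \[0, 1\].
#' @param channel_meta Data frame with columns `light`, `light_nm`, `i_rel`,
#'   `filter_nm`, one row per frame; (light, i_rel, filter_nm) must be unique.
#' @return An object of class `image_stack` with `frames`, `channel_meta`,
#'   `height`, `width`.
#' @export
image_stack <- function(frames, channel_meta) {
  if (!is.list(frames) || length(frames) == 0) {
    stop("frames must be a non-empty list of matrices", call. = FALSE)
  }
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("format error: frames do not share identical dimensions",
         call. = FALSE)
  }
  if (nrow(channel_meta) != length(frames)) {
    stop("channel_meta must have one row per frame", call. = FALSE)
  }
  needed <- c("light", "light_nm", "i_rel", "filter_nm")
  if (!all(needed %in% names(channel_meta))) {
    stop("channel_meta needs columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(channel_meta[, c("light", "i_rel", "filter_nm")])) {
    stop("manifest error: duplicate (light, i_rel, filter_nm) channel",
         call. = FALSE)
  }
  structure(
    list(frames = frames,
         channel_meta = as.data.frame(channel_meta, row.names = NULL),
         height = dims[1, 1], width = dims[2, 1]),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  cat(sprintf("image stack: %d channels, %d x %d px\n",
              length(x$frames), x$width, x$height))
  invisible(x)
}

#' Number of channels in a stack
#' @param stack An [image_stack()].
#' @return Integer channel count.
#' @export
n_channels <- function(stack) length(stack$frames)

#' Write a stack as per-channel 8-bit grayscale PNGs plus a TSV manifest
#'
#' Files are named `<light>_<Irel>_<filterNm>.png`; the manifest
#' (`manifest.tsv`) lists filename, light, center_nm, I_rel, filter_nm in
#' channel order. Intensities are quantized to 8 bits on write.
#'
#' @param stack An [image_stack()].
#' @param dir Output directory (created if needed).
#' @return Path of the written manifest, invisibly.
#' @export
write_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "image_stack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- stack$channel_meta
  fnames <- sprintf("%s_%d_%d.png", meta$light, meta$i_rel, meta$filter_nm)
  for (i in seq_along(stack$frames)) {
    png::writePNG(stack$frames[[i]], file.path(dir, fnames[i]))
  }
  manifest <- data.frame(filename = fnames, light = meta$light,
                         center_nm = meta$light_nm, I_rel = meta$i_rel,
                         filter_nm = meta$filter_nm)
  path <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a stack from its TSV manifest
#'
#' Loads frames in manifest order. 8-bit PNGs map to \[0, 1\] by v/255 and
#' 16-bit by v/65535. Unknown manifest columns are ignored with a warning;
#' missing files, mismatched dimensions and duplicate channels are errors.
#'
#' @param manifest_path Path to a `manifest.tsv` written by [write_stack()].
#' @return An [image_stack()].
#' @export
read_stack <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    stop("I/O error: manifest not found: ", manifest_path, call. = FALSE)
  }
  man <- utils::read.table(manifest_path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  needed <- c("filename", "light", "center_nm", "I_rel", "filter_nm")
  if (!all(needed %in% names(man))) {
    stop("manifest error: missing columns ",
         paste(setdiff(needed, names(man)), collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(man), needed)
  if (length(extra)) {
    warning("ignoring unknown manifest columns: ",
            paste(extra, collapse = ", "), call. = FALSE)
  }
  dir <- dirname(manifest_path)
  frames <- lapply(man$filename, function(f) {
    path <- file.path(dir, f)
    if (!file.exists(path)) {
      stop("I/O error: missing image file: ", path, call. = FALSE)
    }
    img <- png::readPNG(path)
    if (length(dim(img)) == 3) img <- img[, , 1]  # collapse gray-encoded RGB
    img
  })
  meta <- data.frame(light = man$light, light_nm = man$center_nm,
                     i_rel = man$I_rel, filter_nm = man$filter_nm)
  image_stack(frames, meta)
}

#' Rectangular pixel region
#'
#' 0-based, x rightward, y downward; `(x0, y0)` inclusive top-left, extent
#' half-open, so the region covers columns `x0 .. x0+width-1`.
#'
#' @param x0,y0 Top-left corner, px.
#' @param width,height Extent, px; positive.
#' @return An object of class `px_region`.
#' @export
px_region <- function(x0, y0, width, height) {
  if (x0 < 0 || y0 < 0 || width <= 0 || height <= 0) {
    stop("geometry error: region must have non-negative origin and positive extent",
         call. = FALSE)
  }
  structure(list(x0 = as.integer(x0), y0 = as.integer(y0),
                 width = as.integer(width), height = as.integer(height)),
            class = "px_region")
}

check_region_inside <- function(region, height, width) {
  if (region$x0 + region$width > width || region$y0 + region$height > height) {
    stop(sprintf("geometry error: region (%d,%d)+%dx%d exceeds %d x %d frame",
                 region$x0, region$y0, region$width, region$height,
                 width, height), call. = FALSE)
  }
}

#' Crop every frame of a stack to a region
#'
#' @param stack An [image_stack()].
#' @param region A [px_region()] fully inside the frame.
#' @return The cropped [image_stack()]; channel metadata unchanged.
#' @export
crop <- function(stack, region) {
  stopifnot(inherits(stack, "image_stack"), inherits(region, "px_region"))
  check_region_inside(region, stack$height, stack$width)
  rows <- region$y0 + seq_len(region$height)
  cols <- region$x0 + seq_len(region$width)
  image_stack(lapply(stack$frames, function(f) f[rows, cols, drop = FALSE]),
              stack$channel_meta)
}

#' Extract the single frame matching a light / filter condition
#'
#' @param stack An [image_stack()].
#' @param light Light name.
#' @param filter_nm Filter center, nm.
#' @return List with `frame` (matrix) and `meta` (one-row data frame).
#' @export
select_channel <- function(stack, light, filter_nm) {
  meta <- stack$channel_meta
  hit <- which(meta$light == light & meta$filter_nm == filter_nm)
  if (length(hit) != 1) {
    stop(sprintf("lookup error: %d channels match (%s, %g nm)",
                 length(hit), light, filter_nm), call. = FALSE)
  }
  list(frame = stack$frames[[hit]], meta = meta[hit, , drop = FALSE])
}

#' Write / read a binary mask as a 0/255 PNG
#' @param mask A [stain_mask()] or logical matrix.
#' @param path PNG path.
#' @return `path` invisibly (write); a `stain_mask` (read).
#' @export
write_mask <- function(mask, path) {
  m <- if (inherits(mask, "stain_mask")) mask$mask else mask
  png::writePNG(matrix(as.numeric(m), nrow(m), ncol(m)), path)
  invisible(path)
}

#' @rdname write_mask
#' @param source Provenance string for the mask read back.
#' @export
read_mask <- function(path, source = path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  stain_mask(img > 0.5, source = source)
}
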