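#' 2-D grayscale image with physical pixel size and validity mask
#'
#' The basic raster container used throughout the package. `pixels` holds
#' non-negative intensities (8-bit scale for fundus images, micrometres for
#' rasterized thickness maps). `valid_mask` marks pixels inside the original
#' scanned region; pixels introduced by resampling padding are flagged
#' invalid and are excluded from histograms, correlations and sector means.
#'
#' @param pixels numeric matrix of non-negative intensities (rows = y,
#'   columns = x; y increases downward).
#' @param pixel_size_mm physical size of one pixel in mm. The canonical
#'   working frame is 512 x 512 pixels over a 3 x 3 mm field of view,
#'   i.e. `3/512` mm per pixel (the default scales with the matrix width).
#' @param valid_mask logical matrix of the same shape; `NULL` means all
#'   pixels are valid.
#' @return an object of class `image2d`.
#' @export
image2d <- function(pixels, pixel_size_mm = 3 / ncol(pixels), valid_mask = NULL) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) {
    stop("image must have positive dimensions", call. = FALSE)
  }
  if (!is.numeric(pixel_size_mm) || pixel_size_mm <= 0) {
    stop("`pixel_size_mm` must be > 0", call. = FALSE)
  }
  if (is.null(valid_mask)) {
    valid_mask <- matrix(TRUE, nrow(pixels), ncol(pixels))
  }
  valid_mask <- as.matrix(valid_mask)
  storage.mode(valid_mask) <- "logical"
  if (!all(dim(valid_mask) == dim(pixels))) {
    stop("`valid_mask` must have the same shape as `pixels`", call. = FALSE)
  }
  structure(list(pixels = pixels, pixel_size_mm = pixel_size_mm,
                 valid_mask = valid_mask),
            class = "image2d")
}

#' @export
print.image2d <- function(x, ...) {
  cat(sprintf("<image2d %d x %d, %.4f mm/px, %.1f%% valid>\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_mm,
              100 * mean(x$valid_mask)))
  invisible(x)
}

#' Binary blood-vessel mask aligned to an image frame
#'
#' @param mask matrix with values in \{0, 1\} (logical accepted).
#' @param pixel_size_mm physical pixel size of the frame the mask lives in.
#' @param valid_mask optional validity mask (same semantics as [image2d()]).
#' @return an object of class `vessel_mask`.
#' @export
vessel_mask <- function(mask, pixel_size_mm = 3 / ncol(mask), valid_mask = NULL) {
  mask <- as.matrix(mask)
  if (is.logical(mask)) storage.mode(mask) <- "double"
  if (!all(mask %in% c(0, 1))) {
    stop("vessel mask values must be 0 or 1", call. = FALSE)
  }
  img <- image2d(mask, pixel_size_mm, valid_mask)
  structure(list(mask = img$pixels, pixel_size_mm = img$pixel_size_mm,
                 valid_mask = img$valid_mask),
            class = "vessel_mask")
}

#' @export
print.vessel_mask <- function(x, ...) {
  cat(sprintf("<vessel_mask %d x %d, vessel fraction %.2f%%>\n",
              nrow(x$mask), ncol(x$mask), 100 * mean(x$mask)))
  invisible(x)
}

#' Common overlapped scanning region of a reference and transformed targets
#'
#' The overlap mask is true exactly where the reference is valid and every
#' transformed target is valid. All precision/recall counts and co-aligned
#' feature means are restricted to this region.
#'
#' @param reference `image2d` or `vessel_mask` in the reference frame.
#' @param targets a single transformed image/mask or a list of them, all in
#'   the reference frame (i.e. already warped).
#' @return an object of class `overlap_mask` with fields `mask` (logical
#'   matrix) and `empty` (flag set when no pixel survives; a warning is
#'   emitted rather than an error).
#' @export
overlap_region <- function(reference, targets) {
  if (inherits(targets, c("image2d", "vessel_mask"))) targets <- list(targets)
  m <- reference$valid_mask
  for (tg in targets) {
    if (!all(dim(tg$valid_mask) == dim(m))) {
      stop("all frames must share one shape", call. = FALSE)
    }
    m <- m & tg$valid_mask
  }
  empty <- !any(m)
  if (empty) warning("overlap region is empty", call. = FALSE)
  structure(list(mask = m, empty = empty), class = "overlap_mask")
}

#' Read / write 8-bit grayscale PNG rasters
#'
#' Vessel masks are stored strictly as \{0, 255\} on disk and mapped to
#' \{0, 1\} in memory.
#'
#' @param path file path.
#' @param pixel_size_mm physical pixel size to attach on read.
#' @name png_io
NULL

#' @rdname png_io
#' @export
read_image_png <- function(path, pixel_size_mm = NULL) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 3L) arr <- arr[, , 1L]
  px <- arr * 255
  image2d(px, pixel_size_mm %||% (3 / ncol(px)))
}

#' @rdname png_io
#' @param image an `image2d` (intensities on the 8-bit scale).
#' @export
write_image_png <- function(image, path) {
  png::writePNG(pmin(pmax(image$pixels / 255, 0), 1), path)
  invisible(path)
}

#' @rdname png_io
#' @export
read_vessel_mask_png <- function(path, pixel_size_mm = NULL) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 3L) arr <- arr[, , 1L]
  v <- round(arr * 255)
  if (!all(v %in% c(0, 255))) {
    stop("vessel mask PNG must contain only 0 and 255", call. = FALSE)
  }
  vessel_mask(v / 255, pixel_size_mm %||% (3 / ncol(v)))
}

#' @rdname png_io
#' @param mask a `vessel_mask`.
#' @export
write_vessel_mask_png <- function(mask, path) {
  png::writePNG(mask$mask, path)
  invisible(path)
}
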