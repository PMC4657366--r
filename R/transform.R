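#' Similarity transform (translation, rotation, isotropic scale)
#'
#' The linear transformation model used by both registration algorithms:
#' scaling about the image center, then rotation about the image center,
#' then translation. Rotation is in degrees, positive counter-clockwise as
#' displayed (y increases downward in the raster). The identity is
#' `(0, 0, 0, 1)`.
#'
#' @param tx_px,ty_px translation in pixels (x = columns rightward,
#'   y = rows downward).
#' @param rotation_deg rotation in degrees, counter-clockwise as displayed.
#' @param scale isotropic scale factor, must be positive.
#' @return an object of class `similarity_transform`.
#' @export
similarity_transform <- function(tx_px = 0, ty_px = 0, rotation_deg = 0, scale = 1) {
  if (!is.numeric(scale) || length(scale) != 1L || is.na(scale) || scale <= 0) {
    stop_octlongreg("`scale` must be a positive number",
                    "octlongreg_invalid_transform")
  }
  structure(list(tx_px = as.double(tx_px), ty_px = as.double(ty_px),
                 rotation_deg = as.double(rotation_deg),
                 scale = as.double(scale)),
            class = "similarity_transform")
}

#' @export
print.similarity_transform <- function(x, ...) {
  cat(sprintf("<similarity_transform t=(%.3f, %.3f) px, rot=%.3f deg, scale=%.4f>\n",
              x$tx_px, x$ty_px, x$rotation_deg, x$scale))
  invisible(x)
}

# 2x2 rotation matrix for our convention (y down, positive angle CCW on
# screen): R(theta) = [[cos, sin], [-sin, cos]] acting on (dx, dy).
.rot_mat <- function(theta_deg) {
  th <- theta_deg * pi / 180
  matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
}

#' Compose two similarity transforms
#'
#' `compose_transforms(outer, inner)` is the transform that acts like
#' applying `inner` first and `outer` second:
#' `apply_transform(img, compose_transforms(o, i))` equals
#' `apply_transform(apply_transform(img, i), o)` up to one resampling error.
#' Used to report a single final transform for a coarse + fine registration.
#'
#' @param outer,inner `similarity_transform` objects.
#' @return a `similarity_transform`.
#' @export
compose_transforms <- function(outer, inner) {
  R <- .rot_mat(outer$rotation_deg)
  t_new <- outer$scale * (R %*% c(inner$tx_px, inner$ty_px)) +
    c(outer$tx_px, outer$ty_px)
  similarity_transform(t_new[1], t_new[2],
                       outer$rotation_deg + inner$rotation_deg,
                       outer$scale * inner$scale)
}

#' Invert a similarity transform
#'
#' @param t a `similarity_transform`.
#' @return the transform `u` with `compose_transforms(u, t)` equal to the
#'   identity (exactly, in the transform algebra).
#' @export
invert_transform <- function(t) {
  Rinv <- .rot_mat(-t$rotation_deg)
  tt <- -(Rinv %*% c(t$tx_px, t$ty_px)) / t$scale
  similarity_transform(tt[1], tt[2], -t$rotation_deg, 1 / t$scale)
}

#' Forward-map points through a similarity transform
#'
#' @param t a `similarity_transform`.
#' @param xy n x 2 matrix of 0-based pixel-center coordinates (x, y).
#' @param dim frame dimensions `c(nrow, ncol)` defining the rotation/scale
#'   center `((ncol-1)/2, (nrow-1)/2)`.
#' @return n x 2 matrix of mapped coordinates.
#' @export
transform_points <- function(t, xy, dim) {
  xy <- matrix(as.double(xy), ncol = 2)
  ctr <- c((dim[2] - 1) / 2, (dim[1] - 1) / 2)
  d <- sweep(xy, 2, ctr)
  R <- .rot_mat(t$rotation_deg)
  out <- t$scale * t(R %*% t(d))
  sweep(out, 2, ctr + c(t$tx_px, t$ty_px), `+`)
}

#' Resample an image or vessel mask under a similarity transform
#'
#' The reference frame is held fixed; the output raster has the same shape
#' and pixel size as the input, with geometry: scale about the image center,
#' then rotate about the center, then translate. The validity mask is
#' transported along (nearest-neighbour), so pixels that fall outside the
#' source — or, for bilinear interpolation, pixels whose 2 x 2 support
#' touches an invalid source pixel — are zero-filled and flagged invalid.
#'
#' @param x an `image2d` or `vessel_mask`. Vessel masks are always warped
#'   with nearest-neighbour interpolation so values stay binary.
#' @param t a `similarity_transform`.
#' @param interpolation `"bilinear"` (default for images) or `"nearest"`.
#' @return an object of the same class as `x`.
#' @export
apply_transform <- function(x, t, interpolation = c("bilinear", "nearest")) {
  UseMethod("apply_transform")
}

#' @export
apply_transform.image2d <- function(x, t, interpolation = c("bilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  if (!inherits(t, "similarity_transform")) {
    stop_octlongreg("`t` must be a similarity_transform",
                    "octlongreg_invalid_transform")
  }
  w <- cpp_warp_similarity(x$pixels, x$valid_mask, t$tx_px, t$ty_px,
                           t$rotation_deg * pi / 180, t$scale,
                           interpolation == "bilinear")
  image2d(w$pixels, x$pixel_size_mm, w$valid)
}

#' @export
apply_transform.vessel_mask <- function(x, t, interpolation = "nearest") {
  if (!identical(interpolation, "nearest")) {
    stop("vessel masks must use nearest-neighbour interpolation", call. = FALSE)
  }
  w <- cpp_warp_similarity(x$mask, x$valid_mask, t$tx_px, t$ty_px,
                           t$rotation_deg * pi / 180, t$scale, FALSE)
  vessel_mask(w$pixels, x$pixel_size_mm, w$valid)
}

#' Serialize / deserialize a transform as a JSON record
#'
#' The on-disk format is a flat object
#' `{"tx_px": ..., "ty_px": ..., "rotation_deg": ..., "scale": ...}`.
#'
#' @param t a `similarity_transform`.
#' @param path file path.
#' @name transform_json
#' @export
write_transform_json <- function(t, path) {
  jsonlite::write_json(unclass(t), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname transform_json
#' @export
read_transform_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  similarity_transform(x$tx_px, x$ty_px, x$rotation_deg, x$scale)
}
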