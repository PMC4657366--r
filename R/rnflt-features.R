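#' Rasterize a polar RNFLT map onto a Cartesian annulus
#'
#' Bridges the polar thickness grid to the Cartesian similarity transforms:
#' every pixel inside the scanned annulus takes the thickness of its
#' nearest polar sample; pixels outside the annulus are invalid. Pixel
#' values are micrometres.
#'
#' @param map an `rnflt_map`.
#' @param size output frame side length in pixels.
#' @param pixel_size_mm pixel size; the default places the 3 mm field of
#'   view across the frame so the annulus fits with margin.
#' @return an `image2d` whose `valid_mask` is the annulus.
#' @export
rasterize_map <- function(map, size = 512, pixel_size_mm = 3 / size) {
  r_in <- map$ring_radius_mm[1]
  r_out <- map$ring_radius_mm[length(map$ring_radius_mm)]
  n_rings <- nrow(map$thickness_um)
  n_ascans <- ncol(map$thickness_um)
  ctr <- (size - 1) / 2
  xs <- ((0:(size - 1)) - ctr) * pixel_size_mm
  X <- matrix(xs, size, size, byrow = TRUE)
  Y <- matrix(xs, size, size)
  r <- sqrt(X^2 + Y^2)
  inside <- r >= r_in & r <= r_out
  px <- matrix(0, size, size)
  ring <- pmin(pmax(round((r[inside] - r_in) / (r_out - r_in) * (n_rings - 1)),
                    0), n_rings - 1)
  psi <- atan2(-Y[inside], X[inside]) * 180 / pi
  phi <- .psi_to_phi(psi, map$laterality)
  col <- round((phi - map$theta0_deg) / (360 / n_ascans)) %% n_ascans
  px[inside] <- map$thickness_um[cbind(ring + 1, col + 1)]
  image2d(px, pixel_size_mm, inside)
}

#' Resample a thickness raster back to the polar grid
#'
#' Inverse of [rasterize_map()] (nearest pixel); mainly a resampling audit
#' tool.
#'
#' @param raster an `image2d` from [rasterize_map()].
#' @param laterality,theta0_deg orientation of the output map.
#' @param n_rings,n_ascans polar grid size.
#' @return an `rnflt_map`.
#' @export
polar_resample <- function(raster, laterality = "OD", theta0_deg = 0,
                           n_rings = 100, n_ascans = 100) {
  size <- nrow(raster$pixels)
  ctr <- (size - 1) / 2
  radii <- seq(0.75, 1.5, length.out = n_rings)
  phi <- (theta0_deg + (0:(n_ascans - 1)) * 360 / n_ascans) %% 360
  psi <- if (laterality == "OD") (180 - phi) %% 360 else phi
  r_px <- radii / raster$pixel_size_mm
  # pull boundary rings 0.75 px inside the annulus so the rounded pixel
  # cannot fall on an out-of-annulus (zero-filled) neighbour
  r_px <- pmin(pmax(r_px, r_px[1] + 0.75), r_px[length(r_px)] - 0.75)
  X <- pmin(pmax(round(ctr + outer(r_px, cos(psi * pi / 180))), 0), size - 1)
  Y <- pmin(pmax(round(ctr + outer(r_px, -sin(psi * pi / 180))), 0), size - 1)
  th <- matrix(raster$pixels[cbind(as.vector(Y) + 1, as.vector(X) + 1)],
               n_rings, n_ascans)
  rnflt_map(pmax(th, 1), laterality, theta0_deg, radii)
}

#' Co-align rasterized RNFLT maps and compute their common overlap
#'
#' Each session's thickness raster is warped into the reference frame by
#' its session transform (the correction estimated by registering the
#' session's fundus/vessel image), and the common overlap region — pixels
#' valid in every aligned raster — is returned for feature computation.
#'
#' @param maps list of `rnflt_map` objects.
#' @param transforms list of `similarity_transform` corrections, one per map.
#' @param size,pixel_size_mm raster geometry (see [rasterize_map()]).
#' @return list with `rasters` (aligned `image2d`s) and `overlap`
#'   (`overlap_mask`). An empty common overlap is an error naming the
#'   session that removed the most pixels.
#' @export
align_maps <- function(maps, transforms, size = 512, pixel_size_mm = 3 / size) {
  stopifnot(length(maps) == length(transforms))
  rasters <- vector("list", length(maps))
  for (i in seq_along(maps)) {
    r <- rasterize_map(maps[[i]], size, pixel_size_mm)
    rasters[[i]] <- apply_transform(r, transforms[[i]], "bilinear")
  }
  ov <- suppressWarnings(overlap_region(rasters[[1]], rasters[-1]))
  if (ov$empty) {
    worst <- which.min(vapply(rasters, function(r) sum(r$valid_mask), 0))
    stop_octlongreg(
      sprintf("empty common overlap; session %d retains the fewest valid pixels (%d)",
              worst, sum(rasters[[worst]]$valid_mask)),
      "octlongreg_empty_overlap")
  }
  list(rasters = rasters, overlap = ov)
}

.feature_names <- c("all_rings", "temporal", "superior", "nasal", "inferior",
                    sprintf("hour_%02d", 1:12))

# Per-pixel sector assignment for a raster frame. Angles psi are measured
# CCW from screen right (y up); in OD presentation nasal sits at psi = 0,
# superior at 90, temporal at 180, inferior at 270, and clock hour h is the
# 30-degree sector centered at psi = 90 - 30 h (hour 12 superior, hours
# increasing clockwise). OS rasters are mirrored about the vertical axis
# before assignment so labels follow the OD convention.
.sector_index <- function(size, pixel_size_mm, laterality) {
  ctr <- (size - 1) / 2
  xs <- (0:(size - 1)) - ctr
  X <- matrix(xs, size, size, byrow = TRUE)
  if (laterality == "OS") X <- -X
  Y <- matrix(xs, size, size)
  psi <- atan2(-Y, X) * 180 / pi
  quadrant <- floor(((psi + 45) %% 360) / 90) + 1  # 1=N 2=S 3=T 4=I
  hour <- ((floor((90 - psi) / 30 + 0.5) - 1) %% 12) + 1
  list(quadrant = quadrant, hour = hour)
}

#' Compute the 17 RNFLT feature parameters
#'
#' All-rings average (mean over all valid annulus pixels), the four TSNI
#' quadrant averages (90-degree sectors centered on the temporal, superior,
#' nasal and inferior meridians), and the twelve 30-degree clock-hour
#' averages in the right-eye (OD) clockwise convention, hour 12 centered on
#' the superior meridian. Left-eye (OS) rasters are mirrored before sector
#' assignment. A sector with no valid pixels yields a flagged `NA`.
#'
#' @param raster an `image2d` holding thickness values on the annulus
#'   (e.g. from [rasterize_map()] or [align_maps()]).
#' @param mask optional `overlap_mask` (or logical matrix) restricting the
#'   computation, intersected with the raster's validity mask.
#' @param laterality `"OD"` or `"OS"`.
#' @return an object of class `rnflt_features`: list with `values` (named
#'   17-vector, micrometres) and `n` (valid sample count per feature).
#' @export
compute_features <- function(raster, mask = NULL, laterality = "OD") {
  m <- .resolve_mask(raster, mask)
  if (!any(m)) {
    stop_octlongreg("no valid pixels for feature computation",
                    "octlongreg_degenerate_input")
  }
  size <- nrow(raster$pixels)
  sec <- .sector_index(size, raster$pixel_size_mm, laterality)
  v <- raster$pixels[m]
  quad <- sec$quadrant[m]
  hour <- sec$hour[m]
  vals <- c(all_rings = mean(v),
            temporal = NA_real_, superior = NA_real_, nasal = NA_real_,
            inferior = NA_real_,
            stats::setNames(rep(NA_real_, 12), sprintf("hour_%02d", 1:12)))
  ns <- stats::setNames(c(length(v), rep(0L, 16)), .feature_names)
  qmap <- c(nasal = 1, superior = 2, temporal = 3, inferior = 4)
  for (qn in names(qmap)) {
    sel <- quad == qmap[[qn]]
    ns[qn] <- sum(sel)
    if (ns[qn] > 0) vals[qn] <- mean(v[sel])
  }
  for (h in 1:12) {
    nm <- sprintf("hour_%02d", h)
    sel <- hour == h
    ns[nm] <- sum(sel)
    if (ns[nm] > 0) vals[nm] <- mean(v[sel])
  }
  structure(list(values = vals, n = ns), class = "rnflt_features")
}

#' @export
print.rnflt_features <- function(x, ...) {
  cat("<rnflt_features (um)>\n")
  print(round(x$values, 2))
  invisible(x)
}

#' Feature series before and after registration
#'
#' The unregistered branch computes the 17 features per session on each
#' full annulus; the registered branch first co-aligns all of a subject's
#' rasters with the supplied corrections and computes features on the
#' subject's common overlap region.
#'
#' @param records a `session_series`.
#' @param transforms optional list parallel to `records` of
#'   `similarity_transform` corrections (identity for reference sessions);
#'   `NULL` computes the unregistered branch only.
#' @param size,pixel_size_mm raster geometry for feature computation.
#' @return long-format data frame with columns `subject`, `day`, `feature`,
#'   `value`, `registered`, `n_valid`.
#' @export
feature_series <- function(records, transforms = NULL, size = 256,
                           pixel_size_mm = 3 / size) {
  subj <- vapply(records, `[[`, "", "subject_id")
  rows <- list()
  add <- function(rec, fv, registered) {
    rows[[length(rows) + 1L]] <<- data.frame(
      subject = rec$subject_id, day = rec$day, feature = .feature_names,
      value = as.numeric(fv$values[.feature_names]), registered = registered,
      n_valid = as.integer(fv$n[.feature_names]))
  }
  for (i in seq_along(records)) {
    r <- rasterize_map(records[[i]]$rnflt, size, pixel_size_mm)
    add(records[[i]], compute_features(r, laterality = records[[i]]$rnflt$laterality),
        FALSE)
  }
  if (!is.null(transforms)) {
    stopifnot(length(transforms) == length(records))
    for (sid in unique(subj)) {
      idx <- which(subj == sid)
      al <- align_maps(lapply(records[idx], `[[`, "rnflt"), transforms[idx],
                       size, pixel_size_mm)
      for (j in seq_along(idx)) {
        rec <- records[[idx[j]]]
        add(rec, compute_features(al$rasters[[j]], al$overlap,
                                  rec$rnflt$laterality), TRUE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
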