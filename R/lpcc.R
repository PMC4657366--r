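#' Log-polar transform of a vessel mask or image
#'
#' Resamples the raster onto an (angle, log-radius) grid about `origin`, so
#' that rotation about the origin becomes a circular shift along the angle
#' axis and isotropic scaling becomes a shift along the log-radius axis.
#' `grid[i, j]` is the bilinear sample at
#' `origin + r_j (cos theta_i, -sin theta_i)` (y down, angle
#' counter-clockwise as displayed) with `r_j = r_min exp(j D)`,
#' `D = ln(r_max/r_min) / (n_logr_bins - 1)`, `theta_i = i 360 / n_angle_bins`
#' degrees. Samples falling outside the frame are zero.
#'
#' @param mask a `vessel_mask`, `image2d`, or plain matrix.
#' @param origin `(x, y)` in 0-based pixel coordinates; default frame center.
#'   Must lie inside the frame.
#' @param n_angle_bins,n_logr_bins grid size; the defaults (360 x 384, the
#'   fine registration level) give one angle bin per degree and a
#'   log-radius bin width near 1% in scale.
#' @param r_min_px inner sampling radius (> 0, avoids the log singularity).
#' @param r_max_px outer sampling radius; default the frame half-width minus
#'   one (samples beyond the frame edge contribute zeros).
#' @return an object of class `log_polar_image`.
#' @export
log_polar_transform <- function(mask, origin = NULL, n_angle_bins = 360,
                                n_logr_bins = 384, r_min_px = 2,
                                r_max_px = NULL) {
  m <- if (inherits(mask, "vessel_mask")) mask$mask
       else if (inherits(mask, "image2d")) mask$pixels
       else as.matrix(mask)
  H <- nrow(m); W <- ncol(m)
  if (is.null(origin)) origin <- c((W - 1) / 2, (H - 1) / 2)
  if (origin[1] < 0 || origin[1] > W - 1 || origin[2] < 0 || origin[2] > H - 1) {
    stop("`origin` must lie inside the frame", call. = FALSE)
  }
  if (is.null(r_max_px)) r_max_px <- min(H, W) / 2 - 1
  if (r_min_px <= 0 || r_max_px <= r_min_px) {
    stop("need 0 < r_min_px < r_max_px", call. = FALSE)
  }
  grid <- cpp_logpolar_sample(m, origin[1], origin[2], as.integer(n_angle_bins),
                              as.integer(n_logr_bins), r_min_px, r_max_px)
  structure(list(grid = grid, n_angle_bins = as.integer(n_angle_bins),
                 n_logr_bins = as.integer(n_logr_bins),
                 r_min_px = r_min_px, r_max_px = r_max_px, origin = origin),
            class = "log_polar_image")
}

#' @export
print.log_polar_image <- function(x, ...) {
  cat(sprintf("<log_polar_image %d angle x %d log-radius bins, r = %.1f..%.1f px>\n",
              x$n_angle_bins, x$n_logr_bins, x$r_min_px, x$r_max_px))
  invisible(x)
}

# delta (log-radius bin width) of a log_polar_image
.lp_delta <- function(lp) log(lp$r_max_px / lp$r_min_px) / (lp$n_logr_bins - 1)

#' FFT cross-correlation of two log-polar images
#'
#' Correlation is circular along the (periodic) angle axis and linear along
#' the log-radius axis, which is zero-padded; the peak location gives the
#' rotation shift (angle bins, wrapped into `(-n/2, n/2]`) and the scale
#' shift (log-radius bins). `C(u, v) = sum_ij ref[i, j] tgt[i+u, j+v]`, so
#' for `tgt` equal to `ref` shifted by `(k, m)` the peak sits at `(k, m)`.
#'
#' @param ref_lp,tgt_lp `log_polar_image` objects with identical geometry.
#' @param max_scale_shift_bins largest log-radius shift searched; `NULL`
#'   (default) searches all `n_logr_bins - 1` shifts with full zero-padding.
#' @param normalize divide the correlation by the product of the two grids'
#'   L2 norms (off by default; raw correlation matches the published
#'   method).
#' @return list with `peak_value`, `rotation_shift_bins`,
#'   `scale_shift_bins`, and `surface` (matrix indexed `[u + 1, ]` for angle
#'   shift `u = 0..n_angle-1` circular, and padded log-radius columns where
#'   shift `v >= 0` is column `v + 1` and `v < 0` is column `P + v + 1`).
#' @export
cross_correlate_logpolar <- function(ref_lp, tgt_lp, max_scale_shift_bins = NULL,
                                     normalize = FALSE) {
  geom <- c("n_angle_bins", "n_logr_bins", "r_min_px", "r_max_px")
  if (!identical(ref_lp[geom], tgt_lp[geom])) {
    stop("log-polar geometries must match", call. = FALSE)
  }
  na <- ref_lp$n_angle_bins; nr <- ref_lp$n_logr_bins
  m <- max_scale_shift_bins %||% (nr - 1)
  pad <- nr + m
  rp <- cbind(ref_lp$grid, matrix(0, na, pad - nr))
  tp <- cbind(tgt_lp$grid, matrix(0, na, pad - nr))
  C <- Re(stats::fft(Conj(stats::fft(rp)) * stats::fft(tp), inverse = TRUE)) /
    (na * pad)
  if (normalize) {
    nrm <- sqrt(sum(ref_lp$grid^2)) * sqrt(sum(tgt_lp$grid^2))
    if (nrm > 0) C <- C / nrm
  }
  vcols <- c(seq_len(m + 1), pad - rev(seq_len(m)) + 1)  # shifts 0..m, -m..-1
  sub <- C[, vcols, drop = FALSE]
  peak <- arrayInd(which.max(sub), dim(sub))
  u <- peak[1] - 1L
  if (u > na / 2) u <- u - na
  v <- if (peak[2] <= m + 1) peak[2] - 1L else peak[2] - 1L - (2L * m + 1L)
  list(peak_value = sub[peak[1], peak[2]],
       rotation_shift_bins = as.integer(u),
       scale_shift_bins = as.integer(v),
       surface = C)
}

#' Search configuration for the log-polar cross-correlation registration
#'
#' Defaults follow the published two-resolution schedule: a coarse pass on
#' masks subsampled to 1/4 size with origin candidates within +-10
#' (subsampled) pixels of the center, then a fine pass at full resolution
#' with origin candidates within +-4 pixels; total translation is bounded by
#' 40 px (about 0.23 mm in the canonical frame). Log-polar bin counts per
#' level default to 180 x 128 (coarse) and 360 x 256 (fine), i.e. one angle
#' bin = 1 degree at the fine level.
#'
#' @param global_translation_bound_px reject final estimates whose
#'   translation components exceed this bound.
#' @param coarse_subsample_factor integer subsampling factor (block mean).
#' @param coarse_origin_halfwidth_px origin search half-width at the coarse
#'   (subsampled) level.
#' @param fine_origin_halfwidth_px origin search half-width at the fine
#'   level.
#' @param coarse_n_angle_bins,coarse_n_logr_bins,fine_n_angle_bins,fine_n_logr_bins
#'   log-polar grid sizes per level; the fine defaults give one angle bin =
#'   1 degree and a log-radius bin width under 1.3% in scale, so bin
#'   quantization stays inside a 0.01 scale-recovery tolerance.
#' @param r_min_px inner sampling radius (both levels).
#' @param max_scale_shift_bins log-radius shift search half-range; 32 bins
#'   cover scale factors well beyond the 0.85-1.15 window of interest.
#' @param normalize per-origin normalized correlation (off by default).
#' @return an object of class `lpcc_search_config`.
#' @export
lpcc_search_config <- function(global_translation_bound_px = 40,
                               coarse_subsample_factor = 4,
                               coarse_origin_halfwidth_px = 10,
                               fine_origin_halfwidth_px = 4,
                               coarse_n_angle_bins = 180,
                               coarse_n_logr_bins = 128,
                               fine_n_angle_bins = 360,
                               fine_n_logr_bins = 384,
                               r_min_px = 2,
                               max_scale_shift_bins = 32,
                               normalize = FALSE) {
  cfg <- as.list(environment())
  num <- unlist(cfg[names(cfg) != "normalize"])
  if (any(num <= 0)) stop("all bounds and sizes must be > 0", call. = FALSE)
  structure(cfg, class = "lpcc_search_config")
}

# Smallest 5-smooth integer >= n (fast FFT length).
.good_fft_size <- function(n) {
  k <- n
  repeat {
    m <- k
    for (p in c(2, 3, 5)) while (m %% p == 0) m <- m / p
    if (m == 1) return(as.integer(k))
    k <- k + 1
  }
}

# Block-mean subsampling (masks become fractional vessel densities, which
# is fine for correlation).
.block_mean <- function(m, f) {
  H <- (nrow(m) %/% f) * f; W <- (ncol(m) %/% f) * f
  m <- m[seq_len(H), seq_len(W), drop = FALSE]
  hi <- (seq_len(H) - 1L) %/% f
  wi <- (seq_len(W) - 1L) %/% f
  t(rowsum(t(rowsum(m, hi)), wi)) / f^2
}

# Candidate origin offsets ordered closest-to-center first (ties toward
# smaller y then x), so exact correlation ties resolve to small translations.
.origin_offsets <- function(hw) {
  g <- expand.grid(dx = -hw:hw, dy = -hw:hw)
  g[order(g$dx^2 + g$dy^2, abs(g$dy), abs(g$dx), g$dy, g$dx), ]
}

#' Origin scan: log-polar cross-correlation over candidate origins
#'
#' The reference log-polar image is computed once at the frame center; the
#' target is resampled about every candidate origin and correlated against
#' it. At the global correlation maximum the winning origin gives the
#' translation (`origin - center`), and the peak's shifts give rotation
#' (`shift * angle bin width`) and scale (`exp(shift * D)`). The returned
#' `transform` is the *correction* (apply it to the target to align it with
#' the reference); the raw pose estimate is in `$misalignment`.
#'
#' @param ref_mask,tgt_mask `vessel_mask` objects (or matrices) in a common
#'   frame.
#' @param origin_candidates n x 2 matrix of (x, y) candidate origins in the
#'   target, 0-based pixel coordinates.
#' @param params list with `n_angle_bins`, `n_logr_bins`, `r_min_px`,
#'   `r_max_px` (optional), `max_scale_shift_bins`, `normalize`.
#' @return a `registration_result` with an extra `misalignment` field and a
#'   per-origin peak trace.
#' @export
lpcc_search_origins <- function(ref_mask, tgt_mask, origin_candidates, params) {
  rm_ <- if (inherits(ref_mask, "vessel_mask")) ref_mask$mask else as.matrix(ref_mask)
  tm_ <- if (inherits(tgt_mask, "vessel_mask")) tgt_mask$mask else as.matrix(tgt_mask)
  if (!all(dim(rm_) == dim(tm_))) stop("masks must share one frame", call. = FALSE)
  origin_candidates <- matrix(as.double(as.matrix(origin_candidates)), ncol = 2)
  if (nrow(origin_candidates) == 0L) {
    stop("empty origin candidate set", call. = FALSE)
  }
  H <- nrow(rm_); W <- ncol(rm_)
  ctr <- c((W - 1) / 2, (H - 1) / 2)
  na <- params$n_angle_bins; nr <- params$n_logr_bins
  rmin <- params$r_min_px
  rmax <- params$r_max_px %||% (min(H, W) / 2 - 1)
  ms <- params$max_scale_shift_bins %||% 32
  pad <- .good_fft_size(nr + ms)
  if (any(origin_candidates[, 1] < 0 | origin_candidates[, 1] > W - 1 |
          origin_candidates[, 2] < 0 | origin_candidates[, 2] > H - 1)) {
    stop("origin candidates must lie inside the frame", call. = FALSE)
  }
  ref_lp <- cpp_logpolar_sample(rm_, ctr[1], ctr[2], as.integer(na),
                                as.integer(nr), rmin, rmax)
  scan <- cpp_lpcc_scan(ref_lp, tm_, origin_candidates, as.integer(na),
                        as.integer(nr), rmin, rmax, as.integer(pad),
                        as.integer(ms), isTRUE(params$normalize))
  delta <- log(rmax / rmin) / (nr - 1)
  o <- origin_candidates[scan$origin_index, ]
  mis <- similarity_transform(o[1] - ctr[1], o[2] - ctr[2],
                              scan$angle_shift * 360 / na,
                              exp(scan$logr_shift * delta))
  trace <- data.frame(origin_x = origin_candidates[, 1],
                      origin_y = origin_candidates[, 2],
                      peak = scan$origin_peaks)
  res <- registration_result(invert_transform(mis), scan$peak_value, trace, "LPCC")
  res$misalignment <- mis
  res
}

#' Log-polar cross-correlation registration (coarse + fine)
#'
#' Coarse pass on 1/4-subsampled masks (origin half-width 10 subsampled
#' pixels, translation estimate scaled back by 4), whose correction is
#' applied to the target; then a fine pass at full resolution (origin
#' half-width 4), re-estimating all of translation, rotation and scale. The
#' final correction is `compose(fine, coarse)`; its translation components
#' are checked against the global 40 px bound and a bound-violation error
#' naming the offending component is raised if exceeded, rather than
#' returning a silently wrong answer.
#'
#' @param ref_mask,tgt_mask `vessel_mask` objects in a common frame.
#' @param config an [lpcc_search_config()].
#' @return a `registration_result`; `transform` is the correction to apply
#'   to the target, `misalignment` the estimated pose of the target.
#' @export
lpcc_register <- function(ref_mask, tgt_mask, config = lpcc_search_config()) {
  f <- config$coarse_subsample_factor
  rs <- .block_mean(ref_mask$mask, f)
  ts <- .block_mean(tgt_mask$mask, f)
  ctr_s <- c((ncol(rs) - 1) / 2, (nrow(rs) - 1) / 2)
  offs <- .origin_offsets(config$coarse_origin_halfwidth_px)
  cand_s <- cbind(ctr_s[1] + offs$dx, ctr_s[2] + offs$dy)
  coarse <- lpcc_search_origins(rs, ts, cand_s,
    list(n_angle_bins = config$coarse_n_angle_bins,
         n_logr_bins = config$coarse_n_logr_bins,
         r_min_px = config$r_min_px,
         max_scale_shift_bins = config$max_scale_shift_bins,
         normalize = config$normalize))
  mis_c <- coarse$misalignment
  boundary_hit <- max(abs(mis_c$tx_px), abs(mis_c$ty_px)) >=
    config$coarse_origin_halfwidth_px
  if (boundary_hit) {
    warning("coarse origin search hit its boundary; ",
            "the true translation may exceed the search bounds", call. = FALSE)
  }
  mis_c <- similarity_transform(mis_c$tx_px * f, mis_c$ty_px * f,
                                mis_c$rotation_deg, mis_c$scale)
  corr_c <- invert_transform(mis_c)
  tgt2 <- apply_transform(tgt_mask, corr_c)

  ctr_f <- c((ncol(ref_mask$mask) - 1) / 2, (nrow(ref_mask$mask) - 1) / 2)
  offs_f <- .origin_offsets(config$fine_origin_halfwidth_px)
  cand_f <- cbind(ctr_f[1] + offs_f$dx, ctr_f[2] + offs_f$dy)
  fine <- lpcc_search_origins(ref_mask, tgt2, cand_f,
    list(n_angle_bins = config$fine_n_angle_bins,
         n_logr_bins = config$fine_n_logr_bins,
         r_min_px = config$r_min_px,
         max_scale_shift_bins = config$max_scale_shift_bins,
         normalize = config$normalize))
  correction <- compose_transforms(fine$transform, corr_c)

  bound <- config$global_translation_bound_px
  for (comp in c("tx_px", "ty_px")) {
    if (abs(correction[[comp]]) > bound) {
      stop_octlongreg(
        sprintf("estimated translation %s = %.1f px exceeds the %g px search bound",
                comp, correction[[comp]], bound),
        "octlongreg_bound_violation")
    }
  }
  res <- registration_result(correction, fine$objective,
                             list(coarse = coarse$stage_trace,
                                  fine = fine$stage_trace),
                             "LPCC")
  res$misalignment <- invert_transform(correction)
  res$stages <- list(coarse = mis_c, fine = fine$misalignment)
  res$boundary_hit <- boundary_hit
  res
}
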