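#' Search configuration for mutual-information registration
#'
#' Defaults follow the published two-stage schedule: a coarse joint search
#' translating the target from -25 to 25 px in both directions in 5 px
#' steps while rotating -10 to 10 degrees in 2 degree steps (scale fixed at
#' 1), followed by five sequential fine 1-D searches — scaling 0.85-1.15 in
#' 0.01 steps, x-translation -20..20 px in 1 px steps, y-translation
#' likewise, rotation -20..20 degrees in 0.1 degree steps, and scaling
#' again. Fine grids are centered on the current estimate (relative
#' offsets), so the wide fine rotation range acts as a refinement window
#' around the coarse result.
#'
#' @param coarse_translation_range_px,coarse_translation_step_px coarse
#'   translation half-range and step (px).
#' @param coarse_rotation_range_deg,coarse_rotation_step_deg coarse rotation
#'   half-range and step (degrees).
#' @param fine_scale_range,fine_scale_step fine scale half-range about 1 and
#'   step (unitless factors).
#' @param fine_translation_range_px,fine_translation_step_px fine
#'   translation half-range and step (px).
#' @param fine_rotation_range_deg,fine_rotation_step_deg fine rotation
#'   half-range and step (degrees).
#' @param n_intensity_bins number of equal-width histogram bins.
#' @param intensity_range intensity interval the bins span (8-bit scale).
#' @return an object of class `mi_search_config`.
#' @export
mi_search_config <- function(coarse_translation_range_px = 25,
                             coarse_translation_step_px = 5,
                             coarse_rotation_range_deg = 10,
                             coarse_rotation_step_deg = 2,
                             fine_scale_range = 0.15,
                             fine_scale_step = 0.01,
                             fine_translation_range_px = 20,
                             fine_translation_step_px = 1,
                             fine_rotation_range_deg = 20,
                             fine_rotation_step_deg = 0.1,
                             n_intensity_bins = 64,
                             intensity_range = c(0, 255)) {
  cfg <- list(coarse_translation_range_px = coarse_translation_range_px,
              coarse_translation_step_px = coarse_translation_step_px,
              coarse_rotation_range_deg = coarse_rotation_range_deg,
              coarse_rotation_step_deg = coarse_rotation_step_deg,
              fine_scale_range = fine_scale_range,
              fine_scale_step = fine_scale_step,
              fine_translation_range_px = fine_translation_range_px,
              fine_translation_step_px = fine_translation_step_px,
              fine_rotation_range_deg = fine_rotation_range_deg,
              fine_rotation_step_deg = fine_rotation_step_deg,
              n_intensity_bins = as.integer(n_intensity_bins),
              intensity_range = intensity_range)
  steps <- cfg[grep("step", names(cfg))]
  if (any(unlist(steps) <= 0)) stop("all search steps must be > 0", call. = FALSE)
  ranges <- cfg[grep("range_", names(cfg))]
  if (any(unlist(ranges) <= 0)) stop("all search ranges must be > 0", call. = FALSE)
  structure(cfg, class = "mi_search_config")
}

# Map intensities to 0-based equal-width bin indices over [lo, hi].
# Same arithmetic as the compiled search kernel so both paths bin
# identically at the bin edges.
.bin_index <- function(v, n_bins, lo, hi) {
  i <- floor((v - lo) * (n_bins / (hi - lo)))
  pmin(pmax(i, 0), n_bins - 1)
}

.entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

# MI (bits) from a joint count matrix; marginals of the joint histogram are
# by construction the per-image histograms, so MI >= 0 up to rounding.
.mi_from_joint <- function(h) {
  n <- sum(h)
  p <- h / n
  hx <- .entropy_bits(rowSums(p))
  hy <- .entropy_bits(colSums(p))
  hxy <- .entropy_bits(as.vector(p))
  list(mi = hx + hy - hxy, hx = hx, hy = hy, hxy = hxy)
}

.resolve_mask <- function(image, mask) {
  if (is.null(mask)) return(image$valid_mask)
  if (inherits(mask, "overlap_mask")) mask <- mask$mask
  mask & image$valid_mask
}

#' Shannon entropy of a masked image (bits)
#'
#' `H = -sum p(x_i) log2 p(x_i)` over an equal-width histogram of the masked
#' pixel intensities. The result lies in `[0, log2(n_bins)]`.
#'
#' @param image an `image2d`.
#' @param mask optional logical matrix or `overlap_mask` further restricting
#'   the image's own validity mask.
#' @param n_bins number of histogram bins (default 64).
#' @param range intensity interval spanned by the bins (default `c(0, 255)`).
#' @return entropy in bits.
#' @export
shannon_entropy <- function(image, mask = NULL, n_bins = 64, range = c(0, 255)) {
  m <- .resolve_mask(image, mask)
  v <- image$pixels[m]
  if (length(v) == 0L) {
    stop_octlongreg("entropy undefined on an empty mask",
                    "octlongreg_degenerate_input")
  }
  counts <- tabulate(.bin_index(v, n_bins, range[1], range[2]) + 1L, n_bins)
  .entropy_bits(counts / sum(counts))
}

#' Mutual information between two images (bits)
#'
#' `MI(A, B) = H(A) + H(B) - H(A, B)` with the joint entropy computed from
#' the joint histogram of intensity pairs on a common equal-width binning.
#' Only pixels valid in both images (intersected with `mask` if given)
#' enter the histograms.
#'
#' @inheritParams shannon_entropy
#' @param a,b `image2d` objects of equal shape.
#' @return mutual information in bits (non-negative up to rounding).
#' @export
mutual_information <- function(a, b, mask = NULL, n_bins = 64, range = c(0, 255)) {
  if (!all(dim(a$pixels) == dim(b$pixels))) {
    stop("images must share one shape", call. = FALSE)
  }
  m <- .resolve_mask(a, mask) & b$valid_mask
  if (!any(m)) {
    stop_octlongreg("mutual information undefined on an empty mask",
                    "octlongreg_degenerate_input")
  }
  bi <- .bin_index(a$pixels[m], n_bins, range[1], range[2])
  bj <- .bin_index(b$pixels[m], n_bins, range[1], range[2])
  h <- matrix(tabulate(bi * n_bins + bj + 1L, n_bins * n_bins), n_bins, n_bins,
              byrow = TRUE)
  .mi_from_joint(h)$mi
}

# NaN-code invalid pixels so the search kernel reads one matrix per image.
.pack_image <- function(image) {
  p <- image$pixels
  p[!image$valid_mask] <- NA_real_
  p
}

# MI objective for a candidate transform applied to the *original* target
# (fused warp + joint histogram; no intermediate image is materialised).
.mi_objective_packed <- function(ref_packed, tgt_packed, t, config) {
  h <- cpp_mi_joint_hist(ref_packed, tgt_packed,
                         t$tx_px, t$ty_px, t$rotation_deg * pi / 180, t$scale,
                         config$n_intensity_bins,
                         config$intensity_range[1], config$intensity_range[2])
  if (sum(h) == 0) return(-Inf)
  .mi_from_joint(h)$mi
}

.mi_objective <- function(reference, target, t, config) {
  .mi_objective_packed(.pack_image(reference), .pack_image(target), t, config)
}

# Lexicographic closeness-to-identity key used to break exact MI ties, so
# the identity wins degenerate cases.
.identity_key <- function(t) {
  c(abs(t$tx_px) + abs(t$ty_px), abs(t$rotation_deg), abs(t$scale - 1))
}

.closer_to_identity <- function(a, b) {
  ka <- .identity_key(a); kb <- .identity_key(b)
  d <- ka - kb
  i <- which(d != 0)
  length(i) > 0 && d[i[1]] < 0
}

registration_result <- function(transform, objective, stage_trace, algorithm) {
  structure(list(transform = transform, objective = objective,
                 stage_trace = stage_trace, algorithm = algorithm),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("<registration_result [%s] objective=%.6g>\n", x$algorithm,
              x$objective))
  print(x$transform)
  invisible(x)
}

.trace_row <- function(stage, t, objective) {
  data.frame(stage = stage, tx_px = t$tx_px, ty_px = t$ty_px,
             rotation_deg = t$rotation_deg, scale = t$scale,
             objective = objective)
}

#' Coarse mutual-information registration
#'
#' Exhaustive joint search over the coarse (tx, ty, rotation) grid with the
#' scale fixed at 1; the three parameters are varied simultaneously, which
#' avoids stalling in the local maxima that sequential 1-D searches hit at
#' this stage. Returns the argmax of MI; the trace records every evaluated
#' triple.
#'
#' @param reference,target `image2d` objects in a common frame.
#' @param config an [mi_search_config()].
#' @return a `registration_result`.
#' @export
mi_coarse_register <- function(reference, target, config = mi_search_config()) {
  txs <- seq(-config$coarse_translation_range_px, config$coarse_translation_range_px,
             by = config$coarse_translation_step_px)
  rots <- seq(-config$coarse_rotation_range_deg, config$coarse_rotation_range_deg,
              by = config$coarse_rotation_step_deg)
  n <- length(txs)^2 * length(rots)
  trace <- data.frame(stage = rep("coarse", n), tx_px = NA_real_, ty_px = NA_real_,
                      rotation_deg = NA_real_, scale = 1, objective = NA_real_)
  refp <- .pack_image(reference); tgtp <- .pack_image(target)
  best <- NULL; best_mi <- -Inf; k <- 0L
  for (rot in rots) for (ty in txs) for (tx in txs) {
    cand <- similarity_transform(tx, ty, rot, 1)
    mi <- .mi_objective_packed(refp, tgtp, cand, config)
    k <- k + 1L
    trace$tx_px[k] <- tx; trace$ty_px[k] <- ty; trace$rotation_deg[k] <- rot
    trace$objective[k] <- mi
    if (mi > best_mi || (mi == best_mi && .closer_to_identity(cand, best))) {
      best <- cand; best_mi <- mi
    }
  }
  registration_result(best, best_mi, trace, "MI")
}

#' Fine mutual-information registration
#'
#' Five sequential exhaustive 1-D searches (scaling, x-translation,
#' y-translation, rotation, scaling again), each centered on the current
#' estimate and updating it. Every candidate is evaluated by resampling the
#' *original* target with the full candidate transform, so interpolation
#' error does not accumulate across stages. The objective is non-decreasing
#' over the five stages.
#'
#' @inheritParams mi_coarse_register
#' @param coarse the coarse-stage transform (e.g. from
#'   [mi_coarse_register()]); the fine grids are centered on it.
#' @return a `registration_result` whose transform refines `coarse`.
#' @export
mi_fine_register <- function(reference, target, coarse,
                             config = mi_search_config()) {
  refp <- .pack_image(reference); tgtp <- .pack_image(target)
  cur <- coarse
  cur_mi <- .mi_objective_packed(refp, tgtp, cur, config)
  trace <- .trace_row("fine_start", cur, cur_mi)
  scale_facs <- seq(1 - config$fine_scale_range, 1 + config$fine_scale_range,
                    by = config$fine_scale_step)
  toffs <- seq(-config$fine_translation_range_px, config$fine_translation_range_px,
               by = config$fine_translation_step_px)
  roffs <- seq(-config$fine_rotation_range_deg, config$fine_rotation_range_deg,
               by = config$fine_rotation_step_deg)
  stages <- list(list(name = "fine_scale_1", par = "scale", grid = scale_facs),
                 list(name = "fine_tx", par = "tx", grid = toffs),
                 list(name = "fine_ty", par = "ty", grid = toffs),
                 list(name = "fine_rotation", par = "rot", grid = roffs),
                 list(name = "fine_scale_2", par = "scale", grid = scale_facs))
  for (stg in stages) {
    for (g in stg$grid) {
      cand <- switch(stg$par,
        scale = similarity_transform(cur$tx_px, cur$ty_px, cur$rotation_deg,
                                     cur$scale * g),
        tx = similarity_transform(cur$tx_px + g, cur$ty_px, cur$rotation_deg,
                                  cur$scale),
        ty = similarity_transform(cur$tx_px, cur$ty_px + g, cur$rotation_deg,
                                  cur$scale),
        rot = similarity_transform(cur$tx_px, cur$ty_px, cur$rotation_deg + g,
                                   cur$scale))
      mi <- .mi_objective_packed(refp, tgtp, cand, config)
      if (mi > cur_mi || (mi == cur_mi && .closer_to_identity(cand, cur))) {
        cur <- cand; cur_mi <- mi
      }
    }
    trace <- rbind(trace, .trace_row(stg$name, cur, cur_mi))
  }
  registration_result(cur, cur_mi, trace, "MI")
}

#' Mutual-information registration (coarse + fine)
#'
#' Runs [mi_coarse_register()] followed by [mi_fine_register()]. The
#' returned transform is the one that, applied to the target, maximises MI
#' against the fixed reference — i.e. the correction for the target's
#' misalignment.
#'
#' @inheritParams mi_coarse_register
#' @param keep_full_trace keep the full coarse evaluation grid in the trace
#'   (default `FALSE` keeps only per-stage argmax summaries).
#' @return a `registration_result`.
#' @export
mi_register <- function(reference, target, config = mi_search_config(),
                        keep_full_trace = FALSE) {
  coarse <- mi_coarse_register(reference, target, config)
  fine <- mi_fine_register(reference, target, coarse$transform, config)
  coarse_trace <- if (keep_full_trace) coarse$stage_trace else
    .trace_row("coarse", coarse$transform, coarse$objective)
  registration_result(fine$transform, fine$objective,
                      rbind(coarse_trace, fine$stage_trace), "MI")
}
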