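#' Specification of a synthetic retinal vessel tree
#'
#' Emulates the manually segmented "five widest vessels with branches" used
#' by the semi-automatic registration: a small number of main vessels
#' radiate from a central optic-nerve-head disc region, meander outward
#' with smooth random curvature, taper, and occasionally branch.
#'
#' @param n_main_vessels number of main vessels (>= 1, default 5).
#' @param branch_probability per-step probability that a walker spawns a
#'   branch.
#' @param width_px_range vessel half-width bounds in pixels `c(min, max)`.
#' @param seed RNG seed; generation is bit-reproducible for a fixed seed.
#' @return an object of class `vessel_tree_spec`.
#' @export
vessel_tree_spec <- function(n_main_vessels = 5, branch_probability = 0.04,
                             width_px_range = c(2, 6), seed = 1) {
  if (!is.numeric(n_main_vessels) || n_main_vessels < 1) {
    stop("`n_main_vessels` must be >= 1", call. = FALSE)
  }
  if (branch_probability < 0 || branch_probability > 1) {
    stop("`branch_probability` must be in [0, 1]", call. = FALSE)
  }
  if (length(width_px_range) != 2L || any(width_px_range <= 0) ||
      diff(width_px_range) < 0) {
    stop("`width_px_range` must be increasing positive bounds", call. = FALSE)
  }
  structure(list(n_main_vessels = as.integer(n_main_vessels),
                 branch_probability = branch_probability,
                 width_px_range = width_px_range, seed = seed),
            class = "vessel_tree_spec")
}

# Stamp a filled disc of radius r (px) at (x, y) into matrix m (0-based coords).
.stamp_disc <- function(m, x, y, r) {
  n <- nrow(m)
  xs <- max(0, floor(x - r)):min(n - 1, ceiling(x + r))
  ys <- max(0, floor(y - r)):min(n - 1, ceiling(y + r))
  if (length(xs) == 0L || length(ys) == 0L) return(m)
  dd <- outer((ys - y)^2, (xs - x)^2, `+`)
  sel <- dd <= r^2
  m[cbind(rep(ys, length(xs))[as.vector(sel)] + 1L,
          rep(xs, each = length(ys))[as.vector(sel)] + 1L)] <- 1
  m
}

#' Generate a synthetic vessel-tree mask
#'
#' @param spec a [vessel_tree_spec()].
#' @param size frame side length in pixels (canonical 512).
#' @param pixel_size_mm physical pixel size (default 3 mm field of view).
#' @return a `vessel_mask`.
#' @export
generate_vessel_tree <- function(spec, size = 512, pixel_size_mm = 3 / size) {
  with_seed(spec$seed, {
    m <- matrix(0, size, size)
    ctr <- (size - 1) / 2
    start_r <- 0.20 / pixel_size_mm  # vessels emerge at the ONH disc margin
    base <- runif(1, 0, 2 * pi)
    # widths are specified in canonical 512 px frame units; scale with the
    # working frame so physical vessel width is frame-invariant
    w_hi <- spec$width_px_range[2] * size / 512
    w_lo <- spec$width_px_range[1] * size / 512
    walkers <- vector("list", spec$n_main_vessels)
    for (i in seq_len(spec$n_main_vessels)) {
      a <- base + (i - 1) * 2 * pi / spec$n_main_vessels + rnorm(1, 0, 0.06)
      walkers[[i]] <- list(x = ctr + start_r * cos(a), y = ctr - start_r * sin(a),
                           dir = a, w = runif(1, 0.8 * w_hi, w_hi))
    }
    max_steps <- 4L * size
    while (length(walkers) > 0L) {
      wk <- walkers[[1L]]; walkers <- walkers[-1L]
      for (s in seq_len(max_steps)) {
        m <- .stamp_disc(m, wk$x, wk$y, wk$w)
        # radial pull keeps vessels diverging from the disc
        radial <- atan2(-(wk$y - ctr), wk$x - ctr)
        dd <- ((radial - wk$dir + pi) %% (2 * pi)) - pi
        wk$dir <- wk$dir + 0.15 * dd + rnorm(1, 0, 0.06)
        wk$x <- wk$x + 2 * cos(wk$dir)
        wk$y <- wk$y - 2 * sin(wk$dir)
        wk$w <- wk$w * 0.9965
        if (wk$w > 1.4 * w_lo && stats::runif(1) < spec$branch_probability) {
          walkers[[length(walkers) + 1L]] <-
            list(x = wk$x, y = wk$y,
                 dir = wk$dir + sample(c(-1, 1), 1) * stats::runif(1, 0.35, 0.8),
                 w = wk$w * 0.65)
        }
        if (wk$x < 2 || wk$y < 2 || wk$x > size - 3 || wk$y > size - 3 ||
            wk$w < 0.6 * w_lo) break
      }
    }
    vessel_mask(m, pixel_size_mm)
  })
}

# Low-frequency Gaussian-filtered white noise (zero mean, unit sd), via FFT.
.smooth_noise <- function(size, sigma_px) {
  z <- matrix(stats::rnorm(size^2), size, size)
  f <- c(0:(size %/% 2), -((size - size %/% 2 - 1):1)) / size
  H <- exp(-2 * pi^2 * sigma_px^2 * outer(f^2, f^2, `+`))
  sm <- Re(stats::fft(stats::fft(z) * H, inverse = TRUE)) / size^2
  sm / stats::sd(sm)
}

#' Generate a fundus-like intensity image from a vessel mask
#'
#' Produces a smooth low-frequency background with a bright optic-nerve-head
#' disc at the center, a mild stochastic texture, and vessels rendered at
#' least 20 gray levels darker than their local background — an intensity
#' stand-in for the en-face projection obtained by axially summing OCT
#' B-scans. Intensities are on the 8-bit scale `[0, 255]`.
#'
#' @param vessels a `vessel_mask`.
#' @param background_seed RNG seed for the background and texture.
#' @return an `image2d`.
#' @export
generate_fundus <- function(vessels, background_seed = 1) {
  with_seed(background_seed, {
    size <- nrow(vessels$mask)
    psz <- vessels$pixel_size_mm
    ctr <- (size - 1) / 2
    xs <- ((0:(size - 1)) - ctr) * psz
    bg <- matrix(135, size, size)
    # a few broad illumination blobs
    for (b in seq_len(3)) {
      bx <- stats::runif(1, -1, 1); by <- stats::runif(1, -1, 1)
      amp <- stats::runif(1, -18, 18); sg <- stats::runif(1, 0.6, 1.1)
      bg <- bg + amp * exp(-(outer((xs - by)^2, (xs - bx)^2, `+`)) / (2 * sg^2))
    }
    r2 <- outer(xs^2, xs^2, `+`)
    bg <- bg + 65 * exp(-r2 / (2 * 0.45^2))          # bright ONH disc
    bg <- bg + 6 * .smooth_noise(size, 2)            # fine texture
    bg <- pmin(pmax(bg, 62), 235)
    px <- bg
    px[vessels$mask == 1] <- bg[vessels$mask == 1] - 42
    image2d(pmin(pmax(px, 0), 255), psz)
  })
}
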