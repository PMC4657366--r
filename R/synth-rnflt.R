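#' Polar RNFL thickness map
#'
#' The container for a peripapillary ring-scan thickness map: 100 equally
#' spaced ring B-scans with ring diameters 1.5 to 3.0 mm (radii 0.75 to
#' 1.5 mm), each ring holding 100 a-scans. Rows index rings (inner to
#' outer), columns index a-scans in clockwise order (right-eye view)
#' starting at `theta0_deg` from the temporal meridian.
#'
#' @param thickness_um 100 x 100 numeric matrix of thickness in micrometres,
#'   all values > 0.
#' @param laterality `"OD"` (right eye) or `"OS"` (left eye; mirrored before
#'   sector assignment so features follow the OD clock convention).
#' @param theta0_deg angular position of a-scan index 1, in degrees
#'   clockwise from the temporal meridian (default 0).
#' @param ring_radius_mm per-ring radii; default equally spaced 0.75-1.5 mm.
#' @return an object of class `rnflt_map`.
#' @export
rnflt_map <- function(thickness_um, laterality = c("OD", "OS"), theta0_deg = 0,
                      ring_radius_mm = seq(0.75, 1.5, length.out = nrow(thickness_um))) {
  laterality <- match.arg(laterality)
  thickness_um <- as.matrix(thickness_um)
  if (any(!is.finite(thickness_um)) || any(thickness_um <= 0)) {
    stop("thickness values must be positive and finite", call. = FALSE)
  }
  if (length(ring_radius_mm) != nrow(thickness_um) ||
      any(diff(ring_radius_mm) <= 0)) {
    stop("`ring_radius_mm` must be strictly increasing, one per ring",
         call. = FALSE)
  }
  structure(list(thickness_um = thickness_um, ring_radius_mm = ring_radius_mm,
                 theta0_deg = theta0_deg, laterality = laterality),
            class = "rnflt_map")
}

#' @export
print.rnflt_map <- function(x, ...) {
  cat(sprintf("<rnflt_map %d rings x %d a-scans [%s], mean %.1f um>\n",
              nrow(x$thickness_um), ncol(x$thickness_um), x$laterality,
              mean(x$thickness_um)))
  invisible(x)
}

#' Specification of the angular RNFLT profile
#'
#' Defines the double-hump (superior/inferior-thick) angular thickness
#' profile via its four quadrant mean thicknesses, plus radial decay,
#' per-sample measurement noise, and an optional true longitudinal trend.
#' Defaults are the quadrant intercepts reported for healthy primate eyes.
#'
#' @param quadrant_means_um named mean thickness per quadrant
#'   (temporal, superior, nasal, inferior), micrometres, all > 0.
#' @param radial_decay fractional thinning from the innermost to the
#'   outermost ring (0 = radially flat).
#' @param noise_sd_um per-sample Gaussian measurement noise (micrometres).
#' @param session_sd_um SD of a per-acquisition global thickness offset
#'   (instrument reproducibility error: axial calibration and layer
#'   segmentation shift the whole map together between sessions). This is
#'   the noise floor of heavily averaged features such as the all-rings
#'   mean, which per-sample noise alone would leave unrealistically small.
#' @param slope_um_per_day true longitudinal trend added to every sample
#'   (default 0: healthy, stable thickness).
#' @return an object of class `rnflt_profile_spec`.
#' @export
rnflt_profile_spec <- function(quadrant_means_um = c(temporal = 81.65,
                                                     superior = 112.17,
                                                     nasal = 82.74,
                                                     inferior = 132.22),
                               radial_decay = 0, noise_sd_um = 6,
                               session_sd_um = 2.5,
                               slope_um_per_day = 0) {
  need <- c("temporal", "superior", "nasal", "inferior")
  if (!all(need %in% names(quadrant_means_um))) {
    stop("`quadrant_means_um` must name temporal, superior, nasal, inferior",
         call. = FALSE)
  }
  if (any(quadrant_means_um <= 0)) stop("quadrant means must be > 0", call. = FALSE)
  if (noise_sd_um < 0 || session_sd_um < 0) {
    stop("noise SDs must be >= 0", call. = FALSE)
  }
  if (radial_decay < 0 || radial_decay >= 1) {
    stop("`radial_decay` must be in [0, 1)", call. = FALSE)
  }
  structure(list(quadrant_means_um = quadrant_means_um[need],
                 radial_decay = radial_decay, noise_sd_um = noise_sd_um,
                 session_sd_um = session_sd_um,
                 slope_um_per_day = slope_um_per_day),
            class = "rnflt_profile_spec")
}

# Periodic cubic angular profile whose *quadrant means* equal the specified
# values. Knots sit at the quadrant-center angles phi = 0 (T), 90 (S),
# 180 (N), 270 (I), measured clockwise from the temporal meridian in OD
# view; knot values are obtained by solving a 4x4 linear system because a
# spline through the means themselves would not average back to them.
.profile_fun <- function(quadrant_means_um, radial_decay = 0) {
  knots <- c(0, 90, 180, 270)
  cardinal <- lapply(1:4, function(k) {
    y <- rep(0, 4); y[k] <- 1
    stats::splinefun(c(knots, 360), c(y, y[1]), method = "periodic")
  })
  phi <- seq(0, 360, length.out = 3601)[-3601]
  B <- vapply(cardinal, function(f) f(phi), numeric(length(phi)))
  quad <- floor(((phi + 45) %% 360) / 90) + 1  # 1=T (phi ~ 0), 2=S, 3=N, 4=I
  M <- t(vapply(1:4, function(q) colMeans(B[quad == q, , drop = FALSE]),
                numeric(4)))
  mean_g <- 1 - radial_decay / 2
  v <- solve(M, as.numeric(quadrant_means_um) / mean_g)
  f <- stats::splinefun(c(knots, 360), c(v, v[1]), method = "periodic")
  function(phi_deg) f(phi_deg %% 360)
}

# Map the displayed angle psi (degrees CCW from screen-right, y up) to the
# profile angle phi (clockwise from the temporal meridian). In the OD view
# nasal sits at screen right (psi = 0), temporal at screen left; OS is the
# mirror image about the vertical axis.
.psi_to_phi <- function(psi_deg, laterality) {
  if (laterality == "OD") (180 - psi_deg) %% 360 else psi_deg %% 360
}

# Analytic thickness field (um) at points given in px relative to the frame
# center (y down). Radius is clamped to the scanned annulus so the field is
# defined everywhere; this lets misaligned acquisitions sample it.
.rnflt_field <- function(profile, laterality = "OD",
                         r_in_mm = 0.75, r_out_mm = 1.5) {
  pf <- .profile_fun(profile$quadrant_means_um, profile$radial_decay)
  function(x_px, y_px, pixel_size_mm) {
    x <- x_px * pixel_size_mm; y <- y_px * pixel_size_mm
    r <- pmin(pmax(sqrt(x^2 + y^2), r_in_mm), r_out_mm)
    psi <- atan2(-y, x) * 180 / pi
    g <- 1 - profile$radial_decay * (r - r_in_mm) / (r_out_mm - r_in_mm)
    pf(.psi_to_phi(psi, laterality)) * g
  }
}

#' Generate a synthetic polar RNFLT map
#'
#' Samples the analytic double-hump thickness field on the nominal ring-scan
#' grid, adds the linear trend `slope_um_per_day * day` and per-sample
#' Gaussian noise. When `true_transform` is given the field is sampled
#' through the inverse transform, emulating an acquisition whose scan ring
#' was misplaced relative to the reference session (the same ground-truth
#' transform that misaligns the session's fundus image).
#'
#' @param profile an [rnflt_profile_spec()].
#' @param day days since baseline (>= 0).
#' @param seed RNG seed for the measurement noise.
#' @param laterality,theta0_deg map orientation metadata (see [rnflt_map()]).
#' @param true_transform optional `similarity_transform` (ground-truth
#'   session misalignment, in pixels of the frame given by `pixel_size_mm`).
#' @param pixel_size_mm pixel size used to interpret `true_transform`.
#' @return an `rnflt_map`; the attribute `n_clipped` counts samples clipped
#'   at the 1 um floor after noise.
#' @export
generate_rnflt_map <- function(profile, day = 0, seed = 1, laterality = "OD",
                               theta0_deg = 0, true_transform = NULL,
                               pixel_size_mm = 3 / 512) {
  stopifnot(inherits(profile, "rnflt_profile_spec"), day >= 0)
  n_rings <- 100L; n_ascans <- 100L
  radii <- seq(0.75, 1.5, length.out = n_rings)
  phi <- (theta0_deg + (0:(n_ascans - 1)) * 360 / n_ascans) %% 360
  psi <- if (laterality == "OD") (180 - phi) %% 360 else phi
  # nominal sample positions in px relative to center (y down)
  r_px <- radii / pixel_size_mm
  X <- outer(r_px, cos(psi * pi / 180))
  Y <- outer(r_px, -sin(psi * pi / 180))
  if (!is.null(true_transform)) {
    t <- true_transform
    Rinv <- .rot_mat(-t$rotation_deg)
    dx <- X - t$tx_px; dy <- Y - t$ty_px
    Xq <- (Rinv[1, 1] * dx + Rinv[1, 2] * dy) / t$scale
    Yq <- (Rinv[2, 1] * dx + Rinv[2, 2] * dy) / t$scale
    X <- Xq; Y <- Yq
  }
  field <- .rnflt_field(profile, laterality)
  th <- matrix(field(as.vector(X), as.vector(Y), pixel_size_mm),
               n_rings, n_ascans) + profile$slope_um_per_day * day
  if (profile$noise_sd_um > 0) {
    th <- th + with_seed(seed, matrix(stats::rnorm(n_rings * n_ascans,
                                                   0, profile$noise_sd_um),
                                      n_rings, n_ascans))
  }
  if (profile$session_sd_um > 0) {
    th <- th + with_seed(derive_seed(seed, 77),
                         stats::rnorm(1, 0, profile$session_sd_um))
  }
  n_clipped <- sum(th < 1)
  th[th < 1] <- 1
  out <- rnflt_map(th, laterality, theta0_deg, radii)
  attr(out, "n_clipped") <- n_clipped
  out
}

#' Read / write a polar RNFLT map as CSV
#'
#' Plain 100 x 100 matrix, rows = rings (inner to outer), columns = a-scans;
#' orientation metadata travels separately.
#'
#' @param map an `rnflt_map`.
#' @param path file path.
#' @name rnflt_csv
#' @export
write_rnflt_csv <- function(map, path) {
  utils::write.table(map$thickness_um, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname rnflt_csv
#' @inheritParams rnflt_map
#' @export
read_rnflt_csv <- function(path, laterality = "OD", theta0_deg = 0) {
  th <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  dimnames(th) <- NULL
  rnflt_map(th, laterality, theta0_deg)
}
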