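#' Session-to-session misalignment (jitter) model
#'
#' Inter-session misalignment has two parts: an i.i.d. zero-mean Gaussian
#' component in x/y-translation and rotation with a log-normal scale factor
#' (operator placement of the scan ring, globe orientation), and a small
#' linear temporal drift (progressive change in eye positioning over the
#' study, the mechanism that turns misalignment into spurious longitudinal
#' trends). Draws falling outside the registration search bounds are
#' rejected and redrawn.
#'
#' @param sd_tx_px translation SD in pixels (applies to x and y).
#' @param sd_rot_deg rotation SD in degrees.
#' @param sd_scale SD of log(scale).
#' @param drift_tx_px_per_day,drift_ty_px_per_day,drift_rot_deg_per_day
#'   linear drift of the mean misalignment per day since baseline.
#' @return a list of class `longitudinal_jitter`.
#' @export
longitudinal_jitter <- function(sd_tx_px = 5, sd_rot_deg = 3, sd_scale = 0.02,
                                drift_tx_px_per_day = 0.03,
                                drift_ty_px_per_day = -0.02,
                                drift_rot_deg_per_day = 0.03) {
  if (sd_tx_px < 0 || sd_rot_deg < 0 || sd_scale < 0) {
    stop("jitter SDs must be >= 0", call. = FALSE)
  }
  structure(list(sd_tx_px = sd_tx_px, sd_rot_deg = sd_rot_deg,
                 sd_scale = sd_scale,
                 drift_tx_px_per_day = drift_tx_px_per_day,
                 drift_ty_px_per_day = drift_ty_px_per_day,
                 drift_rot_deg_per_day = drift_rot_deg_per_day),
            class = "longitudinal_jitter")
}

# Acceptance bounds for drawn transforms: keep sessions registrable by both
# algorithms (MI coarse +-25 px / +-10 deg; LPCC translation bound 40 px;
# fine scale window 0.85-1.15).
.jitter_bounds <- list(t_px = 22, rot_deg = 9.5, scale = c(0.87, 1.13))

# Draw one session misalignment; counts redraws in the enclosing env.
.draw_transform <- function(jitter, day, counter_env) {
  repeat {
    tx <- jitter$drift_tx_px_per_day * day + stats::rnorm(1, 0, jitter$sd_tx_px)
    ty <- jitter$drift_ty_px_per_day * day + stats::rnorm(1, 0, jitter$sd_tx_px)
    rot <- jitter$drift_rot_deg_per_day * day + stats::rnorm(1, 0, jitter$sd_rot_deg)
    sc <- exp(stats::rnorm(1, 0, jitter$sd_scale))
    ok <- abs(tx) <= .jitter_bounds$t_px && abs(ty) <= .jitter_bounds$t_px &&
      abs(rot) <= .jitter_bounds$rot_deg &&
      sc >= .jitter_bounds$scale[1] && sc <= .jitter_bounds$scale[2]
    if (ok) return(similarity_transform(tx, ty, rot, sc))
    counter_env$n_redraws <- counter_env$n_redraws + 1L
  }
}

#' Simulate a longitudinal multi-subject imaging series
#'
#' Generates, per subject, a reference-frame vessel tree, fundus image and
#' thickness field, then renders each imaging session by warping the
#' reference rasters (and resampling the thickness field) through a random
#' ground-truth misalignment drawn from the jitter model. The first session
#' of each subject (day 0) is the reference and carries the identity
#' transform. The published study followed one eye of each of three
#' primates weekly over 30 weeks, retaining 8, 16 and 16 sessions.
#'
#' @param n_subjects number of subjects.
#' @param sessions_per_subject integer vector (recycled) of sessions per
#'   subject, e.g. `c(8, 16, 16)`.
#' @param total_days study duration in days (sessions sit on a weekly grid).
#' @param jitter a [longitudinal_jitter()].
#' @param profile an [rnflt_profile_spec()].
#' @param seed root RNG seed; every generated quantity derives from it.
#' @param frame_size working frame side length in pixels.
#' @param vessel_spec optional [vessel_tree_spec()] template (its seed is
#'   re-derived per subject).
#' @param fundus_noise_sd per-session additive intensity noise (gray levels).
#' @return a list of session records (class `session_series`); each record
#'   has `subject_id`, `day`, `fundus`, `vessels`, `rnflt`,
#'   `true_transform`, and `reference` (flag). The attribute `n_redraws`
#'   counts jitter draws rejected at the search bounds.
#' @export
simulate_longitudinal_series <- function(n_subjects = 3,
                                         sessions_per_subject = c(8, 16, 16),
                                         total_days = 210,
                                         jitter = longitudinal_jitter(),
                                         profile = rnflt_profile_spec(),
                                         seed = 1, frame_size = 512,
                                         vessel_spec = NULL,
                                         fundus_noise_sd = 2) {
  sessions_per_subject <- rep_len(sessions_per_subject, n_subjects)
  psz <- 3 / frame_size
  counter <- new.env(); counter$n_redraws <- 0L
  records <- list()
  for (s in seq_len(n_subjects)) {
    sub_seed <- derive_seed(seed, 100 + s)
    vs <- vessel_spec %||% vessel_tree_spec()
    vs$seed <- derive_seed(sub_seed, 1)
    vessels_ref <- generate_vessel_tree(vs, frame_size, psz)
    fundus_ref <- generate_fundus(vessels_ref, derive_seed(sub_seed, 2))
    n_sess <- sessions_per_subject[s]
    n_weeks <- max(1L, floor(total_days / 7))
    days <- with_seed(derive_seed(sub_seed, 3),
                      c(0, sort(sample(seq_len(n_weeks), n_sess - 1L))) * 7)
    for (k in seq_len(n_sess)) {
      sess_seed <- derive_seed(sub_seed, 10 + k)
      is_ref <- k == 1L
      tt <- if (is_ref) similarity_transform() else
        with_seed(sess_seed, .draw_transform(jitter, days[k], counter))
      fundus <- apply_transform(fundus_ref, tt)
      if (fundus_noise_sd > 0) {
        noise <- with_seed(derive_seed(sess_seed, 1),
                           matrix(stats::rnorm(frame_size^2, 0, fundus_noise_sd),
                                  frame_size, frame_size))
        fundus$pixels <- pmin(pmax(fundus$pixels + noise * fundus$valid_mask, 0), 255)
      }
      vessels <- apply_transform(vessels_ref, tt)
      rnflt <- generate_rnflt_map(profile, days[k],
                                  seed = derive_seed(sess_seed, 2),
                                  true_transform = if (is_ref) NULL else tt,
                                  pixel_size_mm = psz)
      records[[length(records) + 1L]] <-
        list(subject_id = sprintf("S%02d", s), day = days[k], fundus = fundus,
             vessels = vessels, rnflt = rnflt, true_transform = tt,
             reference = is_ref)
    }
  }
  structure(records, class = "session_series",
            frame_size = frame_size, pixel_size_mm = psz,
            n_redraws = counter$n_redraws)
}

#' @export
print.session_series <- function(x, ...) {
  subj <- vapply(x, `[[`, "", "subject_id")
  cat(sprintf("<session_series: %d sessions, %d subjects, frame %d px>\n",
              length(x), length(unique(subj)), attr(x, "frame_size")))
  invisible(x)
}

#' Write a session record to a directory
#'
#' Writes `fundus.png`, `vessels.png`, `rnflt.csv` and `meta.json`
#' (including the ground-truth transform) — the on-disk session layout used
#' by the command-line pipeline.
#'
#' @param record one element of a `session_series`.
#' @param dir output directory (created if needed).
#' @export
write_session <- function(record, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_image_png(record$fundus, file.path(dir, "fundus.png"))
  write_vessel_mask_png(record$vessels, file.path(dir, "vessels.png"))
  write_rnflt_csv(record$rnflt, file.path(dir, "rnflt.csv"))
  meta <- list(subject_id = record$subject_id, day = record$day,
               reference = record$reference,
               laterality = record$rnflt$laterality,
               theta0_deg = record$rnflt$theta0_deg,
               true_transform = unclass(record$true_transform))
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
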