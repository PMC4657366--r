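noise_free <- rnflt_profile_spec(noise_sd_um = 0, session_sd_um = 0)

test_that("rasterization fills the annulus with nearest polar samples", {
  flat <- rnflt_profile_spec(quadrant_means_um = c(temporal = 100, superior = 100,
                                                   nasal = 100, inferior = 100),
                             noise_sd_um = 0, session_sd_um = 0)
  r <- rasterize_map(generate_rnflt_map(flat, 0, 1), 256)
  expect_lt(max(abs(r$pixels[r$valid_mask] - 100)), 1e-9)
  expect_true(all(r$pixels[!r$valid_mask] == 0))
  idx <- which(r$valid_mask, arr.ind = TRUE)
  ctr <- (256 - 1) / 2
  rad <- sqrt((idx[, 1] - 1 - ctr)^2 + (idx[, 2] - 1 - ctr)^2)
  psz <- r$pixel_size_mm
  expect_lt(abs(min(rad) - 0.75 / psz), 1)
  expect_lt(abs(max(rad) - 1.5 / psz), 1)
})

test_that("polar -> raster -> polar round-trip is faithful for a smooth map", {
  m <- generate_rnflt_map(noise_free, 0, 1)
  m2 <- polar_resample(rasterize_map(m, 512))
  expect_lt(mean(abs(m2$thickness_um - m$thickness_um)), 1)
})

test_that("the 17 features equal a per-pixel loop oracle", {
  m <- generate_rnflt_map(rnflt_profile_spec(noise_sd_um = 4, session_sd_um = 0),
                          0, 3)
  r <- rasterize_map(m, 128)
  fv <- compute_features(r)
  expect_lt(max(abs(fv$values - loop_features(r))), 1e-9)
  # constant map: every feature equals the constant
  flat <- rnflt_profile_spec(quadrant_means_um = c(temporal = 100, superior = 100,
                                                   nasal = 100, inferior = 100),
                             noise_sd_um = 0, session_sd_um = 0)
  fc <- compute_features(rasterize_map(generate_rnflt_map(flat, 0, 1), 128))
  expect_equal(unname(fc$values), rep(100, 17))
})

test_that("sector assignment partitions the annulus", {
  r <- rasterize_map(generate_rnflt_map(noise_free, 0, 1), 128)
  fv <- compute_features(r)
  expect_equal(sum(fv$n[2:5]), fv$n[["all_rings"]])
  expect_equal(sum(fv$n[6:17]), fv$n[["all_rings"]])
  # area-weighted quadrant mean reproduces the all-rings average
  aw <- sum(fv$values[2:5] * fv$n[2:5]) / sum(fv$n[2:5])
  expect_lt(abs(aw - fv$values[["all_rings"]]), 1e-9)
})

test_that("quadrant features recover sharp-boundary quadrant means", {
  m <- generate_rnflt_map(noise_free, 0, 1)
  # overwrite with sharp quadrant blocks in the map's own angular frame
  phi <- (0:99) * 3.6
  quad <- floor(((phi + 45) %% 360) / 90) + 1  # 1=T 2=S 3=N 4=I
  vals <- c(81.65, 112.17, 82.74, 132.22)
  m$thickness_um <- matrix(vals[quad], 100, 100, byrow = TRUE)
  fv <- compute_features(rasterize_map(m, 256))
  expect_lt(max(abs(fv$values[c("temporal", "superior", "nasal", "inferior")] -
                    vals)), 0.5)
})

test_that("a 30-degree rotation permutes the clock-hour features by one", {
  r <- rasterize_map(generate_rnflt_map(noise_free, 0, 1), 256)
  f0 <- compute_features(r)
  f1 <- compute_features(apply_transform(r, similarity_transform(0, 0, 30, 1)))
  h0 <- f0$values[sprintf("hour_%02d", 1:12)]
  h1 <- f1$values[sprintf("hour_%02d", 1:12)]
  expect_lt(max(abs(h1 - h0[c(2:12, 1)])), 1)
})

test_that("OS maps mirror onto the OD labeling convention", {
  fOD <- compute_features(rasterize_map(generate_rnflt_map(noise_free, 0, 1), 128))
  mOS <- generate_rnflt_map(noise_free, 0, 1, laterality = "OS")
  fOS <- compute_features(rasterize_map(mOS, 128), laterality = "OS")
  expect_lt(max(abs(fOS$values - fOD$values)), 1e-9)
})

test_that("alignment with the known correction makes features shift-invariant", {
  m0 <- generate_rnflt_map(noise_free, 0, 1)
  tt <- similarity_transform(10, 0, 0, 1)
  m1 <- generate_rnflt_map(noise_free, 0, 1, true_transform = tt,
                           pixel_size_mm = 3 / 256)
  al <- align_maps(list(m0, m1), list(similarity_transform(), invert_transform(tt)),
                   256)
  fa <- compute_features(al$rasters[[1]], al$overlap)
  fb <- compute_features(al$rasters[[2]], al$overlap)
  expect_lt(max(abs(fa$values - fb$values)), 1)
  # the common mask is the brute-force AND of the aligned validity masks
  expected <- al$rasters[[1]]$valid_mask & al$rasters[[2]]$valid_mask
  expect_identical(al$overlap$mask, expected)
  # all-identity transforms keep the full annulus
  al0 <- align_maps(list(m0, m0), list(similarity_transform(), similarity_transform()),
                    256)
  expect_identical(al0$overlap$mask, al0$rasters[[1]]$valid_mask)
})

test_that("feature series accounting covers both branches", {
  quiet <- longitudinal_jitter(sd_tx_px = 0, sd_rot_deg = 0, sd_scale = 0,
                               drift_tx_px_per_day = 0, drift_ty_px_per_day = 0,
                               drift_rot_deg_per_day = 0)
  series <- simulate_longitudinal_series(2, c(3, 3), jitter = quiet, seed = 4,
                                         frame_size = 128)
  ident <- lapply(series, function(r) similarity_transform())
  ft <- feature_series(series, ident, size = 128)
  expect_equal(nrow(ft), 6 * 17 * 2)
  # zero jitter: registered and unregistered values agree within resampling
  wide <- merge(ft[!ft$registered, c("subject", "day", "feature", "value")],
                ft[ft$registered, c("subject", "day", "feature", "value")],
                by = c("subject", "day", "feature"))
  expect_lt(max(abs(wide$value.x - wide$value.y)), 1)
})
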