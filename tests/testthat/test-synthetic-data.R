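test_that("vessel-tree generation is deterministic and well-formed", {
  spec <- vessel_tree_spec(seed = 7)
  a <- generate_vessel_tree(spec, 256)
  b <- generate_vessel_tree(spec, 256)
  expect_identical(a$mask, b$mask)
  expect_true(all(a$mask %in% c(0, 1)))
  for (s in 1:3) {
    frac <- mean(generate_vessel_tree(vessel_tree_spec(seed = s), 256)$mask)
    expect_gt(frac, 0.01); expect_lt(frac, 0.15)
  }
})

test_that("invalid vessel-tree specs are rejected at construction", {
  expect_error(vessel_tree_spec(n_main_vessels = 0))
  expect_error(vessel_tree_spec(branch_probability = 1.5))
  expect_error(vessel_tree_spec(width_px_range = c(6, 2)))
})

test_that("unbranched trees have one connected component per main vessel", {
  vm <- generate_vessel_tree(vessel_tree_spec(branch_probability = 0, seed = 3), 256)
  expect_equal(count_components(vm$mask), 5)
})

test_that("fundus rendering darkens vessels against a structured background", {
  vm <- generate_vessel_tree(vessel_tree_spec(seed = 7), 256)
  fd <- generate_fundus(vm, 11)
  expect_true(all(fd$pixels >= 0 & fd$pixels <= 255))
  expect_lt(mean(fd$pixels[vm$mask == 1]) + 20, mean(fd$pixels[vm$mask == 0]))
  # empty mask: background only, non-degenerate dynamic range
  empty <- vessel_mask(matrix(0, 128, 128))
  bg <- generate_fundus(empty, 2)
  expect_gt(diff(range(bg$pixels)), 0)
  # MI self-identity on generated content
  expect_lt(abs(mutual_information(fd, fd) - shannon_entropy(fd)), 1e-12)
})

test_that("noise-free RNFLT maps follow the profile, trend, and quadrant means", {
  flat <- rnflt_profile_spec(quadrant_means_um = c(temporal = 100, superior = 100,
                                                   nasal = 100, inferior = 100),
                             noise_sd_um = 0, session_sd_um = 0)
  m <- generate_rnflt_map(flat, day = 0, seed = 1)
  expect_equal(unname(range(m$thickness_um)), c(100, 100))

  sl <- rnflt_profile_spec(noise_sd_um = 0, session_sd_um = 0,
                           slope_um_per_day = -0.07)
  base <- rnflt_profile_spec(noise_sd_um = 0, session_sd_um = 0)
  d0 <- generate_rnflt_map(base, 0, 1)
  d100 <- generate_rnflt_map(sl, 100, 1)
  expect_equal(d100$thickness_um, d0$thickness_um - 7, tolerance = 1e-12)

  # quadrant averages of the generated map recover the specified means
  phi <- (0:99) * 3.6
  quad <- floor(((phi + 45) %% 360) / 90) + 1  # 1=T 2=S 3=N 4=I
  got <- vapply(1:4, function(q) mean(d0$thickness_um[, quad == q]), 0)
  expect_lt(max(abs(got - c(81.65, 112.17, 82.74, 132.22))), 0.5)
})

test_that("negative thickness after noise is clipped and reported", {
  thin <- rnflt_profile_spec(quadrant_means_um = c(temporal = 3, superior = 3,
                                                   nasal = 3, inferior = 3),
                             noise_sd_um = 10, session_sd_um = 0)
  m <- generate_rnflt_map(thin, 0, 1)
  expect_true(all(m$thickness_um >= 1))
  expect_gt(attr(m, "n_clipped"), 0)
})

test_that("longitudinal series honor the session design and ground truth", {
  quiet <- longitudinal_jitter(sd_tx_px = 0, sd_rot_deg = 0, sd_scale = 0,
                               drift_tx_px_per_day = 0, drift_ty_px_per_day = 0,
                               drift_rot_deg_per_day = 0)
  s0 <- simulate_longitudinal_series(2, c(3, 3), jitter = quiet, seed = 5,
                                     frame_size = 128)
  for (rec in s0) {
    expect_equal(unclass(rec$true_transform), unclass(similarity_transform()))
  }
  series <- simulate_longitudinal_series(3, c(8, 16, 16), seed = 2,
                                         frame_size = 128)
  expect_length(series, 40)
  expect_equal(sum(vapply(series, `[[`, TRUE, "reference")), 3)
  expect_true(all(vapply(series, function(r) r$day >= 0, TRUE)))
  # reference session carries the identity
  refs <- Filter(function(r) r$reference, series)
  for (r in refs) expect_equal(r$true_transform$scale, 1)
  # determinism
  series2 <- simulate_longitudinal_series(3, c(8, 16, 16), seed = 2,
                                          frame_size = 128)
  expect_identical(series[[10]]$fundus$pixels, series2[[10]]$fundus$pixels)
  expect_identical(series[[10]]$rnflt$thickness_um, series2[[10]]$rnflt$thickness_um)
})

test_that("jitter sampler rotation spread matches its nominal SD", {
  jit <- longitudinal_jitter(drift_tx_px_per_day = 0, drift_ty_px_per_day = 0,
                             drift_rot_deg_per_day = 0)
  env <- new.env(); env$n_redraws <- 0L
  set.seed(9)
  rots <- replicate(200, octlongreg:::.draw_transform(jit, 0, env)$rotation_deg)
  expect_lt(abs(sd(rots) - jit$sd_rot_deg) / jit$sd_rot_deg, 0.3)
})

test_that("a session warped back by the inverse truth matches the reference", {
  series <- simulate_longitudinal_series(1, 3, seed = 8, frame_size = 128)
  ref <- series[[1]]; tgt <- series[[3]]
  back <- apply_transform(tgt$vessels, invert_transform(tgt$true_transform))
  ok <- back$valid_mask & ref$vessels$valid_mask
  expect_lt(mean(abs(back$mask[ok] - ref$vessels$mask[ok])), 0.02)
})
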