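test_that("log-polar transform maps rotation and scale to axis shifts", {
  vm <- generate_vessel_tree(vessel_tree_spec(seed = 5), 256)
  lp0 <- log_polar_transform(vm)
  expect_equal(dim(lp0$grid), c(360, 384))
  # all-zero input -> all-zero grid
  expect_true(all(log_polar_transform(vessel_mask(matrix(0, 64, 64)))$grid == 0))

  # rotation by 10 degrees -> +10 angle-bin circular shift (1 deg/bin)
  lp1 <- log_polar_transform(apply_transform(vm, similarity_transform(0, 0, 10, 1)))
  shifted <- rbind(lp0$grid[351:360, ], lp0$grid[1:350, ])
  expect_lt(mean(abs(lp1$grid[, 30:300] - shifted[, 30:300])), 0.05)

  # scaling by 1.1 -> +round(ln(1.1)/D) log-radius-bin shift
  d <- log(lp0$r_max_px / lp0$r_min_px) / (lp0$n_logr_bins - 1)
  m <- round(log(1.1) / d)
  lps <- log_polar_transform(apply_transform(vm, similarity_transform(0, 0, 0, 1.1)))
  shifted2 <- cbind(matrix(0, 360, m), lp0$grid[, 1:(384 - m)])
  expect_lt(mean(abs(lps$grid[, 60:300] - shifted2[, 60:300])), 0.05)

  expect_error(log_polar_transform(vm, origin = c(-5, 10)), "inside the frame")
})

test_that("FFT cross-correlation finds shift-theorem peaks", {
  vm <- generate_vessel_tree(vessel_tree_spec(seed = 5), 256)
  lp0 <- log_polar_transform(vm)
  auto <- cross_correlate_logpolar(lp0, lp0)
  expect_equal(c(auto$rotation_shift_bins, auto$scale_shift_bins), c(0L, 0L))
  expect_equal(auto$peak_value, sum(lp0$grid^2), tolerance = 1e-9)

  # circular shift by 17 angle bins
  g17 <- rbind(lp0$grid[(360 - 16):360, ], lp0$grid[1:(360 - 17), ])
  lp17 <- lp0; lp17$grid <- g17
  cc <- cross_correlate_logpolar(lp0, lp17)
  expect_equal(cc$rotation_shift_bins, 17L)

  lpbad <- log_polar_transform(vm, n_logr_bins = 128)
  expect_error(cross_correlate_logpolar(lp0, lpbad), "geometries")
})

test_that("origin scan recovers translation, rotation and scale", {
  vm <- generate_vessel_tree(vessel_tree_spec(seed = 6), 256)
  ctr <- c((256 - 1) / 2, (256 - 1) / 2)
  params <- list(n_angle_bins = 360, n_logr_bins = 384, r_min_px = 2,
                 max_scale_shift_bins = 32)
  # aligned pair, single center candidate -> identity
  res0 <- lpcc_search_origins(vm, vm, matrix(ctr, 1), params)
  expect_equal(unclass(res0$misalignment), unclass(similarity_transform()))

  # pure translation with truth in the candidate set
  tt <- similarity_transform(6, -4, 0, 1)
  vt <- apply_transform(vm, tt)
  offs <- expand.grid(dx = -10:10, dy = -10:10)
  cand <- cbind(ctr[1] + offs$dx, ctr[2] + offs$dy)
  res <- lpcc_search_origins(vm, vt, cand, params)
  expect_equal(c(res$misalignment$tx_px, res$misalignment$ty_px), c(6, -4))
  expect_equal(nrow(res$stage_trace), nrow(cand))

  # rotation + scale warp recovered within one bin each
  tw <- similarity_transform(0, 0, 8, 1.05)
  vw <- apply_transform(vm, tw)
  resw <- lpcc_search_origins(vm, vw, matrix(ctr, 1), params)
  expect_lt(abs(resw$misalignment$rotation_deg - 8), 1)
  d <- log((min(dim(vm$mask)) / 2 - 1) / 2) / (384 - 1)
  expect_lt(abs(log(resw$misalignment$scale / 1.05)), 1.5 * d)
  expect_error(lpcc_search_origins(vm, vw, cand[0, , drop = FALSE], params),
               "empty")
})

test_that("two-level registration recovers ground truth within quantization", {
  vm <- generate_vessel_tree(vessel_tree_spec(seed = 9), 256)
  res0 <- lpcc_register(vm, vm)
  e0 <- recovery_error(res0$transform, similarity_transform())
  expect_lt(e0["tx"], 1); expect_lt(e0["ty"], 1)
  expect_lt(e0["rot"], 1); expect_lt(e0["scale"], 0.01)

  tt <- similarity_transform(12, -8, 5, 0.97)
  res <- lpcc_register(vm, apply_transform(vm, tt))
  e <- recovery_error(res$transform, tt)
  expect_lt(e["tx"], 1); expect_lt(e["ty"], 1)
  expect_lt(e["rot"], 1); expect_lt(e["scale"], 0.01)
  expect_false(res$boundary_hit)
})

test_that("translations beyond the search bound are flagged, never silent", {
  vm <- generate_vessel_tree(vessel_tree_spec(seed = 12), 256)
  tt <- similarity_transform(60, 0, 0, 1)
  vt <- apply_transform(vm, tt)
  flagged <- tryCatch({
    res <- suppressWarnings(lpcc_register(vm, vt))
    res$boundary_hit
  }, octlongreg_bound_violation = function(e) TRUE)
  expect_true(flagged)
})
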