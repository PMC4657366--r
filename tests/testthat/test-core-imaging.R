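test_that("identity transform is pixelwise exact for both interpolations", {
  set.seed(1)
  img <- image2d(matrix(runif(32 * 32, 0, 255), 32, 32))
  for (interp in c("bilinear", "nearest")) {
    w <- apply_transform(img, similarity_transform(), interp)
    expect_identical(w$pixels, img$pixels)
    expect_true(all(w$valid_mask))
  }
})

test_that("pure translation moves an impulse and invalidates the vacated strip", {
  m <- matrix(0, 33, 33); m[17, 17] <- 200
  w <- apply_transform(image2d(m), similarity_transform(5, 0, 0, 1))
  expect_equal(which(w$pixels == 200, arr.ind = TRUE)[1, ], c(row = 17, col = 22))
  expect_equal(sum(w$pixels), 200)
  expect_equal(sum(!w$valid_mask[1, ]), 5)  # 5-px strip on the left edge
})

test_that("90-degree rotation equals an exact quarter-turn array rotation", {
  set.seed(2)
  cb <- matrix((outer(1:32, 1:32, `+`) %% 2) * 200 + runif(1024, 0, 50), 32, 32)
  r90 <- apply_transform(image2d(cb), similarity_transform(0, 0, 90, 1), "nearest")
  rot_ccw <- function(m) t(m)[ncol(m):1, ]  # counter-clockwise as displayed
  expect_equal(r90$pixels, rot_ccw(cb))
  expect_true(all(r90$valid_mask))
})

test_that("transform composition matches sequential application", {
  expect_equal(unclass(compose_transforms(similarity_transform(),
                                          similarity_transform(3, -2, 10, 1.1))),
               unclass(similarity_transform(3, -2, 10, 1.1)))
  s <- compose_transforms(similarity_transform(1, 0, 0, 1),
                          similarity_transform(2, 0, 0, 1))
  expect_equal(c(s$tx_px, s$ty_px, s$rotation_deg, s$scale), c(3, 0, 0, 1))

  set.seed(3)
  o <- similarity_transform(0, 0, 30, 1)
  i <- similarity_transform(0, 0, 0, 2)
  pts <- matrix(runif(10, 0, 31), 5, 2)
  expect_lt(max(abs(transform_points(compose_transforms(o, i), pts, c(32, 32)) -
                    transform_points(o, transform_points(i, pts, c(32, 32)),
                                     c(32, 32)))), 1e-9)
})

test_that("warping forward then with the inverse recovers a smooth image", {
  xs <- seq(0, 4 * pi, length.out = 128)
  sm <- image2d(127 + 100 * outer(sin(xs), cos(xs)))
  tt <- similarity_transform(3.5, -2.25, 7, 1.04)
  rt <- apply_transform(apply_transform(sm, tt), invert_transform(tt))
  expect_lt(max(abs(rt$pixels[rt$valid_mask] - sm$pixels[rt$valid_mask])), 2)
  cc <- compose_transforms(invert_transform(tt), tt)
  expect_lt(max(abs(c(cc$tx_px, cc$ty_px, cc$rotation_deg, cc$scale - 1))), 1e-12)
})

test_that("non-positive scale is rejected as an invalid transform", {
  expect_error(similarity_transform(scale = 0), class = "octlongreg_invalid_transform")
  expect_error(similarity_transform(scale = -1), class = "octlongreg_invalid_transform")
})

test_that("overlap region is the per-pixel AND of validity masks", {
  ref <- image2d(matrix(1, 32, 32))
  t0 <- apply_transform(ref, similarity_transform())
  expect_true(all(overlap_region(ref, t0)$mask))

  t10 <- apply_transform(ref, similarity_transform(10, 0, 0, 1))
  ov <- overlap_region(ref, t10)
  expect_equal(sum(!ov$mask), 10 * 32)  # 10-px-wide excluded strip

  shifts <- list(c(5, 0), c(0, 5), c(-5, -5))
  tgts <- lapply(shifts, function(s)
    apply_transform(ref, similarity_transform(s[1], s[2], 0, 1)))
  ov3 <- overlap_region(ref, tgts)
  # brute-force per-pixel AND oracle
  expected <- ref$valid_mask
  for (tg in tgts) {
    for (i in 1:32) for (j in 1:32) {
      expected[i, j] <- expected[i, j] && tg$valid_mask[i, j]
    }
  }
  expect_identical(ov3$mask, expected)
  # order invariance
  expect_identical(overlap_region(ref, rev(tgts))$mask, ov3$mask)
  # empty overlap warns and flags rather than erroring
  far <- image2d(matrix(1, 32, 32),
                 valid_mask = matrix(FALSE, 32, 32))
  expect_warning(ove <- overlap_region(ref, far), "empty")
  expect_true(ove$empty)
})

test_that("PNG and JSON round-trips preserve masks and transforms", {
  set.seed(4)
  td <- withr_like_tempdir <- tempfile(); dir.create(td)
  img <- image2d(matrix(round(runif(16 * 16, 0, 255)), 16, 16))
  write_image_png(img, file.path(td, "img.png"))
  expect_equal(read_image_png(file.path(td, "img.png"))$pixels, img$pixels)

  vm <- vessel_mask(matrix(rbinom(16 * 16, 1, 0.2), 16, 16))
  write_vessel_mask_png(vm, file.path(td, "vm.png"))
  expect_identical(read_vessel_mask_png(file.path(td, "vm.png"))$mask, vm$mask)

  tt <- similarity_transform(3.25, -1.5, 2.4, 1.013)
  write_transform_json(tt, file.path(td, "t.json"))
  expect_equal(unclass(read_transform_json(file.path(td, "t.json"))), unclass(tt))
  unlink(td, recursive = TRUE)
})
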