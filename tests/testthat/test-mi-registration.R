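test_that("shannon entropy matches hand-tallied histograms", {
  expect_equal(shannon_entropy(image2d(matrix(100, 8, 8))), 0)
  two <- image2d(matrix(rep(c(10, 200), each = 32), 8, 8))
  expect_equal(shannon_entropy(two), 1)
  # bin counts {32, 16, 8, 8}: H = -(1/2 log 1/2 + 1/4 log 1/4 + 2 * 1/8 log 1/8)
  v <- c(rep(0, 32), rep(100, 16), rep(200, 8), rep(250, 8))
  expect_equal(shannon_entropy(image2d(matrix(v, 8, 8))), 1.75)
  expect_error(shannon_entropy(image2d(matrix(1, 4, 4),
                                       valid_mask = matrix(FALSE, 4, 4))),
               class = "octlongreg_degenerate_input")
})

test_that("mutual information obeys its identities and the triple-sum oracle", {
  set.seed(10)
  for (k in 1:5) {
    a <- image2d(matrix(runif(64, 0, 255), 8, 8))
    b <- image2d(matrix(runif(64, 0, 255), 8, 8))
    expect_lt(abs(mutual_information(a, b) - mi_triple_sum(a$pixels, b$pixels)),
              1e-12)
    expect_lt(abs(mutual_information(a, a) - shannon_entropy(a)), 1e-12)
    expect_lt(abs(mutual_information(a, b) - mutual_information(b, a)), 1e-12)
    expect_lte(mutual_information(a, b),
               min(shannon_entropy(a), shannon_entropy(b)) + 1e-12)
  }
  expect_equal(mutual_information(image2d(matrix(runif(64, 0, 255), 8, 8)),
                                  image2d(matrix(7, 8, 8))), 0)
})

test_that("histograms ignore invalid padding (masked pixels leave MI unchanged)", {
  set.seed(11)
  a <- image2d(matrix(runif(256, 0, 255), 16, 16))
  b <- image2d(matrix(runif(256, 0, 255), 16, 16))
  pad <- function(img) {
    p <- matrix(0, 24, 24); v <- matrix(FALSE, 24, 24)
    p[5:20, 5:20] <- img$pixels; v[5:20, 5:20] <- TRUE
    image2d(p, valid_mask = v)
  }
  expect_equal(mutual_information(pad(a), pad(b)), mutual_information(a, b))
  expect_equal(shannon_entropy(pad(a)), shannon_entropy(a))
})

test_that("search objective equals the criterion evaluated at the transform", {
  p <- mk_registration_pair(21, size = 128)
  tt <- similarity_transform(4, -3, 1.2, 1.01)
  obj <- octlongreg:::.mi_objective(p$ref_fundus, p$tgt_fundus, tt,
                                    mi_search_config())
  warped <- apply_transform(p$tgt_fundus, tt)
  expect_equal(obj, mutual_information(p$ref_fundus, warped), tolerance = 1e-12)
})

test_that("coarse search recovers on-grid shifts exactly and quantizes off-grid", {
  p <- mk_registration_pair(22, size = 128,
                            truth = similarity_transform(10, -5, 0, 1),
                            noise_sd = 0)
  res <- mi_coarse_register(p$ref_fundus, p$tgt_fundus)
  expect_equal(c(res$transform$tx_px, res$transform$ty_px,
                 res$transform$rotation_deg), c(-10, 5, 0))
  expect_equal(nrow(res$stage_trace), 11 * 11 * 11)

  p2 <- mk_registration_pair(23, size = 128,
                             truth = similarity_transform(12, 0, 0, 1),
                             noise_sd = 0)
  res2 <- mi_coarse_register(p2$ref_fundus, p2$tgt_fundus)
  expect_true(res2$transform$tx_px %in% c(-10, -15))
})

test_that("an aligned pair scores its maximum at the identity", {
  p <- mk_registration_pair(24, size = 128,
                            truth = similarity_transform(), noise_sd = 0)
  res <- mi_coarse_register(p$ref_fundus, p$tgt_fundus)
  expect_equal(unclass(res$transform), unclass(similarity_transform(0, 0, 0, 1)))
})

test_that("fine search refines to within one grid step and never degrades MI", {
  p <- mk_registration_pair(25, size = 256,
                            truth = similarity_transform(3, 2, 1.5, 0.95))
  res <- mi_register(p$ref_fundus, p$tgt_fundus)
  err <- recovery_error(res$transform, p$truth)
  expect_lt(err["tx"], 1); expect_lt(err["ty"], 1)
  expect_lt(err["rot"], 0.2); expect_lt(err["scale"], 0.01)
  # objective non-decreasing across the five fine stages
  tr <- res$stage_trace
  fine <- tr$objective[tr$stage != "coarse"]
  expect_true(all(diff(fine) >= -1e-12))
})

test_that("fine stages are monotone in the objective on random cases", {
  for (s in 26:28) {
    p <- mk_registration_pair(s, size = 128)
    res <- mi_fine_register(p$ref_fundus, p$tgt_fundus, similarity_transform())
    expect_true(all(diff(res$stage_trace$objective) >= -1e-12))
  }
})
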