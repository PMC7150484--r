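test_that("region means match direct masked summation", {
  const <- matrix(0.7, 6, 6)
  u <- matrix(0, 6, 6); u[2:4, 2:4] <- 1
  st <- region_means(const, u)
  expect_equal(st$c1, 0.7, tolerance = 1e-6)
  expect_equal(st$c2, 0.7, tolerance = 1e-6)
  img <- matrix(c(1, 0, 0, 0), 2, 2)
  u2 <- matrix(c(1, 0, 0, 0), 2, 2)
  st2 <- region_means(img, u2)
  expect_equal(st2$c1, 1, tolerance = 1e-7)
  expect_equal(st2$c2, 0)
  set.seed(8)
  im <- matrix(runif(64), 8, 8); um <- random_mask(8)
  st3 <- region_means(im, um)
  expect_equal(st3$c1, mean(im[um == 1]), tolerance = 1e-6)
  expect_equal(st3$c2, mean(im[um == 0]), tolerance = 1e-6)
  expect_true(region_means(im, matrix(1, 8, 8))$degenerate)
})

test_that("the balloon step is a cross dilation/erosion", {
  u <- matrix(0, 9, 9); u[5, 5] <- 1
  expect_equal(balloon_step(u, 0), u)
  d <- balloon_step(u, 1)
  expect_equal(sum(d), 5)
  expect_equal(d[4:6, 5], c(1, 1, 1))
  expect_equal(d[5, 4:6], c(1, 1, 1))
  set.seed(9)
  um <- random_mask(16)
  expect_equal(balloon_step(um, -1), oracle_reduce(um, oracle_cross(), "min"))
  expect_error(balloon_step(um, 2))
})

test_that("the attachment sign test follows the region-competition force", {
  # two-level 6x6 image, contour strictly between the levels
  img <- matrix(0.8, 6, 6); img[, 1:3] <- 0.2
  u <- matrix(0, 6, 6); u[, 1:2] <- 1   # contour one column short
  st <- region_means(img, u)
  out <- attachment_step(u, img, acwe_params(), st)
  # column 3 pixels are dark (near c1): enumerated sign test switches them in
  expect_equal(out[, 3], rep(1, 6))
  expect_equal(out[, 5:6], u[, 5:6])    # away from the contour: untouched
  # all-zero embedding has no contour, so nothing changes
  zero <- matrix(0, 6, 6)
  expect_equal(attachment_step(zero, img, acwe_params(),
                               list(c1 = 0.5, c2 = 0.5)), zero)
  # exact tie leaves the pixel unchanged
  tie <- matrix(0.5, 4, 4)
  ut <- matrix(0, 4, 4); ut[, 1:2] <- 1
  expect_equal(attachment_step(ut, tie, acwe_params(),
                               list(c1 = 0.5, c2 = 0.5)), ut)
})

test_that("one MACWE iteration is pixel-exact against the brute-force reference", {
  set.seed(123)
  p <- acwe_params(operator_set = k3(), iters_per_frame = 1L)
  for (rep in 1:25) {
    img <- matrix(runif(32 * 32), 32, 32)
    u <- random_mask(32)
    if (sum(u) == 0 || sum(u) == length(u)) next
    expect_equal(macwe_step(u, img, p),
                 oracle_macwe_step(u, img, oracle_k3_segments()))
  }
})

test_that("an exact two-region partition is a fixed point up to smoothing", {
  img <- matrix(0.8, 40, 40)
  truth <- hifutrack:::disk_mask(40, 40, c(20, 20), 12) * 1
  img[truth == 1] <- 0.2
  p <- acwe_params(operator_set = k3(), iters_per_frame = 1L)
  u1 <- macwe_step(truth, img, p)
  # any pixel differences must be smoothing-invariant boundary pixels
  expect_lt(sum(abs(u1 - truth)), 0.02 * sum(truth))
  u2 <- macwe_step(u1, img, p)
  expect_lt(sum(abs(u2 - u1)), 0.01 * sum(truth))
})

test_that("contour evolution converges on a clean disk and flags degeneracy", {
  img <- matrix(0.8, 80, 80)
  truth <- hifutrack:::disk_mask(80, 80, c(40, 40), 22) * 1
  img[truth == 1] <- 0.2
  init <- translate_mask(scale_mask(truth, 0.8), 4, 3)
  p <- acwe_params(operator_set = k3(), iters_per_frame = 25L)
  u <- evolve_frame(init, img, p)
  expect_gte(dsc(u, truth), 0.98)
  expect_false(attr(u, "degenerate"))
  expect_error(evolve_frame(matrix(0, 8, 8), matrix(0.5, 8, 8), p), "empty")
})

test_that("preoperative initialization maps through the rigid transform", {
  m <- matrix(0, 64, 64); m[20:30, 24:36] <- 1
  ident <- rigid_transform2d()
  expect_equal(init_from_preop(m, ident, c(64, 64)), m)
  # pure translation of 5 px (as mm, via the spacing)
  tr <- rigid_transform2d(translation_mm = c(5 * 0.5, 0))
  shifted <- init_from_preop(m, tr, c(64, 64), spacing_mm = 0.5)
  d <- hifutrack:::mask_centroid(shifted) - hifutrack:::mask_centroid(m)
  expect_lt(abs(d[1] - 5), 0.51)
  expect_lt(abs(d[2]), 0.51)
  # 90-degree rotation moves the centroid to its analytic image
  rot <- rigid_transform2d(rotation = pi / 2)
  rotated <- init_from_preop(m, rot, c(64, 64))
  ctr <- c(65, 65) / 2
  expected <- {
    v <- hifutrack:::mask_centroid(m) - ctr
    c(-v[2], v[1]) + ctr
  }
  expect_lt(max(abs(hifutrack:::mask_centroid(rotated) - expected)), 1)
  expect_error(init_from_preop(m * 0, ident, c(64, 64)), "empty")
  far <- rigid_transform2d(translation_mm = c(1000, 0))
  expect_error(init_from_preop(m, far, c(64, 64)), "outside")
})

test_that("the overflow guard passes candidates through when inactive", {
  img <- matrix(0.8, 30, 30)
  truth <- hifutrack:::disk_mask(30, 30, c(15, 15), 8) * 1
  img[truth == 1] <- 0.2
  st <- region_means(img, truth)
  cand <- balloon_step(truth, 1)
  # contour nowhere near the border: candidate returned verbatim
  out <- overflow_guard(cand, truth, img, acwe_params(), st)
  expect_false(attr(out, "guard_active"))
  attr(out, "guard_active") <- NULL
  expect_equal(out, cand)
  # low outward fraction: guard stays inactive even at the border
  img2 <- matrix(0.2, 30, 30)  # everything looks like background now
  st2 <- list(c1 = 0.9, c2 = 0.2)
  cand2 <- cand; cand2[1, ] <- 1
  out2 <- overflow_guard(cand2, truth, img2, acwe_params(), st2)
  expect_false(attr(out2, "guard_active"))
  # high outward fraction + border contact: only non-growing changes kept
  st3 <- list(c1 = 0.2, c2 = 0.9)
  out3 <- overflow_guard(cand2, truth, img2, acwe_params(), st3)
  expect_true(attr(out3, "guard_active"))
  attr(out3, "guard_active") <- NULL
  expect_equal(out3, cand2 * truth)
})
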