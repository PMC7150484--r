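small_cfg <- function(...) {
  defaults <- list(image_height = 96L, image_width = 96L, n_frames = 30L,
                   lesion_center0 = c(48, 48), lesion_axes0 = c(16, 12),
                   internal_blobs = list(), bladder = NULL,
                   drift_px_per_frame = c(0, 0), oscillation = c(0, 25),
                   deform_amplitude = 0, seed = 5L)
  do.call(phantom_config, utils::modifyList(defaults, list(...)))
}

test_that("the motion schedule evaluates drift, oscillation and jumps", {
  cfg <- small_cfg()
  expect_equal(lesion_geometry(cfg, 5)$center, c(48, 48))
  cfg_d <- small_cfg(drift_px_per_frame = c(0, 1), n_frames = 12L)
  expect_equal(lesion_geometry(cfg_d, 10)$center[2], 48 + 10)
  # jump schedule evaluated by hand: displacement applies from its frame on
  cfg_j <- small_cfg(jumps = list(list(frame = 20, displacement = c(15, 0))))
  expect_equal(lesion_geometry(cfg_j, 25)$center, c(48 + 15, 48))
  expect_equal(lesion_geometry(cfg_j, 19)$center, c(48, 48))
  expect_error(lesion_geometry(cfg, 30), "out of range")
  expect_error(lesion_geometry(cfg, -1), "out of range")
})

test_that("rendering is reproducible and respects the noiseless limit", {
  cfg <- small_cfg()
  expect_identical(render_frame(cfg, 3), render_frame(cfg, 3))
  tpl <- render_frame(cfg, 3, noiseless = TRUE)
  expect_equal(sort(unique(as.vector(tpl))), c(0.35, 0.6))
  expect_false(identical(render_frame(cfg, 3), render_frame(cfg, 4)))
  expect_error(phantom_config(lesion_axes0 = c(0, 10)), "degenerate")
  expect_error(phantom_config(lesion_intensity = 1.2), "0, 1")
})

test_that("speckle is multiplicative with unit mean", {
  cfg <- small_cfg(speckle_shape = 50, image_height = 128L,
                   image_width = 128L, lesion_center0 = c(64, 64))
  fr <- render_frame(cfg, 0)
  tpl <- render_frame(cfg, 0, noiseless = TRUE)
  bg <- tpl == 0.6  # background never clips at shape 50
  expect_gt(sum(bg), 1e4)
  ratio <- fr[bg] / tpl[bg]
  expect_lt(abs(mean(ratio) - 1), 0.01)
  # lesion mean within 3 SEM of the configured echogenicity
  les <- tpl == 0.35
  sem <- 0.35 / sqrt(50) / sqrt(sum(les))
  expect_lt(abs(mean(fr[les]) - 0.35), 3 * sem)
})

test_that("sequences carry exact truth masks and event logs", {
  cfg1 <- small_cfg(n_frames = 1L)
  sq1 <- generate_phantom_sequence(cfg1)
  a <- sum(sq1$truth_masks[[1]])
  analytic <- pi * 16 * 12
  perimeter <- pi * (3 * (16 + 12) - sqrt((3 * 16 + 12) * (16 + 3 * 12)))
  expect_lt(abs(a - analytic), perimeter)
  expect_equal(nrow(sq1$events), 0L)

  cfg_j <- small_cfg(jumps = list(list(frame = 10, displacement = c(9, 5))))
  sq <- generate_phantom_sequence(cfg_j)
  expect_equal(sq$events$frame, 10)
  d <- hifutrack:::mask_centroid(sq$truth_masks[[11]]) -
       hifutrack:::mask_centroid(sq$truth_masks[[10]])
  expect_lt(max(abs(d - c(9, 5))), 1)
  # determinism of the full sequence
  expect_identical(generate_phantom_sequence(cfg_j)$frames,
                   sq$frames)
})

test_that("mask centroids follow the configured geometry", {
  cfg <- phantom_config(image_height = 96L, image_width = 96L, n_frames = 20L,
                        lesion_center0 = c(48, 40), lesion_axes0 = c(16, 12),
                        internal_blobs = list(), bladder = NULL,
                        drift_px_per_frame = c(0.2, 0.3),
                        oscillation = c(1.5, 10), deform_amplitude = 0.05,
                        seed = 2L)
  sq <- generate_phantom_sequence(cfg)
  for (t in c(0L, 7L, 19L)) {
    ctr <- hifutrack:::mask_centroid(sq$truth_masks[[t + 1L]])
    expect_lt(max(abs(ctr - lesion_geometry(cfg, t)$center)), 1)
  }
})

test_that("a lesion leaving the image is rejected unless truncation is allowed", {
  cfg <- small_cfg(drift_px_per_frame = c(0, 3))
  expect_error(generate_phantom_sequence(cfg), "frame time 13")
  cfg_t <- small_cfg(drift_px_per_frame = c(0, 3), allow_truncation = TRUE,
                     n_frames = 15L)
  sq <- generate_phantom_sequence(cfg_t)
  expect_true(all(vapply(sq$truth_masks, sum, numeric(1)) > 0))
})

test_that("the dark out-of-fan band overrides content and truth", {
  cfg <- phantom_preset("truncated", seed = 0)
  sq <- generate_phantom_sequence(cfg)
  fr <- sq$frames[[1]]
  expect_lt(mean(fr[, 1:30]), 0.1)
  expect_equal(sum(sq$truth_masks[[1]][, 1:30]), 0)
  expect_gt(sum(sq$truth_masks[[1]]), 0)
})
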