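test_that("the treatment region is the central quarter of the lesion", {
  les <- hifutrack:::disk_mask(160, 160, c(80, 80), 40) * 1
  reg <- treatment_region(les)
  expect_lt(abs(sum(reg) / sum(les) - 0.25), 0.02)
  expect_true(all(reg <= les))                      # containment
  # the region is (approximately) the concentric half-radius disk
  inner <- hifutrack:::disk_mask(160, 160, c(80, 80), 20) * 1
  expect_gt(dsc(reg, inner), 0.98)
  expect_error(treatment_region(les * 0), "empty")
  tiny <- matrix(0, 10, 10); tiny[5, 5] <- 1
  expect_error(treatment_region(tiny), "too small")
})

test_that("foci lie on the centroid-anchored grid inside the region", {
  # disk region of radius 20 px at 0.25 mm/px = 5 mm; 5 mm pitch
  reg <- hifutrack:::disk_mask(200, 200, c(100, 100), 20) * 1
  foci <- distribute_foci_2d(reg, spacing_mm = 5, pixel_spacing_mm = 0.25)
  expect_equal(nrow(foci), 5)   # centre plus four axis neighbours
  ctr <- (hifutrack:::mask_centroid(reg) - 1) * 0.25
  rel <- cbind(foci$y_mm - ctr[1], foci$x_mm - ctr[2])
  expect_true(all(rel %in% c(-5, 0, 5)))
  expect_true(all(rowSums(abs(rel)) <= 5 + 1e-9))
  # empty region: no foci, no error
  expect_equal(nrow(distribute_foci_2d(reg * 0, 5, 0.25)), 0)
  # default grid pitch is 0.5 cm
  expect_equal(formals(distribute_foci_2d)$spacing_mm, 5)
})

test_that("focus sets equal brute-force grid enumeration on analytic disks", {
  for (r_mm in c(10, 15, 20)) {
    px <- 0.25
    r_px <- r_mm / px
    les <- hifutrack:::disk_mask(400, 400, c(200, 200), r_px) * 1
    reg <- treatment_region(les)
    foci <- distribute_foci_2d(reg, 5, px)
    # independent enumeration: grid points within the half-radius disk
    ctr <- (hifutrack:::mask_centroid(reg) - 1) * px
    cand <- expand.grid(i = -10:10, j = -10:10)
    keep <- sqrt((cand$i * 5)^2 + (cand$j * 5)^2) <= r_mm / 2
    expect_equal(nrow(foci), sum(keep))
    # every focus lies inside the lesion
    rr <- round(foci$y_mm / px) + 1; cc <- round(foci$x_mm / px) + 1
    expect_true(all(les[cbind(rr, cc)] == 1))
  }
})

test_that("3D assembly stacks per-slice plans with monotone focus counts", {
  # sphere-like stack: disk radius shrinking away from the equator
  radii <- c(10, 25, 35, 25, 10)
  slices <- lapply(seq_along(radii), function(i)
    list(slice_index = i - 1L,
         lesion_mask = hifutrack:::disk_mask(120, 120, c(60, 60), radii[i]) * 1))
  plan <- assemble_3d(slices, slice_spacing_mm = 5, spacing_mm = 5,
                      pixel_spacing_mm = 0.5)
  counts <- vapply(plan$slices, function(s) nrow(s$foci), integer(1))
  mid <- which.max(counts)
  expect_true(all(diff(counts[1:mid]) >= 0))
  expect_true(all(diff(counts[mid:length(counts)]) <= 0))
  expect_equal(vapply(plan$slices, `[[`, numeric(1), "z_mm"),
               (seq_along(radii) - 1) * 5)
  # single slice reproduces the 2D distribution
  single <- assemble_3d(slices[3], 5, 5, 0.5)
  expect_equal(single$slices[[1]]$foci,
               distribute_foci_2d(treatment_region(slices[[3]]$lesion_mask),
                                  5, 0.5))
  # empty slice yields an empty layer, duplicate indices are rejected
  empt <- assemble_3d(list(list(slice_index = 0L,
                                lesion_mask = matrix(0, 20, 20))), 5, 5, 0.5)
  expect_equal(nrow(empt$slices[[1]]$foci), 0)
  expect_error(assemble_3d(list(list(slice_index = 1L, lesion_mask = matrix(1, 4, 4)),
                                list(slice_index = 1L, lesion_mask = matrix(1, 4, 4))),
                           5, 5, 0.5), "duplicate")
})

test_that("plans export deterministically as JSON", {
  les <- hifutrack:::disk_mask(100, 100, c(50, 50), 30) * 1
  plan <- assemble_3d(list(list(slice_index = 0L, lesion_mask = les)),
                      5, 5, 0.35)
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  write_plan_json(plan, f1)
  write_plan_json(plan, f2)
  expect_identical(readLines(f1), readLines(f2))
  parsed <- jsonlite::read_json(f1)
  expect_equal(parsed$spacing_mm, 5)
  expect_equal(length(parsed$slices), 1)
})
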