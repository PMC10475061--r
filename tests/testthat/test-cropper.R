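# Mask -> region -> classifier-input pipeline.

test_that("mask_to_region returns exact boxes and handles degenerate masks", {
  m <- matrix(0, 64, 64)
  m[11:20, 21:30] <- 1  # rows 10-19, cols 20-29 in 0-based terms
  r <- mask_to_region(m, margin = 0)
  expect_equal(unclass(r)[c("row_start", "row_end", "col_start", "col_end")],
               list(row_start = 10L, row_end = 20L, col_start = 20L, col_end = 30L))
  full <- mask_to_region(matrix(1, 32, 32), margin = 0)
  expect_equal(c(full$row_start, full$row_end, full$col_start, full$col_end),
               c(0L, 32L, 0L, 32L))
  expect_error(mask_to_region(matrix(0, 8, 8)), class = "svpnet_data_error")
  expect_error(mask_to_region(matrix(0.5, 8, 8)), class = "svpnet_contract_error")
})

test_that("largest component wins, against the flood-fill oracle", {
  set.seed(120)
  for (rep in 1:10) {
    m <- matrix(0, 40, 40)
    # two well-separated rectangles of different sizes
    m[2:6, 2:11] <- 1                     # 50 px
    r0 <- sample(15:25, 1); c0 <- sample(12:25, 1)
    m[r0:(r0 + 9), c0:(c0 + 13)] <- 1     # 140+ px
    want <- oracle_largest_component_bbox(m)
    got <- mask_to_region(m, margin = 0)
    side <- max(want[2] - want[1], want[4] - want[3])
    expect_equal(got$row_end - got$row_start, side)  # square-padded
    expect_equal(got$col_end - got$col_start, side)
    # the box contains the oracle component box
    expect_lte(got$row_start, want[1]); expect_gte(got$row_end, want[2])
    expect_lte(got$col_start, want[3]); expect_gte(got$col_end, want[4])
  }
})

test_that("margin expands the region proportionally", {
  m <- matrix(0, 64, 64)
  m[21:40, 21:40] <- 1  # 20 px square, 0-based (20, 40)
  r <- mask_to_region(m, margin = 0.25)
  expect_equal(c(r$row_start, r$row_end), c(15L, 45L))
  expect_equal(c(r$col_start, r$col_end), c(15L, 45L))
})

test_that("aggregate_regions takes the per-coordinate median", {
  r1 <- bounding_region(10, 20, 10, 20)
  expect_identical(aggregate_regions(list(r1, r1, r1)), r1)
  outlier <- bounding_region(0, 64, 0, 64)
  regs <- c(rep(list(r1), 9), list(outlier))
  expect_identical(aggregate_regions(regs), r1)
  r2 <- bounding_region(12, 22, 12, 22)
  r3 <- bounding_region(14, 24, 14, 24)
  med <- aggregate_regions(list(r1, r2, r3))
  expect_equal(c(med$row_start, med$row_end), c(12L, 22L))
  expect_error(aggregate_regions(list()), class = "svpnet_data_error")
})

test_that("crop_clip honors the classifier contract", {
  set.seed(121)
  frames <- array(runif(40 * 80 * 80), c(40, 80, 80))
  v <- svp_video(frames)
  out <- crop_clip(v, bounding_region(8, 72, 8, 72))
  expect_identical(dim(out), c(30L, 64L, 64L, 1L))
  expect_true(all(out >= 0 & out <= 1))
  # deterministic
  expect_identical(out, crop_clip(v, bounding_region(8, 72, 8, 72)))
  # a region that is already 64x64 is copied pixel for pixel
  out2 <- crop_clip(v, bounding_region(8, 72, 8, 72), size = 64)
  expect_identical(out2[5, , , 1], frames[5, 9:72, 9:72])
  expect_error(crop_clip(v, bounding_region(0, 100, 0, 64)),
               class = "svpnet_contract_error")
  expect_error(crop_clip(svp_video(frames[1:20, , , drop = FALSE]),
                         bounding_region(0, 64, 0, 64)),
               class = "svpnet_contract_error")
})

test_that("luminance conversion matches the Rec.601 weights", {
  set.seed(122)
  rgb <- array(runif(30 * 64 * 64 * 3), c(30, 64, 64, 3))
  v <- svp_video(rgb)
  out <- crop_clip(v, bounding_region(0, 64, 0, 64))
  lum <- 0.299 * rgb[7, , , 1] + 0.587 * rgb[7, , , 2] + 0.114 * rgb[7, , , 3]
  expect_equal(out[7, , , 1], lum, tolerance = 1e-12)
})

test_that("localize_and_crop falls back to a center crop only when allowed", {
  frames <- array(runif(30 * 64 * 64), c(30, 64, 64))
  v <- svp_video(frames)
  empty <- list(matrix(0, 64, 64))
  expect_error(localize_and_crop(v, empty), class = "svpnet_data_error")
  lc <- localize_and_crop(v, empty, fallback_center = TRUE)
  expect_identical(dim(lc$input), c(30L, 64L, 64L, 1L))
})
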