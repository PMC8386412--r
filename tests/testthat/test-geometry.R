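test_that("detect_spot localizes a bright disk to within 2 px / 3 px radius", {
  img <- make_disk_image(256, list(c(128, 128, 40, 0.9)), background = 0.1)
  circ <- detect_spot(img, radius_range = c(20, 60))
  expect_lte(abs(circ$center_row - 128), 2)
  expect_lte(abs(circ$center_col - 128), 2)
  expect_lte(abs(circ$radius - 40), 3)
  expect_gt(circ$score, 0.5)
})

test_that("detect_spot signals spot-not-found on a structureless image", {
  img <- plate_image(matrix(0.5, 128, 128), id = "flat")
  expect_error(detect_spot(img), class = "ringscan_spot_not_found")
})

test_that("the radius range excludes distractor disks", {
  img <- make_disk_image(256, list(c(100, 90, 40, 0.9), c(200, 200, 15, 0.9)),
                         background = 0.1)
  circ <- detect_spot(img, radius_range = c(30, 50))
  expect_lte(abs(circ$center_row - 100), 2)
  expect_lte(abs(circ$center_col - 90), 2)
  expect_lte(abs(circ$radius - 40), 3)
})

test_that("detect_spot validates the radius range", {
  img <- make_disk_image(128)
  expect_error(detect_spot(img, radius_range = c(0, 30)), "radius_range")
  expect_error(detect_spot(img, radius_range = c(10, 80)), "radius_range")
})

test_that("detect_plate_edge finds the rim radius to within 1%", {
  img <- make_disk_image(384, list(c(192, 192, 160, 0.6)), background = 0.05)
  circ <- detect_plate_edge(img)
  expect_lte(abs(circ$radius - 160) / 160, 0.01)
  expect_lte(abs(circ$center_row - 192), 2)
  expect_lte(abs(circ$center_col - 192), 2)
})

test_that("detect_plate_edge rejects images with no circular boundary", {
  set.seed(1)
  img <- plate_image(matrix(runif(192 * 192), 192, 192), id = "noise")
  expect_error(detect_plate_edge(img), class = "ringscan_plate_not_found")
})

test_that("detect_plate_edge returns the outer circle, not the inner spot", {
  img <- make_disk_image(384, list(c(192, 192, 160, 0.5), c(192, 192, 25, 0.95)),
                         background = 0.05)
  circ <- detect_plate_edge(img)
  expect_lte(abs(circ$radius - 160) / 160, 0.01)
})

test_that("fallback_spot recovers the center of a bright blob", {
  img <- make_disk_image(256, list(c(120, 140, 30, 0.9)), background = 0.2)
  circ <- fallback_spot(img)
  expect_lte(abs(circ$center_row - 120), 2)
  expect_lte(abs(circ$center_col - 140), 2)
  expect_lte(abs(circ$radius - 30), 3)
  expect_equal(circ$score, 0)
})

test_that("to_polar on a uniform image is uniform", {
  img <- plate_image(matrix(0.5, 128, 128))
  pol <- to_polar(img, c(64.5, 64.5), r_max = 50, n_angles = 36)
  expect_equal(dim(pol$values), c(50, 36))
  expect_equal(max(abs(pol$values - 0.5)), 0, tolerance = 1e-12)
})

test_that("to_polar rows are constant for a radially symmetric image", {
  n <- 129
  ctr <- c(65, 65)
  d <- sqrt((matrix(1:n, n, n) - ctr[1])^2 +
            (matrix(1:n, n, n, byrow = TRUE) - ctr[2])^2)
  img <- plate_image(pmin(d / 100, 1), id = "cone")
  pol <- to_polar(img, ctr, r_max = 55, n_angles = 90)
  row_sd <- apply(pol$values, 1, stats::sd)
  expect_lt(max(row_sd), 0.01)
  # and the per-row mean matches brute-force distance binning
  oracle <- brute_radial_binning(img, ctr, n_bins = 55)
  expect_lt(max(abs(rowMeans(pol$values) - oracle)), 0.02)
})

test_that("a bright angular sector occupies the expected polar columns", {
  n <- 129
  ctr <- c(65, 65)
  rows <- matrix(1:n, n, n)
  cols <- matrix(1:n, n, n, byrow = TRUE)
  ang <- (atan2(ctr[1] - rows, cols - ctr[2]) * 180 / pi) %% 360
  px <- matrix(0, n, n)
  px[ang >= 0 & ang < 90] <- 1
  img <- plate_image(px, id = "sector")
  n_angles <- 36
  pol <- to_polar(img, ctr, r_max = 40, n_angles = n_angles)
  # drop innermost radii where interpolation straddles the apex
  body <- pol$values[10:40, ]
  bright <- colSums(body > 0.5) == nrow(body)
  expect_equal(sum(bright), ceiling(n_angles / 4))
})

test_that("rotating the image by a bin multiple permutes polar columns", {
  set.seed(3)
  n <- 121
  base <- matrix(0.2, n, n)
  base[40:60, 70:90] <- 0.9
  base[80:100, 30:45] <- 0.6
  img <- plate_image(ringscan:::.gauss_blur(base, 2), id = "asym")
  ctr <- c((n + 1) / 2, (n + 1) / 2)
  n_angles <- 36
  pol0 <- to_polar(img, ctr, r_max = 45, n_angles = n_angles)
  rot <- plate_image(rotate90_ccw(img$pixels), id = "rot")
  pol90 <- to_polar(rot, ctr, r_max = 45, n_angles = n_angles)
  # content rotated +90 degrees CCW: the rotated plate at angle theta shows
  # the original at theta - 90
  shift <- n_angles / 4
  permuted <- pol0$values[, ((seq_len(n_angles) - 1 - shift) %% n_angles) + 1]
  expect_lt(max(abs(pol90$values - permuted)), 0.01)
  # row multisets unchanged within interpolation tolerance
  expect_lt(max(abs(apply(pol90$values, 1, sort) - apply(pol0$values, 1, sort))),
            0.01)
})

test_that("to_polar truncates out-of-frame radii and records it", {
  img <- plate_image(matrix(0.5, 128, 128))
  pol <- to_polar(img, c(64.5, 64.5), r_max = 100, n_angles = 36)
  expect_false(is.na(pol$truncated_at))
  expect_lte(pol$n_radii, 63)
  expect_error(to_polar(img, c(64, 64), r_max = -1), "r_max")
  expect_error(to_polar(img, c(64, 64), r_max = 30, n_angles = 4), "n_angles")
})

test_that("pixel-to-mm conversion is exact, linear and invertible", {
  cal <- calibration(plate_circle(100, 100, 500), plate_diameter_mm = 100)
  expect_identical(px_to_mm(30, cal), 3)
  expect_identical(px_to_mm(0, cal), 0)
  expect_identical(mm_to_px(px_to_mm(123.456, cal), cal), 123.456)
  # linear and strictly monotone
  v <- sort(runif(50, 0, 500))
  out <- px_to_mm(v, cal)
  expect_true(all(diff(out) > 0))
  expect_equal(px_to_mm(2 * v, cal), 2 * out)
  # manual override bypasses the circle
  cal2 <- calibration(mm_per_px = 0.25)
  expect_identical(px_to_mm(8, cal2), 2)
  expect_error(calibration(), "plate circle|mm_per_px")
  expect_error(calibration(mm_per_px = -1), "positive")
})
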