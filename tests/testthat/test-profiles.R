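polar_from_matrix <- function(values, radial_step = 1) {
  structure(
    list(values = values, n_radii = nrow(values), n_angles = ncol(values),
         radial_step = radial_step, center = c(0, 0), truncated_at = NA_real_),
    class = "polar_image"
  )
}

test_that("clockscan_profile averages angular slices", {
  pol <- polar_from_matrix(matrix(0.5, 20, 12))
  expect_equal(clockscan_profile(pol)$intensity, rep(0.5, 20))
  half <- polar_from_matrix(cbind(matrix(1, 20, 6), matrix(0, 20, 6)))
  expect_equal(clockscan_profile(half)$intensity, rep(0.5, 20))
  expect_equal(clockscan_profile(half)$kind, "mean")
})

test_that("clockscan profile of a synthetic plate matches pixel binning", {
  tr <- small_world(noise_sigma = 0.02, gradient_amplitude = 0, seed = 5)
  img <- generate_plate(tr)$image
  ctr <- c((tr$img_size + 1) / 2, (tr$img_size + 1) / 2)
  pol <- to_polar(img, ctr, r_max = 100, n_angles = 360)
  prof <- clockscan_profile(pol)
  oracle <- brute_radial_binning(img, ctr, n_bins = pol$n_radii)
  expect_lt(max(abs(prof$intensity - oracle)), 0.02)
})

test_that("median_profile is the per-radius median and resists occlusions", {
  pol <- polar_from_matrix(matrix(0.3, 15, 10))
  expect_equal(median_profile(pol)$intensity, rep(0.3, 15))
  # 90% of columns at 0.8, 10% occluded to 0: median stays 0.8
  occ <- polar_from_matrix(cbind(matrix(0.8, 15, 18), matrix(0, 15, 2)))
  expect_equal(median_profile(occ)$intensity, rep(0.8, 15))
  # repeating 0.2, 0.4, 0.6 -> median 0.4
  rep3 <- polar_from_matrix(matrix(rep(c(0.2, 0.4, 0.6), 5), 15, 15, byrow = TRUE))
  expect_equal(median_profile(rep3)$intensity, rep(0.4, 15))
})

test_that("mean and median profiles agree when rows are constant", {
  set.seed(2)
  vals <- matrix(rep(runif(30), 16), 30, 16)
  pol <- polar_from_matrix(vals)
  expect_equal(clockscan_profile(pol)$intensity, median_profile(pol)$intensity)
})

test_that("median profile is invariant to a sub-majority of corrupted columns", {
  set.seed(4)
  base <- runif(25)
  n_angles <- 21
  for (n_bad in c(1, 5, 10)) { # up to floor((n_angles - 1) / 2)
    vals <- matrix(base, 25, n_angles)
    vals[, seq_len(n_bad)] <- matrix(runif(25 * n_bad), 25, n_bad)
    expect_equal(median_profile(polar_from_matrix(vals))$intensity, base)
  }
})

test_that("smooth_profile preserves constants and affine interiors", {
  const <- radial_profile(rep(0.4, 40), kind = "mean")
  expect_equal(smooth_profile(const, 5)$intensity, rep(0.4, 40))
  ramp <- radial_profile(seq(0.1, 0.9, length.out = 40), kind = "mean")
  sm <- smooth_profile(ramp, 5)$intensity
  expect_equal(sm[3:38], ramp$intensity[3:38], tolerance = 1e-12)
  expect_equal(smooth_profile(ramp, 5)$kind, "filtered")
})

test_that("a unit impulse spreads to window weights", {
  x <- rep(0, 40); x[20] <- 1
  sm <- smooth_profile(radial_profile(x, kind = "mean"), 5)$intensity
  expect_equal(sm[18:22], rep(0.2, 5), tolerance = 1e-12)
  expect_equal(sm[c(1:17, 23:40)], rep(0, 35), tolerance = 1e-12)
})

test_that("smoothing windows are validated", {
  p <- radial_profile(runif(40), kind = "mean")
  expect_error(smooth_profile(p, 4), "odd")
  expect_error(smooth_profile(p, 1), "odd")
  expect_error(smooth_profile(p, 21), "odd|length/4")
})

test_that("moving average never leaves the input range", {
  set.seed(9)
  for (i in 1:20) {
    x <- runif(60)
    sm <- smooth_profile(radial_profile(x, kind = "median"), 11)$intensity
    expect_gte(min(sm), min(x) - 1e-12)
    expect_lte(max(sm), max(x) + 1e-12)
  }
})

test_that("savitzky_golay smoothing is available behind the same interface", {
  # SG of order 2 reproduces a quadratic exactly away from the boundary
  t <- seq_len(60)
  q <- 0.2 + 0.01 * t + 0.0001 * t^2
  q <- q / max(q) * 0.8
  sm <- smooth_profile(radial_profile(q, kind = "mean"), 9,
                       method = "savitzky_golay")$intensity
  expect_equal(sm[5:56], q[5:56], tolerance = 1e-9)
})

test_that("derivative uses central differences and enforces filtering order", {
  const <- smooth_profile(radial_profile(rep(0.5, 40), kind = "mean"), 5)
  expect_equal(derivative(const)$intensity, rep(0, 40))
  s <- 0.8 / 39
  ramp <- radial_profile(seq(0.1, 0.9, length.out = 40), kind = "filtered")
  d <- derivative(ramp)$intensity
  expect_equal(d[2:39], rep(s, 38), tolerance = 1e-12)
  expect_equal(derivative(ramp)$kind, "derivative")
  expect_error(derivative(radial_profile(runif(40), kind = "mean")), "filtered")
})

test_that("a filtered blurred edge has its derivative extremum at the midpoint", {
  # real edges are blurred sigmoids; their filtered derivative has a unique
  # interior minimum at the transition center
  x <- 0.2 + 0.6 * stats::pnorm(-(seq_len(50) - 25.5) / 2)
  filt <- smooth_profile(radial_profile(x, kind = "median"), 7)
  d <- derivative(filt)$intensity
  expect_lte(abs(which.min(d) - 25.5), 1)
})

test_that("derivative sign changes are bounded by plateau boundaries", {
  # piecewise-monotone: up, flat, down -> at most 2 sign changes after
  # smoothing (ignoring zero-derivative plateaus)
  x <- c(seq(0.1, 0.8, length.out = 20), rep(0.8, 15),
         seq(0.8, 0.2, length.out = 20))
  d <- derivative(smooth_profile(radial_profile(x, kind = "mean"), 5))$intensity
  sgn <- sign(d[abs(d) > 1e-9])
  expect_lte(sum(diff(sgn) != 0), 2)
})

test_that("radial_profile validates kinds and ranges", {
  expect_error(radial_profile(rep(0.5, 4)), "8 bins")
  expect_error(radial_profile(rep(1.5, 20), kind = "mean"), "\\[0, 1\\]")
  d <- radial_profile(rep(-0.5, 20), kind = "derivative")
  expect_s3_class(d, "radial_profile")
  expect_equal(profile_radii(d)[1:3], c(0.5, 1.5, 2.5))
  cal <- calibration(mm_per_px = 0.2)
  expect_equal(profile_radii(d, cal)[1], 0.1)
})
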