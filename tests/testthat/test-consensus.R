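polar_stub <- function(values, radial_step = 1) {
  structure(
    list(values = values, n_radii = nrow(values), n_angles = ncol(values),
         radial_step = radial_step, center = c(0, 0), truncated_at = NA_real_),
    class = "polar_image"
  )
}

test_that("bootstrap_composite resamples columns with replacement, deterministically", {
  vals <- matrix(rep(0.7, 20 * 12), 20, 12)
  pol <- polar_stub(vals)
  set.seed(1)
  expect_equal(bootstrap_composite(pol)$values, vals)

  p <- polar_stub(matrix(runif(20 * 30), 20, 30))
  set.seed(5)
  r1 <- bootstrap_composite(p)
  set.seed(5)
  r2 <- bootstrap_composite(p)
  expect_identical(r1$values, r2$values)
  expect_identical(dim(r1$values), c(20L, 30L))
  # resampled columns are drawn from the input columns
  expect_true(all(r1$values %in% p$values))
})

test_that("bootstrap coverage matches the 1 - 1/e law", {
  n_angles <- 360
  pol <- polar_stub(matrix(0.5, 8, n_angles))
  set.seed(17)
  frac <- replicate(500, {
    cols <- sample.int(n_angles, n_angles, replace = TRUE)
    length(unique(cols)) / n_angles
  })
  expect_lt(abs(mean(frac) - (1 - (1 - 1 / n_angles)^n_angles)), 0.02)
})

test_that("extract_candidates finds the valley and ring bounds of a step pattern", {
  # distinct edge magnitudes so every sequential argmin/argmax is unique:
  # drops of 0.70 (spot->valley), +0.60 (valley->ring), -0.65 (ring->lawn)
  x <- c(rep(0.9, 20), rep(0.2, 25), rep(0.8, 25), rep(0.15, 30))
  filt <- smooth_profile(radial_profile(x, kind = "median"), 5)
  cand <- extract_candidates(filt, spot_hint = 14, noise_floor = 0.02)
  expect_lte(abs(cand$valley_inner - 20), 2)
  expect_lte(abs(cand$valley_outer - 45), 2)
  expect_lte(abs(cand$ring_outer - 70), 2)
  expect_lte(abs(cand$spot_edge - 20), 2)
})

test_that("a constant profile yields no features", {
  filt <- smooth_profile(radial_profile(rep(0.5, 60), kind = "median"), 5)
  cand <- extract_candidates(filt, spot_hint = 10, noise_floor = 0)
  expect_true(all(is.na(unlist(cand))))
})

test_that("a spot-only profile yields a spot edge but no valley or ring", {
  x <- c(rep(0.9, 15), rep(0.2, 60)) # single descending edge, no recovery
  filt <- smooth_profile(radial_profile(x, kind = "median"), 5)
  cand <- extract_candidates(filt, spot_hint = 12, noise_floor = 0.02)
  expect_false(is.na(cand$spot_edge))
  expect_lte(abs(cand$spot_edge - 15), 2)
  expect_true(is.na(cand$valley_inner))
  expect_true(is.na(cand$valley_outer))
  expect_true(is.na(cand$ring_outer))
})

test_that("extract_candidates validates inputs", {
  raw <- radial_profile(runif(40), kind = "median")
  expect_error(extract_candidates(raw, 10, 0.01), "filtered")
  filt <- smooth_profile(raw, 5)
  expect_error(extract_candidates(filt, 100, 0.01), "profile range")
})

test_that("consensus takes the histogram mode with deterministic tie-breaks", {
  mk <- function(bins_list) {
    cands <- lapply(bins_list, function(b) {
      structure(list(spot_edge = NA_integer_, valley_inner = b[1],
                     valley_outer = b[2], ring_outer = NA_integer_),
                class = "candidate_features")
    })
    feature_distribution(cands)
  }
  cal <- calibration(mm_per_px = 0.5)
  # degenerate: all replicates agree on bin 42 (valley 42-50)
  d <- mk(rep(list(c(42L, 50L)), 10))
  f <- consensus(d, cal, support_floor = 0.2)
  expect_equal(f$valley_inner_px, 41.5) # center of bin 42
  expect_equal(f$support[["valley"]], 1.0)
  expect_equal(f$valley_inner_mm, 41.5 * 0.5)
  # explicit mode count: 80 replicates at bin 40, 20 at bin 60
  d2 <- mk(c(rep(list(c(40L, 70L)), 80), rep(list(c(60L, 70L)), 20)))
  f2 <- consensus(d2, cal)
  expect_equal(f2$valley_inner_px, 39.5)
  # support below the floor: found in 10% of replicates only
  cands <- c(rep(list(structure(list(spot_edge = NA_integer_,
                                     valley_inner = 30L, valley_outer = 40L,
                                     ring_outer = NA_integer_),
                                class = "candidate_features")), 2),
             rep(list(structure(list(spot_edge = NA_integer_,
                                     valley_inner = NA_integer_,
                                     valley_outer = NA_integer_,
                                     ring_outer = NA_integer_),
                                class = "candidate_features")), 18))
  f3 <- consensus(feature_distribution(cands), cal, support_floor = 0.2)
  expect_true(is.na(f3$valley_inner_mm))
  expect_equal(f3$support[["valley"]], 0.1)
})

test_that("quantify_plate recovers known feature radii on a synthetic plate", {
  tr <- default_world(spot_radius_mm = 4, valley_inner_mm = 4,
                      valley_outer_mm = 9, ring_outer_mm = 16,
                      noise_sigma = 0.05, transition_sigma_px = 2, seed = 21)
  img <- generate_plate(tr)$image
  f <- quantify_plate(img, default_config(B = 100L, seed = 8))
  err <- abs(features_mm(f) - truth_mm(tr))
  expect_true(all(err <= 0.5), info = paste(round(err, 3), collapse = " "))
})

test_that("a featureless lawn yields absent valley and ring", {
  tr <- default_world(levels = c(off_plate = 0.05, background = 0.35,
                                 spot = 0.351, valley = 0.349, ring = 0.351),
                      noise_sigma = 0.03, seed = 31)
  img <- generate_plate(tr)$image
  f <- quantify_plate(img, default_config(B = 60L, seed = 2))
  expect_true(is.na(f$valley_inner_mm))
  expect_true(is.na(f$valley_outer_mm))
  expect_true(is.na(f$ring_outer_mm))
})

test_that("quantify_plate is deterministic and leaves the RNG state alone", {
  tr <- small_world(noise_sigma = 0.04, seed = 3)
  img <- generate_plate(tr)$image
  cfg <- default_config(B = 40L, seed = 13)
  set.seed(1234)
  before <- runif(1)
  set.seed(1234)
  f1 <- quantify_plate(img, cfg)
  after <- runif(1)
  f2 <- quantify_plate(img, cfg)
  expect_identical(as.data.frame(f1), as.data.frame(f2))
  expect_identical(before, after) # caller RNG stream untouched
})

test_that("emitted features always respect the radial ordering", {
  for (s in 1:6) {
    tr <- small_world(noise_sigma = 0.08, transition_sigma_px = 2, seed = s)
    img <- generate_plate(tr)$image
    f <- quantify_plate(img, default_config(B = 40L, seed = s))
    v <- features_px(f)
    present <- v[!is.na(v)]
    if (length(present) > 1) {
      expect_true(all(diff(present) >= 0),
                  info = paste(names(present), round(present, 1), collapse = ", "))
    }
  }
})

test_that("feature support never rises with more noise", {
  sigmas <- c(0.02, 0.1, 0.25)
  n_seeds <- 20
  sup <- matrix(0, length(sigmas), 3,
                dimnames = list(NULL, c("spot", "valley", "ring")))
  for (i in seq_along(sigmas)) {
    for (s in seq_len(n_seeds)) {
      tr <- small_world(noise_sigma = sigmas[i], seed = s)
      img <- generate_plate(tr)$image
      f <- quantify_plate(img, default_config(B = 30L, seed = s))
      sup[i, ] <- sup[i, ] + f$support / n_seeds
    }
  }
  for (feat in colnames(sup)) {
    expect_true(all(diff(sup[, feat]) <= 1e-9),
                info = sprintf("%s: %s", feat,
                               paste(round(sup[, feat], 3), collapse = " -> ")))
  }
})
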