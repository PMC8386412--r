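#' Bootstrap composite of angular slices
#'
#' Draws `n_angles` columns of the polar image uniformly with replacement
#' and assembles them into a composite polar image of the same shape — one
#' bootstrap replicate of the plate's angular slices. Consumes the current
#' R random number stream (seed it with `set.seed()` for reproducibility;
#' [quantify_plate()] manages this itself).
#'
#' @param polar A [to_polar()] result.
#' @return A `polar_image` of identical shape whose columns are a
#'   with-replacement resample of the input's columns.
#' @export
bootstrap_composite <- function(polar) {
  stopifnot(inherits(polar, "polar_image"))
  cols <- sample.int(polar$n_angles, polar$n_angles, replace = TRUE)
  out <- polar
  out$values <- polar$values[, cols, drop = FALSE]
  out
}

#' Noise floor for feature acceptance
#'
#' Estimates how large a derivative extremum must be to count as a real
#' feature rather than residual noise: `k` times the (Gaussian-consistent)
#' median absolute deviation of the derivative over the outer background
#' annulus — the outermost `background_frac` of radius bins, which on a
#' correctly cropped plate hold only the featureless cheater lawn.
#'
#' @param deriv A [radial_profile()] of kind `"derivative"`.
#' @param k Multiplier on the MAD (default 4).
#' @param background_frac Fraction of outermost bins treated as background
#'   (default 0.15).
#' @return A non-negative scalar in intensity-per-bin units.
#' @export
estimate_noise_floor <- function(deriv, k = 4, background_frac = 0.15) {
  stopifnot(inherits(deriv, "radial_profile"), deriv$kind == "derivative")
  n <- length(deriv$intensity)
  tail_bins <- max(8L, ceiling(background_frac * n))
  x <- deriv$intensity[(n - tail_bins + 1):n]
  k * stats::mad(x)
}

#' Per-radius noise floor for feature acceptance
#'
#' A median profile is noisier near the center than at the rim: an annulus
#' of radius `r` holds only about `2 * pi * r` distinct pixels, so when
#' `n_angles` exceeds that, the angular samples overlap and the effective
#' sample count saturates at the circumference. Anchoring the floor on the
#' outer background annulus (see [estimate_noise_floor()]) and applying it
#' flat would therefore under-threshold the inner radii. This function
#' scales the tail-anchored floor by the square root of the effective
#' sample ratio, giving a per-bin threshold vector.
#'
#' @inheritParams estimate_noise_floor
#' @param n_angles Angular slices of the polar image the profile came from.
#' @return Numeric vector, one threshold per radius bin.
#' @export
noise_floor_profile <- function(deriv, k = 4, background_frac = 0.15,
                                n_angles = 360L) {
  base <- estimate_noise_floor(deriv, k = k, background_frac = background_frac)
  n <- length(deriv$intensity)
  tail_bins <- max(8L, ceiling(background_frac * n))
  eff <- function(r) pmin(2 * pi * r, n_angles)
  r_bins <- seq_len(n) - 0.5
  tail_mid <- n - tail_bins / 2
  base * sqrt(eff(tail_mid) / eff(r_bins))
}

#' Candidate feature bounds from one filtered profile
#'
#' Locates the radial pattern features on a single (composite) profile by
#' sequential extremum search on its derivative:
#' \itemize{
#'   \item `spot_edge`: the steepest descent within 1.5x the rough spot
#'     radius (the circle finder is coarse; the derivative refines it);
#'   \item `valley_inner`: the derivative minimum beyond `spot_edge`
#'     (intensity dropping into the inhibition valley);
#'   \item `valley_outer`: the derivative maximum beyond `valley_inner`
#'     (intensity rising out of the valley into the cheater ring — also
#'     the ring's inner bound);
#'   \item `ring_outer`: the next derivative minimum beyond `valley_outer`
#'     (intensity falling from the dense ring back to the lawn).
#' }
#' The sequential windows enforce the radial ordering by construction. An
#' extremum whose derivative magnitude is below `noise_floor` is reported
#' absent (`NA`); its location still anchors the next search window so the
#' scan stays deterministic. Valley bounds are reported as a pair: if
#' either fails the floor, both are absent.
#'
#' @param profile A [radial_profile()] of kind `"filtered"`.
#' @param spot_hint Rough spot radius in radius bins.
#' @param noise_floor Minimum derivative magnitude: a scalar, or a vector
#'   with one threshold per radius bin (see [noise_floor_profile()]).
#' @param min_separation Guard distance (bins) between consecutive
#'   extrema of opposite sign. Within half a filter window of a strong
#'   edge the derivative carries that edge's own residual, so an opposite
#'   extremum found there is not a distinct feature. [quantify_polar()]
#'   passes the filter support radius, `(smooth_window - 1) / 2 + 1`;
#'   the default 0 reproduces the bare sequential scan. Same-sign searches
#'   (spot edge to valley inner) are never guarded: in the canonical
#'   pattern those two bounds share one transition.
#' @return A list of class `candidate_features` with integer radius bins
#'   `spot_edge`, `valley_inner`, `valley_outer`, `ring_outer` (`NA` when
#'   absent).
#' @export
extract_candidates <- function(profile, spot_hint, noise_floor,
                               min_separation = 0L) {
  stopifnot(inherits(profile, "radial_profile"), profile$kind == "filtered")
  d <- derivative(profile)$intensity
  n <- length(d)
  if (spot_hint < 1 || spot_hint > n) {
    stop("spot_hint must lie within the profile range", call. = FALSE)
  }

  argext <- function(from, to, which = c("min", "max")) {
    if (from > to) return(NULL)
    w <- d[from:to]
    pos <- if (match.arg(which) == "min") which.min(w) else which.max(w)
    list(bin = from + pos - 1L, value = w[pos])
  }
  if (!length(noise_floor) %in% c(1L, n)) {
    stop("noise_floor must be a scalar or one value per radius bin", call. = FALSE)
  }
  floor_at <- function(bin) {
    if (length(noise_floor) == 1L) noise_floor else noise_floor[bin]
  }
  # The 1e-8 guard keeps float dust on perfectly flat profiles (where the
  # MAD floor is exactly zero) from registering as features.
  passes <- function(e) {
    !is.null(e) && abs(e$value) >= max(floor_at(e$bin), 1e-8)
  }

  guard <- as.integer(min_separation)
  spot <- argext(1L, min(n, as.integer(floor(1.5 * spot_hint))), "min")
  spot_anchor <- if (is.null(spot)) 1L else spot$bin
  vin  <- argext(spot_anchor + 1L, n, "min")
  vin_anchor <- if (is.null(vin)) spot_anchor else vin$bin
  vout <- argext(vin_anchor + 1L + guard, n, "max")
  vout_anchor <- if (is.null(vout)) vin_anchor else vout$bin
  ring <- argext(vout_anchor + 1L + guard, n, "min")

  valley_ok <- passes(vin) && passes(vout)
  structure(
    list(
      spot_edge    = if (passes(spot)) spot$bin else NA_integer_,
      valley_inner = if (valley_ok) vin$bin else NA_integer_,
      valley_outer = if (valley_ok) vout$bin else NA_integer_,
      ring_outer   = if (passes(ring)) ring$bin else NA_integer_
    ),
    class = "candidate_features"
  )
}

#' Distributions of candidate features over bootstrap replicates
#'
#' @param candidates List of [extract_candidates()] results, one per
#'   replicate.
#' @return An object of class `feature_distribution`: per-feature multisets
#'   of candidate radius bins, the replicate count `B`, and per-feature
#'   `support` (fraction of replicates in which the feature was found; the
#'   valley counts as found only when both bounds are).
#' @export
feature_distribution <- function(candidates) {
  B <- length(candidates)
  stopifnot(B >= 1)
  pull <- function(field) {
    v <- vapply(candidates, function(x) as.integer(x[[field]]), integer(1))
    v[!is.na(v)]
  }
  bins <- list(
    spot_edge    = pull("spot_edge"),
    valley_inner = pull("valley_inner"),
    valley_outer = pull("valley_outer"),
    ring_outer   = pull("ring_outer")
  )
  structure(
    list(
      bins = bins, B = B,
      support = c(
        spot   = length(bins$spot_edge) / B,
        valley = length(bins$valley_inner) / B,
        ring   = length(bins$ring_outer) / B
      )
    ),
    class = "feature_distribution"
  )
}

# Histogram mode of integer radius bins; bins of `bin_width` radius bins,
# ties toward the smaller radius. Returns the center of the winning bin in
# radius-bin units, or NA for an empty multiset.
.mode_bin <- function(bins, bin_width = 1) {
  if (length(bins) == 0) return(NA_real_)
  grp <- (bins - 1L) %/% bin_width
  counts <- table(factor(grp, levels = sort(unique(grp))))
  win <- as.integer(names(counts)[which.max(counts)])
  win * bin_width + (bin_width + 1) / 2
}

#' Consensus pattern features from bootstrap distributions
#'
#' Selects, for each feature, the mode of its candidate distribution
#' (histogram with `bin_width` radius bins, ties toward the smaller
#' radius), drops features whose support falls below `support_floor`,
#' enforces the radial ordering `spot_edge <= valley_inner < valley_outer
#' <= ring_outer` among surviving features, and converts radii to
#' millimeters.
#'
#' @param dist A [feature_distribution()].
#' @param cal A [calibration()].
#' @param radial_step Radial bin width of the underlying polar image (px).
#' @param bin_width Histogram bin width in radius bins (default 1).
#' @param support_floor Minimum fraction of replicates (default 0.2).
#' @param seed,config_digest Provenance stamped into the result.
#' @param id Image label.
#' @return An object of class `pattern_features`.
#' @export
consensus <- function(dist, cal, radial_step = 1, bin_width = 1,
                      support_floor = 0.2, seed = NA_integer_,
                      config_digest = NA_character_, id = "plate") {
  stopifnot(inherits(dist, "feature_distribution"), dist$B >= 1)
  bin_to_px <- function(b) (b - 0.5) * radial_step
  modes <- lapply(dist$bins, .mode_bin, bin_width = bin_width)
  sup <- dist$support

  keep <- c(
    spot_edge    = sup[["spot"]] >= support_floor && !is.na(modes$spot_edge),
    valley_inner = sup[["valley"]] >= support_floor && !is.na(modes$valley_inner),
    valley_outer = sup[["valley"]] >= support_floor && !is.na(modes$valley_outer),
    ring_outer   = sup[["ring"]] >= support_floor && !is.na(modes$ring_outer)
  )
  # Radial ordering must hold among present features; modes are computed
  # per-feature so pathological multimodality can disorder them. The valley
  # is dropped whole if its bounds invert; a ring that fails to clear the
  # valley's outer bound is dropped (it is the derived feature).
  if (keep[["valley_inner"]] && modes$valley_inner >= modes$valley_outer) {
    keep[["valley_inner"]] <- keep[["valley_outer"]] <- FALSE
  }
  if (keep[["spot_edge"]] && keep[["valley_inner"]] &&
      modes$spot_edge > modes$valley_inner) {
    if (sup[["spot"]] < sup[["valley"]]) keep[["spot_edge"]] <- FALSE
    else keep[["valley_inner"]] <- keep[["valley_outer"]] <- FALSE
  }
  if (keep[["ring_outer"]] && keep[["valley_outer"]] &&
      modes$ring_outer < modes$valley_outer) {
    keep[["ring_outer"]] <- FALSE
  }

  px <- vapply(names(keep), function(f) {
    if (keep[[f]]) bin_to_px(modes[[f]]) else NA_real_
  }, numeric(1))
  mm <- px_to_mm(px, cal)
  structure(
    list(
      spot_edge_mm = mm[["spot_edge"]], valley_inner_mm = mm[["valley_inner"]],
      valley_outer_mm = mm[["valley_outer"]], ring_outer_mm = mm[["ring_outer"]],
      spot_edge_px = px[["spot_edge"]], valley_inner_px = px[["valley_inner"]],
      valley_outer_px = px[["valley_outer"]], ring_outer_px = px[["ring_outer"]],
      support = sup, B = dist$B, seed = seed,
      config_digest = config_digest, mm_per_px = cal$mm_per_px, id = id,
      distribution = dist
    ),
    class = "pattern_features"
  )
}

#' @export
print.pattern_features <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "absent" else sprintf("%.2f mm", v)
  cat(sprintf("<pattern_features '%s'> B = %d, seed = %s\n", x$id, x$B, x$seed))
  cat(sprintf("  spot edge    : %-10s (support %.2f)\n", fmt(x$spot_edge_mm), x$support[["spot"]]))
  cat(sprintf("  valley       : %s - %s (support %.2f)\n",
              fmt(x$valley_inner_mm), fmt(x$valley_outer_mm), x$support[["valley"]]))
  cat(sprintf("  ring outer   : %-10s (support %.2f)\n", fmt(x$ring_outer_mm), x$support[["ring"]]))
  cat(sprintf("  scale        : %.4f mm/px\n", x$mm_per_px))
  invisible(x)
}

#' @export
as.data.frame.pattern_features <- function(x, ...) {
  data.frame(
    image_id = x$id,
    spot_edge_mm = x$spot_edge_mm, valley_inner_mm = x$valley_inner_mm,
    valley_outer_mm = x$valley_outer_mm, ring_outer_mm = x$ring_outer_mm,
    spot_edge_px = x$spot_edge_px, valley_inner_px = x$valley_inner_px,
    valley_outer_px = x$valley_outer_px, ring_outer_px = x$ring_outer_px,
    support_spot = x$support[["spot"]], support_valley = x$support[["valley"]],
    support_ring = x$support[["ring"]],
    B = x$B, seed = x$seed, mm_per_px = x$mm_per_px,
    config_digest = x$config_digest,
    stringsAsFactors = FALSE
  )
}

#' Quantify the radial growth pattern of one plate image
#'
#' The full pipeline: rough spot detection (Hough, with a centroid
#' fallback), plate-rim detection for millimeter calibration, polar
#' transform around the spot center, then `B` bootstrap replicates — each
#' resamples angular slices with replacement, takes the per-radius median,
#' smooths, differentiates, and extracts candidate feature bounds — and
#' finally mode consensus across replicates.
#'
#' With `B = 1` no resampling is performed: the median profile of the full
#' polar image is analyzed directly (the "single profile" the bootstrap is
#' compared against).
#'
#' The result is a pure function of the image, the configuration and the
#' seed; the caller's random number state is left untouched.
#'
#' @param image A [plate_image()].
#' @param config A [default_config()] list (any subset of fields may be
#'   overridden).
#' @return A [consensus()] `pattern_features` object, with the mean
#'   (clockscan-style) and median radial profiles of the full polar image
#'   attached as `$profiles` and the detected circles as `$spot` /
#'   `$plate` for inspection.
#' @export
quantify_plate <- function(image, config = default_config()) {
  stopifnot(inherits(image, "plate_image"))
  config <- utils::modifyList(default_config(), config)
  dg <- config_digest(config)

  if (identical(config$preprocess, "contrast_stretch")) {
    image <- contrast_stretch(image)
  }

  spot <- tryCatch(
    detect_spot(image, radius_range = config$spot_radius_range,
                score_floor = config$spot_score_floor),
    ringscan_spot_not_found = function(e) fallback_spot(image)
  )

  plate <- NULL
  if (is.null(config$mm_per_px)) {
    plate <- detect_plate_edge(image, score_floor = config$plate_score_floor)
    cal <- calibration(plate, plate_diameter_mm = config$plate_diameter_mm)
  } else {
    plate <- tryCatch(
      detect_plate_edge(image, score_floor = config$plate_score_floor),
      ringscan_plate_not_found = function(e) NULL
    )
    cal <- calibration(plate, plate_diameter_mm = config$plate_diameter_mm,
                       mm_per_px = config$mm_per_px)
  }

  # Profile the plate interior: stop short of the rim so the lawn-to-rim
  # drop is not mistaken for a growth feature.
  reach <- min(spot$center_row - 1, image$height - spot$center_row,
               spot$center_col - 1, image$width - spot$center_col)
  r_max <- reach
  if (!is.null(plate)) {
    off <- sqrt((spot$center_row - plate$center_row)^2 +
                (spot$center_col - plate$center_col)^2)
    r_max <- min(r_max, config$r_max_frac * (plate$radius - off))
  }
  polar <- to_polar(image, spot, r_max = r_max,
                    n_angles = config$n_angles, radial_step = config$radial_step)
  # a rough (fallback) spot radius can exceed the profiled range on
  # featureless plates; the hint is only a search-window anchor, so clamp it
  spot_hint <- min(max(spot$radius / config$radial_step, 1), polar$n_radii)

  feats <- quantify_polar(polar, spot_hint, cal, config, id = image$id)
  feats$spot <- spot
  feats$plate <- plate
  feats
}

#' Bootstrap-consensus features from a polar image
#'
#' The post-geometry stage of [quantify_plate()], exposed so callers with
#' a known center and calibration (synthetic benchmarks, robustness
#' studies on corrupted slices) can run the bootstrap directly.
#'
#' @param polar A [to_polar()] result.
#' @param spot_hint Rough spot radius in radius bins.
#' @param cal A [calibration()].
#' @param config A [default_config()] list.
#' @param id Label stamped into the result.
#' @return A `pattern_features` object (see [consensus()]), with the mean
#'   and median profiles of the full polar image attached as `$profiles`.
#' @export
quantify_polar <- function(polar, spot_hint, cal, config = default_config(),
                           id = "plate") {
  stopifnot(inherits(polar, "polar_image"))
  config <- utils::modifyList(default_config(), config)
  dg <- config_digest(config)

  if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    old_seed <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old_seed, envir = .GlobalEnv), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(list = ".Random.seed", envir = .GlobalEnv)),
            add = TRUE)
  }
  set.seed(config$seed)

  # short profiles (poor crop, tiny plate) cannot carry the configured
  # window; clamp to the largest valid odd width instead of failing
  win <- as.integer(config$smooth_window)
  win_max <- floor(polar$n_radii / 4)
  if (win_max %% 2 == 0) win_max <- win_max - 1L
  if (win > win_max) win <- max(3L, win_max)

  one_rep <- function(pol) {
    prof <- median_profile(pol)
    filt <- smooth_profile(prof, window = win,
                           method = config$smooth_method)
    floor_b <- noise_floor_profile(derivative(filt), k = config$noise_floor_k,
                                   background_frac = config$background_frac,
                                   n_angles = polar$n_angles)
    # effect-size cutoff: an intensity step of min_step through an MA(w)
    # filter peaks at min_step / w in the derivative
    floor_b <- pmax(floor_b, config$min_step / win)
    extract_candidates(filt, spot_hint, floor_b,
                       min_separation = (win - 1L) %/% 2L + 1L)
  }
  cands <- vector("list", config$B)
  if (config$B == 1L) {
    cands[[1]] <- one_rep(polar)
  } else {
    for (b in seq_len(config$B)) cands[[b]] <- one_rep(bootstrap_composite(polar))
  }

  feats <- consensus(feature_distribution(cands), cal,
                     radial_step = config$radial_step,
                     bin_width = config$bin_width,
                     support_floor = config$support_floor,
                     seed = config$seed, config_digest = dg, id = id)
  feats$truncated_at <- polar$truncated_at
  feats$profiles <- list(
    mean = clockscan_profile(polar),
    median = median_profile(polar)
  )
  feats$calibration <- cal
  feats
}

#' Percentile contrast stretch
#'
#' Optional preprocessing: linearly rescales intensities so the 1st and
#' 99th percentiles map to 0 and 1 (clipped). Off by default; whether the
#' original photographs were contrast-adjusted before analysis is unknown,
#' so the pipeline makes it an explicit, recorded choice.
#'
#' @param image A [plate_image()].
#' @return A [plate_image()].
#' @export
contrast_stretch <- function(image) {
  q <- stats::quantile(image$pixels, c(0.01, 0.99), names = FALSE)
  if (q[2] <= q[1]) return(image)
  px <- pmin(pmax((image$pixels - q[1]) / (q[2] - q[1]), 0), 1)
  plate_image(px, source_bit_depth = image$source_bit_depth, id = image$id)
}
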