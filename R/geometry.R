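#' Circle descriptor
#'
#' Centers are in (row, col) pixel coordinates, 1-based like R matrices.
#' `score` is a detection confidence in `[0, 1]`: interior-brightness
#' contrast for spots, perimeter edge coverage for plate rims.
#'
#' @param center_row,center_col Center coordinates (px, may be subpixel).
#' @param radius Radius (px), strictly positive.
#' @param score Confidence in `[0, 1]`.
#' @return An object of class `plate_circle`.
#' @export
plate_circle <- function(center_row, center_col, radius, score = 1) {
  if (radius <= 0) stop("circle radius must be positive", call. = FALSE)
  structure(
    list(center_row = as.numeric(center_row), center_col = as.numeric(center_col),
         radius = as.numeric(radius), score = min(max(as.numeric(score), 0), 1)),
    class = "plate_circle"
  )
}

#' @export
print.plate_circle <- function(x, ...) {
  cat(sprintf("<circle> center (%.1f, %.1f) px, radius %.1f px, score %.2f\n",
              x$center_row, x$center_col, x$radius, x$score))
  invisible(x)
}

# Central-difference gradient; borders are zeroed so every gradient is
# two-sided. Returns gx (along columns), gy (along rows), and magnitude.
.image_gradient <- function(px) {
  h <- nrow(px); w <- ncol(px)
  gx <- matrix(0, h, w)
  gy <- matrix(0, h, w)
  gx[, 2:(w - 1)] <- (px[, 3:w] - px[, 1:(w - 2)]) / 2
  gy[2:(h - 1), ] <- (px[3:h, ] - px[1:(h - 2), ]) / 2
  list(gx = gx, gy = gy, mag = sqrt(gx^2 + gy^2))
}

# Separable Gaussian blur with reflected boundaries; kernel reaches 3 sigma.
.gauss_blur <- function(px, sigma) {
  if (sigma <= 0) return(px)
  k <- max(1L, ceiling(3 * sigma))
  t <- (-k):k
  kern <- exp(-t^2 / (2 * sigma^2))
  kern <- kern / sum(kern)
  conv_cols <- function(m) {
    n <- nrow(m)
    padded <- m[c((k + 1):2, 1:n, (n - 1):(n - k)), , drop = FALSE]
    out <- stats::filter(padded, kern, sides = 2)
    matrix(out[(k + 1):(k + n), ], n, ncol(m))
  }
  t(conv_cols(t(conv_cols(px))))
}

# Gradient-direction circular Hough accumulation on a pre-smoothed image
# (plate photographs are noisy; without smoothing the edge map is mostly
# noise). Every edge pixel casts two votes per candidate radius, one along
# its gradient and one against it, at the nearest integer center. Votes are
# integer counts, so the argmax is deterministic. Ties resolve toward the
# smaller radius, then array order (smaller row, then column).
.hough_circles <- function(px, radii, edge_quantile = 0.95, blur_sigma = 2) {
  h <- nrow(px); w <- ncol(px)
  g <- .image_gradient(.gauss_blur(px, blur_sigma))
  interior <- g$mag[2:(h - 1), 2:(w - 1)]
  thr <- stats::quantile(interior, edge_quantile, names = FALSE)
  idx <- which(g$mag >= thr & g$mag > 0)
  if (length(idx) == 0) return(NULL)
  er <- ((idx - 1L) %% h) + 1L
  ec <- ((idx - 1L) %/% h) + 1L
  ux <- g$gx[idx] / g$mag[idx]
  uy <- g$gy[idx] / g$mag[idx]
  best <- list(votes = 0L, row = NA_integer_, col = NA_integer_, radius = NA_real_)
  for (rad in radii) {
    vr <- round(c(er + rad * uy, er - rad * uy))
    vc <- round(c(ec + rad * ux, ec - rad * ux))
    ok <- vr >= 1 & vr <= h & vc >= 1 & vc <= w
    if (!any(ok)) next
    lin <- (vc[ok] - 1L) * h + vr[ok]
    acc <- tabulate(lin, nbins = h * w)
    k <- which.max(acc)
    if (acc[k] > best$votes) {
      best <- list(votes = acc[k],
                   row = ((k - 1L) %% h) + 1L,
                   col = ((k - 1L) %/% h) + 1L,
                   radius = rad)
    }
  }
  if (best$votes == 0L) return(NULL)
  best$edge_thr <- thr
  best$edge_mag <- g$mag
  best
}

# Edge-contrast score of a circle: the fraction of 360 perimeter samples
# whose smoothed gradient magnitude clears the edge threshold.
.rim_score <- function(edge_mag, edge_thr, row, col, radius) {
  theta <- 2 * pi * (0:359) / 360
  rr <- row - radius * sin(theta)
  cc <- col + radius * cos(theta)
  ok <- rr >= 1 & rr <= nrow(edge_mag) & cc >= 1 & cc <= ncol(edge_mag)
  if (!any(ok)) return(0)
  m <- .bilinear(edge_mag, matrix(rr[ok], nrow = 1), matrix(cc[ok], nrow = 1))
  mean(m >= edge_thr)
}

# Interior-vs-surround brightness contrast of a candidate bright disk.
.spot_score <- function(px, row, col, radius) {
  h <- nrow(px); w <- ncol(px)
  d2 <- outer((seq_len(h) - row)^2, (seq_len(w) - col)^2, `+`)
  inside <- d2 <= (0.8 * radius)^2
  ann <- d2 >= (1.2 * radius)^2 & d2 <= (1.6 * radius)^2
  if (!any(inside) || !any(ann)) return(0)
  min(max(mean(px[inside]) - mean(px[ann]), 0), 1)
}

#' Detect the central growth spot
#'
#' Finds the brightest circular blob whose radius falls inside
#' `radius_range`, using a gradient-direction circular Hough transform.
#' The localization is deliberately "rough" (integer-pixel): downstream
#' stages tolerate several pixels of center error because feature radii are
#' refined on the radial profile itself.
#'
#' @param image A [plate_image()].
#' @param radius_range Numeric `c(min, max)` radius in px; must lie inside
#'   `(0, min(height, width)/2)`.
#' @param score_floor Minimum interior-contrast score to accept (default 0.05).
#' @return A [plate_circle()]. Signals a condition of class
#'   `ringscan_spot_not_found` when no circle clears the floor.
#' @export
detect_spot <- function(image, radius_range = NULL, score_floor = 0.05) {
  stopifnot(inherits(image, "plate_image"))
  m <- min(image$height, image$width)
  if (is.null(radius_range)) radius_range <- c(5, round(0.2 * m))
  if (radius_range[1] <= 0 || radius_range[2] >= m / 2 ||
      radius_range[1] > radius_range[2]) {
    stop("radius_range must lie within (0, min(height, width)/2)", call. = FALSE)
  }
  radii <- seq(ceiling(radius_range[1]), floor(radius_range[2]))
  cand <- .hough_circles(image$pixels, radii)
  if (!is.null(cand)) {
    sc <- .spot_score(image$pixels, cand$row, cand$col, cand$radius)
    if (sc >= score_floor) {
      return(plate_circle(cand$row, cand$col, cand$radius, sc))
    }
  }
  stop(structure(
    class = c("ringscan_spot_not_found", "error", "condition"),
    list(message = sprintf("spot not found in '%s' (no bright circle in radius range [%g, %g])",
                           image$id, radius_range[1], radius_range[2]),
         call = NULL)
  ))
}

#' Fallback spot estimate from bright-pixel centroid
#'
#' Used when the Hough detector finds nothing. The initial center is the
#' intensity-weighted centroid of pixels above the 95th intensity
#' percentile; the radius is the first annulus whose mean intensity drops
#' below the midpoint between the central and background levels (or
#' `max_radius` when it never drops, e.g. a featureless lawn). Because the
#' global centroid is easily skewed by glare sectors or illumination
#' tilt, the center is then refined: the centroid is recomputed from
#' pixels within 1.5x the current radius that exceed the midpoint level,
#' which converges onto the spot itself.
#'
#' @param image A [plate_image()].
#' @param max_radius Largest radius considered (default `min(h, w) / 4`).
#' @param iterations Local refinement passes (default 2).
#' @return A [plate_circle()] with score 0 (the fallback carries no
#'   detection confidence).
#' @export
fallback_spot <- function(image, max_radius = NULL, iterations = 2L) {
  stopifnot(inherits(image, "plate_image"))
  px <- image$pixels
  h <- nrow(px); w <- ncol(px)
  if (is.null(max_radius)) max_radius <- floor(min(h, w) / 4)
  thr <- stats::quantile(px, 0.95, names = FALSE)
  mask <- px > thr
  if (!any(mask)) mask <- px >= thr # constant image: fall back to everything
  wsum <- sum(px[mask])
  cr <- sum(row(px)[mask] * px[mask]) / wsum
  cc <- sum(col(px)[mask] * px[mask]) / wsum

  # midpoint-rule radius from a given center
  annular <- function(cr, cc) {
    d <- sqrt((row(px) - cr)^2 + (col(px) - cc)^2)
    bins <- pmin(floor(d) + 1L, as.integer(max_radius) + 1L)
    keep <- d <= max_radius
    ann_mean <- tapply(px[keep], bins[keep], mean)
    mid <- (ann_mean[[1]] + mean(px[d > max_radius])) / 2
    below <- which(ann_mean < mid)
    list(radius = if (length(below)) as.numeric(names(ann_mean)[below[1]])
                  else max_radius,
         mid = mid, d = d)
  }
  est <- annular(cr, cc)
  for (it in seq_len(iterations)) {
    sel <- est$d <= 1.5 * est$radius & px > est$mid
    if (!any(sel)) break
    wsum <- sum(px[sel])
    cr <- sum(row(px)[sel] * px[sel]) / wsum
    cc <- sum(col(px)[sel] * px[sel]) / wsum
    est <- annular(cr, cc)
  }
  plate_circle(cr, cc, est$radius, score = 0)
}

#' Detect the outer plate rim
#'
#' Finds the largest high-contrast circular boundary via the same Hough
#' accumulation as [detect_spot()], searched over large radii
#' (0.25 to 0.75 of the smaller image dimension). The rim circle anchors
#' the pixel-to-millimeter calibration against the known plate diameter.
#'
#' @param image A [plate_image()].
#' @param radius_range Optional `c(min, max)` radius in px; defaults to
#'   `c(0.25, 0.75) * min(height, width)`.
#' @param score_floor Minimum edge coverage of the rim: the fraction of the
#'   circumference lying on above-threshold gradient (default 0.3).
#' @param edge_quantile Gradient-magnitude quantile defining edge pixels
#'   (default 0.85; lower than the spot detector's because the rim is often
#'   the weakest edge on a patterned plate and must stay in the edge map).
#' @return A [plate_circle()]. Signals `ringscan_plate_not_found` when no
#'   boundary qualifies; callers may then supply `mm_per_px` manually.
#' @export
detect_plate_edge <- function(image, radius_range = NULL, score_floor = 0.3,
                              edge_quantile = 0.85) {
  stopifnot(inherits(image, "plate_image"))
  m <- min(image$height, image$width)
  if (is.null(radius_range)) radius_range <- c(ceiling(0.25 * m), floor(0.75 * m))
  radii <- seq(ceiling(radius_range[1]), floor(radius_range[2]))
  cand <- .hough_circles(image$pixels, radii, edge_quantile = edge_quantile)
  fail <- function() stop(structure(
    class = c("ringscan_plate_not_found", "error", "condition"),
    list(message = sprintf("plate edge not found in '%s'", image$id), call = NULL)
  ))
  if (is.null(cand) || cand$radius < 0.25 * m) fail()
  support <- .rim_score(cand$edge_mag, cand$edge_thr, cand$row, cand$col,
                        cand$radius)
  if (support < score_floor) fail()
  plate_circle(cand$row, cand$col, cand$radius, support)
}

#' Polar resampling of a plate image
#'
#' Builds a radius-by-angle raster: row `r` holds intensities sampled at
#' distance `(r - 0.5) * radial_step` px from the center (bin centers, so
#' row 1 is the innermost annulus), column `a` at angle
#' `2 * pi * (a - 1) / n_angles`. Angle 0 points along the +column axis and
#' angles increase counterclockwise (row coordinate decreasing). Sampling
#' is bilinear. Each column is one "angular slice" through the plate — the
#' unit the bootstrap later resamples.
#'
#' If the requested `r_max` would read outside the frame it is truncated to
#' the last fully contained radius, recorded in the `truncated_at` field.
#'
#' @param image A [plate_image()].
#' @param center A [plate_circle()] (its center is used) or numeric
#'   `c(row, col)`.
#' @param r_max Outermost radius to sample (px).
#' @param n_angles Number of angular slices (>= 8; default 360, one per
#'   degree).
#' @param radial_step Radial bin width in px (default 1).
#' @return An object of class `polar_image`: `values` (n_radii x n_angles
#'   matrix), `n_radii`, `n_angles`, `radial_step`, `center`,
#'   `truncated_at` (NA when no truncation occurred).
#' @export
to_polar <- function(image, center, r_max, n_angles = 360L, radial_step = 1) {
  stopifnot(inherits(image, "plate_image"))
  if (inherits(center, "plate_circle")) center <- c(center$center_row, center$center_col)
  if (r_max <= 0) stop("r_max must be positive", call. = FALSE)
  if (n_angles < 8) stop("n_angles must be at least 8", call. = FALSE)
  if (radial_step <= 0) stop("radial_step must be positive", call. = FALSE)
  px <- image$pixels
  h <- nrow(px); w <- ncol(px)
  # Bilinear sampling needs both neighbors in-frame: clamp to the frame
  # border minus one interpolation cell.
  reach <- min(center[1] - 1, h - center[1], center[2] - 1, w - center[2])
  truncated_at <- NA_real_
  if (r_max > reach) {
    truncated_at <- reach
    r_max <- reach
  }
  n_radii <- floor(r_max / radial_step)
  if (n_radii < 1) stop("r_max too small for the requested radial_step", call. = FALSE)
  theta <- 2 * pi * (seq_len(n_angles) - 1) / n_angles
  rr <- (seq_len(n_radii) - 0.5) * radial_step
  # row = center_row - rho*sin(theta) (counterclockwise in image coords),
  # col = center_col + rho*cos(theta)
  rows <- center[1] - outer(rr, sin(theta))
  cols <- center[2] + outer(rr, cos(theta))
  vals <- .bilinear(px, rows, cols)
  structure(
    list(values = vals, n_radii = n_radii, n_angles = as.integer(n_angles),
         radial_step = radial_step, center = center, truncated_at = truncated_at),
    class = "polar_image"
  )
}

# Vectorized bilinear interpolation at (possibly matrix-shaped) coordinates.
.bilinear <- function(px, rows, cols) {
  h <- nrow(px); w <- ncol(px)
  r0 <- floor(rows); c0 <- floor(cols)
  fr <- rows - r0; fc <- cols - c0
  r0 <- pmin(pmax(r0, 1), h - 1); c0 <- pmin(pmax(c0, 1), w - 1)
  i00 <- (c0 - 1) * h + r0
  v <- (1 - fr) * (1 - fc) * px[i00] +
       (1 - fr) * fc       * px[i00 + h] +
       fr       * (1 - fc) * px[i00 + 1] +
       fr       * fc       * px[i00 + h + 1]
  array(v, dim = dim(rows))
}

#' @export
print.polar_image <- function(x, ...) {
  cat(sprintf("<polar_image> %d radii x %d angles, step %.2f px/bin%s\n",
              x$n_radii, x$n_angles, x$radial_step,
              if (is.na(x$truncated_at)) "" else sprintf(" (truncated at %.1f px)", x$truncated_at)))
  invisible(x)
}

#' Pixel-to-millimeter calibration
#'
#' Petri dishes have a known diameter (100 mm for the large culture plates
#' these assays use), so a detected rim circle fixes the physical scale:
#' `mm_per_px = plate_diameter_mm / (2 * radius_px)`.
#'
#' @param plate_circle A [plate_circle()] for the rim, or `NULL` when
#'   `mm_per_px` is given directly.
#' @param plate_diameter_mm Physical plate diameter (default 100 mm).
#' @param mm_per_px Optional manual override; bypasses the rim circle.
#' @return An object of class `plate_calibration` with `mm_per_px`,
#'   `plate_diameter_mm` and `plate_circle`.
#' @export
calibration <- function(plate_circle = NULL, plate_diameter_mm = 100,
                        mm_per_px = NULL) {
  if (is.null(mm_per_px)) {
    if (is.null(plate_circle)) {
      stop("calibration needs either a plate circle or an explicit mm_per_px",
           call. = FALSE)
    }
    mm_per_px <- plate_diameter_mm / (2 * plate_circle$radius)
  }
  if (!is.finite(mm_per_px) || mm_per_px <= 0) {
    stop("mm_per_px must be strictly positive", call. = FALSE)
  }
  structure(
    list(mm_per_px = mm_per_px, plate_diameter_mm = plate_diameter_mm,
         plate_circle = plate_circle),
    class = "plate_calibration"
  )
}

#' Convert pixel lengths to millimeters
#'
#' @param value_px Length(s) in px.
#' @param cal A [calibration()].
#' @return Length(s) in mm.
#' @export
px_to_mm <- function(value_px, cal) {
  stopifnot(inherits(cal, "plate_calibration"))
  value_px * cal$mm_per_px
}

#' Convert millimeter lengths to pixels
#'
#' Exact inverse of [px_to_mm()].
#'
#' @inheritParams px_to_mm
#' @param value_mm Length(s) in mm.
#' @return Length(s) in px.
#' @export
mm_to_px <- function(value_mm, cal) {
  stopifnot(inherits(cal, "plate_calibration"))
  value_mm / cal$mm_per_px
}
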