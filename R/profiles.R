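#' Radial intensity profile
#'
#' A 1D signal over radius bins: the object feature extraction works on.
#' `kind` records the provenance: `"mean"` (clockscan-style average),
#' `"median"` (bootstrap composite profile), `"filtered"` (after
#' smoothing), or `"derivative"` (after differentiation, units of intensity
#' per bin).
#'
#' @param intensity Numeric vector over radius bins (bin centers at
#'   `(i - 0.5) * radial_step` px).
#' @param radial_step Radial bin width (px).
#' @param origin Center `c(row, col)` the profile was measured from.
#' @param kind One of `"mean"`, `"median"`, `"filtered"`, `"derivative"`.
#' @return An object of class `radial_profile`.
#' @export
radial_profile <- function(intensity, radial_step = 1,
                           origin = c(NA_real_, NA_real_),
                           kind = c("mean", "median", "filtered", "derivative")) {
  kind <- match.arg(kind)
  if (length(intensity) < 8) stop("radial profile needs at least 8 bins", call. = FALSE)
  if (radial_step <= 0) stop("radial_step must be positive", call. = FALSE)
  if (kind != "derivative" && (min(intensity) < 0 || max(intensity) > 1)) {
    stop("intensity profile values must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(intensity = as.numeric(intensity), radial_step = radial_step,
         origin = origin, kind = kind),
    class = "radial_profile"
  )
}

#' @export
print.radial_profile <- function(x, ...) {
  cat(sprintf("<radial_profile kind=%s> %d bins, step %.2f px/bin, range [%.3f, %.3f]\n",
              x$kind, length(x$intensity), x$radial_step,
              min(x$intensity), max(x$intensity)))
  invisible(x)
}

#' Radii of the profile bins
#'
#' @param profile A [radial_profile()].
#' @param cal Optional [calibration()]; when supplied, radii are in mm.
#' @return Bin-center radii in px (or mm).
#' @export
profile_radii <- function(profile, cal = NULL) {
  r <- (seq_along(profile$intensity) - 0.5) * profile$radial_step
  if (!is.null(cal)) r <- px_to_mm(r, cal)
  r
}

#' Mean radial intensity profile (clockscan style)
#'
#' Averages the polar image over all angular slices at each radius — the
#' classic averaged radial intensity trace used to compare growth patterns
#' between strains.
#'
#' @param polar A [to_polar()] result.
#' @return A [radial_profile()] of kind `"mean"`.
#' @export
clockscan_profile <- function(polar) {
  stopifnot(inherits(polar, "polar_image"))
  radial_profile(rowMeans(polar$values), radial_step = polar$radial_step,
                 origin = polar$center, kind = "mean")
}

#' Median radial intensity profile
#'
#' The median over angular slices at each radius. The median is what makes
#' each bootstrap composite robust: an occlusion (glare, label) corrupting
#' a minority of slices leaves the per-radius median untouched.
#'
#' @param polar A [to_polar()] result.
#' @return A [radial_profile()] of kind `"median"`.
#' @export
median_profile <- function(polar) {
  stopifnot(inherits(polar, "polar_image"))
  radial_profile(matrixStats::rowMedians(polar$values),
                 radial_step = polar$radial_step,
                 origin = polar$center, kind = "median")
}

# Reflect-pad a vector by k samples on each side (boundary sample not
# repeated: the mirror is about the end point).
.reflect_pad <- function(x, k) {
  n <- length(x)
  c(x[(k + 1):2], x, x[(n - 1):(n - k)])
}

#' Smooth a radial profile
#'
#' Noise filtering before differentiation. The default is a centered
#' moving average with reflected-boundary padding (output length equals
#' input length); a second-order Savitzky-Golay filter is available behind
#' the same interface for users who want less flattening of narrow
#' features.
#'
#' @param profile A [radial_profile()] of kind `"mean"`, `"median"` or
#'   `"filtered"`.
#' @param window Odd window length in bins, between 3 and `length/4`.
#' @param method `"moving_average"` (default) or `"savitzky_golay"`.
#' @return A [radial_profile()] of kind `"filtered"`.
#' @export
smooth_profile <- function(profile, window = 11L,
                           method = c("moving_average", "savitzky_golay")) {
  stopifnot(inherits(profile, "radial_profile"))
  method <- match.arg(method)
  n <- length(profile$intensity)
  if (window %% 2 == 0 || window < 3 || window > n / 4) {
    stop(sprintf("window must be odd and within [3, length/4] = [3, %d], got %s",
                 floor(n / 4), window), call. = FALSE)
  }
  k <- (window - 1L) %/% 2L
  padded <- .reflect_pad(profile$intensity, k)
  coef <- if (method == "moving_average") {
    rep(1 / window, window)
  } else {
    # Degree-2 least-squares fit evaluated at the window center: the first
    # row of (X'X)^-1 X' for X = [1, t, t^2], t = -k..k.
    t <- (-k):k
    X <- cbind(1, t, t^2)
    solve(crossprod(X), t(X))[1, ]
  }
  sm <- as.numeric(stats::filter(padded, coef, sides = 2))[(k + 1):(k + n)]
  # Convex-combination filters cannot leave [0,1]; SG can overshoot a hair.
  sm <- pmin(pmax(sm, 0), 1)
  radial_profile(sm, radial_step = profile$radial_step,
                 origin = profile$origin, kind = "filtered")
}

#' Differentiate a filtered radial profile
#'
#' Central differences on interior bins, one-sided at the two ends, in
#' units of intensity per bin. Only filtered profiles may be
#' differentiated: differentiating raw noise would swamp the feature
#' extrema, so the smoothing step is enforced, not just recommended.
#'
#' @param profile A [radial_profile()] of kind `"filtered"`.
#' @return A [radial_profile()] of kind `"derivative"`, same length.
#' @export
derivative <- function(profile) {
  stopifnot(inherits(profile, "radial_profile"))
  if (profile$kind != "filtered") {
    stop("derivative requires a filtered profile (call smooth_profile first)",
         call. = FALSE)
  }
  x <- profile$intensity
  n <- length(x)
  d <- numeric(n)
  d[1] <- x[2] - x[1]
  d[n] <- x[n] - x[n - 1]
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / 2
  radial_profile(d, radial_step = profile$radial_step,
                 origin = profile$origin, kind = "derivative")
}
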