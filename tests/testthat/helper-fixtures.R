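# Fixture builders and independent oracles shared across test files.

# Flat image with optional bright disks: list(c(row, col, radius, value), ...)
make_disk_image <- function(size = 256L, disks = list(), background = 0.1,
                            id = "disk") {
  px <- matrix(background, size, size)
  rows <- matrix(seq_len(size), size, size)
  cols <- matrix(seq_len(size), size, size, byrow = TRUE)
  for (d in disks) {
    inside <- (rows - d[1])^2 + (cols - d[2])^2 <= d[3]^2
    px[inside] <- d[4]
  }
  plate_image(px, id = id)
}

# Independent oracle for radial profiles: bin raw pixels by Euclidean
# distance to the center, no polar transform involved. Bin i collects
# pixels with distance in [(i-1), i) * radial_step.
brute_radial_binning <- function(image, center, n_bins, radial_step = 1) {
  px <- image$pixels
  d <- sqrt((row(px) - center[1])^2 + (col(px) - center[2])^2)
  bin <- floor(d / radial_step) + 1
  means <- rep(NA_real_, n_bins)
  for (i in seq_len(n_bins)) {
    sel <- bin == i
    if (any(sel)) means[i] <- mean(px[sel])
  }
  means
}

# 90-degree counterclockwise rotation of an image matrix.
rotate90_ccw <- function(px) t(px)[ncol(px):1, , drop = FALSE]

# The standard synthetic world used by most end-to-end tests: the default
# fig5-like geometry at the default 512 px frame.
default_world <- function(...) synthetic_truth(...)

# A small, fast world for property sweeps: 256 px frame, 112 px plate.
small_world <- function(...) {
  synthetic_truth(plate_radius_px = 112, img_size = 256L, ...)
}

# Per-feature pixel radii of a truth object (ground truth in px).
truth_px <- function(truth) {
  c(spot_edge = truth$spot_radius_mm,
    valley_inner = truth$valley_inner_mm,
    valley_outer = truth$valley_outer_mm,
    ring_outer = truth$ring_outer_mm) / truth$mm_per_px
}

# Feature radii of a pattern_features object as a named mm vector.
features_mm <- function(f) {
  c(spot_edge = f$spot_edge_mm, valley_inner = f$valley_inner_mm,
    valley_outer = f$valley_outer_mm, ring_outer = f$ring_outer_mm)
}

features_px <- function(f) {
  c(spot_edge = f$spot_edge_px, valley_inner = f$valley_inner_px,
    valley_outer = f$valley_outer_px, ring_outer = f$ring_outer_px)
}

truth_mm <- function(truth) {
  c(spot_edge = truth$spot_radius_mm, valley_inner = truth$valley_inner_mm,
    valley_outer = truth$valley_outer_mm, ring_outer = truth$ring_outer_mm)
}
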