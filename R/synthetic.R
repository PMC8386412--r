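#' Ground-truth parameters for a synthetic plate image
#'
#' Describes an idealized photographed plate: a bright circular plate on a
#' dark background carrying a central producer spot, an inhibition valley
#' annulus, and a dense outer ring annulus, with smooth radial
#' transitions, additive camera noise, a linear illumination tilt, and
#' optional angular occlusions (glare / label artifacts) — the
#' imperfections the bootstrap-consensus detector exists to survive.
#'
#' The default geometry mirrors the qualitative spot/valley/ring layout of
#' an optogenetic producer spotted on a cheater lawn: a 3 mm spot, a
#' valley from 3 to 9 mm, and a dense ring out to 20 mm on a 100 mm plate.
#' The intensity levels are presets (bright spot 0.9, dark valley 0.15,
#' dense ring 0.75 over a 0.35 lawn, off-plate 0.05), not measurements.
#'
#' @param plate_radius_px Plate rim radius in the rendered image (px).
#' @param img_size Rendered image side length (px, square).
#' @param spot_radius_mm,valley_inner_mm,valley_outer_mm,ring_outer_mm
#'   Feature radii (mm); must satisfy
#'   `0 < spot <= valley_inner < valley_outer <= ring_outer < plate radius`.
#' @param plate_diameter_mm Physical plate diameter (mm).
#' @param levels Named intensities: `off_plate`, `background` (lawn),
#'   `spot`, `valley`, `ring`; must satisfy `spot > valley` and
#'   `ring > valley`.
#' @param transition_sigma_px Gaussian edge blur of radial transitions (px).
#' @param noise_sigma Additive Gaussian noise s.d. (intensity units).
#' @param gradient_amplitude Peak-to-peak linear illumination tilt across
#'   the frame, as a fraction of the intensity range.
#' @param occlusions List of `c(start_deg, end_deg)` angular sectors
#'   (counterclockwise from the +x axis) forced to the lawn level, emulating
#'   glare or labels.
#' @param center_offset `c(row, col)` offset of the plate center from the
#'   image center (px).
#' @param seed RNG seed for the noise field.
#' @return An object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(plate_radius_px = 230,
                            img_size = 512L,
                            spot_radius_mm = 3,
                            valley_inner_mm = 3,
                            valley_outer_mm = 9,
                            ring_outer_mm = 20,
                            plate_diameter_mm = 100,
                            levels = c(off_plate = 0.05, background = 0.35,
                                       spot = 0.9, valley = 0.15, ring = 0.75),
                            transition_sigma_px = 2,
                            noise_sigma = 0.05,
                            gradient_amplitude = 0.05,
                            occlusions = list(),
                            center_offset = c(0, 0),
                            seed = 1L) {
  radii_mm <- c(spot = spot_radius_mm, valley_inner = valley_inner_mm,
                valley_outer = valley_outer_mm, ring_outer = ring_outer_mm)
  plate_radius_mm <- plate_diameter_mm / 2
  if (!(0 < spot_radius_mm)) {
    stop("invalid truth: spot_radius_mm must be positive", call. = FALSE)
  }
  if (!(spot_radius_mm <= valley_inner_mm)) {
    stop("invalid truth: ordering violated, need spot_radius_mm <= valley_inner_mm",
         call. = FALSE)
  }
  if (!(valley_inner_mm < valley_outer_mm)) {
    stop("invalid truth: ordering violated, need valley_inner_mm < valley_outer_mm",
         call. = FALSE)
  }
  if (!(valley_outer_mm <= ring_outer_mm)) {
    stop("invalid truth: ordering violated, need valley_outer_mm <= ring_outer_mm",
         call. = FALSE)
  }
  if (!(ring_outer_mm < plate_radius_mm)) {
    stop("invalid truth: ordering violated, need ring_outer_mm < plate radius",
         call. = FALSE)
  }
  need <- c("off_plate", "background", "spot", "valley", "ring")
  if (!all(need %in% names(levels))) {
    stop("levels must name off_plate, background, spot, valley, ring", call. = FALSE)
  }
  if (!(levels[["spot"]] > levels[["valley"]] && levels[["ring"]] > levels[["valley"]])) {
    stop("invalid truth: intensity ordering requires spot > valley and ring > valley",
         call. = FALSE)
  }
  structure(
    list(plate_radius_px = plate_radius_px, img_size = as.integer(img_size),
         spot_radius_mm = spot_radius_mm, valley_inner_mm = valley_inner_mm,
         valley_outer_mm = valley_outer_mm, ring_outer_mm = ring_outer_mm,
         plate_diameter_mm = plate_diameter_mm,
         levels = levels[need], transition_sigma_px = transition_sigma_px,
         noise_sigma = noise_sigma, gradient_amplitude = gradient_amplitude,
         occlusions = occlusions, center_offset = center_offset,
         seed = as.integer(seed),
         mm_per_px = plate_radius_mm / plate_radius_px),
    class = "synthetic_truth"
  )
}

# Radial edge positions (px) and the level to the right of each edge.
.truth_edges <- function(truth) {
  px <- function(mm) mm / truth$mm_per_px
  lv <- truth$levels
  list(
    edges = c(px(truth$spot_radius_mm), px(truth$valley_inner_mm),
              px(truth$valley_outer_mm), px(truth$ring_outer_mm),
              truth$plate_radius_px),
    levels = c(lv[["spot"]], lv[["background"]], lv[["valley"]],
               lv[["ring"]], lv[["background"]], lv[["off_plate"]])
  )
}

#' Analytic radial intensity of a synthetic plate
#'
#' The closed-form noiseless, tilt-free radial profile of
#' [generate_plate()]: a step function over
#' spot / lawn / valley / ring / lawn / off-plate levels whose transitions
#' are Gaussian-blurred sigmoids (exact steps when
#' `transition_sigma_px = 0`). Used as the independent oracle for the
#' rendered image's measured profile.
#'
#' @param truth A [synthetic_truth()].
#' @param r_px Radii (px) to evaluate at.
#' @return Intensities in `[0, 1]`.
#' @export
analytic_radial_profile <- function(truth, r_px) {
  e <- .truth_edges(truth)
  s <- truth$transition_sigma_px
  if (s <= 0) {
    # exact step function: interval lookup, no floating-point telescoping;
    # r == edge takes the outer level, matching pnorm(0) = 1/2 rounding out
    return(e$levels[findInterval(r_px, e$edges) + 1])
  }
  v <- rep(e$levels[1], length(r_px))
  for (i in seq_along(e$edges)) {
    v <- v + (e$levels[i + 1] - e$levels[i]) * stats::pnorm((r_px - e$edges[i]) / s)
  }
  v
}

#' Render a synthetic plate image
#'
#' Renders the radial pattern described by a [synthetic_truth()]: the
#' blurred radial step function, plus the linear illumination tilt, plus
#' i.i.d. Gaussian noise clipped to `[0, 1]`, with occlusion sectors
#' stamped to the lawn level last (they model saturating glare, which
#' carries no noise). Deterministic given `truth$seed`; the caller's RNG
#' state is preserved.
#'
#' @param truth A [synthetic_truth()].
#' @return A list with `image` (a [plate_image()]) and `truth` (the input,
#'   echoed so image and oracle travel together).
#' @export
generate_plate <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  n <- truth$img_size
  ctr <- (n + 1) / 2 + truth$center_offset
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  r <- sqrt((rows - ctr[1])^2 + (cols - ctr[2])^2)
  px <- matrix(analytic_radial_profile(truth, r), n, n)

  if (truth$gradient_amplitude != 0) {
    px <- px + truth$gradient_amplitude * ((cols - (n + 1) / 2) / n)
  }

  if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    old_seed <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old_seed, envir = .GlobalEnv), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(list = ".Random.seed", envir = .GlobalEnv)),
            add = TRUE)
  }
  set.seed(truth$seed)
  if (truth$noise_sigma > 0) {
    px <- px + matrix(stats::rnorm(n * n, 0, truth$noise_sigma), n, n)
  }
  px <- pmin(pmax(px, 0), 1)

  if (length(truth$occlusions)) {
    ang <- (atan2(ctr[1] - rows, cols - ctr[2]) * 180 / pi) %% 360
    on_plate <- r <= truth$plate_radius_px
    for (sec in truth$occlusions) {
      a0 <- sec[1] %% 360; a1 <- sec[2] %% 360
      hit <- if (a0 <= a1) ang >= a0 & ang < a1 else ang >= a0 | ang < a1
      px[hit & on_plate] <- truth$levels[["background"]]
    }
  }

  img <- plate_image(px, source_bit_depth = 16L,
                     id = sprintf("synthetic_seed%d", truth$seed))
  list(image = img, truth = truth)
}

#' Generate a fixture suite of synthetic plates
#'
#' Expands a grid of noise, blur and occlusion levels across seeds, renders
#' each plate, and writes image + truth-JSON pairs plus a manifest CSV of
#' every generating parameter. Regenerating with the same arguments yields
#' byte-identical files.
#'
#' @param dir Output directory (created if needed).
#' @param noise_sigmas,blur_sigmas Numeric grids for noise s.d. and edge
#'   blur (px).
#' @param occlusion_fracs Fractions of the circle occluded by a single
#'   contiguous sector starting at angle 0 (0 = none).
#' @param seeds Integer seeds, one image per grid point per seed.
#' @param base_truth Template [synthetic_truth()] the grid perturbs.
#' @param format `"tif"` (16-bit, default) or `"png"` (8-bit).
#' @return Invisibly, the manifest data frame (also written to
#'   `manifest.csv` in `dir`).
#' @export
generate_suite <- function(dir, noise_sigmas = c(0, 0.02, 0.05),
                           blur_sigmas = c(1, 3),
                           occlusion_fracs = c(0, 0.1),
                           seeds = 1:5,
                           base_truth = synthetic_truth(),
                           format = c("tif", "png")) {
  format <- match.arg(format)
  grid <- expand.grid(noise_sigma = noise_sigmas, blur = blur_sigmas,
                      occlusion = occlusion_fracs, seed = seeds,
                      KEEP.OUT.ATTRS = FALSE)
  if (nrow(grid) == 0) stop("empty generation grid", call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    occ <- if (g$occlusion > 0) list(c(0, 360 * g$occlusion)) else list()
    truth <- utils::modifyList(base_truth, list(
      noise_sigma = g$noise_sigma, transition_sigma_px = g$blur,
      occlusions = occ, seed = as.integer(g$seed)
    ))
    class(truth) <- "synthetic_truth"
    id <- sprintf("plate_n%04.0f_b%02.0f_o%02.0f_s%03d",
                  g$noise_sigma * 1000, g$blur * 10, g$occlusion * 100, g$seed)
    out <- generate_plate(truth)
    out$image$id <- id
    img_path <- file.path(dir, paste0(id, ".", format))
    write_image(out$image, img_path, bit_depth = 16L)
    jsonlite::write_json(.truth_record(truth, id), file.path(dir, paste0(id, ".json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    rows[[i]] <- data.frame(.truth_record(truth, id), stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

# Flat, JSON/CSV-friendly view of a truth object.
.truth_record <- function(truth, id) {
  list(
    image_id = id,
    plate_radius_px = truth$plate_radius_px, img_size = truth$img_size,
    spot_radius_mm = truth$spot_radius_mm,
    valley_inner_mm = truth$valley_inner_mm,
    valley_outer_mm = truth$valley_outer_mm,
    ring_outer_mm = truth$ring_outer_mm,
    plate_diameter_mm = truth$plate_diameter_mm,
    level_off_plate = truth$levels[["off_plate"]],
    level_background = truth$levels[["background"]],
    level_spot = truth$levels[["spot"]],
    level_valley = truth$levels[["valley"]],
    level_ring = truth$levels[["ring"]],
    transition_sigma_px = truth$transition_sigma_px,
    noise_sigma = truth$noise_sigma,
    gradient_amplitude = truth$gradient_amplitude,
    occlusion_deg = if (length(truth$occlusions)) {
      paste(vapply(truth$occlusions, function(s) paste(s, collapse = ":"),
                   character(1)), collapse = ";")
    } else "",
    center_offset_row = truth$center_offset[1],
    center_offset_col = truth$center_offset[2],
    seed = truth$seed,
    mm_per_px = truth$mm_per_px
  )
}
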