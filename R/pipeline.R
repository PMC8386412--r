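#' Default pipeline configuration
#'
#' Every tunable of the quantification pipeline with its documented
#' default. Pass any subset of overrides to [quantify_plate()] or
#' [run_batch()]; unknown keys are rejected so typos fail loudly.
#'
#' @param ... Named overrides of the defaults.
#' @return A named list of class `ringscan_config`:
#' \describe{
#'   \item{n_angles}{Angular slices in the polar transform (360: one per
#'     degree).}
#'   \item{radial_step}{Radial bin width, px (1).}
#'   \item{smooth_window}{Profile filter window, bins, odd (11).}
#'   \item{smooth_method}{`"moving_average"` or `"savitzky_golay"`.}
#'   \item{B}{Bootstrap replicates (500, "hundreds"; `B = 1` disables
#'     resampling).}
#'   \item{support_floor}{Minimum fraction of replicates for a feature to
#'     be reported (0.2).}
#'   \item{noise_floor_k}{Derivative-extremum threshold, in MADs of the
#'     background-annulus derivative (4).}
#'   \item{background_frac}{Outermost fraction of radius bins treated as
#'     featureless background for the noise floor (0.15).}
#'   \item{min_step}{Smallest intensity step (fraction of the dynamic
#'     range) that counts as a feature (0.02). Statistical floors alone
#'     cannot reject systematic illumination ripples, which scale with the
#'     background estimate; this is the effect-size cutoff that does.}
#'   \item{bin_width}{Consensus histogram bin width, radius bins (1).}
#'   \item{plate_diameter_mm}{Physical plate diameter (100).}
#'   \item{mm_per_px}{Manual scale override; `NULL` means calibrate from
#'     the detected rim.}
#'   \item{spot_radius_range}{`c(min, max)` spot Hough radii, px; `NULL`
#'     means `c(5, 0.2 * min(h, w))`.}
#'   \item{spot_score_floor, plate_score_floor}{Detection confidence
#'     floors (0.05, 0.3).}
#'   \item{r_max_frac}{Fraction of the rim radius out to which profiles
#'     are measured (0.92), keeping the rim's own edge out of the signal.}
#'   \item{preprocess}{`"none"` (default) or `"contrast_stretch"`.}
#'   \item{seed}{RNG seed for the bootstrap (1).}
#' }
#' @export
default_config <- function(...) {
  cfg <- list(
    n_angles = 360L,
    radial_step = 1,
    smooth_window = 11L,
    smooth_method = "moving_average",
    B = 500L,
    support_floor = 0.2,
    noise_floor_k = 4,
    background_frac = 0.15,
    min_step = 0.02,
    bin_width = 1,
    plate_diameter_mm = 100,
    mm_per_px = NULL,
    spot_radius_range = NULL,
    spot_score_floor = 0.05,
    plate_score_floor = 0.3,
    r_max_frac = 0.92,
    preprocess = "none",
    seed = 1L
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) {
    stop(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = c("ringscan_config", "list"))
}

#' Read a pipeline configuration from YAML
#'
#' Unspecified keys keep their [default_config()] values.
#'
#' @param path Path to a YAML file of config keys.
#' @return A `ringscan_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  do.call(default_config, vals)
}

#' Stable digest of a configuration
#'
#' A short hash of the canonicalized (name-sorted, JSON-serialized) config,
#' embedded in every output row so results can always be traced to the
#' exact settings that produced them.
#'
#' @param config A config list.
#' @return A 12-character hex string.
#' @export
config_digest <- function(config) {
  config <- config[order(names(config))]
  canon <- jsonlite::toJSON(lapply(unclass(config), function(x) x),
                            auto_unbox = TRUE, digits = NA, null = "null")
  substr(digest::digest(as.character(canon), algo = "sha256"), 1, 12)
}

#' Quantify a batch of plate images
#'
#' Runs [quantify_plate()] over every PNG/TIFF in a directory (or an
#' explicit vector of files). One failing image does not abort the batch:
#' its error lands in the `failures` table and processing continues.
#'
#' @param input Directory containing images, or a character vector of
#'   image paths.
#' @param config A [default_config()] list.
#' @param out_csv Optional path; when given, the feature table is written
#'   there with stable column order via [write_features_csv()].
#' @param log_path Optional path for a line-delimited JSON log (one record
#'   per image: circles, truncation, supports, or the error).
#' @return A list of class `ringscan_batch`: `features` (data frame, one
#'   row per successful image), `failures` (data frame `image_id`,
#'   `error`), `results` (the full `pattern_features` objects), `config`,
#'   `config_digest`, and `ok` (TRUE when nothing failed).
#' @export
run_batch <- function(input, config = default_config(), out_csv = NULL,
                      log_path = NULL) {
  paths <- if (length(input) == 1 && dir.exists(input)) {
    list.files(input, pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE,
               full.names = TRUE)
  } else {
    input
  }
  paths <- sort(paths)
  if (length(paths) == 0) {
    stop("input contains no readable images (.png/.tif/.tiff)", call. = FALSE)
  }
  config <- utils::modifyList(default_config(), config)
  dg <- config_digest(config)
  log_con <- NULL
  if (!is.null(log_path)) {
    log_con <- file(log_path, open = "wt")
    on.exit(close(log_con), add = TRUE)
  }
  emit_log <- function(rec) {
    if (!is.null(log_con)) {
      writeLines(as.character(jsonlite::toJSON(rec, auto_unbox = TRUE,
                                               digits = NA, null = "null")),
                 log_con)
    }
  }

  feats <- list(); fails <- list(); results <- list()
  for (p in paths) {
    id <- tools::file_path_sans_ext(basename(p))
    res <- tryCatch({
      img <- load_image(p)
      quantify_plate(img, config)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      fails[[id]] <- data.frame(image_id = id, error = conditionMessage(res),
                                stringsAsFactors = FALSE)
      emit_log(list(image_id = id, status = "error",
                    error = conditionMessage(res)))
    } else {
      feats[[id]] <- as.data.frame(res)
      results[[id]] <- res
      emit_log(list(
        image_id = id, status = "ok",
        spot = res$spot[c("center_row", "center_col", "radius", "score")],
        plate = if (is.null(res$plate)) NULL else
          res$plate[c("center_row", "center_col", "radius", "score")],
        truncated_at = if (is.na(res$truncated_at)) NULL else res$truncated_at,
        support = as.list(res$support)
      ))
    }
  }
  features <- if (length(feats)) do.call(rbind, unname(feats)) else
    as.data.frame(matrix(nrow = 0, ncol = 0))
  failures <- if (length(fails)) do.call(rbind, unname(fails)) else
    data.frame(image_id = character(), error = character(),
               stringsAsFactors = FALSE)
  if (!is.null(out_csv) && length(feats)) write_features_csv(features, out_csv)
  structure(
    list(features = features, failures = failures, results = results,
         config = config, config_digest = dg, ok = nrow(failures) == 0),
    class = "ringscan_batch"
  )
}

#' @export
print.ringscan_batch <- function(x, ...) {
  cat(sprintf("<ringscan_batch> %d quantified, %d failed (config %s)\n",
              nrow(x$features), nrow(x$failures), x$config_digest))
  invisible(x)
}

# Stable schema for feature output; order is part of the contract.
.features_columns <- c(
  "image_id", "spot_edge_mm", "valley_inner_mm", "valley_outer_mm",
  "ring_outer_mm", "spot_edge_px", "valley_inner_px", "valley_outer_px",
  "ring_outer_px", "support_spot", "support_valley", "support_ring",
  "B", "seed", "mm_per_px", "config_digest"
)

#' Write the feature table with a stable schema
#'
#' Columns are emitted in a fixed, documented order and numbers with full
#' precision, so identical runs produce byte-identical CSVs.
#'
#' @param features Data frame from [run_batch()] or rbind-ed
#'   `as.data.frame(pattern_features)` rows.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(features, path) {
  missing_cols <- setdiff(.features_columns, names(features))
  if (length(missing_cols)) {
    stop(sprintf("feature table missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  df <- features[, .features_columns]
  df <- df[order(df$image_id), , drop = FALSE]
  fmt <- function(x) {
    if (is.numeric(x)) vapply(x, function(v) {
      if (is.na(v)) "NA" else format(v, digits = 15, scientific = FALSE, trim = TRUE)
    }, character(1)) else as.character(x)
  }
  out <- vapply(df, fmt, character(nrow(df)))
  if (nrow(df) == 1L) out <- matrix(out, nrow = 1, dimnames = list(NULL, names(df)))
  lines <- c(paste(.features_columns, collapse = ","),
             apply(out, 1, paste, collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Overlay radial intensity profiles
#'
#' The strain-comparison plot: one averaged radial intensity trace per
#' plate, radius on the x axis (mm when a calibration is supplied, px
#' otherwise), intensity on the y axis.
#'
#' @param profiles A list of [radial_profile()] objects (all with the same
#'   `radial_step`).
#' @param labels Character labels, one per profile (legend, in input
#'   order). Defaults to list names or `profile 1..n`.
#' @param cal Optional [calibration()] shared by all profiles; converts
#'   the radius axis to mm.
#' @param file Optional output path (`.png` or `.svg` by extension); when
#'   `NULL`, draws on the current device.
#' @param width,height Device size in inches (PNG rendered at 150 dpi).
#' @return `file` (or `NULL`), invisibly.
#' @export
plot_profiles <- function(profiles, labels = NULL, cal = NULL, file = NULL,
                          width = 6, height = 4) {
  if (inherits(profiles, "radial_profile")) profiles <- list(profiles)
  if (length(profiles) == 0) stop("need at least one profile", call. = FALSE)
  steps <- vapply(profiles, function(p) p$radial_step, numeric(1))
  if (length(unique(steps)) != 1) {
    stop("profiles have mismatched radial_step; rescale before plotting",
         call. = FALSE)
  }
  if (is.null(labels)) {
    labels <- if (!is.null(names(profiles))) names(profiles)
              else paste("profile", seq_along(profiles))
  }
  if (!is.null(file)) {
    ext <- tolower(tools::file_ext(file))
    if (ext == "png") {
      grDevices::png(file, width = width, height = height, units = "in",
                     res = 150)
    } else if (ext == "svg") {
      grDevices::svg(file, width = width, height = height)
    } else {
      stop(sprintf("unsupported plot format '.%s' (use .png or .svg)", ext),
           call. = FALSE)
    }
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  xlab <- if (is.null(cal)) "radius (px)" else "radius (mm)"
  cols <- grDevices::hcl.colors(max(3, length(profiles)), "Dark 3")
  xmax <- max(vapply(profiles, function(p) max(profile_radii(p, cal)), numeric(1)))
  graphics::plot(NULL, xlim = c(0, xmax), ylim = c(0, 1), xlab = xlab,
                 ylab = "mean intensity (a.u.)")
  for (i in seq_along(profiles)) {
    graphics::lines(profile_radii(profiles[[i]], cal),
                    profiles[[i]]$intensity, col = cols[i], lwd = 2)
  }
  graphics::legend("topright", legend = labels, col = cols[seq_along(profiles)],
                   lwd = 2, bty = "n")
  invisible(file)
}
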