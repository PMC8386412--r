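#' Plate image container
#'
#' A `plate_image` holds a single grayscale raster of a photographed agar
#' plate, normalized to unit intensity. It is the raw observable every
#' downstream stage (circle detection, polar transform, profiling) consumes.
#'
#' @param pixels Numeric matrix of intensities in `[0, 1]`; rows are image
#'   rows (top to bottom), columns are image columns (left to right).
#' @param source_bit_depth Bit depth of the file the raster came from
#'   (8 or 16). Synthetic images default to 16.
#' @param id Character label, usually the filename stem.
#'
#' @return An object of class `plate_image` with fields `pixels`, `height`,
#'   `width`, `source_bit_depth` and `id`.
#' @export
plate_image <- function(pixels, source_bit_depth = 16L, id = "plate") {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  }
  if (anyNA(pixels) || any(!is.finite(pixels))) {
    stop("plate image rejected: intensities must all be finite", call. = FALSE)
  }
  if (min(pixels) < 0 || max(pixels) > 1) {
    stop("plate image rejected: intensities outside [0, 1]", call. = FALSE)
  }
  if (nrow(pixels) < 64L || ncol(pixels) < 64L) {
    stop(sprintf(
      "plate image rejected: dimensions %dx%d below the 64x64 minimum",
      nrow(pixels), ncol(pixels)
    ), call. = FALSE)
  }
  if (!source_bit_depth %in% c(8L, 16L)) {
    stop("plate image rejected: source_bit_depth must be 8 or 16", call. = FALSE)
  }
  structure(
    list(
      pixels = unname(pixels),
      height = nrow(pixels),
      width = ncol(pixels),
      source_bit_depth = as.integer(source_bit_depth),
      id = as.character(id)
    ),
    class = "plate_image"
  )
}

#' @export
print.plate_image <- function(x, ...) {
  cat(sprintf(
    "<plate_image '%s'> %d x %d px, %d-bit source, intensity [%.3f, %.3f]\n",
    x$id, x$height, x$width, x$source_bit_depth,
    min(x$pixels), max(x$pixels)
  ))
  invisible(x)
}

# Rec. 709 luminance weights, fixed for reproducibility across cameras.
.luma <- c(0.2126, 0.7152, 0.0722)

#' Load a plate photograph
#'
#' Reads an 8- or 16-bit grayscale or RGB image from PNG or TIFF, collapses
#' RGB to Rec. 709 luminance (0.2126 R + 0.7152 G + 0.0722 B), and scales
#' intensities to `[0, 1]` by the source bit depth. TIFF support covers
#' baseline uncompressed files (the common microscope/gel-imager export).
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return A [plate_image()] whose `id` is the filename stem.
#' @export
load_image <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("cannot read image: file '%s' does not exist", path),
         call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    arr <- png::readPNG(path)
    # readPNG already scales by bit depth; recover depth from metadata-free
    # heuristic: the png package always returns [0,1], so record 8 unless the
    # file header says 16.
    depth <- .png_bit_depth(path)
  } else if (ext %in% c("tif", "tiff")) {
    tf <- read_tiff_baseline(path)
    arr <- tf$data
    depth <- tf$bit_depth
  } else {
    stop(sprintf("cannot read image '%s': unsupported format '.%s' (use PNG or TIFF)",
                 path, ext), call. = FALSE)
  }
  px <- .collapse_to_gray(arr, path)
  px[px < 0] <- 0
  px[px > 1] <- 1
  plate_image(px, source_bit_depth = depth,
              id = tools::file_path_sans_ext(basename(path)))
}

# Grayscale matrix from a [0,1] array: pass-through for 2D, luminance for RGB,
# alpha dropped.
.collapse_to_gray <- function(arr, path) {
  if (is.matrix(arr)) return(arr)
  if (length(dim(arr)) == 3L) {
    nc <- dim(arr)[3]
    if (nc == 1L) return(arr[, , 1L])
    if (nc %in% c(2L)) return(arr[, , 1L]) # gray + alpha
    if (nc %in% c(3L, 4L)) {
      return(.luma[1] * arr[, , 1L] + .luma[2] * arr[, , 2L] + .luma[3] * arr[, , 3L])
    }
  }
  stop(sprintf("cannot read image '%s': unsupported channel layout", path),
       call. = FALSE)
}

# PNG bit depth straight from the IHDR chunk (byte 25 of the file).
.png_bit_depth <- function(path) {
  hdr <- readBin(path, "raw", n = 26L)
  if (length(hdr) < 26L) {
    stop(sprintf("cannot read image '%s': truncated PNG header", path),
         call. = FALSE)
  }
  depth <- as.integer(hdr[25L])
  if (!depth %in% c(8L, 16L)) {
    stop(sprintf("cannot read image '%s': unsupported bit depth %d (need 8 or 16)",
                 path, depth), call. = FALSE)
  }
  depth
}

#' Write a plate image
#'
#' Writes intensities back to disk as grayscale. PNG output is 8-bit (the
#' `png` package's writer); TIFF output (the package's baseline
#' uncompressed writer) honors `bit_depth` and is the format to use when
#' 16-bit precision matters.
#'
#' @param image A [plate_image()].
#' @param path Output path; format chosen by extension (`.png`, `.tif`).
#' @param bit_depth 8 or 16 (TIFF only; PNG always writes 8).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path, bit_depth = 16L) {
  stopifnot(inherits(image, "plate_image"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(image$pixels, target = path)
  } else if (ext %in% c("tif", "tiff")) {
    write_tiff_baseline(image$pixels, path, bit_depth = bit_depth)
  } else {
    stop(sprintf("unsupported output format '.%s'", ext), call. = FALSE)
  }
  invisible(path)
}
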