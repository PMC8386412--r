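# Baseline TIFF I/O.
#
# No TIFF reader ships with this package's dependency set, so a minimal
# codec is implemented here. Scope is deliberately narrow: single-image
# baseline TIFF, uncompressed (Compression = 1), grayscale or RGB, 8 or 16
# bits per sample, either byte order, strip-organized. That covers the
# uncompressed exports of gel imagers and scientific cameras; anything else
# (LZW, tiles, planar-separate, palettes) is rejected with a clear message.

.tiff_u16 <- function(raw2, le) {
  if (le) as.integer(raw2[1]) + 256L * as.integer(raw2[2])
  else    as.integer(raw2[2]) + 256L * as.integer(raw2[1])
}

.tiff_u32 <- function(raw4, le) {
  b <- as.numeric(as.integer(raw4))
  if (le) b[1] + 256 * b[2] + 65536 * b[3] + 16777216 * b[4]
  else    b[4] + 256 * b[3] + 65536 * b[2] + 16777216 * b[1]
}

# Read one IFD entry's value vector (SHORT/LONG only, which is all the
# baseline tags use).
.tiff_entry_values <- function(bytes, entry_off, le) {
  tag   <- .tiff_u16(bytes[entry_off + 0:1], le)
  type  <- .tiff_u16(bytes[entry_off + 2:3], le)
  count <- .tiff_u32(bytes[entry_off + 4:7], le)
  size  <- c(`1` = 1L, `3` = 2L, `4` = 4L)[as.character(type)]
  if (is.na(size)) return(list(tag = tag, values = NULL))
  nbytes <- size * count
  voff <- if (nbytes <= 4) entry_off + 8 else .tiff_u32(bytes[entry_off + 8:11], le) + 1
  vals <- numeric(count)
  for (i in seq_len(count)) {
    o <- voff + (i - 1) * size
    vals[i] <- switch(as.character(type),
      `1` = as.numeric(bytes[o]),
      `3` = .tiff_u16(bytes[o + 0:1], le),
      `4` = .tiff_u32(bytes[o + 0:3], le)
    )
  }
  list(tag = tag, values = vals)
}

#' Read a baseline uncompressed TIFF
#'
#' @param path Path to the file.
#' @return List with `data` (matrix for grayscale, `h x w x channels` array
#'   for RGB, intensities scaled to `[0, 1]`) and `bit_depth` (8 or 16).
#' @keywords internal
read_tiff_baseline <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  if (length(bytes) < 8) stop(sprintf("cannot read image '%s': not a TIFF", path), call. = FALSE)
  order_tag <- rawToChar(bytes[1:2])
  le <- identical(order_tag, "II")
  if (!le && !identical(order_tag, "MM")) {
    stop(sprintf("cannot read image '%s': not a TIFF (bad byte-order mark)", path), call. = FALSE)
  }
  if (.tiff_u16(bytes[3:4], le) != 42) {
    stop(sprintf("cannot read image '%s': not a TIFF (bad magic)", path), call. = FALSE)
  }
  ifd <- .tiff_u32(bytes[5:8], le) + 1
  n_entries <- .tiff_u16(bytes[ifd + 0:1], le)
  tags <- list()
  for (k in seq_len(n_entries)) {
    e <- .tiff_entry_values(bytes, ifd + 2 + (k - 1) * 12, le)
    if (!is.null(e$values)) tags[[as.character(e$tag)]] <- e$values
  }
  need <- function(tag, default = NULL) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) {
      if (is.null(default)) {
        stop(sprintf("cannot read image '%s': TIFF missing required tag %d", path, tag),
             call. = FALSE)
      }
      default
    } else v
  }
  width  <- need(256)
  height <- need(257)
  bps    <- need(258, 1)
  comp   <- need(259, 1)
  spp    <- need(277, 1)
  planar <- need(284, 1)
  strip_offsets <- need(273)
  strip_counts  <- need(279, width * height * spp * bps[1] / 8)
  if (comp != 1) {
    stop(sprintf("cannot read image '%s': compressed TIFF not supported (compression=%d)",
                 path, comp), call. = FALSE)
  }
  if (planar != 1) {
    stop(sprintf("cannot read image '%s': planar-separate TIFF not supported", path), call. = FALSE)
  }
  depth <- unique(bps)
  if (length(depth) != 1 || !depth %in% c(8, 16)) {
    stop(sprintf("cannot read image '%s': unsupported bit depth %s (need 8 or 16)",
                 path, paste(bps, collapse = "/")), call. = FALSE)
  }
  if (!spp %in% c(1, 3)) {
    stop(sprintf("cannot read image '%s': %d samples per pixel not supported", path, spp),
         call. = FALSE)
  }
  payload <- raw(sum(strip_counts))
  pos <- 1
  for (i in seq_along(strip_offsets)) {
    o <- strip_offsets[i] + 1
    n <- strip_counts[i]
    payload[pos:(pos + n - 1)] <- bytes[o:(o + n - 1)]
    pos <- pos + n
  }
  n_samples <- width * height * spp
  if (depth == 8) {
    vals <- as.integer(payload[seq_len(n_samples)])
    maxv <- 255
  } else {
    m <- matrix(as.integer(payload[seq_len(2 * n_samples)]), nrow = 2)
    vals <- if (le) m[1, ] + 256L * m[2, ] else m[2, ] + 256L * m[1, ]
    maxv <- 65535
  }
  vals <- vals / maxv
  if (spp == 1) {
    data <- matrix(vals, nrow = height, ncol = width, byrow = TRUE)
  } else {
    # Samples are interleaved R,G,B per pixel, rows top-to-bottom.
    data <- array(0, dim = c(height, width, 3))
    for (ch in 1:3) {
      data[, , ch] <- matrix(vals[seq(ch, n_samples, by = 3)],
                             nrow = height, ncol = width, byrow = TRUE)
    }
  }
  list(data = data, bit_depth = as.integer(depth))
}

.tiff_pack_u16 <- function(x) {
  # little-endian
  as.raw(rbind(x %% 256L, x %/% 256L))
}

.tiff_pack_u32 <- function(x) {
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256, (x %/% 16777216) %% 256))
}

#' Write a baseline uncompressed grayscale TIFF (little-endian, one strip)
#'
#' @param pixels Matrix of intensities in `[0, 1]`.
#' @param path Output path.
#' @param bit_depth 8 or 16.
#' @keywords internal
write_tiff_baseline <- function(pixels, path, bit_depth = 16L) {
  stopifnot(is.matrix(pixels), bit_depth %in% c(8L, 16L))
  h <- nrow(pixels); w <- ncol(pixels)
  maxv <- 2^bit_depth - 1
  q <- as.integer(round(pmin(pmax(t(pixels), 0), 1) * maxv)) # row-major order
  payload <- if (bit_depth == 8L) as.raw(q) else .tiff_pack_u16(q)
  entry <- function(tag, type, count, value) {
    c(.tiff_pack_u16(tag), .tiff_pack_u16(type), .tiff_pack_u32(count), value)
  }
  short_val <- function(x) c(.tiff_pack_u16(x), as.raw(c(0, 0)))
  n_entries <- 8L
  ifd_off <- 8L
  data_off <- ifd_off + 2L + n_entries * 12L + 4L
  entries <- c(
    entry(256, 3, 1, short_val(w)),                   # ImageWidth
    entry(257, 3, 1, short_val(h)),                   # ImageLength
    entry(258, 3, 1, short_val(bit_depth)),           # BitsPerSample
    entry(259, 3, 1, short_val(1)),                   # Compression: none
    entry(262, 3, 1, short_val(1)),                   # Photometric: BlackIsZero
    entry(273, 4, 1, .tiff_pack_u32(data_off)),       # StripOffsets
    entry(277, 3, 1, short_val(1)),                   # SamplesPerPixel
    entry(279, 4, 1, .tiff_pack_u32(length(payload))) # StripByteCounts
  )
  out <- c(
    charToRaw("II"), .tiff_pack_u16(42), .tiff_pack_u32(ifd_off),
    .tiff_pack_u16(n_entries), entries, .tiff_pack_u32(0),
    payload
  )
  writeBin(out, path)
  invisible(path)
}
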