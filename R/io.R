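#' Read a grayscale image from PNG or NIfTI
#'
#' @param path path to an 8/16-bit grayscale PNG or a NIfTI-1 file
#'   (`.nii` / `.nii.gz`).
#' @param slice for 3-D NIfTI volumes, the 1-based axial slice index to
#'   extract; `NULL` selects the middle slice. Ignored for PNG and 2-D NIfTI.
#' @return a double-precision matrix of intensities on the raw integer scale
#'   (0..255 or 0..65535 for PNG). The source bit depth, when known, is kept
#'   in the `bit_depth` attribute and drives the default peak signal in
#'   [metric_report()].
#' @export
read_image <- function(path, slice = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  lower <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lower)) {
    vol <- RNifti::readNifti(path)
    arr <- as.array(vol)
    nd <- length(dim(arr))
    if (nd == 2L) {
      img <- arr
    } else if (nd == 3L) {
      k <- if (is.null(slice)) ceiling(dim(arr)[3] / 2) else as.integer(slice)
      if (k < 1L || k > dim(arr)[3]) {
        stop(sprintf("slice %d out of range [1, %d]", k, dim(arr)[3]), call. = FALSE)
      }
      img <- arr[, , k]
    } else {
      stop(sprintf("unsupported NIfTI dimensionality: %d-D (only 2-D/3-D supported)", nd),
           call. = FALSE)
    }
    img <- matrix(as.numeric(img), nrow(img), ncol(img))
    attr(img, "format") <- "nifti"
    return(img)
  }
  if (grepl("\\.png$", lower)) {
    raw_img <- png::readPNG(path, info = TRUE)
    info <- attr(raw_img, "info")
    if (length(dim(raw_img)) == 3L) {
      nc <- dim(raw_img)[3]
      if (nc >= 3L) {
        stop("unsupported format: RGB PNG; convert to single-channel grayscale first",
             call. = FALSE)
      }
      raw_img <- raw_img[, , 1L]  # gray + alpha: keep the gray channel
    }
    bd <- info$bit.depth
    img <- matrix(as.numeric(raw_img) * (2^bd - 1), nrow(raw_img), ncol(raw_img))
    attr(img, "bit_depth") <- bd
    attr(img, "format") <- "png"
    return(img)
  }
  stop(sprintf("unsupported format: %s (expected .png, .nii or .nii.gz)", path),
       call. = FALSE)
}

#' Write a grayscale image to PNG or NIfTI
#'
#' For PNG output, intensities are rounded and clipped to
#' `[0, 2^bit_depth - 1]`; NIfTI output is written as unclipped
#' floating point.
#'
#' @param img numeric matrix.
#' @param path destination ending in `.png`, `.nii` or `.nii.gz`.
#' @param bit_depth 8 or 16; PNG only.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path, bit_depth = 8L) {
  assert_image(img, "img")
  if (!dir.exists(dirname(path))) {
    stop(sprintf("cannot write %s: parent directory does not exist", path), call. = FALSE)
  }
  lower <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lower)) {
    RNifti::writeNifti(img, path)
    return(invisible(path))
  }
  if (!grepl("\\.png$", lower)) {
    stop(sprintf("unsupported format: %s (expected .png, .nii or .nii.gz)", path),
         call. = FALSE)
  }
  if (!bit_depth %in% c(8L, 16L)) {
    stop("invalid parameter: `bit_depth` must be 8 or 16", call. = FALSE)
  }
  peak <- 2^bit_depth - 1
  q <- pmin(pmax(round(img), 0), peak)
  if (bit_depth == 8L) {
    png::writePNG(q / peak, path)
  } else {
    write_png16(q, path)  # png::writePNG emits 8-bit only
  }
  invisible(path)
}

# ---- minimal 16-bit grayscale PNG encoder ---------------------------------
# The linked PNG library writes 8-bit images; 16-bit output is small enough
# to assemble directly: IHDR + one zlib IDAT (filter 0 scanlines) + IEND.

png_crc_table <- local({
  poly <- -306674912L  # 0xEDB88320 as a signed 32-bit integer
  tab <- integer(256L)
  for (n in 0:255) {
    cc <- n
    for (k in 1:8) {
      cc <- if (bitwAnd(cc, 1L) != 0L) {
        bitwXor(poly, bitwShiftR(cc, 1L))
      } else {
        bitwShiftR(cc, 1L)
      }
    }
    tab[n + 1L] <- cc
  }
  tab
})

png_crc32 <- function(bytes) {
  cc <- -1L
  for (b in as.integer(bytes)) {
    cc <- bitwXor(png_crc_table[bitwAnd(bitwXor(cc, b), 255L) + 1L],
                  bitwShiftR(cc, 8L))
  }
  bitwXor(cc, -1L)
}

png_uint32 <- function(x) {
  writeBin(as.integer(x), raw(), size = 4L, endian = "big")
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(png_uint32(length(data)), body, png_uint32(png_crc32(body)))
}

write_png16 <- function(q, path) {
  A <- nrow(q); B <- ncol(q)
  ihdr <- c(png_uint32(B), png_uint32(A),
            as.raw(c(16L, 0L, 0L, 0L, 0L)))  # depth 16, grayscale, no interlace
  v <- as.integer(t(q))                      # row-major scanline order
  pix <- as.raw(rbind(v %/% 256L, v %% 256L))  # big-endian uint16 pairs
  scan <- matrix(pix, nrow = 2L * B)
  lines <- rbind(as.raw(0L), scan)           # filter byte 0 per scanline
  idat <- memCompress(as.vector(lines), type = "gzip")  # zlib stream
  out <- c(as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)),
           png_chunk("IHDR", ihdr),
           png_chunk("IDAT", idat),
           png_chunk("IEND", raw(0)))
  writeBin(out, path)
}
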