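#' Raster types
#'
#' Images are kept in plain base-R containers: an RGB micrograph is an
#' integer array of dimension `height x width x 3` with intensities in
#' 0--255 (class `rgb_image`), a grey image is a numeric matrix (real-valued
#' internally, clamped to \[0, 255\] on output), and a mask is a logical
#' matrix of the same dimensions as the image it annotates.
#'
#' @param x An array of dimension `h x w x 3` with values in \[0, 255\].
#' @return `rgb_image()` returns a validated `rgb_image` object.
#' @examples
#' img <- rgb_image(array(128L, dim = c(4, 6, 3)))
#' dim(img)
#' @export
rgb_image <- function(x) {
  if (!is.array(x) || length(dim(x)) != 3L)
    abort("an RGB image must be a 3-d array (height x width x 3)",
          "fibromat_bad_image")
  if (dim(x)[3] != 3L)
    abort(sprintf("expected 3 colour channels, got %d", dim(x)[3]),
          "fibromat_bad_image")
  if (dim(x)[1] < 1L || dim(x)[2] < 1L)
    abort("image dimensions must be at least 1 x 1", "fibromat_bad_image")
  if (anyNA(x) || min(x) < 0 || max(x) > 255)
    abort("RGB intensities must be in [0, 255]", "fibromat_bad_image")
  storage.mode(x) <- "integer"
  structure(x, class = "rgb_image")
}

#' @rdname rgb_image
#' @export
is_rgb_image <- function(x) inherits(x, "rgb_image")

#' @export
print.rgb_image <- function(x, ...) {
  cat(sprintf("<rgb_image %d x %d>\n", dim(x)[2], dim(x)[1]))
  invisible(x)
}

as_grey_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    abort("grey image must be a numeric matrix", "fibromat_bad_image")
  x
}

clamp255 <- function(x) pmin(pmax(x, 0), 255)

check_mask <- function(mask, ref = NULL, arg = "mask") {
  if (!is.matrix(mask) || !is.logical(mask))
    abort(sprintf("%s must be a logical matrix", arg), "fibromat_bad_image")
  if (!is.null(ref) && !identical(dim(mask), dim(ref)[1:2]))
    abort(sprintf("%s dimensions do not match the image", arg),
          "fibromat_bad_image")
  invisible(mask)
}

#' Read a micrograph from disk
#'
#' Reads a 24-bit RGB raster from BMP, PNG or TIFF. BMP is parsed directly
#' (uncompressed 24-bit, the format the original acquisition workflow
#' produced); PNG and TIFF are decoded by the \pkg{png} and \pkg{tiff}
#' packages. An alpha channel is dropped with a warning; greyscale input is
#' rejected, since the pipeline expects the stain's colour information.
#'
#' @param path Path to a `.bmp`, `.png`, `.tif`/`.tiff` file.
#' @return An [rgb_image].
#' @export
read_image <- function(path) {
  if (!file.exists(path))
    abort(sprintf("image file not found: %s", path), "fibromat_io")
  magic <- readBin(path, "raw", n = 4L)
  arr <- if (length(magic) >= 2 && rawToChar(magic[1:2]) == "BM") {
    read_bmp(path)
  } else if (length(magic) == 4 &&
             identical(magic, as.raw(c(0x89, 0x50, 0x4e, 0x47)))) {
    decode_to_255(try_decode(png::readPNG(path), path), path)
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE) ||
             rawToChar(magic[1:2]) %in% c("II", "MM")) {
    decode_to_255(try_decode(tiff::readTIFF(path), path), path)
  } else if (grepl("\\.png$", path, ignore.case = TRUE)) {
    decode_to_255(try_decode(png::readPNG(path), path), path)
  } else {
    abort(sprintf("unsupported image format: %s", path), "fibromat_io")
  }
  rgb_image(arr)
}

try_decode <- function(expr, path) {
  out <- tryCatch(expr, error = function(e)
    abort(sprintf("cannot decode image %s: %s", path, conditionMessage(e)),
          "fibromat_io"))
  out
}

decode_to_255 <- function(x, path) {
  if (is.matrix(x) || (is.array(x) && dim(x)[3] == 1L))
    abort(sprintf("greyscale image rejected (%s): the pipeline needs RGB input",
                  path), "fibromat_bad_image")
  if (dim(x)[3] == 4L) {
    warn(sprintf("alpha channel dropped: %s", path), "fibromat_alpha_dropped")
    x <- x[, , 1:3, drop = FALSE]
  }
  if (dim(x)[3] != 3L)
    abort(sprintf("expected 3 colour channels in %s, got %d", path, dim(x)[3]),
          "fibromat_bad_image")
  round(x * 255)
}

# minimal reader for uncompressed 24-bit Windows BMP (BI_RGB), bottom-up or
# top-down; no installed package decodes BMP
read_bmp <- function(path) {
  sz <- file.info(path)$size
  raw <- readBin(path, "raw", n = sz)
  if (sz < 54 || rawToChar(raw[1:2]) != "BM")
    abort(sprintf("cannot decode image %s: not a BMP file", path), "fibromat_io")
  u32 <- function(i) sum(as.integer(raw[i + 0:3]) * 256^(0:3))
  s32 <- function(i) { v <- u32(i); if (v >= 2^31) v - 2^32 else v }
  u16 <- function(i) sum(as.integer(raw[i + 0:1]) * 256^(0:1))
  data_offset <- u32(11)
  width  <- s32(19)
  height <- s32(23)
  bpp    <- u16(29)
  compression <- u32(31)
  if (bpp != 24 || compression != 0)
    abort(sprintf("cannot decode image %s: only uncompressed 24-bit BMP is supported",
                  path), "fibromat_io")
  top_down <- height < 0
  height <- abs(height)
  row_bytes <- 4L * ceiling(3L * width / 4)
  if (data_offset + row_bytes * height > sz)
    abort(sprintf("cannot decode image %s: file truncated", path), "fibromat_io")
  px <- as.integer(raw[(data_offset + 1):(data_offset + row_bytes * height)])
  px <- matrix(px, nrow = row_bytes)[seq_len(3L * width), , drop = FALSE]
  # rows arrive bottom-up unless the height was negative; pixels are BGR
  arr <- array(0L, dim = c(height, width, 3))
  row_order <- if (top_down) seq_len(height) else rev(seq_len(height))
  for (ch in 1:3) {
    plane <- px[seq(4L - ch, by = 3L, length.out = width), , drop = FALSE]
    arr[, , ch] <- t(plane)[row_order, , drop = FALSE]
  }
  arr
}

#' Write an RGB image or mask as PNG
#'
#' @param img An [rgb_image] or a logical mask matrix (written as black/white).
#' @param path Output path (`.png`).
#' @return The path, invisibly.
#' @export
write_image <- function(img, path) {
  if (is.logical(img) && is.matrix(img)) {
    png::writePNG(ifelse(img, 1, 0), path)
  } else {
    if (!is_rgb_image(img)) img <- rgb_image(img)
    png::writePNG(unclass(img) / 255, path)
  }
  invisible(path)
}
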