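#' Read an 8-bit PNG image as an RGB array
#'
#' Minimal, dependency-free PNG reader (bundled zlib-backed codec). Supports
#' bit depth 8, colour types gray / RGB / palette / gray+alpha / RGBA (alpha
#' is dropped), filters 0-4, no interlacing. This covers PNGs written by this
#' package and by mainstream encoders at default settings.
#'
#' @param path path to a PNG file.
#' @return integer array of dimension `c(H, W, 3)` with values in 0-255.
#' @seealso [write_png()]
#' @export
read_png <- function(path) {
  if (!file.exists(path)) stopf("cannot read PNG: file not found: %s", path)
  data <- readBin(path, "raw", n = file.info(path)$size)
  .png_decode(data)
}

#' Write an RGB array as an 8-bit PNG image
#'
#' Always writes colour type 2 (RGB), filter 0, a single IDAT chunk at a
#' fixed compression level — output bytes are deterministic for a given
#' pixel array.
#'
#' @param pixels integer array `c(H, W, 3)`, values 0-255.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_png <- function(pixels, path) {
  d <- dim(pixels)
  if (length(d) != 3L || d[3] != 3L)
    stopf("`pixels` must be an H x W x 3 array")
  bytes <- .png_encode(as.integer(pixels), d[1], d[2])
  writeBin(bytes, path)
  invisible(path)
}
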