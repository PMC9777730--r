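#' Construct an elastogram from an RGB pixel array
#'
#' An elastogram is an RGB crop of the SWE colour field together with its
#' validity mask: chromatic pixels carry a stiffness signal, achromatic
#' pixels (black signal voids, grayscale furniture) are rejected from every
#' downstream statistic.
#'
#' @param pixels integer array `c(H, W, 3)`, components 0-255.
#' @param saturation_threshold achromatic threshold for [classify_pixels()].
#' @param source_id identifier string.
#' @param label `"benign"`, `"malignant"` or `"unknown"`.
#' @return object of class `elastogram`: list with `pixels`, `valid_mask`
#'   (H x W logical), `source_id`, `label`.
#' @export
elastogram <- function(pixels, saturation_threshold = 20L,
                       source_id = "image", label = "unknown") {
  d <- dim(pixels)
  if (length(d) != 3L || d[3] != 3L || d[1] < 1L || d[2] < 1L)
    stopf("`pixels` must be a nonempty H x W x 3 array")
  if (any(!is.finite(pixels)) || any(pixels < 0) || any(pixels > 255))
    stopf("pixel components must be in 0..255")
  label <- match.arg(label, c("benign", "malignant", "unknown"))
  storage.mode(pixels) <- "integer"
  flat <- matrix(pixels, ncol = 3L)
  mask <- matrix(is_chromatic(flat, saturation_threshold), d[1], d[2])
  structure(list(pixels = pixels, valid_mask = mask,
                 source_id = as.character(source_id), label = label),
            class = "elastogram")
}

#' @export
print.elastogram <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<elastogram '%s' [%s]: %d x %d px, %d valid (%.1f%%)>\n",
              x$source_id, x$label, d[1], d[2], sum(x$valid_mask),
              100 * mean(x$valid_mask)))
  invisible(x)
}

#' Load an elastogram crop from a PNG file
#'
#' Reads the image, optionally crops it, and computes the validity mask via
#' the achromatic classifier. JPEG input is not decodable with the bundled
#' codec; convert to PNG first (lossless with respect to the decoded JPEG).
#'
#' @param path path to a PNG file.
#' @param saturation_threshold achromatic threshold; default 20.
#' @param crop optional `c(x0, y0, x1, y1)` rectangle in 0-based, half-open
#'   pixel coordinates (x = column, y = row).
#' @param source_id identifier; defaults to the file name.
#' @param label image label; `"unknown"` until assigned from a manifest.
#' @return an [elastogram()] object.
#' @export
load_elastogram <- function(path, saturation_threshold = 20L, crop = NULL,
                            source_id = NULL, label = "unknown") {
  if (grepl("\\.jpe?g$", path, ignore.case = TRUE))
    stopf(paste0("JPEG decoding is not bundled; convert '%s' to PNG first ",
                 "(e.g. `python -c \"from PIL import Image; ",
                 "Image.open('f.jpg').convert('RGB').save('f.png')\"`)"), path)
  px <- read_png(path)
  if (!is.null(crop)) {
    if (length(crop) != 4L) stopf("`crop` must be c(x0, y0, x1, y1)")
    x0 <- crop[1]; y0 <- crop[2]; x1 <- crop[3]; y1 <- crop[4]
    d <- dim(px)
    if (x0 < 0 || y0 < 0 || x1 > d[2] || y1 > d[1] || x0 >= x1 || y0 >= y1)
      stopf("crop rectangle [%g,%g)x[%g,%g) outside image bounds %dx%d",
            x0, x1, y0, y1, d[2], d[1])
    px <- px[(y0 + 1):y1, (x0 + 1):x1, , drop = FALSE]
  }
  elastogram(px, saturation_threshold,
             source_id = source_id %||% basename(path), label = label)
}
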