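#' Build a stiffness colormap
#'
#' Constructs the invertible lookup between tissue stiffness (kPa) and RGB
#' colour used by SWE heatmap displays: low stiffness maps to cool colours,
#' high stiffness to warm colours, linearly over the kPa range. The vendor's
#' exact ramp is not published; the default `"linear-bgr"` variant linearly
#' traverses blue (0,0,255) -> green (0,255,0) -> red (255,0,0), and a
#' `"jet"` variant adds cyan and yellow waypoints so sensitivity to the ramp
#' choice can be probed.
#'
#' Level `i` (0-based) carries stiffness
#' `kpa_min + i * (kpa_max - kpa_min) / (n_levels - 1)`. Along the level
#' index the red component is non-decreasing and the blue component
#' non-increasing, which makes nearest-colour inversion well-posed.
#'
#' @param n_levels number of LUT levels (>= 2); default 256.
#' @param kpa_range ordered `c(min, max)` stiffness range in kPa; default
#'   `c(0, 180)`, the fixed vendor display scale.
#' @param variant ramp identifier, `"linear-bgr"` (default) or `"jet"`.
#' @return an object of class `stiffness_colormap`: list with `levels`
#'   (`n_levels` x 3 integer matrix), `kpa_min`, `kpa_max`, `name`.
#' @examples
#' cm <- build_colormap()
#' stiffness_to_color(0, cm)    # c(0, 0, 255)
#' stiffness_to_color(180, cm)  # c(255, 0, 0)
#' @export
build_colormap <- function(n_levels = 256L, kpa_range = c(0, 180),
                           variant = c("linear-bgr", "jet")) {
  variant <- match.arg(variant)
  if (!is_count(n_levels, min = 2L))
    stopf("`n_levels` must be an integer >= 2")
  if (length(kpa_range) != 2L || !all(is.finite(kpa_range)) ||
      kpa_range[1] >= kpa_range[2])
    stopf("`kpa_range` must be an ordered pair (min < max)")

  waypoints <- switch(variant,
    "linear-bgr" = rbind(c(0, 0, 255), c(0, 255, 0), c(255, 0, 0)),
    "jet" = rbind(c(0, 0, 255), c(0, 255, 255), c(0, 255, 0),
                  c(255, 255, 0), c(255, 0, 0)))
  t <- seq(0, 1, length.out = n_levels)
  knots <- seq(0, 1, length.out = nrow(waypoints))
  levels <- sapply(1:3, function(k)
    round(approx(knots, waypoints[, k], xout = t)$y))
  storage.mode(levels) <- "integer"

  structure(
    list(levels = levels,
         kpa_min = as.numeric(kpa_range[1]),
         kpa_max = as.numeric(kpa_range[2]),
         name = variant),
    class = "stiffness_colormap")
}

# stiffness carried by each LUT level, in level order
level_stiffness <- function(cmap) {
  seq(cmap$kpa_min, cmap$kpa_max, length.out = nrow(cmap$levels))
}

#' @export
print.stiffness_colormap <- function(x, ...) {
  cat(sprintf("<stiffness_colormap '%s': %d levels over %g-%g kPa>\n",
              x$name, nrow(x$levels), x$kpa_min, x$kpa_max))
  invisible(x)
}

#' Map stiffness values to heatmap colours
#'
#' Returns the LUT level whose stiffness is nearest to `kpa`. Values outside
#' the colormap range are clamped (rendered fields may exceed the display
#' scale, as real lesions do).
#'
#' @param kpa numeric vector of stiffness values in kPa; must be finite.
#' @param cmap a [build_colormap()] object.
#' @return for a single value, an integer RGB triple; for a vector, an
#'   `n x 3` integer matrix with columns R, G, B.
#' @export
stiffness_to_color <- function(kpa, cmap) {
  stopifnot(inherits(cmap, "stiffness_colormap"))
  if (!is.numeric(kpa) || length(kpa) == 0L || any(!is.finite(kpa)))
    stopf("`kpa` must be finite numeric")
  L <- nrow(cmap$levels)
  t <- (pmin(pmax(kpa, cmap$kpa_min), cmap$kpa_max) - cmap$kpa_min) /
    (cmap$kpa_max - cmap$kpa_min)
  idx <- as.integer(round(t * (L - 1))) + 1L
  out <- cmap$levels[idx, , drop = FALSE]
  colnames(out) <- c("R", "G", "B")
  if (length(kpa) == 1L) out[1L, ] else out
}

#' Decode heatmap colours back to stiffness
#'
#' Inverts the rendering by nearest-neighbour search in RGB Euclidean
#' distance over the LUT (robust to JPEG chroma noise, unlike analytic ramp
#' inversion); ties break toward the lower-stiffness level. Achromatic
#' (grayscale) pixels carry no stiffness signal and must be masked out by
#' the caller first; passing one is an error.
#'
#' @param rgb an RGB triple or an `n x 3` matrix of 0-255 components.
#' @param cmap a [build_colormap()] object.
#' @param saturation_threshold achromatic rejection threshold passed to
#'   [classify_pixels()]; default 20.
#' @return numeric stiffness in kPa (length n).
#' @export
color_to_stiffness <- function(rgb, cmap, saturation_threshold = 20L) {
  stopifnot(inherits(cmap, "stiffness_colormap"))
  rgb <- as_rgb_matrix(rgb)
  cls <- classify_pixels(rgb, saturation_threshold)
  if (any(cls == "achromatic"))
    stopf("achromatic pixel(s) passed to color_to_stiffness(); mask voids first")
  idx <- .nn_level(rgb, cmap$levels)
  level_stiffness(cmap)[idx]
}

#' Classify pixels as chromatic signal or achromatic void
#'
#' SWE displays render regions without a valid stiffness estimate as
#' grayscale (black signal voids, gray annotation); those pixels must never
#' contribute to histograms or ROI statistics. A pixel is achromatic iff
#' `max(R,G,B) - min(R,G,B) <= saturation_threshold`.
#'
#' @param rgb an RGB triple or `n x 3` matrix, components 0-255.
#' @param saturation_threshold integer 0-255; the default 20 is wide enough
#'   to absorb JPEG ringing on black voids while keeping every saturated
#'   ramp colour.
#' @return character vector, `"chromatic"` or `"achromatic"` per pixel.
#' @examples
#' classify_pixels(c(0, 0, 0))      # achromatic (black void)
#' classify_pixels(c(0, 0, 255))    # chromatic
#' @export
classify_pixels <- function(rgb, saturation_threshold = 20L) {
  rgb <- as_rgb_matrix(rgb)
  ifelse(is_chromatic(rgb, saturation_threshold), "chromatic", "achromatic")
}

# logical form used internally on n x 3 matrices
is_chromatic <- function(rgb, saturation_threshold = 20L) {
  if (!is.numeric(saturation_threshold) || length(saturation_threshold) != 1L ||
      saturation_threshold < 0 || saturation_threshold > 255)
    stopf("`saturation_threshold` must be a single value in 0..255")
  mx <- pmax(rgb[, 1], rgb[, 2], rgb[, 3])
  mn <- pmin(rgb[, 1], rgb[, 2], rgb[, 3])
  (mx - mn) > saturation_threshold
}

as_rgb_matrix <- function(rgb) {
  if (is.null(dim(rgb))) {
    if (length(rgb) != 3L) stopf("an RGB value must have 3 components")
    rgb <- matrix(rgb, nrow = 1L)
  }
  if (ncol(rgb) != 3L) stopf("`rgb` must be an n x 3 matrix")
  if (any(!is.finite(rgb)) || any(rgb < 0) || any(rgb > 255))
    stopf("RGB components must be finite and in 0..255")
  storage.mode(rgb) <- "integer"
  rgb
}

#' Serialize a colormap to JSON
#'
#' Writes `{name, kpa_min, kpa_max, levels: [[r,g,b], ...]}`.
#'
#' @param cmap a [build_colormap()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_colormap <- function(cmap, path) {
  stopifnot(inherits(cmap, "stiffness_colormap"))
  obj <- list(name = cmap$name, kpa_min = cmap$kpa_min,
              kpa_max = cmap$kpa_max,
              levels = unname(apply(cmap$levels, 1, identity, simplify = FALSE)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a colormap from JSON
#'
#' @param path a file written by [write_colormap()] (or hand-authored with
#'   the same schema).
#' @return a `stiffness_colormap` object.
#' @export
read_colormap <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  levels <- obj$levels
  if (is.list(levels)) levels <- do.call(rbind, levels)
  storage.mode(levels) <- "integer"
  if (ncol(levels) != 3L || nrow(levels) < 2L)
    stopf("colormap JSON: `levels` must be a list of >= 2 RGB triples")
  if (is.unsorted(levels[, 1]) || is.unsorted(rev(levels[, 3])))
    stopf("colormap JSON: red must be non-decreasing and blue non-increasing")
  structure(
    list(levels = levels, kpa_min = as.numeric(obj$kpa_min),
         kpa_max = as.numeric(obj$kpa_max), name = as.character(obj$name)),
    class = "stiffness_colormap")
}
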