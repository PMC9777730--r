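#' Define a circular region of interest
#'
#' Conventional SWE readouts place a circular ROI in the centre of the
#' target lesion (and a reference ROI in the surrounding fat pad).
#'
#' @param center `c(row, col)` in 0-based pixel coordinates.
#' @param radius radius in pixels, > 0.
#' @param kind `"target"` or `"reference"`.
#' @return object of class `circular_roi`.
#' @export
circular_roi <- function(center, radius, kind = c("target", "reference")) {
  kind <- match.arg(kind)
  if (length(center) != 2L || any(!is.finite(center)))
    stopf("`center` must be c(row, col)")
  if (!is.numeric(radius) || length(radius) != 1L || !is.finite(radius) ||
      radius <= 0)
    stopf("`radius` must be a single positive number")
  structure(list(center = as.numeric(center), radius = as.numeric(radius),
                 kind = kind),
            class = "circular_roi")
}

#' Boolean mask of a circular ROI
#'
#' Pixel `(r, c)` (0-based) is included iff
#' `(r - center_r)^2 + (c - center_c)^2 <= radius^2` (centre-of-pixel
#' inclusion, no anti-aliased partial pixels), clipped to the image bounds.
#'
#' @param roi a [circular_roi()].
#' @param shape image shape `c(H, W)`.
#' @return `H x W` logical matrix; errors if the circle misses the image
#'   entirely.
#' @export
circular_mask <- function(roi, shape) {
  stopifnot(inherits(roi, "circular_roi"))
  if (length(shape) != 2L || any(shape < 1L))
    stopf("`shape` must be positive c(H, W)")
  H <- as.integer(shape[1]); W <- as.integer(shape[2])
  r <- (0:(H - 1)) - roi$center[1]
  c <- (0:(W - 1)) - roi$center[2]
  mask <- outer(r^2, c^2, `+`) <= roi$radius^2
  if (!any(mask))
    stopf("ROI (centre %g,%g radius %g) does not intersect a %d x %d image",
          roi$center[1], roi$center[2], roi$radius, H, W)
  mask
}

#' ROI stiffness statistics (SWEavg, SWEmax, min, SD)
#'
#' Decodes every valid (chromatic) pixel inside the ROI to kPa via the
#' colormap inversion, then aggregates: pixels are decoded individually and
#' then averaged, not the other way round, so bimodal ROIs are handled
#' correctly. Void pixels are excluded and `n_pixels` reports how many
#' pixels actually contributed.
#'
#' @param img an [elastogram()].
#' @param roi a [circular_roi()].
#' @param cmap a [build_colormap()] object.
#' @return object of class `swe_roi_stats`: list with `mean_kpa`,
#'   `min_kpa`, `max_kpa`, `sd_kpa` (sample SD, `NA` for a single pixel)
#'   and `n_pixels`.
#' @export
roi_stats <- function(img, roi, cmap) {
  stopifnot(inherits(img, "elastogram"))
  mask <- circular_mask(roi, dim(img$pixels)[1:2]) & img$valid_mask
  n <- sum(mask)
  if (n == 0L)
    stopf("ROI lies entirely in signal void: no valid pixels to decode")
  flat <- matrix(img$pixels, ncol = 3L)
  vals <- color_to_stiffness(flat[as.vector(mask), , drop = FALSE], cmap)
  structure(list(mean_kpa = mean(vals), min_kpa = min(vals),
                 max_kpa = max(vals),
                 sd_kpa = if (n > 1L) sd(vals) else NA_real_,
                 n_pixels = n, kind = roi$kind),
            class = "swe_roi_stats")
}

#' @export
print.swe_roi_stats <- function(x, ...) {
  cat(sprintf(
    "<swe_roi_stats [%s]: mean %.1f, min %.1f, max %.1f, sd %s kPa (n=%d)>\n",
    x$kind, x$mean_kpa, x$min_kpa, x$max_kpa,
    ifelse(is.na(x$sd_kpa), "NA", sprintf("%.1f", x$sd_kpa)), x$n_pixels))
  invisible(x)
}

#' Q-box ratio
#'
#' Ratio of the target ROI mean stiffness to the reference (surrounding fat
#' pad) ROI mean stiffness — the vendor's trademarked elasticity-ratio
#' readout.
#'
#' @param target,reference [roi_stats()] results (or bare numeric kPa
#'   means).
#' @return dimensionless ratio.
#' @export
qbox_ratio <- function(target, reference) {
  tm <- if (inherits(target, "swe_roi_stats")) target$mean_kpa else target
  rm <- if (inherits(reference, "swe_roi_stats")) reference$mean_kpa else reference
  if (!is.finite(rm) || rm <= 0)
    stopf("Q-box ratio undefined: reference mean stiffness must be > 0")
  tm / rm
}
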