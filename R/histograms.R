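#' Bin-range partition of the 250-bin histogram
#'
#' The 250 bins are split into four inclusive, disjoint index ranges that
#' jointly cover 1-250: near-black and near-saturated tails are rejected as
#' noise, and the remainder is split into "low-intensity" and
#' "high-intensity" bins used for the AUC descriptors. Defaults: noise
#' 1-14 and 201-250, low 15-100, high 101-200.
#'
#' @param noise_low,low,high,noise_high inclusive `c(from, to)` bin-index
#'   ranges.
#' @return object of class `bin_ranges`.
#' @export
bin_ranges <- function(noise_low = c(1L, 14L), low = c(15L, 100L),
                       high = c(101L, 200L), noise_high = c(201L, 250L)) {
  rg <- list(noise_low = noise_low, low = low, high = high,
             noise_high = noise_high)
  covered <- integer(0)
  for (nm in names(rg)) {
    r <- rg[[nm]]
    if (length(r) != 2L || r[1] > r[2] || r[1] < 1L || r[2] > 250L)
      stopf("bin range `%s` must be an ordered pair within 1..250", nm)
    rg[[nm]] <- as.integer(r)
    covered <- c(covered, r[1]:r[2])
  }
  if (anyDuplicated(covered) || length(covered) != 250L)
    stopf("bin ranges must be disjoint and jointly cover 1..250")
  structure(rg, class = "bin_ranges")
}

N_BINS <- 250L

# 1-based bin index of 8-bit intensities under 250 equal-width half-open
# bins over [0, 256): bin k covers [(k-1)*256/250, k*256/250)
intensity_bin <- function(v) as.integer((as.integer(v) * N_BINS) %/% 256L) + 1L

# intensity at the centre of each bin
bin_centers <- function() ((seq_len(N_BINS) - 0.5) * 256) / N_BINS

CHANNELS <- c("warm", "intermediate", "cool") # R, G, B

#' Extract per-channel 250-bin histograms from an elastogram
#'
#' For each of the warm (R), intermediate (G) and cool (B) channels, counts
#' valid (chromatic) pixels into 250 equal-width half-open bins over
#' `[0, 256)` and normalizes each channel to unit sum. By default the noise
#' bins participate in the normalization and are excluded only at the AUC
#' stage, so AUC fractions are comparable across crops of different sizes;
#' set `exclude_noise_before_normalize = TRUE` to zero the noise ranges
#' first and renormalize over the remaining bins.
#'
#' @param img an [elastogram()].
#' @param exclude_noise_before_normalize logical; see above. Default `FALSE`.
#' @param ranges a [bin_ranges()] object, used only when noise bins are
#'   excluded before normalization.
#' @return object of class `channel_histograms`: list with `counts`
#'   (3 x 250 integer, rows warm/intermediate/cool), `normalized`
#'   (3 x 250 numeric), `n_valid_pixels`.
#' @export
extract_histograms <- function(img, exclude_noise_before_normalize = FALSE,
                               ranges = bin_ranges()) {
  stopifnot(inherits(img, "elastogram"))
  flat <- matrix(img$pixels, ncol = 3L)
  valid <- as.vector(img$valid_mask)
  n_valid <- sum(valid)
  counts <- matrix(0L, nrow = 3L, ncol = N_BINS,
                   dimnames = list(CHANNELS, NULL))
  for (k in 1:3)
    counts[k, ] <- tabulate(intensity_bin(flat[valid, k]), nbins = N_BINS)

  eff <- counts
  if (exclude_noise_before_normalize) {
    stopifnot(inherits(ranges, "bin_ranges"))
    drop <- c(ranges$noise_low[1]:ranges$noise_low[2],
              ranges$noise_high[1]:ranges$noise_high[2])
    eff[, drop] <- 0L
  }
  normalized <- matrix(0, nrow = 3L, ncol = N_BINS,
                       dimnames = list(CHANNELS, NULL))
  for (k in 1:3) {
    s <- sum(eff[k, ])
    if (s > 0) normalized[k, ] <- eff[k, ] / s
  }
  structure(list(counts = counts, normalized = normalized,
                 n_valid_pixels = n_valid),
            class = "channel_histograms")
}

#' @export
print.channel_histograms <- function(x, ...) {
  cat(sprintf("<channel_histograms: %d valid pixels, 3 x %d bins>\n",
              x$n_valid_pixels, ncol(x$counts)))
  invisible(x)
}

match_channel <- function(channel) {
  if (is.numeric(channel)) {
    if (!channel %in% 1:3) stopf("channel index must be 1, 2 or 3")
    return(as.integer(channel))
  }
  match(match.arg(channel, CHANNELS), CHANNELS)
}

#' Bin-range AUC of a channel histogram
#'
#' The "integral tissue signal" descriptor: the sum of the normalized
#' histogram over an inclusive bin-index range.
#'
#' @param hist a [extract_histograms()] result.
#' @param channel `"warm"`, `"intermediate"` or `"cool"` (or index 1-3).
#' @param range inclusive `c(from, to)` bin indices within 1-250.
#' @return a fraction in `[0, 1]`.
#' @export
bin_range_auc <- function(hist, channel, range) {
  stopifnot(inherits(hist, "channel_histograms"))
  k <- match_channel(channel)
  if (length(range) != 2L || range[1] > range[2] ||
      range[1] < 1L || range[2] > N_BINS)
    stopf("`range` must be an ordered pair within 1..%d", N_BINS)
  sum(hist$normalized[k, range[1]:range[2]])
}

#' Skewness of a channel histogram
#'
#' Fisher-Pearson sample skewness (bias-uncorrected third standardized
#' central moment) of bin-centre intensities weighted by the normalized
#' counts. Undefined (returned as `NA` with a warning) when fewer than two
#' valid pixels are present or the channel has zero variance; never
#' reported as 0 in those cases.
#'
#' @inheritParams bin_range_auc
#' @return numeric skewness, or `NA_real_` when undefined.
#' @export
histogram_skewness <- function(hist, channel) {
  stopifnot(inherits(hist, "channel_histograms"))
  k <- match_channel(channel)
  w <- hist$normalized[k, ]
  if (hist$n_valid_pixels < 2L || sum(w) == 0) {
    warning("skewness undefined: fewer than 2 valid pixels", call. = FALSE)
    return(NA_real_)
  }
  x <- bin_centers()
  mu <- sum(w * x)
  m2 <- sum(w * (x - mu)^2)
  if (m2 <= 0) {
    warning("skewness undefined: zero variance", call. = FALSE)
    return(NA_real_)
  }
  sum(w * (x - mu)^3) / m2^1.5
}

#' Per-image descriptor vector
#'
#' Assembles the low/high bin-range AUC per channel (6 values) and skewness
#' per channel (3 values) into one record. Undefined skewness propagates as
#' `NA` fields.
#'
#' @param img an [elastogram()].
#' @param ranges a [bin_ranges()] partition.
#' @param hist optionally a precomputed [extract_histograms()] result for
#'   `img` (avoids recomputation in cohort loops).
#' @return one-row `data.frame` with columns `source_id`, `label`,
#'   `auc_low_*`, `auc_high_*` for warm/intermediate/cool, `skew_*`, and
#'   `n_valid_pixels`.
#' @export
compute_features <- function(img, ranges = bin_ranges(), hist = NULL) {
  stopifnot(inherits(img, "elastogram"), inherits(ranges, "bin_ranges"))
  h <- hist %||% extract_histograms(img)
  out <- list(source_id = img$source_id, label = img$label)
  for (ch in CHANNELS) {
    out[[paste0("auc_low_", ch)]] <- bin_range_auc(h, ch, ranges$low)
    out[[paste0("auc_high_", ch)]] <- bin_range_auc(h, ch, ranges$high)
  }
  for (ch in CHANNELS)
    out[[paste0("skew_", ch)]] <-
      if (h$n_valid_pixels < 2L) NA_real_
      else suppressWarnings(histogram_skewness(h, ch))
  out$n_valid_pixels <- h$n_valid_pixels
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Cohort-mean normalized histogram of one channel
#'
#' Bin-wise arithmetic mean of the per-image normalized histograms; used for
#' group-level histogram displays and the "faithful" KS comparison mode.
#'
#' @param hists nonempty list of [extract_histograms()] results, all from
#'   images with at least one valid pixel.
#' @param channel `"warm"`, `"intermediate"` or `"cool"`.
#' @return numeric vector of 250 fractions summing to 1.
#' @export
cohort_mean_histogram <- function(hists, channel) {
  if (!is.list(hists) || length(hists) == 0L)
    stopf("`hists` must be a nonempty list of channel_histograms")
  k <- match_channel(channel)
  rows <- vapply(hists, function(h) {
    stopifnot(inherits(h, "channel_histograms"))
    if (isTRUE(h$n_valid_pixels == 0L))
      stopf("cohort_mean_histogram: image with empty valid mask")
    h$normalized[k, ]
  }, numeric(N_BINS))
  rowMeans(rows)
}
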