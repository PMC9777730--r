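#' Extract features and histograms for a whole cohort
#'
#' Accepts either a manifest `data.frame` (columns `source_id`, `path`,
#' `label`, optional `crop_x0`, `crop_y0`, `crop_x1`, `crop_y1`) with a
#' base directory, or a list of in-memory [elastogram()] objects. Images
#' whose valid mask is empty are reported with a warning and excluded (not
#' silently dropped); unreadable files produce per-row error records.
#'
#' @param x manifest `data.frame` or list of elastograms.
#' @param dir base directory for manifest paths.
#' @param ranges a [bin_ranges()] partition.
#' @param saturation_threshold achromatic threshold for loading.
#' @param exclude_noise_before_normalize passed to [extract_histograms()].
#' @return list with `features` (data.frame, one row per usable image),
#'   `histograms` (aligned list of `channel_histograms`), `errors`
#'   (data.frame of failed rows: `source_id`, `reason`).
#' @export
extract_cohort_features <- function(x, dir = ".", ranges = bin_ranges(),
                                    saturation_threshold = 20L,
                                    exclude_noise_before_normalize = FALSE) {
  if (is.data.frame(x)) {
    need <- c("source_id", "path", "label")
    if (!all(need %in% names(x)))
      stopf("manifest must have columns: %s", paste(need, collapse = ", "))
    images <- vector("list", nrow(x))
    errors <- list()
    for (i in seq_len(nrow(x))) {
      crop <- NULL
      if (all(c("crop_x0", "crop_y0", "crop_x1", "crop_y1") %in% names(x)) &&
          !is.na(x$crop_x0[i]))
        crop <- c(x$crop_x0[i], x$crop_y0[i], x$crop_x1[i], x$crop_y1[i])
      images[[i]] <- tryCatch(
        load_elastogram(file.path(dir, x$path[i]),
                        saturation_threshold = saturation_threshold,
                        crop = crop, source_id = x$source_id[i],
                        label = x$label[i]),
        error = function(e) {
          errors[[length(errors) + 1L]] <<-
            data.frame(source_id = x$source_id[i],
                       reason = conditionMessage(e),
                       stringsAsFactors = FALSE)
          NULL
        })
    }
    keep <- !vapply(images, is.null, logical(1))
    images <- images[keep]
  } else if (is.list(x)) {
    images <- x
    errors <- list()
  } else stopf("`x` must be a manifest data.frame or a list of elastograms")

  feats <- list(); hists <- list()
  for (img in images) {
    h <- extract_histograms(img, exclude_noise_before_normalize, ranges)
    if (h$n_valid_pixels == 0L) {
      warning(sprintf("image '%s' has an empty valid mask; excluded",
                      img$source_id), call. = FALSE)
      errors[[length(errors) + 1L]] <-
        data.frame(source_id = img$source_id, reason = "empty valid mask",
                   stringsAsFactors = FALSE)
      next
    }
    feats[[length(feats) + 1L]] <- compute_features(img, ranges, hist = h)
    hists[[length(hists) + 1L]] <- h
  }
  list(features = if (length(feats)) do.call(rbind, feats) else NULL,
       histograms = hists,
       errors = if (length(errors)) do.call(rbind, errors)
                else data.frame(source_id = character(0),
                                reason = character(0)))
}

# long-format serialization of per-image normalized histograms, so the KS
# block of cmd_compare can be recomputed from files alone
histograms_to_df <- function(hists, source_ids) {
  do.call(rbind, lapply(seq_along(hists), function(i) {
    h <- hists[[i]]
    data.frame(source_id = source_ids[i],
               channel = rep(CHANNELS, each = N_BINS),
               bin = rep(seq_len(N_BINS), times = 3L),
               normalized = as.vector(t(h$normalized)),
               stringsAsFactors = FALSE)
  }))
}

df_to_histograms <- function(df) {
  ids <- unique(df$source_id)
  hists <- lapply(ids, function(id) {
    sub <- df[df$source_id == id, ]
    normalized <- matrix(0, 3L, N_BINS, dimnames = list(CHANNELS, NULL))
    for (ch in CHANNELS) {
      s <- sub[sub$channel == ch, ]
      normalized[ch, s$bin] <- s$normalized
    }
    structure(list(counts = NULL, normalized = normalized,
                   n_valid_pixels = NA_integer_),
              class = "channel_histograms")
  })
  names(hists) <- ids
  hists
}
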