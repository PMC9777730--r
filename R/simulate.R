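# Seeded synthetic elastogram cohorts. The generator states a fixed world:
# a two-component soft/intermediate background, a centred lesion disc with
# gaussian stiffness, an optional stiff peritumoral rim, and random black
# signal voids. Component means (~15 / ~45 kPa) are chosen to land in the
# cool and intermediate bands of the 0-180 kPa ramp; they are config
# defaults, not claims about tissue.

SOFT_SHAPE <- 9          # gamma shape, both background components
SOFT_MEAN <- 15          # kPa, soft (fat-like) component
INTERMEDIATE_MEAN <- 45  # kPa, intermediate (fibroglandular) component
RIM_SD <- 5              # kPa spread of the stiff rim

#' Lesion and background parameters for the simulator
#'
#' @param mean_kpa,sd_kpa mean and SD of the gaussian lesion stiffness
#'   (truncated at 0 kPa).
#' @param radius_px lesion disc radius in pixels (0 disables the lesion).
#' @param rim_width_px width of the stiff peritumoral rim annulus; 0
#'   (default) disables the rim.
#' @param rim_kpa stiffness of the rim annulus.
#' @param soft_fraction fraction of background pixels drawn from the soft
#'   (~15 kPa) component rather than the intermediate (~45 kPa) one; the
#'   malignancy axis of the simulator (soft-tissue reduction).
#' @return object of class `lesion_params`.
#' @export
lesion_params <- function(mean_kpa = 60, sd_kpa = 20, radius_px = 48,
                          rim_width_px = 0, rim_kpa = 120,
                          soft_fraction = 0.6) {
  if (mean_kpa < 0 || sd_kpa < 0 || radius_px < 0 || rim_width_px < 0 ||
      rim_kpa < 0)
    stopf("lesion parameters must be non-negative")
  if (soft_fraction < 0 || soft_fraction > 1)
    stopf("`soft_fraction` must be in [0, 1]")
  structure(list(mean_kpa = mean_kpa, sd_kpa = sd_kpa, radius_px = radius_px,
                 rim_width_px = rim_width_px, rim_kpa = rim_kpa,
                 soft_fraction = soft_fraction),
            class = "lesion_params")
}

#' Cohort specification for the simulator
#'
#' Defaults mirror the study design the package targets: 32 benign and 64
#' malignant images, with the malignant group differing only in a reduced
#' soft-tissue fraction (0.2 vs 0.6).
#'
#' @param n_benign,n_malignant image counts (>= 1).
#' @param image_shape `c(H, W)` in pixels.
#' @param benign,malignant [lesion_params()] per group.
#' @param void_fraction fraction of pixels blacked out as signal voids,
#'   in `[0, 1)`.
#' @param seed integer master seed; per-image child seeds derive from it.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_benign = 32L, n_malignant = 64L,
                        image_shape = c(256L, 256L),
                        benign = lesion_params(soft_fraction = 0.6),
                        malignant = lesion_params(soft_fraction = 0.2),
                        void_fraction = 0.1, seed = 1L) {
  if (!is_count(n_benign) || !is_count(n_malignant))
    stopf("image counts must be integers >= 1")
  if (length(image_shape) != 2L || any(image_shape < 1L))
    stopf("`image_shape` must be positive c(H, W)")
  stopifnot(inherits(benign, "lesion_params"),
            inherits(malignant, "lesion_params"))
  if (void_fraction < 0 || void_fraction >= 1)
    stopf("`void_fraction` must be in [0, 1)")
  structure(list(n_benign = as.integer(n_benign),
                 n_malignant = as.integer(n_malignant),
                 image_shape = as.integer(image_shape),
                 benign = benign, malignant = malignant,
                 void_fraction = void_fraction, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a stiffness field
#'
#' Background pixels are a two-component mixture: with probability
#' `soft_fraction` a soft gamma component (mean ~15 kPa, SD 5), otherwise
#' an intermediate gamma component (mean ~45 kPa, SD 15; its heavier right
#' tail reflects fibroglandular tissue occasionally reaching high
#' stiffness). A centred disc of `radius_px` receives gaussian stiffness
#' `(mean_kpa, sd_kpa)` truncated at 0; an annulus of `rim_width_px` just
#' outside the disc is set near `rim_kpa`. Deterministic given
#' `rng_seed`.
#'
#' @param params a [lesion_params()].
#' @param shape `c(H, W)`.
#' @param rng_seed integer seed.
#' @return `H x W` numeric matrix of stiffness in kPa.
#' @export
simulate_stiffness_field <- function(params, shape, rng_seed) {
  stopifnot(inherits(params, "lesion_params"))
  if (length(shape) != 2L || any(!is.finite(shape)) || any(shape < 1L))
    stopf("`shape` must be positive c(H, W)")
  H <- as.integer(shape[1]); W <- as.integer(shape[2])
  with_seed(rng_seed, {
    n <- H * W
    soft <- runif(n) < params$soft_fraction
    scale <- ifelse(soft, SOFT_MEAN / SOFT_SHAPE, INTERMEDIATE_MEAN / SOFT_SHAPE)
    field <- matrix(rgamma(n, shape = SOFT_SHAPE) * scale, H, W)

    if (params$radius_px > 0) {
      cr <- (H - 1) / 2; cc <- (W - 1) / 2
      d2 <- outer(((0:(H - 1)) - cr)^2, ((0:(W - 1)) - cc)^2, `+`)
      disc <- d2 <= params$radius_px^2
      field[disc] <- pmax(0, rnorm(sum(disc), params$mean_kpa, params$sd_kpa))
      if (params$rim_width_px > 0) {
        rim <- !disc & d2 <= (params$radius_px + params$rim_width_px)^2
        field[rim] <- pmax(0, rnorm(sum(rim), params$rim_kpa, RIM_SD))
      }
    }
    field
  })
}

#' Render a stiffness field as an elastogram
#'
#' Colour-codes each pixel with [stiffness_to_color()] (values above the
#' colormap range clamp, as real lesions exceed the display scale), then
#' replaces a random `void_fraction` of pixels with black signal voids.
#' The validity mask is recomputed from the rendered pixels, so voids are
#' achromatic by construction.
#'
#' @param field `H x W` stiffness matrix (finite, >= 0).
#' @param cmap a [build_colormap()].
#' @param void_fraction per-pixel void probability in `[0, 1)`.
#' @param rng_seed integer seed for the void pattern.
#' @param source_id,label forwarded to [elastogram()].
#' @return an [elastogram()].
#' @export
render_elastogram <- function(field, cmap, void_fraction = 0, rng_seed = 0L,
                              source_id = "synthetic", label = "unknown") {
  if (any(!is.finite(field)) || any(field < 0))
    stopf("`field` must be finite and >= 0")
  H <- nrow(field); W <- ncol(field)
  rgbs <- stiffness_to_color(as.vector(field), cmap)
  if (is.null(dim(rgbs))) rgbs <- matrix(rgbs, nrow = 1L)
  if (void_fraction > 0) {
    void <- with_seed(rng_seed, runif(H * W) < void_fraction)
    rgbs[void, ] <- 0L
  }
  elastogram(array(rgbs, dim = c(H, W, 3L)), source_id = source_id,
             label = label)
}

# per-image generation shared by simulate_cohort and in-memory cohort loops
simulate_one <- function(params, shape, void_fraction, seed_i, source_id,
                         label) {
  field <- simulate_stiffness_field(params, shape, rng_seed = seed_i)
  render_elastogram(field, cmap = getOption("swehist.cmap") %||%
                      build_colormap(),
                    void_fraction = void_fraction,
                    rng_seed = child_seed(seed_i, 1L),
                    source_id = source_id, label = label)
}

#' Simulate a labelled cohort of synthetic elastograms
#'
#' Generates `n_benign + n_malignant` images with per-image child seeds
#' derived from `spec$seed` (so partial regeneration is reproducible).
#' When `dir` is given, writes one PNG per image plus `manifest.csv`
#' (`source_id`, `path`, `label`) and `ground_truth.csv` (per-image
#' parameters); regeneration under the same spec is byte-identical.
#'
#' @param spec a [cohort_spec()].
#' @param dir output directory (created if needed), or `NULL` to keep the
#'   cohort in memory only.
#' @param cmap colormap used for rendering; default [build_colormap()].
#' @return (invisibly) list with `images` (list of [elastogram()]),
#'   `manifest` (data.frame), `truth` (data.frame), `dir`.
#' @export
simulate_cohort <- function(spec, dir = NULL, cmap = build_colormap()) {
  stopifnot(inherits(spec, "cohort_spec"))
  labels <- c(rep("benign", spec$n_benign), rep("malignant", spec$n_malignant))
  n <- length(labels)
  ids <- sprintf("%s_%03d", labels, c(seq_len(spec$n_benign),
                                      seq_len(spec$n_malignant)))
  images <- vector("list", n)
  truth <- vector("list", n)
  old <- options(swehist.cmap = cmap); on.exit(options(old))
  for (i in seq_len(n)) {
    p <- if (labels[i] == "benign") spec$benign else spec$malignant
    seed_i <- child_seed(spec$seed, i)
    images[[i]] <- simulate_one(p, spec$image_shape, spec$void_fraction,
                                seed_i, ids[i], labels[i])
    truth[[i]] <- data.frame(source_id = ids[i], label = labels[i],
                             seed = seed_i, mean_kpa = p$mean_kpa,
                             sd_kpa = p$sd_kpa, radius_px = p$radius_px,
                             rim_width_px = p$rim_width_px,
                             rim_kpa = p$rim_kpa,
                             soft_fraction = p$soft_fraction,
                             stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)
  manifest <- data.frame(source_id = ids,
                         path = paste0(ids, ".png"),
                         label = labels, stringsAsFactors = FALSE)
  if (!is.null(dir)) {
    if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
      stopf("cannot create output directory: %s", dir)
    for (i in seq_len(n)) {
      path <- file.path(dir, manifest$path[i])
      tryCatch(write_png(images[[i]]$pixels, path),
               error = function(e) stopf("failed writing %s: %s", path,
                                         conditionMessage(e)))
    }
    write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
    write.csv(truth, file.path(dir, "ground_truth.csv"), row.names = FALSE)
  }
  invisible(list(images = images, manifest = manifest, truth = truth,
                 dir = dir))
}
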