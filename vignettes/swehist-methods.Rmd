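---
title: "Methods: histogram-based SWE quantitation in swehist"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: histogram-based SWE quantitation in swehist}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Shear-wave elastography (SWE) estimates tissue stiffness in kPa and
displays it as a pseudocolor heatmap over a fixed vendor scale, 0–180 kPa:
cool colours (blue) for soft tissue, warm colours (red) for stiff tissue.
Malignant breast tissue is typically stiffer than benign tissue, but the
conventional readout — mean/maximum stiffness inside a hand-placed
circular ROI — carries operator bias (where the circle is drawn, whether
the stiff peritumoral rim is included) and discards the spatial
composition of the field.

`swehist` treats the rendered heatmap itself as the measurement. The chain
is:

1. **Colormap inversion.** The display is modelled as an invertible lookup
   table (LUT): level $i$ of $L$ carries stiffness
   $\kappa_i = \kappa_{\min} + i\,(\kappa_{\max}-\kappa_{\min})/(L-1)$ and
   a colour on a monotone cool-to-warm ramp. A linear relation between kPa
   and colour position is *assumed* — the vendor does not publish its LUT,
   and this assumption is the model's weakest link (see Limitations).
2. **Void rejection.** Pixels without a valid stiffness estimate render as
   grayscale (black signal voids). A pixel is achromatic iff
   $\max(R,G,B)-\min(R,G,B) \le \tau$; achromatic pixels never enter any
   statistic.
3. **Channel histograms.** Each of the R (warm), G (intermediate) and
   B (cool) channels of the valid pixels is histogrammed into 250
   equal-width half-open bins over $[0,256)$ and normalized to unit sum.
4. **Descriptors.** Bin indices 1–14 and 201–250 are rejected as noise
   (near-black and near-saturated values dominated by rendering artefacts
   and void edges); the rest splits into low-intensity bins 15–100 and
   high-intensity bins 101–200. Per channel, the bin-range AUC
   $\sum_{k=a}^{b} h(k)$ and the bias-uncorrected Fisher–Pearson skewness
   of bin-centre intensity under $h$ summarise the image. The biomarker of
   interest is the cool-channel low-bin AUC: cool-channel mass moving out
   of the near-saturated soft band into the low-intensity band means the
   soft-tissue fraction of the field has dropped.
5. **Cohort statistics.** Descriptors are compared benign vs malignant by
   Mann–Whitney rank-sum; whole histograms by a two-sample
   Kolmogorov–Smirnov test on vectorized histograms; discrimination by ROC
   analysis of the cool-low AUC (higher = malignant) with Youden index and
   sensitivity at requested specificity.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `kpa_range` | (0, 180) | kPa | fixed vendor display scale, not adjustable on the device |
| `n_levels` | 256 | – | one LUT level per 8-bit display step; quantization error ≤ 180/255 ≈ 0.71 kPa |
| `variant` | `linear-bgr` | – | linear blue→green→red ramp, the stated linearity assumption; `jet` adds cyan/yellow waypoints to probe LUT sensitivity |
| `saturation_threshold` | 20 | 8-bit counts | wide enough to absorb JPEG ringing on black voids, narrow enough to keep every saturated ramp colour (the closest default-LUT colour to gray has channel spread 128) |
| `bin_ranges` | 1–14 / 15–100 / 101–200 / 201–250 | bin index | noise rejection plus low/high split; ranges are validated to partition 1–250 |
| `exclude_noise_before_normalize` | `FALSE` | – | whether normalization happens before (default) or after noise-bin rejection; the order is not fixed by convention, so both are exposed |
| ROI SD | sample (n−1) | kPa | matches vendor-style ROI statistics; documented so comparisons are reproducible |
| `ks_mode` | `faithful` | – | see below |
| `spec_targets` | 0.90 | specificity | conventional high-specificity operating point |

## Design choices where the design was open

**Bin-edge convention.** "250 bins" over 8-bit data does not fix edges.
We use 250 equal-width half-open bins over $[0,256)$, reported 1-based, so
bin $k$ covers $[(k-1)\cdot 1.024,\ k\cdot 1.024)$; intensity 0 falls in
bin 1 and intensity 255 in bin 250. This reproduces the field's bin
arithmetic (e.g. intensity 128 → bin 126) while keeping every 8-bit value
inside exactly one bin.

**Inversion by nearest neighbour.** Colours are decoded by
nearest-neighbour search in RGB Euclidean distance over the LUT rather
than analytic ramp inversion: it is total on chromatic inputs, robust to
JPEG chroma noise, and its error is bounded by one LUT step. Ties break
toward the lower stiffness level (conservative). Out-of-range stiffness
clamps on rendering rather than erroring, since real lesions exceed the
display scale.

**Per-pixel decode, then aggregate.** ROI statistics decode each valid
pixel to kPa and then average — never "average the colour, then decode" —
so bimodal ROIs are handled correctly.

**KS on vectorized histograms.** Treating the 250 bin heights of the two
group-mean histograms as two samples (`ks_mode = "faithful"`) is how
histogram-level KS comparisons are commonly run in imaging pipelines, but
it is statistically unorthodox: bin heights are neither independent nor
identically distributed, so the p-value is a descriptive index, not a
calibrated tail probability. A `pooled` mode (concatenating per-image
histograms) is provided; neither mode's p should be over-read. The
per-descriptor Mann–Whitney tests are the calibrated inference in this
package (their type-I error is verified by simulation in the acceptance
suite).

**Mann–Whitney variants.** Midranks for ties; exact p by full enumeration
of all $\binom{N}{n_1}$ label assignments when $N \le 12$ (a permutation
test, valid under ties); otherwise normal approximation with tie and
continuity corrections. Degenerate all-equal data reports p = 1 with an
explicit flag rather than an error or a silent 0.

**Dunn's post-hoc** uses tie-corrected pooled variance; no adjustment by
default (Bonferroni optional), since multiplicity policy is a reporting
decision, not a property of the statistic.

**Sensitivity at specificity** is the maximum sensitivity among operating
points with specificity ≥ the request — conservative, no interpolation.

**KS p-value.** The asymptotic Kolmogorov series with effective
$n_e = n_1 n_2/(n_1+n_2)$ and the small-sample correction
$\lambda = (\sqrt{n_e}+0.12+0.11/\sqrt{n_e})\,D$, i.e. the convention of
the MATLAB routine this layer reimplements; base R's `ks.test` uses a
slightly different asymptotic and serves as an independent oracle for $D$
in the tests.

**JPEG input.** The R environment this package targets has no documented
JPEG decoder, and a hand-rolled DCT decoder would be out of proportion;
`load_elastogram()` therefore reads PNG (bundled zlib-backed codec,
bit-depth 8, colour types 0/2/3/4/6, filters 0–4) and errors informatively
on JPEG with a one-line conversion recipe. Robustness of the descriptors
to JPEG quality-90 recompression is still tested, via an external
round-trip, on a spatially smooth fixture — which is the relevant case:
vendor heatmaps are smooth, and JPEG robustness is *not* claimed for
pixelwise-independent noise fields.

## The synthetic generator: what it emulates and what it does not

`simulate_stiffness_field()` states a fixed world per image:

* background = two-component mixture: a *soft* component,
  gamma(shape 9, mean 15 kPa, SD 5), drawn with probability
  `soft_fraction`; otherwise an *intermediate* component,
  gamma(shape 9, mean 45 kPa, SD 15). The means land the components in
  the cool and intermediate bands of the 0–180 kPa ramp; the heavier
  intermediate tail reflects fibroglandular tissue occasionally reaching
  high stiffness. These are configuration defaults, not claims about
  tissue.
* lesion = centred disc of `radius_px` with gaussian stiffness
  (`mean_kpa`, `sd_kpa`) truncated at 0; default 60 ± 20 kPa, radius 48 px
  at the default 256×256 canvas (the acceptance suite uses 128×128 with
  radius 24, preserving the lesion/background proportion).
* optional stiff peritumoral rim: an annulus of `rim_width_px` at the
  disc edge near `rim_kpa` (default 120 kPa, SD 5); off by default.
* rendering adds a `void_fraction` (default 0.1) of black signal-void
  pixels, per-pixel Bernoulli.

The malignancy axis of the default cohorts is *soft-tissue reduction
only*: benign `soft_fraction` 0.6 vs malignant 0.2, all lesion parameters
equal, cohort sizes 32 benign / 64 malignant. That makes a green effect
test evidence that the descriptors detect compositional change of the
background — the mechanism of interest — and not simply a stiffer lesion.

Not emulated: ultrasound speckle or any acoustic physics, B-mode anatomy,
spatial correlation of background tissue (pixels are independent),
operator-dependent cropping, vendor annotation overlays, JPEG artefacts
(PNG by default). Consequently a green suite establishes correctness of
the measurement chain and direction/calibration of the statistics on this
stated world — it does not establish clinical performance, and the
clinical effect sizes reported on real cohorts are not reproduced at desk
scale.

Determinism: every image derives a child seed from the cohort seed via a
fixed integer recurrence, so regeneration — including partial
regeneration after growing a cohort — is byte-identical, and the
simulator never perturbs the caller's RNG stream.

## Numerical choices and degenerate inputs

* Normalized histograms of an empty valid mask are all-zero (not NaN);
  skewness on < 2 pixels or zero variance is `NA` with a warning, never 0.
* `compare_cohorts()` drops descriptors that are undefined (all `NA`) in
  either group rather than erroring, so constant images degrade
  gracefully.
* An ROI lying entirely in void is a distinguishable error ("entirely in
  signal void"), not an empty mean.
* Circle membership is centre-of-pixel inclusion, no anti-aliasing —
  deterministic and testable; the pixel-count area of a radius-50 circle
  is within 5% of $\pi r^2$.
* PNG encoding always writes filter-0 rows and one IDAT chunk at a fixed
  compression level, so outputs are byte-deterministic.
* All acceptance thresholds are stated a priori: round-trip error ≤ one
  LUT step; AUC partition to 1e−9; oracle agreement to 1e−12; null
  calibration within the exact binomial 95% band around 0.05 computed at
  run time from the replicate count.

## Known limitations

* The linear kPa↔colour assumption is inherited, not verified; if the
  vendor ramp is perceptually adapted, absolute decoded kPa shift, though
  monotone ordering (and hence rank-based group differences) survives any
  monotone recoding. The `jet` variant exists to probe this sensitivity.
* The faithful KS mode's p-values are descriptive (see above).
* No lesion segmentation, no automatic SWE-panel detection: crops and
  ROIs are caller-provided.
* JPEG files must be converted to PNG before loading.
* The simulator's independence of neighbouring pixels makes its images
  *harder* for JPEG compression and *easier* for histogram statistics
  than real, spatially correlated elastograms; between-image variance of
  descriptors is therefore smaller than clinical reality, and simulated
  p-values should not be compared in magnitude to clinical ones.
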