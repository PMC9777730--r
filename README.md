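# swehist

Histogram-based quantitation of shear-wave elastography (SWE) heatmaps.

Breast SWE renders tissue stiffness (kPa) as a pseudocolor heatmap over a
fixed 0–180 kPa vendor scale: cool colours for soft tissue, warm colours
for stiff tissue. The conventional readout — mean/maximum stiffness inside
a hand-placed circular ROI — depends on where the operator draws the
circle and ignores the peritumoral field. `swehist` quantifies the *whole*
colour field instead: it inverts the colormap, rejects achromatic signal
voids, summarises each image by its per-channel 250-bin RGB histogram, and
reduces the histograms to bin-range area-under-curve (AUC) and skewness
descriptors. The headline biomarker is the **cool-channel low-intensity-bin
AUC**: an increase reflects a reduction of soft-tissue components, which
discriminates malignant from benign lesions where ROI averages do not.

For an image with valid-pixel histogram \(h_c(k)\) (channel *c*, bins
*k* = 1…250 over intensity [0, 256), normalized to unit sum), the package
computes

* bin-range AUC: `AUC_c(a..b) = Σ_{k=a}^{b} h_c(k)`, with noise bins
  1–14 and 201–250 rejected and signal ranges *low* = 15–100,
  *high* = 101–200;
* skewness: the bias-uncorrected third standardized moment of bin-centre
  intensity under `h_c`;
* ROI comparators: SWEavg, SWEmin/max, SD of per-pixel decoded kPa and the
  Q-box ratio (target mean / reference fat-pad mean);
* cohort statistics: two-sample Kolmogorov–Smirnov on vectorized
  histograms, Mann–Whitney rank-sum per descriptor (exact enumeration for
  n₁+n₂ ≤ 12), Kruskal–Wallis with Dunn's post-hoc, Shapiro–Wilk, and ROC
  with trapezoidal AUC, Youden index and sensitivity at requested
  specificity.

Clinical images are replaced by a seeded synthetic-elastogram simulator
(two-component soft/intermediate background, gaussian lesion disc,
optional stiff peritumoral rim, black signal voids), so the entire
pipeline is testable offline. Image IO is a bundled minimal 8-bit PNG
codec (zlib-backed); no external imaging library is needed.

## Worked example

```r
library(swehist)

cm <- build_colormap()              # linear blue->green->red, 0-180 kPa
stiffness_to_color(120, cm)         # 85 170 0  (orange-green, stiff side)
color_to_stiffness(c(170, 85, 0), cm)  # 149.6471 kPa

spec <- cohort_spec(n_benign = 8, n_malignant = 8, image_shape = c(96, 96),
                    benign    = lesion_params(radius_px = 18),
                    malignant = lesion_params(radius_px = 18,
                                              soft_fraction = 0.2),
                    seed = 42)
cohort <- simulate_cohort(spec, dir = tempfile())  # PNGs + manifest.csv
ex <- extract_cohort_features(cohort$images)
compare_cohorts(ex$features, ex$histograms)
```

```
<cohort_report: 8 benign vs 8 malignant>
  KS (faithful mode):
    warm         D = 0.0200, p = 1
    intermediate D = 0.1560, p = 0.003954
    cool         D = 0.1560, p = 0.003954
  rank-sum (benign vs malignant):
    auc_low_warm           p = 0.1563
    auc_high_warm          p = 1
    auc_low_intermediate   p = 0.0009391
    auc_high_intermediate  p = 0.0009391
    auc_low_cool           p = 0.0009391
    ...
  ROC on auc_low_cool: AUC = 1.0000
```

The malignant group was simulated with its background soft-tissue fraction
reduced from 0.6 to 0.2, everything else equal. The cool-channel low-bin
AUC picks that up (benign 0.140 vs malignant 0.232 in the first image of
each group; rank-sum p ≈ 9.4 × 10⁻⁴, the continuity-corrected normal
approximation at complete 8-vs-8 separation),
while the warm-channel descriptors — which track the lesion itself, here
identical between groups — do not. ROI comparators on the same images:

```r
img <- cohort$images[[1]]
st  <- roi_stats(img, circular_roi(c(47.5, 47.5), 18), cm)
# <swe_roi_stats [target]: mean 59.5, min 0.7, max 112.9, sd 20.3 kPa (n=906)>
ref <- roi_stats(img, circular_roi(c(10, 80), 8, kind = "reference"), cm)
qbox_ratio(st, ref)   # 2.24
```

The decoded ROI mean (59.5 kPa) recovers the simulated lesion mean
(60 kPa) to within one LUT quantization step (180/255 ≈ 0.71 kPa per
level; the residual is sampling, not decoding).

## Command line

```sh
Rscript -e 'swehist::swe_cli()' run-all --out cohort_dir --seed 7
# or: simulate / extract / compare individually; --config accepts a JSON
# file; see ?swe_cli. A launcher script ships at
# system.file("cli", "swehist.R", package = "swehist").
```

Outputs: per-image PNGs, `manifest.csv`, `features.csv` (one row per
image: 6 bin-range AUCs, 3 skewnesses, valid-pixel count),
`histograms.csv`, `report.json`.

## Documentation

`vignettes/swehist-methods.Rmd` describes the model and its assumptions,
every tunable parameter with its default and rationale, what the
synthetic generator does and does not emulate, and known limitations.
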