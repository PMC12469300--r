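---
title: "Methods: image-derived morphometry for cell mechanobiology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: image-derived morphometry for cell mechanobiology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mechmorph)
```

## Scope and rationale

Osteosarcoma mechanobiology experiments read out a handful of image-derived
quantities: the size and orientation of nuclei under uniaxial cyclic stretch,
the nuclear-to-cytoplasmic (N/C) area ratio, the complexity of the cell edge
seen by atomic force microscopy (AFM), the roughness of the cell periphery,
and the nuclear enrichment of Src measured as corrected total cell
fluorescence (CTCF). `mechmorph` implements each estimator as a small,
testable function and pairs it with a synthetic-image generator whose presets
are calibrated to published per-condition means for U-2 OS and SAOS-2 cells.
Because the generator knows its own ground truth, every estimator is
validated *closed-loop*: generate with known parameters, measure, and demand
recovery within a stated tolerance.

## Nuclear morphometry and the orientation statistic

Nuclei are segmented objects in a label mask. For each object,
`fit_ellipse()` computes the **moment-equivalent ellipse**: the ellipse with
the region's centroid and normalized second central moments, semi-axes
$a = 2\sqrt{\lambda_1}$, $b = 2\sqrt{\lambda_2}$ from the eigenvalues of the
pixel covariance matrix (with the $1/12$ per-pixel variance term restored).
This is the construction ImageJ's *Fit Ellipse* actually performs, and it is
what we implement — even where protocol descriptions loosely say "minimum
enclosing ellipse", which is a different (larger) ellipse. Area is reported
as pixel count times the squared pixel size rather than $\pi a b$, so that
area is exact for arbitrary (non-elliptical) regions.

The orientation angle $\varphi$ is measured between the major axis and the
x axis — the stretch direction — counter-clockwise with y pointing up, folded
to $(-90^\circ, 90^\circ]$. The alignment statistic is
$\cos 2\varphi$: $+1$ parallel, $-1$ perpendicular, invariant to the
$180^\circ$ axis ambiguity. Classes follow the conventional ranges:
perpendicular for $\cos 2\varphi \in [-1, -0.5]$, parallel for $[0.5, 1]$,
oblique otherwise. Under uniform orientations each named class covers
$60^\circ$ of $180^\circ$, so the expected class fractions are $1/3$ each —
a useful null. Near-circular nuclei have no meaningful axis: objects with
eccentricity below 0.2 (a configurable threshold) are classified `undefined`
and excluded from mean-$\cos 2\varphi$ summaries but reported in the
`fraction_undefined` column, since silently dropping them would bias
population fractions. Objects under 25 px are flagged invalid (segmentation
debris). Whether oblique nuclei should be excluded from downstream
distribution plots is a reporting choice; the package reports all four
fractions and leaves exclusion to the caller.

## Box-counting fractal dimension of the cell edge

The edge pipeline mirrors the AFM post-processing chain: percentile contrast
enhancement (`enhance_contrast()`, default 1st–99th percentile clip), Otsu or
fixed thresholding, largest-connected-component selection, hole filling, and
a one-pixel **inner boundary** (foreground minus its 8-connectivity erosion,
`extract_edge_mask()`). `box_count()` overlays dyadic grids of box size
$\varepsilon$ anchored at the image origin and counts occupied boxes
$N(\varepsilon)$; the fractal dimension is the least-squares slope of
$\log N$ against $\log(1/\varepsilon)$.

Published descriptions of box counting rarely state the scale range or grid
offsets; these are declared choices here, not inferences. The default fit
uses all dyadic scales from $\varepsilon = 4$ to $\min(H, W)/4$:
$\varepsilon = 2$ is counted but excluded because it saturates at pixel
noise, and scales above a quarter of the image lose contrast between curves.
A single origin-anchored grid keeps counts bit-reproducible; translation
sensitivity is below 0.03 in FD for well-resolved masks (a tested property,
not an averaged-away one). Validation anchors: a straight line yields
FD $\approx 1$ exactly, and a 4-iteration triadic Koch curve
(`koch_curve_mask()`, analytic dimension $\log 4/\log 3 \approx 1.2619$)
is recovered within $\pm 0.05$. Counts are additionally pinned to a
brute-force double-loop oracle in the test suite.

## Synthetic contours with tunable fractal dimension

No generative boundary model accompanies published FD measurements, so the
generator uses **radial spectral synthesis**: a star-shaped contour
$r(\theta) = R_0\bigl(1 + \sigma \, s(\theta)\bigr)$ where $s(\theta)$ is a
random Fourier series with coefficient amplitudes $k^{-\beta/2}$ (harmonics
2–256), normalized to unit variance so $\sigma$ (default 0.10) is exactly the
relative roughness amplitude. Star-shapedness guarantees a closed,
non-self-intersecting curve and makes rasterization a vectorized radius
comparison. The spectral slope $\beta$ maps monotonically to the measured
box-counting dimension; this map was calibrated once against the package's
own estimator (30 seeds per $\beta$ on a 1024-px grid) and frozen as a
lookup table inverted by interpolation. Calibrating against our own
estimator is deliberate: it closes the loop between generator and
measurement, which is what the recovery tests require. The calibrated range
is FD $\approx 0.97$–$1.46$; requests outside it raise an error rather than
extrapolate. Mean recovery error over 20 seeds is below 0.012 at all
condition targets (1.029–1.272); single-contour SD is about 0.03.

## Pseudo-AFM height maps and peripheral roughness

`make_height_map()` renders a plateau of constant height inside a contour,
zero outside, with Gaussian texture confined to a peripheral band and
optional global noise — the minimal surface that exercises a roughness
estimator. `peripheral_roughness()` defines the peripheral band as mask
pixels within `band_width` of the boundary (Euclidean distance transform)
and reports the RMS deviation of height from the band's **median** level;
the median is used instead of the mean so a few protrusion pixels do not
drag the reference plane. The default band width of 10 px corresponds to
about 100 nm at the 10 nm/pixel AFM resolution, the size scale of the edge
protrusions of interest. The quantity is named in the literature but its
formula is not printed; this definition is the package's own and is stated
here so results are interpretable. With the band spanning the whole cell
the statistic degenerates to the global RMS, a tested identity.

## CTCF of nuclear Src

CTCF is pure arithmetic and is implemented exactly, with no smoothing or
outlier handling:

$$\mathrm{ID} = \bar{I}_{\mathrm{nuc}} \times A, \qquad
\mathrm{CTCF} = \mathrm{ID} - \bar{I}_{\mathrm{bg}} \times A.$$

The background is the mean intensity of a ring built by morphological
dilation (`background_ring()`, default gap 2 px, width 5 px, excluding
neighbouring cells) — per-cell rings rather than a per-image background,
since the published formula names a background *mean* but not its region;
the geometry is exposed in the configuration. CTCF is offset-invariant
(adding a constant to the image cancels), linear in intensity scaling, and
additive over nucleus partitions; all three are tested to machine precision.
Areas stay in pixels unless a pixel size is supplied, in which case both
terms scale consistently.

## Group statistics

`compare_groups()` is a pooled-variance, two-sided, unpaired Student's
t-test — the convention behind "mean difference ± SEM" reporting — with
Welch's correction behind a flag, and significance stars at the strict
thresholds $p < 0.05, 0.01, 0.001, 0.0001$ ($p = 0.05$ exactly is `ns`).
Zero pooled variance with unequal means is reported as $p = 0$ with a
`degenerate` flag rather than an error, so batch tables keep their shape.
P-values are cross-checked in the tests against numerical integration of
the t density to $10^{-10}$. No multiple-testing correction is applied by
default, matching common single-comparison reporting; callers running many
comparisons should adjust with `p.adjust()`. Detachment and wound-closure
percentages use the standard definitions $100\,n_{\mathrm{rem}}/n_0$ and
$100\,(A_0 - A_t)/A_0$; the latter formula is an assumption documented here
because protocols name the quantity without defining it. A widening wound
yields a negative closure with a warning, not an error.

## The generator presets: what they emulate and what they do not

Presets (`list_presets()`) are calibrated to published condition means:
nuclear areas 553.7 / 749.1 µm² (U-2 OS control / capsaicin) and
612.0 / 827.0 µm² (SAOS-2), N/C ratios 0.26611 / 0.4376 and
0.23349 / 0.19188, edge FDs 1.103 / 1.272 / 1.045 (U-2 OS control /
capsaicin / +antagonist) and 1.051 / 1.029 (SAOS-2), and a twofold nuclear
Src enrichment for the activated U-2 OS condition. Dispersions are not
published per cell, so the generator fixes them once at field-realistic
values: area CV 20 %, N/C ratio SD 0.05, aspect-ratio CV 10 % (aspect mean
1.4–1.6 by line). The perpendicular-biased orientation law is a von Mises
density on $2\varphi$ centred at $180^\circ$ with concentration $\kappa$
(preset knob; $\kappa = 6$ puts ~87 % of nuclei in the perpendicular class) —
any unimodal angular family reproducing the published class fractions would
do, and this one integrates cleanly. Nucleus fields use 0.25 µm/pixel so a
200-nucleus field stays around 3500² px; the confocal acquisition scale
(0.025 µm/pixel) remains the analysis-side default and changes only areas'
pixel counts, not any ratio or angle.

What the generator does **not** emulate: point-spread functions, shot noise,
multi-cell confluence, 3-D structure, or real segmentation error. Passing
closed-loop tests therefore demonstrates estimator correctness — not
robustness to segmentation failure on real micrographs, which must be judged
per dataset.

## Numerical and reproducibility choices

All randomness flows through one integer seed per generator call; the
caller's RNG stream is saved and restored, and identical (preset, seed)
pairs are bit-identical — `run_pipeline()` writes a manifest with config
hash and output checksums to make this auditable. Rasters are 0-based
conceptually, row-major, with pixel centres at integer coordinates; masks
are hard in/out sets. Ellipse placement rejects overlaps by bounding-circle
tests with at most 1000 retries per nucleus before raising a density error
(fields are sized for ~28 % bounding-circle packing, well under the
sequential-adsorption jam). Degenerate inputs raise typed errors: empty
masks, constant images (Otsu undefined), rings fully clipped by borders or
neighbours, fewer than four usable box-counting scales.

Problem sizes used in the validation suite — 20 seeds per FD condition on
1024-px grids, 200-nucleus fields, 100-cell CTCF replicates, 3000-draw
orientation nulls — were chosen so that recovery tolerances (3 SEM bands,
±0.05 FD) are meaningfully tight while the whole suite runs in minutes.

## Worked example

```{r, eval = FALSE}
field <- make_nucleus_field("u2os_capsaicin", n = 200, seed = 7)
nuclei <- measure_nuclei(field$labels, field$pixel_size)
mean(nuclei$area_um2)            # ~749 um^2, the calibration mean
orientation_summary(nuclei[nuclei$valid, ])

ct <- make_fractal_contour("u2os_capsaicin", grid_size = 1024, seed = 1)
box_count(ct$edge)               # FD ~1.27

cell <- make_fluor_cell("u2os_capsaicin", seed = 11)
ring <- background_ring(cell$cell_mask)
ctcf(cell$src, cell$nuclear_mask, ring)
```

## Known limitations

* The FD calibration is tied to the default estimator settings (grid 1024,
  $\sigma = 0.10$, dyadic fit 4–256); other grid sizes reuse the same lookup
  and may carry a small bias (the monotone ordering is preserved).
* The moment ellipse under-covers highly concave nuclei; area (pixel count)
  is unaffected, but orientation of strongly non-elliptical objects should
  be interpreted with care.
* Per-cell background rings assume sparse fields; in dense cultures the
  ring excludes neighbours and may become small — it errors when empty
  rather than returning a noisy mean.
* `compare_groups()` treats supplied values as independent observations; it
  does not model technical-replicate nesting. Record `n` and choose the
  analysis unit accordingly.
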