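---
title: "Measuring circulating tumor cell dimensions from thumbnail galleries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring circulating tumor cell dimensions from thumbnail galleries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctcmorph)
library(dplyr)
```

## The measurement problem

Circulating tumor cells (CTCs) are rare epithelial cells in the blood of
cancer patients. The dominant enumeration platform images
immunomagnetically enriched cells in a cartridge and presents an expert
with per-event thumbnails in three fluorescence channels: DAPI (nuclear
DNA), cytokeratin (CK, epithelial cytoplasm) and CD45 (leukocyte surface
antigen). A CTC is a CK+/DAPI+/CD45&minus; event; a leukocyte is the
mirror image, CK&minus;/DAPI+/CD45+.

Size-based CTC isolation devices are usually tuned on cultured cell lines,
so the actual size distribution of patient-derived CTCs matters. ctcmorph
implements the measurement pipeline for this question: given galleries of
expert-marked events, it segments each channel, measures size and shape,
keeps only events that are unambiguously single cells, converts areas to
equivalent-circle diameters, computes nucleus/cytoplasm ratios, and
compares cohorts with nonparametric rank tests. Because the patient image
archives behind such studies are not public, the package ships a synthetic
cartridge generator with known ground truth; every pipeline stage is
exercised against that truth.

## Segmentation and per-channel measurement

Each thumbnail is a small grayscale raster with a physical pixel size
(default 0.64 µm/px, the value implied by a 6.4 µm scale bar spanning ten
pixels in this class of galleries; always overridable). Segmentation is
deliberately parameter-light and deterministic:

1. normalize the thumbnail to its own intensity range;
2. 3×3 median filter (a vectorized median-of-9 sorting network; the filter
   is the only denoising step and can be disabled);
3. global Otsu threshold;
4. guard: the threshold must exceed the robust background level
   (median + 3 MAD), otherwise the mask is empty — this prevents Otsu from
   splitting the noise floor of background-only thumbnails;
5. drop connected components smaller than `min_component_px` (default 4 px);
6. the union of the surviving components is the event mask.

Keeping the union (rather than the single central component) is a
deliberate choice: thumbnails are centered crops of one marked event, and a
doublet or cluster must contribute *one* area and *one* perimeter so that
the shape classifier can see it is not a single cell.

Per channel we report `area` (foreground pixel count × pixel&nbsp;size²,
µm²), `perimeter` (corner-corrected contour length × pixel size, µm),
`p2a` (below), `mean_intensity`, and `positive` (area &gt; 0 after
segmentation). A channel with an empty mask is negative with undefined
shape values — never an error.

### The perimeter estimator and P2A

The shape statistic is the normalized isoperimetric ratio

$$\mathrm{P2A} = \frac{P^2}{4\pi A},$$

which is 1 for an ideal circle and grows with departure from circularity.
Its bin edges (below) sit between 1 and 4, so a biased perimeter estimator
would corrupt the classification directly: naive counting of boundary-pixel
edges overestimates a digital circle's perimeter by roughly 27%, which
alone would push true single cells across the first bin edge. We therefore
use the Benkrid–Crookes weighted border-pixel estimator (the one
scikit-image's `measure.perimeter` implements), which weights each border
pixel by its local neighborhood pattern. A unit test pins our
implementation to values frozen from scikit-image on identical masks, and
analytic anchors bound the discretization error: a rasterized disk of
radius 10 px measures P2A in [0.95, 1.10], and a large rasterized square
comes within 5% of its analytic $4/\pi \approx 1.273$.

Pixel counting itself is an accurate area estimator for generic disk
placements, but the *lattice* contributes a caveat at very small radii: a
disk of radius 3–4 px placed at special (integer or half-integer) subpixel
offsets can miscount by several percent (the Gauss circle problem). The
tests therefore assert per-disk accuracy (≤ 3% against $\pi r^2$) for
radii 5–30 px at a generic off-lattice placement, and *unbiasedness over
subpixel placements* for the smallest radii. The synthetic renderer
likewise jitters all disk centers by a subpixel offset.

## Singularity classification and the selection cascade

Marked coordinates can contain several touching CTCs. Events are classified
from the CK-channel P2A into four half-open bins with the published edges

| class | P2A |
|---|---|
| single | [0, 1.5) |
| doublet | [1.5, 2.5) |
| small cluster | [2.5, 4) |
| large cluster | [4, ∞) |

with boundary inclusivity exactly as printed (1.5 is a doublet, 4 a large
cluster). The edges are configurable (`p2a_bins()`) because the underlying
shape-ratio definition has circulated with other normalizations; we adopt
$P^2/(4\pi A)$ because it makes a circle score 1, consistent with "single"
occupying [0, 1.5). CK-negative events receive no class at all rather than
a default, so class percentages are always fractions of CK+ events.

The nested selection cascade then mirrors the published analysis:

* `size_eligible`: CK positive **and** classified single — only these enter
  the size analysis;
* `dapi_evaluable`: additionally DAPI positive (nuclear area &gt; 0 µm²)
  and intact (DAPI area strictly smaller than CK area);
* `ncr_eligible`: additionally the DAPI signal itself classifies single
  under the same bins (nucleus categories map doublet → "double", both
  cluster bins → "clustered");
* `leukocyte`: CD45+/DAPI+/CK&minus; with the CD45 signal classified
  single — the CK criteria applied verbatim to the CD45 channel.

`tabulate_counts()` reproduces the per-cohort count table of these stages
and reports *computed* row totals. (The published table's breast-blood row
total is one less than the sum of its own printed cells, 45&nbsp;472 vs
45&nbsp;473; we report the computed sum. The published bladder nucleus
categories 92 + 4 + 2 similarly sum to 98 against a printed 99.)

## Morphometry

Sizes are reported as the diameter of the equal-area circle,
$CD = 2\sqrt{A/\pi}$ (µm). This conversion is validated against all nine
printed (median area, CD) pairs of the source cohorts.

The nucleus/cytoplasm ratio is computed as the **area** ratio
`dapi_area / ck_area`, although the source text mentions diameters: all
seven printed per-cohort NCR values match the ratio of the printed median
areas to within ±0.02 (e.g. 56.1/120.4 = 0.466 → printed 0.47;
52.0/83.6 = 0.622 → 0.62) and none match the diameter ratio (which is the
square root, e.g. 0.68 for the first pair). Numeric agreement trumps the
ambiguous wording; the diameter convention remains available as
`method = "diameter"`. Whether a *cohort* NCR should be the ratio of the
two cohort medians or the median of per-event ratios is likewise not
decidable from the text (the printed breast cell-line value 0.37 sits
between the two), so `summarize_cohorts()` reports both
(`ncr_ratio_of_medians`, `ncr_median_of_ratios`).

Leukocyte events carry their cell signal on CD45, so their morphometry rows
use the CD45 area with `signal = "cd45"`.

## Cohort statistics

Quantiles use linear interpolation (R type 7); the statistics suite used in
the source study does not state its convention, and the difference is far
below the reported precision at these cohort sizes. The IQR is reported as
the single width Q3&nbsp;&minus;&nbsp;Q1, matching the "(IQR 104.9)"
reporting style.

The comparison battery (`comparison_plan()` / `run_comparisons()`) mirrors
the published analysis: Kruskal–Wallis (tie-corrected H, chi-square
approximation) and the independent-samples median test across the four
tumor types, pairwise Mann–Whitney U tests between all tumor types, blood
vs liquor within breast, CTCs vs the matching cultured cell line for breast
and prostate, and leukocytes vs each tumor type. No multiplicity correction
is applied by default — the source analysis applied none — but
`adjust = "bonferroni"` is available.

The Mann–Whitney implementation uses the exact permutation null when the
smaller sample has at most 8 observations and there are no ties, and the
tie-corrected normal approximation without continuity correction otherwise.
An enumeration oracle, written independently of the implementation,
verifies the exact path exhaustively for all sample-size splits with
$n_1 + n_2 \le 10$. The median test classifies against the pooled median
and uses an uncorrected Pearson chi-square; a degenerate pooled
classification (all values equal) yields an explicitly undefined result.

## The synthetic cartridge generator

The generator emulates the statistical structure the analysis assumes, with
published values as its defaults:

* **Areas** are lognormal — the minimal right-skewed positive family that
  can match both a target median and a target IQR. The printed IQRs are
  large relative to their medians (e.g. 104.9 vs 120.4 µm²), which rules
  out symmetric families. The fit is closed form:
  $\mu = \log m$ and $\sigma = \operatorname{asinh}(\mathrm{IQR}/2m)/z_{0.75}$,
  so any positive (median, IQR) pair is attainable exactly.
* **Per-event NCR** is beta-distributed with a fixed concentration
  (default 24) and the shape solved so the median hits the target; the
  nuclear area is NCR × cell area, so nuclei are strictly enclosed by
  construction.
* **Class geometry**: a k-lobed event is drawn as k equal disks in a chain
  with a small (2 px) inter-lobe gap, k = 1/2/3/5 for
  single/doublet/small/large cluster. Because areas and perimeters of the
  lobes both add, the analytic P2A of the chain is exactly k — each class
  lands mid-bin, and the rasterized measurements land there too (verified
  at zero noise). The gap also keeps the median filter from fusing lobes.
* **Leukocytes** are drawn on CD45 + DAPI with CK left at background.
* **Noise**: Gaussian background (level 0.06, σ 0.02 on the 0–1 scale)
  under a 0.55 foreground, roughly an 8-bit thumbnail with a comfortable
  signal-to-background ratio.
* **Presets**: `ctc_study_presets()` builds one spec per source cohort from
  the bundled published tables — medians/IQRs, class mixes, nucleus
  detection-failure and double-nucleus rates, and cohort sizes.

Everything is a deterministic function of the spec seed.

What the generator does **not** emulate: optics (no point-spread function,
no chromatic offsets between channels), real cell morphology (no
eccentricity, texture, or intensity gradients), debris and imaging
artifacts, crowded fields with neighboring cells inside a thumbnail, and
any correlation between cell size and nuclear size beyond the NCR coupling.
Passing recovery tests therefore show that the pipeline measures what the
generator draws — disks of known area under noise — not that it would agree
numerically with any particular segmentation of real cartridges, whose
ground truth is unknowable here.

## Numerical and design choices

* Internal precision is kept everywhere; rounding (diameters to one
  decimal, NCR to two, p-values as "&lt; 0.001") happens only in reporting.
* Marker files use a minimal open XML dialect (one `<event>` element with
  integer `row`/`col` attributes) plus a CSV fallback; the vendor's actual
  schema is proprietary and undocumented, so this is a stand-in, not a
  reconstruction.
* Coordinates are 0-based (row, col); thumbnails are centered crops.
* A missing `material` column defaults to `"blood"`; only breast cohorts
  have cerebrospinal-fluid (liquor) samples.
* TIFFs written by the exporter are 8-bit; physical pixel size travels in
  the run configuration, not the raster, and `read_gallery()` falls back to
  the configured default when a raster carries no resolution tag.
* Test problem sizes were chosen to exercise each claim at the scale it is
  stated for: 5&nbsp;000 rendered events for cohort-level recovery of the
  median diameter (within 3%) and NCR (within ±0.03), 500 null replicates
  for the type-I error of the rank-test stage, 20&nbsp;000 draws for
  distribution-target checks.

## Known limitations

* The original analysis software's segmentation internals are not public;
  numeric agreement with it on real cartridges cannot be asserted, only
  agreement with analytic truth on synthetic data.
* Whether that software's "roundness" feature equals P2A is unknown; the
  analysis here uses P2A only.
* The segmentation assumes the marked event dominates its thumbnail;
  thumbnails whose foreground covers most of the frame would defeat the
  median + 3 MAD background guard.
* Per-event area distributions of the source cohorts are unpublished (only
  medians and IQRs are printed); lognormality is an assumption and is
  labeled as such.
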