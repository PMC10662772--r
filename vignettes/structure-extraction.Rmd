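---
title: "Extracting clean molecular-structure depictions from document pages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting clean molecular-structure depictions from document pages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(molseg)
```

## The problem

Chemistry literature is full of 2-D molecular structure drawings that are
useless to computational pipelines until they have been pulled out of the
page as clean, isolated images. Optical chemical structure recognition
(OCSR) systems that turn a drawing into SMILES or another machine-readable
encoding assume exactly such a clean input; getting it from a real page is
the hard, error-prone first step. Two failure modes dominate when a detector
crops structure regions from a page:

* a single prediction frame can contain **several complete structures**
  (they must be split into one image each), and
* the crop can contain **non-chemical clutter** — caption fragments,
  labels, stray marks — that ends up inside the cropped image.

`molseg` implements a three-stage pipeline that addresses both: *detection*
(find and crop candidate regions, with an expanded prediction frame),
*mask generation* (a pluggable segmenter marks putative structure pixels in
each crop), and *mask calculus* (connected-component labeling plus a
pixel-ratio statistic that separates multi-structure masks and discards
noise components). The output is one clean image per structure, each
traceable to its source page, box and mask component.

## The pixel-ratio statistic

Each crop's mask map is a single-channel raster restricted to the alphabet
{0, 128}, with 128 marking putative structure pixels. Region filling
(connected-component labeling) partitions the foreground into components
with pixel counts $p_1, p_2, \dots$. For each component the **pixel ratio**

$$\mathrm{PR}_i = \frac{p_i}{\max_j\, p_j}$$

compares it to the largest component in the same mask. The rationale: within
one prediction frame, genuine structure masks have pixel counts of the same
order, while noise components are much smaller. A component is kept as a
genuine structure iff its PR **strictly exceeds** the pixel-ratio threshold
(PRT), default 0.5; a component at exactly the threshold is noise. Empirical
PR distributions in multi-mask frames motivate this cut: genuine structure
masks fall in roughly 0.55–1 while noise masks fall in 0–0.2, so 0.5 sits in
the gap. Classification always uses the full-precision quotient; *reported*
PR values are truncated (not rounded) to three decimals, so counts of 5,725
against 89,872 report as 0.063.

The stage then behaves in the two ways a practitioner needs:

* **Denoising** — one big component plus small clutter: only the big one
  exceeds PRT, so exactly one clean image comes out.
* **Separation** — two comparable components: both exceed PRT, so the mask
  is split into two single-component masks and two images come out.

```{r worked-example}
case <- make_mask_case(c(89872L, 5725L))
classify_components(label_components(case$mask))[, c("pixel_count", "pr_reported", "verdict")]
```

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `margin` | 20 px | prediction-frame expansion before cropping; each side moves outward and clips at the page. 10 px risks clipping peripheral atoms; 30 px admits more neighbouring clutter. Margins are rendered-pixel units, so the right value scales with rendering dpi. |
| `prt` | 0.5 | pixel-ratio threshold; strict comparison (`pr > prt`). |
| `connectivity` | 8 | pixel adjacency for region filling. 8 keeps diagonal bond strokes in one region; 4 is available for ablation. |
| `dpi` | 300 | PDF rendering resolution; chosen for legible line art. Directory input bypasses rendering entirely. |
| `background_fill` | 255 | intensity written outside the kept component. |
| `tight_crop` / `tight_margin` | off / 5 px | optional re-framing of an extraction to its component's bounding box. Off by default: the final framing convention is a consumer choice, so the full crop extent is kept unless asked. |
| `min_pixels` | 0 (off) | optional absolute floor on component size, for users whose corpora contain pathological tiny crops; PR alone decides by default. |

Decisions taken where the design was genuinely open:

* **Overlapping expanded frames are kept as-is.** Reconciling overlapping
  detections is a detector concern, not a calculus concern; an optional
  IoU-based dedup (`dedup_iou = 0.9`) exists but is off by default.
* **Ties for largest component** all receive PR = 1 and verdict genuine;
  labels keep raster-scan order so runs are deterministic.
* **Empty masks** (a detector false positive segmented to nothing) yield
  zero extractions with a logged warning — a legitimate outcome, not an
  error.
* **Mask foreground is 128, not 255**, keeping saved masks directly
  comparable with the pipeline's intermediate artifacts.
* **Backends may resize internally but must return a mask at the crop's
  native size**; resize/letterboxing policy is deliberately left to the
  backend behind that contract.

## Backends

Detection and segmentation are pluggable contracts
(`detector_backend()`, `segmenter_backend()`): deterministic procedures
from a page to boxes, and from a crop to a mask. Production deployments of
this kind of pipeline typically plug in trained networks (a YOLO-family
detector, a DeepLab-family segmenter). The package ships rule-based
baselines that operate at desk scale with no model weights:

* `baseline_detect()` binarizes at a global threshold (200/255), labels
  8-connected ink blobs, merges blobs within a 15 px gap, and keeps merged
  boxes passing area (≥ 900 px²), aspect (0.2–5) and ink-density
  (0.01–0.5) windows. The windows accept ring-and-bond line art and reject
  long thin text lines and solid blobs.
* `baseline_segment()` binarizes the crop's luminance and morphologically
  closes with a 4 px disc so ring strokes fuse into one solid component.

Both are honest rule-based detectors in the lineage of classical
bounding-box/pixel-ratio segmenters; they are tuned to the synthetic
corpus below and are not expected to match trained networks on real pages.

## What the synthetic fixtures emulate — and what they don't

`fixture_spec()` + `synth_corpus()` generate document pages with exact,
generated (not estimated) ground truth:

* **Glyphs**: procedurally fused regular hexagons (1–3 rings sharing
  edges) with pendant bond strokes, 120–200 px, stroke width 5 px —
  structure-like line art without a chemistry engine.
* **Text**: pseudo-text dash rows (no font dependency), line height 10 px,
  30 px line spacing, blocks kept 40 px clear of glyph boxes and 20 px
  clear of each other, with density tuned to be rejected by the baseline
  detector's windows.
* **Noise blobs**: small discs (radius 5–7 px) planted in empty corners of
  a glyph's bounding box with ≥ 12 px clearance from strokes — inside the
  detection frame, so they reach the mask stage and must be removed by PR
  filtering. Blob area stays strictly below half the smallest glyph's
  pixel count, keeping the corpus separable at PRT 0.5.
* **Degradations**: `corrupt()` provides the two modes that hurt real
  extractions — low resolution (downscale–upscale) and randomly hued ink.

One corpus seed derives per-page seeds by fixed splitting, so any page
regenerates independently and every run is fully deterministic.

What passing on this corpus shows: the geometry of expansion/cropping, the
exactness of the mask calculus, and the PR filter's behaviour on separable
noise. What it does **not** show: performance on real scanned pages —
anti-aliased or broken strokes, fonts, tables, photographs, curved-arrow
annotations, touching structures, or noise comparable in size to a
structure. Those require trained backends and real corpora; the recovery
rates measured here say nothing quantitative about them.

`make_mask_case()` complements the page generator with exact-count mask
construction (near-square rectangles plus a partial row, connected under
both adjacencies, ≥ 2 px apart), so figure-style worked examples are
reproduced with exact integer arithmetic.

## Numerical choices

* PR is an exact double-precision quotient of integers; truncation to three
  decimals happens only in reporting (`truncate_pr()`).
* Component labels are assigned in raster-scan order of each region's
  first-encountered pixel — deterministic, and stable between the compiled
  labeler and the test suite's independent flood-fill oracle.
* Box coordinates are 0-based half-open; expansion is `pmax`/`pmin`
  clipping, making it monotone in the margin and idempotent at 0.
* PNG is the canonical format because its losslessness makes save/load
  round trips bit-exact, including the {0, 128} alphabet.
* Problem sizes in the test suite were chosen to exercise every contract
  while staying desk-sized: labeling equivalence on 220+ random masks up to
  32×32, recovery on a 50-page corpus with 1–5 structures per page.

## Known limitations

* PDF rendering shells out to `pdftoppm`/`mutool`/`gs` when one is on
  `PATH`; otherwise pages must be supplied as a directory of images (the
  mode the test suite uses throughout).
* The baseline detector's global threshold assumes dark ink on light
  background; inverted or low-contrast scans need a custom backend.
* Corpus-level extraction rates reported for trained-network pipelines on
  real journal corpora are out of this package's reproducible scope; the
  synthetic recovery harness is the supported evaluation.
* A noise component larger than half the dominant structure defeats the PR
  filter by construction; that regime is documented, not solved.
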