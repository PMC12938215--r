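---
title: "Auditing Grad-CAM attention of an ultrasound station classifier"
author: "SonoCAM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing Grad-CAM attention of an ultrasound station classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Deep classifiers for endobronchial ultrasound (EBUS) can assign B-mode
images to mediastinal and hilar lymph-node stations, but a station label
alone does not tell a clinician *why* the model decided as it did. A
practical audit asks a narrower, checkable question: when the model's
Grad-CAM attention is reduced to a coarse grid and thresholded, does the
highlighted region overlap anatomy that clinically identifies the station
(lymph nodes, vessels), or does it sit on artifacts, airway wall, or
uninterpretable texture? SonoCAM implements that audit end to end, with a
synthetic phantom generator standing in for clinical data, so every step —
from pixels to kappa statistics — is reproducible from a single seed.

## The phantom model

Clinical EBUS data are rarely shareable, so the package generates
sector-scan phantoms with exact ground truth. Each frame is built inside a
sector (apex at the top-centre of the raster; row 1 is proximal, matching
conventional B-mode display) as:

1. a smooth background with depth attenuation and mild lateral falloff,
   scaled by the station's echogenicity level;
2. hypoechoic elliptical lymph nodes (interior scaled to 0.35 of
   background, a brighter rim) at the station template's sector position;
3. anechoic vessel discs (intensity ~0.04);
4. an optional echogenic wall arc near the probe (the "other structure"
   category);
5. optional artifacts: an attenuated shadow wedge distal to a reflector and
   periodic reverberation arcs;
6. multiplicative speckle with unit mean (gamma-distributed multiplier,
   relative s.d. `noiseScale`), followed by a light point-spread blur;
7. quality-driven degradation: frames whose quality score falls below the
   interpretability floor (default 0.3) get heavy blur and reduced
   contrast, giving the annotation oracle a deterministic trigger for
   "not interpretable".

Every structure is recorded in a binary mask of the same shape, clipped to
the sector footprint, so overlap questions have exact answers.

**Station templates.** Each of the eight stations has a layout *and
appearance* prior: node cluster position in (depth, angle), node
multiplicity, node and vessel size scales, and background echogenicity.
Left/right pairs mirror in angle and station levels stack in depth. The
appearance component matters: the classification head global-averages the
final feature map, which suppresses purely positional cues, and real
stations genuinely differ in sonographic appearance — node size and number,
adjacent vessel calibre — not only in position. Without appearance
differences the phantom task would be unrealistically hard for exactly the
architecture under audit.

**What the phantoms do not emulate.** No wave propagation, refraction, or
vendor post-processing; speckle is spatially uncorrelated before the PSF
blur; patients are independent draws (no patient-level anatomy shared
across frames). Consequently, passing tests show the *pipeline* is correct
and the harness can learn separable image classes; they do not certify
performance on clinical images.

## The classifier harness

The default `trainConfig()` keeps the published full-scale recipe: 100
epochs maximum, batch 32, AdamW, categorical cross-entropy, learning rate
1e-4, early-stopping patience 20, dropout 0.5, 70/20/10 patient-wise split.
Splitting shuffles patients under the seed and allots whole patients by
largest remainder (ties resolved train → validation → test; every non-zero
fraction receives at least one patient), so no patient ever spans
partitions.

Because no pretrained DenseNet weights can be assumed, the package provides
a small trainable backbone: three 3×3 convolution + ReLU + 2×2 max-pool
stages from a 56×56 input (so the final convolutional map is exactly 7×7,
preserving the grid semantics of the full-scale model), then global average
pooling, dropout, and an 8-way softmax. It is implemented directly in R as
im2col gathers plus BLAS matrix products; gradients are exact backprop
(verified against finite differences to ~1e-8 relative). A frozen
feature-extractor hook (`backbone = list(extract=, dims=)`) covers the
transfer-learning path: only the head is trained on externally computed
feature maps.

Choices worth knowing:

* **Normalization** is per-image min-max to [0, 1]; the standard
  ImageNet-style normalization only makes sense with a pretrained backbone.
* **Augmentation magnitudes** are package choices (the published recipe
  names the five transforms only): gamma in [0.7, 1.5], blur σ in [0, 1.5]
  px, rotation ±15°, contrast scale [0.8, 1.2], one Gaussian-profile shadow
  band of depth 0.3–0.7, each applied with probability 0.5. All
  overridable; identity parameter values are skipped exactly so degenerate
  settings reproduce the input bit for bit.
* **Checkpointing**: the epoch with minimum validation loss is kept, ties
  broken by the earliest epoch; training halts once `patience` epochs pass
  without improvement (`checkpointSelection` exposes the rule).
* **History** logs loss/accuracy/precision/recall per epoch for train and
  validation; precision and recall are micro-averaged, which for
  single-label multi-class prediction equal accuracy — they are logged for
  interface completeness.
* **Desk-scale recipe** (`deskTrainConfig()`): training a from-scratch CNN
  on a few hundred images in 20 epochs needs a larger step and more
  optimizer steps than the full-scale recipe — batch 4, learning rate 2e-3,
  channels (16, 32, 64), milder augmentation (probability 0.3, rotation
  ±10°, shadow 0.2–0.4). Dropout stays at the published 0.5. An optional
  cosine decay is available but off by default (it did not help at this
  scale).

## Grad-CAM on the 7×7 grid

The softmax is removed: the gradient target is the pre-softmax score of the
target class (the predicted class unless overridden). With a
GAP-plus-linear head the gradient of the score with respect to the
designated feature map is computed by running the head's linear operations
in reverse; the channel weight is its spatial average, and the CAM is the
rectified weighted channel sum. The package checks this gradient against
central finite differences on toy networks rather than trusting the
algebra.

Numerical conventions:

* Grids whose native resolution is not 7×7 are bilinearly resampled to 7×7
  *before* normalization.
* Normalization divides by the maximum, so every non-degenerate grid has a
  cell at exactly 1.0 — hence the activation region at the inclusive
  threshold ≥ 0.9 is never empty.
* If the rectified map is identically zero (e.g. a class score constant in
  the features), the grid is flagged `degenerate` and never divided by
  zero; downstream, degenerate regions map to "not interpretable" and are
  excluded from (but counted next to) frequency maps.
* The threshold is applied to grid-cell values, not the upsampled heatmap,
  because annotation operates on grid squares.
* Max-cell ties break at the smallest row-major index; frequency maps
  depend on this, so it is fixed, documented behaviour.
* The region is the *set* of cells ≥ threshold with no connectivity
  requirement.

## Annotation, consensus, agreement

The four categories are `lymph_node_vessel`, `other_structure`,
`artifact`, `not_interpretable`. The human criterion — "does the region
overlap a clinically meaningful structure" — needs a numeric proxy on
phantoms: a region overlaps a mask when at least 25% of one region cell's
pixel footprint intersects it (fraction configurable). Labels follow a
clinical-relevance precedence: quality below the floor or an empty region →
not interpretable; node/vessel overlap → lymph node/vessel; else artifact
overlap → artifact; else other structure. The oracle is deterministic.

Simulated raters report the truth with probability 1−p and otherwise draw
from a confusion kernel row (default: uniform over the other three
labels). Consensus follows the majority rule: three equal labels =
complete agreement; exactly two = majority, the shared label wins; all
distinct = disagreement, pending until an adjudication table resolves it
(in simulation the oracle adjudicates, mirroring a consensus meeting).

Agreement statistics are computed exclusively from the independent
pre-consensus annotations, on the fixed four-category space even when some
categories are unobserved (zero marginals add nothing to chance agreement,
and reports stay comparable across runs). Cohen's κ uses the product of
marginals for chance; Fleiss' κ the pooled category proportions. When
chance agreement is exactly 1 the statistic is returned as NaN with an
`undefined` flag (or 1 when observed agreement is also perfect, for
Cohen). With two raters both statistics are reported; they differ by
chance model and are not interchangeable. Interpretation uses the
Landis–Koch bands (0.41–0.60 "moderate", etc.). Kappas are reported to
three decimals, percentages to one.

## Evaluation

Per-class precision, sensitivity and F1 (harmonic mean of the two) are kept
at full precision and rounded half-away-from-zero to one decimal only at
report time. Zero-denominator cases return 0 and are flagged. Macro
averages weight stations equally; weighted averages use supports, and the
micro identity (weighted sensitivity = trace/n = accuracy) holds exactly
and is property-tested. Stratified metrics partition test images by final
consensus label; within a stratum the class average is macro-style over the
classes actually present (a `weighted` switch is provided — which
convention the stratified table should use is genuinely open, so it is a
config choice rather than hard-coded).

## Reproducibility and problem sizes

A single global seed fans out to per-stage sub-seeds through a documented
hash (`deriveSeed`), logged in the report, so any stage can be re-run in
isolation; the pipeline is byte-reproducible from (config, seed). The
bundled benchmarks generate 10 patients × 40 frames at 64 px
(`easyPhantomConfig()`, the well-separated layout: low speckle, high
quality, enlarged vessels, tight node-size priors) and train for 20 epochs
with `deskTrainConfig()` — sizes chosen so a full audit runs in about two
minutes on one CPU while leaving the classifier far above the 12.5% chance
level (typically 65–85% test accuracy). The realistic-default generator
(`phantomConfig()`) is markedly harder; expect lower accuracy or longer
training there.

## Known limitations

* The phantom's appearance priors make stations separable by design;
  absolute accuracies on phantoms say nothing about clinical data.
* The small backbone has no batch normalization and trains from scratch;
  at very small cohort sizes results vary by a few points across seeds.
* Serialization covers the built-in backbone only; frozen-extractor models
  hold a live function and cannot be written to disk.
* Fleiss' κ is the only multi-rater statistic; weighted κ and
  Krippendorff's α are out of scope, as are ROC/AUC and spatial
  significance testing of frequency maps.
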