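# SonoCAM

SonoCAM audits *where a classifier looks*. It targets a common situation in
AI-assisted endobronchial ultrasound (EBUS): a convolutional network assigns
B-mode images to one of eight mediastinal/hilar lymph-node stations (4L, 4R,
7L, 7R, 10L, 10R, 11L, 11R), and clinicians need to know whether its
attention — visualized with Grad-CAM — actually lands on the anatomy that
justifies the call (lymph nodes and vessels) or on artifacts and background.
The package is aimed at researchers building or validating explainable
ultrasound classifiers who want the whole audit loop as reproducible,
scriptable code.

## What it implements

* **Synthetic phantoms** — sector-scan B-mode-like images with hypoechoic
  elliptical nodes, anechoic vessels, acoustic shadow/reverberation
  artifacts, an echogenic wall arc and multiplicative speckle, organized into
  8 station classes across simulated patients, each frame with exact binary
  ground-truth masks (`generateDataset`).
* **Classifier harness** — patient-wise 70/20/10 splitting with no patient
  leakage, the five standard augmentations (gamma, blur, rotation, contrast,
  Gaussian shadow), and an AdamW-trained small CNN whose last convolutional
  map is 7×7, with a global-average-pooling + dropout(0.5) + softmax head
  over the 8 stations, early stopping on validation loss (`trainModel`).
* **Grad-CAM** — for the designated last convolutional layer, channel
  weights are the spatially averaged gradients of the pre-softmax class
  score `s_c`:

  `α_k = (1/Z) Σ_ij ∂s_c/∂A_k(i,j)`,  `CAM = ReLU(Σ_k α_k A_k)`,

  normalized so the top cell of the 7×7 grid equals 1. The *activation
  region* is every grid cell ≥ 0.9; the max-intensity cell is tracked
  separately (`computeCAM`, `extractRegion`), and max-cell positions
  aggregate into per-station frequency maps (`maxCellFrequency`).
* **Annotation & consensus** — the four-category labelling (lymph
  node/vessel, other structure, artifact, not interpretable) with a
  deterministic mask-overlap oracle, simulated noisy raters, and the
  majority rule: two matching labels decide; three-way disagreement goes to
  adjudication (`oracleLabel`, `simulateRater`, `consensus`).
* **Agreement statistics** — percent agreement, pairwise Cohen's κ, Fleiss'
  κ with Landis–Koch bands (`agreementReport`).
* **Evaluation** — confusion matrix, per-class precision/sensitivity/F1 with
  supports, macro and support-weighted averages (weighted sensitivity =
  overall accuracy), and the same metrics stratified by consensus attention
  category (`aggregateMetrics`, `stratifyMetrics`).

`runPipeline()` chains all stages from one seeded config;
`inst/scripts/usgrad-audit.R` exposes each stage as a shell subcommand.

## Worked example

```r
library(SonoCAM)

cfg <- runConfig(
  phantom = list(imageSize = 64L, nPatients = 10L, framesPerPatient = 40L,
                 angularWidth = 75,
                 speckle = list(meanIntensity = 0.5, noiseScale = 0.15),
                 nodeAxisRange = c(9, 13), vesselRadiusRange = c(3, 5),
                 artifactProbability = 0.15, reverbProbability = 0.1,
                 qualityRange = c(0.8, 1)),
  train = list(epochs = 20L, patience = 20L, batchSize = 4L,
               learningRate = 2e-3, channels = c(16L, 32L, 64L)),
  seed = 1L, outDir = "audit-run")
report <- runPipeline(cfg)

report$tables$averages$accuracy
report$tables$agreement$fleiss
```

On this 400-frame phantom cohort (280 train / 80 validation / 40 test
images, patients disjoint) the run prints an overall test accuracy of
`87.5`%, and the three simulated raters (15% flip probability each) give a
percent agreement of `52.5`% with Fleiss' κ = `0.477` ("moderate"). The
output directory contains the manifest, model checkpoint, training history,
per-image activation grids/regions (`regions.json`), annotations, consensus
labels, agreement report, confusion matrix, per-station max-cell frequency
maps with heatmap panels, and a combined `report.json`/`report.html`.

The exact numbers above are for `seed = 1`; other seeds regenerate the
cohort and re-train, so they vary within a few points.

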