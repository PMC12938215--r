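#' Configuration for the synthetic sector-scan phantom generator
#'
#' Builds and validates the parameter set controlling synthetic EBUS-like
#' B-mode frames: sector geometry, speckle statistics, per-frame structure
#' priors (hypoechoic lymph nodes, anechoic vessels, shadow/reverberation
#' artifacts, an echogenic wall arc), image quality, and cohort size.
#' Lengths are in pixels; size-dependent defaults scale with
#' \code{imageSize}.
#'
#' @param imageSize Square image side in pixels (>= 32). Default 224, the
#'   classifier's native input size; tests typically use 64 for speed.
#' @param angularWidth Sector opening angle in degrees, in (0, 180].
#' @param radialDepth Sector depth in pixels from the apex.
#' @param speckle List with \code{meanIntensity} (background mean, [0,1]) and
#'   \code{noiseScale} (relative s.d. of the multiplicative speckle).
#' @param nodeCountRange Integer range of lymph nodes per frame.
#' @param nodeAxisRange Range of the node major axis length (full axis, px).
#' @param nodeAspectRange Range of minor/major axis ratio.
#' @param vesselCountRange Integer range of vessels per frame.
#' @param vesselRadiusRange Range of vessel radius (px).
#' @param artifactProbability Probability a frame carries an acoustic shadow.
#' @param reverbProbability Probability of a reverberation stripe train.
#' @param otherStructureProbability Probability of the echogenic wall arc.
#' @param qualityRange Range the per-frame quality score is drawn from.
#' @param qualityFloor Quality below which a frame is rendered blurred and
#'   low-contrast (the deterministic trigger for "not interpretable").
#' @param nPatients Number of simulated patients (>= 3, so a patient-wise
#'   70/20/10 split is non-degenerate).
#' @param framesPerPatient Frames generated per patient.
#' @param seed Integer seed for \code{\link{generateDataset}}.
#' @return A validated list of class \code{"PhantomConfig"}.
#' @export
#' @examples
#' cfg <- phantomConfig(imageSize = 64, nPatients = 4, framesPerPatient = 8)
phantomConfig <- function(imageSize = 224L,
                          angularWidth = 70,
                          radialDepth = round(0.92 * imageSize),
                          speckle = list(meanIntensity = 0.5, noiseScale = 0.4),
                          nodeCountRange = c(1L, 3L),
                          nodeAxisRange = round(c(0.10, 0.25) * imageSize),
                          nodeAspectRange = c(0.5, 0.85),
                          vesselCountRange = c(1L, 2L),
                          vesselRadiusRange = round(c(0.03, 0.06) * imageSize),
                          artifactProbability = 0.5,
                          reverbProbability = 0.3,
                          otherStructureProbability = 0.7,
                          qualityRange = c(0.2, 1.0),
                          qualityFloor = 0.3,
                          nPatients = 10L,
                          framesPerPatient = 40L,
                          seed = 1L) {
  rng2 <- function(x) { # YAML sequences may arrive as lists
    x <- as.numeric(unlist(x))
    stopifnot(length(x) == 2L, x[1] <= x[2])
    x
  }
  cfg <- list(imageSize = as.integer(imageSize), angularWidth = angularWidth,
              radialDepth = radialDepth,
              speckle = list(meanIntensity = as.numeric(speckle$meanIntensity),
                             noiseScale = as.numeric(speckle$noiseScale)),
              nodeCountRange = as.integer(rng2(nodeCountRange)),
              nodeAxisRange = rng2(nodeAxisRange),
              nodeAspectRange = rng2(nodeAspectRange),
              vesselCountRange = as.integer(rng2(vesselCountRange)),
              vesselRadiusRange = rng2(vesselRadiusRange),
              artifactProbability = artifactProbability,
              reverbProbability = reverbProbability,
              otherStructureProbability = otherStructureProbability,
              qualityRange = rng2(qualityRange), qualityFloor = qualityFloor,
              nPatients = as.integer(nPatients),
              framesPerPatient = as.integer(framesPerPatient),
              seed = as.integer(seed))
  if (cfg$imageSize < 32L) stop("imageSize must be at least 32")
  if (!(angularWidth > 0 && angularWidth <= 180))
    stop("angularWidth must lie in (0, 180]")
  for (p in c("artifactProbability", "reverbProbability",
              "otherStructureProbability"))
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop(p, " must lie in [0,1]")
  if (any(cfg$qualityRange < 0 | cfg$qualityRange > 1))
    stop("qualityRange must lie in [0,1]")
  if (cfg$nPatients < 3L)
    stop("nPatients must be at least 3 for a patient-wise 70/20/10 split")
  class(cfg) <- "PhantomConfig"
  cfg
}

#' Station layout and appearance templates
#'
#' One prior per station: where, in sector coordinates (depth fraction along
#' the beam, angle fraction across the sector), the station's node cluster
#' and principal vessel sit, plus appearance parameters - node multiplicity,
#' node and vessel size scales and background echogenicity - since real
#' stations differ in sonographic appearance as much as in layout. The eight
#' templates are pairwise distinct (left/right pairs mirror in angle, station
#' levels stack in depth, appearance varies across all eight) so the classes
#' are learnable from image content.
#'
#' @return Data frame with one row per station in \code{stationLevels()} order.
#' @export
#' @examples
#' stationTemplates()
stationTemplates <- function() {
  data.frame(
    station       = stationLevels(),
    nodeAngleFrac = c(0.22, 0.78, 0.32, 0.68, 0.22, 0.78, 0.38, 0.62),
    nodeDepthFrac = c(0.30, 0.30, 0.52, 0.52, 0.70, 0.70, 0.86, 0.86),
    nodeCount     = c(1L, 2L, 1L, 3L, 2L, 1L, 3L, 2L),
    nodeScale     = c(1.40, 1.00, 0.75, 1.00, 1.30, 1.00, 0.75, 1.20),
    vesselScale   = c(1.0, 1.4, 0.7, 1.0, 0.7, 1.6, 1.0, 1.3),
    bgLevel       = c(1.10, 0.95, 1.05, 0.90, 1.00, 1.10, 0.85, 1.00),
    angleJitter   = 0.05,
    depthJitter   = 0.04,
    stringsAsFactors = FALSE
  )
}

# Sector geometry shared by rendering: polar coordinates of every pixel
# relative to the transducer apex at the top-centre (row 1 = proximal).
sectorGeometry <- function(cfg) {
  S <- cfg$imageSize
  apexRow <- 1
  apexCol <- (S + 1) / 2
  rows <- matrix(seq_len(S), S, S)
  cols <- matrix(seq_len(S), S, S, byrow = TRUE)
  rho <- sqrt((rows - apexRow)^2 + (cols - apexCol)^2)
  theta <- atan2(cols - apexCol, rows - apexRow) * 180 / pi # 0 = straight down
  rmin <- 0.04 * S
  inSector <- (abs(theta) <= cfg$angularWidth / 2) &
    rho <= cfg$radialDepth & rho >= rmin
  list(S = S, apexRow = apexRow, apexCol = apexCol, rho = rho, theta = theta,
       sector = inSector * 1)
}

# Pixel-space centre of a (depthFrac, angleFrac) sector position.
sectorPoint <- function(geo, cfg, depthFrac, angleFrac) {
  th <- (angleFrac - 0.5) * cfg$angularWidth * pi / 180
  rr <- depthFrac * cfg$radialDepth
  c(row = geo$apexRow + rr * cos(th), col = geo$apexCol + rr * sin(th))
}

# Rotated-ellipse membership metric: <= 1 inside.
ellipseMetric <- function(geo, centre, semiMajor, semiMinor, phiDeg) {
  rows <- matrix(seq_len(geo$S), geo$S, geo$S)
  cols <- matrix(seq_len(geo$S), geo$S, geo$S, byrow = TRUE)
  dx <- cols - centre["col"]
  dy <- rows - centre["row"]
  phi <- phiDeg * pi / 180
  u <- dx * cos(phi) + dy * sin(phi)
  v <- -dx * sin(phi) + dy * cos(phi)
  (u / semiMajor)^2 + (v / semiMinor)^2
}

#' Generate one synthetic sector-scan frame
#'
#' Renders a single B-mode-like frame for the given station: a smooth
#' depth-attenuated background inside the sector, hypoechoic elliptical lymph
#' nodes at the station's template position, anechoic vessel discs, an
#' optional echogenic wall arc ("other structure"), optional distal shadow
#' wedge and reverberation stripes, multiplicative speckle, and quality-driven
#' degradation. Every synthesized structure is delineated exactly in the
#' returned binary masks.
#'
#' @param config A \code{\link{phantomConfig}}.
#' @param station Station label; one of \code{stationLevels()}.
#' @param patientId Character patient identifier.
#' @param seed Integer seed; the same (config, station, seed) reproduces the
#'   frame bit for bit.
#' @return A \code{\linkS4class{PhantomFrame}}.
#' @export
#' @examples
#' f <- generateFrame(phantomConfig(imageSize = 64), "4L", "P01", seed = 7)
#' frameStation(f)
generateFrame <- function(config, station, patientId = "P00", seed = 1L) {
  if (!station %in% stationLevels())
    stop("unknown station '", station, "'; valid stations: ",
         paste(stationLevels(), collapse = ", "))
  tpl <- stationTemplates()
  tpl <- tpl[tpl$station == station, ]
  geo <- sectorGeometry(config)
  S <- geo$S

  withSeed(seed, {
    depthFrac <- geo$rho / config$radialDepth
    img <- config$speckle$meanIntensity * tpl$bgLevel *
      (1 - 0.30 * depthFrac) *
      (1 - 0.15 * (abs(geo$theta) / (config$angularWidth / 2))^2)
    masks <- list(
      lymph_node = matrix(0, S, S), vessel = matrix(0, S, S),
      artifact = matrix(0, S, S), other_structure = matrix(0, S, S))

    # echogenic wall arc near the probe ("other structure")
    if (stats::runif(1) < config$otherStructureProbability) {
      rho0 <- 0.16 * config$radialDepth
      band <- abs(geo$rho - rho0) <= max(1.5, 0.015 * S) &
        abs(geo$theta) <= 0.40 * config$angularWidth
      img[band] <- img[band] * 2.0
      masks$other_structure[band] <- 1
    }

    # hypoechoic lymph nodes: the template's multiplicity, clamped to the
    # configured prior range
    nNodes <- min(max(tpl$nodeCount, config$nodeCountRange[1]),
                  config$nodeCountRange[2])
    for (k in seq_len(nNodes)) {
      dFr <- tpl$nodeDepthFrac + stats::rnorm(1, 0, tpl$depthJitter) +
        if (k > 1) stats::runif(1, -0.08, 0.08) else 0
      aFr <- tpl$nodeAngleFrac + stats::rnorm(1, 0, tpl$angleJitter) +
        if (k > 1) stats::runif(1, -0.10, 0.10) else 0
      ctr <- sectorPoint(geo, config, min(max(dFr, 0.12), 0.92),
                         min(max(aFr, 0.08), 0.92))
      major <- tpl$nodeScale *
        stats::runif(1, config$nodeAxisRange[1], config$nodeAxisRange[2])
      minor <- major * stats::runif(1, config$nodeAspectRange[1],
                                    config$nodeAspectRange[2])
      phi <- stats::runif(1, 0, 180)
      m <- ellipseMetric(geo, ctr, major / 2, minor / 2, phi)
      inside <- m <= 1
      rim <- m > 1 & m <= 1.35
      img[inside] <- img[inside] * 0.35
      img[rim] <- img[rim] * 1.35
      masks$lymph_node[inside] <- 1
    }

    # anechoic vessels (mirror side of the node cluster)
    nVessels <- if (config$vesselCountRange[2] < 1) 0L else
      min(max(if (tpl$vesselScale >= 1.3) 2L else 1L,
              config$vesselCountRange[1]), config$vesselCountRange[2])
    vesselTheta <- NULL
    for (k in seq_len(nVessels)) {
      dFr <- tpl$nodeDepthFrac - 0.12 + stats::rnorm(1, 0, tpl$depthJitter) +
        if (k > 1) stats::runif(1, -0.10, 0.10) else 0
      aFr <- (1 - tpl$nodeAngleFrac) + stats::rnorm(1, 0, tpl$angleJitter)
      dFr <- min(max(dFr, 0.15), 0.9)
      aFr <- min(max(aFr, 0.08), 0.92)
      ctr <- sectorPoint(geo, config, dFr, aFr)
      rad <- tpl$vesselScale *
        stats::runif(1, config$vesselRadiusRange[1],
                     config$vesselRadiusRange[2])
      m <- ellipseMetric(geo, ctr, rad, rad, 0)
      inside <- m <= 1
      img[inside] <- img[inside] * 0.04
      masks$vessel[inside] <- 1
      if (k == 1) vesselTheta <- (aFr - 0.5) * config$angularWidth
    }

    # acoustic shadow: attenuated wedge distal to a reflector
    if (stats::runif(1) < config$artifactProbability) {
      th0 <- if (!is.null(vesselTheta)) vesselTheta else
        stats::runif(1, -0.3, 0.3) * config$angularWidth
      halfw <- stats::runif(1, 4, 8)
      rho0 <- stats::runif(1, 0.45, 0.60) * config$radialDepth
      wedge <- abs(geo$theta - th0) <= halfw & geo$rho > rho0
      img[wedge] <- img[wedge] * 0.18
      masks$artifact[wedge] <- 1
    }

    # reverberation: periodic bright arcs in an angular window
    if (stats::runif(1) < config$reverbProbability) {
      th0 <- stats::runif(1, -0.25, 0.25) * config$angularWidth
      halfw <- stats::runif(1, 5, 10)
      delta <- stats::runif(1, 0.08, 0.12) * config$radialDepth
      stripes <- matrix(FALSE, S, S)
      for (k in 2:5) {
        stripes <- stripes | (abs(geo$rho - k * delta) <= max(1, 0.008 * S) &
                                abs(geo$theta - th0) <= halfw)
      }
      img[stripes] <- img[stripes] * 1.8
      masks$artifact[stripes] <- 1
    }

    # multiplicative speckle (unit mean, s.d. = noiseScale), light PSF blur
    ns <- config$speckle$noiseScale
    if (ns > 0) {
      noise <- matrix(stats::rgamma(S * S, shape = 1 / ns^2, scale = ns^2), S, S)
      img <- img * noise
    }
    img <- blurMatrix(img, 0.5)

    quality <- stats::runif(1, config$qualityRange[1], config$qualityRange[2])
    if (quality < config$qualityFloor) {
      img <- blurMatrix(img, 0.04 * S)
      img <- mean(img) + 0.35 * (img - mean(img))
    }

    img <- clamp01(img) * geo$sector
    for (nm in names(masks)) masks[[nm]] <- masks[[nm]] * geo$sector

    methods::new("PhantomFrame", image = img, masks = masks,
                 sector = geo$sector, station = station,
                 patientId = patientId, quality = quality)
  })
}

#' Generate a full phantom dataset with manifest
#'
#' Generates \code{nPatients * framesPerPatient} frames, cycling stations
#' within each patient (with a per-patient offset) so every station is
#' represented and roughly balanced, and builds the dataset manifest. When
#' \code{outDir} is given, images and masks are written as 8-bit grayscale
#' PNGs and the manifest as \code{manifest.csv}.
#'
#' @param config A \code{\link{phantomConfig}}; \code{config$seed} drives all
#'   randomness (per-frame sub-seeds are derived deterministically).
#' @param outDir Optional output directory.
#' @return List with \code{frames} (named list of
#'   \code{\linkS4class{PhantomFrame}}) and \code{manifest} (data frame with
#'   columns \code{image, mask_lymph_node, mask_vessel, mask_artifact,
#'   mask_other, station, patient_id, quality}).
#' @export
#' @examples
#' ds <- generateDataset(phantomConfig(imageSize = 64, nPatients = 3,
#'                                     framesPerPatient = 8))
#' nrow(ds$manifest)
generateDataset <- function(config, outDir = NULL) {
  nTotal <- config$nPatients * config$framesPerPatient
  if (nTotal < 8L)
    stop("nPatients * framesPerPatient must be at least 8 to cover all stations")
  stations <- stationLevels()
  patients <- sprintf("P%02d", seq_len(config$nPatients))
  frames <- list()
  rows <- vector("list", nTotal)
  idx <- 0L
  for (p in seq_along(patients)) {
    for (i in seq_len(config$framesPerPatient)) {
      idx <- idx + 1L
      st <- stations[((i - 1L + (p - 1L)) %% 8L) + 1L]
      id <- sprintf("%s_f%03d", patients[p], i)
      fr <- generateFrame(config, st, patients[p],
                          seed = deriveSeed(config$seed, id))
      frames[[id]] <- fr
      rows[[idx]] <- data.frame(
        image = paste0(id, ".png"),
        mask_lymph_node = paste0(id, "_mask_lymph_node.png"),
        mask_vessel = paste0(id, "_mask_vessel.png"),
        mask_artifact = paste0(id, "_mask_artifact.png"),
        mask_other = paste0(id, "_mask_other.png"),
        station = st, patient_id = patients[p],
        quality = fr@quality, stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    for (id in names(frames)) {
      fr <- frames[[id]]
      png::writePNG(round(fr@image * 255) / 255,
                    file.path(outDir, paste0(id, ".png")))
      for (nm in names(fr@masks)) {
        short <- if (nm == "other_structure") "other" else nm
        png::writePNG(fr@masks[[nm]],
                      file.path(outDir, sprintf("%s_mask_%s.png", id, short)))
      }
    }
    writeManifest(manifest, file.path(outDir, "manifest.csv"))
  }
  list(frames = frames, manifest = manifest)
}

#' Well-separated benchmark phantom configuration
#'
#' The "easy" station layout used for desk-scale end-to-end benchmarks: low
#' speckle noise, high-quality frames, few artifacts, tight node-size priors
#' and enlarged vessels, so the eight station templates are well separated
#' and a small classifier trained for a handful of epochs performs far above
#' chance. The default-parameter \code{\link{phantomConfig}} is the realistic
#' (harder) setting; this one exists to exercise the full audit pipeline
#' quickly.
#'
#' @param imageSize Square image side (default 64).
#' @param nPatients,framesPerPatient Cohort size (defaults 10 x 40).
#' @param seed Integer seed.
#' @return A \code{\link{phantomConfig}}.
#' @export
easyPhantomConfig <- function(imageSize = 64L, nPatients = 10L,
                              framesPerPatient = 40L, seed = 1L) {
  phantomConfig(
    imageSize = imageSize, angularWidth = 75,
    speckle = list(meanIntensity = 0.5, noiseScale = 0.15),
    nodeAxisRange = round(c(0.14, 0.20) * imageSize),
    vesselRadiusRange = round(c(0.05, 0.08) * imageSize),
    artifactProbability = 0.15, reverbProbability = 0.1,
    qualityRange = c(0.8, 1),
    nPatients = nPatients, framesPerPatient = framesPerPatient, seed = seed)
}
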