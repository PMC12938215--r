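#' @import methods
NULL

#' Station labels in fixed class order
#'
#' The eight IASLC-style lymph-node station classes, ordered by station number
#' then side. This order is used everywhere a class axis appears (probability
#' vectors, confusion matrices, reports).
#'
#' @return Character vector of length 8.
#' @export
#' @examples
#' stationLevels()
stationLevels <- function() c("4L", "4R", "7L", "7R", "10L", "10R", "11L", "11R")

#' The four attention annotation categories
#'
#' Closed label set used by raters when judging what a Grad-CAM activation
#' region overlaps: lymph node or blood vessel (clinically relevant), another
#' anatomical structure, an ultrasound artifact, or not interpretable.
#'
#' @return Character vector of length 4.
#' @export
#' @examples
#' annotationLabels()
annotationLabels <- function() {
  c("lymph_node_vessel", "other_structure", "artifact", "not_interpretable")
}

#' PhantomFrame: one synthetic sector-scan image with ground truth
#'
#' A single synthetic B-mode-like frame: the grayscale image in [0,1], four
#' binary structure masks (lymph node, vessel, artifact, other structure) of
#' identical shape, the station label, patient id, and a quality score in
#' [0,1]. Masks are exact by construction and zero outside the sector
#' footprint.
#'
#' @slot image Numeric matrix in [0,1]; row 1 is proximal (transducer side).
#' @slot masks Named list of four 0/1 matrices:
#'   \code{lymph_node}, \code{vessel}, \code{artifact}, \code{other_structure}.
#' @slot sector 0/1 matrix marking the insonified sector footprint.
#' @slot station Character, one of \code{stationLevels()}.
#' @slot patientId Character patient identifier.
#' @slot quality Numeric in [0,1]; low values render blurred/low-contrast.
#'
#' @export
setClass("PhantomFrame",
  representation(image = "matrix", masks = "list", sector = "matrix",
                 station = "character", patientId = "character",
                 quality = "numeric"))

setValidity("PhantomFrame", function(object) {
  msg <- character()
  d <- dim(object@image)
  need <- c("lymph_node", "vessel", "artifact", "other_structure")
  if (!identical(sort(names(object@masks)), sort(need)))
    msg <- c(msg, "masks must be named lymph_node, vessel, artifact, other_structure")
  else {
    for (nm in need) {
      if (!identical(dim(object@masks[[nm]]), d))
        msg <- c(msg, sprintf("mask '%s' shape differs from image", nm))
      if (any(object@masks[[nm]][object@sector == 0] != 0))
        msg <- c(msg, sprintf("mask '%s' non-zero outside the sector footprint", nm))
    }
  }
  if (!identical(dim(object@sector), d))
    msg <- c(msg, "sector footprint shape differs from image")
  if (any(object@image < 0 | object@image > 1))
    msg <- c(msg, "image values must lie in [0,1]")
  if (!object@station %in% stationLevels())
    msg <- c(msg, "unknown station label")
  if (object@quality < 0 || object@quality > 1)
    msg <- c(msg, "quality must lie in [0,1]")
  if (length(msg)) msg else TRUE
})

#' @describeIn PhantomFrame The grayscale image matrix.
#' @param frame A \code{PhantomFrame}.
#' @export
frameImage <- function(frame) frame@image

#' @describeIn PhantomFrame Named list of the four binary structure masks.
#' @export
frameMasks <- function(frame) frame@masks

#' @describeIn PhantomFrame Station label of the frame.
#' @export
frameStation <- function(frame) frame@station

#' @describeIn PhantomFrame Patient identifier.
#' @export
framePatient <- function(frame) frame@patientId

#' @describeIn PhantomFrame Quality score in [0,1].
#' @export
frameQuality <- function(frame) frame@quality

setMethod("show", "PhantomFrame", function(object) {
  cat(sprintf("PhantomFrame %dx%d station %s patient %s quality %.2f\n",
              nrow(object@image), ncol(object@image), object@station,
              object@patientId, object@quality))
  area <- vapply(object@masks, sum, numeric(1))
  cat("  mask px:", paste(sprintf("%s=%d", names(area), as.integer(area)),
                          collapse = " "), "\n")
})

#' ActivationGrid: a normalized 7 x 7 Grad-CAM attention map
#'
#' The Grad-CAM map of one image reduced to the 7 x 7 grid used for structured
#' annotation. Non-degenerate grids are scaled so the maximum cell equals 1;
#' a degenerate grid (all rectified class-gradients non-positive) is all zero
#' and flagged rather than divided by zero.
#'
#' @slot values 7 x 7 numeric matrix in [0,1].
#' @slot degenerate Logical flag.
#' @slot targetClass Integer index (1..8) of the class the gradient targeted.
#'
#' @export
setClass("ActivationGrid",
  representation(values = "matrix", degenerate = "logical",
                 targetClass = "integer"))

setValidity("ActivationGrid", function(object) {
  msg <- character()
  if (!identical(dim(object@values), c(7L, 7L)))
    msg <- c(msg, "values must be 7 x 7")
  if (any(object@values < 0))
    msg <- c(msg, "values must be non-negative")
  if (!object@degenerate && abs(max(object@values) - 1) > 1e-9)
    msg <- c(msg, "non-degenerate grid must have max exactly 1")
  if (object@degenerate && any(object@values != 0))
    msg <- c(msg, "degenerate grid must be all zero")
  if (length(msg)) msg else TRUE
})

#' @describeIn ActivationGrid The 7 x 7 matrix of normalized values.
#' @param grid An \code{ActivationGrid}.
#' @export
gridValues <- function(grid) grid@values

#' @describeIn ActivationGrid TRUE if the rectified map was identically zero.
#' @export
isDegenerate <- function(grid) grid@degenerate

#' @describeIn ActivationGrid Index (1..8) of the gradient's target class.
#' @export
targetClass <- function(grid) grid@targetClass

setMethod("show", "ActivationGrid", function(object) {
  cat(sprintf("ActivationGrid (target class %d%s)\n", object@targetClass,
              if (object@degenerate) ", degenerate" else ""))
  print(round(object@values, 2))
})

#' ActivationRegion: thresholded cells and the max-intensity cell
#'
#' The activation region of one grid: every cell with normalized value at or
#' above the threshold (default 0.9), treated collectively as one region
#' regardless of contiguity, plus the single max-intensity cell (ties broken
#' by smallest row-major index).
#'
#' @slot cells Integer matrix with columns \code{row}, \code{col} (1-based).
#' @slot maxCell Integer length-2 (row, col), or \code{NA} when degenerate.
#' @slot threshold Numeric threshold in (0, 1].
#' @slot degenerate Logical; TRUE for a region from a degenerate grid.
#'
#' @export
setClass("ActivationRegion",
  representation(cells = "matrix", maxCell = "integer",
                 threshold = "numeric", degenerate = "logical"))

setValidity("ActivationRegion", function(object) {
  msg <- character()
  if (ncol(object@cells) != 2L) msg <- c(msg, "cells must have 2 columns")
  if (!object@degenerate) {
    if (nrow(object@cells) < 1L)
      msg <- c(msg, "non-degenerate region must contain at least one cell")
    inreg <- any(object@cells[, 1] == object@maxCell[1] &
                 object@cells[, 2] == object@maxCell[2])
    if (!inreg) msg <- c(msg, "maxCell must belong to the region")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn ActivationRegion Integer matrix of (row, col) region cells.
#' @param region An \code{ActivationRegion}.
#' @export
regionCells <- function(region) region@cells

#' @describeIn ActivationRegion The (row, col) of the max-intensity cell.
#' @export
maxCell <- function(region) region@maxCell

#' @describeIn ActivationRegion The threshold that defined the region.
#' @export
regionThreshold <- function(region) region@threshold

#' @describeIn ActivationRegion TRUE when the source grid was degenerate.
#' @export
regionDegenerate <- function(region) region@degenerate

setMethod("show", "ActivationRegion", function(object) {
  if (object@degenerate) {
    cat("ActivationRegion: degenerate (empty)\n")
  } else {
    cat(sprintf("ActivationRegion: %d cell(s) >= %.2f, max at (%d,%d)\n",
                nrow(object@cells), object@threshold,
                object@maxCell[1], object@maxCell[2]))
  }
})

#' FrequencyMap: where the max-intensity cell lands
#'
#' Counts, over a set of images, of how often the max-intensity Grad-CAM cell
#' fell in each of the 49 grid positions; one map per station plus an overall
#' map. Rows run proximal (top) to distal, columns across the probe's
#' left-right axis.
#'
#' @slot scope Station label or \code{"overall"}.
#' @slot counts 7 x 7 non-negative integer matrix.
#' @slot nImages Number of images tallied (equals \code{sum(counts)}).
#'
#' @export
setClass("FrequencyMap",
  representation(scope = "character", counts = "matrix", nImages = "integer"))

setValidity("FrequencyMap", function(object) {
  msg <- character()
  if (!identical(dim(object@counts), c(7L, 7L)))
    msg <- c(msg, "counts must be 7 x 7")
  if (any(object@counts < 0)) msg <- c(msg, "counts must be non-negative")
  if (sum(object@counts) != object@nImages)
    msg <- c(msg, "counts must sum to nImages")
  if (length(msg)) msg else TRUE
})

#' @describeIn FrequencyMap The 7 x 7 count matrix.
#' @param map A \code{FrequencyMap}.
#' @export
mapCounts <- function(map) map@counts

#' @describeIn FrequencyMap Scope label (\code{"overall"} or a station).
#' @export
mapScope <- function(map) map@scope

#' @describeIn FrequencyMap Number of images tallied.
#' @export
mapImages <- function(map) map@nImages

setMethod("show", "FrequencyMap", function(object) {
  cat(sprintf("FrequencyMap [%s], n = %d\n", object@scope, object@nImages))
  print(object@counts)
})

#' AgreementReport: inter-rater agreement statistics
#'
#' Percent agreement, Fleiss' kappa over all raters, pairwise Cohen's kappas,
#' and the Landis-Koch interpretation band for each kappa, computed from the
#' independent (pre-consensus) annotations.
#'
#' @slot percentAgreement Percent of items on which every rater agrees.
#' @slot fleiss Fleiss' kappa (NaN-flagged when chance agreement is 1).
#' @slot cohen Named numeric vector, one kappa per rater pair (\code{"r1-r2"}).
#' @slot interpretations Named character vector of band labels.
#' @slot nItems,nRaters Integer problem size.
#' @slot categories The fixed category set used for chance correction.
#'
#' @export
setClass("AgreementReport",
  representation(percentAgreement = "numeric", fleiss = "numeric",
                 cohen = "numeric", interpretations = "character",
                 nItems = "integer", nRaters = "integer",
                 categories = "character"))

setValidity("AgreementReport", function(object) {
  msg <- character()
  if (object@percentAgreement < 0 || object@percentAgreement > 100)
    msg <- c(msg, "percentAgreement must lie in [0, 100]")
  ok <- function(k) is.nan(k) | (k >= -1 - 1e-12 & k <= 1 + 1e-12)
  if (!all(ok(object@cohen)) || !ok(object@fleiss))
    msg <- c(msg, "kappas must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "AgreementReport", function(object) {
  cat(sprintf("AgreementReport: %d items, %d raters\n",
              object@nItems, object@nRaters))
  cat(sprintf("  percent agreement: %.1f%%\n", object@percentAgreement))
  cat(sprintf("  Fleiss' kappa: %.3f (%s)\n", object@fleiss,
              object@interpretations[["fleiss"]]))
  for (nm in names(object@cohen))
    cat(sprintf("  Cohen's kappa %s: %.3f (%s)\n", nm, object@cohen[[nm]],
                object@interpretations[[nm]]))
})

#' StationModel: a trained eight-station classifier
#'
#' An opaque predictor exposing class probabilities, the spatial feature map
#' of its designated (last) convolutional layer, and analytic gradients of any
#' pre-softmax class score with respect to that feature map - everything
#' Grad-CAM needs.
#'
#' @slot params Named list of weight arrays (convolution kernels, head).
#' @slot arch Internal architecture description (layer shapes, indices).
#' @slot classOrder Character vector of the 8 stations in output order.
#' @slot inputSize Integer side length images are resized to at entry.
#' @slot featureDims Integer length-3: rows, cols, channels of the
#'   designated feature layer (spatial dims at least 2 x 2).
#' @slot selectedEpoch Epoch of the checkpoint with minimum validation loss.
#' @slot history Data frame with per-epoch loss/accuracy/precision/recall
#'   for the train and validation splits.
#'
#' @export
setClass("StationModel",
  representation(params = "list", arch = "list", classOrder = "character",
                 inputSize = "integer", featureDims = "integer",
                 selectedEpoch = "integer", history = "data.frame"))

setValidity("StationModel", function(object) {
  msg <- character()
  if (length(object@classOrder) != 8L)
    msg <- c(msg, "classOrder must have 8 entries")
  if (length(object@featureDims) != 3L || any(object@featureDims[1:2] < 2L))
    msg <- c(msg, "designated feature layer must be spatial (>= 2 x 2)")
  if (length(msg)) msg else TRUE
})

#' @describeIn StationModel Class order of the probability output.
#' @param model A \code{StationModel}.
#' @export
classOrder <- function(model) model@classOrder

#' @describeIn StationModel Per-epoch training history data frame.
#' @export
modelHistory <- function(model) model@history

#' @describeIn StationModel Epoch of the selected (min validation loss) checkpoint.
#' @export
selectedEpoch <- function(model) model@selectedEpoch

setMethod("show", "StationModel", function(object) {
  cat(sprintf("StationModel: input %dx%d, features %dx%dx%d, checkpoint epoch %d\n",
              object@inputSize, object@inputSize, object@featureDims[1],
              object@featureDims[2], object@featureDims[3],
              object@selectedEpoch))
  val <- object@history[object@history$split == "validation", ]
  if (nrow(val))
    cat(sprintf("  best val loss %.4f, val accuracy %.3f at that epoch\n",
                min(val$loss), val$accuracy[which.min(val$loss)]))
})
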