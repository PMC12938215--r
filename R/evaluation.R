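#' Confusion matrix over the fixed station order
#'
#' Rows are true stations, columns predicted stations, both in
#' \code{stationLevels()} order (or a supplied class order).
#'
#' @param trueLabels,predictedLabels Equal-length label vectors.
#' @param classes Class order; defaults to the eight stations.
#' @return Integer matrix with dimnames \code{true} x \code{predicted}.
#' @export
#' @examples
#' confusionCounts(c("4L", "4R"), c("4L", "4L"))
confusionCounts <- function(trueLabels, predictedLabels,
                            classes = stationLevels()) {
  if (length(trueLabels) != length(predictedLabels))
    stop("label vectors differ in length")
  bad <- setdiff(unique(c(trueLabels, predictedLabels)), classes)
  if (length(bad)) stop("unknown label(s): ", paste(bad, collapse = ", "))
  tab <- table(factor(trueLabels, levels = classes),
               factor(predictedLabels, levels = classes))
  m <- matrix(as.integer(tab), length(classes), length(classes),
              dimnames = list(true = classes, predicted = classes))
  m
}

#' Per-class precision, sensitivity and F1
#'
#' For each class: precision = TP/(TP+FP), sensitivity (recall) = TP/(TP+FN),
#' F1 = harmonic mean of the two; support is the true-class row sum. Metrics
#' are percentages kept at full precision (round only at report time).
#' Zero-denominator cases return 0 and are flagged in the \code{flagged}
#' column.
#'
#' @param cm A \code{\link{confusionCounts}} matrix.
#' @return Data frame with columns \code{station}, \code{precision},
#'   \code{sensitivity}, \code{f1}, \code{support}, \code{flagged}.
#' @export
perClassMetrics <- function(cm) {
  classes <- rownames(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  prec <- ifelse(tp + fp > 0, 100 * tp / (tp + fp), 0)
  sens <- ifelse(tp + fn > 0, 100 * tp / (tp + fn), 0)
  f1 <- ifelse(prec + sens > 0, 2 * prec * sens / (prec + sens), 0)
  data.frame(station = classes, precision = as.numeric(prec),
             sensitivity = as.numeric(sens), f1 = as.numeric(f1),
             support = as.integer(rowSums(cm)),
             flagged = as.logical((tp + fp == 0) | (tp + fn == 0)),
             row.names = NULL)
}

#' Macro (unweighted) average of per-class metrics
#'
#' Arithmetic mean of the per-class values, each station weighted equally.
#'
#' @param metrics A \code{\link{perClassMetrics}} data frame.
#' @return Named numeric vector \code{precision}, \code{sensitivity},
#'   \code{f1} (full precision; round at report time).
#' @export
macroAverage <- function(metrics) {
  c(precision = mean(metrics$precision),
    sensitivity = mean(metrics$sensitivity),
    f1 = mean(metrics$f1))
}

#' Support-weighted average of per-class metrics
#'
#' Mean of the per-class values weighted by each station's support (relative
#' frequency in the dataset). For single-label multi-class prediction the
#' weighted sensitivity equals the overall accuracy.
#'
#' @param metrics A \code{\link{perClassMetrics}} data frame.
#' @return Named numeric vector \code{precision}, \code{sensitivity},
#'   \code{f1}.
#' @export
weightedAverage <- function(metrics) {
  if (sum(metrics$support) <= 0) stop("total support must be positive")
  w <- metrics$support / sum(metrics$support)
  c(precision = sum(w * metrics$precision),
    sensitivity = sum(w * metrics$sensitivity),
    f1 = sum(w * metrics$f1))
}

#' Aggregate classification metrics
#'
#' Confusion matrix, per-class table, accuracy, macro and weighted averages.
#'
#' @param trueLabels,predictedLabels Equal-length label vectors.
#' @param classes Class order.
#' @return List with \code{confusion}, \code{perClass}, \code{accuracy} (%),
#'   \code{macro}, \code{weighted}, \code{nImages}.
#' @export
aggregateMetrics <- function(trueLabels, predictedLabels,
                             classes = stationLevels()) {
  cm <- confusionCounts(trueLabels, predictedLabels, classes)
  pc <- perClassMetrics(cm)
  list(confusion = cm, perClass = pc,
       accuracy = 100 * sum(diag(cm)) / sum(cm),
       macro = macroAverage(pc), weighted = weightedAverage(pc),
       nImages = sum(cm))
}

#' Metrics stratified by consensus attention category
#'
#' Partitions the images by their final consensus label and computes
#' accuracy plus averaged precision/sensitivity/F1 within each stratum.
#' Within a stratum the class average is macro-style over the classes
#' actually present (support > 0); \code{averaging = "weighted"} switches to
#' support weighting.
#'
#' @param predictions Data frame with columns \code{image_id},
#'   \code{true_station}, \code{predicted_station}.
#' @param consensusResult A \code{\link{consensus}} (post-adjudication)
#'   result covering every image; pending items are an error.
#' @param classes Class order.
#' @param averaging \code{"macro"} (default) or \code{"weighted"}.
#' @return List with one entry per attention category: \code{accuracy},
#'   \code{precision}, \code{sensitivity}, \code{f1}, \code{support}.
#' @export
stratifyMetrics <- function(predictions, consensusResult,
                            classes = stationLevels(),
                            averaging = c("macro", "weighted")) {
  averaging <- match.arg(averaging)
  stopifnot(all(c("image_id", "true_station", "predicted_station")
                %in% names(predictions)))
  m <- match(predictions$image_id, consensusResult$image_id)
  if (anyNA(m)) {
    miss <- predictions$image_id[is.na(m)]
    stop("no consensus label for: ", paste(utils::head(miss, 5), collapse = ", "))
  }
  lab <- consensusResult$final_label[m]
  if (anyNA(lab)) {
    pend <- predictions$image_id[is.na(lab)]
    stop("pending consensus items: ", paste(utils::head(pend, 5), collapse = ", "))
  }
  out <- list()
  for (cat in unique(lab)) {
    sel <- lab == cat
    cm <- confusionCounts(predictions$true_station[sel],
                          predictions$predicted_station[sel], classes)
    pc <- perClassMetrics(cm)
    present <- pc[pc$support > 0, , drop = FALSE]
    avg <- if (averaging == "macro") macroAverage(present)
           else weightedAverage(present)
    out[[cat]] <- c(accuracy = 100 * sum(diag(cm)) / sum(cm), avg,
                    support = sum(cm))
  }
  out
}

#' Format a metric table at reporting precision
#'
#' Rounds percentage columns to one decimal, half away from zero, leaving
#' supports and flags untouched.
#'
#' @param metrics A \code{\link{perClassMetrics}}-style data frame.
#' @return The data frame with rounded metric columns.
#' @export
formatMetrics <- function(metrics) {
  for (col in intersect(c("precision", "sensitivity", "f1", "accuracy"),
                        names(metrics)))
    metrics[[col]] <- roundHalfUp(metrics[[col]], 1)
  metrics
}
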