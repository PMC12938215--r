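# Format readers/writers with strict schema validation.

manifestColumns <- c("image", "mask_lymph_node", "mask_vessel",
                     "mask_artifact", "mask_other", "station", "patient_id",
                     "quality")

#' Read / write a dataset manifest
#'
#' The manifest is a CSV with header \code{image, mask_lymph_node,
#' mask_vessel, mask_artifact, mask_other, station, patient_id, quality}.
#' Reading validates the schema and values and reports the offending
#' column/line.
#'
#' @param path CSV file path.
#' @return \code{readManifest} returns the manifest data frame.
#' @export
readManifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(manifestColumns, names(df))
  if (length(miss))
    stop("manifest missing column(s): ", paste(miss, collapse = ", "))
  badStation <- which(!df$station %in% stationLevels())
  if (length(badStation))
    stop("manifest line ", badStation[1] + 1L, ": unknown station '",
         df$station[badStation[1]], "'")
  badQ <- which(!is.finite(df$quality) | df$quality < 0 | df$quality > 1)
  if (length(badQ))
    stop("manifest line ", badQ[1] + 1L, ": quality out of [0,1]")
  df[manifestColumns]
}

#' @rdname readManifest
#' @param manifest Manifest data frame.
#' @export
writeManifest <- function(manifest, path) {
  miss <- setdiff(manifestColumns, names(manifest))
  if (length(miss))
    stop("manifest missing column(s): ", paste(miss, collapse = ", "))
  utils::write.csv(manifest[manifestColumns], path, row.names = FALSE)
  invisible(path)
}

#' Read / write annotation records
#'
#' Annotation CSVs carry one rater's label per image:
#' \code{image_id, rater_id, label} with labels drawn from the closed
#' four-category set. Reading validates the schema and every label,
#' reporting the offending line.
#'
#' @param path CSV file path.
#' @return \code{readAnnotations} returns the records data frame.
#' @export
readAnnotations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_id", "rater_id", "label")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("annotation file missing column(s): ", paste(miss, collapse = ", "))
  bad <- which(!df$label %in% annotationLabels())
  if (length(bad))
    stop("annotation line ", bad[1] + 1L, ": invalid label '",
         df$label[bad[1]], "' (valid: ",
         paste(annotationLabels(), collapse = ", "), ")")
  if (anyDuplicated(df[c("image_id", "rater_id")]))
    stop("duplicate (image_id, rater_id) pair in annotation file")
  df[need]
}

#' @rdname readAnnotations
#' @param annotations Records data frame (\code{image_id, rater_id, label}).
#' @export
writeAnnotations <- function(annotations, path) {
  need <- c("image_id", "rater_id", "label")
  stopifnot(all(need %in% names(annotations)))
  bad <- setdiff(unique(annotations$label), annotationLabels())
  if (length(bad)) stop("invalid label(s): ", paste(bad, collapse = ", "))
  utils::write.csv(annotations[need], path, row.names = FALSE)
  invisible(path)
}

#' Read / write consensus results
#'
#' CSV with columns \code{image_id, final_label, agreement_level}.
#'
#' @param path CSV file path.
#' @export
readConsensus <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_id", "final_label", "agreement_level")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("consensus file missing column(s): ", paste(miss, collapse = ", "))
  df[need]
}

#' @rdname readConsensus
#' @param consensusResult Consensus data frame.
#' @export
writeConsensus <- function(consensusResult, path) {
  utils::write.csv(
    consensusResult[c("image_id", "final_label", "agreement_level")],
    path, row.names = FALSE)
  invisible(path)
}

#' Build and validate a pipeline run configuration
#'
#' A run configuration nests per-stage sections (\code{phantom},
#' \code{train}, \code{gradcam}, \code{annotation}) beside a global
#' \code{seed} and \code{outDir}. Unknown keys are rejected anywhere in the
#' tree. Each stage receives a sub-seed derived deterministically from the
#' global seed (logged in the report), so any stage can be re-run in
#' isolation.
#'
#' @param phantom Named list of \code{\link{phantomConfig}} overrides.
#' @param train Named list of \code{\link{trainConfig}} overrides.
#' @param gradcam List with \code{threshold} (default 0.9) and
#'   \code{useTrueClass} (default FALSE: gradients target the predicted
#'   class).
#' @param annotation List with \code{nRaters} (default 3), \code{flipProbability}
#'   (default 0.15), \code{minFraction}, \code{qualityFloor}.
#' @param seed Global integer seed.
#' @param outDir Output directory.
#' @return List of class \code{"RunConfig"}.
#' @export
runConfig <- function(phantom = list(), train = list(), gradcam = list(),
                      annotation = list(), seed = 1L, outDir = tempfile("run")) {
  checkKeys <- function(x, allowed, where) {
    extra <- setdiff(names(x), allowed)
    if (length(extra))
      stop("unknown key(s) in ", where, ": ", paste(extra, collapse = ", "))
  }
  checkKeys(phantom, names(formals(phantomConfig)), "phantom")
  checkKeys(train, names(formals(trainConfig)), "train")
  checkKeys(gradcam, c("threshold", "useTrueClass"), "gradcam")
  checkKeys(annotation, c("nRaters", "flipProbability", "minFraction",
                          "qualityFloor"), "annotation")
  cfg <- list(phantom = phantom, train = train,
              gradcam = list(threshold = gradcam$threshold %||% 0.9,
                             useTrueClass = gradcam$useTrueClass %||% FALSE),
              annotation = list(
                nRaters = annotation$nRaters %||% 3L,
                flipProbability = annotation$flipProbability %||% 0.15,
                minFraction = annotation$minFraction %||% 0.25,
                qualityFloor = annotation$qualityFloor %||% 0.3),
              seed = as.integer(seed), outDir = outDir)
  class(cfg) <- "RunConfig"
  cfg
}

#' Read a run configuration from YAML
#'
#' @param path YAML file with sections \code{phantom}, \code{train},
#'   \code{gradcam}, \code{annotation}, \code{seed}, \code{outDir}.
#' @return A validated \code{\link{runConfig}}.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  allowed <- c("phantom", "train", "gradcam", "annotation", "seed", "outDir")
  extra <- setdiff(names(y), allowed)
  if (length(extra))
    stop("unknown top-level key(s): ", paste(extra, collapse = ", "))
  runConfig(phantom = y$phantom %||% list(), train = y$train %||% list(),
            gradcam = y$gradcam %||% list(),
            annotation = y$annotation %||% list(),
            seed = y$seed %||% 1L,
            outDir = y$outDir %||% tempfile("run"))
}
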