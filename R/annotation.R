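#' Overlap rules for the deterministic annotation oracle
#'
#' The human criterion - does the activation region overlap a clinically
#' meaningful structure - needs a numeric proxy on phantoms with exact masks.
#' A region "overlaps" a mask when at least \code{minFraction} of the pixel
#' footprint of at least one region cell (cell footprint = imageSize/7
#' square) intersects that mask. Frames with quality below
#' \code{qualityFloor} are not interpretable regardless of overlap.
#'
#' @param minFraction Minimum per-cell overlap fraction in [0,1].
#' @param qualityFloor Interpretability floor on the frame quality score.
#' @return List of class \code{"OverlapRules"}.
#' @export
overlapRules <- function(minFraction = 0.25, qualityFloor = 0.3) {
  stopifnot(minFraction >= 0, minFraction <= 1,
            qualityFloor >= 0, qualityFloor <= 1)
  structure(list(minFraction = minFraction, qualityFloor = qualityFloor),
            class = "OverlapRules")
}

#' Deterministic oracle annotation of one activation region
#'
#' Labels the region by the fixed clinical-relevance precedence: a frame
#' below the quality floor, or an empty (degenerate) region, is
#' \code{not_interpretable}; otherwise a region overlapping the lymph-node or
#' vessel mask is \code{lymph_node_vessel}; otherwise one overlapping the
#' artifact mask is \code{artifact}; anything else (background speckle, wall,
#' parenchyma) is \code{other_structure}. Identical inputs always yield the
#' identical label.
#'
#' @param region An \code{\linkS4class{ActivationRegion}} from this frame's
#'   image.
#' @param frame The matching \code{\linkS4class{PhantomFrame}}.
#' @param rules An \code{\link{overlapRules}} list.
#' @return One of \code{annotationLabels()}.
#' @export
oracleLabel <- function(region, frame, rules = overlapRules()) {
  if (frame@quality < rules$qualityFloor) return("not_interpretable")
  if (region@degenerate || nrow(region@cells) == 0L)
    return("not_interpretable")
  S <- nrow(frame@image)
  overlaps <- function(mask) {
    for (i in seq_len(nrow(region@cells))) {
      fp <- cellFootprint(region@cells[i, 1], region@cells[i, 2], S)
      cellArea <- length(fp$rows) * length(fp$cols)
      if (sum(mask[fp$rows, fp$cols]) / cellArea >= rules$minFraction)
        return(TRUE)
    }
    FALSE
  }
  if (overlaps(frame@masks$lymph_node) || overlaps(frame@masks$vessel))
    return("lymph_node_vessel")
  if (overlaps(frame@masks$artifact)) return("artifact")
  "other_structure"
}

#' A simulated noisy rater
#'
#' With probability \code{1 - flipProbability} the rater reports the true
#' label; otherwise it draws from the confusion kernel row of the truth. The
#' default kernel is uniform over the three other labels.
#'
#' @param raterId Character id.
#' @param flipProbability Probability in [0,1] of not reporting the truth.
#' @param kernel 4 x 4 row-stochastic matrix over \code{annotationLabels()}
#'   (rows = truth); used only on flips.
#' @return List of class \code{"RaterModel"}.
#' @export
raterModel <- function(raterId, flipProbability = 0.15, kernel = NULL) {
  labs <- annotationLabels()
  if (is.null(kernel)) {
    kernel <- matrix(1 / 3, 4, 4, dimnames = list(labs, labs))
    diag(kernel) <- 0
  }
  stopifnot(flipProbability >= 0, flipProbability <= 1,
            all(dim(kernel) == c(4, 4)),
            all(abs(rowSums(kernel) - 1) < 1e-9 | rowSums(kernel) == 0))
  structure(list(raterId = raterId, flipProbability = flipProbability,
                 kernel = kernel), class = "RaterModel")
}

#' Simulate a rater's labels
#'
#' Vectorized over items; draws from the current RNG stream (seed with
#' \code{set.seed} or \code{\link{withSeed}}-style wrappers for
#' reproducibility).
#'
#' @param truth Character vector of true labels.
#' @param rater A \code{\link{raterModel}}.
#' @return Character vector of the rater's labels.
#' @export
simulateRater <- function(truth, rater) {
  labs <- annotationLabels()
  stopifnot(all(truth %in% labs))
  out <- truth
  flip <- stats::runif(length(truth)) < rater$flipProbability
  for (i in which(flip)) {
    out[i] <- sample(labs, 1L, prob = rater$kernel[truth[i], ])
  }
  out
}

#' Merge three raters' labels for one image set by the consensus rules
#'
#' Per image: all three labels equal gives \code{complete} agreement with
#' that label; exactly two equal gives \code{majority} with the shared label;
#' all distinct gives \code{disagreement} with the final label pending until
#' adjudication (the consensus-meeting stand-in supplied via
#' \code{\link{adjudicate}}).
#'
#' @param annotations Data frame with columns \code{image_id},
#'   \code{rater_id}, \code{label}; exactly 3 records per image from
#'   distinct raters.
#' @return Data frame with columns \code{image_id}, \code{final_label}
#'   (\code{NA} while pending) and \code{agreement_level}.
#' @export
#' @examples
#' ann <- data.frame(image_id = "i1", rater_id = c("r1", "r2", "r3"),
#'                   label = c("artifact", "artifact", "other_structure"))
#' consensus(ann)
consensus <- function(annotations) {
  stopifnot(all(c("image_id", "rater_id", "label") %in% names(annotations)))
  bad <- setdiff(unique(annotations$label), annotationLabels())
  if (length(bad)) stop("unknown label(s): ", paste(bad, collapse = ", "))
  out <- lapply(split(annotations, annotations$image_id), function(d) {
    if (nrow(d) != 3L)
      stop("image ", d$image_id[1], ": need exactly 3 annotations, got ",
           nrow(d))
    if (anyDuplicated(d$rater_id))
      stop("image ", d$image_id[1], ": duplicate rater id")
    tab <- sort(table(d$label), decreasing = TRUE)
    if (tab[1] == 3L) {
      data.frame(image_id = d$image_id[1], final_label = names(tab)[1],
                 agreement_level = "complete")
    } else if (tab[1] == 2L) {
      data.frame(image_id = d$image_id[1], final_label = names(tab)[1],
                 agreement_level = "majority")
    } else {
      data.frame(image_id = d$image_id[1], final_label = NA_character_,
                 agreement_level = "disagreement")
    }
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Resolve pending disagreement items with an adjudication table
#'
#' Mirrors the consensus meeting: items on which all three raters disagreed
#' receive their final label from the supplied mapping.
#'
#' @param consensusResult A \code{\link{consensus}} result.
#' @param adjudication Data frame with columns \code{image_id},
#'   \code{final_label}.
#' @return The consensus data frame with pending labels filled in.
#' @export
adjudicate <- function(consensusResult, adjudication) {
  stopifnot(all(c("image_id", "final_label") %in% names(adjudication)))
  pending <- is.na(consensusResult$final_label)
  m <- match(consensusResult$image_id[pending], adjudication$image_id)
  if (anyNA(m)) {
    miss <- consensusResult$image_id[pending][is.na(m)]
    stop("no adjudication for: ", paste(utils::head(miss, 5), collapse = ", "))
  }
  lab <- adjudication$final_label[m]
  bad <- setdiff(unique(lab), annotationLabels())
  if (length(bad)) stop("unknown adjudication label(s): ",
                        paste(bad, collapse = ", "))
  consensusResult$final_label[pending] <- lab
  consensusResult
}

#' Distribution of agreement levels
#'
#' Counts and percentages (one decimal, half-away-from-zero) of complete,
#' majority and disagreement items.
#'
#' @param consensusResult A \code{\link{consensus}} result (only the
#'   \code{agreement_level} column is used).
#' @return Data frame with columns \code{level}, \code{count},
#'   \code{percentage}.
#' @export
agreementDistribution <- function(consensusResult) {
  if (nrow(consensusResult) == 0L) stop("empty consensus collection")
  levels <- c("complete", "majority", "disagreement")
  counts <- vapply(levels, function(l)
    sum(consensusResult$agreement_level == l), integer(1))
  data.frame(level = levels, count = as.integer(counts),
             percentage = roundHalfUp(100 * counts / sum(counts), 1))
}
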