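#' Cohen's kappa for two raters
#'
#' Chance-corrected agreement \eqn{\kappa = (p_o - p_e) / (1 - p_e)} with the
#' chance term from the product of the raters' marginal proportions. The
#' kappa is computed on the fixed category space even when some categories
#' are unobserved (zero marginals contribute nothing to chance agreement),
#' keeping reports comparable across runs. If \eqn{p_e = 1} (both raters
#' constant on the same category) the statistic is 1 when observed agreement
#' is perfect and NaN-flagged (attribute \code{undefined}) otherwise.
#'
#' @param a,b Equal-length label vectors (length at least 2).
#' @param categories Fixed category set; defaults to the four annotation
#'   labels.
#' @return Kappa in [-1, 1] (possibly NaN with attribute \code{undefined}).
#' @export
#' @examples
#' cohenKappa(c("a", "a", "b", "b"), c("a", "b", "a", "b"),
#'            categories = c("a", "b"))
cohenKappa <- function(a, b, categories = annotationLabels()) {
  if (length(a) != length(b)) stop("label sequences differ in length")
  if (length(a) < 2L) stop("need at least 2 items")
  bad <- setdiff(unique(c(a, b)), categories)
  if (length(bad)) stop("unknown label(s): ", paste(bad, collapse = ", "))
  n <- length(a)
  po <- mean(a == b)
  pa <- table(factor(a, levels = categories)) / n
  pb <- table(factor(b, levels = categories)) / n
  pe <- sum(as.numeric(pa) * as.numeric(pb))
  if (abs(1 - pe) < 1e-12) {
    if (abs(po - 1) < 1e-12) return(1)
    k <- NaN
    attr(k, "undefined") <- TRUE
    return(k)
  }
  (po - pe) / (1 - pe)
}

#' Fleiss' kappa for multiple raters
#'
#' Standard construction on an items-by-categories vote-count matrix with a
#' constant number of raters per item: per-item agreement
#' \eqn{P_i = (\sum_j n_{ij}^2 - n) / (n(n-1))}, mean \eqn{\bar P}, chance
#' agreement \eqn{\bar P_e = \sum_j p_j^2} from the pooled category
#' proportions, and \eqn{\kappa = (\bar P - \bar P_e)/(1 - \bar P_e)}. When
#' every vote falls in a single category, \eqn{\bar P_e = 1} and the
#' statistic is NaN-flagged rather than divided by zero.
#'
#' @param counts Integer matrix, rows = items, columns = categories; every
#'   row must sum to the same number of raters (at least 2).
#' @return Kappa (possibly NaN with attribute \code{undefined}).
#' @export
#' @examples
#' fleissKappa(matrix(c(3, 0, 0, 3, 2, 1), ncol = 2, byrow = TRUE))
fleissKappa <- function(counts) {
  counts <- as.matrix(counts)
  rs <- rowSums(counts)
  if (length(unique(rs)) != 1L)
    stop("ragged vote table: rows must sum to a constant rater count")
  n <- rs[1]
  if (n < 2) stop("need at least 2 raters per item")
  N <- nrow(counts)
  Pi <- (rowSums(counts^2) - n) / (n * (n - 1))
  Pbar <- mean(Pi)
  pj <- colSums(counts) / (N * n)
  Pe <- sum(pj^2)
  if (abs(1 - Pe) < 1e-12) {
    k <- NaN
    attr(k, "undefined") <- TRUE
    return(k)
  }
  (Pbar - Pe) / (1 - Pe)
}

#' Landis-Koch interpretation band of a kappa value
#'
#' Bands: below 0 poor, 0-0.20 slight, 0.21-0.40 fair, 0.41-0.60 moderate,
#' 0.61-0.80 substantial, 0.81-1.00 almost perfect (band edges at the
#' conventional two-decimal cut points).
#'
#' @param kappa Numeric in [-1, 1].
#' @return Band label, e.g. \code{"moderate"}.
#' @export
#' @examples
#' interpretKappa(0.529)
interpretKappa <- function(kappa) {
  if (is.nan(kappa)) return("undefined")
  if (kappa < -1 - 1e-12 || kappa > 1 + 1e-12)
    stop("kappa must lie in [-1, 1]")
  if (kappa < 0) "poor"
  else if (kappa <= 0.20) "slight"
  else if (kappa <= 0.40) "fair"
  else if (kappa <= 0.60) "moderate"
  else if (kappa <= 0.80) "substantial"
  else "almost perfect"
}

#' Percent agreement across all raters
#'
#' Percentage of items on which every rater assigned the identical label,
#' reported to one decimal (half away from zero).
#'
#' @param labels Complete rectangular matrix or data frame, rows = items,
#'   columns = raters.
#' @return Percentage in [0, 100].
#' @export
#' @examples
#' percentAgreement(cbind(c("a", "a"), c("a", "b")))
percentAgreement <- function(labels) {
  labels <- as.matrix(labels)
  if (anyNA(labels)) stop("missing cells in the label table")
  if (ncol(labels) < 2L) stop("need at least 2 raters")
  allSame <- apply(labels, 1, function(r) all(r == r[1]))
  roundHalfUp(100 * mean(allSame), 1)
}

# Long annotation records -> items x raters wide label matrix.
annotationMatrix <- function(annotations) {
  stopifnot(all(c("image_id", "rater_id", "label") %in% names(annotations)))
  wide <- stats::reshape(
    annotations[c("image_id", "rater_id", "label")],
    idvar = "image_id", timevar = "rater_id", direction = "wide")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$image_id
  colnames(m) <- sub("^label\\.", "", colnames(m))
  if (anyNA(m)) stop("incomplete annotation table: every rater must label every image")
  m[, sort(colnames(m)), drop = FALSE]
}

# Wide label matrix -> items x categories vote counts.
voteCounts <- function(labels, categories = annotationLabels()) {
  t(apply(labels, 1, function(r) table(factor(r, levels = categories))))
}

#' Full inter-rater agreement report
#'
#' Computes percent agreement, Fleiss' kappa over all raters, pairwise
#' Cohen's kappas and interpretation bands from the independent
#' (pre-consensus) annotations, on the fixed four-category space. With two
#' raters both the Cohen and the Fleiss statistic are reported; they differ
#' by chance model and are not interchangeable.
#'
#' @param annotations Long data frame (\code{image_id}, \code{rater_id},
#'   \code{label}) with every rater labelling every image.
#' @param categories Fixed category set.
#' @return An \code{\linkS4class{AgreementReport}}.
#' @export
agreementReport <- function(annotations, categories = annotationLabels()) {
  m <- annotationMatrix(annotations)
  raters <- colnames(m)
  pairs <- utils::combn(raters, 2, simplify = FALSE)
  cohen <- vapply(pairs, function(p)
    as.numeric(cohenKappa(m[, p[1]], m[, p[2]], categories)), numeric(1))
  names(cohen) <- vapply(pairs, paste, "", collapse = "-")
  fl <- as.numeric(fleissKappa(voteCounts(m, categories)))
  interp <- c(fleiss = interpretKappa(fl),
              vapply(cohen, interpretKappa, ""))
  methods::new("AgreementReport",
               percentAgreement = percentAgreement(m),
               fleiss = fl, cohen = cohen, interpretations = interp,
               nItems = nrow(m), nRaters = length(raters),
               categories = categories)
}

#' Serialize an agreement report to JSON
#'
#' Kappas are written to three decimals and percentages to one, matching the
#' reporting precision used throughout.
#'
#' @param report An \code{\linkS4class{AgreementReport}}.
#' @param path JSON file path.
#' @export
writeAgreementReport <- function(report, path) {
  payload <- list(
    percent_agreement = roundHalfUp(report@percentAgreement, 1),
    fleiss = roundHalfUp(report@fleiss, 3),
    cohen = as.list(roundHalfUp(report@cohen, 3)),
    interpretations = as.list(report@interpretations),
    n_items = report@nItems, n_raters = report@nRaters)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
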