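#' Compute a Grad-CAM activation grid for one image
#'
#' Implements gradient-weighted class activation mapping against the model's
#' designated (last) convolutional layer: the softmax is removed and the
#' gradient of the pre-softmax score of the target class with respect to the
#' feature map is spatially averaged per channel to give channel weights; the
#' class activation map is the rectified (ReLU) weighted channel sum. Maps
#' whose native resolution is not 7 x 7 are bilinearly resampled to 7 x 7,
#' then the grid is divided by its maximum so the top cell is exactly 1.
#' When the rectified map is identically zero (all channel contributions
#' non-positive, e.g. a class score constant in the features) the grid is
#' returned all zero and flagged degenerate instead of being divided by zero.
#'
#' @param model A \code{\linkS4class{StationModel}}.
#' @param image Numeric matrix in [0,1].
#' @param targetClass Class index in 1..8 (or a station label); defaults to
#'   the predicted class.
#' @return An \code{\linkS4class{ActivationGrid}}.
#' @export
computeCAM <- function(model, image, targetClass = NULL) {
  feat <- featureMap(model, image)
  scores <- headScores(model@params, feat)
  if (is.null(targetClass)) {
    k <- which.max(scores)
  } else if (is.character(targetClass)) {
    k <- match(targetClass, model@classOrder)
    if (is.na(k)) stop("unknown station '", targetClass, "'")
  } else {
    k <- as.integer(targetClass)
    if (k < 1L || k > length(model@classOrder))
      stop("targetClass must lie in 1..", length(model@classOrder))
  }
  grad <- headFeatureGradient(model@params, dim(feat), k)
  alpha <- apply(grad, 3, mean) # spatially averaged channel weights
  cam <- matrix(0, dim(feat)[1], dim(feat)[2])
  for (ch in seq_len(dim(feat)[3])) cam <- cam + alpha[ch] * feat[, , ch]
  cam <- pmax(cam, 0)
  if (!all(dim(cam) == c(7L, 7L))) cam <- pmax(resizeMatrix(cam, 7L, 7L), 0)
  mx <- max(cam)
  if (mx <= 0) {
    methods::new("ActivationGrid", values = matrix(0, 7, 7),
                 degenerate = TRUE, targetClass = as.integer(k))
  } else {
    methods::new("ActivationGrid", values = cam / mx, degenerate = FALSE,
                 targetClass = as.integer(k))
  }
}

#' Extract the activation region from a grid
#'
#' The region is every grid cell with normalized value at or above the
#' threshold (inclusive, default 0.9), treated collectively as one region with
#' no connectivity requirement, plus the max-intensity cell (ties broken by
#' the smallest row-major index). Because a non-degenerate grid has maximum
#' exactly 1, its region is never empty at any threshold of at most 1. A
#' degenerate grid yields an empty, flagged region for the caller to route to
#' "not interpretable" handling.
#'
#' @param grid An \code{\linkS4class{ActivationGrid}}.
#' @param threshold Numeric in (0, 1].
#' @return An \code{\linkS4class{ActivationRegion}}.
#' @export
#' @examples
#' g <- methods::new("ActivationGrid", values = diag(7), degenerate = FALSE,
#'                   targetClass = 1L)
#' extractRegion(g, 0.9)
extractRegion <- function(grid, threshold = 0.9) {
  stopifnot(methods::is(grid, "ActivationGrid"),
            threshold > 0, threshold <= 1)
  if (grid@degenerate) {
    return(methods::new("ActivationRegion",
                        cells = matrix(integer(), 0, 2,
                                       dimnames = list(NULL, c("row", "col"))),
                        maxCell = c(NA_integer_, NA_integer_),
                        threshold = threshold, degenerate = TRUE))
  }
  v <- grid@values
  hit <- which(v >= threshold, arr.ind = TRUE)
  cells <- matrix(as.integer(hit), ncol = 2,
                  dimnames = list(NULL, c("row", "col")))
  rowMajor <- as.vector(t(v))
  i <- which.max(rowMajor) # first maximum in row-major order
  mc <- c((i - 1L) %/% 7L + 1L, (i - 1L) %% 7L + 1L)
  methods::new("ActivationRegion", cells = cells,
               maxCell = as.integer(mc), threshold = threshold,
               degenerate = FALSE)
}

#' Render the grid/region overlay on an image
#'
#' Produces an RGB array: the continuous (bilinearly upsampled) heat map as a
#' semi-transparent warm tint, thin grid lines of the 7 x 7 tiling, region
#' cells tinted green and the max-intensity cell tinted red.
#'
#' @param image Numeric matrix in [0,1].
#' @param region An \code{\linkS4class{ActivationRegion}}.
#' @param grid The matching \code{\linkS4class{ActivationGrid}}.
#' @param alpha Tint opacity in [0,1].
#' @return Numeric array \code{nrow x ncol x 3} in [0,1].
#' @export
renderOverlay <- function(image, region, grid, alpha = 0.35) {
  S <- nrow(image)
  out <- array(rep(image, 3), c(dim(image), 3))
  if (!grid@degenerate) {
    heat <- clamp01(resizeMatrix(grid@values, nrow(image), ncol(image)))
    out[, , 1] <- out[, , 1] * (1 - alpha * heat) + alpha * heat
    out[, , 3] <- out[, , 3] * (1 - alpha * heat)
  }
  tint <- function(rows, cols, channel) {
    for (ch in 1:3) {
      w <- if (ch == channel) alpha else 0
      out[rows, cols, ch] <<- out[rows, cols, ch] * (1 - alpha) + w
    }
  }
  if (nrow(region@cells) > 0) {
    for (i in seq_len(nrow(region@cells))) {
      fp <- cellFootprint(region@cells[i, 1], region@cells[i, 2], S)
      isMax <- !region@degenerate &&
        region@cells[i, 1] == region@maxCell[1] &&
        region@cells[i, 2] == region@maxCell[2]
      tint(fp$rows, fp$cols, if (isMax) 1L else 2L)
    }
  }
  lines <- unique(c(floor(S * (0:7) / 7), 1))
  lines <- pmin(pmax(lines, 1), S)
  out[lines, , ] <- 0.85
  out[, lines, ] <- 0.85
  clamp01(out)
}

#' Tally max-intensity cell positions into frequency maps
#'
#' Counts, per station and overall, how often the max-intensity square landed
#' in each of the 49 grid positions. Degenerate regions are excluded from the
#' maps and reported as a separate count, so each map's counts still sum to
#' the number of images it tallies.
#'
#' @param regions List of \code{\linkS4class{ActivationRegion}} objects.
#' @param stations Character vector of station labels, one per region.
#' @return List with \code{perStation} (named list of
#'   \code{\linkS4class{FrequencyMap}}), \code{overall} (a
#'   \code{FrequencyMap}), and \code{nDegenerate}.
#' @export
maxCellFrequency <- function(regions, stations) {
  if (length(regions) == 0L) stop("empty region collection")
  stopifnot(length(regions) == length(stations))
  keep <- !vapply(regions, regionDegenerate, logical(1))
  nDeg <- sum(!keep)
  regions <- regions[keep]
  stations <- stations[keep]
  if (length(regions) == 0L)
    stop("all regions are degenerate; nothing to tally")
  tally <- function(rs) {
    counts <- matrix(0L, 7, 7)
    for (r in rs) {
      mc <- r@maxCell
      counts[mc[1], mc[2]] <- counts[mc[1], mc[2]] + 1L
    }
    counts
  }
  perStation <- list()
  for (st in unique(stations)) {
    counts <- tally(regions[stations == st])
    perStation[[st]] <- methods::new("FrequencyMap", scope = st,
                                     counts = counts,
                                     nImages = sum(counts))
  }
  overall <- Reduce(`+`, lapply(perStation, mapCounts))
  list(perStation = perStation,
       overall = methods::new("FrequencyMap", scope = "overall",
                              counts = overall, nImages = sum(overall)),
       nDegenerate = nDeg)
}

#' Render frequency maps as heat-map panels
#'
#' One panel per station plus the overall panel; colour intensity is
#' proportional to count, zero counts render as the background colour. Rows
#' are displayed proximal (top) to distal, columns across the probe's
#' left-right axis. When \code{file} is given the panels are written as a PNG.
#'
#' @param freq A \code{\link{maxCellFrequency}} result.
#' @param file Optional PNG path.
#' @return Invisibly, the list of matrices rendered (one per panel).
#' @export
renderHeatmaps <- function(freq, file = NULL) {
  panels <- c(lapply(freq$perStation, mapCounts),
              list(overall = mapCounts(freq$overall)))
  draw <- function() {
    n <- length(panels)
    nc <- ceiling(sqrt(n))
    nr <- ceiling(n / nc)
    op <- graphics::par(mfrow = c(nr, nc), mar = c(1, 1, 2, 1))
    on.exit(graphics::par(op))
    pal <- grDevices::colorRampPalette(c("white", "darkred"))(64)
    for (nm in names(panels)) {
      m <- panels[[nm]]
      # flip rows so row 1 (proximal) is drawn at the top
      graphics::image(t(m[7:1, ]), col = pal, axes = FALSE,
                      zlim = c(0, max(1, max(m))), main = nm)
      graphics::box()
    }
  }
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 900)
    draw()
    grDevices::dev.off()
  } else if (interactive()) {
    draw()
  }
  invisible(panels)
}

#' Export/import activation grids and regions as JSON
#'
#' One record per image: the 49 grid values row-major, the region cells, the
#' max cell, the gradient target class and the degenerate flag.
#'
#' @param grids Named list of \code{\linkS4class{ActivationGrid}}s.
#' @param regions Named list of matching \code{\linkS4class{ActivationRegion}}s.
#' @param path JSON file path.
#' @return \code{writeRegions} returns \code{path} invisibly;
#'   \code{readRegions} returns a list with \code{grids} and \code{regions}.
#' @export
writeRegions <- function(grids, regions, path) {
  stopifnot(identical(names(grids), names(regions)))
  recs <- lapply(names(grids), function(id) {
    g <- grids[[id]]; r <- regions[[id]]
    list(image_id = id, target_class = g@targetClass,
         grid = as.numeric(t(g@values)),
         region_cells = unname(apply(r@cells, 1, as.list)),
         max_cell = if (r@degenerate) NULL else as.list(r@maxCell),
         threshold = r@threshold,
         degenerate = g@degenerate)
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname writeRegions
#' @export
readRegions <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  grids <- list(); regions <- list()
  for (rec in recs) {
    if (is.null(rec$image_id) || is.null(rec$grid) || length(rec$grid) != 49)
      stop("malformed region record (need image_id and 49 grid values)")
    v <- matrix(as.numeric(unlist(rec$grid)), 7, 7, byrow = TRUE)
    g <- methods::new("ActivationGrid", values = v,
                      degenerate = isTRUE(rec$degenerate),
                      targetClass = as.integer(rec$target_class))
    grids[[rec$image_id]] <- g
    cells <- if (length(rec$region_cells))
      do.call(rbind, lapply(rec$region_cells, function(x)
        as.integer(unlist(x)))) else matrix(integer(), 0, 2)
    colnames(cells) <- c("row", "col")
    regions[[rec$image_id]] <- methods::new(
      "ActivationRegion", cells = cells,
      maxCell = if (isTRUE(rec$degenerate)) c(NA_integer_, NA_integer_)
                else as.integer(unlist(rec$max_cell)),
      threshold = as.numeric(rec$threshold %||% 0.9),
      degenerate = isTRUE(rec$degenerate))
  }
  list(grids = grids, regions = regions)
}
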