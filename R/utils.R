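#' Run an expression with a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds the Mersenne-Twister generator with
#' \code{seed}, evaluates \code{expr}, and restores the previous state, so
#' package internals never perturb user-level randomness.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of \code{expr}.
#' @keywords internal
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

#' Derive a per-stage sub-seed from a global seed
#'
#' Deterministically maps a (seed, tag) pair to an integer below 2^31 so each
#' pipeline stage gets its own reproducible RNG stream and can be re-run in
#' isolation.
#'
#' @param seed Integer global seed.
#' @param tag Character stage tag, e.g. \code{"phantom"}.
#' @return A single integer in [1, 2^31 - 2].
#' @export
#' @examples
#' deriveSeed(1, "phantom")
deriveSeed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  m <- 2147483647 # 2^31 - 1, prime
  h <- 0
  for (ch in utf8ToInt(tag)) h <- (h * 131 + ch) %% m
  s <- (abs(as.numeric(seed)) %% m)
  as.integer(((s * 1000003 + h) %% (m - 1)) + 1)
}

# Round half away from zero (the convention the source tables use), to `digits`.
roundHalfUp <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

clamp01 <- function(x) {
  # index assignment keeps dim/dimnames (pmin/pmax with a leading scalar drops them)
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# matrix [row, col] (row 1 = top) <-> EBImage Image (x = column-first)
asEB <- function(m) EBImage::Image(t(m))
fromEB <- function(im) t(EBImage::imageData(im))

# Bilinear resize of a [0,1] matrix to w x h (rows x cols).
resizeMatrix <- function(m, nrowOut, ncolOut) {
  fromEB(EBImage::resize(asEB(m), w = ncolOut, h = nrowOut))
}

# Gaussian blur; sigma in pixels. sigma <= 0 is the identity.
blurMatrix <- function(m, sigma) {
  if (sigma <= 0) return(m)
  fromEB(EBImage::gblur(asEB(m), sigma = sigma))
}

# Rotation about the image centre, bilinear, zero fill, same shape.
rotateMatrix <- function(m, degrees) {
  if (degrees == 0) return(m)
  fromEB(EBImage::rotate(asEB(m), angle = degrees,
                         output.dim = c(ncol(m), nrow(m)), bg.col = 0))
}

# Pixel row/col ranges of grid cell (r, c) in an n x n image tiled 7 x 7.
cellFootprint <- function(r, c, imageSize, gridSize = 7L) {
  rows <- (floor(imageSize * (r - 1) / gridSize) + 1):floor(imageSize * r / gridSize)
  cols <- (floor(imageSize * (c - 1) / gridSize) + 1):floor(imageSize * c / gridSize)
  list(rows = rows, cols = cols)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
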