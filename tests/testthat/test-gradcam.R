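test_that("channel weights match central finite differences on a toy network", {
  # toy model: small random 3-conv-layer backbone; the gradient of the
  # pre-softmax class score w.r.t. the designated feature map is checked
  # against central finite differences of the head forward pass
  m <- untrainedModel(seed = 12, netInputSize = 56L, channels = c(3L, 4L, 5L))
  set.seed(13)
  img <- matrix(runif(56 * 56), 56, 56)
  feat <- featureMap(m, img)
  for (k in c(1L, 5L)) {
    grad <- SonoCAM:::headFeatureGradient(m@params, dim(feat), k)
    h <- 1e-5
    fd <- array(0, dim(feat))
    for (i in seq_along(feat)) {
      fp <- feat; fm <- feat
      fp[i] <- fp[i] + h
      fm[i] <- fm[i] - h
      fd[i] <- (SonoCAM:::headScores(m@params, fp)[k] -
                  SonoCAM:::headScores(m@params, fm)[k]) / (2 * h)
    }
    denom <- pmax(abs(fd), 1e-8)
    expect_lt(max(abs(grad - fd) / denom), 1e-4)
    # spatially averaged channel weights agree too
    expect_lt(max(abs(apply(grad, 3, mean) - apply(fd, 3, mean)) /
                    pmax(abs(apply(fd, 3, mean)), 1e-8)), 1e-4)
  }
})

test_that("a single-channel linear score reproduces the feature map as CAM", {
  # with one feature channel and unit head weight, score = mean(feature map),
  # so the CAM is the (rectified) feature map itself, normalized by its max
  m <- untrainedModel(seed = 14, channels = c(3L, 4L, 1L))
  m@params$Wfc <- matrix(0, 8, 1)
  m@params$Wfc[2, 1] <- 1
  m@params$bfc <- numeric(8)
  set.seed(15)
  img <- matrix(runif(56 * 56), 56, 56)
  feat <- featureMap(m, img)[, , 1]
  g <- computeCAM(m, img, targetClass = 2L)
  expect_false(isDegenerate(g))
  expect_equal(gridValues(g), pmax(feat, 0) / max(feat), tolerance = 1e-10)
})

test_that("a score constant in the features yields a degenerate grid", {
  m <- untrainedModel(seed = 16)
  m@params$Wfc[3, ] <- 0 # class 3 score does not depend on the features
  set.seed(17)
  img <- matrix(runif(56 * 56), 56, 56)
  g <- computeCAM(m, img, targetClass = 3L)
  expect_true(isDegenerate(g))
  expect_true(all(gridValues(g) == 0))
  r <- extractRegion(g)
  expect_true(regionDegenerate(r))
  expect_equal(nrow(regionCells(r)), 0L)
})

test_that("non-degenerate grids have max exactly 1 and a non-empty region at 0.9", {
  m <- untrainedModel(seed = 18)
  set.seed(19)
  for (i in 1:25) {
    img <- matrix(runif(64 * 64), 64, 64)
    g <- computeCAM(m, img)
    if (isDegenerate(g)) next
    expect_equal(max(gridValues(g)), 1.0)
    r <- extractRegion(g, 0.9)
    expect_gte(nrow(regionCells(r)), 1L)
  }
})

test_that("target class validation and default", {
  m <- untrainedModel(seed = 20)
  img <- matrix(0.5, 64, 64)
  expect_error(computeCAM(m, img, targetClass = 9L), "1..8")
  expect_error(computeCAM(m, img, targetClass = 0L), "1..8")
  expect_error(computeCAM(m, img, targetClass = "5R"), "unknown station")
  p <- predictProba(m, img)
  g <- computeCAM(m, img)
  expect_equal(targetClass(g), unname(which.max(p)))
})

test_that("region extraction matches an exhaustive 49-cell scan", {
  set.seed(21)
  for (i in 1:100) {
    g <- randomGrid()
    thr <- sample(c(0.5, 0.7, 0.9, 1.0), 1)
    r <- extractRegion(g, thr)
    v <- gridValues(g)
    # brute force: scan all 49 cells
    brute <- NULL
    bestVal <- -Inf; bestCell <- NULL
    for (row in 1:7) for (col in 1:7) {
      if (v[row, col] >= thr) brute <- rbind(brute, c(row, col))
      if (v[row, col] > bestVal) { bestVal <- v[row, col]; bestCell <- c(row, col) }
    }
    got <- regionCells(r)
    expect_equal(got[order(got[, 1], got[, 2]), , drop = FALSE],
                 brute[order(brute[, 1], brute[, 2]), , drop = FALSE],
                 ignore_attr = TRUE)
    expect_equal(unname(maxCell(r)), bestCell)
  }
})

test_that("max-cell ties break at the smallest row-major index", {
  v <- matrix(0.5, 7, 7)
  v[3, 2] <- 1; v[2, 5] <- 1 # row-major order visits (2,5) first
  r <- extractRegion(gridFrom(v))
  expect_equal(unname(maxCell(r)), c(2L, 5L))
  uni <- extractRegion(gridFrom(matrix(1, 7, 7)))
  expect_equal(nrow(regionCells(uni)), 49L)
  expect_equal(unname(maxCell(uni)), c(1L, 1L))
  one <- matrix(0.5, 7, 7); one[4, 6] <- 1
  r1 <- extractRegion(gridFrom(one))
  expect_equal(nrow(regionCells(r1)), 1L)
  expect_equal(unname(regionCells(r1)[1, ]), c(4L, 6L))
})

test_that("raising the threshold never enlarges the region", {
  set.seed(22)
  for (i in 1:50) {
    g <- randomGrid()
    sizes <- vapply(c(0.3, 0.5, 0.7, 0.9, 1.0), function(t)
      nrow(regionCells(extractRegion(g, t))), integer(1))
    expect_true(all(diff(sizes) <= 0))
  }
})

test_that("overlay rendering returns RGB with red max cell and green region", {
  set.seed(23)
  img <- matrix(runif(70 * 70), 70, 70)
  g <- randomGrid()
  r <- extractRegion(g, 0.9)
  out <- renderOverlay(img, r, g)
  expect_identical(dim(out), c(70L, 70L, 3L))
  expect_true(all(out >= 0 & out <= 1))
  mc <- maxCell(r)
  fp <- SonoCAM:::cellFootprint(mc[1], mc[2], 70)
  px <- out[fp$rows[2], fp$cols[2], ]
  expect_gt(px[1], px[2]) # max cell tinted red
  # degenerate region: overlay is the image plus grid lines only
  gd <- gridFrom(matrix(0, 7, 7), degenerate = TRUE)
  rd <- extractRegion(gd)
  outd <- renderOverlay(img, rd, gd)
  expect_identical(dim(outd), c(70L, 70L, 3L))
})

test_that("frequency maps tally max cells and conserve counts", {
  # fixed cells
  rs <- replicate(10, regionFrom(c(3, 3)), simplify = FALSE)
  fq <- maxCellFrequency(rs, rep("4L", 10))
  expect_equal(mapCounts(fq$perStation[["4L"]])[3, 3], 10L)
  expect_equal(sum(mapCounts(fq$perStation[["4L"]])), 10L)
  # 500 random regions against a brute-force tally, plus conservation
  set.seed(24)
  cells <- cbind(sample(1:7, 500, TRUE), sample(1:7, 500, TRUE))
  sts <- sample(stationLevels(), 500, TRUE)
  regions <- lapply(seq_len(500), function(i) regionFrom(cells[i, ]))
  fq <- maxCellFrequency(regions, sts)
  brute <- matrix(0L, 7, 7)
  for (i in 1:500) brute[cells[i, 1], cells[i, 2]] <-
    brute[cells[i, 1], cells[i, 2]] + 1L
  expect_equal(mapCounts(fq$overall), brute)
  expect_equal(mapImages(fq$overall),
               sum(vapply(fq$perStation, mapImages, integer(1))))
  expect_equal(Reduce(`+`, lapply(fq$perStation, mapCounts)),
               mapCounts(fq$overall))
  # permutation invariance
  perm <- sample(500)
  fq2 <- maxCellFrequency(regions[perm], sts[perm])
  expect_equal(mapCounts(fq2$overall), mapCounts(fq$overall))
  # degenerate regions are excluded but reported
  dg <- methods::new("ActivationRegion",
                     cells = matrix(integer(), 0, 2),
                     maxCell = c(NA_integer_, NA_integer_),
                     threshold = 0.9, degenerate = TRUE)
  fq3 <- maxCellFrequency(c(regions[1:5], list(dg)), c(sts[1:5], "4L"))
  expect_equal(fq3$nDegenerate, 1L)
  expect_equal(mapImages(fq3$overall), 5L)
  expect_error(maxCellFrequency(list(), character()), "empty")
})

test_that("heatmap rendering emits one panel per station plus overall", {
  set.seed(25)
  regions <- replicate(30, regionFrom(c(sample(7, 1), sample(7, 1))),
                       simplify = FALSE)
  sts <- rep(c("4L", "7R", "11L"), each = 10)
  fq <- maxCellFrequency(regions, sts)
  f <- tempfile(fileext = ".png")
  panels <- renderHeatmaps(fq, f)
  expect_length(panels, 4L) # 3 stations + overall
  expect_true(file.exists(f))
  single <- maxCellFrequency(regions[1:10], rep("4L", 10))
  p1 <- renderHeatmaps(single)
  expect_length(p1, 2L)
  expect_equal(p1[["4L"]], p1[["overall"]])
})

test_that("grids and regions round-trip through the JSON export", {
  set.seed(26)
  grids <- list(); regions <- list()
  for (id in c("a", "b", "c")) {
    g <- randomGrid()
    grids[[id]] <- g
    regions[[id]] <- extractRegion(g, 0.9)
  }
  grids[["d"]] <- gridFrom(matrix(0, 7, 7), degenerate = TRUE)
  regions[["d"]] <- extractRegion(grids[["d"]])
  path <- tempfile(fileext = ".json")
  writeRegions(grids, regions, path)
  back <- readRegions(path)
  for (id in names(grids)) {
    expect_equal(gridValues(back$grids[[id]]), gridValues(grids[[id]]),
                 tolerance = 1e-12)
    expect_equal(regionCells(back$regions[[id]]),
                 regionCells(regions[[id]]), ignore_attr = TRUE)
    expect_identical(regionDegenerate(back$regions[[id]]),
                     regionDegenerate(regions[[id]]))
  }
})
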