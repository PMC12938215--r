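# Shared fixtures, all built in code at test time.

# Tiny phantom config for fast frame-level tests.
tinyConfig <- function(nPatients = 4L, framesPerPatient = 8L, ...) {
  phantomConfig(imageSize = 64L, nPatients = nPatients,
                framesPerPatient = framesPerPatient, ...)
}

# A small untrained model (random weights) with the full 7x7 feature contract.
untrainedModel <- function(seed = 1, netInputSize = 56L,
                           channels = c(4L, 6L, 8L)) {
  plan <- SonoCAM:::nnPlan(netInputSize, channels, 8L)
  params <- SonoCAM:::nnInit(plan, seed = seed)
  methods::new("StationModel", params = params,
               arch = list(type = "small", netInputSize = netInputSize,
                           channels = channels, plan = plan),
               classOrder = stationLevels(), inputSize = netInputSize,
               featureDims = as.integer(plan$featureDims),
               selectedEpoch = 0L,
               history = data.frame(epoch = integer(), split = character(),
                                    loss = numeric(), accuracy = numeric(),
                                    precision = numeric(), recall = numeric()))
}

# Build an ActivationGrid directly from a 7x7 value matrix.
gridFrom <- function(values, degenerate = FALSE, target = 1L) {
  methods::new("ActivationGrid", values = values, degenerate = degenerate,
               targetClass = as.integer(target))
}

# Normalized random 7x7 grid (max exactly 1).
randomGrid <- function() {
  v <- matrix(stats::runif(49), 7, 7)
  gridFrom(v / max(v))
}

# Long annotation data frame from an items x raters label matrix.
annotationsFrom <- function(m) {
  raters <- paste0("r", seq_len(ncol(m)))
  out <- do.call(rbind, lapply(seq_len(ncol(m)), function(j)
    data.frame(image_id = sprintf("i%04d", seq_len(nrow(m))),
               rater_id = raters[j], label = m[, j],
               stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

# A PhantomFrame with hand-placed masks for annotation-oracle tests.
handFrame <- function(imageSize = 70L, quality = 1,
                      nodeCells = NULL, vesselCells = NULL,
                      artifactCells = NULL) {
  blank <- matrix(0, imageSize, imageSize)
  sector <- matrix(1, imageSize, imageSize)
  fill <- function(cells) {
    m <- blank
    if (!is.null(cells)) {
      for (i in seq_len(nrow(cells))) {
        fp <- SonoCAM:::cellFootprint(cells[i, 1], cells[i, 2], imageSize)
        m[fp$rows, fp$cols] <- 1
      }
    }
    m
  }
  methods::new("PhantomFrame", image = blank + 0.5,
               masks = list(lymph_node = fill(nodeCells),
                            vessel = fill(vesselCells),
                            artifact = fill(artifactCells),
                            other_structure = blank),
               sector = sector, station = "4L", patientId = "P01",
               quality = quality)
}

regionFrom <- function(cells, threshold = 0.9) {
  cells <- matrix(as.integer(cells), ncol = 2,
                  dimnames = list(NULL, c("row", "col")))
  methods::new("ActivationRegion", cells = cells,
               maxCell = cells[1, ], threshold = threshold,
               degenerate = FALSE)
}
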