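#' Training configuration for the station classifier
#'
#' Defaults follow the published training recipe for the full-scale model:
#' 100 epochs, batch size 32, AdamW, categorical cross-entropy, learning rate
#' 1e-4, early-stopping patience 20, dropout 0.5 on the pooled features, and
#' a 70/20/10 patient-wise split. The small trainable backbone resizes inputs
#' internally to \code{netInputSize} (must be divisible by 8) so its final
#' convolutional map is exactly 7 x 7 when \code{netInputSize = 56}.
#'
#' @param epochs Maximum training epochs.
#' @param batchSize Mini-batch size.
#' @param learningRate AdamW learning rate.
#' @param weightDecay Decoupled weight decay (applied to weights, not biases).
#' @param patience Early-stopping patience in epochs (must not exceed
#'   \code{epochs}).
#' @param dropoutRate Dropout rate on the pooled feature vector.
#' @param splitFractions Train/validation/test fractions (sum to 1).
#' @param nClasses Number of stations; fixed at 8.
#' @param inputSize Nominal dataset image side (images of any size are
#'   resized at entry).
#' @param netInputSize Side length the small backbone operates at.
#' @param channels Channel widths of the three convolution stages.
#' @param augment An \code{\link{augmentParams}} list.
#' @param lrSchedule \code{"constant"} or \code{"cosine"} (cosine decay of
#'   the learning rate to a tenth of its base value over \code{epochs}).
#' @param seed Integer seed covering initialisation, shuffling, augmentation
#'   and dropout.
#' @return Validated list of class \code{"TrainConfig"}.
#' @export
trainConfig <- function(epochs = 100L, batchSize = 32L, learningRate = 1e-4,
                        weightDecay = 1e-4, patience = 20L, dropoutRate = 0.5,
                        splitFractions = c(0.70, 0.20, 0.10), nClasses = 8L,
                        inputSize = 224L, netInputSize = 56L,
                        channels = c(8L, 16L, 32L),
                        augment = augmentParams(),
                        lrSchedule = c("constant", "cosine"), seed = 1L) {
  lrSchedule <- match.arg(lrSchedule)
  cfg <- list(epochs = as.integer(epochs), batchSize = as.integer(batchSize),
              learningRate = learningRate, weightDecay = weightDecay,
              patience = as.integer(patience), dropoutRate = dropoutRate,
              splitFractions = as.numeric(unlist(splitFractions)),
              nClasses = as.integer(nClasses),
              inputSize = as.integer(inputSize),
              netInputSize = as.integer(netInputSize),
              channels = as.integer(unlist(channels)), augment = augment,
              lrSchedule = lrSchedule, seed = as.integer(seed))
  if (abs(sum(cfg$splitFractions) - 1) > 1e-9)
    stop("splitFractions must sum to 1")
  if (cfg$patience > cfg$epochs) stop("patience must not exceed epochs")
  if (cfg$nClasses != 8L) stop("nClasses is fixed at 8")
  class(cfg) <- "TrainConfig"
  cfg
}

#' Augmentation parameters
#'
#' The five training-set augmentations - gamma transformation, Gaussian
#' blurring, rotation, contrast scaling, and a Gaussian shadow band - each
#' applied independently with its own probability. The magnitude defaults are
#' package choices (the published recipe names the transforms only) and are
#' fully overridable.
#'
#' @param pGamma,pBlur,pRotation,pContrast,pShadow Per-transform application
#'   probabilities.
#' @param gammaRange Exponent range for the gamma transform.
#' @param blurSigmaRange Gaussian blur sigma range, pixels.
#' @param rotationRange Rotation range, degrees.
#' @param contrastRange Contrast scale range about the image mean.
#' @param shadowDepthRange Peak attenuation of the shadow band.
#' @return List of class \code{"AugmentParams"}.
#' @export
augmentParams <- function(pGamma = 0.5, pBlur = 0.5, pRotation = 0.5,
                          pContrast = 0.5, pShadow = 0.5,
                          gammaRange = c(0.7, 1.5),
                          blurSigmaRange = c(0, 1.5),
                          rotationRange = c(-15, 15),
                          contrastRange = c(0.8, 1.2),
                          shadowDepthRange = c(0.3, 0.7)) {
  p <- list(pGamma = pGamma, pBlur = pBlur, pRotation = pRotation,
            pContrast = pContrast, pShadow = pShadow,
            gammaRange = gammaRange, blurSigmaRange = blurSigmaRange,
            rotationRange = rotationRange, contrastRange = contrastRange,
            shadowDepthRange = shadowDepthRange)
  for (nm in c("pGamma", "pBlur", "pRotation", "pContrast", "pShadow"))
    if (p[[nm]] < 0 || p[[nm]] > 1) stop(nm, " must lie in [0,1]")
  class(p) <- "AugmentParams"
  p
}

#' Apply stochastic training augmentations to one image
#'
#' Draws from the current RNG stream (seed it with \code{set.seed} or let
#' \code{\link{trainModel}} manage it). Each transform is applied with its
#' configured probability; identity parameter values (gamma 1, sigma 0,
#' rotation 0, scale 1, depth 0) are skipped exactly, so degenerate
#' parameters reproduce the input bit for bit. Output is clamped to [0,1]
#' and keeps the input shape.
#'
#' @param image Numeric matrix with values in [0,1].
#' @param params An \code{\link{augmentParams}} list.
#' @return Augmented matrix, same shape, values in [0,1].
#' @export
augmentImage <- function(image, params = augmentParams()) {
  stopifnot(is.matrix(image))
  out <- image
  if (stats::runif(1) < params$pGamma) {
    g <- stats::runif(1, params$gammaRange[1], params$gammaRange[2])
    if (g != 1) out <- out^g
  }
  if (stats::runif(1) < params$pBlur) {
    s <- stats::runif(1, params$blurSigmaRange[1], params$blurSigmaRange[2])
    if (s > 0) out <- blurMatrix(out, s)
  }
  if (stats::runif(1) < params$pRotation) {
    a <- stats::runif(1, params$rotationRange[1], params$rotationRange[2])
    if (a != 0) out <- rotateMatrix(out, a)
  }
  if (stats::runif(1) < params$pContrast) {
    s <- stats::runif(1, params$contrastRange[1], params$contrastRange[2])
    if (s != 1) {
      m <- mean(out)
      out <- m + s * (out - m)
    }
  }
  if (stats::runif(1) < params$pShadow) {
    d <- stats::runif(1, params$shadowDepthRange[1], params$shadowDepthRange[2])
    c0 <- stats::runif(1, 1, ncol(out))
    sw <- stats::runif(1, 0.10, 0.25) * ncol(out)
    if (d > 0) {
      prof <- 1 - d * exp(-((seq_len(ncol(out)) - c0)^2) / (2 * sw^2))
      out <- sweep(out, 2, prof, "*")
    }
  }
  clamp01(out)
}

#' Patient-wise train/validation/test split
#'
#' Shuffles patients with the given seed, then allots whole patients to the
#' three partitions by largest remainder on patient counts (ties broken in
#' train, validation, test order), so no patient ever contributes frames to
#' more than one partition. Every partition with a non-zero fraction receives
#' at least one patient, so small cohorts still yield a usable test set.
#'
#' @param manifest Dataset manifest data frame (needs \code{image} and
#'   \code{patient_id} columns).
#' @param fractions Length-3 fractions summing to 1.
#' @param seed Integer shuffle seed.
#' @return List with frame-id vectors \code{train}, \code{validation},
#'   \code{test} and the per-partition \code{patients} map.
#' @export
#' @examples
#' ds <- generateDataset(phantomConfig(imageSize = 64, nPatients = 5,
#'                                     framesPerPatient = 8))
#' sp <- splitPatientwise(ds$manifest, seed = 1)
#' lengths(sp$patients)
splitPatientwise <- function(manifest, fractions = c(0.70, 0.20, 0.10),
                             seed = 1L) {
  stopifnot(length(fractions) == 3L, abs(sum(fractions) - 1) < 1e-9)
  patients <- unique(manifest$patient_id)
  nNonEmpty <- sum(fractions > 0)
  if (length(patients) < nNonEmpty)
    stop("fewer patients (", length(patients), ") than non-empty partitions (",
         nNonEmpty, ")")
  shuffled <- withSeed(seed, sample(patients))
  n <- length(patients)
  quota <- n * fractions
  counts <- floor(quota)
  rem <- quota - counts
  short <- n - sum(counts)
  if (short > 0) {
    take <- order(-rem, seq_along(rem))[seq_len(short)]
    counts[take] <- counts[take] + 1
  }
  # every partition with a non-zero fraction gets at least one patient
  for (k in which(fractions > 0 & counts == 0)) {
    donor <- which.max(counts)
    counts[donor] <- counts[donor] - 1
    counts[k] <- counts[k] + 1
  }
  bounds <- cumsum(counts)
  pt <- list(train = shuffled[seq_len(counts[1])],
             validation = if (counts[2] > 0)
               shuffled[(bounds[1] + 1):bounds[2]] else character(),
             test = if (counts[3] > 0)
               shuffled[(bounds[2] + 1):bounds[3]] else character())
  ids <- sub("\\.png$", "", manifest$image)
  out <- lapply(pt, function(p) ids[manifest$patient_id %in% p])
  out$patients <- pt
  out
}

#' Early-stopping checkpoint selection
#'
#' Given a sequence of per-epoch validation losses, reports the epoch whose
#' checkpoint would be kept (minimum validation loss, ties broken by earliest
#' epoch) and the epoch at which training halts (the first epoch lying
#' \code{patience} epochs past the best so far, or the final epoch).
#'
#' @param valLosses Numeric vector of validation losses, one per epoch.
#' @param patience Patience in epochs.
#' @return List with \code{selectedEpoch} and \code{stopEpoch}.
#' @export
#' @examples
#' checkpointSelection(c(1, 0.5, 0.3, rep(0.4, 25)), patience = 20)
checkpointSelection <- function(valLosses, patience) {
  best <- Inf
  bestEpoch <- 0L
  stopEpoch <- length(valLosses)
  for (e in seq_along(valLosses)) {
    if (valLosses[e] < best) {
      best <- valLosses[e]
      bestEpoch <- e
    }
    if (e - bestEpoch >= patience) {
      stopEpoch <- e
      break
    }
  }
  list(selectedEpoch = bestEpoch, stopEpoch = stopEpoch)
}

# Resize to the network input and min-max normalize (constant images pass
# through unchanged; min-max stretch is the small backbone's normalization).
preprocessImage <- function(image, netInputSize) {
  if (!all(dim(image) == netInputSize))
    image <- resizeMatrix(image, netInputSize, netInputSize)
  rg <- range(image)
  if (rg[2] > rg[1]) image <- (image - rg[1]) / (rg[2] - rg[1])
  image
}

# Stack a list of matrices into the (npix x B) activation layout.
stackImages <- function(images, netInputSize) {
  vapply(images, function(m) as.numeric(preprocessImage(m, netInputSize)),
         numeric(netInputSize^2))
}

evalSplit <- function(plan, params, X, yIdx, batchSize = 256L) {
  n <- ncol(X)
  loss <- 0; correct <- 0
  for (s in seq(1, n, by = batchSize)) {
    e <- min(s + batchSize - 1, n)
    fw <- nnForward(plan, params, X[, s:e, drop = FALSE])
    p <- fw$probs[cbind(yIdx[s:e], seq_len(e - s + 1))]
    loss <- loss + sum(-log(pmax(p, 1e-12)))
    correct <- correct + sum(apply(fw$probs, 2, which.max) == yIdx[s:e])
  }
  c(loss = loss / n, accuracy = correct / n)
}

#' Train the eight-station classifier
#'
#' Trains on the frames of the training partition with on-the-fly
#' augmentation, monitors loss/accuracy/precision/recall on train and
#' validation each epoch, applies early stopping, and returns the checkpoint
#' from the epoch with minimum validation loss (ties broken by earliest).
#' Precision and recall in the history are micro-averaged, which for
#' single-label multi-class prediction coincides with accuracy.
#'
#' The default backbone (\code{"small"}) is a compact trainable CNN whose
#' final convolutional map is 7 x 7, preserving the grid semantics of the
#' published full-scale model. Alternatively, \code{backbone} may be a list
#' \code{list(extract = function(image) featureArray, dims = c(r, c, ch))}
#' describing a frozen feature extractor (the transfer-learning path); then
#' only the pooled-dropout-softmax head is trained.
#'
#' @param frames Named list of \code{\linkS4class{PhantomFrame}} objects (or
#'   lists with \code{image} and \code{station}), names matching the split's
#'   frame ids.
#' @param split A \code{\link{splitPatientwise}} result.
#' @param config A \code{\link{trainConfig}}.
#' @param backbone \code{"small"} or a frozen-extractor list (see Details).
#' @return A \code{\linkS4class{StationModel}}.
#' @export
trainModel <- function(frames, split, config = trainConfig(),
                       backbone = "small") {
  getImage <- function(f) if (methods::is(f, "PhantomFrame")) f@image else f$image
  getStation <- function(f)
    if (methods::is(f, "PhantomFrame")) f@station else f$station
  if (length(split$train) == 0L) stop("empty training partition")
  missing <- setdiff(c(split$train, split$validation), names(frames))
  if (length(missing))
    stop("frames missing for ids: ", paste(utils::head(missing, 5), collapse = ", "))

  classes <- stationLevels()
  custom <- is.list(backbone)
  if (!custom && !identical(backbone, "small"))
    stop("backbone must be \"small\" or a list(extract=, dims=)")

  trainIds <- split$train
  valIds <- split$validation
  yTrain <- match(vapply(frames[trainIds], getStation, ""), classes)
  yVal <- match(vapply(frames[valIds], getStation, ""), classes)

  if (custom) {
    return(trainHeadOnly(frames, trainIds, valIds, yTrain, yVal, config,
                         backbone, classes, getImage))
  }

  plan <- nnPlan(config$netInputSize, config$channels, config$nClasses)
  trainImgs <- lapply(frames[trainIds], getImage)
  Xval <- stackImages(lapply(frames[valIds], getImage), config$netInputSize)

  withSeed(deriveSeed(config$seed, "train"), {
    params <- nnInit(plan, seed = stats::runif(1, 1, 2^30))
    state <- adamwInit(params)
    hist <- list()
    best <- Inf; bestEpoch <- 0L; bestParams <- params
    for (epoch in seq_len(config$epochs)) {
      lrNow <- if (config$lrSchedule == "cosine")
        config$learningRate * (0.55 + 0.45 * cos(pi * (epoch - 1) /
                                                   max(1, config$epochs - 1)))
      else config$learningRate
      ord <- sample(length(trainIds))
      epLoss <- 0; epCorrect <- 0
      for (s in seq(1, length(ord), by = config$batchSize)) {
        e <- min(s + config$batchSize - 1, length(ord))
        bIdx <- ord[s:e]
        imgs <- lapply(trainImgs[bIdx], augmentImage, params = config$augment)
        X <- stackImages(imgs, config$netInputSize)
        fw <- nnForward(plan, params, X, dropoutRate = config$dropoutRate,
                        training = TRUE)
        yB <- yTrain[bIdx]
        p <- fw$probs[cbind(yB, seq_along(yB))]
        epLoss <- epLoss + sum(-log(pmax(p, 1e-12)))
        epCorrect <- epCorrect + sum(apply(fw$probs, 2, which.max) == yB)
        grads <- nnBackward(plan, params, fw, yB)
        upd <- adamwStep(params, grads, state, lr = lrNow,
                         weightDecay = config$weightDecay)
        params <- upd$params
        state <- upd$state
      }
      trLoss <- epLoss / length(trainIds)
      trAcc <- epCorrect / length(trainIds)
      vm <- evalSplit(plan, params, Xval, yVal)
      hist[[length(hist) + 1]] <- data.frame(
        epoch = epoch, split = c("train", "validation"),
        loss = c(trLoss, vm["loss"]), accuracy = c(trAcc, vm["accuracy"]),
        precision = c(trAcc, vm["accuracy"]),
        recall = c(trAcc, vm["accuracy"]))
      if (vm["loss"] < best) {
        best <- vm["loss"]
        bestEpoch <- epoch
        bestParams <- params
      }
      if (epoch - bestEpoch >= config$patience) break
    }
    history <- do.call(rbind, hist)
    rownames(history) <- NULL
    methods::new("StationModel", params = bestParams,
                 arch = list(type = "small", netInputSize = config$netInputSize,
                             channels = config$channels, plan = plan),
                 classOrder = classes,
                 inputSize = config$netInputSize,
                 featureDims = as.integer(plan$featureDims),
                 selectedEpoch = as.integer(bestEpoch), history = history)
  })
}

# Head-only training over a frozen feature extractor.
trainHeadOnly <- function(frames, trainIds, valIds, yTrain, yVal, config,
                          backbone, classes, getImage) {
  dims <- as.integer(backbone$dims)
  nf <- dims[1] * dims[2]
  gap <- function(id) {
    f <- backbone$extract(getImage(frames[[id]]))
    apply(array(f, c(nf, dims[3])), 2, mean)
  }
  Gtr <- vapply(trainIds, gap, numeric(dims[3]))
  Gval <- vapply(valIds, gap, numeric(dims[3]))
  withSeed(deriveSeed(config$seed, "train"), {
    params <- list(
      Wfc = matrix(stats::rnorm(8 * dims[3], 0, sqrt(1 / dims[3])), 8, dims[3]),
      bfc = numeric(8))
    state <- adamwInit(params)
    hist <- list()
    best <- Inf; bestEpoch <- 0L; bestParams <- params
    headEval <- function(G, y) {
      S <- params$Wfc %*% G + params$bfc
      E <- exp(sweep(S, 2, apply(S, 2, max), "-"))
      pr <- sweep(E, 2, colSums(E), "/")
      c(loss = mean(-log(pmax(pr[cbind(y, seq_along(y))], 1e-12))),
        accuracy = mean(apply(pr, 2, which.max) == y))
    }
    for (epoch in seq_len(config$epochs)) {
      ord <- sample(length(trainIds))
      for (s in seq(1, length(ord), by = config$batchSize)) {
        e <- min(s + config$batchSize - 1, length(ord))
        b <- ord[s:e]
        G <- Gtr[, b, drop = FALSE]
        keep <- 1 - config$dropoutRate
        M <- matrix(stats::rbinom(length(G), 1, keep), nrow(G)) / keep
        Gd <- G * M
        S <- params$Wfc %*% Gd + params$bfc
        E <- exp(sweep(S, 2, apply(S, 2, max), "-"))
        pr <- sweep(E, 2, colSums(E), "/")
        dS <- pr
        dS[cbind(yTrain[b], seq_along(b))] <-
          dS[cbind(yTrain[b], seq_along(b))] - 1
        dS <- dS / length(b)
        grads <- list(Wfc = dS %*% t(Gd), bfc = rowSums(dS))
        upd <- adamwStep(params, grads, state, lr = config$learningRate,
                         weightDecay = config$weightDecay)
        params <- upd$params
        state <- upd$state
      }
      tm <- headEval(Gtr, yTrain)
      vm <- headEval(Gval, yVal)
      hist[[length(hist) + 1]] <- data.frame(
        epoch = epoch, split = c("train", "validation"),
        loss = c(tm["loss"], vm["loss"]),
        accuracy = c(tm["accuracy"], vm["accuracy"]),
        precision = c(tm["accuracy"], vm["accuracy"]),
        recall = c(tm["accuracy"], vm["accuracy"]))
      if (vm["loss"] < best) {
        best <- vm["loss"]; bestEpoch <- epoch; bestParams <- params
      }
      if (epoch - bestEpoch >= config$patience) break
    }
    history <- do.call(rbind, hist)
    rownames(history) <- NULL
    methods::new("StationModel", params = bestParams,
                 arch = list(type = "custom", dims = dims,
                             extract = backbone$extract),
                 classOrder = classes, inputSize = dims[1] * 8L,
                 featureDims = dims, selectedEpoch = as.integer(bestEpoch),
                 history = history)
  })
}

#' Feature map of the designated convolutional layer
#'
#' Runs the backbone forward and returns the post-ReLU spatial feature map
#' Grad-CAM differentiates against.
#'
#' @param model A \code{\linkS4class{StationModel}}.
#' @param image Numeric matrix in [0,1].
#' @return Array of dimension \code{model@featureDims}.
#' @export
featureMap <- function(model, image) {
  if (model@arch$type == "custom") {
    f <- model@arch$extract(image)
    return(array(f, model@featureDims))
  }
  plan <- model@arch$plan
  x <- preprocessImage(image, model@arch$netInputSize)
  fw <- nnForward(plan, model@params, matrix(as.numeric(x), ncol = 1))
  array(fw$features, model@featureDims)
}

#' Class probabilities for one image
#'
#' Resizes/normalizes the image to the model's input contract and returns the
#' softmax probability vector over the eight stations in fixed class order;
#' the argmax is the predicted station. Inference is deterministic (dropout
#' inactive).
#'
#' @param model A \code{\linkS4class{StationModel}}.
#' @param image Numeric matrix.
#' @return Named numeric vector of length 8 summing to 1.
#' @export
predictProba <- function(model, image) {
  if (!is.matrix(image) || !is.numeric(image))
    stop("image must be a numeric matrix")
  feat <- featureMap(model, image)
  s <- headScores(model@params, feat)
  e <- exp(s - max(s))
  p <- e / sum(e)
  names(p) <- model@classOrder
  p
}

#' Save / load a trained model
#'
#' \code{saveModel} writes the model as a single JSON checkpoint plus a small
#' JSON sidecar (\code{<path>.meta.json}) with class order, input size,
#' designated feature layer and selected epoch; \code{loadModel} restores it.
#' Models with a custom (frozen) extractor cannot be serialized because the
#' extractor is a live function.
#'
#' @param model A \code{\linkS4class{StationModel}}.
#' @param path Checkpoint file path.
#' @return \code{loadModel} returns a \code{\linkS4class{StationModel}};
#'   \code{saveModel} returns \code{path} invisibly.
#' @export
saveModel <- function(model, path) {
  if (model@arch$type != "small")
    stop("only models with the built-in small backbone can be serialized")
  payload <- list(
    params = lapply(model@params, function(p)
      list(dim = dim(p) %||% length(p), data = as.numeric(p))),
    arch = list(type = "small", netInputSize = model@arch$netInputSize,
                channels = model@arch$channels),
    classOrder = model@classOrder, inputSize = model@inputSize,
    featureDims = model@featureDims, selectedEpoch = model@selectedEpoch,
    history = model@history)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  meta <- list(class_order = model@classOrder,
               input_size = model@inputSize,
               feature_layer = sprintf("conv3 (%dx%dx%d)",
                                       model@featureDims[1],
                                       model@featureDims[2],
                                       model@featureDims[3]),
               selected_epoch = model@selectedEpoch)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- lapply(payload$params, function(p) {
    if (length(p$dim) == 2L) matrix(p$data, p$dim[1], p$dim[2])
    else as.numeric(p$data)
  })
  plan <- nnPlan(payload$arch$netInputSize, payload$arch$channels, 8L)
  methods::new("StationModel", params = params,
               arch = list(type = "small",
                           netInputSize = as.integer(payload$arch$netInputSize),
                           channels = as.integer(payload$arch$channels),
                           plan = plan),
               classOrder = payload$classOrder,
               inputSize = as.integer(payload$inputSize),
               featureDims = as.integer(payload$featureDims),
               selectedEpoch = as.integer(payload$selectedEpoch),
               history = as.data.frame(payload$history))
}

#' Write the training history as CSV
#'
#' @param model A \code{\linkS4class{StationModel}}.
#' @param path CSV path; columns \code{epoch,split,loss,accuracy,precision,recall}.
#' @export
writeHistory <- function(model, path) {
  utils::write.csv(model@history, path, row.names = FALSE)
  invisible(path)
}

#' Desk-scale training configuration
#'
#' The training recipe for small phantom benchmarks: 20 epochs, batch size 4
#' (many optimizer steps per epoch on a few hundred images), learning rate
#' 2e-3 for the from-scratch small backbone, channel widths (16, 32, 64),
#' the published dropout rate of 0.5, and mild augmentation (each transform
#' with probability 0.3, rotation within 10 degrees, shadow depth 0.2-0.4).
#' The default \code{\link{trainConfig}} keeps the published full-scale
#' hyperparameters instead.
#'
#' @param epochs Training epochs (default 20; patience is set equal, so all
#'   epochs run unless validation loss stalls).
#' @param seed Integer seed.
#' @return A \code{\link{trainConfig}}.
#' @export
deskTrainConfig <- function(epochs = 20L, seed = 1L) {
  trainConfig(
    epochs = epochs, patience = epochs, batchSize = 4L, learningRate = 2e-3,
    channels = c(16L, 32L, 64L), dropoutRate = 0.5,
    augment = augmentParams(pGamma = 0.3, pBlur = 0.3, pRotation = 0.3,
                            pContrast = 0.3, pShadow = 0.3,
                            rotationRange = c(-10, 10),
                            shadowDepthRange = c(0.2, 0.4)),
    seed = seed)
}
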