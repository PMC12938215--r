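# Small trainable convolutional backbone, implemented directly in R.
#
# Three 3x3 same-padded convolution + ReLU + 2x2 max-pool stages reduce a
# 56 x 56 single-channel input to a 7 x 7 spatial feature map (the designated
# Grad-CAM layer), followed by global average pooling, dropout and a fully
# connected softmax head over the eight stations. Convolutions are computed
# as im2col gathers followed by BLAS matrix products, so training stays fast
# on one CPU without compiled code.
#
# Layout conventions (all column-major):
#   activations  X : (h*w*channels) x batch, pixel index fastest
#   patch matrix P : (npix*batch) x (9*cin), row = pixel + (b-1)*npix
#   conv weights W : (9*cin) x cout, column order (dr, dc, channel)

# im2col gather indices for a 3x3 same-padded convolution on h x w x cin.
# Entries index the input flattened as (pixel, channel), with h*w*cin + 1
# addressing an appended zero "pad" row; the map is injective per column.
makeIm2col <- function(h, w, cin) {
  npix <- h * w
  pad <- npix * cin + 1L
  rs <- rep(seq_len(h), w)
  cs <- rep(seq_len(w), each = h)
  base <- matrix(0L, npix, 9L)
  k <- 0L
  for (dc in -1:1) for (dr in -1:1) {
    k <- k + 1L
    sr <- rs + dr; sc <- cs + dc
    ok <- sr >= 1 & sr <= h & sc >= 1 & sc <= w
    base[, k] <- ifelse(ok, (sc - 1L) * h + sr, NA_integer_)
  }
  idx <- matrix(0L, npix, 9L * cin)
  for (ch in seq_len(cin)) {
    cols <- (ch - 1L) * 9L + seq_len(9L)
    shifted <- base + (ch - 1L) * npix
    shifted[is.na(base)] <- pad
    idx[, cols] <- shifted
  }
  idx
}

# Architecture plan: layer dims and gather indices for a given input size.
nnPlan <- function(inputSize = 56L, channels = c(8L, 16L, 32L), nClasses = 8L) {
  if (inputSize %% 8L != 0L)
    stop("inputSize must be divisible by 8 (three 2x2 pooling stages)")
  sizes <- c(inputSize, inputSize / 2L, inputSize / 4L)
  cins <- c(1L, channels[1], channels[2])
  layers <- vector("list", 3L)
  for (l in 1:3) {
    layers[[l]] <- list(h = sizes[l], w = sizes[l], cin = cins[l],
                        cout = channels[l],
                        idx = makeIm2col(sizes[l], sizes[l], cins[l]))
  }
  list(inputSize = as.integer(inputSize), channels = as.integer(channels),
       nClasses = as.integer(nClasses), layers = layers,
       featureDims = c(inputSize / 8L, inputSize / 8L, channels[3]))
}

# He-initialised parameters.
nnInit <- function(plan, seed = 1L) {
  withSeed(seed, {
    params <- list()
    for (l in 1:3) {
      ly <- plan$layers[[l]]
      fanIn <- 9L * ly$cin
      params[[paste0("W", l)]] <-
        matrix(stats::rnorm(fanIn * ly$cout, 0, sqrt(2 / fanIn)), fanIn, ly$cout)
      params[[paste0("b", l)]] <- numeric(ly$cout)
    }
    cTop <- plan$channels[3]
    params$Wfc <- matrix(stats::rnorm(plan$nClasses * cTop, 0, sqrt(1 / cTop)),
                         plan$nClasses, cTop)
    params$bfc <- numeric(plan$nClasses)
    params
  })
}

# Gather the patch matrix for one conv layer.
gatherPatches <- function(X, idx, npix, B) {
  Xpad <- rbind(X, 0)
  P <- matrix(0, npix * B, ncol(idx))
  for (k in seq_len(ncol(idx))) P[, k] <- Xpad[idx[, k], ]
  P
}

# (npix*B) x cout  ->  (npix*cout) x B
oToX <- function(O, npix, B, cout) {
  dim(O) <- c(npix, B, cout)
  O <- aperm(O, c(1, 3, 2))
  dim(O) <- c(npix * cout, B)
  O
}

# (npix*cout) x B  ->  (npix*B) x cout
xToO <- function(X, npix, B, cout) {
  dim(X) <- c(npix, cout, B)
  X <- aperm(X, c(1, 3, 2))
  dim(X) <- c(npix * B, cout)
  X
}

# 2x2 max pool on (h*w*c) x B; returns pooled X and argmax masks.
poolForward <- function(X, h, w, cc, B) {
  arr <- array(X, c(h, w, cc, B))
  i1 <- seq(1, h, 2); i2 <- seq(2, h, 2)
  j1 <- seq(1, w, 2); j2 <- seq(2, w, 2)
  s1 <- arr[i1, j1, , , drop = FALSE]; s2 <- arr[i2, j1, , , drop = FALSE]
  s3 <- arr[i1, j2, , , drop = FALSE]; s4 <- arr[i2, j2, , , drop = FALSE]
  m <- pmax(s1, s2, s3, s4)
  w1 <- s1 == m
  w2 <- (s2 == m) & !w1
  w3 <- (s3 == m) & !(w1 | w2)
  w4 <- (s4 == m) & !(w1 | w2 | w3)
  out <- m
  dim(out) <- c((h / 2) * (w / 2) * cc, B)
  list(out = out, masks = list(w1, w2, w3, w4))
}

poolBackward <- function(dOut, masks, h, w, cc, B) {
  dm <- array(dOut, c(h / 2, w / 2, cc, B))
  darr <- array(0, c(h, w, cc, B))
  i1 <- seq(1, h, 2); i2 <- seq(2, h, 2)
  j1 <- seq(1, w, 2); j2 <- seq(2, w, 2)
  darr[i1, j1, , ] <- dm * masks[[1]]
  darr[i2, j1, , ] <- darr[i2, j1, , , drop = FALSE] + dm * masks[[2]]
  darr[i1, j2, , ] <- darr[i1, j2, , , drop = FALSE] + dm * masks[[3]]
  darr[i2, j2, , ] <- darr[i2, j2, , , drop = FALSE] + dm * masks[[4]]
  dim(darr) <- c(h * w * cc, B)
  darr
}

# Full forward pass. X: (inputSize^2) x B. Returns probabilities, pre-softmax
# scores, the post-ReLU feature map of the designated layer, and caches.
nnForward <- function(plan, params, X, dropoutRate = 0, training = FALSE) {
  B <- ncol(X)
  caches <- vector("list", 3L)
  for (l in 1:3) {
    ly <- plan$layers[[l]]
    npix <- ly$h * ly$w
    P <- gatherPatches(X, ly$idx, npix, B)
    Z <- P %*% params[[paste0("W", l)]]
    Z <- sweep(Z, 2, params[[paste0("b", l)]], "+")
    A <- pmax(Z, 0)
    Xa <- oToX(A, npix, B, ly$cout)
    pf <- poolForward(Xa, ly$h, ly$w, ly$cout, B)
    caches[[l]] <- list(P = P, reluMask = Z > 0, poolMasks = pf$masks)
    X <- pf$out
  }
  fd <- plan$featureDims
  nf <- fd[1] * fd[2]
  feat <- X # (nf * channels) x B, post-ReLU, post-pool
  Garr <- array(feat, c(nf, fd[3], B))
  G <- colMeans(Garr) # fd[3] x B
  if (B == 1L) G <- matrix(G, ncol = 1L)
  if (training && dropoutRate > 0) {
    keep <- 1 - dropoutRate
    M <- matrix(stats::rbinom(length(G), 1L, keep), nrow(G), ncol(G)) / keep
  } else {
    M <- matrix(1, nrow(G), ncol(G))
  }
  Gd <- G * M
  S <- params$Wfc %*% Gd + params$bfc # nClasses x B
  Smax <- apply(S, 2, max)
  E <- exp(sweep(S, 2, Smax, "-"))
  probs <- sweep(E, 2, colSums(E), "/")
  list(probs = probs, scores = S, features = feat, G = G,
       caches = caches, dropMask = M, B = B)
}

# Backward pass for mean cross-entropy over the batch.
nnBackward <- function(plan, params, fwd, yIdx) {
  B <- fwd$B
  fd <- plan$featureDims
  nf <- fd[1] * fd[2]
  dS <- fwd$probs
  dS[cbind(yIdx, seq_len(B))] <- dS[cbind(yIdx, seq_len(B))] - 1
  dS <- dS / B
  grads <- list()
  Gd <- fwd$G * fwd$dropMask
  grads$Wfc <- dS %*% t(Gd)
  grads$bfc <- rowSums(dS)
  dG <- (t(params$Wfc) %*% dS) * fwd$dropMask # fd[3] x B
  dX <- matrix(rep(as.vector(dG) / nf, each = nf), nf * fd[3], B)
  for (l in 3:1) {
    ly <- plan$layers[[l]]
    npix <- ly$h * ly$w
    cache <- caches <- fwd$caches[[l]]
    dXa <- poolBackward(dX, cache$poolMasks, ly$h, ly$w, ly$cout, B)
    dA <- xToO(dXa, npix, B, ly$cout)
    dZ <- dA * cache$reluMask
    grads[[paste0("W", l)]] <- t(cache$P) %*% dZ
    grads[[paste0("b", l)]] <- colSums(dZ)
    if (l > 1L) {
      dP <- dZ %*% t(params[[paste0("W", l)]])
      nIn <- ly$h * ly$w * ly$cin
      dXpad <- matrix(0, nIn + 1L, B)
      for (k in seq_len(ncol(ly$idx))) {
        rows <- ly$idx[, k]
        dXpad[rows, ] <- dXpad[rows, ] + matrix(dP[, k], npix, B)
      }
      dX <- dXpad[seq_len(nIn), , drop = FALSE]
    }
  }
  grads
}

adamwInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

# AdamW: Adam moments with decoupled weight decay (decay not applied to biases).
adamwStep <- function(params, grads, state, lr, weightDecay = 1e-4,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    upd <- mhat / (sqrt(vhat) + eps)
    if (grepl("^W", nm)) upd <- upd + weightDecay * params[[nm]]
    params[[nm]] <- params[[nm]] - lr * upd
  }
  list(params = params, state = state)
}

# Forward of the classification head alone: features -> pre-softmax scores.
# `features` is an (rows x cols x channels) array of the designated layer.
headScores <- function(params, features) {
  fd <- dim(features)
  G <- apply(features, 3, mean)
  as.numeric(params$Wfc %*% G + params$bfc)
}

# Backpropagated gradient of one pre-softmax class score with respect to the
# designated feature map: d score_k / d F = Wfc[k, ch] / (rows * cols),
# obtained by running the head's linear operations in reverse.
headFeatureGradient <- function(params, featureDims, targetClass) {
  e <- numeric(nrow(params$Wfc)); e[targetClass] <- 1
  dG <- as.numeric(t(params$Wfc) %*% e)
  nf <- featureDims[1] * featureDims[2]
  array(rep(dG / nf, each = nf), dim = featureDims)
}
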