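# Neural-network building blocks: dense / batch-norm / ReLU / residual
# blocks / row L2 normalization, with hand-written forward and backward
# passes in base R matrix arithmetic. Networks are lists of layer objects;
# gradients mirror the layer structure so the optimizer can walk both in
# parallel.

denseLayer <- function(inDim, outDim) {
  bound <- 1 / sqrt(inDim)
  list(type = "dense",
       W = matrix(rnorm(inDim * outDim, sd = sqrt(2 / inDim)), inDim, outDim),
       b = runif(outDim, -bound, bound))
}

bnLayer <- function(dim, momentum = 0.1, eps = 1e-5) {
  list(type = "bn", gamma = rep(1, dim), beta = numeric(dim),
       runMean = numeric(dim), runVar = rep(1, dim),
       momentum = momentum, eps = eps)
}

reluLayer <- function() list(type = "relu")
l2normLayer <- function() list(type = "l2norm")

resblockLayer <- function(dim) {
  list(type = "resblock",
       sub = list(denseLayer(dim, dim), bnLayer(dim), reluLayer(),
                  denseLayer(dim, dim), bnLayer(dim)))
}

layerForward <- function(layer, X, train) {
  switch(layer$type,
    dense = list(out = sweep(X %*% layer$W, 2, layer$b, "+"),
                 cache = list(X = X), layer = layer),
    bn = {
      if (train) {
        mu <- colMeans(X)
        va <- colMeans(sweep(X, 2, mu, "-")^2)
        layer$runMean <- (1 - layer$momentum) * layer$runMean + layer$momentum * mu
        layer$runVar <- (1 - layer$momentum) * layer$runVar + layer$momentum * va
      } else {
        mu <- layer$runMean; va <- layer$runVar
      }
      invstd <- 1 / sqrt(va + layer$eps)
      xhat <- sweep(sweep(X, 2, mu, "-"), 2, invstd, "*")
      list(out = sweep(sweep(xhat, 2, layer$gamma, "*"), 2, layer$beta, "+"),
           cache = list(xhat = xhat, invstd = invstd, train = train),
           layer = layer)
    },
    relu = list(out = pmax(X, 0), cache = list(mask = X > 0), layer = layer),
    l2norm = {
      r <- pmax(sqrt(rowSums(X^2)), 1e-12)
      Y <- X / r
      list(out = Y, cache = list(Y = Y, r = r), layer = layer)
    },
    resblock = {
      h <- X; caches <- vector("list", length(layer$sub))
      for (k in seq_along(layer$sub)) {
        fw <- layerForward(layer$sub[[k]], h, train)
        h <- fw$out; caches[[k]] <- fw$cache; layer$sub[[k]] <- fw$layer
      }
      out <- pmax(X + h, 0)
      list(out = out, cache = list(caches = caches, mask = (X + h) > 0),
           layer = layer)
    },
    stop("unknown layer type: ", layer$type))
}

layerBackward <- function(layer, cache, G) {
  switch(layer$type,
    dense = list(gIn = G %*% t(layer$W),
                 grads = list(W = crossprod(cache$X, G), b = colSums(G))),
    bn = {
      if (!isTRUE(cache$train)) {
        gIn <- sweep(G, 2, layer$gamma * cache$invstd, "*")
        return(list(gIn = gIn,
                    grads = list(gamma = colSums(G * cache$xhat),
                                 beta = colSums(G))))
      }
      N <- nrow(G)
      gGamma <- colSums(G * cache$xhat)
      gBeta <- colSums(G)
      Gx <- sweep(G, 2, layer$gamma, "*")
      gIn <- sweep(Gx - matrix(colMeans(Gx), N, ncol(G), byrow = TRUE) -
                     cache$xhat * matrix(colMeans(Gx * cache$xhat), N,
                                         ncol(G), byrow = TRUE),
                   2, cache$invstd, "*")
      list(gIn = gIn, grads = list(gamma = gGamma, beta = gBeta))
    },
    relu = list(gIn = G * cache$mask, grads = list()),
    l2norm = {
      gIn <- (G - cache$Y * rowSums(G * cache$Y)) / cache$r
      list(gIn = gIn, grads = list())
    },
    resblock = {
      Gm <- G * cache$mask
      h <- Gm
      grads <- vector("list", length(layer$sub))
      for (k in rev(seq_along(layer$sub))) {
        bw <- layerBackward(layer$sub[[k]], cache$caches[[k]], h)
        grads[[k]] <- bw$grads; h <- bw$gIn
      }
      list(gIn = Gm + h, grads = list(sub = grads))
    },
    stop("unknown layer type: ", layer$type))
}

netForward <- function(net, X, train = FALSE) {
  caches <- vector("list", length(net$layers))
  penultimate <- NULL
  h <- X
  for (k in seq_along(net$layers)) {
    if (identical(k, net$penultimateAfter + 1L)) penultimate <- h
    fw <- layerForward(net$layers[[k]], h, train)
    h <- fw$out; caches[[k]] <- fw$cache; net$layers[[k]] <- fw$layer
  }
  list(out = h, caches = caches, penultimate = penultimate, net = net)
}

netBackward <- function(net, caches, G) {
  grads <- vector("list", length(net$layers))
  h <- G
  for (k in rev(seq_along(net$layers))) {
    bw <- layerBackward(net$layers[[k]], caches[[k]], h)
    grads[[k]] <- bw$grads; h <- bw$gIn
  }
  list(grads = grads, gIn = h)
}

# --- parameter walking -----------------------------------------------------

layerParamNames <- function(layer) {
  switch(layer$type, dense = c("W", "b"), bn = c("gamma", "beta"),
         resblock = "sub", character(0))
}

# f(value, gradValue, stateValue, name) applied at each numeric parameter;
# returns updated (layers, state) pair
walkParams <- function(layers, grads, state, f) {
  for (k in seq_along(layers)) {
    layer <- layers[[k]]
    for (nm in layerParamNames(layer)) {
      if (nm == "sub") {
        res <- walkParams(layer$sub, grads[[k]]$sub, state[[k]]$sub, f)
        layer$sub <- res$layers
        state[[k]]$sub <- res$state
      } else {
        res <- f(layer[[nm]], grads[[k]][[nm]], state[[k]][[nm]], nm)
        layer[[nm]] <- res$value
        state[[k]][[nm]] <- res$state
      }
    }
    layers[[k]] <- layer
  }
  list(layers = layers, state = state)
}

zeroStateLike <- function(layers) {
  lapply(layers, function(layer) {
    st <- list()
    for (nm in layerParamNames(layer)) {
      st[[nm]] <- if (nm == "sub") list(sub = zeroStateLike(layer$sub))$sub
      else list(m = 0 * layer[[nm]], v = 0 * layer[[nm]])
    }
    st
  })
}

netParamCount <- function(net) {
  count <- function(layers) sum(vapply(layers, function(layer) {
    s <- 0
    for (nm in layerParamNames(layer))
      s <- s + if (nm == "sub") count(layer$sub) else length(layer[[nm]])
    s
  }, numeric(1)))
  count(net$layers)
}

# --- encoders --------------------------------------------------------------

#' Encoder configuration
#'
#' Shared-space contract: both encoders project to the same `embedDim` and
#' end in an explicit row-normalization layer, so all outputs are unit-norm.
#'
#' @param embedDim embedding dimension d (default 512; the desk-scale
#'   studies in this package use 64).
#' @param imageChannels expected input channels (default 5).
#' @param imageHidden width of the image encoder trunk.
#' @param imageBlocks number of residual blocks in the image encoder.
#' @param structureHidden hidden widths of the structure encoder (default
#'   four layers of 1024 units).
#' @param batchNorm use batch normalization (default TRUE).
#' @return list of class `encoderConfig`.
#' @export
encoderConfig <- function(embedDim = 512L, imageChannels = 5L,
                          imageHidden = 256L, imageBlocks = 2L,
                          structureHidden = c(1024L, 1024L, 1024L, 1024L),
                          batchNorm = TRUE) {
  stopifnot(embedDim > 0, all(structureHidden > 0), imageHidden > 0)
  structure(list(embedDim = as.integer(embedDim),
                 imageChannels = as.integer(imageChannels),
                 imageHidden = as.integer(imageHidden),
                 imageBlocks = as.integer(imageBlocks),
                 structureHidden = as.integer(structureHidden),
                 batchNorm = isTRUE(batchNorm)),
            class = "encoderConfig")
}

#' Create a randomly initialized image encoder
#'
#' A residual multilayer perceptron on flattened channels-first pixels: an
#' input projection, `imageBlocks` residual blocks (dense + batch norm +
#' ReLU, identity skip), a linear projection to `embedDim` and explicit L2
#' row normalization. The activation entering the final projection is
#' exposed as the penultimate feature vector for linear probing.
#'
#' @param channels,height,width input image geometry.
#' @param config an [encoderConfig()].
#' @param seed integer seed for weight initialization.
#' @return encoder object (list with class `phenomolEncoder`).
#' @export
newImageEncoder <- function(channels, height, width,
                            config = encoderConfig(), seed = 1L) {
  old <- globalRNGState(); on.exit(restoreRNGState(old), add = TRUE)
  set.seed(seed)
  if (channels != config$imageChannels)
    stop(sprintf("channel mismatch: input has %d, config expects %d",
                 channels, config$imageChannels))
  inDim <- channels * height * width
  h <- config$imageHidden
  layers <- list(denseLayer(inDim, h))
  if (config$batchNorm) layers <- c(layers, list(bnLayer(h)))
  layers <- c(layers, list(reluLayer()))
  for (i in seq_len(config$imageBlocks))
    layers <- c(layers, list(resblockLayer(h)))
  nTrunk <- length(layers)
  layers <- c(layers, list(denseLayer(h, config$embedDim), l2normLayer()))
  structure(list(kind = "image", layers = layers,
                 penultimateAfter = nTrunk,
                 channels = channels, height = height, width = width,
                 inputDim = inDim, embedDim = config$embedDim,
                 config = config),
            class = "phenomolEncoder")
}

#' Create a randomly initialized structure encoder
#'
#' A fully-connected network on binary fingerprints: hidden layers of
#' `structureHidden` units with ReLU activations and batch normalization,
#' then a linear projection to `embedDim` and L2 row normalization.
#'
#' @param inputBits fingerprint length the encoder accepts.
#' @inheritParams newImageEncoder
#' @return encoder object (list with class `phenomolEncoder`).
#' @export
newStructureEncoder <- function(inputBits, config = encoderConfig(),
                                seed = 2L) {
  old <- globalRNGState(); on.exit(restoreRNGState(old), add = TRUE)
  set.seed(seed)
  widths <- config$structureHidden
  layers <- list()
  prev <- inputBits
  for (w in widths) {
    layers <- c(layers, list(denseLayer(prev, w)))
    if (config$batchNorm) layers <- c(layers, list(bnLayer(w)))
    layers <- c(layers, list(reluLayer()))
    prev <- w
  }
  nTrunk <- length(layers)
  layers <- c(layers, list(denseLayer(prev, config$embedDim), l2normLayer()))
  structure(list(kind = "structure", layers = layers,
                 penultimateAfter = nTrunk,
                 inputDim = as.integer(inputBits), embedDim = config$embedDim,
                 config = config),
            class = "phenomolEncoder")
}

#' @export
print.phenomolEncoder <- function(x, ...) {
  cat(sprintf("%s encoder: %d -> %d, %d parameters\n", x$kind,
              x$inputDim, x$embedDim, netParamCount(x)))
  invisible(x)
}

flattenPixels <- function(pixels) {
  d <- dim(pixels)
  stopifnot(length(d) == 4L)
  out <- matrix(pixels, nrow = d[1L])  # column-major over (C,H,W)
  out
}

#' Encode images into the shared embedding space
#'
#' In eval mode (`train = FALSE`, the default) the encoder is a pure
#' function of its input and weights: batch normalization uses running
#' statistics and repeated calls give identical output.
#'
#' @param encoder an image encoder from [newImageEncoder()].
#' @param pixels N x C x H x W array (real-valued, already preprocessed),
#'   a [BioimageSet-class], or an N x (C*H*W) matrix.
#' @param ids row identifiers; defaults to `image_id` for a `BioimageSet`.
#' @return [EmbeddingMatrix-class] with unit-norm rows and an attribute
#'   `"penultimate"` holding the pre-projection feature matrix.
#' @export
imageEncode <- function(encoder, pixels, ids = NULL) {
  stopifnot(inherits(encoder, "phenomolEncoder"), encoder$kind == "image")
  if (is(pixels, "BioimageSet")) {
    if (is.null(ids)) ids <- imageMeta(pixels)$image_id
    pixels <- pixelData(pixels)
  }
  X <- if (is.matrix(pixels)) pixels else {
    d <- dim(pixels)
    if (d[2L] != encoder$channels)
      stop(sprintf("channel mismatch: input has %d channels, encoder expects %d",
                   d[2L], encoder$channels))
    flattenPixels(pixels)
  }
  if (ncol(X) != encoder$inputDim)
    stop(sprintf("input dimension %d does not match encoder input %d",
                 ncol(X), encoder$inputDim))
  fw <- netForward(encoder, X, train = FALSE)
  emb <- embeddingMatrix(fw$out, ids = ids %||% as.character(seq_len(nrow(X))),
                         normalize = FALSE)
  emb@normalized <- TRUE
  validObject(emb)
  attr(emb, "penultimate") <- fw$penultimate
  emb
}

#' Encode fingerprints into the shared embedding space
#'
#' @param encoder a structure encoder from [newStructureEncoder()].
#' @param fps N x bits binary matrix (rownames used as ids when `ids` is
#'   NULL) or a [MoleculeSet-class].
#' @param ids row identifiers.
#' @return [EmbeddingMatrix-class] with unit-norm rows and a
#'   `"penultimate"` attribute.
#' @export
structureEncode <- function(encoder, fps, ids = NULL) {
  stopifnot(inherits(encoder, "phenomolEncoder"), encoder$kind == "structure")
  if (is(fps, "MoleculeSet")) {
    if (is.null(ids)) ids <- moleculeMeta(fps)$molecule_id
    fps <- fingerprints(fps)
  }
  fps <- as.matrix(fps)
  if (ncol(fps) != encoder$inputDim)
    stop(sprintf("fingerprint length %d does not match encoder input %d",
                 ncol(fps), encoder$inputDim))
  fw <- netForward(encoder, fps, train = FALSE)
  emb <- embeddingMatrix(fw$out,
                         ids = ids %||% rownames(fps) %||%
                           as.character(seq_len(nrow(fps))),
                         normalize = FALSE)
  emb@normalized <- TRUE
  validObject(emb)
  attr(emb, "penultimate") <- fw$penultimate
  emb
}

`%||%` <- function(a, b) if (is.null(a)) b else a
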