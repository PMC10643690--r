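#' Specification of a synthetic paired image/fingerprint dataset
#'
#' Parameters of the synthetic-data generator. Each molecule carries a latent
#' vector; its binary fingerprint is a thresholded random projection of the
#' latent and each of its image views renders a noisy copy of the latent as
#' per-channel Gaussian blobs (centre, amplitude and width affine in latent
#' coordinates). `noiseSd` is the mutual-information knob between the two
#' modalities: at `noiseSd = 0` views of a molecule are identical, and as
#' `noiseSd` grows cross-modal decoding degrades to chance.
#'
#' @slot nMolecules number of molecules.
#' @slot viewsPerMolecule image views generated per molecule.
#' @slot latentDim dimension of the shared latent vector.
#' @slot channels image channels (5 in the Cell-Painting-style protocol).
#' @slot height,width image size in pixels.
#' @slot fpBits fingerprint length in bits (must be a multiple of 8).
#' @slot noiseSd standard deviation of the per-view latent jitter (latent
#'   coordinates have unit variance, so 0.3 means 30% view noise).
#' @slot nPlates number of assay plates, assigned round-robin.
#' @slot nMoaClasses number of mechanism-of-action-style latent clusters.
#' @slot seed integer seed governing all randomness of the generator.
#' @seealso [syntheticSpec()], [generatePairedDataset()]
#' @export
setClass("SyntheticSpec", representation(
  nMolecules = "integer", viewsPerMolecule = "integer",
  latentDim = "integer", channels = "integer",
  height = "integer", width = "integer",
  fpBits = "integer", noiseSd = "numeric",
  nPlates = "integer", nMoaClasses = "integer", seed = "integer"))

setValidity("SyntheticSpec", function(object) {
  msg <- character()
  if (object@nMolecules < 1L) msg <- c(msg, "nMolecules must be >= 1")
  if (object@viewsPerMolecule < 1L) msg <- c(msg, "viewsPerMolecule must be >= 1")
  if (object@latentDim < 1L) msg <- c(msg, "latentDim must be >= 1")
  if (object@fpBits < object@latentDim) msg <- c(msg, "fpBits must be >= latentDim")
  if (object@fpBits %% 8L != 0L) msg <- c(msg, "fpBits must be a multiple of 8")
  if (object@nMoaClasses > object@nMolecules)
    msg <- c(msg, "nMoaClasses must be <= nMolecules")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be non-negative")
  if (object@channels < 1L || object@height < 1L || object@width < 1L)
    msg <- c(msg, "channels, height and width must be >= 1")
  if (object@nPlates < 1L) msg <- c(msg, "nPlates must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Create a synthetic dataset specification
#'
#' Defaults are the desk-scale study conditions used throughout the package:
#' 500 molecules with 4 views each (2,000 pairs), a 16-dimensional latent,
#' 5-channel 16x16 views, 256-bit fingerprints and pixel noise 0.3.
#'
#' @param nMolecules,viewsPerMolecule,latentDim,channels,height,width,fpBits
#'   see [SyntheticSpec-class].
#' @param noiseSd,nPlates,nMoaClasses,seed see [SyntheticSpec-class].
#' @return A validated [SyntheticSpec-class] object.
#' @examples
#' syntheticSpec(nMolecules = 10, viewsPerMolecule = 2, seed = 7)
#' @export
syntheticSpec <- function(nMolecules = 500L, viewsPerMolecule = 4L,
                          latentDim = 16L, channels = 5L,
                          height = 16L, width = 16L, fpBits = 256L,
                          noiseSd = 0.3, nPlates = 6L, nMoaClasses = 20L,
                          seed = 1L) {
  new("SyntheticSpec",
      nMolecules = as.integer(nMolecules),
      viewsPerMolecule = as.integer(viewsPerMolecule),
      latentDim = as.integer(latentDim), channels = as.integer(channels),
      height = as.integer(height), width = as.integer(width),
      fpBits = as.integer(fpBits), noiseSd = as.numeric(noiseSd),
      nPlates = as.integer(nPlates),
      nMoaClasses = as.integer(min(as.integer(nMoaClasses), as.integer(nMolecules))),
      seed = as.integer(seed))
}

#' A set of multi-channel microscopy image views
#'
#' Pixel data for N views stored channels-first as an N x C x H x W array,
#' together with per-view metadata (plate, well, view index, molecule).
#'
#' @slot pixels numeric array, N x C x H x W (channels-first).
#' @slot bitDepth 8 or 16; pixel values must lie within the declared depth.
#' @slot meta data.frame with columns `image_id`, `plate_id`, `well_id`,
#'   `view_index`, `molecule_id`, one row per view.
#' @export
setClass("BioimageSet", representation(
  pixels = "array", bitDepth = "integer", meta = "data.frame"))

setValidity("BioimageSet", function(object) {
  msg <- character()
  d <- dim(object@pixels)
  if (length(d) != 4L) msg <- c(msg, "pixels must be an N x C x H x W array")
  if (!object@bitDepth %in% c(8L, 16L)) msg <- c(msg, "bitDepth must be 8 or 16")
  need <- c("image_id", "plate_id", "well_id", "view_index", "molecule_id")
  if (!all(need %in% names(object@meta)))
    msg <- c(msg, paste("meta must contain:", paste(need, collapse = ", ")))
  if (length(d) == 4L && nrow(object@meta) != d[1L])
    msg <- c(msg, "meta rows must match first pixel dimension")
  if (length(d) == 4L && d[2L] < 1L) msg <- c(msg, "at least one channel required")
  mx <- suppressWarnings(max(object@pixels))
  if (is.finite(mx) && mx > 2^object@bitDepth - 1 + 1e-8)
    msg <- c(msg, "pixel values exceed declared bit depth")
  if (is.finite(mx) && min(object@pixels) < 0) msg <- c(msg, "negative pixel values")
  if (length(msg)) msg else TRUE
})

#' A set of molecules with fingerprints
#'
#' @slot meta data.frame with columns `molecule_id`, `smiles`, and optionally
#'   `moa`, `scaffold_key`.
#' @slot fingerprints binary matrix (molecules x bits), \{0,1\}-valued, with
#'   rownames equal to `molecule_id`.
#' @export
setClass("MoleculeSet", representation(
  meta = "data.frame", fingerprints = "matrix"))

setValidity("MoleculeSet", function(object) {
  msg <- character()
  if (!all(c("molecule_id", "smiles") %in% names(object@meta)))
    msg <- c(msg, "meta must contain molecule_id and smiles")
  if (nrow(object@fingerprints) != nrow(object@meta))
    msg <- c(msg, "fingerprint rows must match meta rows")
  if (length(object@fingerprints) &&
      !all(object@fingerprints %in% c(0, 1)))
    msg <- c(msg, "fingerprints must be 0/1-valued")
  if (length(msg)) msg else TRUE
})

#' Unit-norm embedding matrix aligned with record identifiers
#'
#' N x d real matrix of embeddings with one id per row. When `normalized` is
#' `TRUE` every row has Euclidean norm 1 (within 1e-6), the contract assumed
#' by the contrastive objectives and all similarity-based evaluations.
#'
#' @slot ids character vector of record identifiers (length N).
#' @slot vectors N x d numeric matrix.
#' @slot normalized logical flag; when TRUE row norms are validated.
#' @seealso [embeddingMatrix()], [similarityMatrix()]
#' @export
setClass("EmbeddingMatrix", representation(
  ids = "character", vectors = "matrix", normalized = "logical"))

setValidity("EmbeddingMatrix", function(object) {
  msg <- character()
  if (length(object@ids) != nrow(object@vectors))
    msg <- c(msg, "ids must match number of rows")
  if (anyDuplicated(object@ids)) msg <- c(msg, "ids must be unique")
  if (isTRUE(object@normalized) && nrow(object@vectors)) {
    nrm <- sqrt(rowSums(object@vectors^2))
    if (any(abs(nrm - 1) > 1e-6))
      msg <- c(msg, "normalized=TRUE but some row norms differ from 1 by > 1e-6")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an EmbeddingMatrix
#'
#' @param vectors N x d numeric matrix.
#' @param ids row identifiers; defaults to rownames of `vectors`.
#' @param normalize if TRUE (default) rows are rescaled to unit norm first.
#' @return An [EmbeddingMatrix-class].
#' @export
embeddingMatrix <- function(vectors, ids = rownames(vectors), normalize = TRUE) {
  vectors <- as.matrix(vectors)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(vectors)))
  if (normalize && nrow(vectors)) vectors <- l2Normalize(vectors)
  rownames(vectors) <- ids
  new("EmbeddingMatrix", ids = as.character(ids), vectors = vectors,
      normalized = normalize)
}

#' Stored-pattern memory of a continuous modern Hopfield network
#'
#' Row-aligned stored image embeddings `U` and structure embeddings `V`
#' (both unit-norm) with the inverse-temperature-like scaling `beta`.
#' During training the memory defaults to the current mini-batch.
#'
#' @slot U M x d matrix of stored image embeddings.
#' @slot V M x d matrix of stored structure embeddings.
#' @slot beta non-negative softmax scaling; 0 retrieves the memory mean,
#'   large values retrieve the stored pattern nearest the query.
#' @seealso [hopfieldMemory()], [hopfieldRetrieve()]
#' @export
setClass("HopfieldMemory", representation(
  U = "matrix", V = "matrix", beta = "numeric"))

setValidity("HopfieldMemory", function(object) {
  msg <- character()
  if (!identical(dim(object@U), dim(object@V)))
    msg <- c(msg, "U and V must be row-aligned with identical dimensions")
  if (object@beta < 0) msg <- c(msg, "beta must be non-negative")
  for (nm in c("U", "V")) {
    m <- slot(object, nm)
    if (nrow(m) == 0L) { msg <- c(msg, paste(nm, "must be non-empty")); next }
    if (any(abs(sqrt(rowSums(m^2)) - 1) > 1e-6))
      msg <- c(msg, paste(nm, "rows must be unit-norm"))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a HopfieldMemory
#' @param U,V row-aligned unit-norm stored embeddings (M x d matrices).
#' @param beta non-negative scaling (default 22).
#' @return A [HopfieldMemory-class].
#' @export
hopfieldMemory <- function(U, V = U, beta = 22) {
  new("HopfieldMemory", U = as.matrix(U), V = as.matrix(V),
      beta = as.numeric(beta))
}

#' Cross-modal retrieval report
#'
#' Per-query ranks of the matched item together with top-k accuracies (in
#' percent) and exact 95% Clopper-Pearson confidence intervals.
#'
#' @slot direction `"structure_retrieval"` (image query, molecule candidates)
#'   or `"image_retrieval"` (molecule query, image candidates).
#' @slot nCandidates number of candidate items per query.
#' @slot ranks integer vector, rank of the matched candidate per query.
#' @slot metrics data.frame with columns `k`, `accuracy`, `ci_lower`,
#'   `ci_upper` (all accuracies in percent).
#' @export
setClass("RetrievalReport", representation(
  direction = "character", nCandidates = "integer",
  ranks = "integer", metrics = "data.frame"))

setValidity("RetrievalReport", function(object) {
  msg <- character()
  m <- object@metrics
  if (!all(c("k", "accuracy", "ci_lower", "ci_upper") %in% names(m)))
    msg <- c(msg, "metrics must have k, accuracy, ci_lower, ci_upper")
  if (nrow(m) > 1L && is.unsorted(m$accuracy[order(m$k)]))
    msg <- c(msg, "top-k accuracy must be non-decreasing in k")
  if (nrow(m) && (any(m$accuracy < 0) || any(m$accuracy > 100)))
    msg <- c(msg, "accuracies must lie in [0, 100]")
  if (length(object@ranks) && any(object@ranks < 1L))
    msg <- c(msg, "ranks must be >= 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SyntheticSpec", function(object) {
  cat("SyntheticSpec:", object@nMolecules, "molecules x",
      object@viewsPerMolecule, "views,",
      sprintf("%dx%dx%d", object@channels, object@height, object@width),
      "pixels,", object@fpBits, "fp bits, latentDim", object@latentDim,
      ", noiseSd", object@noiseSd, ", seed", object@seed, "\n")
})

setMethod("show", "BioimageSet", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("BioimageSet: %d views (%d x %d x %d, %d-bit), %d plates, %d molecules\n",
              d[1], d[2], d[3], d[4], object@bitDepth,
              length(unique(object@meta$plate_id)),
              length(unique(object@meta$molecule_id))))
})

setMethod("show", "MoleculeSet", function(object) {
  cat(sprintf("MoleculeSet: %d molecules, %d fingerprint bits\n",
              nrow(object@meta), ncol(object@fingerprints)))
})

setMethod("show", "EmbeddingMatrix", function(object) {
  cat(sprintf("EmbeddingMatrix: %d x %d%s\n", nrow(object@vectors),
              ncol(object@vectors),
              if (isTRUE(object@normalized)) " (unit-norm rows)" else ""))
})

setMethod("show", "HopfieldMemory", function(object) {
  cat(sprintf("HopfieldMemory: %d stored pattern pairs, d = %d, beta = %g\n",
              nrow(object@U), ncol(object@U), object@beta))
})

setMethod("show", "RetrievalReport", function(object) {
  cat(sprintf("RetrievalReport (%s): %d queries vs %d candidates\n",
              object@direction, length(object@ranks), object@nCandidates))
  m <- object@metrics
  for (i in seq_len(nrow(m)))
    cat(sprintf("  top-%-2d %6.2f%%  [%.3g, %.3g]\n",
                m$k[i], m$accuracy[i], m$ci_lower[i], m$ci_upper[i]))
})

#' @describeIn BioimageSet-class number of image views
#' @param x object
#' @export
setGeneric("nViews", function(x) standardGeneric("nViews"))
#' @rdname BioimageSet-class
#' @export
setMethod("nViews", "BioimageSet", function(x) dim(x@pixels)[1L])

#' Accessors for pixel data and metadata
#' @param x a [BioimageSet-class]
#' @return `pixelData` returns the N x C x H x W array; `imageMeta` the
#'   metadata data.frame.
#' @export
setGeneric("pixelData", function(x) standardGeneric("pixelData"))
#' @rdname pixelData
#' @export
setMethod("pixelData", "BioimageSet", function(x) x@pixels)
#' @rdname pixelData
#' @export
setGeneric("imageMeta", function(x) standardGeneric("imageMeta"))
#' @rdname pixelData
#' @export
setMethod("imageMeta", "BioimageSet", function(x) x@meta)

#' Accessors for molecule data
#' @param x a [MoleculeSet-class]
#' @export
setGeneric("fingerprints", function(x) standardGeneric("fingerprints"))
#' @rdname fingerprints
#' @export
setMethod("fingerprints", "MoleculeSet", function(x) x@fingerprints)
#' @rdname fingerprints
#' @export
setGeneric("moleculeMeta", function(x) standardGeneric("moleculeMeta"))
#' @rdname fingerprints
#' @export
setMethod("moleculeMeta", "MoleculeSet", function(x) x@meta)

#' Accessors for embeddings
#' @param x an [EmbeddingMatrix-class]
#' @export
setGeneric("embVectors", function(x) standardGeneric("embVectors"))
#' @rdname embVectors
#' @export
setMethod("embVectors", "EmbeddingMatrix", function(x) x@vectors)
#' @rdname embVectors
#' @export
setGeneric("embIds", function(x) standardGeneric("embIds"))
#' @rdname embVectors
#' @export
setMethod("embIds", "EmbeddingMatrix", function(x) x@ids)

#' Accessors for retrieval reports
#' @param x a [RetrievalReport-class]
#' @export
setGeneric("reportMetrics", function(x) standardGeneric("reportMetrics"))
#' @rdname reportMetrics
#' @export
setMethod("reportMetrics", "RetrievalReport", function(x) x@metrics)
#' @rdname reportMetrics
#' @export
setGeneric("queryRanks", function(x) standardGeneric("queryRanks"))
#' @rdname reportMetrics
#' @export
setMethod("queryRanks", "RetrievalReport", function(x) x@ranks)

#' Row-wise L2 normalization
#'
#' @param m numeric matrix.
#' @param eps guard against zero rows.
#' @return matrix with unit-norm rows.
#' @export
l2Normalize <- function(m, eps = 1e-12) {
  m / pmax(sqrt(rowSums(m^2)), eps)
}
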