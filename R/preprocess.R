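#' Convert 16-bit image stacks to 8-bit with hot-pixel clipping
#'
#' Per channel, pixel values above the (1 - clipFraction) quantile (the
#' order-statistic quantile of the sorted values) are clipped to that
#' quantile, and the clipped channel is then linearly rescaled to 0..255 and
#' rounded. The default removes the 0.0028% of pixels with the highest
#' values. The map is monotone in the input. A channel with zero dynamic
#' range maps to the full-scale constant 255.
#'
#' The clip quantile is computed per image and per channel.
#'
#' @param pixels 16-bit pixels: a C x H x W array (one image), an
#'   N x C x H x W array, or a [BioimageSet-class].
#' @param clipFraction fraction of highest-valued pixels to clip,
#'   in `[0, 1)`; default `0.0028e-2` (i.e. 0.0028%).
#' @return same shape as the input with 8-bit values (0..255); for a
#'   `BioimageSet`, a new set with `bitDepth = 8`.
#' @export
convert16to8 <- function(pixels, clipFraction = 0.0028e-2) {
  if (clipFraction < 0 || clipFraction >= 1)
    stop("clipFraction must be in [0, 1)")
  if (is(pixels, "BioimageSet")) {
    if (pixels@bitDepth != 16L) stop("input BioimageSet must be 16-bit")
    out <- convert16to8(pixels@pixels, clipFraction)
    return(new("BioimageSet", pixels = out, bitDepth = 8L, meta = pixels@meta))
  }
  d <- dim(pixels)
  if (is.null(d) || length(pixels) == 0L) stop("empty image")
  if (length(d) == 3L) {
    out <- pixels
    for (cc in seq_len(d[1L]))
      out[cc, , ] <- clipRescale8(pixels[cc, , ], clipFraction)
    return(out)
  }
  if (length(d) == 4L) {
    out <- pixels
    for (i in seq_len(d[1L])) for (cc in seq_len(d[2L]))
      out[i, cc, , ] <- clipRescale8(pixels[i, cc, , ], clipFraction)
    return(out)
  }
  stop("pixels must be a CxHxW or NxCxHxW array")
}

# order-statistic (type 1) upper quantile, clip, min-max rescale to 0..255
clipRescale8 <- function(x, clipFraction) {
  if (clipFraction > 0) {
    q <- quantile(x, probs = 1 - clipFraction, type = 1, names = FALSE)
    x <- pmin(x, q)
  }
  lo <- min(x); hi <- max(x)
  if (hi <= lo) return(array(255, dim = dim(x)))
  round((x - lo) / (hi - lo) * 255)
}

#' Per-channel mean and standard deviation over a set of images
#'
#' Statistics intended for [normalizeImages()]; compute them on the training
#' split only and reuse them for validation and test images.
#'
#' @param pixels N x C x H x W array or 8-bit [BioimageSet-class].
#' @param indices rows (images) to use; default all.
#' @return list with numeric vectors `mean` and `sd` of length C.
#' @export
computeChannelStats <- function(pixels, indices = NULL) {
  if (is(pixels, "BioimageSet")) pixels <- pixels@pixels
  stopifnot(length(dim(pixels)) == 4L)
  if (!is.null(indices)) pixels <- pixels[indices, , , , drop = FALSE]
  C <- dim(pixels)[2L]
  m <- numeric(C); s <- numeric(C)
  for (cc in seq_len(C)) {
    v <- as.numeric(pixels[, cc, , ])
    m[cc] <- mean(v)
    s[cc] <- sd(v)
  }
  list(mean = m, sd = s)
}

#' Normalize images by per-channel mean and standard deviation
#'
#' Computes `(x - mean) / sd` per channel with statistics supplied by the
#' caller (calculated on the training split). Normalizing the training set
#' by its own statistics yields per-channel mean ~0 and sd ~1.
#'
#' @param pixels 8-bit pixels: C x H x W or N x C x H x W array, or a
#'   [BioimageSet-class].
#' @param channelMeans,channelSds numeric vectors of length C; all sds must
#'   be positive.
#' @return real-valued array of the same shape (a plain array also for
#'   `BioimageSet` input, since values are no longer bit-depth bounded).
#' @export
normalizeImages <- function(pixels, channelMeans, channelSds) {
  if (is(pixels, "BioimageSet")) pixels <- pixels@pixels
  d <- dim(pixels)
  C <- if (length(d) == 3L) d[1L] else if (length(d) == 4L) d[2L] else
    stop("pixels must be a CxHxW or NxCxHxW array")
  stopifnot(length(channelMeans) == C, length(channelSds) == C)
  if (any(channelSds <= 0)) stop("zero or negative channel sd")
  out <- pixels
  if (length(d) == 3L) {
    for (cc in seq_len(C))
      out[cc, , ] <- (pixels[cc, , ] - channelMeans[cc]) / channelSds[cc]
  } else {
    for (cc in seq_len(C))
      out[, cc, , ] <- (pixels[, cc, , ] - channelMeans[cc]) / channelSds[cc]
  }
  out
}

#' Crop (and optionally rescale) an image under the training/eval policies
#'
#' Two policies are supported. `"retrieval"` crops to `cropSize` x
#' `cropSize`: a uniformly random position in training, the centre crop in
#' evaluation (`"eval"` is an alias for the deterministic variant). The
#' reference protocol crops 520 x 696 inputs to 520 x 520. `"activity"`
#' first takes the same crop and then rescales it (bilinear) to `outSize` x
#' `outSize`, 320 x 320 in the reference protocol.
#'
#' @param image C x H x W array, at least `cropSize` in both dimensions.
#' @param mode `"retrieval"`, `"activity"` or `"eval"`.
#' @param cropSize square crop side (default 520).
#' @param outSize activity-mode output side (default 320).
#' @param train logical; random crop position when TRUE, centre when FALSE.
#'   `mode = "eval"` forces FALSE.
#' @return C x cropSize x cropSize array (`"retrieval"`/`"eval"`) or
#'   C x outSize x outSize (`"activity"`).
#' @export
cropPolicy <- function(image, mode = c("retrieval", "activity", "eval"),
                       cropSize = 520L, outSize = 320L, train = FALSE) {
  mode <- match.arg(mode)
  d <- dim(image)
  if (length(d) != 3L) stop("image must be a C x H x W array")
  H <- d[2L]; W <- d[3L]
  if (H < cropSize || W < cropSize)
    stop(sprintf("image %dx%d smaller than crop size %d", H, W, cropSize))
  if (mode == "eval") train <- FALSE
  offH <- if (train) sample.int(H - cropSize + 1L, 1L) else (H - cropSize) %/% 2L + 1L
  offW <- if (train) sample.int(W - cropSize + 1L, 1L) else (W - cropSize) %/% 2L + 1L
  crop <- image[, offH:(offH + cropSize - 1L), offW:(offW + cropSize - 1L),
                drop = FALSE]
  if (mode != "activity") return(crop)
  out <- array(0, dim = c(d[1L], outSize, outSize))
  for (cc in seq_len(d[1L]))
    out[cc, , ] <- EBImage::resize(crop[cc, , ], w = outSize, h = outSize)
  out
}

#' Filter degenerate columns and standardize a feature table
#'
#' Drops non-numeric columns and columns whose standard deviation across all
#' samples is zero, then standardizes the remaining columns by the mean and
#' standard deviation of the training rows. Intended for externally supplied
#' per-image feature tables (e.g. morphological profiling features).
#'
#' @param table data.frame of features; rownames are sample ids.
#' @param trainIds rownames belonging to the training split.
#' @return data.frame of standardized numeric features (training rows have
#'   column mean ~0 and sd ~1), with attribute `"dropped"` naming removed
#'   columns.
#' @export
standardizeFeatureTable <- function(table, trainIds) {
  stopifnot(is.data.frame(table))
  trainIds <- intersect(as.character(trainIds), rownames(table))
  if (!length(trainIds)) stop("no training rows found in table")
  numeric_ok <- vapply(table, is.numeric, logical(1))
  sdAll <- vapply(seq_along(table), function(j) {
    if (!numeric_ok[j]) return(NA_real_)
    sd(table[[j]])
  }, numeric(1))
  keep <- numeric_ok & !is.na(sdAll) & sdAll > 0
  if (!any(keep)) stop("all columns dropped (non-numeric or zero sd)")
  dropped <- names(table)[!keep]
  out <- table[, keep, drop = FALSE]
  mu <- colMeans(out[trainIds, , drop = FALSE])
  sg <- vapply(out[trainIds, , drop = FALSE], sd, numeric(1))
  if (any(sg == 0))
    sg[sg == 0] <- 1  # constant within train but not globally: leave centred
  out[] <- sweep(sweep(out, 2, mu, "-"), 2, sg, "/")
  attr(out, "dropped") <- dropped
  out
}
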