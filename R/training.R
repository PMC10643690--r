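#' Cosine-annealed learning rate with warm-up and hard restarts
#'
#' Linear ramp from 0 to `baseLr` over `warmupSteps`, then cosine decay to
#' 0 within each cycle of `stepsPerCycle` steps, with a hard reset to
#' `baseLr` at every cycle boundary.
#'
#' @param step step index (0-based); vectorized.
#' @param baseLr peak learning rate.
#' @param warmupSteps warm-up length in steps (0 disables warm-up).
#' @param stepsPerCycle cycle length in steps for the hard restarts.
#' @return learning rate(s).
#' @examples
#' lrSchedule(0, 1e-3, warmupSteps = 100, stepsPerCycle = 700)   # 0
#' lrSchedule(100, 1e-3, warmupSteps = 100, stepsPerCycle = 700) # 1e-3
#' @export
lrSchedule <- function(step, baseLr, warmupSteps = 20000L,
                       stepsPerCycle = 10000L) {
  if (any(step < 0)) stop("step must be non-negative")
  stopifnot(baseLr >= 0, warmupSteps >= 0, stepsPerCycle >= 1)
  ifelse(step < warmupSteps,
         baseLr * step / max(warmupSteps, 1L),
         {
           pos <- (step - warmupSteps) %% stepsPerCycle
           baseLr * (1 + cos(pi * pos / stepsPerCycle)) / 2
         })
}

#' Training configuration
#'
#' Optimization follows Adam with decoupled weight decay (weight decay 0.1
#' applied to dense weight matrices only, not biases or batch-norm
#' parameters) and the cosine warm-restart schedule of [lrSchedule()]. The
#' nominal warm-up of 20,000 steps is automatically scaled down to a tenth
#' of the total step budget for short runs.
#'
#' @param batchSize mini-batch size (default 256; must be >= 2 for the
#'   InfoLOOB objective).
#' @param steps total optimization steps.
#' @param baseLr peak learning rate (default 1e-3).
#' @param weightDecay decoupled weight decay coefficient (default 0.1).
#' @param warmupSteps nominal warm-up steps (default 20000, auto-scaled to
#'   `min(warmupSteps, steps / 10)`).
#' @param restartEpochs hard-restart period in epochs (default 7).
#' @param objective `"infonce"` (embeddings used directly) or
#'   `"infoloob_hopfield"` (Hopfield-retrieved embeddings, leave-one-out
#'   bound).
#' @param tauInv inverse temperature; defaults to 14.3 for infonce
#'   (retrieval regime) and 30 for infoloob_hopfield (activity regime).
#' @param beta Hopfield scaling for infoloob_hopfield (default 22).
#' @param seed integer seed for batch shuffling.
#' @return list of class `trainConfig`.
#' @export
trainConfig <- function(batchSize = 256L, steps = 2000L, baseLr = 1e-3,
                        weightDecay = 0.1, warmupSteps = 20000L,
                        restartEpochs = 7L,
                        objective = c("infonce", "infoloob_hopfield"),
                        tauInv = NULL, beta = 22, seed = 1L) {
  objective <- match.arg(objective)
  if (is.null(tauInv)) tauInv <- if (objective == "infonce") 14.3 else 30
  stopifnot(batchSize >= 1, steps >= 1, warmupSteps >= 0, tauInv > 0,
            beta >= 0, weightDecay >= 0)
  if (objective == "infoloob_hopfield" && batchSize < 2)
    stop("batchSize must be >= 2 for the infoloob objective")
  structure(list(batchSize = as.integer(batchSize), steps = as.integer(steps),
                 baseLr = baseLr, weightDecay = weightDecay,
                 warmupSteps = as.integer(warmupSteps),
                 restartEpochs = as.integer(restartEpochs),
                 objective = objective, tauInv = tauInv, beta = beta,
                 seed = as.integer(seed)),
            class = "trainConfig")
}

adamUpdate <- function(net, grads, state, lr, weightDecay,
                       step, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^step
  bc2 <- 1 - beta2^step
  f <- function(value, grad, st, name) {
    st$m <- beta1 * st$m + (1 - beta1) * grad
    st$v <- beta2 * st$v + (1 - beta2) * grad^2
    upd <- (st$m / bc1) / (sqrt(st$v / bc2) + eps)
    # decoupled decay: applied directly to dense weights, independent of
    # the loss gradient
    if (name == "W") upd <- upd + weightDecay * value
    list(value = value - lr * upd, state = st)
  }
  res <- walkParams(net$layers, grads, state, f)
  net$layers <- res$layers
  list(net = net, state = res$state)
}

#' Train the image and structure encoders contrastively
#'
#' Joint optimization of both encoders on matched (image, fingerprint)
#' batches with the configured contrastive objective. The loss of each step
#' is recorded; a non-finite loss aborts with a diagnostic. With a fixed
#' config seed the trace is reproducible on a single device.
#'
#' @param imageEnc,structEnc encoders from [newImageEncoder()] /
#'   [newStructureEncoder()].
#' @param imageMat N x D matrix of preprocessed, flattened images (rows
#'   aligned with `fpMat`).
#' @param fpMat N x bits binary fingerprint matrix; row i is the molecule
#'   matched to image row i.
#' @param config a [trainConfig()].
#' @return list with trained `imageEnc`, `structEnc`, the `config`, and
#'   `trace` (data.frame step, lr, loss).
#' @export
trainContrastive <- function(imageEnc, structEnc, imageMat, fpMat, config) {
  stopifnot(inherits(config, "trainConfig"),
            nrow(imageMat) == nrow(fpMat))
  n <- nrow(imageMat)
  bs <- min(config$batchSize, n)
  stepsPerEpoch <- max(1L, n %/% bs)
  # the reference schedule restarts every 7 epochs over a ~63-epoch run,
  # i.e. about nine cycles; for short desk runs the literal 7-epoch period
  # would collapse to a few dozen steps, so the cycle never drops below a
  # ninth of the step budget
  stepsPerCycle <- max(config$restartEpochs * stepsPerEpoch,
                       as.integer(ceiling(config$steps / 9)))
  warmup <- min(config$warmupSteps, config$steps %/% 10L)

  old <- globalRNGState(); on.exit(restoreRNGState(old), add = TRUE)
  set.seed(config$seed)

  stImg <- zeroStateLike(imageEnc$layers)
  stStr <- zeroStateLike(structEnc$layers)
  trace <- data.frame(step = seq_len(config$steps) - 1L, lr = NA_real_,
                      loss = NA_real_)
  perm <- sample.int(n)
  posInEpoch <- 0L

  for (s in seq_len(config$steps)) {
    if (posInEpoch + bs > n) { perm <- sample.int(n); posInEpoch <- 0L }
    idx <- perm[posInEpoch + seq_len(bs)]
    posInEpoch <- posInEpoch + bs

    fwX <- netForward(imageEnc, imageMat[idx, , drop = FALSE], train = TRUE)
    fwZ <- netForward(structEnc, fpMat[idx, , drop = FALSE], train = TRUE)
    imageEnc <- fwX$net; structEnc <- fwZ$net

    lg <- if (config$objective == "infonce")
      infonceLossGrad(fwX$out, fwZ$out, config$tauInv)
    else infoloobLossGrad(fwX$out, fwZ$out, config$beta, config$tauInv)

    if (!is.finite(lg$loss))
      stop(sprintf("numerical failure: loss %s at step %d", lg$loss, s - 1L))

    lr <- lrSchedule(s - 1L, config$baseLr, warmup, stepsPerCycle)
    trace$lr[s] <- lr; trace$loss[s] <- lg$loss

    if (lr > 0) {
      bwX <- netBackward(imageEnc, fwX$caches, lg$gX)
      bwZ <- netBackward(structEnc, fwZ$caches, lg$gZ)
      up <- adamUpdate(imageEnc, bwX$grads, stImg, lr, config$weightDecay, s)
      imageEnc <- up$net; stImg <- up$state
      up <- adamUpdate(structEnc, bwZ$grads, stStr, lr, config$weightDecay, s)
      structEnc <- up$net; stStr <- up$state
    }
  }
  list(imageEnc = imageEnc, structEnc = structEnc, config = config,
       trace = trace)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a self-describing directory: the full weights (RDS)
#' plus a JSON sidecar with the configuration and seed. A save/load
#' round-trip reproduces embeddings bit-for-bit.
#'
#' @param model list holding encoders and config (as returned by
#'   [trainContrastive()]), plus any extra entries to preserve.
#' @param dir checkpoint directory (created if missing).
#' @return `saveCheckpoint` invisibly returns `dir`; `loadCheckpoint`
#'   returns the model list.
#' @export
saveCheckpoint <- function(model, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  saveRDS(model, file.path(dir, "weights.rds"))
  cfg <- model$config
  jsonlite::write_json(
    list(class = class(cfg), config = unclass(cfg),
         embedDim = model$imageEnc$embedDim,
         saved = format(Sys.time(), tz = "UTC")),
    file.path(dir, "config.json"), auto_unbox = TRUE, pretty = TRUE,
    null = "null")
  invisible(dir)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(dir) {
  readRDS(file.path(dir, "weights.rds"))
}
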