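test_that("learning-rate schedule follows warm-up, cosine decay and restarts", {
  expect_equal(lrSchedule(0, 1e-3, warmupSteps = 100, stepsPerCycle = 700), 0)
  expect_equal(lrSchedule(0, 1e-3, warmupSteps = 0, stepsPerCycle = 700), 1e-3)
  expect_equal(lrSchedule(100, 1e-3, warmupSteps = 100, stepsPerCycle = 700),
               1e-3)
  expect_equal(lrSchedule(50, 1e-3, warmupSteps = 100, stepsPerCycle = 700),
               5e-4)
  # closed-form mid-cycle value
  t <- 180; w <- 100; cyc <- 700
  expect_equal(lrSchedule(t, 2e-3, w, cyc),
               2e-3 * (1 + cos(pi * (t - w) / cyc)) / 2)
  # hard restart at the cycle boundary
  expect_equal(lrSchedule(w + cyc, 2e-3, w, cyc), 2e-3)
  expect_lt(lrSchedule(w + cyc - 1, 2e-3, w, cyc), 1e-5)
  expect_error(lrSchedule(-1, 1e-3), "non-negative")
})

test_that("AdamW applies decoupled decay exactly as the hand-computed update", {
  # one dense weight, one bias; single step from zero moments
  net <- list(layers = list(list(type = "dense",
                                 W = matrix(2), b = 1)))
  grads <- list(list(W = matrix(0.5), b = -0.25))
  st <- phenomol:::zeroStateLike(net$layers)
  lr <- 0.1; wd <- 0.1
  up <- phenomol:::adamUpdate(net, grads, st, lr, wd, step = 1)
  # mhat = g, vhat = g^2 => adam direction = g/(|g| + eps) = sign(g)
  expect_equal(up$net$layers[[1]]$W[1, 1],
               2 - lr * (0.5 / (0.5 + 1e-8) + wd * 2), tolerance = 1e-12)
  # bias: no weight decay
  expect_equal(up$net$layers[[1]]$b,
               1 - lr * (-0.25 / (0.25 + 1e-8)), tolerance = 1e-12)
  # zero gradient: weights shrink purely by the decay term, bias frozen
  up2 <- phenomol:::adamUpdate(net, list(list(W = matrix(0), b = 0)),
                               phenomol:::zeroStateLike(net$layers),
                               lr, wd, step = 1)
  expect_equal(up2$net$layers[[1]]$W[1, 1], 2 - lr * wd * 2)
  expect_equal(up2$net$layers[[1]]$b, 1)
})

makeToyData <- function(n = 64L, seed = 30L) {
  spec <- syntheticSpec(nMolecules = n, viewsPerMolecule = 1L,
                        latentDim = 6L, channels = 2L, height = 8L,
                        width = 8L, fpBits = 32L, noiseSd = 0.1,
                        nMoaClasses = 4L, seed = seed)
  ds <- generatePairedDataset(spec)
  prep <- prepareImageMatrix(ds$images, seq_len(n))
  list(X = prep$matrix, Z = fingerprints(ds$molecules), ds = ds)
}

toyCfg <- encoderConfig(embedDim = 8L, imageChannels = 2L, imageHidden = 16L,
                        imageBlocks = 1L, structureHidden = c(16L,  16L))

test_that("a short run reduces the contrastive loss on synthetic pairs", {
  toy <- makeToyData()
  imgEnc <- newImageEncoder(2, 8, 8, toyCfg, seed = 1L)
  strEnc <- newStructureEncoder(32, toyCfg, seed = 2L)
  tc <- trainConfig(batchSize = 32L, steps = 50L, seed = 3L)
  fit <- trainContrastive(imgEnc, strEnc, toy$X, toy$Z[rownames(toy$Z), ], tc)
  expect_equal(nrow(fit$trace), 50L)
  expect_lt(mean(tail(fit$trace$loss, 10)), mean(head(fit$trace$loss, 10)))
})

test_that("frozen encoders (zero learning rate) give a constant loss trace", {
  toy <- makeToyData(32L)
  imgEnc <- newImageEncoder(2, 8, 8, toyCfg, seed = 4L)
  strEnc <- newStructureEncoder(32, toyCfg, seed = 5L)
  tc <- trainConfig(batchSize = 32L, steps = 8L, baseLr = 0, warmupSteps = 0L,
                    seed = 6L)
  fit <- trainContrastive(imgEnc, strEnc, toy$X, toy$Z, tc)
  expect_equal(length(unique(round(fit$trace$loss, 12))), 1L)
})

test_that("a fixed seed reproduces the loss trace exactly", {
  toy <- makeToyData(48L)
  run <- function() {
    imgEnc <- newImageEncoder(2, 8, 8, toyCfg, seed = 7L)
    strEnc <- newStructureEncoder(32, toyCfg, seed = 8L)
    trainContrastive(imgEnc, strEnc, toy$X, toy$Z,
                     trainConfig(batchSize = 16L, steps = 12L, seed = 9L))
  }
  expect_identical(run()$trace, run()$trace)
})

test_that("non-finite losses abort with a diagnostic", {
  toy <- makeToyData(32L)
  bad <- toy$X; bad[1, 1] <- NaN
  imgEnc <- newImageEncoder(2, 8, 8, toyCfg, seed = 10L)
  strEnc <- newStructureEncoder(32, toyCfg, seed = 11L)
  expect_error(
    trainContrastive(imgEnc, strEnc, bad, toy$Z,
                     trainConfig(batchSize = 32L, steps = 5L, seed = 12L)),
    "numerical failure")
})

test_that("infoloob training also optimizes and respects batch contract", {
  toy <- makeToyData(48L)
  imgEnc <- newImageEncoder(2, 8, 8, toyCfg, seed = 13L)
  strEnc <- newStructureEncoder(32, toyCfg, seed = 14L)
  tc <- trainConfig(batchSize = 16L, steps = 40L,
                    objective = "infoloob_hopfield", seed = 15L)
  expect_equal(tc$tauInv, 30)
  fit <- trainContrastive(imgEnc, strEnc, toy$X, toy$Z, tc)
  expect_lt(mean(tail(fit$trace$loss, 10)), mean(head(fit$trace$loss, 5)))
  expect_error(trainConfig(batchSize = 1L, objective = "infoloob_hopfield"),
               "batchSize")
})

test_that("checkpoints round-trip embeddings bit-for-bit", {
  toy <- makeToyData(32L)
  imgEnc <- newImageEncoder(2, 8, 8, toyCfg, seed = 16L)
  strEnc <- newStructureEncoder(32, toyCfg, seed = 17L)
  fit <- trainContrastive(imgEnc, strEnc, toy$X, toy$Z,
                          trainConfig(batchSize = 16L, steps = 10L, seed = 18L))
  dir <- tempfile("ckpt")
  saveCheckpoint(fit, dir)
  expect_true(file.exists(file.path(dir, "config.json")))
  fit2 <- loadCheckpoint(dir)
  e1 <- imageEncode(fit$imageEnc, toy$X)
  e2 <- imageEncode(fit2$imageEnc, toy$X)
  expect_identical(embVectors(e1), embVectors(e2))
})
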