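test_that("generation is bit-identical under a fixed seed", {
  spec <- syntheticSpec(nMolecules = 10L, viewsPerMolecule = 2L, seed = 7L)
  d1 <- generatePairedDataset(spec)
  d2 <- generatePairedDataset(spec)
  expect_identical(pixelData(d1$images), pixelData(d2$images))
  expect_identical(fingerprints(d1$molecules), fingerprints(d2$molecules))
  expect_identical(d1$pairing, d2$pairing)
})

test_that("noiseless views of one molecule are identical", {
  spec <- syntheticSpec(nMolecules = 3L, viewsPerMolecule = 2L,
                        noiseSd = 0, seed = 5L)
  ds <- generatePairedDataset(spec)
  px <- pixelData(ds$images)
  meta <- imageMeta(ds$images)
  for (mol in unique(meta$molecule_id)) {
    ix <- which(meta$molecule_id == mol)
    expect_identical(px[ix[1], , , ], px[ix[2], , , ])
  }
})

test_that("invalid specs are rejected", {
  expect_error(syntheticSpec(nMolecules = 0L), "nMolecules")
  expect_error(syntheticSpec(viewsPerMolecule = 0L), "viewsPerMolecule")
  expect_error(syntheticSpec(noiseSd = -0.1), "noiseSd")
  expect_error(syntheticSpec(fpBits = 8L, latentDim = 16L), "fpBits")
})

test_that("shapes, metadata and the pairing bijection hold", {
  spec <- tinySpec()
  ds <- generatePairedDataset(spec)
  px <- pixelData(ds$images)
  expect_equal(dim(px), c(24L, 3L, 8L, 8L))
  expect_true(all(px >= 0 & px <= 65535))
  expect_equal(nViews(ds$images), 24L)
  # bijection: each image id appears once and maps to a valid molecule
  expect_false(anyDuplicated(ds$pairing$image_id) > 0)
  expect_setequal(unique(ds$pairing$molecule_id),
                  moleculeMeta(ds$molecules)$molecule_id)
  counts <- table(ds$pairing$molecule_id)
  expect_true(all(counts == spec@viewsPerMolecule))
  # every molecule has a MoA class, number of classes as configured
  expect_lte(length(unique(moleculeMeta(ds$molecules)$moa)), 4L)
  # fingerprints binary with declared width
  fps <- fingerprints(ds$molecules)
  expect_equal(dim(fps), c(12L, 32L))
  expect_true(all(fps %in% c(0, 1)))
})

test_that("same-molecule same-plate collisions exist but not all views collide", {
  spec <- syntheticSpec(nMolecules = 8L, viewsPerMolecule = 4L, seed = 3L)
  ds <- generatePairedDataset(spec)
  meta <- imageMeta(ds$images)
  byMol <- split(meta$plate_id, meta$molecule_id)
  nPlatesPerMol <- vapply(byMol, function(p) length(unique(p)), 1L)
  expect_true(all(nPlatesPerMol >= 2L))  # views spread over plates
  expect_true(all(nPlatesPerMol < 4L))   # but some views share a plate
})

test_that("latent decoding oracle recovers the pairing at low noise", {
  spec <- syntheticSpec(nMolecules = 50L, viewsPerMolecule = 2L,
                        latentDim = 8L, noiseSd = 0.1, seed = 11L)
  ds <- generatePairedDataset(spec)
  expect_gte(oraclePairingRecovery(ds, spec), 45L)
})

test_that("large noise drives pairing recovery towards chance", {
  spec <- syntheticSpec(nMolecules = 30L, viewsPerMolecule = 2L,
                        latentDim = 8L, noiseSd = 8, seed = 12L)
  ds <- generatePairedDataset(spec)
  expect_lte(oraclePairingRecovery(ds, spec), 9L)  # chance = 1
})

test_that("label matrix honours sparsity, determinism and noise contract", {
  ds <- generatePairedDataset(tinySpec())
  full <- generateLabelMatrix(ds, nTasks = 5L, sparsity = 1, seed = 2L)
  expect_false(anyNA(full))
  expect_true(all(full %in% c(0, 1)))
  expect_identical(full, generateLabelMatrix(ds, nTasks = 5L, sparsity = 1,
                                             seed = 2L))
  sparse <- generateLabelMatrix(ds, nTasks = 5L, sparsity = 0.5, seed = 2L)
  expect_gt(sum(is.na(sparse)), 0L)
  expect_error(generateLabelMatrix(ds, nTasks = 0L), "nTasks")
  expect_error(generateLabelMatrix(ds, nTasks = 2L, sparsity = 0), "sparsity")
})

test_that("flip noise caps a direct-fit probe near its analytic ceiling", {
  # 10% label flips bound the achievable AUC at
  # 0.9^2 + 2 * 0.9 * 0.1 * 0.5 = 0.90 for a perfect predictor, so the
  # direct glm fit on the generator's own latents must land close below it
  spec <- syntheticSpec(nMolecules = 500L, viewsPerMolecule = 1L, seed = 31L)
  ds <- generatePairedDataset(spec)
  labels <- generateLabelMatrix(ds, nTasks = 8L, sparsity = 1,
                                labelFlip = 0.1, seed = 32L)
  lat <- ds$truth$latents
  set.seed(33)
  tr <- sample(nrow(lat), 350L)
  te <- setdiff(seq_len(nrow(lat)), tr)
  aucs <- vapply(seq_len(ncol(labels)), function(t) {
    fit <- suppressWarnings(
      glm(labels[tr, t] ~ ., data = as.data.frame(lat[tr, ]),
          family = binomial()))
    p <- predict(fit, as.data.frame(lat[te, ]), type = "response")
    oracleAuc(p, labels[te, t])
  }, numeric(1))
  expect_gt(mean(aucs), 0.85)
  expect_lt(mean(aucs), 0.95)
  # at the default 5% flip rate the ceiling moves to ~0.95
  lab5 <- generateLabelMatrix(ds, nTasks = 8L, sparsity = 1,
                              labelFlip = 0.05, seed = 32L)
  aucs5 <- vapply(seq_len(ncol(lab5)), function(t) {
    fit <- suppressWarnings(
      glm(lab5[tr, t] ~ ., data = as.data.frame(lat[tr, ]),
          family = binomial()))
    oracleAuc(predict(fit, as.data.frame(lat[te, ]), type = "response"),
              lab5[te, t])
  }, numeric(1))
  expect_gt(mean(aucs5), 0.9)
})
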