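test_that("rankMatched handles identity, antipodal and random cases", {
  E <- embeddingMatrix(diag(4), ids = sprintf("q%d", 1:4))
  pr <- data.frame(query_id = sprintf("q%d", 1:4),
                   candidate_id = sprintf("q%d", 1:4))
  expect_true(all(rankMatched(E, E, pr) == 1L))
  # matched candidate antipodal to the query among orthogonal distractors
  q <- embeddingMatrix(matrix(c(1, 0, 0), 1), ids = "q")
  cand <- embeddingMatrix(rbind(c(0, 1, 0), c(0, 0, 1), c(-1, 0, 0)),
                          ids = c("a", "b", "m"))
  expect_equal(unname(rankMatched(q, cand,
    data.frame(query_id = "q", candidate_id = "m"))), 3L)
  # 5x5 random case against a brute-force sort oracle
  set.seed(40)
  Q <- embeddingMatrix(matrix(rnorm(25), 5), ids = sprintf("q%d", 1:5))
  C <- embeddingMatrix(matrix(rnorm(25), 5), ids = sprintf("c%d", 1:5))
  pr2 <- data.frame(query_id = sprintf("q%d", 1:5),
                    candidate_id = sprintf("c%d", sample(5)))
  r <- rankMatched(Q, C, pr2)
  for (i in 1:5) {
    s <- drop(embVectors(C) %*% embVectors(Q)[i, ])
    ord <- order(-s, seq_along(s))  # descending, index tie-break
    expect_equal(unname(r[i]), which(ord == match(pr2$candidate_id[i],
                                                  embIds(C))))
  }
  expect_error(rankMatched(Q, C, data.frame(query_id = "zz",
                                            candidate_id = "c1")), "missing")
})

test_that("top-k accuracy counts hits in percent and is monotone", {
  expect_equal(topkAccuracy(c(1, 1, 1), 1), 100)
  expect_equal(topkAccuracy(c(1, 3, 11), 10), 100 * 2 / 3)
  expect_error(topkAccuracy(c(1, 2), 0), "k must be")
  ranks <- c(1, 2, 5, 9, 30)
  accs <- vapply(c(1, 5, 10, 30), function(k) topkAccuracy(ranks, k),
                 numeric(1))
  expect_true(all(diff(accs) >= 0))
})

test_that("Clopper-Pearson intervals reproduce printed bounds and the tail oracle", {
  ci1 <- clopperPearsonCI(1, 2115)
  expect_equal(unname(signif(ci1, 2)), c(0.0012, 0.26), tolerance = 1e-8)
  expect_equal(unname(round(ci1[2], 3)), 0.263)
  ci5 <- clopperPearsonCI(5, 2115)
  expect_equal(unname(signif(ci5, 3)), c(0.0768, 0.551))
  expect_equal(unname(clopperPearsonCI(0, 100))[1], 0)
  expect_equal(unname(clopperPearsonCI(100, 100))[2], 100)
  # independent binomial-tail bisection oracle
  for (x in c(1, 5, 10)) {
    expect_equal(unname(clopperPearsonCI(x, 2115)),
                 oracleClopperPearson(x, 2115), tolerance = 1e-6)
  }
  expect_error(clopperPearsonCI(1, 0), "n must be")
  # interval always contains the point estimate
  set.seed(41)
  for (i in 1:20) {
    n <- sample(5:500, 1); x <- sample(0:n, 1)
    ci <- clopperPearsonCI(x, n)
    expect_lte(ci[1], 100 * x / n + 1e-9)
    expect_gte(ci[2], 100 * x / n - 1e-9)
  }
})

test_that("retrieval evaluation reports both directions with sane chance level", {
  set.seed(42)
  ids <- sprintf("m%03d", 1:50)
  E <- embeddingMatrix(matrix(rnorm(50 * 8), 50), ids = sprintf("i%03d", 1:50))
  S <- embeddingMatrix(embVectors(E), ids = ids)  # identical embeddings
  pairing <- data.frame(image_id = sprintf("i%03d", 1:50), molecule_id = ids)
  rep <- retrievalEval(E, S, pairing)
  expect_equal(reportMetrics(rep$structure_retrieval)$accuracy[1], 100)
  expect_equal(reportMetrics(rep$image_retrieval)$accuracy[1], 100)
  # invariance under joint permutation of the pairing rows
  p <- sample.int(50)
  rep2 <- retrievalEval(E, S, pairing[p, ])
  expect_equal(reportMetrics(rep2$structure_retrieval),
               reportMetrics(rep$structure_retrieval))
  expect_error(retrievalEval(E, S, pairing[1, , drop = FALSE]), "at least 2")
})

test_that("random embeddings score at chance covered by the exact interval", {
  set.seed(43)
  hits <- 0L; total <- 0L
  for (s in 1:3) {
    E <- embeddingMatrix(matrix(rnorm(200 * 16), 200),
                         ids = sprintf("i%d", 1:200))
    S <- embeddingMatrix(matrix(rnorm(200 * 16), 200),
                         ids = sprintf("m%d", 1:200))
    pairing <- data.frame(image_id = sprintf("i%d", 1:200),
                          molecule_id = sprintf("m%d", 1:200))
    rep <- retrievalEval(E, S, pairing)
    hits <- hits + sum(queryRanks(rep$structure_retrieval) == 1L)
    total <- total + 200L
  }
  ci <- clopperPearsonCI(hits, total)
  expect_gte(0.5, ci[1])  # chance level 100/200 = 0.5%
  expect_lte(0.5, ci[2])
})

test_that("subsampled candidate sets implement the 1-vs-99 protocol", {
  set.seed(44)
  E <- embeddingMatrix(matrix(rnorm(150 * 8), 150), ids = sprintf("i%d", 1:150))
  S <- embeddingMatrix(matrix(rnorm(150 * 8), 150), ids = sprintf("m%d", 1:150))
  pairing <- data.frame(image_id = sprintf("i%d", 1:150),
                        molecule_id = sprintf("m%d", 1:150))
  rep <- retrievalEval(E, S, pairing, subsample = 99L, seed = 2L)
  expect_equal(rep$structure_retrieval@nCandidates, 100L)
  expect_true(all(queryRanks(rep$structure_retrieval) <= 100L))
})

test_that("reference sets filter same-molecule same-plate queries", {
  # 3 classes x 2 plates fixture, enumerable by hand
  meta <- data.frame(
    image_id = sprintf("i%d", 1:12),
    molecule_id = rep(c("A", "B", "C"), each = 4),
    plate_id = rep(c("p1", "p1", "p2", "p2"), 3),
    stringsAsFactors = FALSE)
  refs <- buildReferenceSet(meta, "molecule_id", seed = 1L)
  expect_equal(sort(refs$references$class), c("A", "B", "C"))
  expect_equal(nrow(refs$references), 3L)
  # hand enumeration: each molecule has 4 views, 2 per plate; removing the
  # reference and its same-plate sibling leaves exactly 2 queries per class
  expect_equal(nrow(refs$queries), 6L)
  expect_equal(as.vector(table(refs$queries$class)), c(2L, 2L, 2L))
  # no query shares molecule and plate with any reference
  refKey <- with(merge(refs$references, meta,
                       by = "image_id"), paste(molecule_id, plate_id))
  qKey <- with(merge(refs$queries, meta, by = "image_id"),
               paste(molecule_id, plate_id))
  expect_length(intersect(refKey, qKey), 0L)
  # a class whose images all share one plate is dropped with a warning
  meta2 <- meta
  meta2$plate_id[meta2$molecule_id == "C"] <- "p1"
  meta2 <- meta2[meta2$molecule_id != "C" | seq_len(12) %in% 9:10, ]
  expect_warning(r2 <- buildReferenceSet(meta2, "molecule_id", seed = 1L),
                 "dropping")
  expect_false("C" %in% r2$references$class)
})

test_that("zero-shot evaluation also works with mechanism-of-action classes", {
  ds <- generatePairedDataset(tinySpec(viewsPerMolecule = 4L))
  meta <- imageMeta(ds$images)
  mm <- moleculeMeta(ds$molecules)
  meta$moa <- mm$moa[match(meta$molecule_id, mm$molecule_id)]
  refs <- buildReferenceSet(meta, classKey = "moa", seed = 3L)
  expect_equal(sort(unique(refs$references$class)),
               sort(unique(meta$moa)))
  expect_false(anyDuplicated(refs$references$class) > 0)
  # queries keep only images outside every reference (molecule, plate) pair
  refIdx <- match(refs$references$image_id, meta$image_id)
  badKeys <- paste(meta$molecule_id[refIdx], meta$plate_id[refIdx])
  qIdx <- match(refs$queries$image_id, meta$image_id)
  expect_false(any(paste(meta$molecule_id[qIdx],
                         meta$plate_id[qIdx]) %in% badKeys))
})

test_that("untrained encoders retrieve at chance level", {
  ds <- generatePairedDataset(syntheticSpec(nMolecules = 200L,
                                            viewsPerMolecule = 1L,
                                            seed = 50L))
  meta <- imageMeta(ds$images)
  prep <- prepareImageMatrix(ds$images, seq_len(200))
  cfg <- encoderConfig(embedDim = 16L, imageHidden = 32L, imageBlocks = 0L,
                       structureHidden = c(32L, 32L))
  embI <- imageEncode(newImageEncoder(5, 16, 16, cfg, seed = 51L),
                      prep$matrix, ids = meta$image_id)
  embS <- structureEncode(newStructureEncoder(256L, cfg, seed = 52L),
                          fingerprints(ds$molecules))
  rep <- retrievalEval(embI, embS,
                       data.frame(image_id = meta$image_id,
                                  molecule_id = meta$molecule_id))
  m <- reportMetrics(rep$structure_retrieval)
  # chance is 0.5%; an untrained model must not exceed a few percent and
  # its exact interval must reach down to (or below) chance
  expect_lt(m$accuracy[m$k == 1], 5)
  expect_lte(m$ci_lower[m$k == 1], 0.5)
})

test_that("zero-shot classification reproduces manual softmax scores", {
  refs <- embeddingMatrix(diag(4), ids = sprintf("r%d", 1:4))
  q <- embeddingMatrix(rbind(diag(4)[2, ], c(0.5, 0.5, 0.5, 0.5)),
                       ids = c("q1", "q2"))
  out <- zeroshotClassify(q, refs, refLabels = sprintf("cls%d", 1:4),
                          queryLabels = c("cls2", "cls1"), ks = 1:4)
  expect_equal(unname(rowSums(out$scores)), c(1, 1))
  expect_equal(out$ranks[1], 1L)
  # manual softmax for the first query: sims (0, 1, 0, 0)
  expect_equal(out$scores[1, ], setNames(exp(c(0, 1, 0, 0)) /
                                           sum(exp(c(0, 1, 0, 0))),
                                         sprintf("cls%d", 1:4)))
  # accuracy monotone in k, 100% at k = n_classes
  expect_true(all(diff(out$metrics$accuracy) >= 0))
  expect_equal(out$metrics$accuracy[4], 100)
  expect_error(zeroshotClassify(q, refs, sprintf("cls%d", 1:3),
                                c("cls2", "cls1")), "misaligned")
})

test_that("rank-statistic AUC matches pair counting, pROC and hand formula", {
  scores <- c(0.9, 0.8, 0.7, 0.6, 0.55, 0.5, 0.4, 0.3, 0.2, 0.1)
  labels <- c(1, 1, 0, 1, 0, 1, 0, 0, 1, 0)
  # Mann-Whitney by hand: ranks of positives 10,9,7,5,2 -> sum 33
  expect_equal(aucRank(scores, labels), (33 - 5 * 6 / 2) / 25)
  expect_equal(aucRank(scores, labels), oracleAuc(scores, labels))
  skip_if_not_installed("pROC")
  expect_equal(aucRank(scores, labels),
               as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE))))
  # midrank tie handling
  tied <- c(0.5, 0.5, 0.5, 0.2)
  tlab <- c(1, 0, 1, 0)
  expect_equal(aucRank(tied, tlab), oracleAuc(tied, tlab))
})

test_that("linear probing solves separable tasks and skips degenerate ones", {
  set.seed(45)
  n <- 120
  X <- matrix(rnorm(n * 6), n)
  X[, 1] <- X[, 1] + 3 * sign(X[, 1])    # wide-margin signal feature
  rownames(X) <- sprintf("m%03d", seq_len(n))
  y1 <- as.integer(X[, 1] > 0)           # perfectly separable
  y2 <- rep(1L, n)                        # single class -> skipped
  labels <- cbind(task_a = y1, task_b = y2)
  rownames(labels) <- rownames(X)
  split <- makeSplit(rownames(X), "random_by_molecule", seed = 46L)
  pr <- linearProbe(X, labels, split)
  expect_equal(pr$results$task, "task_a")
  expect_equal(pr$results$auc, 1.0)
  expect_equal(pr$skipped, "task_b")
  expect_equal(pr$summary$n_auc_gt_0.9, 1L)
})
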