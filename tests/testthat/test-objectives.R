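test_that("similarity matrix matches the double-loop oracle", {
  expect_equal(similarityMatrix(diag(3), diag(3)), diag(3))
  x <- matrix(c(1, 0), 1); y <- matrix(c(-1, 0), 1)
  expect_equal(similarityMatrix(x, y)[1, 1], -1)
  set.seed(20)
  X <- l2Normalize(matrix(rnorm(9), 3))
  Z <- l2Normalize(matrix(rnorm(9), 3))
  S <- similarityMatrix(X, Z)
  for (i in 1:3) for (j in 1:3)
    expect_equal(S[i, j], sum(X[i, ] * Z[j, ]))
  expect_true(all(S >= -1 - 1e-12 & S <= 1 + 1e-12))
  expect_error(similarityMatrix(X, l2Normalize(matrix(rnorm(8), 2))),
               "dimensions differ")
})

test_that("InfoNCE reproduces hand-derived values and rejects bad input", {
  expect_equal(infonceLoss(matrix(1, 1, 1), matrix(1, 1, 1), 5), 0)
  expect_equal(infonceLoss(diag(2), diag(2), tauInv = 1),
               2 * log(1 + exp(-1)))
  expect_error(infonceLoss(matrix(2, 1, 1), matrix(1, 1, 1), 1), "unit-norm")
})

test_that("InfoNCE matches the O(N^2) loop oracle and is permutation invariant", {
  set.seed(21)
  for (N in c(2L, 5L, 16L)) {
    X <- l2Normalize(matrix(rnorm(N * 6), N))
    Z <- l2Normalize(matrix(rnorm(N * 6), N))
    expect_equal(infonceLoss(X, Z, 4), oracleInfonce(X, Z, 4),
                 tolerance = 1e-6)
    p <- sample.int(N)
    expect_equal(infonceLoss(X[p, ], Z[p, ], 4), infonceLoss(X, Z, 4))
  }
})

test_that("lowering an un-matched score strictly lowers the loss", {
  set.seed(22)
  S <- matrix(rnorm(16), 4)
  l0 <- phenomol:::infonceOnScores(S)$loss
  S[1, 3] <- S[1, 3] - 0.5
  expect_lt(phenomol:::infonceOnScores(S)$loss, l0)
})

test_that("losses stay finite at large inverse temperature", {
  set.seed(23)
  X <- l2Normalize(matrix(rnorm(24), 4))
  Z <- l2Normalize(matrix(rnorm(24), 4))
  expect_true(is.finite(infonceLoss(X, Z, 1000)))
  expect_true(is.finite(infoloobLoss(X, Z, beta = 22, tauInv = 1000)))
})

test_that("Hopfield retrieval interpolates between memory mean and nearest pattern", {
  M <- diag(2)
  mean2 <- matrix(1 / sqrt(2), 1, 2)
  expect_equal(hopfieldRetrieve(M, matrix(c(1, 0), 1), beta = 0), mean2)
  expect_equal(hopfieldRetrieve(M, matrix(c(0.3, 0.1), 1) /
                                  sqrt(0.1), beta = 0), mean2)
  near <- hopfieldRetrieve(M, matrix(c(1, 0), 1), beta = 1e4)
  expect_lt(max(abs(near - matrix(c(1, 0), 1))), 1e-4)
  expect_error(hopfieldRetrieve(matrix(numeric(0), 0, 2), diag(2), 1),
               "empty")
})

test_that("finite-beta retrieval equals the softmax oracle with unit-norm output", {
  set.seed(24)
  M <- l2Normalize(matrix(rnorm(15), 3))
  Q <- l2Normalize(matrix(rnorm(10), 2))
  R <- hopfieldRetrieve(M, Q, beta = 1)
  for (i in 1:2)
    expect_equal(R[i, ], oracleHopfield(M, Q[i, ], 1), tolerance = 1e-12)
  expect_true(all(abs(sqrt(rowSums(R^2)) - 1) < 1e-9))
  # pre-normalization retrieval is a convex combination of stored patterns
  fw <- phenomol:::hopForward(M, Q, 1)
  P <- fw$cache$P
  expect_true(all(P >= 0))
  expect_equal(rowSums(P), c(1, 1))
})

test_that("InfoLOOB handles degenerate and analytic cases", {
  expect_error(infoloobLoss(matrix(1, 1, 1), matrix(1, 1, 1)), "N >= 2")
  # N = 2 orthonormal matched pairs, beta = 0: retrievals collapse to the
  # common mean, numerator equals the single denominator term
  expect_equal(infoloobLoss(diag(2), diag(2), beta = 0, tauInv = 1), 0)
})

test_that("InfoLOOB matches the loop oracle for random batches", {
  set.seed(25)
  for (N in c(3L, 8L)) {
    X <- l2Normalize(matrix(rnorm(N * 5), N))
    Z <- l2Normalize(matrix(rnorm(N * 5), N))
    expect_equal(infoloobLoss(X, Z, beta = 2, tauInv = 3),
                 oracleInfoloob(X, Z, 2, 3), tolerance = 1e-6)
  }
})

test_that("large-beta InfoLOOB approaches the leave-one-out bound on raw embeddings", {
  set.seed(26)
  X <- l2Normalize(matrix(rnorm(5 * 4), 5))
  Z <- l2Normalize(matrix(rnorm(5 * 4), 5))
  # beta -> inf: retrieval returns the stored pattern nearest each query;
  # oracle computes the same limit independently
  expect_equal(infoloobLoss(X, Z, beta = 5e3, tauInv = 2),
               oracleInfoloob(X, Z, 5e3, 2), tolerance = 1e-6)
})

test_that("loss gradients agree with finite differences", {
  set.seed(27)
  N <- 4L; d <- 5L
  X <- l2Normalize(matrix(rnorm(N * d), N))
  Z <- l2Normalize(matrix(rnorm(N * d), N))
  fd <- function(f, M, eps = 1e-6) {
    G <- M * 0
    for (i in seq_along(M)) {
      Mp <- M; Mp[i] <- M[i] + eps
      Mm <- M; Mm[i] <- M[i] - eps
      G[i] <- (f(Mp) - f(Mm)) / (2 * eps)
    }
    G
  }
  g <- phenomol:::infonceLossGrad(X, Z, 3)
  expect_lt(max(abs(g$gX - fd(function(M)
    phenomol:::infonceLossGrad(M, Z, 3)$loss, X))), 1e-6)
  expect_lt(max(abs(g$gZ - fd(function(M)
    phenomol:::infonceLossGrad(X, M, 3)$loss, Z))), 1e-6)
  g2 <- phenomol:::infoloobLossGrad(X, Z, 2, 3)
  expect_lt(max(abs(g2$gX - fd(function(M)
    phenomol:::infoloobLossGrad(M, Z, 2, 3)$loss, X))), 1e-6)
  expect_lt(max(abs(g2$gZ - fd(function(M)
    phenomol:::infoloobLossGrad(X, M, 2, 3)$loss, Z))), 1e-6)
})

test_that("bilinear scores and objective follow the matrix algebra", {
  expect_equal(bilinearScore(c(1, 0), c(1, 0), diag(2)), 1)
  set.seed(28)
  x <- rnorm(2); z <- rnorm(2); W <- matrix(rnorm(4), 2)
  expect_equal(bilinearScore(x, z, W),
               x[1] * W[1, 1] * z[1] + x[1] * W[1, 2] * z[2] +
                 x[2] * W[2, 1] * z[1] + x[2] * W[2, 2] * z[2])
  expect_error(bilinearScore(c(1, 0, 0), c(1, 0), diag(2)), "W must be")
  Xf <- matrix(rnorm(12), 4); Zf <- matrix(rnorm(12), 4)
  expect_equal(bilinearInfonce(Xf, Zf, matrix(0, 3, 3), 2), 2 * log(4))
  # general case agrees with the loop oracle on the score matrix
  W <- matrix(rnorm(9), 3)
  S <- 2 * Xf %*% W %*% t(Zf)
  t1 <- 0; t2 <- 0
  for (i in 1:4) {
    t1 <- t1 + log(exp(S[i, i]) / sum(exp(S[i, ])))
    t2 <- t2 + log(exp(S[i, i]) / sum(exp(S[, i])))
  }
  expect_equal(bilinearInfonce(Xf, Zf, W, 2), -t1 / 4 - t2 / 4)
})
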