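# Contrastive objectives: symmetric InfoNCE, continuous modern Hopfield
# retrieval, and the leave-one-out InfoLOOB bound on retrieved embeddings.
# All log-sum-exp computations subtract the row/column maximum, so losses
# are finite for any finite input even at large inverse temperatures.

asUnitMatrix <- function(x, what = "embeddings") {
  if (is(x, "EmbeddingMatrix")) x <- embVectors(x)
  x <- as.matrix(x)
  if (nrow(x) && any(abs(sqrt(rowSums(x^2)) - 1) > 1e-6))
    stop(what, " must have unit-norm rows")
  x
}

#' Cosine similarity matrix between two embedding sets
#'
#' Entry (i, j) is the inner product of unit-norm rows `x_i` and `z_j`,
#' hence a cosine similarity in `[-1, 1]`.
#'
#' @param X,Z [EmbeddingMatrix-class] objects or unit-norm matrices with a
#'   common embedding dimension.
#' @return N x M numeric matrix.
#' @export
similarityMatrix <- function(X, Z) {
  X <- asUnitMatrix(X); Z <- asUnitMatrix(Z)
  if (ncol(X) != ncol(Z))
    stop(sprintf("embedding dimensions differ: %d vs %d", ncol(X), ncol(Z)))
  tcrossprod(X, Z)
}

rowLse <- function(S) {
  m <- apply(S, 1, max)
  m + log(rowSums(exp(S - m)))
}

#' Symmetric InfoNCE contrastive loss
#'
#' The mean of two cross-entropy terms over the scaled similarity matrix
#' `S = tauInv * X Z^T`: images-over-structures (softmax across each row)
#' and structures-over-images (softmax across each column), with matched
#' pairs on the diagonal. The value is non-negative, invariant under a
#' joint row permutation of `(X, Z)`, and exactly 0 for a single pair.
#'
#' @param X,Z matched unit-norm embeddings (row i of X pairs with row i of
#'   Z); [EmbeddingMatrix-class] or matrix.
#' @param tauInv inverse temperature scaling the cosine similarities
#'   (default 14.3, the retrieval-mode setting).
#' @return scalar loss.
#' @examples
#' X <- diag(2)
#' infonceLoss(X, X, tauInv = 1)  # 2 * log(1 + exp(-1))
#' @export
infonceLoss <- function(X, Z, tauInv = 14.3) {
  X <- asUnitMatrix(X); Z <- asUnitMatrix(Z)
  stopifnot(nrow(X) == nrow(Z), ncol(X) == ncol(Z), tauInv > 0)
  infonceOnScores(tauInv * tcrossprod(X, Z))$loss
}

# loss and d(loss)/d(scores) for the symmetric two-term objective on an
# arbitrary score matrix
infonceOnScores <- function(S) {
  N <- nrow(S)
  lossRow <- mean(rowLse(S) - diag(S))
  lossCol <- mean(rowLse(t(S)) - diag(S))
  P <- exp(S - apply(S, 1, max)); P <- P / rowSums(P)
  Q <- exp(t(S) - apply(S, 2, max)); Q <- t(Q / rowSums(Q))
  list(loss = lossRow + lossCol, gS = (P + Q - 2 * diag(N)) / N)
}

infonceLossGrad <- function(X, Z, tauInv) {
  r <- infonceOnScores(tauInv * tcrossprod(X, Z))
  list(loss = r$loss,
       gX = tauInv * r$gS %*% Z,
       gZ = tauInv * t(r$gS) %*% X)
}

# --- Hopfield retrieval ----------------------------------------------------

hopForward <- function(memory, queries, beta) {
  A <- tcrossprod(queries, memory)          # K x M
  S <- beta * A
  P <- exp(S - apply(S, 1, max))
  P <- P / rowSums(P)
  R <- P %*% memory
  r <- pmax(sqrt(rowSums(R^2)), 1e-12)
  list(Rn = R / r, cache = list(memory = memory, queries = queries,
                                P = P, r = r, Rn = R / r, beta = beta))
}

hopBackward <- function(cache, G) {
  GR <- (G - cache$Rn * rowSums(G * cache$Rn)) / cache$r
  GP <- tcrossprod(GR, cache$memory)        # GR %*% t(memory), K x M
  gM <- crossprod(cache$P, GR)
  Spg <- cache$P * GP
  GA <- cache$beta * (Spg - cache$P * rowSums(Spg))
  gQ <- GA %*% cache$memory
  gM <- gM + crossprod(GA, cache$queries)
  list(gM = gM, gQ = gQ)
}

#' Continuous modern Hopfield retrieval
#'
#' For each query q, returns the softmax-weighted combination of the stored
#' patterns, `memory^T softmax(beta * memory q)`, renormalized to unit norm.
#' `beta = 0` retrieves the (normalized) average of the stored patterns for
#' every query; as `beta` grows the retrieval approaches the stored pattern
#' most similar to the query. Before normalization the retrieval lies in
#' the convex hull of the stored patterns.
#'
#' @param memory M x d matrix of unit-norm stored patterns (or a
#'   [HopfieldMemory-class], whose `U` slot and `beta` are used).
#' @param queries K x d matrix of query vectors.
#' @param beta non-negative softmax scaling.
#' @return K x d matrix of unit-norm retrieved patterns.
#' @examples
#' M <- diag(2)
#' hopfieldRetrieve(M, matrix(c(1, 0), 1), beta = 0)  # mean of e1, e2
#' @export
hopfieldRetrieve <- function(memory, queries, beta = 22) {
  if (is(memory, "HopfieldMemory")) {
    if (missing(beta)) beta <- memory@beta
    memory <- memory@U
  }
  memory <- as.matrix(memory)
  queries <- if (is(queries, "EmbeddingMatrix")) embVectors(queries)
             else as.matrix(queries)
  if (!nrow(memory)) stop("empty Hopfield memory")
  if (beta < 0) stop("beta must be non-negative")
  if (ncol(memory) != ncol(queries))
    stop("memory and query dimensions differ")
  hopForward(memory, queries, beta)$Rn
}

# --- InfoLOOB --------------------------------------------------------------

# row-wise log-sum-exp excluding the diagonal entry
offdiagRowLse <- function(S) {
  N <- nrow(S)
  off <- S; diag(off) <- -Inf
  m <- apply(off, 1, max)
  m + log(rowSums(exp(off - m)))
}

offdiagSoftmaxRows <- function(S) {
  off <- S; diag(off) <- -Inf
  P <- exp(off - apply(off, 1, max))
  P / rowSums(P)
}

#' InfoLOOB loss on Hopfield-retrieved embeddings
#'
#' Stores the current batch in two continuous modern Hopfield networks
#' (image memory `U = X`, structure memory `V = Z`), retrieves
#' image-retrieved and structure-retrieved versions of both modalities
#' (`U_x, U_z, V_x, V_z`, each renormalized), and evaluates the symmetric
#' leave-one-out bound: the denominator sums only over un-matched pairs
#' (j != i), which avoids the saturation of InfoNCE. The value can be
#' negative. Requires at least two pairs (the leave-one-out denominator is
#' empty for N = 1).
#'
#' @inheritParams infonceLoss
#' @param beta Hopfield scaling (default 22). `beta = 0` collapses every
#'   retrieval to the batch mean.
#' @param tauInv inverse temperature (default 30, the activity-mode
#'   setting).
#' @return scalar loss.
#' @export
infoloobLoss <- function(X, Z, beta = 22, tauInv = 30) {
  X <- asUnitMatrix(X); Z <- asUnitMatrix(Z)
  stopifnot(nrow(X) == nrow(Z), ncol(X) == ncol(Z), tauInv > 0, beta >= 0)
  if (nrow(X) < 2L)
    stop("infoloobLoss requires N >= 2: leave-one-out denominator is empty")
  infoloobLossGrad(X, Z, beta, tauInv)$loss
}

infoloobLossGrad <- function(X, Z, beta, tauInv) {
  N <- nrow(X)
  cUx <- hopForward(X, X, beta)
  cUz <- hopForward(X, Z, beta)
  cVx <- hopForward(Z, X, beta)
  cVz <- hopForward(Z, Z, beta)
  Ux <- cUx$Rn; Uz <- cUz$Rn; Vx <- cVx$Rn; Vz <- cVz$Rn

  S1 <- tauInv * tcrossprod(Ux, Uz)
  S2 <- tauInv * tcrossprod(Vx, Vz)
  loss <- mean(offdiagRowLse(S1) - diag(S1)) +
    mean(offdiagRowLse(t(S2)) - diag(S2))

  G1 <- (offdiagSoftmaxRows(S1) - diag(N)) / N
  G2 <- (t(offdiagSoftmaxRows(t(S2))) - diag(N)) / N
  gUx <- tauInv * G1 %*% Uz; gUz <- tauInv * crossprod(G1, Ux)
  gVx <- tauInv * G2 %*% Vz; gVz <- tauInv * crossprod(G2, Vx)

  b1 <- hopBackward(cUx$cache, gUx)
  b2 <- hopBackward(cUz$cache, gUz)
  b3 <- hopBackward(cVx$cache, gVx)
  b4 <- hopBackward(cVz$cache, gVz)
  list(loss = loss,
       gX = b1$gM + b1$gQ + b2$gM + b3$gQ,
       gZ = b2$gQ + b3$gM + b4$gM + b4$gQ)
}

# --- bilinear baseline -----------------------------------------------------

#' Bilinear similarity score and its InfoNCE objective
#'
#' Baseline model scoring an (image feature, molecule feature) pair by the
#' bilinear form `y = x^T W z` with a trainable weight matrix `W`. The
#' training objective replaces the cosine similarities of [infonceLoss()]
#' with these bilinear scores, computed symmetrically between modalities.
#'
#' @param x,z feature vectors of lengths matching `nrow(W)` and `ncol(W)`.
#' @param W weight matrix, `length(x)` x `length(z)`.
#' @return `bilinearScore`: scalar score.
#' @examples
#' bilinearScore(c(1, 0), c(1, 0), diag(2))  # 1
#' @export
bilinearScore <- function(x, z, W) {
  x <- as.numeric(x); z <- as.numeric(z)
  if (!identical(dim(W), c(length(x), length(z))))
    stop("W must be length(x) x length(z)")
  drop(crossprod(x, W %*% z))
}

#' @rdname bilinearScore
#' @param Xf,Zf matched feature matrices (rows aligned).
#' @param tauInv inverse temperature.
#' @return `bilinearInfonce`: scalar symmetric InfoNCE loss on the score
#'   matrix `tauInv * Xf W Zf^T`.
#' @export
bilinearInfonce <- function(Xf, Zf, W, tauInv = 14.3) {
  Xf <- as.matrix(Xf); Zf <- as.matrix(Zf)
  stopifnot(nrow(Xf) == nrow(Zf))
  if (!identical(dim(W), c(ncol(Xf), ncol(Zf))))
    stop("W must be ncol(Xf) x ncol(Zf)")
  infonceOnScores(tauInv * Xf %*% W %*% t(Zf))$loss
}
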