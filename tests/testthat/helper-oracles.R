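# Independent brute-force oracles used to freeze expected values.

# O(N^2) loop implementation of the symmetric InfoNCE objective (Eq.-level
# transcription, no matrix algebra shared with the implementation).
oracleInfonce <- function(X, Z, tauInv) {
  N <- nrow(X)
  t1 <- 0; t2 <- 0
  for (i in seq_len(N)) {
    num <- exp(tauInv * sum(X[i, ] * Z[i, ]))
    den1 <- 0; den2 <- 0
    for (j in seq_len(N)) {
      den1 <- den1 + exp(tauInv * sum(X[i, ] * Z[j, ]))
      den2 <- den2 + exp(tauInv * sum(X[j, ] * Z[i, ]))
    }
    t1 <- t1 + log(num / den1)
    t2 <- t2 + log(num / den2)
  }
  -t1 / N - t2 / N
}

# explicit softmax retrieval for a single query (max-shifted for large beta)
oracleHopfield <- function(memory, q, beta) {
  s <- beta * as.vector(memory %*% q)
  w <- exp(s - max(s))
  w <- w / sum(w)
  r <- colSums(memory * w)
  r / sqrt(sum(r^2))
}

# loop implementation of InfoLOOB on Hopfield-retrieved embeddings
oracleInfoloob <- function(X, Z, beta, tauInv) {
  N <- nrow(X)
  ret <- function(memory, q) oracleHopfield(memory, q, beta)
  Ux <- t(sapply(seq_len(N), function(i) ret(X, X[i, ])))
  Uz <- t(sapply(seq_len(N), function(i) ret(X, Z[i, ])))
  Vx <- t(sapply(seq_len(N), function(i) ret(Z, X[i, ])))
  Vz <- t(sapply(seq_len(N), function(i) ret(Z, Z[i, ])))
  t1 <- 0; t2 <- 0
  for (i in seq_len(N)) {
    den1 <- 0; den2 <- 0
    for (j in seq_len(N)) {
      if (j == i) next
      den1 <- den1 + exp(tauInv * sum(Ux[i, ] * Uz[j, ]))
      den2 <- den2 + exp(tauInv * sum(Vx[j, ] * Vz[i, ]))
    }
    t1 <- t1 + tauInv * sum(Ux[i, ] * Uz[i, ]) - log(den1)
    t2 <- t2 + tauInv * sum(Vx[i, ] * Vz[i, ]) - log(den2)
  }
  -t1 / N - t2 / N
}

# exact binomial tail inversion by root search (independent of qbeta)
oracleClopperPearson <- function(x, n, level = 0.95) {
  alpha <- 1 - level
  lower <- if (x == 0) 0 else
    uniroot(function(p) pbinom(x - 1, n, p, lower.tail = FALSE) - alpha / 2,
            c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  upper <- if (x == n) 1 else
    uniroot(function(p) pbinom(x, n, p) - alpha / 2,
            c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  c(lower, upper) * 100
}

# AUC by explicit positive/negative pair counting with midrank ties
oracleAuc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  s <- 0
  for (p in pos) for (q in neg)
    s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# latent decoding oracle: inverts the generator's blob rendering from the
# per-molecule mean image and matches molecules to fingerprints by latent
# correlation. Returns the number of correctly matched molecules.
oraclePairingRecovery <- function(ds, spec) {
  px <- pixelData(ds$images) / 65535
  meta <- imageMeta(ds$images)
  rend <- ds$truth$render
  H <- spec@height; W <- spec@width
  C <- spec@channels; L <- spec@latentDim
  xs <- matrix(rep(seq_len(W), each = H), H, W)
  ys <- matrix(rep(seq_len(H), W), H, W)
  nM <- spec@nMolecules
  dec <- matrix(NA_real_, nM, L)
  for (m in seq_len(nM)) {
    ids <- which(meta$molecule_id == sprintf("mol_%04d", m))
    mi <- apply(px[ids, , , , drop = FALSE], c(2, 3, 4), mean)
    for (cc in seq_len(C)) {
      j <- 3L * (cc - 1L)
      ch <- pmax(mi[cc, , ] - rend$background, 0)
      mass <- sum(ch)
      if (mass <= 0) next
      cx <- sum(ch * xs) / mass; cy <- sum(ch * ys) / mass
      s2 <- sum(ch * ((xs - cx)^2 + (ys - cy)^2)) / (2 * mass)
      if (j + 1 <= L) dec[m, j + 1] <- (cx - (W + 1) / 2) / (rend$shiftScale * W)
      if (j + 2 <= L) dec[m, j + 2] <- (cy - (H + 1) / 2) / (rend$shiftScale * H)
      jw <- 3L * C + cc
      sig2 <- if (jw <= L) s2 else rend$sigma^2
      if (jw <= L) dec[m, jw] <- log(sqrt(s2) / rend$sigma) / rend$widthScale
      if (j + 3 <= L) dec[m, j + 3] <- (mass / (2 * pi * sig2) - rend$ampBase) /
        rend$ampScale
    }
  }
  fps <- fingerprints(ds$molecules)
  fpLat <- (2 * fps - 1) %*% ds$truth$projection
  use <- which(colSums(!is.na(dec)) == nM)
  A <- scale(dec[, use, drop = FALSE]); B <- scale(fpLat[, use, drop = FALSE])
  S <- A %*% t(B)
  sum(apply(S, 1, which.max) == seq_len(nM))
}

# tiny deterministic spec used across tests; ... overrides any default
tinySpec <- function(...) {
  defaults <- list(nMolecules = 12L, viewsPerMolecule = 2L, latentDim = 6L,
                   channels = 3L, height = 8L, width = 8L, fpBits = 32L,
                   noiseSd = 0.1, nPlates = 3L, nMoaClasses = 4L, seed = 42L)
  do.call(syntheticSpec, utils::modifyList(defaults, list(...)))
}
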