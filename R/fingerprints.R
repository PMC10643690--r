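#' Morgan-style circular fingerprint of a molecule
#'
#' Extended-connectivity (circular) fingerprint: atoms start from an
#' invariant of (atomic number, heavy degree, charge, attached hydrogens,
#' ring membership, aromaticity, and — when `useChirality` — the tetrahedral
#' parity tag), and identifiers are iteratively rehashed with the sorted
#' (bond type, neighbour identifier) pairs over `radius` rounds. All
#' identifiers from all rounds are folded modulo `nBits` into a binary
#' vector. Input SMILES are canonicalized first, so kekulization variants of
#' the same molecule yield identical fingerprints.
#'
#' The hash is a deterministic 32-bit FNV-1a over the identifier stream;
#' fingerprints are reproducible across platforms and sessions but the
#' specific bit positions are not interchangeable with other toolkits'
#' circular fingerprints.
#'
#' @param smiles a SMILES string; unparseable input is rejected with the
#'   offending string in the error message.
#' @param radius neighbourhood radius in bonds (default 3).
#' @param nBits fingerprint length (default 1024).
#' @param useChirality include tetrahedral parity in atom invariants
#'   (default TRUE).
#' @return integer vector of 0/1 of length `nBits`.
#' @examples
#' fp <- morganFingerprint("CCO")
#' sum(fp)
#' @export
morganFingerprint <- function(smiles, radius = 3L, nBits = 1024L,
                              useChirality = TRUE) {
  mol <- parseSmiles(canonicalSmiles(smiles))
  foldBits(morganIdentifiers(mol, radius, useChirality), nBits)
}

# all circular identifiers (rounds 0..radius) of an annotated molecule
morganIdentifiers <- function(mol, radius, useChirality) {
  at <- mol$atoms; bd <- mol$bonds
  nA <- nrow(at)
  nbrs <- lapply(seq_len(nA), function(a) {
    k <- which(bd$a1 == a | bd$a2 == a)
    other <- ifelse(bd$a1[k] == a, bd$a2[k], bd$a1[k])
    code <- ifelse(bd$aromatic[k], 4, bd$order[k])
    list(other = other, code = code)
  })
  ids <- vapply(seq_len(nA), function(a) {
    inv <- c(at$atomicNum[a], at$degree[a], at$charge[a], at$nH[a],
             as.integer(at$inRing[a]), as.integer(at$aromatic[a]))
    if (useChirality) inv <- c(inv, at$chiral[a])
    hashIntVec(inv)
  }, numeric(1))
  all_ids <- ids
  if (radius >= 1L) for (r in seq_len(radius)) {
    newIds <- vapply(seq_len(nA), function(a) {
      nb <- nbrs[[a]]
      if (!length(nb$other)) return(hashIntVec(c(r, ids[a])))
      ord <- order(nb$code, ids[nb$other])
      hashIntVec(c(r, ids[a],
                   as.numeric(rbind(nb$code[ord], ids[nb$other][ord]))))
    }, numeric(1))
    ids <- newIds
    all_ids <- c(all_ids, ids)
  }
  all_ids
}

foldBits <- function(ids, nBits) {
  fp <- integer(nBits)
  fp[unique(as.integer(ids %% nBits)) + 1L] <- 1L
  fp
}

#' Linear-path count fingerprint
#'
#' Enumerates all simple linear atom-bond paths of 1 to `maxPath` bonds,
#' hashes each path in its canonical (lexicographically smaller) direction,
#' and folds the path counts modulo `nBits`. The count vector is the
#' topological analogue of count-based daylight-style fingerprints; it is
#' binarized (count >= 1) by [combinedFingerprint()].
#'
#' @inheritParams morganFingerprint
#' @param nBits folded length (default 8192).
#' @param maxPath maximum path length in bonds (default 5).
#' @return integer vector of length `nBits` with per-bit path counts.
#' @export
countFingerprint <- function(smiles, nBits = 8192L, maxPath = 5L) {
  mol <- parseSmiles(canonicalSmiles(smiles))
  ids <- pathIdentifiers(mol, maxPath)
  counts <- integer(nBits)
  if (length(ids)) {
    tab <- table(as.integer(ids %% nBits))
    # every path is enumerated once from each end
    counts[as.integer(names(tab)) + 1L] <- as.integer(tab) %/% 2L
  }
  counts
}

pathIdentifiers <- function(mol, maxPath) {
  at <- mol$atoms; bd <- mol$bonds
  nA <- nrow(at)
  if (!nrow(bd)) return(numeric(0))
  atomCode <- at$atomicNum * 10 + as.integer(at$aromatic)
  adj <- lapply(seq_len(nA), function(a) {
    k <- which(bd$a1 == a | bd$a2 == a)
    list(other = ifelse(bd$a1[k] == a, bd$a2[k], bd$a1[k]),
         code = ifelse(bd$aromatic[k], 4, bd$order[k]))
  })
  acc <- numeric(0)
  push <- function(id) acc <<- c(acc, id)
  walk <- function(path, codes, visited) {
    a <- path[length(path)]
    nb <- adj[[a]]
    for (t in seq_along(nb$other)) {
      b <- nb$other[t]
      if (visited[b]) next
      p2 <- c(path, b); c2 <- c(codes, nb$code[t])
      seqF <- as.numeric(rbind(atomCode[p2],
                               c(c2, 0)))[seq_len(2L * length(p2) - 1L)]
      seqR <- as.numeric(rbind(atomCode[rev(p2)],
                               c(rev(c2), 0)))[seq_len(2L * length(p2) - 1L)]
      canon <- if (isTRUE(all(seqF == seqR)) ||
                   lexLess(seqF, seqR)) seqF else seqR
      push(hashIntVec(c(length(c2), canon)))
      if (length(c2) < maxPath) {
        v2 <- visited; v2[b] <- TRUE
        walk(p2, c2, v2)
      }
    }
  }
  for (a in seq_len(nA)) {
    v <- rep(FALSE, nA); v[a] <- TRUE
    walk(a, numeric(0), v)
  }
  acc
}

lexLess <- function(x, y) {
  d <- which(x != y)
  if (!length(d)) FALSE else x[d[1]] < y[d[1]]
}

#' Combined Morgan + path-count fingerprint
#'
#' Element-wise maximum of the circular fingerprint folded to `nBits` and
#' the binarized (count >= 1) linear-path count fingerprint folded to
#' `nBits`: a bit is set if it is set in either source. This is the
#' 8192-bit molecule representation used for the retrieval objective.
#'
#' @inheritParams morganFingerprint
#' @param nBits final length (default 8192).
#' @return integer 0/1 vector of length `nBits`.
#' @export
combinedFingerprint <- function(smiles, nBits = 8192L, radius = 3L,
                                useChirality = TRUE) {
  m <- morganFingerprint(smiles, radius = radius, nBits = nBits,
                         useChirality = useChirality)
  p <- 1L * (countFingerprint(smiles, nBits = nBits) >= 1L)
  pmax(m, p)
}

#' Bemis-Murcko-style scaffold key
#'
#' Strips terminal atoms iteratively until only ring systems and their
#' linkers remain, then hashes the remaining subgraph (atom types,
#' aromaticity, bond orders) into a canonical key by iterative neighbourhood
#' refinement. Molecules sharing the same ring-and-linker framework receive
#' the same key; acyclic molecules all map to `"acyclic"`.
#'
#' @param smiles a SMILES string.
#' @return character scaffold key.
#' @export
scaffoldKey <- function(smiles) {
  mol <- parseSmiles(canonicalSmiles(smiles))
  at <- mol$atoms; bd <- mol$bonds
  if (!any(at$inRing)) return("acyclic")
  keep <- rep(TRUE, nrow(at))
  repeat {
    deg <- integer(nrow(at))
    for (k in seq_len(nrow(bd))) {
      if (keep[bd$a1[k]] && keep[bd$a2[k]]) {
        deg[bd$a1[k]] <- deg[bd$a1[k]] + 1L
        deg[bd$a2[k]] <- deg[bd$a2[k]] + 1L
      }
    }
    drop <- keep & deg <= 1L & !at$inRing
    if (!any(drop)) break
    keep[drop] <- FALSE
  }
  idx <- which(keep)
  remap <- match(seq_len(nrow(at)), idx)
  sb <- bd[keep[bd$a1] & keep[bd$a2], , drop = FALSE]
  ids <- vapply(idx, function(a) hashIntVec(
    c(at$atomicNum[a], as.integer(at$aromatic[a]))), numeric(1))
  nb <- lapply(seq_along(idx), function(i) {
    a <- idx[i]
    k <- which(sb$a1 == a | sb$a2 == a)
    list(other = remap[ifelse(sb$a1[k] == a, sb$a2[k], sb$a1[k])],
         code = ifelse(sb$aromatic[k], 4, sb$order[k]))
  })
  for (r in seq_len(max(1L, length(idx)))) {
    ids <- vapply(seq_along(idx), function(i) {
      o <- order(nb[[i]]$code, ids[nb[[i]]$other])
      hashIntVec(c(ids[i], as.numeric(rbind(nb[[i]]$code[o],
                                            ids[nb[[i]]$other][o]))))
    }, numeric(1))
  }
  sprintf("scaf_%08x", as.integer(
    hashIntVec(c(length(idx), nrow(sb), sort(ids))) %% 2^31))
}

#' Pack a binary fingerprint to a hex string (and back)
#'
#' @param fp integer 0/1 vector whose length is a multiple of 8.
#' @return `fpToHex`: hex string; `hexToFp`: integer 0/1 vector.
#' @export
fpToHex <- function(fp) {
  stopifnot(length(fp) %% 8L == 0L)
  paste(as.character(packBits(as.integer(fp) > 0L, "raw")), collapse = "")
}

#' @rdname fpToHex
#' @param hex hex string produced by `fpToHex`.
#' @export
hexToFp <- function(hex) {
  raw <- as.raw(strtoi(substring(hex, seq(1, nchar(hex), 2),
                                 seq(2, nchar(hex), 2)), 16L))
  as.integer(rawToBits(raw))
}
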