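# Minimal SMILES graph parser.
#
# Public fingerprint functions canonicalize input through OpenBabel first
# (see canonicalSmiles), so this parser only needs to handle the canonical
# dialect: organic-subset and bracket atoms, aromatic lowercase forms, ring
# closures (including %nn), branches, bond symbols -=#:$ and the stereo
# marks / \ (read as single bonds), '.'-separated components, charges,
# tetrahedral @/@@ tags and bracket H counts.

.ATOMIC_NUM <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, P = 15, S = 16,
                 Cl = 17, Br = 35, I = 53, Si = 14, Se = 34, As = 33)
.DEFAULT_VALENCE <- c(B = 3, C = 4, N = 3, O = 2, P = 3, S = 2,
                      F = 1, Cl = 1, Br = 1, I = 1)

#' Canonicalize a SMILES string
#'
#' Converts to OpenBabel canonical SMILES so that kekulization variants of
#' the same molecule map to one representation before any hashing.
#'
#' @param smiles a SMILES string.
#' @return canonical SMILES string.
#' @export
canonicalSmiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", smiles)),
    error = function(e) "")
  out <- sub("[\t\n ].*$", "", out)
  if (!nzchar(out)) stop("unparseable SMILES: ", smiles)
  out
}

# Parse a SMILES string into an atom/bond graph. Returns list(atoms, bonds):
# atoms: data.frame(elem, atomicNum, aromatic, charge, chiral, explicitH)
# bonds: data.frame(a1, a2, order, aromatic)
parseSmiles <- function(smiles) {
  chars <- strsplit(smiles, "")[[1]]
  n <- length(chars)
  atoms <- list(); bonds <- list()
  prev <- 0L; pendingBond <- NA_character_
  stack <- integer(0)
  ringOpen <- list()  # ring digit -> list(atom, bond)
  i <- 1L

  addAtom <- function(elem, aromatic, charge = 0L, chiral = 0L,
                      explicitH = NA_integer_) {
    atoms[[length(atoms) + 1L]] <<- list(
      elem = elem, aromatic = aromatic, charge = charge, chiral = chiral,
      explicitH = explicitH)
    length(atoms)
  }
  addBond <- function(a1, a2, sym) {
    if (is.na(sym)) {
      arom <- atoms[[a1]]$aromatic && atoms[[a2]]$aromatic
      ord <- 1
    } else {
      arom <- identical(sym, ":")
      ord <- switch(sym, "-" = 1, "/" = 1, "\\" = 1, "=" = 2, "#" = 3,
                    "$" = 4, ":" = 1, 1)
    }
    bonds[[length(bonds) + 1L]] <<- list(a1 = a1, a2 = a2, order = ord,
                                         aromatic = arom)
  }
  connect <- function(idx) {
    if (prev > 0L) addBond(prev, idx, pendingBond)
    pendingBond <<- NA_character_
    prev <<- idx
  }
  ringBond <- function(num) {
    key <- as.character(num)
    if (!is.null(ringOpen[[key]])) {
      op <- ringOpen[[key]]
      sym <- if (!is.na(pendingBond)) pendingBond else op$bond
      addBond(op$atom, prev, sym)
      ringOpen[[key]] <<- NULL
    } else {
      ringOpen[[key]] <- list(atom = prev, bond = pendingBond)
      ringOpen <<- ringOpen
    }
    pendingBond <<- NA_character_
  }

  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop("unclosed bracket atom in SMILES: ", smiles)
      body <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      m <- regmatches(body, regexec(
        "^([0-9]*)([A-Za-z][a-z]?|\\*)(@@|@)?(H[0-9]*)?([+-][0-9]*|[+]+|[-]+)?$",
        body))[[1]]
      if (!length(m)) stop("cannot parse bracket atom [", body, "]")
      sym <- m[3]
      aromatic <- sym == tolower(sym) && sym != "*"
      elem <- if (aromatic) paste0(toupper(substr(sym, 1, 1)),
                                   substring(sym, 2)) else sym
      chiral <- if (m[4] == "@") 1L else if (m[4] == "@@") 2L else 0L
      hc <- if (nzchar(m[5])) {
        if (m[5] == "H") 1L else as.integer(substring(m[5], 2))
      } else 0L
      charge <- if (nzchar(m[6])) {
        cs <- m[6]
        if (cs %in% c("+", "-")) as.integer(paste0(cs, "1"))
        else if (grepl("^[+]+$", cs)) nchar(cs)
        else if (grepl("^[-]+$", cs)) -nchar(cs)
        else as.integer(cs)
      } else 0L
      idx <- addAtom(elem, aromatic, charge, chiral, hc)
      connect(idx)
      i <- j + 1L
    } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      two <- if (i < n) paste0(ch, chars[i + 1L]) else ""
      if (two %in% c("Cl", "Br")) {
        idx <- addAtom(two, FALSE); i <- i + 2L
      } else {
        idx <- addAtom(ch, FALSE); i <- i + 1L
      }
      connect(idx)
    } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      idx <- addAtom(toupper(ch), TRUE)
      connect(idx)
      i <- i + 1L
    } else if (ch %in% c("-", "=", "#", "$", ":", "/", "\\")) {
      pendingBond <- ch; i <- i + 1L
    } else if (ch == "(") {
      stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      if (!length(stack)) stop("unbalanced parenthesis in SMILES: ", smiles)
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (grepl("[0-9]", ch)) {
      ringBond(as.integer(ch)); i <- i + 1L
    } else if (ch == "%") {
      ringBond(as.integer(paste(chars[(i + 1L):(i + 2L)], collapse = "")))
      i <- i + 3L
    } else if (ch == ".") {
      prev <- 0L; pendingBond <- NA_character_; i <- i + 1L
    } else {
      stop("unexpected character '", ch, "' in SMILES: ", smiles)
    }
  }
  if (length(ringOpen)) stop("unclosed ring bond in SMILES: ", smiles)
  if (!length(atoms)) stop("no atoms parsed from SMILES: ", smiles)

  at <- data.frame(
    elem = vapply(atoms, `[[`, "", "elem"),
    aromatic = vapply(atoms, `[[`, TRUE, "aromatic"),
    charge = vapply(atoms, function(a) as.integer(a$charge), 1L),
    chiral = vapply(atoms, function(a) as.integer(a$chiral), 1L),
    explicitH = vapply(atoms, function(a) as.integer(a$explicitH), 1L),
    stringsAsFactors = FALSE)
  at$atomicNum <- unname(.ATOMIC_NUM[at$elem])
  if (anyNA(at$atomicNum)) at$atomicNum[is.na(at$atomicNum)] <- 0
  bd <- if (length(bonds)) data.frame(
    a1 = vapply(bonds, function(b) as.integer(b$a1), 1L),
    a2 = vapply(bonds, function(b) as.integer(b$a2), 1L),
    order = vapply(bonds, `[[`, 1, "order"),
    aromatic = vapply(bonds, `[[`, TRUE, "aromatic"))
  else data.frame(a1 = integer(0), a2 = integer(0), order = numeric(0),
                  aromatic = logical(0))
  annotateMolecule(list(atoms = at, bonds = bd))
}

# Adds per-atom heavy degree, implicit H count and ring membership.
annotateMolecule <- function(mol) {
  at <- mol$atoms; bd <- mol$bonds
  nA <- nrow(at)
  deg <- integer(nA); bsum <- numeric(nA)
  for (k in seq_len(nrow(bd))) {
    o <- if (bd$aromatic[k]) 1.5 else bd$order[k]
    for (a in c(bd$a1[k], bd$a2[k])) {
      deg[a] <- deg[a] + 1L
      bsum[a] <- bsum[a] + o
    }
  }
  nH <- integer(nA)
  for (a in seq_len(nA)) {
    if (!is.na(at$explicitH[a])) { nH[a] <- at$explicitH[a]; next }
    dv <- .DEFAULT_VALENCE[at$elem[a]]
    nH[a] <- if (is.na(dv)) 0L else
      max(0L, as.integer(dv) - as.integer(ceiling(bsum[a] - 1e-9)))
  }
  inRing <- rep(FALSE, nA)
  if (nrow(bd)) {
    g <- igraph::graph_from_edgelist(cbind(bd$a1, bd$a2), directed = FALSE)
    if (igraph::vcount(g) < nA) g <- igraph::add_vertices(g, nA - igraph::vcount(g))
    br <- igraph::bridges(g)
    cyc <- setdiff(seq_len(nrow(bd)), as.integer(br))
    inRing[unique(c(bd$a1[cyc], bd$a2[cyc]))] <- TRUE
    mol$bonds$inRing <- seq_len(nrow(bd)) %in% cyc
  } else {
    mol$bonds$inRing <- logical(0)
  }
  mol$atoms$degree <- deg
  mol$atoms$nH <- nH
  mol$atoms$inRing <- inRing
  mol
}

# 32-bit FNV-1a hash of an integer vector, exact in double arithmetic.
hashIntVec <- function(ints) {
  h <- 2166136261
  for (v in ints) {
    v <- as.numeric(v) %% 4294967296
    for (shift in c(0, 8, 16, 24)) {
      byte <- floor(v / 2^shift) %% 256
      h <- mulmod32(bitxor32(h, byte), 16777619)
    }
  }
  h
}

bitxor32 <- function(a, b) {
  # xor of two non-negative doubles < 2^32 via 16-bit halves
  ah <- a %/% 65536; al <- a %% 65536
  bh <- b %/% 65536; bl <- b %% 65536
  bitwXor(as.integer(ah), as.integer(bh)) * 65536 +
    bitwXor(as.integer(al), as.integer(bl))
}

mulmod32 <- function(a, b) {
  # (a * b) mod 2^32 for 0 <= a < 2^32, 0 <= b < 2^25, exact in doubles
  ah <- a %/% 65536; al <- a %% 65536
  (((ah * b) %% 65536) * 65536 + al * b) %% 4294967296
}
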