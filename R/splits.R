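#' Assign molecules to train/validation/test splits
#'
#' Splits are always at the molecule level, so that every image view of a
#' molecule inherits the molecule's split. `"random_by_molecule"` shuffles
#' molecules by seed and partitions them into `round(cumsum(fractions) * n)`
#' sized blocks. `"scaffold"` groups molecules by `scaffold_key` and assigns
#' whole groups, largest first, greedily to the split with the largest
#' remaining deficit relative to its target fraction, so molecules sharing a
#' scaffold are never separated.
#'
#' @param molecules a [MoleculeSet-class], or a data.frame with
#'   `molecule_id` (and `scaffold_key` for scaffold mode), or a character
#'   vector of molecule ids.
#' @param mode `"random_by_molecule"` or `"scaffold"`.
#' @param fractions length-3 numeric summing to 1: train, valid, test.
#' @param seed integer seed; splits are deterministic under a fixed seed and
#'   invariant to the input ordering of molecules.
#' @return data.frame with columns `molecule_id` and `split` (factor with
#'   levels train/valid/test).
#' @examples
#' makeSplit(sprintf("m%02d", 1:10), "random_by_molecule", seed = 1)
#' @export
makeSplit <- function(molecules, mode = c("random_by_molecule", "scaffold"),
                      fractions = c(0.7, 0.1, 0.2), seed = 1L) {
  mode <- match.arg(mode)
  if (is(molecules, "MoleculeSet")) molecules <- moleculeMeta(molecules)
  if (is.character(molecules))
    molecules <- data.frame(molecule_id = molecules, stringsAsFactors = FALSE)
  stopifnot(is.data.frame(molecules), "molecule_id" %in% names(molecules))
  if (abs(sum(fractions) - 1) > 1e-8 || length(fractions) != 3L)
    stop("fractions must be three values summing to 1")
  n <- nrow(molecules)
  if (n < sum(fractions > 0)) stop("fewer molecules than non-empty sets")
  # order-invariance: canonicalize input order before seeding
  ord <- order(molecules$molecule_id)
  molecules <- molecules[ord, , drop = FALSE]
  levels <- c("train", "valid", "test")

  old <- globalRNGState()
  on.exit(restoreRNGState(old), add = TRUE)
  set.seed(seed)

  if (mode == "random_by_molecule") {
    perm <- sample.int(n)
    bounds <- round(cumsum(fractions) * n)
    sizes <- diff(c(0L, bounds))
    split <- rep(levels, times = sizes)
    out <- data.frame(molecule_id = molecules$molecule_id[perm],
                      split = factor(split, levels = levels),
                      stringsAsFactors = FALSE)
  } else {
    if (!"scaffold_key" %in% names(molecules))
      stop("scaffold mode requires a scaffold_key column")
    groups <- split(molecules$molecule_id, molecules$scaffold_key)
    # shuffle to break ties among equal-sized groups, then largest first
    groups <- groups[sample.int(length(groups))]
    groups <- groups[order(-vapply(groups, length, 1L))]
    target <- fractions * n
    got <- numeric(3)
    assignment <- character(0)
    gnames <- character(0)
    for (gi in seq_along(groups)) {
      deficit <- target - got
      pick <- which.max(deficit)
      got[pick] <- got[pick] + length(groups[[gi]])
      assignment <- c(assignment, rep(levels[pick], length(groups[[gi]])))
      gnames <- c(gnames, groups[[gi]])
    }
    out <- data.frame(molecule_id = gnames,
                      split = factor(assignment, levels = levels),
                      stringsAsFactors = FALSE)
  }
  out[order(out$molecule_id), , drop = FALSE]
}

#' Write / read a split assignment as a JSON manifest
#' @param split data.frame from [makeSplit()].
#' @param path output JSON file.
#' @export
writeSplit <- function(split, path) {
  jsonlite::write_json(split(as.character(split$molecule_id), split$split),
                       path, pretty = TRUE)
  invisible(path)
}

#' @rdname writeSplit
#' @export
readSplit <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- data.frame(
    molecule_id = unlist(x, use.names = FALSE),
    split = factor(rep(names(x), vapply(x, length, 1L)),
                   levels = c("train", "valid", "test")),
    stringsAsFactors = FALSE)
  out[order(out$molecule_id), , drop = FALSE]
}
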