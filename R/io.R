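# Disk formats: multi-page TIFF per view (channels as pages, 16- or 8-bit),
# CSV for molecules (fingerprints hex-packed), pairing and labels, JSON for
# split manifests and run manifests.

#' Write a paired dataset to a directory
#'
#' Layout: `images/<image_id>.tif` (one multi-page TIFF per view, one page
#' per channel), `image_meta.csv`, `molecules.csv` (fingerprints packed as
#' hex), `pairing.csv`, and optionally `labels.csv`.
#'
#' @param dataset list from [generatePairedDataset()].
#' @param dir output directory (created if missing).
#' @param labels optional label matrix from [generateLabelMatrix()].
#' @return invisibly, `dir`.
#' @export
writePairedDataset <- function(dataset, dir, labels = NULL) {
  imgDir <- file.path(dir, "images")
  if (!dir.exists(imgDir)) dir.create(imgDir, recursive = TRUE)
  images <- dataset$images
  px <- pixelData(images)
  meta <- imageMeta(images)
  scale <- 2^images@bitDepth - 1
  bps <- images@bitDepth
  for (i in seq_len(nrow(meta))) {
    # channels-last convention at the file boundary: one page per channel
    pages <- lapply(seq_len(dim(px)[2L]), function(cc) px[i, cc, , ] / scale)
    tiff::writeTIFF(pages, file.path(imgDir, paste0(meta$image_id[i], ".tif")),
                    bits.per.sample = bps)
  }
  write.csv(meta, file.path(dir, "image_meta.csv"), row.names = FALSE)
  mm <- moleculeMeta(dataset$molecules)
  fps <- fingerprints(dataset$molecules)
  mm$fingerprint_hex <- apply(fps, 1, fpToHex)
  mm$fp_bits <- ncol(fps)
  write.csv(mm, file.path(dir, "molecules.csv"), row.names = FALSE)
  write.csv(dataset$pairing, file.path(dir, "pairing.csv"), row.names = FALSE)
  if (!is.null(labels)) {
    lab <- data.frame(molecule_id = rownames(labels), labels,
                      check.names = FALSE)
    write.csv(lab, file.path(dir, "labels.csv"), row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname writePairedDataset
#' @return `readPairedDataset`: list with `images`, `molecules`, `pairing`
#'   and (when present) `labels`.
#' @export
readPairedDataset <- function(dir) {
  meta <- read.csv(file.path(dir, "image_meta.csv"),
                   colClasses = "character")
  meta$view_index <- as.integer(meta$view_index)
  first <- tiff::readTIFF(file.path(dir, "images",
                                    paste0(meta$image_id[1], ".tif")),
                          all = TRUE, as.is = TRUE)
  C <- length(first); H <- nrow(first[[1]]); W <- ncol(first[[1]])
  bitDepth <- if (max(unlist(first)) > 255 ||
                  attr(first[[1]], "bits.per.sample") %||% 16L > 8L) 16L else 8L
  px <- array(0, dim = c(nrow(meta), C, H, W))
  for (i in seq_len(nrow(meta))) {
    pages <- tiff::readTIFF(file.path(dir, "images",
                                      paste0(meta$image_id[i], ".tif")),
                            all = TRUE, as.is = TRUE)
    for (cc in seq_len(C)) px[i, cc, , ] <- pages[[cc]]
  }
  images <- new("BioimageSet", pixels = px, bitDepth = bitDepth, meta = meta)
  mm <- read.csv(file.path(dir, "molecules.csv"), colClasses = "character")
  fps <- t(vapply(mm$fingerprint_hex, hexToFp,
                  integer(as.integer(mm$fp_bits[1]))))
  rownames(fps) <- mm$molecule_id
  keep <- setdiff(names(mm), c("fingerprint_hex", "fp_bits"))
  molecules <- new("MoleculeSet", meta = mm[, keep, drop = FALSE],
                   fingerprints = fps)
  out <- list(images = images, molecules = molecules,
              pairing = read.csv(file.path(dir, "pairing.csv"),
                                 colClasses = "character"))
  labPath <- file.path(dir, "labels.csv")
  if (file.exists(labPath)) {
    lab <- read.csv(labPath, check.names = FALSE)
    m <- as.matrix(lab[, -1, drop = FALSE])
    rownames(m) <- lab$molecule_id
    out$labels <- m
  }
  out
}

#' Read molecules from CSV or SDF
#'
#' CSV input needs `molecule_id` and `smiles` columns. SDF input is
#' converted through OpenBabel; molecule ids come from the SDF title lines
#' (falling back to `mol_<n>` for unnamed records) and the SMILES are
#' canonical.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"csv"` or `"sdf"`.
#' @return data.frame with columns `molecule_id`, `smiles`.
#' @export
readMolecules <- function(path, format = c("auto", "csv", "sdf")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.sdf$", path, ignore.case = TRUE)) "sdf" else "csv"
  if (format == "csv") {
    df <- read.csv(path, colClasses = "character")
    stopifnot(all(c("molecule_id", "smiles") %in% names(df)))
    return(df[, c("molecule_id", "smiles")])
  }
  txt <- paste(readLines(path), collapse = "\n")
  out <- ChemmineOB::convertFormat("SDF", "CAN", txt)
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("no molecules parsed from SDF: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  smiles <- vapply(parts, `[`, "", 1)
  ids <- vapply(seq_along(parts), function(i) {
    nm <- if (length(parts[[i]]) > 1) trimws(parts[[i]][2]) else ""
    if (nzchar(nm)) nm else sprintf("mol_%04d", i)
  }, "")
  data.frame(molecule_id = ids, smiles = smiles, stringsAsFactors = FALSE)
}

#' Write / read an embedding matrix as CSV
#'
#' First column `id`, remaining columns the embedding coordinates.
#'
#' @param emb an [EmbeddingMatrix-class].
#' @param path CSV path.
#' @export
writeEmbeddings <- function(emb, path) {
  df <- data.frame(id = embIds(emb), embVectors(emb), check.names = FALSE)
  colnames(df)[-1] <- sprintf("d%03d", seq_len(ncol(df) - 1L))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEmbeddings
#' @export
readEmbeddings <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  embeddingMatrix(m, ids = as.character(df$id), normalize = FALSE)
}

#' Write a run manifest
#'
#' Every pipeline command records exactly one manifest: the command, its
#' configuration snapshot, seed, input file hashes, output paths and
#' timestamps. Identical manifests imply identical outputs.
#'
#' @param path output JSON path.
#' @param command command name.
#' @param config configuration list snapshot.
#' @param seed integer seed.
#' @param inputs character vector of input files (hashed with md5).
#' @param outputs character vector of output paths.
#' @return invisibly, the manifest list.
#' @export
writeManifest <- function(path, command, config, seed, inputs = character(0),
                          outputs = character(0)) {
  manifest <- list(
    command = command, config = config, seed = seed,
    input_hashes = as.list(tools::md5sum(inputs[file.exists(inputs)])),
    outputs = outputs,
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
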