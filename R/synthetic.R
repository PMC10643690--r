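#' Generate a paired image/fingerprint dataset with shared latent structure
#'
#' Draws one latent vector per molecule and derives both modalities from it.
#' The fingerprint is a deterministic thresholded random sign-projection of
#' the latent (binary, linearly decodable, Morgan-bit-like). Each image view
#' renders the latent as one Gaussian blob per channel whose centre offset
#' and amplitude are affine functions of three latent coordinates and whose
#' log-width reads a fourth (coordinates beyond `4 * channels`, if any,
#' influence only the fingerprint). View-to-view variability enters through
#' the blob parameters: each view renders `latent + noiseSd * N(0, I)`, so
#' the blob intensities and positions encode the latent plus Gaussian
#' noise, and `noiseSd = 0` makes all views of a molecule identical.
#' Pixels are quantized to 16-bit. Plates are assigned round-robin over
#' molecules with views alternating between two adjacent plates, so with
#' three or more views same-molecule/same-plate collisions exist
#' (exercising plate-effect filtering) while each molecule spans two
#' plates. A
#' mechanism-of-action-style class is attached to each molecule as its
#' k-means cluster index in latent space.
#'
#' All randomness flows through a single generator seeded by `spec@seed`;
#' identical specs produce bit-identical output.
#'
#' @param spec a [SyntheticSpec-class].
#' @return list with elements `images` ([BioimageSet-class]), `molecules`
#'   ([MoleculeSet-class]), `pairing` (data.frame `image_id`, `molecule_id`;
#'   a bijection between view ids and their molecule, many views per
#'   molecule), and `truth` (generator ground truth for validation:
#'   `latents`, `projection`, `render` parameters).
#' @examples
#' ds <- generatePairedDataset(syntheticSpec(nMolecules = 5,
#'   viewsPerMolecule = 2, seed = 7))
#' ds$images
#' @export
generatePairedDataset <- function(spec) {
  stopifnot(is(spec, "SyntheticSpec"))
  validObject(spec)
  nM <- spec@nMolecules; nV <- spec@viewsPerMolecule
  C <- spec@channels; H <- spec@height; W <- spec@width
  L <- spec@latentDim

  old <- globalRNGState()
  on.exit(restoreRNGState(old), add = TRUE)
  set.seed(spec@seed)

  latents <- matrix(rnorm(nM * L), nM, L)
  projection <- matrix(sample(c(-1, 1), spec@fpBits * L, replace = TRUE),
                       spec@fpBits, L)
  fps <- t(1L * (projection %*% t(latents) > 0))  # nM x fpBits, integer 0/1
  moleculeIds <- sprintf("mol_%04d", seq_len(nM))
  rownames(fps) <- moleculeIds

  # fixed rendering geometry: channel c reads latent coords 3c-2, 3c-1
  # (centre offsets) and 3c (amplitude); coordinates beyond 3*channels are
  # encoded as per-channel blob widths (coord 3C+c modulates channel c), so
  # up to 4*channels latent coordinates are visible in the pixels
  sigma <- 0.16 * min(H, W)
  shiftScale <- 0.12; widthScale <- 0.15
  ampBase <- 0.6; ampScale <- 0.2; background <- 0.08
  xs <- matrix(rep(seq_len(W), each = H), H, W)
  ys <- matrix(rep(seq_len(H), W), H, W)

  k <- min(spec@nMoaClasses, nM)
  moa <- if (k >= nM) seq_len(nM) else
    kmeans(latents, centers = k, nstart = 5, iter.max = 50)$cluster

  nImg <- nM * nV
  pixels <- array(0, dim = c(nImg, C, H, W))
  meta <- data.frame(
    image_id = character(nImg), plate_id = character(nImg),
    well_id = character(nImg), view_index = integer(nImg),
    molecule_id = character(nImg), stringsAsFactors = FALSE)

  renderLatent <- function(l) {
    out <- array(0, dim = c(C, H, W))
    for (cc in seq_len(C)) {
      j <- 3L * (cc - 1L)
      dx <- if (j + 1L <= L) shiftScale * W * l[j + 1L] else 0
      dy <- if (j + 2L <= L) shiftScale * H * l[j + 2L] else 0
      amp <- if (j + 3L <= L) ampBase + ampScale * l[j + 3L] else ampBase
      amp <- min(max(amp, 0.1), 1)
      jw <- 3L * C + cc
      sig <- if (jw <= L) sigma * exp(widthScale * l[jw]) else sigma
      cx <- (W + 1) / 2 + dx; cy <- (H + 1) / 2 + dy
      out[cc, , ] <- background +
        amp * exp(-((xs - cx)^2 + (ys - cy)^2) / (2 * sig^2))
    }
    out
  }

  idx <- 0L
  for (m in seq_len(nM)) {
    l <- latents[m, ]
    for (v in seq_len(nV)) {
      idx <- idx + 1L
      f <- renderLatent(l + spec@noiseSd * rnorm(L))
      f <- pmin(pmax(f, 0), 1)
      pixels[idx, , , ] <- round(f * 65535)
      plate <- ((m - 1L) + (v - 1L) %% 2L) %% spec@nPlates + 1L
      meta$image_id[idx] <- sprintf("img_%04d_v%d", m, v)
      meta$plate_id[idx] <- sprintf("plate_%02d", plate)
      meta$well_id[idx] <- sprintf("well_%03d", (m - 1L) %/% spec@nPlates + 1L)
      meta$view_index[idx] <- v
      meta$molecule_id[idx] <- moleculeIds[m]
    }
  }

  images <- new("BioimageSet", pixels = pixels, bitDepth = 16L, meta = meta)
  molMeta <- data.frame(molecule_id = moleculeIds,
                        smiles = sprintf("synthetic:%s", moleculeIds),
                        moa = sprintf("moa_%02d", moa),
                        stringsAsFactors = FALSE)
  molecules <- new("MoleculeSet", meta = molMeta, fingerprints = fps)
  pairing <- meta[, c("image_id", "molecule_id")]

  list(images = images, molecules = molecules, pairing = pairing,
       truth = list(latents = `rownames<-`(latents, moleculeIds),
                    projection = projection,
                    render = list(sigma = sigma, shiftScale = shiftScale,
                                  widthScale = widthScale, ampBase = ampBase,
                                  ampScale = ampScale,
                                  background = background)))
}

#' Generate a sparse binary activity-label matrix from molecule latents
#'
#' Each task t draws a random direction w_t in latent space; the label of
#' molecule m is `1(latent_m . w_t > 0)`, flipped with probability
#' `labelFlip`, so a linear probe on informative features can exceed chance
#' while noisy labels bound its ceiling. Entries are observed independently
#' with probability `sparsity`; unobserved entries are `NA`.
#'
#' @param dataset output of [generatePairedDataset()] (or any list with a
#'   `truth$latents` matrix whose rownames are molecule ids).
#' @param nTasks number of binary tasks (> 0).
#' @param sparsity fraction of observed entries, in (0, 1]; 1 means no
#'   missing entries.
#' @param labelFlip label-noise flip probability (default 0.05).
#' @param seed integer seed.
#' @return molecules x tasks matrix of 0/1/NA, with molecule ids as rownames
#'   and task ids as colnames.
#' @export
generateLabelMatrix <- function(dataset, nTasks, sparsity = 0.9,
                                labelFlip = 0.05, seed = 1L) {
  latents <- dataset$truth$latents
  stopifnot(is.matrix(latents))
  if (nTasks < 1L) stop("nTasks must be >= 1")
  if (sparsity <= 0 || sparsity > 1) stop("sparsity must be in (0, 1]")
  if (labelFlip < 0 || labelFlip > 0.5) stop("labelFlip must be in [0, 0.5]")
  old <- globalRNGState()
  on.exit(restoreRNGState(old), add = TRUE)
  set.seed(seed)
  nM <- nrow(latents); L <- ncol(latents)
  Wt <- matrix(rnorm(L * nTasks), L, nTasks)
  y <- 1 * (latents %*% Wt > 0)
  flip <- matrix(runif(nM * nTasks) < labelFlip, nM, nTasks)
  y[flip] <- 1 - y[flip]
  if (sparsity < 1) y[matrix(runif(nM * nTasks) >= sparsity, nM, nTasks)] <- NA
  dimnames(y) <- list(rownames(latents), sprintf("task_%03d", seq_len(nTasks)))
  y
}

# Save/restore the caller's RNG state so generator seeding stays local.
globalRNGState <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

restoreRNGState <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
  invisible(NULL)
}
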