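---
title: "Contrastive co-embedding of microscopy images and chemical structures"
author: "phenomol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contrastive co-embedding of microscopy images and chemical structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

High-throughput phenotypic screens image cells perturbed by small
molecules: the Cell-Painting protocol yields five-channel fluorescence
views of each treated well. Each image is therefore *paired* with the
chemical structure that produced it. phenomol learns a joint embedding
space for the two modalities, so that an image can query a chemical
database (which molecule could cause this phenotype?) and a molecule can
query an image database (what does this compound do to cells?). The same
frozen image representations transfer to downstream tasks: bio-activity
prediction by linear probing, and zero-shot classification of unseen
molecules or mechanisms of action.

## Model

An image encoder $h^x$ and a structure encoder $h^z$ map an image $x_n$
and a molecule $z_n$ to embeddings $\mathbf{x}_n = h^x(x_n)$,
$\mathbf{z}_n = h^z(z_n)$, both normalized to
$\lVert\mathbf{x}_n\rVert = \lVert\mathbf{z}_n\rVert = 1$ in a shared
$d$-dimensional space. Training contrasts matched pairs against
un-matched in-batch pairs.

**InfoNCE** (the CLIP-style objective) is the symmetric cross-entropy of
the scaled similarity matrix $S_{ij} = \tau^{-1}\mathbf{x}_i^\top\mathbf{z}_j$:

$$
\mathcal{L}_{\mathrm{NCE}}
 = -\tfrac1N \sum_i \ln
   \frac{e^{S_{ii}}}{\sum_j e^{S_{ij}}}
   -\tfrac1N \sum_i \ln
   \frac{e^{S_{ii}}}{\sum_j e^{S_{ji}}}.
$$

**Hopfield retrieval.** A continuous modern Hopfield network with stored
patterns $\mathbf{U}$ returns, for query $\mathbf{q}$, the softmax-weighted
pattern combination
$\mathbf{U}\,\mathrm{softmax}(\beta\,\mathbf{U}^\top\mathbf{q})$,
renormalized to unit length. $\beta = 0$ retrieves the normalized memory
mean for every query; $\beta \to \infty$ retrieves the stored pattern
most similar to the query. By default the memory is the current
mini-batch ($\mathbf{U} = \mathbf{X}$, $\mathbf{V} = \mathbf{Z}$).

**InfoLOOB** (the CLOOB-style objective) evaluates a leave-one-out bound
on the four retrievals $\mathbf{U}_{x_i}, \mathbf{U}_{z_i},
\mathbf{V}_{x_i}, \mathbf{V}_{z_i}$; its denominators exclude the
matched pair ($j \ne i$), which prevents the saturation that makes
InfoNCE under-use the covariance structure of the data. Both objectives
are exposed as pure functions (`infonceLoss`, `infoloobLoss`,
`hopfieldRetrieve`) with analytic gradients used by the trainer; the
gradients are verified against finite differences in the test suite.

**Encoders.** The structure encoder is a fully-connected network on
binary fingerprints (reference configuration: four hidden layers of 1024
units, ReLU, batch normalization; projection to $d = 512$). The image
encoder belongs to the residual-network family; at the 16×16-pixel desk
scale used throughout this package a convolutional trunk has no spatial
hierarchy to exploit, so the package implements the family's dense
variant — flattened pixels, a linear trunk stage with batch norm and
ReLU, optional residual blocks (identity skip around a
dense–BN–ReLU–dense–BN stack), projection, and an explicit
row-normalization layer. The activation entering the final projection is
exposed as the penultimate feature vector for linear probing. Desk-scale
default: no residual blocks and a 64-unit trunk — at this input size
deeper trunks measurably *hurt* both retrieval and probing (see
"Problem sizes" below), consistent with the small information content of
a 16×16 blob image; residual depth remains available through
`encoderConfig(imageBlocks = ...)` for larger inputs.

**Optimization.** Adam with decoupled weight decay (0.1, applied to
dense weight matrices only), batch size 256 by default (128 in the desk
study), cosine-annealed learning rate with linear warm-up and hard
restarts. The reference schedule warms up for 20,000 steps and restarts
every 7 epochs over a ~63-epoch run (about nine cycles); both constants
assume thousands of steps per epoch, so for desk runs the warm-up is
auto-scaled to a tenth of the step budget and the restart period never
drops below a ninth of it. The base learning rate is not part of the
reference protocol's printed configuration; the package default is
1e-3, chosen once as a standard Adam setting for networks of this size.

## Preprocessing and featurization

* `convert16to8`: per channel, values above the (1 − 0.0028%) quantile
  (order-statistic convention) are clipped, then min–max rescaled to
  0–255. The clip is computed per image and per channel; a zero-range
  channel maps to full scale. The map is monotone.
* `normalizeImages`: per-channel standardization with statistics from
  the training split only.
* `cropPolicy`: 520×520 random (train) or centre (eval) crops for the
  retrieval regime; crop-then-rescale to 320×320 (bilinear, via EBImage)
  for the activity regime.
* `morganFingerprint`: circular (ECFP-style) hashing, radius 3, 1024
  bits, tetrahedral chirality in the atom invariants. SMILES are
  canonicalized through OpenBabel first, so kekulization variants hash
  identically. The hash is a 32-bit FNV-1a; bit positions are
  reproducible across platforms but not interchangeable with other
  toolkits.
* `combinedFingerprint`: element-wise max of the circular fingerprint
  folded to 8192 bits and a binarized (count ≥ 1) linear-path count
  fingerprint folded to the same 8192-bit space — the "either source
  sets the bit" convention.
* `makeSplit`: molecule-grouped random splits, or scaffold splits that
  assign whole Bemis–Murcko-style scaffold groups greedily (largest
  first, to the split with the largest remaining deficit).
* `standardizeFeatureTable`: drops non-numeric and zero-variance columns
  from externally supplied feature tables, then standardizes by
  training-split statistics.

## The synthetic-data generator

`generatePairedDataset` emulates the *structure* of a phenotypic
screen: a latent vector per molecule (unit-variance coordinates), a
deterministic binary fingerprint (random ±1 projection of the latent,
thresholded at 0 — binary like Morgan bits and linearly decodable), and
image views that render the latent as one Gaussian blob per channel.
Blob centre (two coordinates), amplitude (one) and log-width (one) are
affine in latent coordinates, so a 5-channel view can carry up to 20
latent dimensions; the default 16 are all visible in the pixels.
View-to-view variability enters through the blob parameters: each view
renders `latent + noiseSd · N(0, I)`. `noiseSd` is therefore a
mutual-information knob — at 0, views of a molecule are identical; as it
grows, cross-modal decoding degrades to chance (a property the tests
verify with an independent blob-inversion oracle). Plates are assigned
round-robin over molecules with views alternating between two adjacent
plates, so same-molecule/same-plate collisions exist (plate filtering is
exercised) without confining a molecule to one plate. A
mechanism-of-action-style class is the k-means cluster index of the
latent. One seed drives a single RNG stream; output is bit-identical
under a fixed seed.

What it does **not** emulate: cell morphology, segmentation artifacts,
illumination gradients, batch effects beyond plate ids, correlated
channel noise, or realistic chemistry (the SMILES field is a
placeholder; real SMILES enter only through the fingerprint functions).
Passing the end-to-end tests therefore demonstrates that the training
and evaluation machinery recovers a planted cross-modal signal — not
that the method reaches any particular accuracy on real screens.

`generateLabelMatrix` derives sparse binary tasks from the same latents:
labels are the sign of a random latent projection, flipped with
probability `labelFlip` (default 0.05), observed with probability
`sparsity`. A 10% flip rate caps a perfect predictor's expected AUC at
exactly 0.81 + 2·0.09·0.5 = 0.90; the 5% default leaves headroom (~0.95)
so that probe quality reflects the features rather than the label noise.

## Desk-scale study protocol

`runContrastiveStudy` is the package's end-to-end experiment, also run
by `scripts/acceptance.R`:

| quantity | value |
|---|---|
| molecules × views | 500 × 4 (2,000 pairs) |
| image geometry | 5 × 16 × 16, 16-bit |
| latent dimension | 16; fingerprint 256 bits |
| view noise | 0.3 (latent scale) |
| split | 50% train / 10% valid / 40% test (molecule-grouped) |
| encoders | d = 64; image trunk 64 units, no residual blocks; structure 256-256 |
| training | InfoNCE, τ⁻¹ = 14.3, batch 128, 1,000 steps |
| retrieval eval | 200 held-out molecules, one view each (chance 0.5%) |
| zero-shot eval | one reference view per held-out molecule, plate-filtered queries |
| probing | 12 latent-derived tasks, 90% observed, λ ∈ 10^(−6..6), 70/10/20 |

The 40% test fraction gives exactly 200 held-out molecules so the
retrieval benchmark has the intended 0.5% chance level; the training
split still sees 1,000 image–fingerprint pairs. These sizes were chosen
so the whole study, including preprocessing and evaluation, completes in
a few minutes on one CPU while leaving the learning signal far above
chance.

## Numerical choices

* All log-sum-exp computations subtract the row/column maximum, so both
  losses are finite for any finite input, including τ⁻¹ = 30 and large β.
* Ranking ties (identical similarities) break by candidate index —
  deterministic, and documented in `rankMatched`.
* Clopper–Pearson intervals use the beta-quantile formulation with the
  conventional endpoints at 0 and 100%.
* AUC uses the Mann–Whitney rank statistic with midrank ties.
* F1 is computed at probability threshold 0.5 (the reference protocol
  does not state a threshold; this is the package's assumption).
* Batch normalization uses population statistics within a batch and
  running averages (momentum 0.1) in eval mode, making eval-mode
  encoders pure functions of (input, weights).
* The probe's λ is chosen on validation AUC; ties prefer the larger λ.
* Zero-shot softmax scores use temperature 1; top-k hits are judged on
  the raw similarity order.

## Known limitations

* The image encoder is a dense residual network on flattened pixels;
  convolutional backbones for realistic image sizes are out of scope of
  this desk-scale implementation (the module interface does not change).
* Hopfield memories larger than the current batch are an interface stub:
  `hopfieldRetrieve` accepts any memory, but the trainer always stores
  the current mini-batch.
* Fingerprint bit positions are internally consistent but not
  interchangeable with other toolkits' implementations of circular
  fingerprints.
* Linear probing of penultimate features at desk scale sits well below
  the information ceiling of the synthetic data (see the acceptance
  report): with a thousand training images, the contrastively trained
  trunk encodes the planted latent only approximately, which is the
  expected small-data behaviour of the method, not a harness defect —
  the same probe on the generator's own latents or raw fingerprints
  exceeds 0.93 AUC.
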