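---
title: "Masked graph-attention embeddings for spatial transcriptomics: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Masked graph-attention embeddings for spatial transcriptomics: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stgmae)
```

## The problem and the model

A spatial transcriptomics experiment yields a nonnegative spot-by-gene
matrix $X \in \mathbb{R}^{N \times d_{in}}$ and a planar position per spot.
Spot profiles are noisy — dropouts zero out real signal — and spatial
domains (cortical layers, tumor compartments) are defined jointly by
expression *and* geometry. `stgmae` addresses both with a self-supervised
graph autoencoder: the network must reconstruct each spot's profile from
corrupted inputs using its spatial neighborhood, so the embedding it learns
is simultaneously denoised and spatially coherent.

**Graph.** The spatial neighbor graph is binary and symmetric. For lattice
platforms each spot links to all spots within the minimal radius covering
its $k = 6$ nearest neighbors — on a hexagonal lattice, the 6-ring exactly.
For irregular (single-cell resolution) platforms a fixed radius rule
(`build_sng_radius`) is available. Stored graphs carry no self-loops; the
model adds the self edge at aggregation time so every neighborhood $N_i$
contains $i$.

**Corruption.** Each epoch draws a fresh plan: $\lfloor 0.5N \rfloor$ spots
are masked; $\lfloor 0.05 \cdot |\tilde V| \rfloor$ of those receive the
profile of a uniformly drawn global spot, the rest the learnable input
token $x_{[M]}$; kept spots are untouched. Before each of the two decoding
passes, 50% of the latent rows (drawn uniformly, independent of the input
mask) are overwritten with a second learnable token $h_{[M]}$. The
replacement fraction is set to 0 for microenvironment-heterogeneity runs,
where attention weights — not reconstructions — are the object of interest.

**Network.** Attention layers score each directed neighbor pair as
$e_{ij} = v^\top \sigma(W_0 h_i + W_1 h_j)$ (sigmoid *inside* the scoring
product, so the ranking of neighbors can change per query node — dynamic
rather than static attention), normalize with a per-node softmax
(max-subtraction stabilized), and aggregate
$h_i' = \mathrm{ELU}(\sum_{j \in N_i} att_{ij}\, W_0 h_j)$. The final
encoder layer and the final decoder step aggregate the plain neighbor sum
without attention, exactly as the layer equations state — no degree
normalization, no bias terms, ELU with $\alpha = 1$. The decoder owns no
weights: layer $k$ applies $W_0^{(k)\top}$ and reuses the encoder's
attention $att^{(k-1)}$ verbatim. The "two decoders" of the dual-view
scheme are therefore two invocations of one tied decoder on two different
remaskings. $W_1$ enters only the attention score, never the message — the
layer equations are implemented as printed.

**Loss.** The scaled cosine error
$\mathrm{mean}_i (1 - \cos(x_i, z_i))^\gamma$ is applied twice: view 0 is
scored only on masked spots, view 1 only on kept spots, and an explicit
$WD \sum \lVert W \rVert_2^2$ penalty covers all $W_0$/$W_1$ matrices
across layers (the two weight *families*, which is how we read the
two-term sum in the loss definition). Since both an explicit L2 loss term
and an optimizer weight-decay of the same size would penalize the weights
twice, the explicit term lives in the loss and the Adam update applies no
internal decay; both knobs exist in the code.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `dims` | `c(512, 30)` | encoder widths; the 30-dim latent is what downstream tools consume |
| `mask_ratio` | 0.5 | fraction of spots masked per epoch |
| `replace_ratio` | 0.05 | fraction of masked spots given random profiles (0 for heterogeneity runs) |
| `remask_ratio` | 0.5 | latent rows re-corrupted per decoding view |
| `gamma` | 2 | cosine-error exponent; values in $[1,3]$, larger for complex tissues |
| `lr`, `weight_decay` | 0.001, 0.001 | Adam step size and explicit L2 coefficient |
| `epochs` | 500 | no early stopping; the loss log is stored on the fit |
| `k`, `k_cross` | 6, 7 | within-slice and adjacent-slice covering-neighbor counts |

Counts are rounded with `floor(ratio * N)` — deterministic, and erring
toward under-masking. `gamma = 2` is the midpoint of the conventional
range; it is exposed per fit because complex tissues benefit from faster
down-weighting of easy spots. Epoch counts are not prescribed anywhere
authoritative, so 500 is the package default; the bundled analyses use 300
(single fixture) and 200 (two-slice stack), which is where their loss
curves have long flattened.

## Decisions where the design was genuinely open

* **Masking replacement base set.** The 5% random-replacement fraction is
  taken *of the masked spots* (so 50/47.5/2.5 percent of all spots end up
  kept/tokened/replaced), with replacement sources drawn uniformly from
  all spots. An alternative reading — 5% of all spots — exists; the
  masked-spots reading is implemented.
* **Token semantics.** Masked rows are *replaced by* the learnable token,
  not additively augmented: that is what the masking equation says, and it
  keeps the keep-set rows bit-identical to the input.
* **Softmax denominator.** The attention normalization sums
  $\exp(e_{ij'})$ over $j' \in N_i$. Read literally, the printed
  denominator would not vary with $j'$ and every weight would be 1; that
  contradicts "edge weight between $i$ and $j$", so standard softmax
  normalization is used.
* **Inference protocol.** Embeddings and denoised profiles are computed
  from the *uncorrupted* input with no remasking: inference must be
  deterministic for downstream clustering to be reproducible, and repeated
  `predict()` calls are bit-identical.
* **KNN ties.** The covering radius is the distance to the $k$-th
  neighbor; everything at or inside it is linked (order-independent). A
  $10^{-9}$ relative slack absorbs floating-point noise in lattice
  distance ties, so translated copies of a lattice produce identical edge
  sets. A consequence of the per-spot radius plus union symmetrization is
  that boundary spots always reach $\ge k$ neighbors and can push
  near-boundary interior spots above degree 6; spots deeper than two rings
  from the boundary have degree exactly 6.
* **Stacked slices.** Slices are discrete layers ordered by `slice_idx`;
  there is no metric $z$ coordinate. Cross-slice neighborhoods use the
  same covering-radius idea with cap 7 (the facing spot plus its 6-ring on
  a perfect stack), consecutive pairs are scanned in both directions, and
  non-adjacent slices are never linked — so outer-slice spots see at most
  $6+7$ neighbors and middle-slice spots at most $6+7+7$. A two-slice
  stack uses the merged-pair rule (union KNN), which already produces
  cross-slice edges for aligned slices.
* **Clustering.** Latent embeddings are clustered with a Gaussian mixture
  (mclust, shared ellipsoidal "EEE" covariance), $k$ fixed to the known
  annotation count, initialized from a seeded multi-restart k-means
  partition of the standardized embedding and refined by EM. The k-means
  seeding matters: autoencoder latents routinely contain near-dead
  dimensions with variance orders of magnitude below the informative ones,
  and a shared-covariance EM started from mclust's default hierarchical
  agglomeration is fragile in that geometry, while the k-means-seeded EM is
  stable across fit seeds.
* **iLISI.** Implemented in its original perplexity form: Gaussian kernel
  over the $3 \times 30$ nearest embedding neighbors, bandwidth tuned per
  spot to perplexity 30, inverse Simpson index of the weighted batch
  proportions.

## Numerical choices

Gradients of the full pipeline — attention softmax, ELU, tied decoder,
both tokens — are derived analytically and checked against central finite
differences in the test suite (agreement to ~$10^{-7}$ relative). The
cosine error guards zero-norm rows with an $\varepsilon = 10^{-12}$
threshold (cosine treated as 0, warning emitted, zero gradient). The
softmax subtracts the per-neighborhood maximum before exponentiation.
Isolated nodes attend to themselves with weight 1. Weight matrices use
Glorot-uniform initialization; both mask tokens start at zero and receive
gradient from their first use. All randomness — initialization, per-epoch
plan draws — flows from one seed through one RNG stream in a fixed order,
so a fixed seed reproduces the fit exactly on CPU.

## What the simulator emulates — and what it does not

`simulate_dataset()` produces a hexagonal (or square) lattice, contiguous
band domains (mimicking laminar cortex) or Voronoi blobs, and counts from
a negative binomial with a domain-programmed mean: informative genes
(30% of the panel by default) have mean `nb_mean_base * nb_mean_fold`
inside their domain and `nb_mean_base` outside, followed by independent
Bernoulli dropout. The defaults — base mean 2, fold 4, dispersion size 2,
dropout 0.3, 200 genes, 400 spots — give overdispersed, ~60%-zero count
matrices with a clear but noise-dominated laminar program, the regime the
masking scheme targets. Multi-slice stacks repeat the geometry and apply a
per-slice, per-gene log-normal factor (`batch_log_fc_sd`) to the means,
a multiplicative batch effect.

This emulates dropout, overdispersion, spatial coherence, and slice-level
shifts. It does **not** emulate segmentation errors, spatially varying
library size, cell-type mixtures within spots, irregular tissue
boundaries, or histology — so passing tests demonstrate correct mechanics
and recoverability under the stated noise model, not performance on any
real tissue.

## Problem sizes used by the bundled analyses

The standard-small fixture (hex 20×20 = 400 spots, 200 genes, 4 band
domains, dropout 0.3, seed 7) is fitted for 300 epochs and clustered with
$k = 4$; the two-slice batch analysis uses the same geometry twice
(800 spots, `batch_log_fc_sd = 0.5`) fitted jointly for 200 epochs over
the merged-pair graph. These sizes keep a full run in the low minutes on a
single CPU while leaving the domain signal realistically buried in noise.

## Known limitations

Full-graph training only (no mini-batching): memory grows with
$N \times \max(\text{dims})$, comfortable to a few thousand spots in plain
R. Single attention head. No learning-rate schedule or early stopping.
The iLISI implementation computes a dense distance matrix
($O(N^2)$ memory). Slice alignment is assumed done upstream — coordinates
of stacked slices must already be co-registered.
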