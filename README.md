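# stgmae — dual-remask graph attention autoencoder for spatial transcriptomics

Spot-level spatial transcriptomics (Visium, Slide-seq, Stereo-seq, STARmap,
...) measures a gene expression profile `x_i` at each capture spot `i`
together with its planar position. Two obstacles make spatially coherent
analysis hard: technical **dropouts** (spurious zeros) corrupt individual
spot profiles, and naive expression clustering ignores the tissue geometry.
`stgmae` learns a low-dimensional, spatially informed embedding of every
spot by training a **masked graph autoencoder with dynamic attention** over
the spatial neighbor graph, and uses that embedding for spatial-domain
clustering, microenvironment-heterogeneity inspection (via the learned
attention weights), gene denoising, and implicit batch correction when
several tissue slices are embedded jointly.

## The model

A spatial neighbor graph (SNG) links each spot to the spots inside its
minimal radius covering `k = 6` nearest neighbors (hexagonal-lattice
geometry), or inside a fixed radius for single-cell-resolution platforms.
Stacked slices use adjacency-restricted rules: each spot additionally links
to at most 7 spots of its immediately adjacent slice(s), never further.

Each training epoch corrupts the input: 50% of spots are **masked** (their
profile replaced by a learnable token `x_[M]`, 5% of them instead receiving
a random spot's profile), the rest are **kept** untouched. The encoder
aggregates over graph neighborhoods `N_i` (which include `i` itself) with
dynamic attention

    e_ij = v' sigmoid(W0 h_i + W1 h_j),   att_ij = softmax_j(e_ij)
    h_i^(k) = ELU( sum_{j in N_i} att_ij (W0^(k) h_j^(k-1)) )

with the final encoder layer (default widths 512 → 30) aggregating without
attention. The 30-dimensional embedding `H` is then independently
**remasked twice** (50% of rows overwritten with a second learnable token
`h_[M]`) and each view is decoded by the weight-tied decoder — transposed
encoder weights, encoder attention reused — giving reconstructions `Z0`,
`Z1`. The loss is the scaled cosine error

    L = mean_{i in masked} (1 - cos(x_i, z0_i))^gamma
      + mean_{i in kept}   (1 - cos(x_i, z1_i))^gamma
      + WD * sum ||W||^2

optimized with Adam (lr 0.001, WD 0.001, gamma in [1, 3]). One view learns
to predict what was hidden (noise correction), the other to reproduce what
was visible (detail recovery).

## Worked example

```r
library(stgmae)

d   <- sim_standard_small()          # 400 spots, 200 genes, 4 band domains
p   <- preprocess(d, min_cells = 3)  # filter, normalize, log1p, HVG
fit <- stgmae(p, dims = c(512, 30), epochs = 300, seed = 1)
fit
#> Dual-remask graph attention autoencoder
#>
#> Call:
#>   stgmae(x = p, dims = c(512, 30), epochs = 300, seed = 1)
#>
#> Spots: 400   genes: 200   layers: 200 -> 512 -> 30
#> Epochs: 300   final loss: 0.21993

cl <- cluster_domains(fit$latent, k = 4, seed = 1)   # mclust EEE mixture
ari(cl$labels, as.integer(p$labels))
#> [1] 1
```

The fitted object answers the usual questions: `summary(fit)` (parameter
counts, corruption ratios, loss trajectory), `plot(fit)` (loss curves),
`predict(fit)` / `predict(fit, type = "denoised")`, `residuals(fit)`,
`coef(fit)`, and `attention_edges(fit)` exports the per-edge attention
weights at their tissue positions for microenvironment plots. An ARI of
1 against the generating domains means the embedding recovers the
spatial program exactly on this fixture; clustering a PCA of the same
log-normalized matrix with the identical mixture model gives an ARI of
about 0 on this fixture, because the domain signal sits below the dropout
noise without spatial aggregation.

Multi-slice batch correction works the same way: simulate or load aligned
slices, `concat_slices()` them, and `build_graph()` picks the pair/stack
rules automatically. `ilisi(fit$latent, slice_idx)` quantifies the mixing
(1 = unmixed, number-of-slices = perfect).

A shell entry point wraps the same pipeline for scripted use:

```sh
Rscript exec/stgmae run --config run.cfg --seed 1 --outdir out/
```

with a plain `key = value` config (see `?run_pipeline`); artifacts are
`clusters.tsv`, `embeddings.tsv`, `metrics.json`, `denoised.mtx`,
`attention_edges.tsv`, and reruns skip stages whose inputs are unchanged.

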