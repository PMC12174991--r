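# crysformer

Self-supervised transformer representations of molecular crystals, for
property prediction in crystal-structure-prediction (CSP) and materials
screening workflows: lattice-energy ranking, gas-capacity estimation,
polymorph property surrogates.

Molecular crystal properties depend jointly on local chemistry (bond
networks, hydrogen bonding) and global packing geometry (channels, voids).
`crysformer` encodes both in one multi-modal token sequence:

* **atom tokens** — per-atom graph embeddings from edge-gated message
  passing on the periodic neighbour graph interleaved with line-graph
  (bond-angle) updates, plus rigid-motion-invariant relative positional
  embeddings derived from a randomly perturbed copy of the structure;
* **image tokens** — 1-D (channel) and 2-D (void) persistence images of the
  growing-ball filtration over the atomic point cloud, rescaled per
  structure, cut into 5 x 5 patches, with two `[SCL]` tokens per image
  carrying the maximum persistence and maximum birth;
* laid out as `[CLS]`, atoms, `[SEP]`, 1-D patches, 2 x `[SCL]`, `[SEP]`,
  2-D patches, 2 x `[SCL]`, feeding a BERT-style bidirectional encoder
  (default L = 12, H = 768, A = 12).

Pre-training combines four self-supervised tasks with unit weights:
masked atom prediction (15% masking, 80/10/10 MASK/random/kept), atom pair
classification (200 balanced pairs per crystal; is this pair from the same
molecule?), crystal density prediction from `[CLS]`, and symmetry element
prediction — a 7-dimensional multi-hot label (no element, inversion centre,
mirror, rotation, screw, rotoinversion, glide) derived from the space
group's full operation list, scored by exact match, with inverse-frequency
class weights `w_i ∝ p_i^(-1/ε)`, ε = 1.1. Fine-tuning adds one affine head
on `[CLS]` and trains everything (AdamW, lr 1e-4, weight decay 1e-2, 5%
warm-up then linear decay to zero), reporting MAE, R² and top-n overlap.
Attention rollout maps predictions back to atoms and image patches.

Everything is testable without external data: a fixture generator builds
synthetic molecular crystals (space groups 1, 2, 4, 19) with known density,
symmetry label, molecule membership and engineered channel radii.

## Worked example

```r
library(crysformer)

# a synthetic P2_12_12_1 crystal: water-like molecule at a general position
fx <- make_crystal(space_group = 19, template = "triatomic", seed = 7)
fx$p1
#> <crystal 'fx_sg19_triatomic_s7'>  12 atoms, space group 1
#>   cell: a=11.909 b=10.408 c=9.691 A, volume 1201.19 A^3
#>   elements: H O; molecules assigned: 4

symmetry_elements(19)
#> <symmetry_label> screw
density(fx$p1)
#> [1] 0.0996            # g/cm^3

# persistent homology of the periodic structure
pf <- persistence_features(fx$p1)
pf$diagrams
#> <persistence_diagrams> 144 points; H1: 23 features, H2: 8
c(pf$max_persistence_1d, pf$max_birth_1d)
#> [1] 1.277 4.160       # Angstrom: the [SCL] scalars of the 1-D image

# engineered channels: the max 1-D persistence tracks the pore radius
for (s in make_pore_series(c(2, 3, 4), seed = 1))
  cat(attr(s, "channel_radius"), "->",
      persistence_features(s)$max_persistence_1d, "\n")
#> 2 -> 1.535
#> 3 -> 2.201
#> 4 -> 2.945
```

The first crystal has no pores, so its largest 1-D feature is small
(1.28 Å — intermolecular gaps); in the pore series the dominant feature
grows with the engineered channel radius (persistence ≈ 0.74 r for a
12-membered ring: death at the ring radius, birth at half the atom
spacing).

Training at desk scale:

```r
ds <- make_dataset(200, seed = 11)                     # structures + labels
cfg <- model_config(L = 2, H = 64, A = 4, H_graph = 64,
                    use_images = FALSE, lr = 1e-3)     # reduced encoder
model <- crysformer_model(cfg, c("C", "N", "O", "H"), seed = 1)
model <- pretrain(model, ds$structures, ds$truth$space_group,
                  epochs = 50, batch_size = 8, seed = 1)

holdout <- make_dataset(40, seed = 12)
evaluate_pretrain(model, holdout$structures, holdout$truth$space_group)
#>  map_acc  apc_acc  cdp_mae  sep_exact
#>   1.0000   0.9897   0.0097     1.0000
```

The held-out metrics say: masked elements are recovered perfectly, atom
pairs are assigned to molecules with 99% accuracy, density is predicted to
0.01 g/cm³, and all seven symmetry-element bits are exactly right on every
held-out crystal.

A command-line interface (`inst/cli/crysformer.R`) wraps the same
functions as `make-fixtures`, `featurize`, `pretrain`, `finetune`,
`predict`, `fewshot` and `explain` commands driven by a YAML/JSON run
configuration.

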