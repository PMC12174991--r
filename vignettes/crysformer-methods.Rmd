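---
title: "Methods: multi-modal transformer representations of molecular crystals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-modal transformer representations of molecular crystals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Molecular crystals — periodic solids whose repeat unit is one or more
discrete organic molecules — control applications from pharmaceuticals
(polymorph choice drives solubility and tabletability) to porous materials
for gas storage. Properties such as lattice energy, methane deliverable
capacity or bulk modulus are expensive to compute, which motivates learned
surrogates that transfer across properties and molecule families.

`crysformer` implements a self-supervised transformer for this setting. A
crystal enters the model as a multi-modal token sequence:

* **Atom tokens.** Each atom of the P1-expanded cell carries a graph
  embedding from edge-gated message passing on the periodic neighbour graph,
  interleaved with a line-graph pass that conditions edge updates on bond
  angles, plus a *relative positional embedding* built from internal
  distances of a randomly perturbed copy of the structure.
* **Image tokens.** The 1-D (channels) and 2-D (voids) persistence images of
  the growing-ball filtration over the atomic point cloud, cut into 5 x 5
  patches (100 tokens per image), each linearly projected. Two `[SCL]`
  tokens per image carry the image's own maximum persistence and maximum
  birth, because images are rescaled per structure (below).
* **Special tokens.** `[CLS]` (whole-crystal readout) and `[SEP]`
  (modality separators), in the fixed order `[CLS]`, atoms, `[SEP]`,
  1-D patches, 2 x `[SCL]`, `[SEP]`, 2-D patches, 2 x `[SCL]`.

The encoder is a BERT-style bidirectional transformer (default L = 12
layers, width H = 768, A = 12 heads; all sizes configurable). Pre-training
combines four tasks with unit weights:

* **MAP** — masked atom prediction: 15% of atoms are selected; 80% of those
  become a reserved MASK identity, 10% a random other element, 10% stay
  unchanged. Masking is applied to the graph embedder as well, so neighbours
  cannot leak the identity.
* **APC** — atom pair classification: 200 atom pairs per crystal, half from
  the same molecule and half from different molecules (molecules are the
  connected components of the covalent bond graph). The head is made exactly
  symmetric by summing the two concatenation orders.
* **CDP** — crystal density prediction from the `[CLS]` token (single affine
  head, squared-error loss on standardised labels, MAE reported in g/cm^3).
* **SEP** — symmetry element prediction: the space group is mapped to a
  7-dimensional multi-hot label (no-element/P1, inversion centre, mirror
  plane, rotation axis, screw axis, rotoinversion axis, glide plane); the
  loss is per-element binary cross-entropy with inverse-frequency weights
  `w_i ∝ p_i^(-1/epsilon)`, `epsilon = 1.1`, mean-normalised; the metric is
  exact match over all seven bits.

Fine-tuning initialises a fresh affine head on `[CLS]` and trains all
weights (AdamW, lr 1e-4, weight decay 1e-2, 5% linear warm-up then linear
decay; 50 epochs, batch 32; 80/10/10 random splits), reporting MAE, R^2 and
the top-n overlap between predicted and actual best structures.

## Symmetry elements from first principles

Space-group operations are reconstructed from a stored generator table
(2-5 xyz triplets per group, standard settings) by closure under
composition modulo lattice translations. Every operation is classified by
its rotation part and intrinsic translation: the intrinsic translation is
the projection of the translation onto the operation's invariant subspace,
*reduced modulo the projections of the lattice translations onto that
subspace*. The reduction matters: a diagonal reflection whose translation
projects onto half of an in-plane lattice vector is a shifted mirror, not a
glide; without the reduction, groups such as 113, 117 and 118 are
mislabelled. The test suite checks all 230 groups against an independent
brute-force classifier that decides screw/glide by fixed-point solvability
instead.

Because the fixture world only realises three of the seven element classes,
inverse-frequency weighting with add-one smoothing would hand absent
classes ~97% of the loss mass. `pretrain()` therefore weights observed
classes by the epsilon-damped inverse-frequency rule and gives
never-observed classes the mean weight; `element_weights()` itself retains
the documented add-one behaviour for direct use.

## Persistent homology of periodic structures

The filtration is an alpha complex over a supercell whose perpendicular
widths all reach `min_extent` (default 20 Angstrom): incremental
Bowyer-Watson Delaunay triangulation, CGAL-style alpha values with the
Gabriel correction, and GF(2) boundary-matrix reduction, all in compiled
code, with representative cycles on request. Diagrams are reported in
radius units; alpha and Cech filtrations have identical persistence, which
the tests exploit by comparing against a brute-force min-enclosing-ball
Cech oracle on small generic clouds (1e-6 agreement).

Two numerical choices matter:

* **Symbolic jitter.** Crystalline point sets are exactly degenerate
  (cospherical, coplanar). A deterministic jitter of 1e-7 Angstrom breaks
  ties; effectively planar clouds are jittered at 1e-3 Angstrom because
  sliver tetrahedra at smaller scales defeat double-precision predicates.
* **Finite-size (interior) filter.** A finite cloud cannot distinguish
  features at its own boundary from artefacts of truncating the periodic
  structure. A feature is kept only when its birth simplex lies at least its
  own death radius away from the supercell boundary. Bulk features recur in
  every replica, so an interior copy always survives; open-boundary loops
  are born at the surface and are removed. This is what makes the maximum
  1-D persistence a faithful channel-radius proxy on the pore fixtures.

Persistence images are rasterised per structure on the unit square after
dividing births and persistences by their own maxima, with an isotropic
Gaussian of spread 0.15 (in scaled units — the per-image scaling makes
scaled units the only consistent reading) integrated exactly per pixel via
the error function. The maxima travel with the image as the two `[SCL]`
scalars. An empty diagram yields a zero image with zero scalars.

## The relative positional embedding

The reference description of the positional scheme is a single sentence
(perturb the structure, derive positional embeddings each epoch), so the
concrete construction here is the package's own. Each atom receives, from a
perturbed copy of the structure (sigma = 0.05 Angstrom, redrawn every
epoch):

* its sorted periodic distances to the k = 8 nearest neighbours, and
* its periodic distances to 4 *anchor atoms* drawn at random per epoch and
  shared by all atoms of the structure,

each expanded in a fine radial basis (64 Gaussians; 0-8 Angstrom for
neighbours, 0-12 for anchors) and linearly projected. Built from internal
distances only, the features are invariant under rigid rotation and
translation, and the per-epoch redraw removes any dependence on atom
ordering. The anchors are what make same-molecule membership visible at the
level of individual tokens: two atoms of one molecule agree in every anchor
distance to within the molecular diameter, whereas symmetry-equivalent
atoms of different molecules differ by intermolecular distances. Without
them (k-NN lists alone, coarse basis), same-molecule classification on
symmetry-copy crystals is provably information-starved at the token level,
and the task never leaves chance — a failure mode we verified with a
logistic probe on the raw features.

The absolute variant (per-axis embedding tables over 100 fractional bins,
summed) is deliberately not rigid-motion invariant; it exists as the
positional ablation.

## Initialisation and the reduced training recipe

Residual output projections (the attention out-projection and the second
feed-forward linear) start at zero, so every encoder block is the identity
at initialisation. With a fully random encoder the subtle positional
signals are buried under activation noise and the pair task stalls at
chance; with near-identity initialisation whatever is learnable from the
raw tokens remains learnable end to end, and the attention pathway grows in
as training demands it.

The desk-scale study in the tests and acceptance script uses a reduced
encoder (L = 2, H = 64, A = 4, H_graph = 64, image modality off) trained
for 50 epochs on 200 fixtures at batch 8 with lr 1e-3. The reference
recipe (batch 512, lr 1e-4) is tuned for ~7e5 structures; at 200 structures
it yields about 50 optimiser steps and nothing converges, so the reduced
study trades batch size for step count at a correspondingly higher
learning rate. Configuration defaults keep the reference values.

## The synthetic fixture generator

Fixtures place a rigid molecular template (N2 diatomic, water-like
triatomic, C6 ring, scalable C12 pore ring) at a general position of space
group 1, 2, 4 or 19 — exactly the no-element, inversion-only and screw-only
label classes — expand to P1, and jitter atomic positions at 0.05 Angstrom
(a realistic thermal-displacement scale). Cell shapes follow the packing
the symmetry imposes: P2_1 stacks its two molecules along the screw axis b,
P-1 packs around the inversion centre with isotropic volume doubling,
P2_12_12_1 triples orthogonal screws with fourfold volume. Densities vary
through seeded packing margins. Ground truth (density, symmetry label,
molecule membership, channel radius) is recomputed, not declared.

The pore series stacks 12-membered rings coaxially on a close-packed
hexagonal lattice with a 2.5 Angstrom wall gap, so the engineered channel
is the dominant pore and every other void fills at much smaller radii.

What passing tests on these fixtures demonstrate: the machinery —
featurization, task construction, optimisation, evaluation — is correct and
the tasks are learnable end to end at desk scale. What they do not
demonstrate: chemical accuracy on real CSD-scale data, where molecules are
larger and conformationally flexible, disorder exists, and all seven
symmetry-element classes occur.

## Interpretation

Attention rollout averages heads per layer, mixes the residual as
`0.5 I + 0.5 A` with row renormalisation (the mixing weight is exposed),
multiplies the modified matrices across layers and reads the `[CLS]` row.
Scores are renormalised over non-special tokens so atom and image shares
are comparable; the display clip of 0.005 is applied only at
export/visualisation time. On a pore-size regression the `[SCL]` tokens —
whose maximum 1-D persistence *is* the channel radius up to a geometric
factor — stay enriched above the uniform per-token share (about 2x in the
shipped study). A strong modality contrast (images dominating for geometry
targets, atoms for chemistry targets, as large-scale studies observe)
requires multi-modal pre-training at data scales beyond the desk-scale
fixtures: when a from-scratch toy model can read the target off either
modality, it settles on the compact atom tokens.

## Known limitations

* Persistence of very large supercells is cubic-ish in practice
  (brute-force Bowyer-Watson point location); clouds beyond a few thousand
  points get slow.
* The alpha filtration approximates the periodic (torus) filtration by a
  finite supercell plus the interior filter; features larger than half the
  supercell width are unobservable by construction.
* The autograd engine is single-threaded dense-matrix R; the package is a
  faithful desk-scale implementation, not a GPU training framework.
* Chirality is invisible to the distance/angle features (as in any
  bond-length/bond-angle representation); symmetry discrimination relies on
  packing statistics, not handedness.

## Problem sizes used in the shipped studies

Pre-training: 200 fixtures (2-24 atoms), 50 epochs, reduced encoder; 40
held-out fixtures for task metrics. Fine-tuning comparison: 80 fixtures,
6 epochs, 5 seeds, median MAE. Few-shot: 60 fixtures over three families.
Attribution: 12 pore structures, 5 epochs, full multi-modal sequence.
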