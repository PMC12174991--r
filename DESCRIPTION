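Package: crysformer
Title: Multi-Modal Transformer Representations of Molecular Crystals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Self-supervised transformer representations for molecular
    crystal property prediction. Crystal structures read from CIF are
    expanded to P1, decomposed into molecules, and encoded as a
    multi-modal token sequence that fuses per-atom graph embeddings
    (edge-gated message passing on the periodic bond graph and its line
    graph) with patches of persistent-homology persistence images
    computed from an alpha-complex filtration of the atomic point cloud.
    The encoder is pre-trained with four tasks (masked atom prediction,
    atom pair classification, crystal density prediction, symmetry
    element prediction) and fine-tuned with a single dense head on
    scalar property tables. Includes attention-rollout attribution to
    atoms and image patches, a synthetic crystal fixture generator with
    known ground truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
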