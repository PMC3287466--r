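Package: rotamrf
Title: Protein-Dependent Rotamer Libraries via Markov Random Field Inference
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Re-ranks a backbone-dependent side-chain rotamer library for a
    specific protein backbone. The protein is modelled as a pairwise Markov
    random field over residues (contact edges under a 10 Angstrom rule on
    CA/CB/carbonyl-O atoms), with Boltzmann potentials built from rotamer
    prior probabilities and a SCWRL3-style piecewise repulsive energy.
    Per-residue marginal distributions over rotamers are estimated by
    sum-product inference (loopy, tree-reweighted and generalized belief
    propagation, and mean field), yielding a probability-annotated
    protein-dependent rotamer library and, by top-1 thresholding, a
    side-chain prediction. Includes deterministic synthetic fixtures and
    evaluation under the 40-degree chi criterion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
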