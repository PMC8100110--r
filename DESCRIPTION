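Package: seqAttractors
Title: Genome-Attractor Analysis of Protein Sequences by Semihomologous
    Comparison and Randomly Encoded Neural-Network Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying genome attractors in protein-sequence
    evolution. Implements the semihomologous comparison of amino-acid
    sequences, which classifies each aligned position by whether the two
    residues' codons are identical (R), interconvertible by a single
    transition (#) or transversion ($) point mutation, or separated by two
    or three point mutations (-), together with the derived per-pair and
    per-group statistics and a semihomologous dot matrix. Also implements
    an ensemble of three-layer sigmoid perceptrons trained by on-line
    backpropagation on randomly five-bit-encoded sequences, whose averaged
    outputs quantify evolutionary similarity to a fixed teaching set; and,
    on top of both, orbit radii, distance factors and disturbance rankings
    for named attractor groups. A seeded codon-level evolution simulator
    generates synthetic protein families at controlled divergence and
    transition/transversion bias.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite,
    yaml,
    optparse
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
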