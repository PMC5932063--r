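Package: allokit
Title: Structure-Encoded Allosteric Cross-Talk Analysis of Post-Translational Modification Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for analysing allosteric cross-talk between
    post-translational modification (PTM) sites in multi-domain proteins such
    as the Hsp90 chaperone family. Combines per-column Kullback-Leibler
    conservation and mutual-information coevolution scores (cMI/pMI) from
    multiple sequence alignments, coarse-grained conformational ensembles
    (event-driven square-well discrete molecular dynamics and an elastic
    network Gaussian surrogate), perturbation response scanning (PRS) with
    effector and sensor profiles, solvent accessibility and residue depth,
    flexibility-rigidity index (FRI) profiles, and weighted residue
    interaction networks with shortest-path communication analysis, to
    classify annotated PTM sites as hinges, effectors, sensors, or carriers
    of allosteric signalling.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    igraph,
    bio3d,
    Biostrings
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
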