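Package: booltrain
Title: Boolean Network Training and Attractor Analysis for Signal-to-Transcriptome Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to discretize perturbation time-course expression data,
    train the topology of a prior-knowledge signed network against those data
    with a genetic algorithm, and analyse the resulting Boolean model by
    synchronous attractor simulation under stimulus and inhibitor clamping.
    Includes a deterministic synchronous Boolean engine with brute-force and
    sampling-based basin analysis, Hill-function discretization of fold
    changes, CAST time-course clustering, HiT-MDS embedding with
    skew-Gaussian outlier scores, a packaged 63-node prior-knowledge network
    and 32-node final model of NGF-induced PC12 cell differentiation, and
    synthetic-data generators for recovery benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    igraph,
    optparse
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
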