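Package: nanospring
Title: Mechanics of Elastomeric Nematocyst Proteins from Force Spectroscopy,
    Umbrella Sampling, Collapse Kinetics and Amide-I Spectroscopy
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative analyses for establishing the elastomeric character
    of intrinsically disordered structural proteins such as the silk-like
    nematocyst wall protein Cnidoin. Provides worm-like-chain (WLC)
    force-extension evaluation, inversion and least-squares fitting; AFM
    single-molecule force-spectroscopy trace parsing, cohesin-dockerin
    double-rupture fingerprint detection in contour-length space, and
    population statistics of fitted contour and persistence lengths;
    reconstruction of potentials of mean force from harmonically biased
    umbrella-sampling windows by the weighted histogram analysis method
    (WHAM) with mean-force profiling; first-passage detection and
    exponential lifetime estimation for force-quench chain-collapse
    trajectories, plus a polyproline-II dihedral-fraction metric; amide-I
    band decomposition of mid-infrared spectra into Gaussian components
    with AICc-weighted model averaging and peak-width statistics; and
    sequence-level disorder metrics (composition, charge-hydropathy
    classification, elastic-motif scanning). Seeded synthetic-data
    generators emulate the AFM instrument, the biased and force-quench
    molecular-dynamics sampling, and the FTIR plate reader, so every
    analysis stage is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    Biostrings,
    stats,
    graphics,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
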