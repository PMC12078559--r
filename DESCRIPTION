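Package: photoswim
Title: Simulation and Trajectory Analysis of Photoswitchable DNA Condensate
    Swimming
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for studying light-driven motility of photoswitchable DNA
    condensates. Implements a deterministic two-state (liquid/dissociated)
    mass- and momentum-exchange model of condensate swimming under alternating
    UV/Vis irradiation, frequency sweeps and a momentum-exchange ablation;
    FFT-accelerated mean-square-displacement analysis of 2D particle tracks
    with a signed diffusion coefficient; stepwise swimming-displacement
    bookkeeping and the characteristic cycle-time / threshold-frequency
    estimate; a rule-based temperature to flow-mode classifier; and synthetic
    trajectory generators with known ground truth for validating the analysis
    chain.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
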