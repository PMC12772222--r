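Package: silknmr
Title: NMR Relaxation, Chemical-Shift, and Ensemble-Interaction Analytics
    for Spider-Silk Protein Phase Separation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for studies of spidroin liquid-liquid phase
    separation and fiber assembly: monoexponential fitting of 15N T1/T2
    relaxation decays with Monte-Carlo errors, heteronuclear NOE and R2/R1,
    reduced spectral-density mapping to J(0), J(wN) and J(0.87wH);
    chemical-shift perturbation analysis across sample states with
    per-nucleus significance thresholds, random-coil-referenced secondary
    structure classification (including multi-component resonances) and
    predicted-versus-experimental shift statistics; geometry analytics on
    multi-model PDB coordinate ensembles (hydrogen bonds and residue-pair
    frequencies, ion-binding fractions and conditional contact statistics,
    hydration-shell displacement, cation-pi detection and classification,
    simplified Kabsch-Sander secondary-structure assignment); and a
    synthetic-data generator that plants known ground truth for every input
    class so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    minpack.lm,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
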