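Package: thermpot
Title: Temperature-Dependent Statistical Potentials for Protein Melting
    Temperature Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts protein melting temperatures (Tm) within homologous
    families using temperature-dependent knowledge-based statistical
    potentials. Datasets of mesostable and thermostable protein structures
    are used to derive distance-dependent pair potentials (side-chain
    geometric centers) and backbone torsion-angle-domain propensity
    potentials by Boltzmann inversion, with neighbor-bin smoothing and a
    sparse-data shrinkage correction. Folding free energies evaluated with
    potentials derived at low and high temperature are combined linearly,
    and the meso-thermo free-energy difference is regressed against
    experimental Tm, with jack-knife cross-validation and iterative
    worst-predicted exclusion. Includes dataset management (Tm estimation
    from host environmental temperature by global regression, per-family
    regression, and sequence-identity transfer; redundancy culling),
    a synthetic homologous-family generator with planted
    temperature-dependent contact propensities, and a command-line
    interface covering the full workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
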