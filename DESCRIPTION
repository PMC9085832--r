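Package: channelrot
Title: Inter-Subunit Contacts, Domain Rotation and Gating Analysis for
    Tetrameric Ion-Channel Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Post-processing of structural ensembles of homotetrameric
    ion channels (multi-model PDB, one model per frame) together with the
    accompanying electrophysiology and patch-clamp fluorometry analysis
    stack. Implements per-frame hydrogen-bond and salt-bridge detection
    with per-subunit-pair occurrence frequencies, a centre-of-mass
    dihedral metric for the rotation of the C-linker/cyclic
    nucleotide-binding domain about the pore axis, residue-wise
    side-chain root mean square fluctuations with significance-masked
    between-state differences, gate geometry metrics, Boltzmann
    steady-state activation fits, delayed mono-exponential kinetics,
    Hill concentration-binding fits, and reference-dye background
    subtraction for confocal patch-clamp fluorometry. A synthetic-data
    module generates toy tetramer ensembles and recordings with known
    ground truth so that every analysis stage carries a closure test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
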