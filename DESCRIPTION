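Package: collagencg
Title: Coarse-Grained Martini 3 Parametrization and Analysis of Collagen Fibrils
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for building and validating Martini 3 coarse-grained
    models of fibrillar collagen. Maps atomistic collagen chains to backbone
    beads by center-of-geometry mapping, derives bonded parameters by direct
    (and bimodal) Boltzmann inversion with a sequence-specific dual bond
    rule for proline/hydroxyproline, emits GROMACS-dialect topologies for
    triple helices with intrahelical Go contacts and for divalent (HLKNL)
    and trivalent (PYD) cross-links, estimates solvation and transfer free
    energies from forward/backward nonequilibrium work distributions via the
    Crooks/Bennett maximum-likelihood estimator, and computes structural and
    mechanical observables of collagen fibrils: rise per residue, residues
    per turn, end-to-end distance, overlap/gap strain ratio, binned bond
    force profiles and bead-level solvent-accessible surface area. Includes
    generators for all synthetic test inputs (ideal triple helices,
    Boltzmann-distributed bonded samples, Crooks-consistent work sets, toy
    gap/overlap fibrils).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    graphics,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
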