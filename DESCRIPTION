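Package: idpcryo
Title: Structural and Functional Analysis of Disordered Cryoprotective Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A quantitative analysis chain connecting the secondary and
    quaternary structure of intrinsically disordered proteins (IDPs) to
    their membrane- and enzyme-protective function during freeze-thaw
    stress.  Implements structural statistics over molecular-dynamics
    style trajectories (RMSD, hydrogen bonds, residue contact maps,
    helicity timelines, backbone orientational correlation, hydrophobic
    moments), small-angle scattering compaction analysis (Guinier,
    Guinier-Porod and dimensionless Kratky analysis), solution
    hydrodynamics (cumulant and regularized DLS inversion, static light
    scattering masses, infinite-dilution extrapolation, CD helicity),
    and surface-occupancy-normalized dose-response fitting of
    cryoprotection assays (carboxyfluorescein leakage, LDH retention,
    electrolyte-leakage LT50).  A synthetic-data module generates every
    input with known ground truth so the full pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
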