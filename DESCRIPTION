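Package: mechunfold
Title: Force-Probe Molecular Dynamics Unfolding Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for force-probe (steered) molecular dynamics
    studies of mechanical protein unfolding. Reads GROMACS-style pull-force
    traces and PDB/GRO structures; computes Shrake-Rupley solvent-accessible
    surface areas and inter-region contact areas; detects unfolding events
    from equilibrium-baseline IQR thresholds on contact-area series; extracts
    first-peak rupture forces from Gaussian-smoothed force profiles; fits the
    Bell model of dynamic force spectroscopy across a pulling-velocity
    ladder; estimates unfolding-barrier differences from first-unfolding
    counts by a Bayesian binomial-logistic argument; and classifies unfolding
    pathways (shearing vs tearing) from helix tilt angles via ROC analysis.
    A seeded synthetic-data generator emulates every input so the full
    pipeline is testable without molecular dynamics trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    bio3d
Config/testthat/edition: 3
RoxygenNote: 7.3.3
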