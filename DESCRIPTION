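Package: PPiMSM
Title: Markov State Models for Pyrophosphate Release Kinetics from Trajectory Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds and validates Markov state models (MSMs) of pyrophosphate
    (PPi) release from bacterial RNA polymerase, and of diffusive model systems,
    from time-ordered trajectory data. Provides greedy k-center geometric
    clustering under pluggable metrics (including ligand RMSD after Kabsch
    superposition on a bridge-helix-like alignment subset), sliding-window
    transition counting with a re-crossing (dwell) filter, ergodic trimming,
    row-normalized transition matrix estimation, implied-timescale lag
    validation, PCCA+ metastable lumping, mean-first-passage-time linear
    solves, trajectory bootstrap uncertainties, residence-probability
    validation, and potential-of-mean-force projections. Includes calibrated
    synthetic generators (Markov jump processes and overdamped Langevin
    dynamics on explicit potentials) with exact thermodynamic and kinetic
    ground truth so every stage of the pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, igraph, yaml
Suggests: testthat (>= 3.0.0), withr, jsonlite, knitr, rmarkdown
Config/testthat/edition: 3
biocViews: Software, StructuralPrediction, Clustering, TimeCourse
RoxygenNote: 7.3.3
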