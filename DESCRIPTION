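Package: dediffr
Title: Simulation and Analysis of Event-Related fMRI Memory Experiments
Version: 0.1.0
Authors@R: person("Packaged", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to simulate and analyse event-related fMRI studies of
    associative recognition memory and age-related neural dedifferentiation.
    Includes a constraint-satisfying experimental-design builder for
    paired-associate study/test lists over a hierarchical stimulus set, a
    synthetic 4D BOLD generator with planted representational geometry,
    condition-dependent regional activation and trial-wise hippocampal-cortical
    coupling, condition-level and single-trial (least-squares-all) general
    linear models with a canonical double-gamma haemodynamic response and
    discrete-cosine high-pass filtering, sphere/localizer/seed region-of-
    interest construction on voxel grids, encoding-phase representational
    similarity analysis with distinctiveness difference scores, beta-series
    functional connectivity by trial type, mixed between/within ANOVAs and
    behavioural scoring, and an end-to-end pipeline with a command-line
    interface. Reads and writes NIfTI-1 volumes and BIDS-style tab-separated
    event tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
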