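Package: dpipk
Title: In Vitro-In Silico Performance Assessment of Carrier-Based Dry Powder Inhalers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reduces cascade-impactor (Next Generation Impactor) stage-mass
    measurements of dry powder inhaler blends to aerodynamic descriptors
    (emitted dose, fine particle mass and fraction, MMAD and GSD from a
    probit/log-normal fit), computes particle- and bulk-level powder
    descriptors (Kelvin pore radius, Heywood diameter, shape coefficient,
    compact tensile strength, shear-cell and pressure-titration summaries),
    predicts regional lung deposition of a log-normal aerosol with a
    deterministic one-dimensional typical-path airway model
    (impaction/sedimentation/diffusion kernels), simulates systemic
    pharmacokinetics of inhaled salbutamol with a pulmonary absorption model
    coupled to a perfusion-limited whole-body PBPK model, and screens
    formulation attributes against predicted performance with Pearson
    correlation matrices and two-way ANOVA without replication. A synthetic
    data generator emulates impactor runs and powder descriptor tables so the
    whole workflow is testable without instrument data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pheatmap,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
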