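Package: hipsccm
Title: Electrophysiology and Calcium Handling of Human iPSC-Derived Cardiomyocytes
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ordinary-differential-equation model of the ventricular-like human
    induced pluripotent stem cell-derived cardiomyocyte (hiPSC-CM), with a
    three-gate ryanodine-receptor formulation of sarcoplasmic-reticulum calcium
    release. Provides stiff-solver simulation protocols (spontaneous and paced
    activity, conductance blocks, extracellular ion challenges), extraction of
    action-potential and calcium-transient biomarkers, delayed-afterdepolarization
    detection, a biomarker-range cost function with a bounded Nelder-Mead
    calibration driver, synthetic waveform fixtures with analytically known
    biomarkers, and one-command reproduction harnesses for the model's
    validation experiments.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
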