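Package: hogmix
Title: Distributive, Processive and Mixed Phosphorylation Models of the
    Yeast HOG Pathway
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Mechanistic ordinary-differential-equation models of Hog1
    activation in the Saccharomyces cerevisiae high-osmolarity glycerol
    (HOG) pathway.  Builds an overcomplete reaction network whose submodel
    topologies differ in the Hog1 dual-phosphorylation mechanism
    (distributive, processive or mixed), in positive-feedback targets with
    catalytic and affinity components, and in negative feedback on Ssk2.
    Submodels are fitted to multimodal activation data (mass-spectrometry
    fold changes, western-blot percent phosphorylation, single-cell
    nuclear-to-cytosolic Hog1 ratios and cell-area traces) by multistart
    likelihood optimization with multivariate-normal resampling, ranked by
    AIC, and interrogated with processivity scores, Hill/EC50
    ultrasensitivity fits, protein-level robustness ensembles and
    Harrell-Davis quantile-shift statistics.  A synthetic-data generator
    emulates the structure of the multimodal fitting corpus for model
    recovery and identifiability experiments.
License: MIT
Encoding: UTF-8
NeedsCompilation: yes
Depends: R (>= 4.1)
Imports:
    deSolve,
    graphics,
    grDevices,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
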