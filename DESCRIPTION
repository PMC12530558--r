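Package: spnmorph
Title: Morphometry, Repair and Passive Cable Modelling of Striatal Projection Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative comparison of striatal projection neuron (SPN)
    dendritic morphologies across species. Reads, standardises and resamples SWC
    reconstructions; detects and repairs slice-cut dendrites by grafting intact
    branches scored against mirror-predicted morphometry; computes per-segment,
    per-branch and per-neuron morphometry including Sholl profiles, taper fits,
    the diameter versus subtree-length law and soma Feret diameters; fits a
    sigmoid spine-density model with a spine membrane-area correction for
    compartmental models; simulates the passive branched cable equation with
    AMPA/NMDA synapses for electrotonic analysis and species-rescaling
    experiments; and generates seeded synthetic SPN morphologies and spine
    inventories with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
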