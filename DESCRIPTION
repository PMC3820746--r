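Package: furrowquant
Title: Segmentation and Fidelity Quantification of Cellularization Furrow-Canal Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the fidelity of Drosophila cellularization from
    surface-view fluorescence micrographs. Implements a six-step morphological
    segmentation of the furrow-canal network (coarse Gaussian smoothing,
    thresholding, topology-preserving thinning, weak-link recovery, compartment
    extraction and boundary-artifact removal), per-cell nucleus counting and
    the mononucleate-cells-to-nuclei ratio by quadrat sampling, furrow-canal
    intensity measurement, RNA-FISH transcription-spot genotyping of embryos,
    and a synthetic-embryo image generator with planted ground truth for
    validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
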