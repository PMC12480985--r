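Package: imepipe
Title: Analysis Pipeline for Chronic Intracortical Microelectrode Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative readouts of chronic intracortical
    microelectrode (IME) experiments with nanoparticle drug delivery:
    single-unit extracellular recording quality control and metrics
    (common-median referencing, robust-sigma threshold detection, artifact
    rejection, PCA/k-means unit isolation, SNR and spike-rate summaries,
    ROUT outlier removal), active-electrode-yield statistics with
    two-proportion z-tests, concentric-ring immunohistochemistry
    quantification around the implant site (distance-transform ring
    binning, background-bin normalization, blob-based neuron counting),
    and nanoparticle drug chemistry (internal-standard HPLC calibration,
    encapsulation efficiency, withdrawal-corrected cumulative release and
    biexponential release kinetics). A synthetic-data module generates
    every input with known ground truth so the full pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    cluster,
    signal,
    minpack.lm,
    EBImage,
    tiff,
    jsonlite,
    yaml,
    withr,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
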