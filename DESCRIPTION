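Package: qimnet
Title: Multimodality Tumor Imaging Kinetics and Correlation Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Kinetic-model analysis of multimodality tumor imaging and
    network analysis of the resulting quantitative imaging metrics.
    Implements voxelwise fitting of the monoexponential (ADC) and
    intravoxel-incoherent-motion (IVIM) models for diffusion-weighted MRI,
    the fast-exchange-regime (shutter-speed) water-exchange model for
    dynamic contrast-enhanced MRI, and the irreversible two-tissue
    compartment model with blood volume for dynamic FMISO PET, together
    with variable-flip-angle T1 mapping, image-based input-function
    fitting, and static uptake metrics (TBR, SUL). Lesion-level metrics
    are assembled into Spearman correlation networks thresholded on
    significance, and community structure is detected with a signed
    spin-glass Potts Hamiltonian minimized by simulated annealing with
    multi-restart consensus. A synthetic lesion cohort generator with a
    Gaussian-copula rank-correlation structure provides ground truth for
    end-to-end parameter-recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    minpack.lm,
    igraph,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
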