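Package: nbrmech
Title: Simulation, Detection and Classification of Negative BOLD Response
    Mechanisms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Windkessel/balloon forward modelling of the four mechanisms that
    can generate negative BOLD responses (NBRs) around interictal epileptiform
    discharges - enhanced cortical inhibition, neuronal disruption of network
    activity, altered neurometabolic/vascular coupling, and arterial blood
    stealing - together with positive BOLD responses. Provides a coupled
    neuronal/vascular/metabolic ODE simulator, a synthetic 4D fMRI scan
    generator with 1/f^p noise, GLM detection with an F contrast and
    family-wise error control, flexible hemodynamic response function (HRF)
    estimation via an exogenous autoregressive (ARX) model with AIC order
    selection and permutation confidence bands, and a PCA + support vector
    machine classifier that assigns an NBR mechanism to an estimated HRF.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'utils.R'
    'stimulus.R'
    'arx.R'
    'presets.R'
    'simulate.R'
    'scan.R'
    'classify.R'
    'glm.R'
    'nifti.R'
    'pipeline.R'
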