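#' @import methods
#' @importFrom stats rnorm runif rpois fft spline qf pf quantile sd prcomp
#'   convolve dgamma rexp var mvfft
#' @importFrom utils read.delim write.table head tail
#' @useDynLib nbrmech, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Timed impulse events driving the biophysical models
#'
#' A train of short rectangular pulses standing in for interictal
#' epileptiform discharges (IEDs).  Onsets are seconds from the start of the
#' series; amplitudes are dimensionless per-event weights; the pulse width
#' defaults to 0.1 s (IEDs last roughly 70-200 ms).
#'
#' @slot onsets numeric, strictly increasing, in [0, duration)
#' @slot amplitudes numeric, non-negative, one per onset
#' @slot pulseWidth numeric scalar, seconds (> 0)
#' @slot duration numeric scalar, total series length in seconds
#' @exportClass StimulusTrain
setClass("StimulusTrain",
  representation(onsets = "numeric", amplitudes = "numeric",
                 pulseWidth = "numeric", duration = "numeric"),
  prototype(onsets = numeric(0), amplitudes = numeric(0),
            pulseWidth = 0.1, duration = 600),
  validity = function(object) {
    msg <- character(0)
    if (length(object@amplitudes) != length(object@onsets))
      msg <- c(msg, "onsets and amplitudes must have equal length")
    if (length(object@onsets) > 1 && any(diff(object@onsets) <= 0))
      msg <- c(msg, "onsets must be strictly increasing")
    if (length(object@onsets) &&
        (any(object@onsets < 0) || any(object@onsets >= object@duration)))
      msg <- c(msg, "onsets must lie in [0, duration)")
    if (any(object@amplitudes < 0))
      msg <- c(msg, "amplitudes must be >= 0")
    if (length(object@pulseWidth) != 1 || object@pulseWidth <= 0)
      msg <- c(msg, "pulseWidth must be a positive scalar")
    if (length(object@duration) != 1 || object@duration <= 0)
      msg <- c(msg, "duration must be a positive scalar")
    if (length(msg)) msg else TRUE
  })

#' Neuronal population parameters
#'
#' Two-population (excitatory/inhibitory) neural mass in the style of the
#' two-state DCM component.  \code{useRecovery = TRUE} switches the
#' excitatory population to its modulatory/recovery configuration (time
#' constant \code{tau_e2}, reduced self-connectivity \code{c_e2}), the
#' regime used by the network-disruption (NDA) mechanism.
#'
#' @slot tau_e1 excitatory response time (s)
#' @slot tau_i1 inhibitory response time (s)
#' @slot tau_e2 modulatory/recovery excitatory time constant (s)
#' @slot c_ee intralaminar excitatory self-connectivity, in [0, 1)
#' @slot c_e2 reduced excitatory self-connectivity for NDA, in [0, 1)
#' @slot c_ei excitatory-to-inhibitory coupling
#' @slot c_ie inhibitory-to-excitatory coupling
#' @slot a_e external-input gain, excitatory population (may be negative:
#'   suppressive input)
#' @slot a_i external-input gain, inhibitory population
#' @slot useRecovery logical: use (tau_e2, c_e2) for the excitatory state
#' @exportClass NeuralParams
setClass("NeuralParams",
  representation(tau_e1 = "numeric", tau_i1 = "numeric", tau_e2 = "numeric",
                 c_ee = "numeric", c_e2 = "numeric", c_ei = "numeric",
                 c_ie = "numeric", a_e = "numeric", a_i = "numeric",
                 useRecovery = "logical"),
  prototype(tau_e1 = 0.5, tau_i1 = 0.5, tau_e2 = 3, c_ee = 0.3, c_e2 = 0.01,
            c_ei = 1, c_ie = 1, a_e = 1, a_i = 0.3, useRecovery = FALSE),
  validity = function(object) {
    msg <- character(0)
    for (s in c("tau_e1", "tau_i1", "tau_e2"))
      if (slot(object, s) <= 0) msg <- c(msg, paste(s, "must be > 0"))
    for (s in c("c_ee", "c_e2"))
      if (slot(object, s) < 0 || slot(object, s) >= 1)
        msg <- c(msg, paste(s, "must lie in [0, 1)"))
    if (length(msg)) msg else TRUE
  })

#' Vascular (Windkessel/balloon) parameters
#'
#' Defaults follow the standard balloon model at 1.5 T: tau_s = 1.54 s,
#' tau_f = 2.44 s, tau_0 = 2 s, alpha = 0.32, V0 = 0.04, k1 = 7 E0,
#' k2 = 2, k3 = 2 E0 - 0.2 (E0 = 0.4).  \code{R_A} is the shared-artery
#' resistance expressed as a fraction of the total steady-state path
#' resistance (0 disables the two-region coupling); \code{L_A} its
#' normalized inertance.
#'
#' @slot epsilon neurovascular coupling gain (1/s)
#' @slot tau_s vasoactive-signal decay (s)
#' @slot tau_f flow autoregulation (s)
#' @slot tau_0 mean transit time (s)
#' @slot alpha Grubb outflow exponent, in (0, 1)
#' @slot tau_visc viscoelastic compliance time constant (s)
#' @slot R_A shared-artery resistance fraction, in [0, 1)
#' @slot L_A shared-artery inertance (normalized, > 0)
#' @slot V0 resting venous blood-volume fraction, in (0, 0.1]
#' @slot k1,k2,k3 BOLD observation coefficients
#' @exportClass VascularParams
setClass("VascularParams",
  representation(epsilon = "numeric", tau_s = "numeric", tau_f = "numeric",
                 tau_0 = "numeric", alpha = "numeric", tau_visc = "numeric",
                 R_A = "numeric", L_A = "numeric", V0 = "numeric",
                 k1 = "numeric", k2 = "numeric", k3 = "numeric"),
  prototype(epsilon = 0.4, tau_s = 1.54, tau_f = 2.44, tau_0 = 2,
            alpha = 0.32, tau_visc = 5, R_A = 0, L_A = 0.1, V0 = 0.04,
            k1 = 2.8, k2 = 2, k3 = 0.6),
  validity = function(object) {
    msg <- character(0)
    for (s in c("tau_s", "tau_f", "tau_0", "L_A"))
      if (slot(object, s) <= 0) msg <- c(msg, paste(s, "must be > 0"))
    if (object@tau_visc < 0) msg <- c(msg, "tau_visc must be >= 0")
    if (object@R_A < 0 || object@R_A >= 1)
      msg <- c(msg, "R_A must lie in [0, 1)")
    if (object@alpha <= 0 || object@alpha >= 1)
      msg <- c(msg, "alpha must lie in (0, 1)")
    if (object@V0 <= 0 || object@V0 > 0.1)
      msg <- c(msg, "V0 must lie in (0, 0.1]")
    if (length(msg)) msg else TRUE
  })

#' Metabolic (oxygen-to-tissue transport) parameters
#'
#' @slot kappa neurometabolic coupling gain (1/s, >= 0); the default 0.05
#'   together with epsilon = 0.4 gives the normal flow/metabolism gain
#'   ratio of 8
#' @slot E0 resting oxygen extraction fraction, in (0, 1)
#' @slot tau_m metabolic signal decay (s)
#' @slot tau_m2 metabolic feedback (s)
#' @slot tau_g tissue-O2 time constant (s)
#' @slot tau_g2 tissue-O2 homeostatic return time (s); keeps the tissue O2
#'   pool bounded over long event trains
#' @exportClass MetabolicParams
setClass("MetabolicParams",
  representation(kappa = "numeric", E0 = "numeric", tau_m = "numeric",
                 tau_m2 = "numeric", tau_g = "numeric", tau_g2 = "numeric"),
  prototype(kappa = 0.05, E0 = 0.4, tau_m = 5, tau_m2 = 5, tau_g = 2,
            tau_g2 = 10),
  validity = function(object) {
    msg <- character(0)
    if (object@kappa < 0) msg <- c(msg, "kappa must be >= 0")
    if (object@E0 <= 0 || object@E0 >= 1)
      msg <- c(msg, "E0 must lie in (0, 1)")
    for (s in c("tau_m", "tau_m2", "tau_g", "tau_g2"))
      if (slot(object, s) <= 0) msg <- c(msg, paste(s, "must be > 0"))
    if (length(msg)) msg else TRUE
  })

.MECHANISMS <- c("PBR", "ECI", "NDA", "ANC", "ABS")

#' Full parameter vector of the biophysical model
#'
#' @slot mechanism one of "PBR", "ECI", "NDA", "ANC", "ABS"
#' @slot neural list of \linkS4class{NeuralParams}, one per region (two for
#'   ABS, one otherwise)
#' @slot vascular \linkS4class{VascularParams}
#' @slot metabolic \linkS4class{MetabolicParams}
#' @slot samplingRanges named list of c(lo, hi) pairs; names address
#'   parameters as "neural1.tau_i1", "vascular.epsilon", "metabolic.kappa"
#' @exportClass MechanismParams
setClass("MechanismParams",
  representation(mechanism = "character", neural = "list",
                 vascular = "VascularParams", metabolic = "MetabolicParams",
                 samplingRanges = "list"),
  validity = function(object) {
    msg <- character(0)
    if (!object@mechanism %in% .MECHANISMS)
      msg <- c(msg, paste("unknown mechanism:", object@mechanism))
    nr <- length(object@neural)
    if (!all(vapply(object@neural, is, TRUE, "NeuralParams")))
      msg <- c(msg, "neural must be a list of NeuralParams")
    if (object@mechanism == "ABS") {
      if (nr != 2) msg <- c(msg, "ABS requires two regions")
    } else {
      if (nr != 1) msg <- c(msg, "non-ABS mechanisms are single-region")
      if (object@vascular@R_A > 0)
        msg <- c(msg, "only ABS may have R_A > 0")
    }
    if (object@mechanism == "NDA" && nr == 1 &&
        !object@neural[[1]]@useRecovery)
      msg <- c(msg, "NDA requires the recovery configuration (useRecovery)")
    for (nm in names(object@samplingRanges)) {
      rg <- object@samplingRanges[[nm]]
      if (length(rg) != 2 || rg[1] > rg[2])
        msg <- c(msg, paste("invalid sampling range for", nm))
    }
    if (length(msg)) msg else TRUE
  })

#' Time-resolved state trajectory of a simulated mechanism
#'
#' @slot t time grid (s)
#' @slot regions list (one element per region) of data.frames with columns
#'   x_e, x_i, s, f, v, q, m, g, E, y (neuronal states, vasoactive signal,
#'   normalized CBF/CBV/deoxyhemoglobin/CMRO2/tissue O2, oxygen extraction
#'   fraction, BOLD fractional signal change)
#' @slot fA shared-artery flow (two-region model; length 0 otherwise)
#' @slot mechanism mechanism label
#' @slot params the \linkS4class{MechanismParams} that generated it
#' @exportClass StateTrajectory
setClass("StateTrajectory",
  representation(t = "numeric", regions = "list", fA = "numeric",
                 mechanism = "character", params = "MechanismParams"))

#' 4D synthetic fMRI scan series
#'
#' @slot data 4D array (x, y, z, t) of signal intensities
#' @slot voxelSize mm triple; the default 3 x 3 x 8 matches 3-mm in-plane
#'   voxels and 6-mm slices with a 2-mm gap
#' @slot TR repetition time (s)
#' @slot sliceOrder acquisition sequence of the z slices
#' @exportClass ScanSeries
setClass("ScanSeries",
  representation(data = "array", voxelSize = "numeric", TR = "numeric",
                 sliceOrder = "integer"),
  validity = function(object) {
    msg <- character(0)
    if (length(dim(object@data)) != 4)
      msg <- c(msg, "data must be a 4D array")
    if (length(object@voxelSize) != 3 || any(object@voxelSize <= 0))
      msg <- c(msg, "voxelSize must be three positive numbers")
    if (object@TR <= 0) msg <- c(msg, "TR must be > 0")
    if (length(object@sliceOrder) &&
        !setequal(object@sliceOrder, seq_len(dim(object@data)[3])))
      msg <- c(msg, "sliceOrder must permute the slice indices")
    if (length(msg)) msg else TRUE
  })

#' ARX model of a BOLD series with exogenous event input
#'
#' y_i = mu_i + sum_{j=1..p} phi_j y_{i-j} + sum_{j=1..r} theta_j s_{i-j-d}
#' + eps_i, with mu_i a polynomial drift.
#'
#' @slot p AR order
#' @slot r exogenous order
#' @slot d onset delay in scans
#' @slot driftOrder polynomial drift degree
#' @slot phi,theta,drift estimated coefficients
#' @slot sigma innovation standard deviation
#' @slot aic Akaike information criterion (N log sigma^2 + 2 k)
#' @slot n effective sample size used in the fit
#' @exportClass ArxModel
setClass("ArxModel",
  representation(p = "integer", r = "integer", d = "integer",
                 driftOrder = "integer", phi = "numeric", theta = "numeric",
                 drift = "numeric", sigma = "numeric", aic = "numeric",
                 n = "integer"),
  validity = function(object) {
    msg <- character(0)
    if (object@p < 0 || object@r < 0 || object@d < 0)
      msg <- c(msg, "orders p, r, d must be >= 0")
    if (length(object@phi) != object@p)
      msg <- c(msg, "phi must have length p")
    if (length(object@theta) != object@r)
      msg <- c(msg, "theta must have length r")
    if (length(msg)) msg else TRUE
  })

#' Fixed-length hemodynamic response function
#'
#' At the defaults (TR = 2 s, 32 s support) the HRF has exactly 16 samples.
#'
#' @slot values HRF samples at TR spacing
#' @slot TR sampling interval (s)
#' @slot delay onset delay d in scans
#' @slot ciLo,ciHi optional per-sample confidence bounds
#' @slot model the \linkS4class{ArxModel} it was reconstructed from (or NULL)
#' @exportClass HRF
setClass("HRF",
  representation(values = "numeric", TR = "numeric", delay = "integer",
                 ciLo = "numericOrNULL", ciHi = "numericOrNULL",
                 model = "ANY"),
  prototype(TR = 2, delay = 0L, ciLo = NULL, ciHi = NULL, model = NULL))

#' GLM design matrix
#'
#' For each condition the three regressors (canonical HRF, temporal
#' derivative, dispersion derivative, each convolved with the event train),
#' plus confounds and an intercept.
#'
#' @slot X numeric matrix, one row per scan
#' @slot labels column labels
#' @slot conditionCols list mapping each condition to its 3 column indices
#' @exportClass DesignMatrix
setClass("DesignMatrix",
  representation(X = "matrix", labels = "character",
                 conditionCols = "list"),
  validity = function(object) {
    msg <- character(0)
    if (ncol(object@X) != length(object@labels))
      msg <- c(msg, "labels must match the number of columns")
    keep <- apply(object@X, 2, function(col) any(col != 0))
    if (!all(keep)) msg <- c(msg, "design contains an all-zero column")
    if (length(msg)) msg else TRUE
  })

#' Fitted GLM
#'
#' @slot beta coefficient matrix (one column per voxel)
#' @slot sigma2 residual variance per voxel
#' @slot rho pooled lag-1 autocorrelation used for prewhitening
#' @slot dof residual degrees of freedom
#' @slot design the \linkS4class{DesignMatrix} (whitened)
#' @exportClass GlmFit
setClass("GlmFit",
  representation(beta = "matrix", sigma2 = "numeric", rho = "numeric",
                 dof = "numeric", design = "DesignMatrix"),
  validity = function(object) {
    msg <- character(0)
    if (any(object@sigma2 < 0)) msg <- c(msg, "sigma2 must be >= 0")
    if (abs(object@rho) >= 1) msg <- c(msg, "|rho| must be < 1")
    if (length(msg)) msg else TRUE
  })

#' PCA feature set for HRF classification
#'
#' @slot scores (n x 3) component scores
#' @slot labels per-row mechanism class
#' @slot basis (hrf length x 3) component loadings
#' @slot center mean HRF removed before projection
#' @slot explainedVariance per-component fraction of variance
#' @exportClass FeatureSet
setClass("FeatureSet",
  representation(scores = "matrix", labels = "factor", basis = "matrix",
                 center = "numeric", explainedVariance = "numeric"),
  validity = function(object) {
    msg <- character(0)
    if (nrow(object@scores) != length(object@labels))
      msg <- c(msg, "labels must match the number of score rows")
    if (ncol(object@scores) != ncol(object@basis))
      msg <- c(msg, "scores and basis disagree on component count")
    if (length(msg)) msg else TRUE
  })

#' Trained mechanism classifier (PCA basis + one-vs-one Gaussian SVM)
#'
#' @slot basis,center PCA projection applied to normalized HRFs
#' @slot svms list of pairwise binary SVMs
#' @slot classes class labels
#' @slot kernelScale Gaussian kernel scale (coarse: 4 sqrt(n features))
#' @slot boxConstraint SVM box constraint C
#' @slot seed training seed
#' @exportClass MechanismModel
setClass("MechanismModel",
  representation(basis = "matrix", center = "numeric", svms = "list",
                 classes = "character", kernelScale = "numeric",
                 boxConstraint = "numeric", seed = "integer"))
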