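#' @include AllClasses.R
NULL

#' Extract the BOLD time course of a trajectory
#'
#' @param object a \linkS4class{StateTrajectory}
#' @param region region index (ABS has two; the NBR region is region 2)
#' @return numeric vector of fractional BOLD signal change on the solver
#'   output grid
#' @export
setGeneric("bold", function(object, region = 1L) standardGeneric("bold"))

#' @rdname bold
#' @export
setMethod("bold", "StateTrajectory", function(object, region = 1L) {
  object@regions[[region]]$y
})

#' Relative cerebral blood flow of a trajectory
#' @inheritParams bold
#' @export
setGeneric("cbf", function(object, region = 1L) standardGeneric("cbf"))

#' @rdname cbf
#' @export
setMethod("cbf", "StateTrajectory", function(object, region = 1L) {
  object@regions[[region]]$f
})

#' Relative cerebral blood volume of a trajectory
#' @inheritParams bold
#' @export
setGeneric("cbv", function(object, region = 1L) standardGeneric("cbv"))

#' @rdname cbv
#' @export
setMethod("cbv", "StateTrajectory", function(object, region = 1L) {
  object@regions[[region]]$v
})

#' Time grid of a trajectory
#' @param object a \linkS4class{StateTrajectory}
#' @export
setGeneric("timeGrid", function(object) standardGeneric("timeGrid"))

#' @rdname timeGrid
#' @export
setMethod("timeGrid", "StateTrajectory", function(object) object@t)

#' Number of regions in a trajectory or parameter set
#' @param object a StateTrajectory or MechanismParams
#' @export
setGeneric("nRegions", function(object) standardGeneric("nRegions"))

#' @rdname nRegions
#' @export
setMethod("nRegions", "StateTrajectory",
          function(object) length(object@regions))

#' @rdname nRegions
#' @export
setMethod("nRegions", "MechanismParams",
          function(object) length(object@neural))

#' Mechanism label
#' @param object an object carrying a mechanism class label
#' @export
setGeneric("mechanism", function(object) standardGeneric("mechanism"))

#' @rdname mechanism
#' @export
setMethod("mechanism", "MechanismParams", function(object) object@mechanism)

#' @rdname mechanism
#' @export
setMethod("mechanism", "StateTrajectory", function(object) object@mechanism)

#' HRF sample values
#' @param object an \linkS4class{HRF}
#' @export
setGeneric("hrfValues", function(object) standardGeneric("hrfValues"))

#' @rdname hrfValues
#' @export
setMethod("hrfValues", "HRF", function(object) object@values)

#' Polarity (sign of the extremum) of an HRF
#' @param object an \linkS4class{HRF}
#' @return +1 or -1
#' @export
setGeneric("polarity", function(object) standardGeneric("polarity"))

#' @rdname polarity
#' @export
setMethod("polarity", "HRF", function(object) {
  v <- object@values
  as.numeric(sign(v[which.max(abs(v))]))
})

#' Design matrix as a plain matrix
#' @param object a \linkS4class{DesignMatrix}
#' @export
setGeneric("designMatrix", function(object) standardGeneric("designMatrix"))

#' @rdname designMatrix
#' @export
setMethod("designMatrix", "DesignMatrix", function(object) object@X)

#' Scan data as a 4D array
#' @param object a \linkS4class{ScanSeries}
#' @export
setGeneric("scanData", function(object) standardGeneric("scanData"))

#' @rdname scanData
#' @export
setMethod("scanData", "ScanSeries", function(object) object@data)

#' Number of volumes in a scan series
#' @param object a \linkS4class{ScanSeries}
#' @export
setGeneric("nVolumes", function(object) standardGeneric("nVolumes"))

#' @rdname nVolumes
#' @export
setMethod("nVolumes", "ScanSeries", function(object) dim(object@data)[4])

setMethod("show", "StimulusTrain", function(object) {
  cat("StimulusTrain:", length(object@onsets), "events over",
      object@duration, "s (pulse width", object@pulseWidth, "s)\n")
})

setMethod("show", "MechanismParams", function(object) {
  cat("MechanismParams:", object@mechanism, "-", length(object@neural),
      "region(s)\n")
  v <- object@vascular; m <- object@metabolic
  cat("  epsilon =", v@epsilon, " kappa =", m@kappa,
      if (object@mechanism == "ABS") paste(" R_A =", v@R_A) else "", "\n")
  if (length(object@samplingRanges))
    cat("  sampled parameters:",
        paste(names(object@samplingRanges), collapse = ", "), "\n")
})

setMethod("show", "StateTrajectory", function(object) {
  cat("StateTrajectory:", object@mechanism, "-", length(object@t),
      "time points,", length(object@regions), "region(s)\n")
  for (j in seq_along(object@regions)) {
    y <- object@regions[[j]]$y
    cat(sprintf("  region %d: BOLD range [%.4g, %.4g]\n", j, min(y), max(y)))
  }
})

setMethod("show", "ScanSeries", function(object) {
  d <- dim(object@data)
  cat(sprintf("ScanSeries: %d x %d x %d voxels, %d volumes (TR = %g s, voxel %g x %g x %g mm)\n",
              d[1], d[2], d[3], d[4], object@TR, object@voxelSize[1],
              object@voxelSize[2], object@voxelSize[3]))
})

setMethod("show", "ArxModel", function(object) {
  cat(sprintf("ArxModel: p = %d, r = %d, d = %d, drift order %d (AIC %.2f, sigma %.4g)\n",
              object@p, object@r, object@d, object@driftOrder, object@aic,
              object@sigma))
})

setMethod("show", "HRF", function(object) {
  cat(sprintf("HRF: %d samples at TR = %g s, delay %d scan(s), polarity %+d\n",
              length(object@values), object@TR, object@delay,
              as.integer(polarity(object))))
  if (!is.null(object@ciLo)) cat("  with permutation confidence band\n")
})

setMethod("show", "GlmFit", function(object) {
  cat(sprintf("GlmFit: %d coefficients x %d voxels (AR(1) rho = %.3f, dof = %g)\n",
              nrow(object@beta), ncol(object@beta), object@rho, object@dof))
})

setMethod("show", "FeatureSet", function(object) {
  cat(sprintf("FeatureSet: %d HRFs x %d components (%s)\n",
              nrow(object@scores), ncol(object@scores),
              paste(sprintf("%.1f%%", 100 * object@explainedVariance),
                    collapse = ", ")))
})

setMethod("show", "MechanismModel", function(object) {
  cat("MechanismModel:", paste(object@classes, collapse = "/"),
      sprintf("- Gaussian kernel scale %.3f, C = %g, %d pairwise SVMs\n",
              object@kernelScale, object@boxConstraint, length(object@svms)))
})
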