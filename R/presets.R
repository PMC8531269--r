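#' @include AllClasses.R utils.R
NULL

#' Mechanism presets
#'
#' Returns the default parameter vector and uniform sampling ranges for one
#' of the five response classes:
#' \describe{
#'   \item{PBR}{positive BOLD response; neurovascular gain epsilon = 0.4 and
#'     neurometabolic gain kappa = 0.05 (ratio 8, the normal value).}
#'   \item{ECI}{enhanced cortical inhibition; elevated inhibitory input gain
#'     a_i and a long inhibitory response time tau_i1 (sampled in 2-20 s).
#'     Longer inhibitory recovery spreads a fixed inhibitory charge over
#'     time, so the NBR amplitude falls with tau_i1.}
#'   \item{NDA}{neuronal disruption of network activity; reduced excitatory
#'     self-connectivity c_e2 = 0.01, suppressive external input
#'     (a_e < 0) and a slow recovery time tau_e2 (sampled in 1-6 s,
#'     bracketing the patient-fitted 3 s).}
#'   \item{ANC}{altered neurometabolic/vascular coupling; kappa sampled in
#'     0.3-0.7 1/s (default 0.51, a patient-fitted value) with epsilon kept
#'     at 0.4, so oxygen consumption outpaces flow.}
#'   \item{ABS}{arterial blood stealing; two regions share a supply artery
#'     with resistance fraction R_A sampled in 0.05-0.3 (default 0.17, a
#'     patient-fitted value).  Region 1 is driven (PBR-like); region 2 is
#'     passive and shows the NBR.}
#' }
#'
#' @param mechanism one of "PBR", "ECI", "NDA", "ANC", "ABS"
#' @return a \linkS4class{MechanismParams}
#' @examples
#' p <- makePreset("PBR")
#' p@vascular@epsilon / p@metabolic@kappa  # 8
#' @export
makePreset <- function(mechanism) {
  .check(is.character(mechanism) && length(mechanism) == 1 &&
           mechanism %in% .MECHANISMS,
         paste("unknown mechanism label:",
               paste(as.character(mechanism), collapse = ", ")))
  neu <- new("NeuralParams")
  vas <- new("VascularParams")
  met <- new("MetabolicParams")
  jit <- function(x, frac = 0.25) c(x * (1 - frac), x * (1 + frac))
  switch(mechanism,
    PBR = {
      ranges <- list("neural1.a_e" = jit(neu@a_e),
                     "vascular.epsilon" = jit(vas@epsilon),
                     "metabolic.kappa" = jit(met@kappa))
      new("MechanismParams", mechanism = "PBR", neural = list(neu),
          vascular = vas, metabolic = met, samplingRanges = ranges)
    },
    ECI = {
      neu@a_i <- 2; neu@a_e <- 0.2; neu@tau_i1 <- 6
      ranges <- list("neural1.tau_i1" = c(4, 16),
                     "neural1.a_i" = jit(neu@a_i))
      new("MechanismParams", mechanism = "ECI", neural = list(neu),
          vascular = vas, metabolic = met, samplingRanges = ranges)
    },
    NDA = {
      neu@useRecovery <- TRUE; neu@c_e2 <- 0.01; neu@tau_e2 <- 3
      neu@a_e <- -1; neu@a_i <- 0; neu@c_ei <- 1.5
      ranges <- list("neural1.tau_e2" = c(1, 6),
                     "neural1.a_e" = c(-1.25, -0.75))
      new("MechanismParams", mechanism = "NDA", neural = list(neu),
          vascular = vas, metabolic = met, samplingRanges = ranges)
    },
    ANC = {
      met@kappa <- 0.51
      ranges <- list("metabolic.kappa" = c(0.3, 0.7),
                     "neural1.a_e" = jit(neu@a_e))
      new("MechanismParams", mechanism = "ANC", neural = list(neu),
          vascular = vas, metabolic = met, samplingRanges = ranges)
    },
    ABS = {
      passive <- new("NeuralParams", a_e = 0, a_i = 0)
      vas@R_A <- 0.17
      # stealing is not activity-driven in the passive branch: with the
      # fast neurovascular feedback constant the stolen-flow region is
      # dominated by a compensatory rebound instead of an NBR, so the
      # branch flow feedback is slowed to autoregulation timescales
      vas@tau_f <- 40
      # shared-artery inertance delays the steal so the passive-region dip
      # peaks at canonical-HRF latency rather than at flow-rise onset
      vas@L_A <- 6
      ranges <- list("vascular.R_A" = c(0.05, 0.3),
                     "neural1.a_e" = jit(neu@a_e))
      new("MechanismParams", mechanism = "ABS", neural = list(neu, passive),
          vascular = vas, metabolic = met, samplingRanges = ranges)
    })
}

# Set a parameter addressed as "neural<k>.<slot>", "vascular.<slot>" or
# "metabolic.<slot>" inside a MechanismParams.
setParam <- function(params, name, value) {
  parts <- strsplit(name, ".", fixed = TRUE)[[1]]
  .check(length(parts) == 2, paste("malformed parameter path:", name))
  comp <- parts[1]; sl <- parts[2]
  if (grepl("^neural[0-9]+$", comp)) {
    k <- as.integer(sub("neural", "", comp))
    .check(k >= 1 && k <= length(params@neural),
           paste("no such region:", comp))
    slot(params@neural[[k]], sl) <- value
  } else if (comp == "vascular") {
    slot(params@vascular, sl) <- value
  } else if (comp == "metabolic") {
    slot(params@metabolic, sl) <- value
  } else stop("unknown parameter component: ", comp, call. = FALSE)
  validObject(params)
  params
}

getParam <- function(params, name) {
  parts <- strsplit(name, ".", fixed = TRUE)[[1]]
  comp <- parts[1]; sl <- parts[2]
  if (grepl("^neural[0-9]+$", comp))
    slot(params@neural[[as.integer(sub("neural", "", comp))]], sl)
  else if (comp == "vascular") slot(params@vascular, sl)
  else slot(params@metabolic, sl)
}

#' Draw a random parameter vector from a preset's sampling ranges
#'
#' Each free parameter is drawn independently and uniformly on its
#' (lo, hi) interval (the trial-to-trial variability model of the
#' classification experiment); all other parameters keep their preset
#' values.
#'
#' @param preset a \linkS4class{MechanismParams} with non-empty
#'   samplingRanges
#' @param seed RNG seed for reproducibility
#' @return a \linkS4class{MechanismParams} with sampled values
#' @export
sampleParameters <- function(preset, seed = NULL) {
  rg <- preset@samplingRanges
  .check(length(rg) > 0, "preset has no sampling ranges")
  for (nm in names(rg))
    .check(rg[[nm]][1] <= rg[[nm]][2],
           paste("sampling range lo > hi for", nm))
  draws <- withSeed(seed, {
    vapply(rg, function(b) runif(1, b[1], b[2]), numeric(1))
  })
  out <- preset
  for (nm in names(draws)) out <- setParam(out, nm, unname(draws[[nm]]))
  out@samplingRanges <- list()
  out
}
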