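#' @include AllClasses.R presets.R stimulus.R
NULL

# ---- reference right-hand sides -------------------------------------------
# These pure-R derivative functions document the model equations and serve
# as the independent oracle for the compiled integrator.

effNeural <- function(np) {
  if (np@useRecovery) c(tau_e = np@tau_e2, c_e = np@c_e2)
  else c(tau_e = np@tau_e1, c_e = np@c_ee)
}

#' Neuronal state derivatives
#'
#' Two-population neural mass:
#' \deqn{dx_e/dt = (-x_e + c_e x_e - c_{ie} x_i + a_e u)/\tau_e}
#' \deqn{dx_i/dt = (-x_i + c_{ei} x_e + a_i u)/\tau_{i1}}
#' with (tau_e, c_e) = (tau_e1, c_ee), or (tau_e2, c_e2) in the recovery
#' configuration.  The input gains scale with 1/tau, so a slower population
#' integrates the same input charge over a longer window - this is what
#' makes the ECI amplitude fall as the inhibitory recovery lengthens.  The
#' net drive passed downstream is n(t) = x_e.
#'
#' @param state numeric c(x_e, x_i)
#' @param params a \linkS4class{NeuralParams}
#' @param u external input value
#' @return numeric c(dx_e, dx_i)
#' @export
neuralDerivatives <- function(state, params, u) {
  .check(all(is.finite(state)) && is.finite(u),
         "non-finite neuronal state or input")
  e <- effNeural(params)
  x_e <- state[1]; x_i <- state[2]
  c((-x_e + e["c_e"] * x_e - params@c_ie * x_i + params@a_e * u) /
      e["tau_e"],
    (-x_i + params@c_ei * x_e + params@a_i * u) / params@tau_i1,
    use.names = FALSE)
}

#' Single-region hemodynamic derivatives (uncoupled Windkessel)
#'
#' \deqn{ds/dt = \epsilon n - s/\tau_s - (f-1)/\tau_f, \quad df/dt = s}
#' \deqn{dv/dt = (f - v^{1/\alpha}) / (\tau_0 + \tau_{visc})}
#' \deqn{f_{out} = v^{1/\alpha} + \tau_{visc} dv/dt}
#' \deqn{dq/dt = (m - f_{out} q / v) / \tau_0}
#' with m the normalized CMRO2 supplied by the metabolic component.
#'
#' @param state numeric c(s, f, v, q)
#' @param params a \linkS4class{VascularParams}
#' @param n neural drive
#' @param m normalized CMRO2 (default 1 = baseline)
#' @return numeric c(ds, df, dv, dq)
#' @export
hemoDerivativesSingle <- function(state, params, n, m = 1) {
  s <- state[1]; f <- state[2]; v <- state[3]; q <- state[4]
  .check(f > 0 && v > 0 && q > 0, "f, v and q must stay positive")
  fv <- v^(1 / params@alpha)
  dv <- (f - fv) / (params@tau_0 + params@tau_visc)
  fout <- fv + params@tau_visc * dv
  c(params@epsilon * n - s / params@tau_s - (f - 1) / params@tau_f,
    s,
    dv,
    (m - fout * q / v) / params@tau_0)
}

#' Coupled two-region hemodynamics (shared supply artery)
#'
#' Circuit analogy: each branch carries a flow conductance g_j with
#' dg_j/dt = s_j; the node pressure is P = f_A/(g_1+g_2) and branch flows
#' f_j = P g_j, so f_1 + f_2 = f_A identically.  The shared artery obeys
#' L_A df_A/dt = P_a - R_abs f_A - P with R_abs = 0.5 R_A/(1 - R_A) (R_A is
#' the fraction of total steady-state path resistance in the artery) and
#' P_a fixed by baseline f_j = 1.  With R_A = 0 the node is an ideal source
#' (P = 1, f_j = g_j) and each region follows the single-region law
#' exactly.
#'
#' @param states list of two numeric c(s, g, v, q) state vectors
#' @param params a \linkS4class{VascularParams}
#' @param drives numeric length 2, neural drives n_j
#' @param fA shared-artery flow state
#' @param m normalized CMRO2 per region (length 2)
#' @return list(dstates = list of c(ds, dg, dv, dq), dfA, flows)
#' @export
hemoDerivativesCoupled <- function(states, params, drives, fA = 2,
                                   m = c(1, 1)) {
  .check(length(states) == 2, "exactly two regions are required")
  .check(params@R_A >= 0 && params@L_A > 0, "need R_A >= 0 and L_A > 0")
  g <- vapply(states, `[`, numeric(1), 2)
  if (params@R_A > 0) {
    Rabs <- 0.5 * params@R_A / (1 - params@R_A)
    Pa <- 2 * Rabs + 1
    P <- fA / sum(g)
    flows <- P * g
    dfA <- (Pa - Rabs * fA - P) / params@L_A
  } else {
    flows <- g
    dfA <- 0
  }
  dstates <- lapply(1:2, function(j) {
    s <- states[[j]][1]; v <- states[[j]][3]; q <- states[[j]][4]
    f <- flows[j]
    .check(f > 0 && v > 0 && q > 0, "f, v and q must stay positive")
    fv <- v^(1 / params@alpha)
    dv <- (f - fv) / (params@tau_0 + params@tau_visc)
    fout <- fv + params@tau_visc * dv
    c(params@epsilon * drives[j] - s / params@tau_s - (f - 1) / params@tau_f,
      s,
      dv,
      (m[j] - fout * q / v) / params@tau_0)
  })
  list(dstates = dstates, dfA = dfA, flows = flows)
}

#' Oxygen-to-tissue transport derivatives
#'
#' The metabolic signal mirrors the vasoactive cascade with gain kappa:
#' \deqn{dw/dt = \kappa n - w/\tau_m - (m-1)/\tau_{m2}, \quad dm/dt = w}
#' Flow-dependent oxygen extraction \eqn{E(f) = 1-(1-E_0)^{1/f}} and tissue
#' O2 \deqn{dg/dt = (f E(f)/E_0 - m)/\tau_g - (g-1)/\tau_{g2},} where the
#' last term is a slow homeostatic return (tau_g2 = 10 s) that keeps the
#' tissue O2 pool bounded over long event trains; the tissue O2 state is an
#' observable and feeds nothing downstream.
#'
#' @param state numeric c(w, m, g)
#' @param params a \linkS4class{MetabolicParams}
#' @param n neural drive
#' @param f normalized flow
#' @return numeric c(dw, dm, dg) with attribute "E" (extraction fraction)
#' @export
ottDerivatives <- function(state, params, n, f) {
  w <- state[1]; m <- state[2]; g <- state[3]
  .check(m > 0 && g > 0, "m and g must stay positive")
  E <- 1 - (1 - params@E0)^(1 / f)
  out <- c(params@kappa * n - w / params@tau_m - (m - 1) / params@tau_m2,
           w,
           (f * E / params@E0 - m) / params@tau_g -
             (g - 1) / params@tau_g2)
  attr(out, "E") <- E
  out
}

#' BOLD observation equation
#'
#' \deqn{y = V_0 (k_1 (1-q) + k_2 (1-q/v) + k_3 (1-v))}
#'
#' @param v normalized blood volume (> 0)
#' @param q normalized deoxyhemoglobin (> 0)
#' @param params a \linkS4class{VascularParams}
#' @return fractional BOLD signal change
#' @export
boldSignal <- function(v, q, params) {
  .check(all(v > 0) && all(q > 0), "v and q must be positive")
  params@V0 * (params@k1 * (1 - q) + params@k2 * (1 - q / v) +
                 params@k3 * (1 - v))
}

# ---- production integrator -------------------------------------------------

parsToList <- function(params) {
  nr <- length(params@neural)
  neu <- vapply(params@neural, function(np) {
    e <- effNeural(np)
    c(e["tau_e"], np@tau_i1, e["c_e"], np@c_ei, np@c_ie, np@a_e, np@a_i)
  }, numeric(7))
  v <- params@vascular; m <- params@metabolic
  list(nregions = nr, neural = matrix(neu, nrow = 7),
       epsilon = v@epsilon, tau_s = v@tau_s, tau_f = v@tau_f,
       tau_0 = v@tau_0, alpha = v@alpha, tau_visc = v@tau_visc,
       R_A = v@R_A, L_A = v@L_A, V0 = v@V0, k1 = v@k1, k2 = v@k2,
       k3 = v@k3, kappa = m@kappa, E0 = m@E0, tau_m = m@tau_m,
       tau_m2 = m@tau_m2, tau_g = m@tau_g, tau_g2 = m@tau_g2)
}

#' Simulate a mechanism's response to a stimulus train
#'
#' Integrates the composed neuronal / vascular / metabolic system with a
#' fixed-step RK4 scheme whose steps are aligned to the pulse edges (the
#' right-hand side is smooth within every step), and returns all states on
#' a regular output grid.
#'
#' @param params a \linkS4class{MechanismParams} (see \code{\link{makePreset}})
#' @param stim a \linkS4class{StimulusTrain}
#' @param dt solver step bound (s)
#' @param tEnd end of integration (s); defaults to the train duration
#' @param dtOut output sampling interval (s)
#' @return a \linkS4class{StateTrajectory}
#' @examples
#' tr <- simulateMechanism(makePreset("PBR"),
#'                         stimulusTrain(5, duration = 60), tEnd = 60)
#' max(bold(tr)) > 0
#' @export
simulateMechanism <- function(params, stim, dt = 0.02, tEnd = stim@duration,
                              dtOut = 0.1) {
  .check(dt > 0, "dt must be > 0")
  .check(stim@duration <= tEnd + 1e-9, "stim duration must be <= tEnd")
  validObject(params)
  nr <- length(params@neural)
  mat <- .integrate_model(parsToList(params), stim@onsets, stim@amplitudes,
                          stim@pulseWidth, tEnd, dt, dtOut)
  cols <- c("x_e", "x_i", "s", "f", "v", "q", "m", "g", "E", "y")
  regions <- lapply(seq_len(nr), function(j) {
    d <- as.data.frame(mat[, 1 + (j - 1) * 10 + seq_len(10), drop = FALSE])
    names(d) <- cols
    d
  })
  fA <- if (nr == 2) mat[, ncol(mat)] else numeric(0)
  new("StateTrajectory", t = mat[, 1], regions = regions, fA = fA,
      mechanism = params@mechanism, params = params)
}

#' Resample a trajectory's BOLD signal to the scanner TR grid
#'
#' Cubic interpolation of the solver output onto scan times 0, TR, 2 TR,
#' ...; a 10-min series at TR = 2 s yields exactly 300 samples.
#'
#' @param traj a \linkS4class{StateTrajectory}
#' @param TR repetition time (s)
#' @param region region index
#' @return numeric vector of length floor(duration / TR)
#' @export
boldAtTR <- function(traj, TR, region = 1L) {
  tmax <- max(traj@t)
  n <- floor(tmax / TR + 1e-9)
  tout <- (seq_len(n) - 1) * TR
  spline(traj@t, bold(traj, region), xout = tout)$y
}

#' Summary metrics of a negative BOLD response
#'
#' \code{nbrAmplitude} is |min y|; \code{nbrRecoveryTime} is the time from
#' the BOLD minimum until the response has recovered to within
#' \code{frac} of that minimum.  The default fraction (0.25) sits above the
#' amplitude of the secondary Windkessel ripple (about 20 percent of the
#' dip), so the metric tracks the neural recovery rather than the
#' vascular ringing.
#'
#' @param traj a \linkS4class{StateTrajectory}
#' @param region region index
#' @param frac recovery fraction (default 0.25)
#' @export
nbrAmplitude <- function(traj, region = 1L) abs(min(bold(traj, region)))

#' @rdname nbrAmplitude
#' @export
nbrRecoveryTime <- function(traj, region = 1L, frac = 0.25) {
  y <- bold(traj, region); t <- traj@t
  i0 <- which.min(y)
  below <- which(y <= frac * y[i0])  # y[i0] < 0
  below <- below[below >= i0]
  t[max(below)] - t[i0]
}

#' Export a trajectory as a delimited text table
#'
#' One column per state, prefixed by region for multi-region models.
#'
#' @param traj a \linkS4class{StateTrajectory}
#' @param path output file
#' @export
writeTrajectory <- function(traj, path) {
  out <- data.frame(t = traj@t)
  for (j in seq_along(traj@regions)) {
    d <- traj@regions[[j]]
    names(d) <- paste0("r", j, "_", names(d))
    out <- cbind(out, d)
  }
  if (length(traj@fA)) out$fA <- traj@fA
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
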