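# Shared oracles and fixtures, independent of the compiled integrator.

# Reference RK4 integration of the single-region model built purely from the
# exported R derivative functions (the documented equations).  Used to
# cross-check the compiled path.
rIntegrateSingle <- function(params, stim, tEnd, dt = 0.01) {
  neu <- params@neural[[1]]; vas <- params@vascular; met <- params@metabolic
  uAt <- function(t) {
    sum(stim@amplitudes[t >= stim@onsets & t < stim@onsets + stim@pulseWidth])
  }
  state <- c(xe = 0, xi = 0, s = 0, f = 1, v = 1, q = 1, w = 0, m = 1, g = 1)
  deriv <- function(x, u) {
    dn <- neuralDerivatives(x[1:2], neu, u)
    dh <- hemoDerivativesSingle(x[3:6], vas, n = x[1], m = x[8])
    dm <- ottDerivatives(x[7:9], met, n = x[1], f = x[4])
    c(dn, dh, as.numeric(dm))
  }
  # step boundaries aligned to pulse edges so u is constant within steps
  edges <- sort(unique(c(0, tEnd, stim@onsets, stim@onsets + stim@pulseWidth)))
  edges <- edges[edges >= 0 & edges <= tEnd]
  ts <- c(0); ys <- c(boldSignal(1, 1, vas)); states <- list(state)
  for (k in seq_len(length(edges) - 1)) {
    a <- edges[k]; b <- edges[k + 1]
    u <- uAt((a + b) / 2)
    nst <- max(1, ceiling((b - a) / dt))
    h <- (b - a) / nst
    for (i in seq_len(nst)) {
      k1 <- deriv(state, u)
      k2 <- deriv(state + h / 2 * k1, u)
      k3 <- deriv(state + h / 2 * k2, u)
      k4 <- deriv(state + h * k3, u)
      state <- state + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    ts <- c(ts, b)
    ys <- c(ys, boldSignal(state[5], state[6], vas))
    states <- c(states, list(state))
  }
  list(t = ts, y = ys, states = states)
}

# shared cache so expensive fixtures are computed once per test run
.cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# small labeled ensemble reused by classifier tests
smallEnsemble <- function() {
  cached("smallEnsemble", generateTrainingEnsemble(M = 8, seed = 42))
}
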