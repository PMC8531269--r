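# Forward model: derivative contracts, presets, integration invariants.

test_that("all derivative components vanish at baseline", {
  neu <- new("NeuralParams"); vas <- new("VascularParams")
  met <- new("MetabolicParams")
  expect_equal(neuralDerivatives(c(0, 0), neu, 0), c(0, 0))
  expect_equal(hemoDerivativesSingle(c(0, 1, 1, 1), vas, n = 0), rep(0, 4))
  vas2 <- vas; vas2@R_A <- 0.17
  cp <- hemoDerivativesCoupled(list(c(0, 1, 1, 1), c(0, 1, 1, 1)), vas2,
                               drives = c(0, 0), fA = 2)
  expect_equal(cp$dstates[[1]], rep(0, 4))
  expect_equal(cp$dfA, 0)
  expect_equal(sum(cp$flows), 2)
  om <- ottDerivatives(c(0, 1, 1), met, n = 0, f = 1)
  expect_equal(as.numeric(om), rep(0, 3))
  expect_equal(attr(om, "E"), met@E0)
})

test_that("positive input drives the excitatory population upward", {
  neu <- new("NeuralParams")
  d <- neuralDerivatives(c(0, 0), neu, 1)
  expect_gt(d[1], 0)
  expect_error(neuralDerivatives(c(NA, 0), neu, 1), "non-finite")
})

test_that("decoupled step response reaches 63% of plateau at tau_e1", {
  neu <- new("NeuralParams", c_ee = 0, c_ei = 0, c_ie = 0, a_e = 1,
             tau_e1 = 0.8)
  # closed form: x(t) = a_e*u*(1 - exp(-t/tau)); verify via RK4 on the
  # exported derivative
  x <- c(0, 0); dt <- 0.001; tGrid <- seq(dt, 8, by = dt)
  xs <- numeric(length(tGrid))
  for (i in seq_along(tGrid)) {
    k1 <- neuralDerivatives(x, neu, 1)
    k2 <- neuralDerivatives(x + dt / 2 * k1, neu, 1)
    k3 <- neuralDerivatives(x + dt / 2 * k2, neu, 1)
    k4 <- neuralDerivatives(x + dt * k3, neu, 1)
    x <- x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    xs[i] <- x[1]
  }
  plateau <- xs[length(xs)]
  t63 <- tGrid[min(which(xs >= (1 - exp(-1)) * plateau))]
  expect_equal(t63, 0.8, tolerance = 0.01)
})

test_that("volume converges to F^alpha under clamped flow", {
  vas <- new("VascularParams", tau_visc = 0)
  Fc <- 1.4
  v <- 1
  for (i in 1:40000) {
    dv <- (Fc - v^(1 / vas@alpha)) / vas@tau_0
    v <- v + 0.01 * dv
  }
  expect_equal(v, Fc^vas@alpha, tolerance = 1e-6)
  # same steady state through the exported derivative
  d <- hemoDerivativesSingle(c(0, Fc, Fc^vas@alpha, 1), vas, n = 0)
  expect_equal(d[3], 0, tolerance = 1e-12)
})

test_that("BOLD observation equation is the stated algebra", {
  vas <- new("VascularParams")
  expect_equal(boldSignal(1, 1, vas), 0)
  expect_equal(boldSignal(1, 0.9, vas),
               vas@V0 * (0.1 * vas@k1 + 0.1 * vas@k2))
  expect_equal(boldSignal(1.1, 1.05, vas),
               vas@V0 * (vas@k1 * (1 - 1.05) + vas@k2 * (1 - 1.05 / 1.1) +
                           vas@k3 * (1 - 1.1)))
  expect_error(boldSignal(-1, 1, vas), "positive")
})

test_that("presets carry the published anchors", {
  p <- makePreset("PBR")
  expect_identical(p@vascular@epsilon / p@metabolic@kappa, 8)
  expect_identical(makePreset("NDA")@neural[[1]]@c_e2, 0.01)
  expect_equal(makePreset("ANC")@metabolic@kappa, 0.51)
  expect_equal(makePreset("ABS")@vascular@R_A, 0.17)
  expect_error(makePreset("XYZ"), "unknown mechanism")
  # ranges bracket their defaults
  for (mech in c("PBR", "ECI", "NDA", "ANC", "ABS")) {
    pr <- makePreset(mech)
    for (nm in names(pr@samplingRanges)) {
      rg <- pr@samplingRanges[[nm]]
      d <- nbrmech:::getParam(pr, nm)
      expect_true(rg[1] <= d && d <= rg[2], label = paste(mech, nm))
    }
  }
})

test_that("parameter sampling is uniform, in range and reproducible", {
  pre <- makePreset("ECI")
  s1 <- sampleParameters(pre, seed = 3)
  s2 <- sampleParameters(pre, seed = 3)
  expect_equal(s1@neural[[1]]@tau_i1, s2@neural[[1]]@tau_i1)
  draws <- vapply(1:10000, function(i)
    sampleParameters(pre, seed = i)@neural[[1]]@tau_i1, numeric(1))
  rg <- pre@samplingRanges[["neural1.tau_i1"]]
  expect_true(all(draws >= rg[1] & draws <= rg[2]))
  se <- diff(rg) / sqrt(12) / sqrt(10000)
  expect_lt(abs(mean(draws) - mean(rg)), 3 * se)
  bad <- pre
  bad@samplingRanges[["neural1.tau_i1"]] <- c(5, 2)
  expect_error(sampleParameters(bad, seed = 1), "lo > hi")
})

test_that("zero stimulus keeps every state at baseline for 600 s", {
  for (mech in c("PBR", "ABS")) {
    tr <- simulateMechanism(makePreset(mech),
                            stimulusTrain(numeric(0), duration = 600),
                            tEnd = 600)
    for (j in seq_len(nRegions(tr)))
      expect_lt(max(abs(bold(tr, j))), 1e-6)
  }
})

test_that("compiled integrator matches the R derivative oracle", {
  stim <- stimulusTrain(c(3, 9.5), duration = 40)
  for (mech in c("PBR", "ECI", "NDA", "ANC")) {
    pars <- makePreset(mech)
    ref <- rIntegrateSingle(pars, stim, tEnd = 40, dt = 0.01)
    tr <- simulateMechanism(pars, stim, dt = 0.01, tEnd = 40, dtOut = 0.1)
    yAtRef <- bold(tr)[match(round(ref$t, 6), round(tr@t, 6))]
    keep <- !is.na(yAtRef)
    expect_gt(sum(keep), 5)
    expect_lt(max(abs(yAtRef[keep] - ref$y[keep])), 1e-8)
  }
})

test_that("halving the solver step changes BOLD by < 1e-4", {
  stim <- stimulusTrain(5, duration = 90)
  for (mech in c("ECI", "ABS")) {
    reg <- if (mech == "ABS") 2L else 1L
    ya <- bold(simulateMechanism(makePreset(mech), stim, dt = 0.02,
                                 tEnd = 90), reg)
    yb <- bold(simulateMechanism(makePreset(mech), stim, dt = 0.01,
                                 tEnd = 90), reg)
    expect_lt(max(abs(ya - yb)), 1e-4)
  }
})

test_that("rCBF peaks before BOLD for the positive response", {
  tr <- simulateMechanism(makePreset("PBR"), stimulusTrain(5, duration = 90),
                          tEnd = 90)
  expect_lt(tr@t[which.max(cbf(tr))], tr@t[which.max(bold(tr))])
})

test_that("R_A = 0 reduces the coupled model to the single-region law", {
  stim <- stimulusTrain(5, duration = 90)
  pars <- makePreset("ABS")
  pars@vascular@R_A <- 0
  coupled <- simulateMechanism(pars, stim, tEnd = 90)
  single <- makePreset("PBR")
  single@neural[[1]] <- pars@neural[[1]]
  single@vascular <- pars@vascular   # same tau_f etc., R_A already 0
  ref <- simulateMechanism(single, stim, tEnd = 90)
  expect_lt(max(abs(bold(coupled, 1) - bold(ref, 1))), 1e-4)
  expect_equal(max(abs(bold(coupled, 2))), 0)  # passive region silent
})

test_that("shared-artery flow is conserved at every output step", {
  tr <- simulateMechanism(makePreset("ABS"), stimulusTrain(5, duration = 90),
                          tEnd = 90)
  expect_lt(max(abs(tr@fA - (cbf(tr, 1) + cbf(tr, 2)))), 1e-9)
  expect_equal(tr@fA[1], 2)
})

test_that("sign contracts hold at the preset defaults", {
  stim <- stimulusTrain(5, duration = 90)
  for (mech in c("PBR", "ECI", "NDA", "ANC", "ABS")) {
    reg <- if (mech == "ABS") 2L else 1L
    y <- bold(simulateMechanism(makePreset(mech), stim, tEnd = 90), reg)
    if (mech == "PBR") expect_gt(max(y), abs(min(y)))
    else expect_gt(abs(min(y)), max(y))
  }
})
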