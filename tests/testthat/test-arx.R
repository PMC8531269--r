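# ARX HRF estimation: fitting, order selection, reconstruction, bands.

# simulate data exactly from the ARX difference equation
arxSim <- function(n, phi, theta, d, s, sigma = 0, drift = 0) {
  y <- numeric(n)
  p <- length(phi); r <- length(theta)
  eps <- if (sigma > 0) rnorm(n, 0, sigma) else numeric(n)
  for (i in seq_len(n)) {
    acc <- drift + if (sigma > 0) eps[i] else 0
    if (p > 0) for (j in 1:p) if (i - j >= 1) acc <- acc + phi[j] * y[i - j]
    if (r > 0) for (j in 1:r) {
      k <- i - j - d
      if (k >= 1) acc <- acc + theta[j] * s[k]
    }
    y[i] <- acc
  }
  y
}

test_that("noiseless ARX data is recovered exactly at the true orders", {
  set.seed(5)
  s <- rbinom(300, 1, 0.1)
  phi <- 0.5; theta <- c(0.4, 0.8, 0.3, -0.2)
  y <- arxSim(300, phi, theta, d = 1, s = s)
  fit <- fitArx(y, s, p = 1, r = 4, d = 1, driftOrder = 0)
  expect_equal(fit@phi, phi, tolerance = 1e-8)
  expect_equal(fit@theta, theta, tolerance = 1e-8)
  expect_lt(fit@sigma, 1e-8)
})

test_that("null input yields theta estimates indistinguishable from zero", {
  # under H0 each |t| < 2 with probability ~0.95, so pool the t values
  set.seed(6)
  tvals <- unlist(lapply(1:100, function(i) {
    y <- arxSim(300, 0.3, numeric(0), 0, numeric(300), sigma = 1)
    s <- numeric(300); s[seq(10, 290, by = 25)] <- 1  # events, no effect
    reg <- nbrmech:::arxRegressors(y, s, p = 1, r = 4, d = 0,
                                   driftOrder = 0, istart = 6)
    fit <- stats::lm(reg$yy ~ reg$X - 1)
    summary(fit)$coefficients[3:6, "t value"]
  }))
  expect_gte(mean(abs(tvals) < 2), 0.9)
  expect_lt(abs(mean(tvals)), 0.1)
})

test_that("a constant series is absorbed by the drift term", {
  y <- rep(4.2, 100)
  s <- numeric(100); s[c(20, 60)] <- 1
  fit <- fitArx(y, s, p = 0, r = 2, d = 0, driftOrder = 0)
  expect_lt(fit@sigma, 1e-10)
  expect_equal(fit@theta, c(0, 0), tolerance = 1e-10)
})

test_that("collinear regressors raise an informative error", {
  y <- rep(1, 100)  # constant y makes the AR lag collinear with drift0
  s <- numeric(100); s[50] <- 1
  expect_error(fitArx(y, s, p = 1, r = 1, d = 0, driftOrder = 0),
               "collinearity")
})

test_that("order selection minimizes AIC over the grid", {
  set.seed(7)
  s <- rbinom(300, 1, 0.1)
  y <- arxSim(300, 0.5, c(0.5, 1, 0.4), d = 1, s = s, sigma = 0.1)
  grid <- list(p = 1:2, r = 2:4, d = 0:2, drift = 0)
  best <- selectOrders(y, s, grid)
  # argmin property: no stable grid cell beats the returned AIC
  istart <- max(max(grid$p), max(grid$r) + max(grid$d)) + 1L
  for (p in grid$p) for (r in grid$r) for (d in grid$d) {
    m <- tryCatch(fitArx(y, s, p, r, d, 0, istart = istart),
                  error = function(e) NULL)
    if (!is.null(m) && nbrmech:::arStable(m@phi))
      expect_gte(m@aic, best@aic - 1e-9)
  }
  # a single-cell grid returns that model
  one <- selectOrders(y, s, list(p = 2, r = 3, d = 1, drift = 1))
  expect_identical(c(one@p, one@r, one@d, one@driftOrder),
                   c(2L, 3L, 1L, 1L))
})

test_that("order selection is consistent at moderate SNR", {
  set.seed(8)
  hits <- vapply(1:100, function(i) {
    s <- rbinom(300, 1, 0.08)
    theta <- c(0.1, 0.5, 1, 0.9, 0.5, 0.1, -0.2, -0.1)
    sigNoiseless <- arxSim(300, 0.5, theta, d = 1, s = s)
    sigma <- sd(sigNoiseless) / 5          # SNR 5
    y <- arxSim(300, 0.5, theta, d = 1, s = s, sigma = sigma)
    m <- selectOrders(y, s, list(p = 1:3, r = 8, d = 0:3, drift = 0))
    m@p == 1L && m@d == 1L
  }, logical(1))
  expect_gte(mean(hits), 0.6)
})

test_that("HRF reconstruction is the impulse response of the fit", {
  # FIR case: p = 0 puts theta at lags d+1 .. d+r
  m <- new("ArxModel", p = 0L, r = 3L, d = 2L, driftOrder = 0L,
           phi = numeric(0), theta = c(5, 3, 1), drift = 0, sigma = 0,
           aic = 0, n = 100L)
  h <- reconstructHrf(m)
  expect_length(h@values, 16)
  expect_equal(h@values[1:7], c(0, 0, 0, 5, 3, 1, 0))
  # general case matches a direct recursion of the difference equation
  m2 <- new("ArxModel", p = 2L, r = 4L, d = 1L, driftOrder = 0L,
            phi = c(0.9, -0.3), theta = c(1, 2, 1, 0.5), drift = 0,
            sigma = 0, aic = 0, n = 100L)
  h2 <- reconstructHrf(m2)@values
  s <- c(1, numeric(39))
  ref <- arxSim(40, m2@phi, m2@theta, m2@d, s)
  # h_{i} equals the recursion output at index i+1 (impulse at index 1)
  expect_equal(h2, ref[1:16], tolerance = 1e-12)
  # unstable AR polynomial is rejected
  mb <- m2; mb@phi <- c(1.5, 0.2)
  expect_error(reconstructHrf(mb), "unstable")
})

test_that("normalization preserves polarity and is idempotent", {
  h <- new("HRF", values = c(0, -2, -4, -1), TR = 2, delay = 0L)
  n1 <- normalizeHrf(h)
  expect_equal(max(abs(n1@values)), 1)
  expect_equal(min(n1@values), -1)
  expect_equal(polarity(n1), -1)
  expect_equal(normalizeHrf(n1)@values, n1@values)
  expect_error(normalizeHrf(new("HRF", values = rep(0, 4), TR = 2,
                                delay = 0L)), "all-zero")
})

test_that("permutation bands are reproducible and cover the null", {
  set.seed(9)
  y <- arxSim(300, 0.3, numeric(0), 0, numeric(300), sigma = 1)
  s <- numeric(300); s[sample(20:280, 20)] <- 1
  model <- fitArx(y, s, p = 1, r = 8, d = 0, driftOrder = 0)
  ci1 <- permutationCi(y, s, model, nPerm = 200, seed = 4)
  ci2 <- permutationCi(y, s, model, nPerm = 200, seed = 4)
  expect_identical(ci1$lo, ci2$lo)
  # null data: the zero line lies inside the band at >= 90% of time points
  expect_gte(mean(ci1$lo <= 0 & 0 <= ci1$hi), 0.9)
  # degenerate levels span the whole null range
  ciFull <- permutationCi(y, s, model, nPerm = 100, levels = c(0, 100),
                          seed = 4)
  expect_equal(ciFull$lo, apply(ciFull$null, 2, min))
  expect_error(permutationCi(y, numeric(300), model, nPerm = 10),
               "at least 2 events")
})

test_that("a known HRF convolved with events is recovered (SNR >= 3)", {
  set.seed(10)
  b <- canonicalBasis(2)
  hTrue <- b$h[1:16]
  cors <- vapply(1:50, function(i) {
    tr <- poissonTrain(2.6, 600, seed = 3000 + i)
    s <- binEvents(tr, 300, 2)
    clean <- as.numeric(stats::filter(c(rep(0, 15), s), hTrue,
                                      sides = 1))[16:315]
    noise <- as.numeric(arima.sim(list(ar = 0.3), 300))
    noise <- noise / sd(noise) * sd(clean) / 3
    est <- normalizeHrf(estimateHrf(clean + noise, tr))@values
    cor(est, hTrue)
  }, numeric(1))
  expect_gte(median(cors), 0.95)
})

test_that("negative-polarity responses never flip sign noiselessly", {
  set.seed(12)
  b <- canonicalBasis(2)
  hNeg <- -b$h[1:16]
  flips <- vapply(1:20, function(i) {
    tr <- poissonTrain(2.6, 600, seed = 4000 + i)
    s <- binEvents(tr, 300, 2)
    clean <- as.numeric(stats::filter(c(rep(0, 15), s), hNeg,
                                      sides = 1))[16:315]
    polarity(estimateHrf(clean, tr)) == -1
  }, logical(1))
  expect_true(all(flips))
})

test_that("matrix input is averaged as an ROI series", {
  set.seed(13)
  tr <- poissonTrain(2.6, 600, seed = 77)
  s <- binEvents(tr, 300, 2)
  b <- canonicalBasis(2)
  clean <- as.numeric(stats::filter(c(rep(0, 15), s), b$h[1:16],
                                    sides = 1))[16:315]
  Y <- cbind(clean + rnorm(300, 0, 0.05), clean + rnorm(300, 0, 0.05))
  h1 <- estimateHrf(Y, tr)
  h2 <- estimateHrf(rowMeans(Y), tr)
  expect_identical(h1@values, h2@values)
})
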