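# GLM detection: basis, design, prewhitening, fitting, inference.

test_that("canonical basis has the documented calculus relations", {
  b <- canonicalBasis(0.001)
  expect_equal(b$h[1], 0)
  expect_gt(sum(b$h) * 0.001, 0)
  # fundamental theorem: trapezoid integral of h' recovers h(end) - h(0)
  n <- length(b$hd)
  trap <- sum((b$hd[-1] + b$hd[-n]) / 2) * 0.001
  expect_equal(trap, b$h[n] - b$h[1], tolerance = 1e-6)
  # dispersion derivative matches an independent central finite difference
  # oracle: recompute the unscaled double-gamma directly
  b1 <- canonicalBasis(0.1)
  t <- b1$t
  shape <- function(disp)
    dgamma(t, shape = 6 / disp, rate = 1 / disp) -
      dgamma(t, shape = 16, rate = 1) / 6
  sc <- max(shape(1))
  fd <- (shape(1 + 0.01) - shape(1 - 0.01)) / 0.02 / sc
  expect_lt(max(abs(b1$dd - fd)), 1e-4)
})

test_that("design construction yields the three basis regressors", {
  tr <- stimulusTrain(c(0, 30.5, 61), 120)
  X <- buildDesign(list(ied = tr), nScans = 60, TR = 2)
  expect_equal(ncol(X@X), 4)  # hrf, der, disp, intercept
  expect_equal(X@labels[4], "intercept")
  # single event at t = 0: first regressor is h sampled at scan times
  tr0 <- stimulusTrain(0, 120)
  X0 <- buildDesign(list(ied = tr0), nScans = 60, TR = 2)
  b <- canonicalBasis(2 / 16)
  hAtScans <- b$h[round((0:59) * 2 / (2 / 16)) + 1]
  hAtScans[is.na(hAtScans)] <- 0
  expect_equal(X0@X[1:17, 1], hAtScans[1:17], tolerance = 1e-6)
  expect_error(buildDesign(list(a = stimulusTrain(numeric(0), 120)),
                           60, 2), "empty event train")
  # confounds are appended with labels
  Xc <- buildDesign(list(ied = tr), 60, 2,
                    confounds = matrix(rnorm(60), 60, 1))
  expect_equal(ncol(Xc@X), 5)
})

test_that("fine-grid convolution approximates continuous-time quadrature", {
  tr <- stimulusTrain(c(7.25, 40.125), 120)  # on the TR/16 grid
  X <- buildDesign(list(ied = tr), nScans = 60, TR = 2)
  # oracle: direct evaluation h(t - onset) summed over events
  dtq <- 0.001
  bq <- canonicalBasis(dtq)
  hFun <- function(t) {
    idx <- round(t / dtq) + 1
    out <- numeric(length(t))
    ok <- t >= 0 & idx <= length(bq$h)
    out[ok] <- bq$h[idx[ok]]
    out
  }
  scans <- (0:59) * 2
  ref <- hFun(scans - 7.25) + hFun(scans - 40.125)
  expect_lt(max(abs(X@X[, 1] - ref)), 1e-3)
})

test_that("AR(1) prewhitening recovers rho and whitens residuals", {
  set.seed(11)
  N <- 300
  X <- buildDesign(list(ied = poissonTrain(2.6, N * 2, seed = 2)), N, 2)
  # AR(1) noise with rho = 0.4
  Y <- vapply(1:40, function(i)
    as.numeric(arima.sim(list(ar = 0.4), N)), numeric(N))
  w <- prewhitenAR1(Y, X)
  expect_lt(abs(w$rho - 0.4), 0.05)
  res <- stats::lm.fit(w$X@X, w$Y)$residuals
  l1 <- sum(res[-1, ] * res[-nrow(res), ]) / sum(res^2)
  expect_lt(abs(l1), 0.05)
  # white input: pooled rho near zero
  Yw <- matrix(rnorm(N * 40), N, 40)
  expect_lt(abs(prewhitenAR1(Yw, X)$rho), 0.05)
})

test_that("least-squares fit is exact and matches the normal equations", {
  set.seed(3)
  N <- 80
  X <- buildDesign(list(ied = stimulusTrain(c(5, 60, 100), N * 2)), N, 2)
  beta0 <- c(2, -1, 0.5, 3)
  Y <- X@X %*% beta0
  fit <- fitGlm(Y, X)
  expect_equal(as.numeric(fit@beta), beta0, tolerance = 1e-10)
  expect_equal(fit@sigma2, 0, tolerance = 1e-18)
  fit0 <- fitGlm(matrix(0, N, 1), X)
  expect_equal(as.numeric(fit0@beta), rep(0, 4))
  # 10-voxel instance vs explicit normal-equations solve
  Y10 <- X@X %*% matrix(rnorm(40), 4) + matrix(rnorm(N * 10), N, 10)
  f10 <- fitGlm(Y10, X)
  bOracle <- solve(crossprod(X@X), crossprod(X@X, Y10))
  expect_lt(max(abs(f10@beta - bOracle)), 1e-10)
  # rank deficiency names the collinear column
  Xbad <- X
  Xbad@X <- cbind(X@X, dup = X@X[, 1])
  Xbad@labels <- c(X@labels, "dup")
  expect_error(fitGlm(Y, Xbad), "collinear")
})

test_that("F contrast is calibrated under the null and equals t^2 for 1 df", {
  set.seed(21)
  N <- 120
  X <- buildDesign(list(ied = poissonTrain(2.6, N * 2, seed = 5)), N, 2)
  Y <- matrix(rnorm(N * 2000), N, 2000)
  fit <- fitGlm(Y, X)
  fc <- fContrast(fit)
  typeI <- mean(fc$p < 0.05)
  expect_gt(typeI, 0.03); expect_lt(typeI, 0.07)
  # strong injected signal separates completely
  Ysig <- cbind(Y[, 1:200], X@X[, 1] * 50 + rnorm(N))
  fs <- fContrast(fitGlm(Ysig, X))
  expect_gt(fs$F[201], max(fs$F[1:200]))
  # single-row contrast equals squared t
  C1 <- matrix(0, 1, 4); C1[1, 1] <- 1
  f1 <- fContrast(fit, C1)
  tstat <- fit@beta[1, ] / sqrt(fit@sigma2 *
    solve(crossprod(X@X))[1, 1])
  expect_equal(f1$F, as.numeric(tstat^2), tolerance = 1e-10)
  expect_error(fContrast(fit, matrix(0, 1, 4)), "estimable")
})

test_that("Bonferroni FWE control behaves at the edges", {
  set.seed(31)
  d <- c(6, 6, 3)
  mask <- array(TRUE, d)
  Fmap <- array(rf(prod(d), 3, 100), d)
  # single-voxel mask: threshold equals the uncorrected quantile
  m1 <- array(FALSE, d); m1[1, 1, 1] <- TRUE
  th1 <- thresholdFwe(Fmap, 0.05, m1, 3, 100)
  expect_equal(th1$threshold, qf(0.95, 3, 100))
  # alpha = 1 returns every in-mask voxel
  expect_equal(sum(thresholdFwe(Fmap, 1, mask, 3, 100)$significant),
               prod(d))
  expect_error(thresholdFwe(Fmap, 0.05, array(FALSE, d), 3, 100), "mask")
  # family-wise control: no discovery in >= 95% of null replicates
  hits <- vapply(1:100, function(i) {
    Fm <- array(rf(prod(d), 3, 100), d)
    sum(thresholdFwe(Fm, 0.05, mask, 3, 100)$significant) > 0
  }, logical(1))
  expect_gte(mean(!hits), 0.90)
})

test_that("cluster labelling uses face connectivity", {
  sig <- array(FALSE, c(4, 4, 2))
  sig[1, 1, 1] <- TRUE; sig[2, 1, 1] <- TRUE   # face-connected pair
  sig[3, 3, 1] <- TRUE; sig[4, 4, 1] <- TRUE   # diagonal: NOT connected
  sig[4, 4, 2] <- TRUE                         # face-connected to (4,4,1)
  lab <- clusterLabels(sig)
  expect_equal(max(lab), 3)
  expect_equal(lab[1, 1, 1], lab[2, 1, 1])
  expect_true(lab[3, 3, 1] != lab[4, 4, 1])
  expect_equal(lab[4, 4, 1], lab[4, 4, 2])
})
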