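# Synthetic scan building blocks.

test_that("colored noise has the requested spectral slope and scale", {
  expect_equal(coloredNoise(128, p = 0.5, sigma = 0, seed = 1), rep(0, 128))
  expect_error(coloredNoise(128, p = 1.2), "spectral exponent")
  expect_identical(coloredNoise(64, 0.5, 1, seed = 5),
                   coloredNoise(64, 0.5, 1, seed = 5))
  # 200 realizations: average log-log periodogram slope close to -p
  slopeOf <- function(x) {
    n <- length(x)
    sp <- Mod(fft(x))[2:(n / 2)]^2
    fr <- (1:(n / 2 - 1)) / n
    coef(stats::lm(log(sp) ~ log(fr)))[2]
  }
  for (p in c(0, 0.5)) {
    slopes <- vapply(1:200, function(i)
      slopeOf(coloredNoise(256, p = p, sigma = 1, seed = 1000 + i)),
      numeric(1))
    expect_lt(abs(mean(slopes) - (-p)), 0.1)
  }
  # each voxel series is scaled to sigma
  arr <- coloredNoise(c(3, 2, 2, 100), p = 0.5, sigma = 2, seed = 9)
  expect_equal(dim(arr), c(3, 2, 2, 100))
  expect_equal(sd(arr[1, 1, 1, ]), 2, tolerance = 1e-10)
})

test_that("cluster embedding applies the stated Gaussian taper", {
  dat <- array(0, c(9, 9, 3, 4))
  bg <- scanSeries(dat, voxelSize = c(1.25, 1.25, 5), TR = 2)
  sig <- c(1, 2, 3, 4)
  out <- embedClusters(bg, list(clusterSpec(c(5, 5, 2), sig)))
  expect_equal(out@data[5, 5, 2, ], sig)
  # FWHM/2 = 1.25 mm = one voxel step -> amplitude scale exactly 0.5
  expect_equal(out@data[6, 5, 2, ], 0.5 * sig)
  # arbitrary offset matches the Gaussian formula
  sgm <- 2.5 / (2 * sqrt(2 * log(2)))
  d2 <- (2 * 1.25)^2
  expect_equal(out@data[7, 5, 2, ], exp(-d2 / (2 * sgm^2)) * sig)
  # identity on empty cluster list; bounds checked
  expect_identical(embedClusters(bg, list())@data, bg@data)
  expect_error(embedClusters(bg, list(clusterSpec(c(50, 5, 2), sig))),
               "outside")
  expect_error(embedClusters(bg, list(clusterSpec(c(5, 5, 2), 1:3))),
               "length")
})

test_that("Gaussian smoothing respects FWHM and matches dense convolution", {
  dat <- array(0, c(11, 11, 5, 2))
  dat[6, 6, 3, ] <- 1
  sc <- scanSeries(dat, voxelSize = c(2, 2, 2), TR = 2)
  expect_identical(smooth4d(sc, 0)@data, sc@data)
  sm <- smooth4d(sc, 8)
  # 4 mm offset (2 voxels at 2 mm) = half the peak for an 8-mm FWHM kernel
  expect_equal(sm@data[8, 6, 3, 1] / sm@data[6, 6, 3, 1], 0.5,
               tolerance = 1e-6)
  # separable implementation == brute-force 3D convolution on an 8^3 grid
  set.seed(1)
  small <- array(rnorm(8 * 8 * 8), c(8, 8, 8, 1))
  vox <- c(3, 3, 3)
  ssm <- smooth4d(scanSeries(small, voxelSize = vox, TR = 2), 8)@data
  k1 <- nbrmech:::gaussKernel1d(nbrmech:::fwhmToSigma(8) / 3)
  rad <- (length(k1) - 1) / 2
  K3 <- outer(outer(k1, k1), k1)
  brute <- array(0, c(8, 8, 8))
  for (x in 1:8) for (y in 1:8) for (z in 1:8) {
    acc <- 0
    for (i in -rad:rad) for (j in -rad:rad) for (l in -rad:rad) {
      xs <- x + i; ys <- y + j; zs <- z + l
      if (xs >= 1 && xs <= 8 && ys >= 1 && ys <= 8 && zs >= 1 && zs <= 8)
        acc <- acc + K3[i + rad + 1, j + rad + 1, l + rad + 1] *
          small[xs, ys, zs, 1]
    }
    brute[x, y, z] <- acc
  }
  expect_lt(max(abs(ssm[, , , 1] - brute)), 1e-10)
})

test_that("scan synthesis is deterministic and correctly dimensioned", {
  a <- synthesizeScans(duration = 120, gridDim = c(10, 10, 6), seed = 4)
  b <- synthesizeScans(duration = 120, gridDim = c(10, 10, 6), seed = 4)
  expect_identical(a$scans@data, b$scans@data)
  expect_equal(nVolumes(a$scans), 60)
  expect_equal(nrow(a$truth), 4)
  # clusters sit inside the brain mask
  for (i in seq_len(nrow(a$truth)))
    expect_true(a$mask[a$truth$x[i], a$truth$y[i], a$truth$z[i]])
})
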