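#' @include AllClasses.R simulate.R utils.R
NULL

#' Construct a scan series
#'
#' @param data 4D array (x, y, z, t)
#' @param voxelSize mm triple (default 3 x 3 x 8: 3-mm in-plane, 6-mm
#'   slices with a 2-mm gap)
#' @param TR repetition time (s)
#' @param sliceOrder acquisition order of the slices (default interleaved:
#'   odd slices then even)
#' @return a \linkS4class{ScanSeries}
#' @export
scanSeries <- function(data, voxelSize = c(3, 3, 8), TR = 2,
                       sliceOrder = NULL) {
  nz <- dim(data)[3]
  if (is.null(sliceOrder))
    sliceOrder <- c(seq(1, nz, by = 2), seq(2, nz, by = 2))
  new("ScanSeries", data = data, voxelSize = voxelSize, TR = TR,
      sliceOrder = as.integer(sliceOrder))
}

#' Spatial cluster specification for signal embedding
#'
#' @slot center voxel index triple
#' @slot signal time series to embed (intensity units)
#' @slot taperFwhmMm Gaussian amplitude FWHM (mm), default 2.5
#' @slot radiusMm cluster extent (mm), default 9
#' @slot label optional mechanism label
#' @exportClass ClusterSpec
setClass("ClusterSpec",
  representation(center = "numeric", signal = "numeric",
                 taperFwhmMm = "numeric", radiusMm = "numeric",
                 label = "character"),
  prototype(taperFwhmMm = 2.5, radiusMm = 9, label = ""))

#' @rdname ClusterSpec-class
#' @param center,signal,taperFwhmMm,radiusMm,label see slots
#' @export
clusterSpec <- function(center, signal, taperFwhmMm = 2.5, radiusMm = 9,
                        label = "") {
  .check(taperFwhmMm > 0, "taperFwhmMm must be > 0")
  new("ClusterSpec", center = as.numeric(center),
      signal = as.numeric(signal), taperFwhmMm = taperFwhmMm,
      radiusMm = radiusMm, label = label)
}

#' Temporally colored (1/f^p) noise
#'
#' Spectral shaping of white Gaussian noise: the Fourier coefficients are
#' scaled by f^(-p/2) so the power spectral density is proportional to
#' 1/f^p (0 <= p < 1; p = 0 is white), then each series is rescaled to
#' standard deviation sigma.  For a 4D shape, every voxel receives an
#' independent series.
#'
#' @param shape series length n, or a 4D dim vector (x, y, z, t)
#' @param p spectral exponent, in [0, 1)
#' @param sigma noise standard deviation
#' @param seed RNG seed
#' @return numeric vector of length n, or a 4D array
#' @export
coloredNoise <- function(shape, p = 0.5, sigma = 1, seed = NULL) {
  .check(p >= 0 && p < 1, "spectral exponent p must lie in [0, 1)")
  if (length(shape) == 1) { n <- shape; nv <- 1L }
  else { .check(length(shape) == 4, "shape must be n or a 4D dim vector")
         n <- shape[4]; nv <- prod(shape[1:3]) }
  if (sigma == 0) {
    out <- if (nv == 1L) numeric(n) else array(0, shape)
    return(out)
  }
  k <- 0:(n - 1)
  fr <- pmin(k, n - k) / n          # cycles per sample
  w <- c(0, fr[-1]^(-p / 2))        # zero the DC term
  x <- withSeed(seed, {
    z <- matrix(rnorm(n * nv), n, nv)
    sh <- mvfft(z) * w
    Re(mvfft(sh, inverse = TRUE)) / n
  })
  sds <- apply(x, 2, sd)
  x <- sweep(x, 2, ifelse(sds > 0, sds / sigma, 1), "/")
  if (nv == 1L) as.numeric(x) else array(t(x), shape)
}

#' Uniform-intensity ellipsoidal background volume
#'
#' Stand-in for a real EPI background: a brain-shaped ellipsoid of uniform
#' mean intensity inside an otherwise empty grid.
#'
#' @param gridDim voxel grid dimensions (x, y, z)
#' @param intensity mean intensity inside the ellipsoid
#' @param fill fraction of each half-extent covered by the ellipsoid
#' @return list(volume = 3D array, mask = logical 3D array)
#' @export
backgroundVolume <- function(gridDim, intensity = 100, fill = 0.9) {
  ctr <- (gridDim + 1) / 2
  ax <- fill * (gridDim - 1) / 2
  g <- expand.grid(x = seq_len(gridDim[1]), y = seq_len(gridDim[2]),
                   z = seq_len(gridDim[3]))
  r2 <- ((g$x - ctr[1]) / ax[1])^2 + ((g$y - ctr[2]) / ax[2])^2 +
    ((g$z - ctr[3]) / ax[3])^2
  mask <- array(r2 <= 1, gridDim)
  vol <- array(0, gridDim)
  vol[mask] <- intensity
  list(volume = vol, mask = mask)
}

# Gaussian amplitude taper around a cluster center; truncated at 3 SD and
# at the cluster radius.
clusterTaper <- function(gridDim, voxelSize, center, fwhmMm, radiusMm) {
  sigma <- fwhmToSigma(fwhmMm)
  rmax <- min(radiusMm, 3 * sigma)
  g <- expand.grid(x = seq_len(gridDim[1]), y = seq_len(gridDim[2]),
                   z = seq_len(gridDim[3]))
  d2 <- ((g$x - center[1]) * voxelSize[1])^2 +
    ((g$y - center[2]) * voxelSize[2])^2 +
    ((g$z - center[3]) * voxelSize[3])^2
  w <- exp(-d2 / (2 * sigma^2))
  w[d2 > rmax^2] <- 0
  array(w, gridDim)
}

#' Embed signal clusters into a scan series
#'
#' Each voxel within a cluster receives the cluster's time series scaled
#' by a Gaussian of the stated FWHM centered at the cluster center
#' (truncated at 3 SD / the cluster radius); the background is preserved
#' elsewhere.
#'
#' @param background a \linkS4class{ScanSeries}
#' @param clusters list of \linkS4class{ClusterSpec}
#' @return a \linkS4class{ScanSeries} with the signals added
#' @export
embedClusters <- function(background, clusters) {
  dat <- background@data
  d <- dim(dat)
  for (cl in clusters) {
    .check(all(cl@center >= 1) && all(cl@center <= d[1:3]),
           "cluster center outside the voxel grid")
    .check(length(cl@signal) == d[4],
           "cluster signal length must equal the number of volumes")
    w <- clusterTaper(d[1:3], background@voxelSize, cl@center,
                      cl@taperFwhmMm, cl@radiusMm)
    nz <- which(w > 0)
    for (v in nz)
      dat[((1:d[4]) - 1) * prod(d[1:3]) + v] <-
        dat[((1:d[4]) - 1) * prod(d[1:3]) + v] + w[v] * cl@signal
  }
  background@data <- dat
  background
}

# 1D Gaussian kernel (voxel units), truncated at 3 SD, unit sum.
gaussKernel1d <- function(sigmaVox) {
  if (sigmaVox <= 0) return(1)
  rad <- max(1L, ceiling(3 * sigmaVox))
  k <- exp(-((-rad):rad)^2 / (2 * sigmaVox^2))
  k / sum(k)
}

# convolve a 4D array along one spatial axis with zero padding
convolveAxis <- function(dat, kernel, axis) {
  if (length(kernel) == 1) return(dat)
  rad <- (length(kernel) - 1) / 2
  out <- array(0, dim(dat))
  n <- dim(dat)[axis]
  for (j in seq_along(kernel)) {
    off <- j - rad - 1
    src <- seq_len(n) + off
    ok <- src >= 1 & src <= n
    if (!any(ok)) next
    di <- which(ok); si <- src[ok]
    if (axis == 1)
      out[di, , , ] <- out[di, , , ] + kernel[j] * dat[si, , , ]
    else if (axis == 2)
      out[, di, , ] <- out[, di, , ] + kernel[j] * dat[, si, , ]
    else
      out[, , di, ] <- out[, , di, ] + kernel[j] * dat[, , si, ]
  }
  out
}

#' Frame-wise 3D Gaussian smoothing of a scan series
#'
#' Separable Gaussian convolution in millimetre units (anisotropic voxels
#' respected); fwhmMm = 0 returns the input unchanged.
#'
#' @param series a \linkS4class{ScanSeries}
#' @param fwhmMm smoothing kernel FWHM in mm (default 8, the standard
#'   preprocessing value)
#' @return smoothed \linkS4class{ScanSeries}
#' @export
smooth4d <- function(series, fwhmMm = 8) {
  .check(fwhmMm >= 0, "fwhmMm must be >= 0")
  if (fwhmMm == 0) return(series)
  dat <- series@data
  for (axis in 1:3) {
    sigmaVox <- fwhmToSigma(fwhmMm) / series@voxelSize[axis]
    dat <- convolveAxis(dat, gaussKernel1d(sigmaVox), axis)
  }
  series@data <- dat
  series
}

#' Synthesize a GLM-validation scan series
#'
#' Implements the full synthetic-scan protocol: a shared Poisson event
#' train drives one simulated BOLD response per mechanism; each response
#' is embedded as a spatial cluster (Gaussian taper, FWHM 2.5 mm) in a
#' uniform ellipsoidal background; 1/f^p noise is added to every in-brain
#' voxel with ONE global standard deviation set by the largest clean peak
#' signal (peak-SNR \code{snr}, so mechanisms keep their natural amplitude
#' ordering and blood stealing stays the weakest); finally the volumes are
#' smoothed with an 8-mm FWHM kernel.
#'
#' @param duration series length (s); 600 s at TR = 2 gives 300 volumes
#' @param TR repetition time (s)
#' @param gridDim voxel grid (x, y, z)
#' @param voxelSize mm triple
#' @param mechanisms mechanisms to embed (default PBR, NDA, ANC, ABS; the
#'   reference experiment omits ECI, whose waveform duplicates ABS)
#' @param centers optional matrix of cluster centers (one row per
#'   mechanism); defaults to four well-separated in-brain sites
#' @param rate Poisson event rate (events/min)
#' @param noiseP spectral exponent of the 1/f^p noise
#' @param snr peak-signal to noise-SD ratio at cluster centers (measured
#'   on the smoothed series the GLM analyzes)
#' @param smoothFwhm post-hoc smoothing FWHM (mm)
#' @param baseIntensity background intensity
#' @param peakPct peak percent-signal change of the embedded responses;
#'   blood stealing is embedded at 40 percent of it (its NBR is the
#'   weakest), so it remains the least significant mechanism
#' @param seed RNG seed
#' @param sampleParams if TRUE, draw each mechanism's parameters from the
#'   preset sampling ranges instead of using the defaults
#' @return list(scans, clean, train, truth, sigma, mask): the noisy
#'   smoothed series, the clean unsmoothed one, the event train, a
#'   data.frame of cluster centers/labels, the noise SD (intensity units)
#'   and the brain mask
#' @export
synthesizeScans <- function(duration = 600, TR = 2,
                            gridDim = c(20, 20, 10),
                            voxelSize = c(3, 3, 8),
                            mechanisms = c("PBR", "NDA", "ANC", "ABS"),
                            centers = NULL, rate = 2.6, noiseP = 0.5,
                            snr = 1.5, smoothFwhm = 8,
                            baseIntensity = 100, peakPct = 1, seed = NULL,
                            sampleParams = FALSE) {
  seeds <- deriveSeeds(seed, 2 + length(mechanisms))
  train <- poissonTrain(rate, duration, seed = seeds[1])
  nT <- floor(duration / TR)
  bg <- backgroundVolume(gridDim, baseIntensity)
  if (is.null(centers)) {
    ctr <- round((gridDim + 1) / 2)
    off <- pmax(2, round(gridDim * 0.22))
    cand <- rbind(ctr + c(-off[1], 0, 0), ctr + c(off[1], 0, 0),
                  ctr + c(0, -off[2], 0), ctr + c(0, off[2], 0),
                  ctr + c(0, 0, -off[3]))
    centers <- cand[seq_along(mechanisms), , drop = FALSE]
  }
  signals <- vector("list", length(mechanisms))
  for (i in seq_along(mechanisms)) {
    pre <- makePreset(mechanisms[i])
    pars <- if (sampleParams) sampleParameters(pre, seed = seeds[2 + i])
            else pre
    traj <- simulateMechanism(pars, train, tEnd = duration)
    reg <- if (mechanisms[i] == "ABS") 2L else 1L
    y <- boldAtTR(traj, TR, region = reg)
    # embed at a physiological percent-signal-change scale: the raw model
    # amplitudes are in arbitrary gain units and span orders of magnitude
    rel <- if (mechanisms[i] == "ABS") 0.4 else 1
    signals[[i]] <- y / max(abs(y)) * (peakPct / 100) * rel
  }
  dat <- array(rep(bg$volume, nT), c(gridDim, nT))
  clean <- scanSeries(dat, voxelSize, TR)
  clusters <- lapply(seq_along(mechanisms), function(i)
    clusterSpec(centers[i, ], baseIntensity * signals[[i]],
                label = mechanisms[i]))
  clean <- embedClusters(clean, clusters)
  # the SNR contract holds on the series the GLM sees: after smoothing,
  # the largest cluster-center peak is snr times the noise SD.  The
  # smoothing attenuation of white-ish noise is the kernel l2 norm.
  cleanSm <- smooth4d(clean, smoothFwhm)
  peakSm <- max(vapply(seq_along(mechanisms), function(i)
    max(abs(cleanSm@data[centers[i, 1], centers[i, 2], centers[i, 3], ] -
              mean(cleanSm@data[centers[i, 1], centers[i, 2],
                                centers[i, 3], ]))), numeric(1)))
  noiseAtten <- prod(vapply(1:3, function(a) {
    k <- gaussKernel1d(fwhmToSigma(smoothFwhm) / voxelSize[a])
    sqrt(sum(k^2))
  }, numeric(1)))
  sigma <- if (smoothFwhm > 0) peakSm / snr / noiseAtten
           else baseIntensity *
             max(vapply(signals, function(x) max(abs(x)), numeric(1))) / snr
  noisy <- clean
  noise <- coloredNoise(c(gridDim, nT), p = noiseP, sigma = sigma,
                        seed = seeds[2])
  maskRep <- array(rep(bg$mask, nT), c(gridDim, nT))
  noisy@data <- noisy@data + noise * maskRep
  noisy <- smooth4d(noisy, smoothFwhm)
  # keep signal support strictly inside the brain mask after smoothing
  noisy@data <- noisy@data * maskRep
  truth <- data.frame(mechanism = mechanisms, x = centers[, 1],
                      y = centers[, 2], z = centers[, 3])
  list(scans = noisy, clean = clean, train = train, truth = truth,
       sigma = sigma, mask = bg$mask)
}
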