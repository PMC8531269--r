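#' @include AllClasses.R stimulus.R
NULL

#' Canonical HRF basis: double-gamma, temporal and dispersion derivatives
#'
#' The canonical BOLD HRF is the standard double-gamma (peak delay 6 s,
#' undershoot delay 16 s, unit dispersions, peak:undershoot ratio 6),
#' scaled to unit peak.  The temporal derivative is analytic; the
#' dispersion derivative is the derivative with respect to the peak
#' dispersion parameter (central finite difference with step 1e-4).
#'
#' @param dt sampling interval (s)
#' @param length basis support (s), default 32
#' @param peakDelay,undershootDelay,dispersion,ratio canonical parameters
#' @return list(t, h, hd, dd): time grid, HRF, temporal derivative,
#'   dispersion derivative
#' @export
canonicalBasis <- function(dt, length = 32, peakDelay = 6,
                           undershootDelay = 16, dispersion = 1,
                           ratio = 6) {
  .check(dt > 0, "dt must be > 0")
  t <- seq(0, length, by = dt)
  shape <- function(tt, disp)
    dgamma(tt, shape = peakDelay / disp, rate = 1 / disp) -
      dgamma(tt, shape = undershootDelay / dispersion,
             rate = 1 / dispersion) / ratio
  h0 <- shape(t, dispersion)
  sc <- max(h0)
  h <- h0 / sc
  # analytic temporal derivative of the two gamma densities
  dg <- function(tt, a, b) ifelse(tt > 0,
    dgamma(tt, shape = a, rate = b) * ((a - 1) / tt - b), 0)
  hd <- (dg(t, peakDelay / dispersion, 1 / dispersion) -
           dg(t, undershootDelay / dispersion, 1 / dispersion) / ratio) / sc
  eps <- 1e-4
  dd <- (shape(t, dispersion + eps) - shape(t, dispersion - eps)) /
    (2 * eps) / sc
  list(t = t, h = h, hd = hd, dd = dd)
}

#' Build a GLM design matrix from event trains
#'
#' For each condition the event train is laid down as unit impulses on a
#' fine grid (dt = TR / fineFactor), convolved with the canonical HRF, its
#' temporal derivative and its dispersion derivative, and sampled at the
#' scan times.  An optional slice-timing shift is applied to the inputs
#' first; confound columns and an intercept are appended.
#'
#' @param trains named list of \linkS4class{StimulusTrain} (one per
#'   condition); a single train is accepted
#' @param nScans number of scans N
#' @param TR repetition time (s)
#' @param confounds optional numeric matrix (N x Nr) of nuisance regressors
#' @param sliceN,sliceNz slice position and slice count for the timing
#'   shift (sliceN = 0 disables it)
#' @param fineFactor microtime resolution divisor (default 16)
#' @return a \linkS4class{DesignMatrix}
#' @export
buildDesign <- function(trains, nScans, TR, confounds = NULL, sliceN = 0,
                        sliceNz = 1, fineFactor = 16) {
  if (is(trains, "StimulusTrain")) trains <- list(task = trains)
  .check(length(trains) > 0, "at least one condition is required")
  if (is.null(names(trains)) || any(names(trains) == ""))
    names(trains) <- paste0("cond", seq_along(trains))
  for (nm in names(trains))
    .check(length(trains[[nm]]@onsets) > 0,
           paste0("condition '", nm, "' has an empty event train"))
  dtf <- TR / fineFactor
  tEnd <- nScans * TR
  nf <- ceiling(tEnd / dtf) + 1
  basis <- canonicalBasis(dtf)
  scanIdx <- round((0:(nScans - 1)) * TR / dtf) + 1
  cols <- list(); labs <- character(0); condCols <- list()
  for (nm in names(trains)) {
    tr <- trains[[nm]]
    if (sliceN > 0) tr <- sliceTimingShift(tr, sliceN, sliceNz, TR)
    u <- numeric(nf)
    bins <- round(tr@onsets / dtf) + 1
    keep <- bins >= 1 & bins <= nf
    for (k in which(keep)) u[bins[k]] <- u[bins[k]] + tr@amplitudes[k]
    first <- length(cols) + 1L
    for (b in c("h", "hd", "dd")) {
      conv <- convolve(u, rev(basis[[b]]), type = "open")[seq_len(nf)]
      cols[[length(cols) + 1L]] <- conv[scanIdx]
    }
    labs <- c(labs, paste0(nm, c(".hrf", ".der", ".disp")))
    condCols[[nm]] <- first:(first + 2L)
  }
  X <- do.call(cbind, cols)
  if (!is.null(confounds)) {
    confounds <- as.matrix(confounds)
    .check(nrow(confounds) == nScans, "confounds must have N rows")
    cn <- colnames(confounds)
    if (is.null(cn)) cn <- paste0("confound", seq_len(ncol(confounds)))
    X <- cbind(X, confounds)
    labs <- c(labs, cn)
  }
  X <- cbind(X, 1)
  labs <- c(labs, "intercept")
  colnames(X) <- labs
  new("DesignMatrix", X = X, labels = labs, conditionCols = condCols)
}

#' Prewhiten data and design with a pooled AR(1) model
#'
#' The lag-1 autocorrelation is estimated from the OLS residuals pooled
#' over all supplied voxels (one value per volume, as in the standard
#' implementation) and both sides of the GLM are filtered with
#' (1 - rho L); the first row is scaled by sqrt(1 - rho^2).
#'
#' @param Y numeric vector or (N x V) matrix of voxel series
#' @param X a \linkS4class{DesignMatrix}
#' @return list(Y, X, rho) with whitened data and design
#' @export
prewhitenAR1 <- function(Y, X) {
  Y <- as.matrix(Y)
  M <- X@X
  .check(nrow(Y) == nrow(M), "Y and design disagree on scan count")
  .check(nrow(M) > ncol(M), "need more scans than regressors")
  res <- stats::lm.fit(M, Y)$residuals
  res <- as.matrix(res)
  num <- sum(res[-1, ] * res[-nrow(res), ])
  den <- sum(res^2)
  rho <- if (den > 0) num / den else 0
  if (abs(rho) >= 1) stop("AR(1) estimate |rho| >= 1", call. = FALSE)
  wh <- function(A) {
    B <- A
    B[1, ] <- sqrt(1 - rho^2) * A[1, ]
    B[-1, ] <- A[-1, , drop = FALSE] -
      rho * A[-nrow(A), , drop = FALSE]
    B
  }
  Xw <- X
  Xw@X <- wh(M)
  colnames(Xw@X) <- X@labels
  list(Y = wh(Y), X = Xw, rho = rho)
}

#' Fit the GLM by least squares
#'
#' @param Y numeric vector or (N x V) matrix (typically prewhitened)
#' @param X a \linkS4class{DesignMatrix} (typically prewhitened)
#' @param rho the AR(1) coefficient used for whitening (bookkeeping)
#' @return a \linkS4class{GlmFit}
#' @export
fitGlm <- function(Y, X, rho = 0) {
  Y <- as.matrix(Y)
  M <- X@X
  qrX <- qr(M)
  if (qrX$rank < ncol(M)) {
    bad <- X@labels[qrX$pivot[(qrX$rank + 1):ncol(M)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qrX, Y)
  resid <- Y - M %*% beta
  dof <- nrow(M) - qrX$rank
  sigma2 <- colSums(resid^2) / dof
  new("GlmFit", beta = as.matrix(beta), sigma2 = as.numeric(sigma2),
      rho = rho, dof = dof, design = X)
}

#' F contrast on a fitted GLM
#'
#' Standard extra-sum-of-squares F statistic for H0: C beta = 0, with
#' (rank(C), dof) reference distribution.  The default contrast selects
#' the three basis coefficients (canonical, temporal derivative,
#' dispersion) of the first condition - the identity contrast used for
#' response detection.
#'
#' @param fit a \linkS4class{GlmFit}
#' @param contrast numeric matrix with one row per constraint, or a vector
#'   of coefficient indices (expanded to an identity contrast on them)
#' @return list(F, df1, df2, p): per-voxel F values and reference
#'   distribution
#' @export
fContrast <- function(fit, contrast = NULL) {
  ncf <- nrow(fit@beta)
  if (is.null(contrast)) contrast <- fit@design@conditionCols[[1]]
  if (is.vector(contrast) && !is.matrix(contrast)) {
    idx <- as.integer(contrast)
    .check(all(idx >= 1 & idx <= ncf), "contrast index out of range")
    C <- matrix(0, length(idx), ncf)
    C[cbind(seq_along(idx), idx)] <- 1
  } else C <- as.matrix(contrast)
  .check(ncol(C) == ncf, "contrast has wrong coefficient dimension")
  M <- fit@design@X
  XtXi <- chol2inv(chol(crossprod(M)))
  mid <- C %*% XtXi %*% t(C)
  ev <- eigen(mid, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= max(ev) * 1e-12)
    stop("contrast is not estimable", call. = FALSE)
  midInv <- solve(mid)
  Cb <- C %*% fit@beta
  r <- nrow(C)
  num <- colSums(Cb * (midInv %*% Cb)) / r
  Fv <- num / fit@sigma2
  Fv[fit@sigma2 == 0] <- Inf
  list(F = as.numeric(Fv), df1 = r, df2 = fit@dof,
       p = pf(as.numeric(Fv), r, fit@dof, lower.tail = FALSE))
}

#' Label connected clusters of a logical 3D map (face connectivity)
#'
#' @param sig logical 3D array
#' @return integer array of cluster labels (0 = background)
#' @export
clusterLabels <- function(sig) {
  d <- dim(sig)
  lab <- array(0L, d)
  nxt <- 0L
  idx <- which(sig)
  nb <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
              c(0, 0, 1), c(0, 0, -1))
  for (start in idx) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      z <- (v - 1) %/% (d[1] * d[2]) + 1
      rem <- (v - 1) %% (d[1] * d[2])
      yy <- rem %/% d[1] + 1
      xx <- rem %% d[1] + 1
      for (k in seq_len(nrow(nb))) {
        cx <- xx + nb[k, 1]; cy <- yy + nb[k, 2]; cz <- z + nb[k, 3]
        if (cx < 1 || cx > d[1] || cy < 1 || cy > d[2] ||
            cz < 1 || cz > d[3]) next
        w <- (cz - 1) * d[1] * d[2] + (cy - 1) * d[1] + cx
        if (sig[w] && lab[w] == 0L) {
          lab[w] <- nxt
          queue <- c(queue, w)
        }
      }
    }
  }
  lab
}

#' Family-wise-error thresholding of an F map
#'
#' Bonferroni correction over the in-mask voxels: the per-voxel level is
#' alpha / m, exact and conservative (stricter than random-field theory).
#'
#' @param Fmap numeric 3D array of F values
#' @param alpha family-wise level, in (0, 1]
#' @param mask logical 3D array of analyzed voxels
#' @param df1,df2 reference-distribution degrees of freedom
#' @return list(significant: logical array; labels: cluster labels (face
#'   connectivity); threshold; indices: matrix of significant voxel
#'   coordinates)
#' @export
thresholdFwe <- function(Fmap, alpha = 0.05, mask, df1, df2) {
  .check(alpha > 0 && alpha <= 1, "alpha must lie in (0, 1]")
  .check(any(mask), "empty mask")
  m <- sum(mask)
  # alpha = 1 disables correction entirely (every in-mask voxel returned)
  thr <- if (alpha >= 1) 0 else qf(1 - alpha / m, df1, df2)
  sig <- array(FALSE, dim(Fmap))
  sig[mask] <- Fmap[mask] > thr
  list(significant = sig, labels = clusterLabels(sig), threshold = thr,
       indices = which(sig, arr.ind = TRUE))
}

#' Detect event-locked responses in a scan series
#'
#' End-to-end GLM detection: builds the three-basis design from the event
#' trains, prewhitens with a pooled AR(1) model, fits all in-mask voxels,
#' computes the identity F contrast per condition (default: first), and
#' applies family-wise-error thresholding.
#'
#' @param scans a \linkS4class{ScanSeries}
#' @param trains named list of \linkS4class{StimulusTrain}
#' @param alpha family-wise level
#' @param mask logical 3D array (default: voxels with nonzero temporal
#'   mean)
#' @param confounds optional nuisance matrix
#' @return list(Fmap, significant, labels, threshold, fit, rho, table)
#'   where table summarizes detected clusters (peak voxel, size, peak F)
#' @export
detectResponses <- function(scans, trains, alpha = 0.05, mask = NULL,
                            confounds = NULL) {
  dat <- scans@data
  d <- dim(dat)
  N <- d[4]
  if (is.null(mask))
    mask <- array(apply(dat, 1:3, function(v) any(v != 0)), d[1:3])
  X <- buildDesign(trains, N, scans@TR, confounds = confounds)
  Ym <- matrix(aperm(dat, c(4, 1, 2, 3)), nrow = N)   # time x all voxels
  Y <- Ym[, as.vector(mask), drop = FALSE]            # time x in-mask
  w <- prewhitenAR1(Y, X)
  fit <- fitGlm(w$Y, w$X, rho = w$rho)
  fc <- fContrast(fit)
  Fmap <- array(0, d[1:3])
  Fmap[mask] <- fc$F
  th <- thresholdFwe(Fmap, alpha, mask, fc$df1, fc$df2)
  tab <- NULL
  if (any(th$significant)) {
    labs <- th$labels
    tab <- do.call(rbind, lapply(seq_len(max(labs)), function(l) {
      vox <- which(labs == l, arr.ind = TRUE)
      fv <- Fmap[labs == l]
      pk <- vox[which.max(fv), ]
      data.frame(cluster = l, size = nrow(vox), peakF = max(fv),
                 x = pk[1], y = pk[2], z = pk[3])
    }))
  }
  list(Fmap = Fmap, significant = th$significant, labels = th$labels,
       threshold = th$threshold, fit = fit, rho = w$rho, table = tab,
       df = c(fc$df1, fc$df2), mask = mask)
}
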