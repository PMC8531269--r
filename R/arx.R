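#' @include AllClasses.R stimulus.R
NULL

# Default AIC search grid: spans the 32-s HRF support at TR = 2 s.
defaultArxGrid <- function() {
  list(p = 1:3, r = 4:16, d = 0:3, drift = 0:3)
}

# polynomial drift columns on time scaled to [-1, 1]
driftColumns <- function(n, order) {
  tt <- seq(-1, 1, length.out = n)
  vapply(0:order, function(k) tt^k, numeric(n))
}

arStable <- function(phi) {
  if (!length(phi)) return(TRUE)
  all(Mod(polyroot(c(1, -phi))) > 1 + 1e-8)
}

# Assemble lagged regressor columns for rows istart..N.
arxRegressors <- function(y, s, p, r, d, driftOrder, istart) {
  n <- length(y)
  idx <- istart:n
  cols <- driftColumns(length(idx), driftOrder)
  labs <- paste0("drift", 0:driftOrder)
  if (p > 0) {
    ylag <- vapply(1:p, function(j) y[idx - j], numeric(length(idx)))
    cols <- cbind(cols, ylag)
    labs <- c(labs, paste0("phi", 1:p))
  }
  if (r > 0) {
    slag <- vapply(1:r, function(j) s[idx - j - d], numeric(length(idx)))
    cols <- cbind(cols, slag)
    labs <- c(labs, paste0("theta", 1:r))
  }
  colnames(cols) <- labs
  list(X = cols, yy = y[idx])
}

#' Fit an ARX model of a BOLD series with exogenous events
#'
#' Least-squares fit of
#' \deqn{y_i = \mu_i + \sum_{j=1}^p \phi_j y_{i-j} +
#'       \sum_{j=1}^r \theta_j s_{i-j-d} + \epsilon_i}
#' where mu_i is a polynomial drift of degree \code{driftOrder} and s is
#' the per-scan event input.  The model score is
#' AIC = N log(sigma-hat^2) + 2 k with k the number of linear coefficients.
#'
#' @param y BOLD series (one value per scan)
#' @param s exogenous input per scan (see \code{\link{binEvents}})
#' @param p,r,d AR order, exogenous order, onset delay (scans)
#' @param driftOrder drift polynomial degree
#' @param istart first modelled row (defaults to the smallest row allowed
#'   by the requested lags; a larger common value makes AICs comparable
#'   across a search grid)
#' @return an \linkS4class{ArxModel}
#' @export
fitArx <- function(y, s, p, r, d, driftOrder = 0, istart = NULL) {
  n <- length(y)
  .check(length(s) == n, "y and s must have equal length")
  need <- max(p, r + d) + 1L
  if (is.null(istart)) istart <- need
  .check(istart >= need, "istart too small for the requested lags")
  .check(n > istart + p + r + driftOrder + 1,
         "series too short for the requested orders")
  reg <- arxRegressors(y, s, p, r, d, driftOrder, istart)
  fit <- stats::.lm.fit(reg$X, reg$yy)
  if (fit$rank < ncol(reg$X)) {
    bad <- colnames(reg$X)[fit$pivot[(fit$rank + 1):ncol(reg$X)]]
    stop("regressor collinearity: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  cf <- fit$coefficients[order(fit$pivot)]
  names(cf) <- colnames(reg$X)
  neff <- length(reg$yy)
  rss <- sum(fit$residuals^2)
  sig2 <- rss / neff
  k <- p + r + driftOrder + 1
  aic <- neff * log(max(sig2, .Machine$double.xmin)) + 2 * k
  new("ArxModel", p = as.integer(p), r = as.integer(r), d = as.integer(d),
      driftOrder = as.integer(driftOrder),
      phi = if (p > 0) unname(cf[paste0("phi", 1:p)]) else numeric(0),
      theta = if (r > 0) unname(cf[paste0("theta", 1:r)]) else numeric(0),
      drift = unname(cf[paste0("drift", 0:driftOrder)]),
      sigma = sqrt(sig2), aic = aic, n = as.integer(neff))
}

#' Select ARX orders by exhaustive AIC search
#'
#' Fits every (p, r, d, drift order) combination on a common sample (rows
#' beyond the largest lag in the grid, so AICs are comparable) and returns
#' the AIC-minimizing model.  Candidates whose AR polynomial is unstable
#' (roots inside the unit circle) are excluded, since the HRF cannot be
#' reconstructed from them.  Ties are broken toward fewer parameters, then
#' smaller delay d, then smaller p.
#'
#' @param y,s as in \code{\link{fitArx}}
#' @param grid list with integer vectors p, r, d, drift
#' @return the selected \linkS4class{ArxModel}
#' @export
selectOrders <- function(y, s, grid = defaultArxGrid()) {
  .check(length(grid$p) > 0 && length(grid$r) > 0 && length(grid$d) > 0 &&
           length(grid$drift) > 0, "empty search grid")
  istart <- max(max(grid$p), max(grid$r) + max(grid$d)) + 1L
  cand <- expand.grid(p = grid$p, r = grid$r, d = grid$d,
                      drift = grid$drift)
  cand$k <- cand$p + cand$r + cand$drift + 1
  # deterministic tie-break order: fewer parameters, smaller d, smaller p
  cand <- cand[order(cand$k, cand$d, cand$p, cand$r, cand$drift), ]
  best <- NULL
  bestAic <- Inf
  lastErr <- NULL
  for (i in seq_len(nrow(cand))) {
    m <- tryCatch(
      fitArx(y, s, cand$p[i], cand$r[i], cand$d[i], cand$drift[i],
             istart = istart),
      error = function(e) e)
    if (inherits(m, "error")) { lastErr <- m; next }
    if (!arStable(m@phi)) next
    if (m@aic < bestAic - 1e-9) { best <- m; bestAic <- m@aic }
  }
  if (is.null(best))
    stop("no ARX candidate could be fitted",
         if (!is.null(lastErr)) paste0(" (last error: ",
                                       conditionMessage(lastErr), ")"),
         call. = FALSE)
  best
}

#' Reconstruct the HRF from a fitted ARX model
#'
#' The HRF is the impulse response of the fitted difference equation: a
#' unit pulse is placed in the exogenous input (drift removed) and the
#' recursion iterated, so sample i satisfies
#' h_i = sum_j phi_j h_{i-j} + theta_{i-d} (1 <= i-d <= r).  At the
#' defaults (TR = 2 s, 32-s support) this yields exactly 16 samples.
#'
#' @param model an \linkS4class{ArxModel} (stable AR polynomial required)
#' @param nPoints number of HRF samples
#' @param TR sampling interval (s)
#' @return an \linkS4class{HRF}
#' @export
reconstructHrf <- function(model, nPoints = 16, TR = 2) {
  .check(arStable(model@phi),
         "unstable AR polynomial: HRF reconstruction undefined")
  h <- numeric(nPoints)
  for (i in seq_len(nPoints) - 1L) {          # i = 0 .. nPoints-1
    acc <- 0
    if (model@p > 0) for (j in seq_len(model@p))
      if (i - j >= 0) acc <- acc + model@phi[j] * h[i - j + 1L]
    je <- i - model@d
    if (je >= 1 && je <= model@r) acc <- acc + model@theta[je]
    h[i + 1L] <- acc
  }
  new("HRF", values = h, TR = TR, delay = model@d, model = model)
}

#' Normalize an HRF by the maximum of its absolute value
#'
#' Polarity is preserved and the operation is idempotent.
#'
#' @param hrf an \linkS4class{HRF}
#' @return normalized \linkS4class{HRF} with max |values| = 1
#' @export
normalizeHrf <- function(hrf) {
  mx <- max(abs(hrf@values))
  .check(mx > 0, "cannot normalize an all-zero HRF")
  hrf@values <- hrf@values / mx
  if (!is.null(hrf@ciLo)) hrf@ciLo <- hrf@ciLo / mx
  if (!is.null(hrf@ciHi)) hrf@ciHi <- hrf@ciHi / mx
  hrf
}

#' Permutation confidence band for an estimated HRF
#'
#' Builds the empirical null distribution of "no event-locked response" by
#' repositioning the events uniformly over the scan indices (event count
#' and amplitudes preserved), re-estimating the HRF for each permutation at
#' the model orders selected on the observed data, and taking per-sample
#' percentiles (default 5 and 95).
#'
#' @param y BOLD series
#' @param s per-scan event input with at least 2 events
#' @param model the \linkS4class{ArxModel} selected on the observed data
#' @param nPerm number of permutations (reference protocol: 5000)
#' @param levels percentile pair
#' @param seed RNG seed
#' @param nPoints,TR HRF geometry
#' @return list(lo, hi, null) where null is the (nPerm x nPoints) matrix of
#'   permuted HRFs
#' @export
permutationCi <- function(y, s, model, nPerm = 5000, levels = c(5, 95),
                          seed = NULL, nPoints = 16, TR = 2) {
  ev <- which(s != 0)
  .check(length(ev) >= 2, "permutation band requires at least 2 events")
  n <- length(y)
  istart <- max(model@p, model@r + model@d) + 1L
  null <- withSeed(seed, {
    out <- matrix(NA_real_, nPerm, nPoints)
    for (b in seq_len(nPerm)) {
      sp <- numeric(n)
      pos <- sample.int(n, length(ev), replace = TRUE)
      for (k in seq_along(ev)) sp[pos[k]] <- sp[pos[k]] + s[ev[k]]
      fit <- tryCatch(
        fitArx(y, sp, model@p, model@r, model@d, model@driftOrder,
               istart = istart),
        error = function(e) NULL)
      if (is.null(fit)) next
      out[b, ] <- reconstructHrf(fit, nPoints, TR)@values
    }
    out
  })
  ok <- stats::complete.cases(null)
  .check(sum(ok) >= 2, "too few successful permutations")
  null <- null[ok, , drop = FALSE]
  lo <- apply(null, 2, quantile, probs = levels[1] / 100, names = FALSE)
  hi <- apply(null, 2, quantile, probs = levels[2] / 100, names = FALSE)
  list(lo = lo, hi = hi, null = null)
}

#' Estimate an HRF from a series and an event train
#'
#' Convenience wrapper: bins the events per scan, runs the AIC order
#' search, reconstructs the HRF, and optionally attaches a permutation
#' confidence band.  A matrix input is averaged across columns first (the
#' ROI convention: mean series of the in-ROI voxels).
#'
#' @param y numeric series (scans) or matrix (scans x voxels)
#' @param events a \linkS4class{StimulusTrain} or a per-scan input vector
#' @param TR repetition time (s)
#' @param support HRF support in seconds (16 samples at the defaults)
#' @param grid ARX search grid
#' @param nPerm permutations for the confidence band (0 = none)
#' @param levels percentile pair for the band
#' @param seed RNG seed for the band
#' @return an \linkS4class{HRF} (with model attached)
#' @export
estimateHrf <- function(y, events, TR = 2, support = 32,
                        grid = defaultArxGrid(), nPerm = 0,
                        levels = c(5, 95), seed = NULL) {
  if (is.matrix(y)) y <- rowMeans(y)
  s <- if (is(events, "StimulusTrain")) binEvents(events, length(y), TR)
       else as.numeric(events)
  nPoints <- round(support / TR)
  model <- selectOrders(y, s, grid)
  hrf <- reconstructHrf(model, nPoints, TR)
  if (nPerm > 0) {
    ci <- permutationCi(y, s, model, nPerm = nPerm, levels = levels,
                        seed = seed, nPoints = nPoints, TR = TR)
    hrf@ciLo <- ci$lo
    hrf@ciHi <- ci$hi
  }
  hrf
}

#' Write an HRF (and its band) as delimited text
#'
#' Columns: time, value and, when present, lo/hi confidence bounds.
#'
#' @param hrf an \linkS4class{HRF}
#' @param path output file
#' @export
writeHrf <- function(hrf, path) {
  out <- data.frame(time = (seq_along(hrf@values) - 1) * hrf@TR,
                    value = hrf@values)
  if (!is.null(hrf@ciLo)) { out$lo <- hrf@ciLo; out$hi <- hrf@ciHi }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
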