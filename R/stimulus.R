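#' @include AllClasses.R utils.R
NULL

#' Construct a stimulus train
#'
#' @param onsets event onsets in seconds from series start (strictly
#'   increasing, within [0, duration))
#' @param duration total series length (s)
#' @param amplitudes per-event weights (recycled scalar allowed); default 1
#' @param pulseWidth pulse width in seconds (default 0.1 s, the scale of an
#'   interictal discharge)
#' @return a \linkS4class{StimulusTrain}
#' @examples
#' stimulusTrain(c(10, 55.5, 120), duration = 300)
#' @export
stimulusTrain <- function(onsets, duration, amplitudes = 1,
                          pulseWidth = 0.1) {
  onsets <- as.numeric(onsets)
  if (length(amplitudes) == 1) amplitudes <- rep(amplitudes, length(onsets))
  new("StimulusTrain", onsets = onsets,
      amplitudes = as.numeric(amplitudes), pulseWidth = pulseWidth,
      duration = duration)
}

#' Homogeneous Poisson train of impulse events
#'
#' Draws event times from a homogeneous Poisson process, the generative
#' model used for surrogate interictal discharges (average rate 2.6 events
#' per minute in the reference protocol).
#'
#' @param rate events per minute (>= 0)
#' @param duration series length in seconds
#' @param seed RNG seed (optional)
#' @param pulseWidth pulse width (s)
#' @return a \linkS4class{StimulusTrain}
#' @export
poissonTrain <- function(rate, duration, seed = NULL, pulseWidth = 0.1) {
  .check(rate >= 0, "rate must be >= 0")
  onsets <- withSeed(seed, {
    n <- rpois(1, rate * duration / 60)
    sort(runif(n, 0, duration))
  })
  # strict monotonicity: nudge (astronomically unlikely) ties apart
  while (any(diff(onsets) <= 0))
    onsets <- sort(onsets + c(0, cumsum(diff(onsets) <= 0) * 1e-9))
  stimulusTrain(onsets, duration, 1, pulseWidth)
}

#' Shift a train for slice acquisition timing
#'
#' Slice n (0-based position in the acquisition sequence) of an N_z-slice
#' volume is acquired n TR / N_z after the volume onset, so the input is
#' advanced by that amount: u(t + n TR / N_z).  Events shifted before the
#' series start are dropped.
#'
#' @param train a \linkS4class{StimulusTrain}
#' @param n slice position in the acquisition sequence (0-based, < Nz)
#' @param Nz number of slices
#' @param TR repetition time (s)
#' @return shifted \linkS4class{StimulusTrain}
#' @export
sliceTimingShift <- function(train, n, Nz, TR) {
  .check(n >= 0 && n < Nz, "slice position n must satisfy 0 <= n < Nz")
  shift <- n * TR / Nz
  keep <- train@onsets - shift >= 0
  stimulusTrain(train@onsets[keep] - shift, train@duration,
                train@amplitudes[keep], train@pulseWidth)
}

#' Read / write BIDS-style event tables
#'
#' Tab-delimited tables with columns onset, duration, amplitude, condition
#' (seconds, 0-based from series start).  `readEvents` returns one
#' \linkS4class{StimulusTrain} per condition.
#'
#' @param path file path
#' @param seriesDuration total series length in seconds
#' @param pulseWidth pulse width used for the returned trains; if NA the
#'   table's duration column is used (its median)
#' @return named list of \linkS4class{StimulusTrain}
#' @export
readEvents <- function(path, seriesDuration, pulseWidth = NA) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  .check(all(c("onset", "duration") %in% names(tab)),
         "events table needs onset and duration columns")
  if (is.null(tab$condition)) tab$condition <- "event"
  if (is.null(tab$amplitude)) tab$amplitude <- 1
  out <- lapply(split(tab, tab$condition), function(d) {
    d <- d[order(d$onset), ]
    pw <- if (is.na(pulseWidth)) stats::median(d$duration) else pulseWidth
    if (!is.finite(pw) || pw <= 0) pw <- 0.1
    stimulusTrain(d$onset, seriesDuration, d$amplitude, pw)
  })
  out
}

#' @rdname readEvents
#' @param trains named list of StimulusTrain (or a single train)
#' @export
writeEvents <- function(trains, path) {
  if (is(trains, "StimulusTrain")) trains <- list(event = trains)
  rows <- do.call(rbind, lapply(names(trains), function(nm) {
    tr <- trains[[nm]]
    data.frame(onset = tr@onsets,
               duration = rep(tr@pulseWidth, length(tr@onsets)),
               amplitude = tr@amplitudes,
               condition = rep(nm, length(tr@onsets)))
  }))
  rows <- rows[order(rows$onset), ]
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Bin a stimulus train to per-scan exogenous inputs
#'
#' Sums event amplitudes falling in each TR interval; scan i (time
#' (i-1) TR) collects events with onset in [(i-1) TR, i TR).
#'
#' @param train a \linkS4class{StimulusTrain}
#' @param nScans number of scans
#' @param TR repetition time (s)
#' @return numeric vector of length nScans
#' @export
binEvents <- function(train, nScans, TR) {
  s <- numeric(nScans)
  idx <- floor(train@onsets / TR) + 1L
  keep <- idx >= 1 & idx <= nScans
  for (k in which(keep)) s[idx[k]] <- s[idx[k]] + train@amplitudes[k]
  s
}
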