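#' @include AllClasses.R glm.R arx.R classify.R nifti.R
NULL

defaultConfig <- function() {
  list(
    geometry = list(gridDim = c(20, 20, 10), voxelSize = c(3, 3, 8)),
    timing = list(TR = 2, duration = 600),
    simulation = list(rate = 2.6, noiseP = 0.5, snr = 1.5,
                      smoothFwhm = 8),
    estimation = list(nPerm = 200, ciLevels = c(5, 95),
                      roiRadiusMm = 10),
    classifier = list(M = 51, k = 5, kernel = "coarse-gaussian",
                      modelPath = NULL),
    detection = list(alpha = 0.05),
    seed = 1L)
}

#' Read and validate a pipeline configuration (JSON)
#'
#' Unknown keys (top level or within a section) are rejected; missing
#' keys take their documented defaults.
#'
#' @param path JSON file
#' @return validated configuration list
#' @export
readConfig <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  def <- defaultConfig()
  bad <- setdiff(names(cfg), names(def))
  .check(length(bad) == 0,
         paste("unknown configuration keys:", paste(bad, collapse = ", ")))
  for (sec in names(cfg)) {
    if (is.list(def[[sec]])) {
      badk <- setdiff(names(cfg[[sec]]), names(def[[sec]]))
      .check(length(badk) == 0,
             paste0("unknown keys in '", sec, "': ",
                    paste(badk, collapse = ", ")))
      def[[sec]][names(cfg[[sec]])] <- cfg[[sec]]
    } else def[[sec]] <- cfg[[sec]]
  }
  def
}

#' Save / load a trained mechanism classifier
#'
#' @param model a \linkS4class{MechanismModel}
#' @param path archive file path
#' @export
saveMechanismModel <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveMechanismModel
#' @export
readMechanismModel <- function(path) {
  m <- readRDS(path)
  .check(is(m, "MechanismModel"), "file does not contain a classifier")
  m
}

roiSphere <- function(dim3, voxelSize, center, radiusMm) {
  g <- expand.grid(x = seq_len(dim3[1]), y = seq_len(dim3[2]),
                   z = seq_len(dim3[3]))
  d2 <- ((g$x - center[1]) * voxelSize[1])^2 +
    ((g$y - center[2]) * voxelSize[2])^2 +
    ((g$z - center[3]) * voxelSize[3])^2
  array(d2 <= radiusMm^2, dim3)
}

#' Run the detection / estimation / classification pipeline
#'
#' Stages: (a) GLM detection of voxels locked to the events, (b) HRF
#' estimation on the mean series of a 10-mm sphere around each detected
#' cluster peak, with a permutation confidence band, (c) mechanism
#' classification of each normalized HRF.  Results and a stage log are
#' written under \code{outDir}.
#'
#' @param config configuration list (see \code{\link{readConfig}}) or a
#'   JSON path
#' @param scans a \linkS4class{ScanSeries} or a NIfTI path
#' @param trains named list of \linkS4class{StimulusTrain}, or an events
#'   table path
#' @param model optional \linkS4class{MechanismModel}; if NULL one is
#'   trained from a fresh simulated ensemble (config$classifier)
#' @param outDir output directory
#' @return list(detection, hrfs, labels, log, model), invisibly written
#'   to outDir
#' @export
runPipeline <- function(config, scans, trains, model = NULL,
                        outDir = tempfile("nbrmech")) {
  if (is.character(config)) config <- readConfig(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logLines <- character(0)
  stamp <- function(msg) {
    line <- paste0(format(Sys.time(), "%H:%M:%S"), "  ", msg)
    logLines <<- c(logLines, line)
  }
  fail <- function(stage, e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  if (is.character(scans)) scans <- readNifti(scans)
  if (is.character(trains))
    trains <- readEvents(trains, nVolumes(scans) * scans@TR)
  if (is(trains, "StimulusTrain")) trains <- list(task = trains)
  .check(length(trains) > 0 && all(vapply(trains, function(tr)
    length(tr@onsets) > 0, TRUE)), "empty events: nothing to analyze")

  stamp("stage detect: GLM + F contrast + FWE threshold")
  det <- tryCatch(
    detectResponses(scans, trains, alpha = config$detection$alpha),
    error = function(e) fail("detect", e))
  writeNifti(array(det$Fmap, c(dim(det$Fmap), 1)),
             file.path(outDir, "fmap.nii"),
             voxelSize = scans@voxelSize, TR = scans@TR)
  writeNifti(array(det$significant * 1, c(dim(det$Fmap), 1)),
             file.path(outDir, "significant.nii"),
             voxelSize = scans@voxelSize, TR = scans@TR)
  if (!is.null(det$table))
    write.table(det$table, file.path(outDir, "clusters.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  stamp(sprintf("  %d significant voxel(s), %d cluster(s)",
                sum(det$significant),
                if (is.null(det$table)) 0L else nrow(det$table)))

  if (is.null(model)) {
    stamp("stage train: simulating classifier ensemble")
    model <- tryCatch({
      mp <- config$classifier$modelPath
      if (!is.null(mp) && file.exists(mp)) readMechanismModel(mp)
      else {
        ens <- generateTrainingEnsemble(M = config$classifier$M,
                                        seed = config$seed,
                                        TR = config$timing$TR,
                                        duration = config$timing$duration,
                                        rate = config$simulation$rate,
                                        noiseP = config$simulation$noiseP)
        trainClassifier(buildFeatures(ens$hrfs, ens$labels),
                        kernel = config$classifier$kernel,
                        seed = config$seed)
      }
    }, error = function(e) fail("train", e))
  }

  stamp("stage estimate/classify: ROI HRFs + permutation bands")
  hrfs <- list(); labs <- NULL
  if (!is.null(det$table)) {
    d3 <- dim(det$Fmap)
    N <- nVolumes(scans)
    Ym <- matrix(aperm(scans@data, c(4, 1, 2, 3)), nrow = N)
    for (i in seq_len(nrow(det$table))) {
      ctr <- c(det$table$x[i], det$table$y[i], det$table$z[i])
      roi <- roiSphere(d3, scans@voxelSize, ctr,
                       config$estimation$roiRadiusMm) & det$mask
      ys <- rowMeans(Ym[, as.vector(roi), drop = FALSE])
      h <- tryCatch(
        estimateHrf(ys, trains[[1]], TR = scans@TR,
                    nPerm = config$estimation$nPerm,
                    levels = config$estimation$ciLevels,
                    seed = config$seed + i),
        error = function(e) fail("estimate-hrf", e))
      hn <- normalizeHrf(h)
      pred <- tryCatch(predictMechanism(model, hn),
                       error = function(e) fail("classify", e))
      hrfs[[i]] <- hn
      writeHrf(hn, file.path(outDir, sprintf("hrf_cluster%02d.tsv", i)))
      labs <- rbind(labs, data.frame(
        cluster = i, x = ctr[1], y = ctr[2], z = ctr[3],
        peakF = det$table$peakF[i], polarity = polarity(hn),
        mechanism = pred$label))
      stamp(sprintf("  cluster %d @ (%d,%d,%d): %s (polarity %+d)", i,
                    ctr[1], ctr[2], ctr[3], pred$label,
                    as.integer(polarity(hn))))
    }
    write.table(labs, file.path(outDir, "labels.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  writeLines(logLines, file.path(outDir, "log.txt"))
  invisible(list(detection = det, hrfs = hrfs, labels = labs,
                 log = logLines, model = model, outDir = outDir))
}

#' Regenerate the package's reference simulation products
#'
#' \describe{
#'   \item{fig1}{single-impulse parameter sweeps per mechanism (BOLD,
#'     rCBF, rCBV curves) with the four monotonicity properties
#'     summarized.}
#'   \item{fig2}{synthetic-scan GLM detection maps and cluster table.}
#'   \item{fig3}{classification ensemble, five-fold CV confusion matrix
#'     and misclassification summary.}
#' }
#'
#' @param which "fig1", "fig2" or "fig3"
#' @param dir output directory
#' @param seed RNG seed
#' @param M trials per class (fig3)
#' @return figure-specific summary list (files are written to dir)
#' @export
reproduceFigure <- function(which, dir = tempfile("nbrmech_fig"),
                            seed = 1, M = 51) {
  .check(which %in% c("fig1", "fig2", "fig3"),
         paste("unknown figure key:", which))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (which == "fig1") {
    sweeps <- list(
      ECI = list(param = "neural1.tau_i1", values = c(2, 6, 20)),
      NDA = list(param = "neural1.tau_e2", values = c(1, 3, 6)),
      ANC = list(param = "metabolic.kappa", values = c(0.3, 0.51, 0.7)),
      ABS = list(param = "vascular.R_A", values = c(0.05, 0.17, 0.3)))
    stim <- stimulusTrain(5, duration = 90)
    out <- list()
    for (mech in names(sweeps)) {
      sw <- sweeps[[mech]]
      region <- if (mech == "ABS") 2L else 1L
      curves <- lapply(sw$values, function(v) {
        pars <- setParam(makePreset(mech), sw$param, v)
        traj <- simulateMechanism(pars, stim, tEnd = 90)
        data.frame(t = traj@t, bold = bold(traj, region),
                   rcbf = cbf(traj, region), rcbv = cbv(traj, region),
                   param = v)
      })
      tab <- do.call(rbind, curves)
      write.table(tab, file.path(dir, paste0("fig1_", mech, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      amp <- vapply(curves, function(d) abs(min(d$bold)), numeric(1))
      rec <- vapply(sw$values, function(v) {
        pars <- setParam(makePreset(mech), sw$param, v)
        nbrRecoveryTime(simulateMechanism(pars, stim, tEnd = 90), region)
      }, numeric(1))
      out[[mech]] <- list(values = sw$values, nbrAmplitude = amp,
                          recoveryTime = rec)
    }
    out$monotonic <- c(
      ECI_amplitude_decreasing = all(diff(out$ECI$nbrAmplitude) < 0),
      NDA_recovery_increasing = all(diff(out$NDA$recoveryTime) > 0),
      ANC_amplitude_increasing = all(diff(out$ANC$nbrAmplitude) > 0),
      ABS_amplitude_increasing = all(diff(out$ABS$nbrAmplitude) > 0))
    write.table(data.frame(property = names(out$monotonic),
                           holds = out$monotonic),
                file.path(dir, "fig1_monotonicity.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    out
  } else if (which == "fig2") {
    syn <- synthesizeScans(seed = seed, snr = 4)
    det <- detectResponses(syn$scans, list(ied = syn$train),
                           mask = syn$mask)
    writeNifti(array(det$Fmap, c(dim(det$Fmap), 1)),
               file.path(dir, "fig2_fmap.nii"),
               voxelSize = syn$scans@voxelSize)
    if (!is.null(det$table))
      write.table(det$table, file.path(dir, "fig2_clusters.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    hit <- vapply(seq_len(nrow(syn$truth)), function(i)
      det$significant[syn$truth$x[i], syn$truth$y[i], syn$truth$z[i]],
      logical(1))
    medF <- vapply(seq_len(nrow(syn$truth)), function(i) {
      roi <- roiSphere(dim(det$Fmap), syn$scans@voxelSize,
                       c(syn$truth$x[i], syn$truth$y[i], syn$truth$z[i]),
                       6)
      stats::median(det$Fmap[roi & det$significant])
    }, numeric(1))
    summary <- cbind(syn$truth, detected = hit, medianF = medF)
    write.table(summary, file.path(dir, "fig2_summary.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    list(detection = det, truth = summary)
  } else {
    exp <- ensembleExperiment(seeds = seed, M = M)
    cv <- attr(exp, "results")[[1]]
    write.table(as.data.frame.matrix(cv$confusion),
                file.path(dir, "fig3_confusion.tsv"), sep = "\t",
                quote = FALSE)
    write.table(exp, file.path(dir, "fig3_summary.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    list(summary = exp, confusion = cv$confusion,
         misclassificationPct = exp$misclassificationPct)
  }
}
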