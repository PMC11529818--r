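## Orchestration: a single configuration object carrying every threshold
## with its default, and the two end-to-end analyses (behaviour session,
## connectome). All randomness flows from the config seed; re-running with
## an identical config yields identical outputs.

#' Analysis run configuration
#'
#' Collects every tunable of the pipeline with its default. The config
#' round-trips losslessly through JSON ([writeRunConfig()] /
#' [readRunConfig()]).
#'
#' @param frameRate behavioural frame rate, Hz (default 100).
#' @param stimOnS,stimOffS light window, seconds (defaults 0.5, 15.5).
#' @param units rig length unit ("mm" or "um"), declared, never inferred.
#' @param confidenceMin 2D-confidence gate for triangulation (0.7).
#' @param maxGapMs gap-interpolation bound, ms (500).
#' @param smoothMs proportion-smoothing window, ms (250).
#' @param binS rank-sum bin width, s (0.5).
#' @param alpha per-bin significance cutoff (0.01).
#' @param minBoutMs first-bout minimum duration, ms (30).
#' @param thresholds classifier thresholds, see [aggressionThresholds()].
#' @param peakThresholds sex-specific wingspan peak thresholds, mm
#'   (c(male = 0.22, female = 0.25)).
#' @param preWindowS wingspan baseline window, s (10).
#' @param habituationWindowS within-bout habituation window, s (2).
#' @param nResamples bootstrap resamples (10000).
#' @param synapseCutoff connectome edge cutoff (10).
#' @param maxIntermediates 0 or 1 intermediate neurons per path (1).
#' @param excludeIntermediates node ids barred as intermediates (none; the
#'   unrestricted default — set to the source/target classes to compare
#'   against a restricted variant).
#' @param k number of source clusters (3).
#' @param linkage clustering linkage (average).
#' @param strongThreshold cluster-profile binarization threshold (20).
#' @param rowFilterMinTotal PCA row filter on total weight (300).
#' @param pcaCenter centre normalised rows before PCA (TRUE).
#' @param cvFolds SVM cross-validation folds (10).
#' @param seed master seed.
#' @return list of class `flyaggrConfig`.
#' @export
runConfig <- function(frameRate = 100, stimOnS = 0.5, stimOffS = 15.5,
                      units = "mm", confidenceMin = 0.7, maxGapMs = 500,
                      smoothMs = 250, binS = 0.5, alpha = 0.01,
                      minBoutMs = 30, thresholds = aggressionThresholds(),
                      peakThresholds = c(male = 0.22, female = 0.25),
                      preWindowS = 10, habituationWindowS = 2,
                      nResamples = 10000, synapseCutoff = 10,
                      maxIntermediates = 1,
                      excludeIntermediates = character(), k = 3,
                      linkage = "average", strongThreshold = 20,
                      rowFilterMinTotal = 300, pcaCenter = TRUE,
                      cvFolds = 10, seed = 1) {
  cfg <- as.list(environment())
  class(cfg) <- "flyaggrConfig"
  cfg
}

#' Write / read a run configuration as JSON
#'
#' @param config a [runConfig()].
#' @param path file path.
#' @return the path (writing) or a config (reading).
#' @export
writeRunConfig <- function(config, path) {
  cfg <- unclass(config)
  cfg$peakThresholds <- as.list(cfg$peakThresholds)  # keep names in JSON
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$thresholds <- do.call(aggressionThresholds, as.list(raw$thresholds))
  raw$peakThresholds <- unlist(raw$peakThresholds)
  raw$excludeIntermediates <- as.character(raw$excludeIntermediates)
  do.call(runConfig, raw)
}

#' Behavioural session analysis
#'
#' Runs the behaviour pipeline on a set of per-trial keypoint tracks:
#' gap interpolation, observables, frame classification, bout extraction
#' and first-bout latencies, and the per-fly proportion time course per
#' action.
#'
#' @param tracks list of per-trial [Keypoint3DTrack-class] objects.
#' @param arena an [ArenaGeometry-class] (or `NULL` to skip elevation and
#'   the alert stance).
#' @param config a [runConfig()].
#' @return list with `observables` (per trial), `ethograms` (per trial),
#'   `latencies` (data.frame trial x action), `proportions` (named list of
#'   smoothed per-action time courses).
#' @export
analyzeBehavior <- function(tracks, arena = NULL, config = runConfig()) {
  obs <- lapply(tracks, function(tr)
    computeObservables(interpolateGaps(tr, config$maxGapMs), arena = arena))
  ethos <- lapply(obs, classifyFrames, thresholds = config$thresholds)
  lat <- do.call(rbind, lapply(seq_along(ethos), function(i) {
    row <- data.frame(trial = i)
    for (a in actionNames())
      row[[a]] <- firstBoutLatency(ethos[[i]], a, config$stimOnS,
                                   config$minBoutMs)
    row
  }))
  props <- stats::setNames(lapply(actionNames(), function(a)
    proportionTimecourse(ethos, a, config$smoothMs)), actionNames())
  list(observables = obs, ethograms = ethos, latencies = lat,
       proportions = props)
}

#' Connectome analysis
#'
#' Runs the connectome pipeline on a loaded graph: source-to-DN
#' equivalent-weight matrix (with NT decomposition), cosine-similarity
#' hierarchical clustering of the sources, cluster-to-DN strong profiles,
#' and the PCA biplot with SVM separating planes when both labelings have
#' two classes among the retained rows.
#'
#' @param graph a [ConnectomeGraph-class].
#' @param sourceTypes node types used as sources (default "CL062").
#' @param targetTypes node types used as targets (default "DN").
#' @param config a [runConfig()].
#' @return list with `weights` ([EquivalentWeightMatrix-class]),
#'   `clusters` ([ClusterResult-class]), `profile` (see
#'   [clusterDnProfile()]), `biplot` (a [BiplotResult-class] or `NULL`
#'   when too few rows survive the total-weight filter), `svm` (or `NULL`),
#'   `summary` (plain list of headline numbers).
#' @export
analyzeConnectome <- function(graph, sourceTypes = "CL062",
                              targetTypes = "DN", config = runConfig()) {
  nodes <- nodeTable(graph)
  sources <- nodes$id[nodes$type %in% sourceTypes]
  targets <- nodes$id[nodes$type %in% targetTypes]
  if (!length(sources) || !length(targets))
    stop("no sources or targets of the requested types")
  ewm <- equivalentWeightMatrix(graph, sources, targets, ntPaths = TRUE,
                                maxIntermediates = config$maxIntermediates,
                                excludeIntermediates = config$excludeIntermediates)
  sim <- cosineSimilarityMatrix(ewm)
  cl <- clusterSources(sim, k = config$k, linkage = config$linkage)
  W <- eqWeights(ewm)[rownames(sim), , drop = FALSE]
  prof <- clusterDnProfile(W, clusterLabels(cl), config$strongThreshold)

  biplot <- tryCatch(pcaBiplot(ewm, config$rowFilterMinTotal,
                               center = config$pcaCenter),
                     error = function(e) NULL)
  svm <- NULL
  if (!is.null(biplot)) {
    kept <- rownames(biplot@scores)
    hemi <- nodes$hemisphere[match(kept, nodes$id)]
    cls <- nodes$type[match(kept, nodes$id)]
    if (length(unique(hemi)) == 2L && length(unique(cls)) == 2L &&
        min(table(hemi)) >= 2L && min(table(cls)) >= 2L) {
      svm <- svmPlanes(biplot@scores, hemi, cls, cvFolds = config$cvFolds,
                       seed = config$seed)
    }
  }
  summary <- list(
    nSources = length(sources), nTargets = length(targets),
    clusterSizes = as.integer(table(clusterLabels(cl))),
    nStrongDns = as.integer(rowSums(prof$strong)),
    varianceExplained = if (!is.null(biplot)) biplot@varianceExplained,
    cvLosses = if (!is.null(svm)) svm$cvLosses,
    planeAngleDeg = if (!is.null(svm)) svm$planeAngleDeg)
  list(weights = ewm, clusters = cl, profile = prof, biplot = biplot,
       svm = svm, summary = summary)
}

#' Write fixture files for both pipelines
#'
#' Generates a synthetic pose session and a synthetic connectome from the
#' config seed and writes them in the CSV formats the pipeline reads
#' (observables, ethograms, connectome edge/node tables, scripts as JSON),
#' so generated fixtures double as format tests.
#'
#' @param outDir output directory (created if needed).
#' @param config a [runConfig()].
#' @param nTrials trials in the pose fixture (default 3, kept small).
#' @return invisibly, the vector of written paths.
#' @export
simulateFixtures <- function(outDir, config = runConfig(), nTrials = 3) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  ps <- poseScript(nTrials = nTrials, bouts = defaultBoutSchedule(nTrials),
                   seed = config$seed)
  ses <- generatePoseSession(ps)
  beh <- analyzeBehavior(ses$tracks, ses$arena, config)
  paths <- character(0)
  p <- file.path(outDir, "pose_script.json"); writePoseScript(ps, p)
  paths <- c(paths, p)
  for (i in seq_along(beh$ethograms)) {
    p <- file.path(outDir, sprintf("observables_trial%02d.csv", i))
    writeObservablesCsv(beh$observables[[i]], p); paths <- c(paths, p)
    p <- file.path(outDir, sprintf("ethogram_trial%02d.csv", i))
    writeEthogramCsv(beh$ethograms[[i]], p); paths <- c(paths, p)
  }
  cs <- connectomeScript(seed = config$seed)
  gen <- generateConnectome(cs)
  p <- file.path(outDir, "connectome_script.json"); writeConnectomeScript(cs, p)
  paths <- c(paths, p)
  writeConnectomeCsv(gen$graph, file.path(outDir, "edges.csv"),
                     file.path(outDir, "nodes.csv"))
  paths <- c(paths, file.path(outDir, c("edges.csv", "nodes.csv")))
  invisible(paths)
}

#' Write an analysis summary as JSON
#'
#' @param summary a plain list (e.g. `analyzeConnectome(...)$summary`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSummaryJson <- function(summary, path) {
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
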