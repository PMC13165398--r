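# Data-format layer and the end-to-end pipeline driver. Keypoint tracks
# travel as CSV with a documented header; tensors, factors and summaries are
# written as CSV/JSON with seeds and a config hash for provenance.

KEYPOINT_SCHEMA <- c("frame", "timestamp",
                     as.vector(rbind(paste0("x_", KEYPOINTS),
                                     paste0("y_", KEYPOINTS))),
                     paste0("vis_", KEYPOINTS))

#' Write a keypoint track to CSV
#'
#' Columns: frame, timestamp, x/y per keypoint (NA when invisible), then
#' 0/1 visibility flags per keypoint.
#'
#' @param track a [KeypointTrack-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeKeypoints <- function(track, path) {
  df <- data.frame(frame = track@frame, timestamp = track@timestamp,
                   track@coords,
                   matrix(as.integer(track@visible), nrow = nFrames(track),
                          dimnames = list(NULL, paste0("vis_", KEYPOINTS))),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a keypoint track from CSV
#'
#' Validates the schema, drops (and counts) frames that appear more than
#' once — the duplicate-keypoint drop rule applied upstream of all feature
#' computation — and returns a validated track. The drop count is recorded
#' in the track's `meta`.
#'
#' @param path CSV file written by [writeKeypoints()] (or matching its
#'   schema).
#' @param tankSize tank (width, height) in pixels.
#' @param fps frames per second of the recording.
#' @return a [KeypointTrack-class].
#' @export
readKeypoints <- function(path, tankSize = c(400, 250), fps = 20) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (nrow(df) == 0) stop("empty keypoint file: ", path)
  missingCols <- setdiff(KEYPOINT_SCHEMA, names(df))
  if (length(missingCols))
    stop("keypoint file missing columns: ",
         paste(missingCols, collapse = ", "))
  dup <- duplicated(df$frame) | duplicated(df$frame, fromLast = TRUE)
  nDropped <- length(unique(df$frame[dup]))
  df <- df[!dup, , drop = FALSE]
  if (nrow(df) == 0) stop("all frames dropped as duplicates in ", path)
  df <- df[order(df$frame), , drop = FALSE]
  coords <- as.matrix(df[, as.vector(rbind(paste0("x_", KEYPOINTS),
                                           paste0("y_", KEYPOINTS)))])
  visible <- as.matrix(df[, paste0("vis_", KEYPOINTS)]) > 0
  dimnames(coords) <- list(NULL, colnames(coords))
  dimnames(visible) <- list(NULL, KEYPOINTS)
  methods::new("KeypointTrack",
    frame = as.integer(df$frame), timestamp = as.numeric(df$timestamp),
    coords = coords, visible = visible, tankSize = as.numeric(tankSize),
    fps = fps, meta = list(droppedDuplicateFrames = nDropped, path = path))
}

#' Pipeline run configuration
#'
#' Bundles every stage's parameters and seeds; the configuration is hashed
#' and written alongside every output so a run can be reproduced exactly.
#'
#' @param sim a [simConfig()].
#' @param pose a [poseConfig()].
#' @param nAnimals cohort size for the simulate stage.
#' @param cohort a [cohortSpec()].
#' @param maxDaysPerAnimal recording-day cap per animal.
#' @param trackSeconds length of the per-animal demo track, seconds.
#' @param hmmStates syllable HMM states fit on the demo track.
#' @param schedule an [emSchedule()] for the syllable HMM.
#' @param cpRank tensor components for the usage-tensor fit.
#' @param KStages life stages.
#' @param penaltyScale change-point penalty scale.
#' @param stages character vector of stages to run, in dependency order.
#' @return a list of class `RunConfig`.
#' @export
runConfig <- function(sim = simConfig(), pose = poseConfig(),
                      nAnimals = 5L, cohort = cohortSpec(),
                      maxDaysPerAnimal = 30L, trackSeconds = 120,
                      hmmStates = 3L, schedule = emSchedule(batchSize = 500L,
                                                           maxEpochs = 3L),
                      cpRank = 4L, KStages = 3L, penaltyScale = 1,
                      stages = c("simulate", "features", "syllables",
                                 "tca", "lifestages")) {
  structure(list(sim = sim, pose = pose, nAnimals = as.integer(nAnimals),
                 cohort = cohort,
                 maxDaysPerAnimal = maxDaysPerAnimal,
                 trackSeconds = trackSeconds,
                 hmmStates = as.integer(hmmStates), schedule = schedule,
                 cpRank = as.integer(cpRank), KStages = as.integer(KStages),
                 penaltyScale = penaltyScale, stages = stages),
            class = "RunConfig")
}

#' Run the full pipeline on synthetic inputs
#'
#' Executes the enabled stages in dependency order on a seeded synthetic
#' cohort: track simulation, pose features and PCs, syllable HMM fitting and
#' decoding on the demo track, usage-tensor construction and non-negative CP
#' fitting on the cohort, and change-point plus life-stage analysis of the
#' resulting age factors. Every output carries the configuration hash and
#' seed; re-running with an identical configuration reproduces identical
#' numbers.
#'
#' @param config a [runConfig()].
#' @param outDir optional directory; when given, CSV/JSON artifacts are
#'   written there.
#' @return a list bundle with one element per executed stage plus
#'   `provenance`.
#' @export
runPipeline <- function(config = runConfig(), outDir = NULL) {
  stopifnot(inherits(config, "RunConfig"))
  bundle <- list(provenance = list(configHash = configHash(config),
                                   seed = config$sim$seed,
                                   version = as.character(
                                     utils::packageVersion("behaviorome"))))
  if ("simulate" %in% config$stages) {
    bundle$cohort <- simulateSyllableCohort(
      config$nAnimals, config$cohort, config$sim,
      maxDaysPerAnimal = config$maxDaysPerAnimal)
    prog <- behaviorProgram(
      programSegment("rest", config$trackSeconds * 0.4),
      programSegment("cruise", config$trackSeconds * 0.3),
      programSegment("burst", config$trackSeconds * 0.1),
      programSegment("reversal", config$trackSeconds * 0.1),
      programSegment("drift", config$trackSeconds * 0.1))
    bundle$track <- simulateTrack(prog, config$sim)
  }
  if ("features" %in% config$stages) {
    pf <- assembleFeatures(bundle$track, config$pose)
    bundle$features <- suppressWarnings(
      reduceToPCs(pf, nPcs = config$pose$nPcs, config = config$pose))
  }
  if ("syllables" %in% config$stages) {
    pcs <- pcScores(bundle$features)
    ok <- stats::complete.cases(pcs)
    obs <- pcs[ok, , drop = FALSE]
    hmm <- stochasticEMFit(obs, config$hmmStates, config$schedule)
    bundle$syllableModel <- hmm
    bundle$syllables <- decodeSyllables(obs, hmm)
  }
  if ("tca" %in% config$stages) {
    tensor <- normalizeUsage(bundle$cohort$tensor)
    model <- fitNonnegCP(tensor, config$cpRank, seed = config$sim$seed)
    bundle$tensor <- tensor
    bundle$cpModel <- model
    truth <- bundle$cohort$truth
    bundle$ageSeries <- ageFactorSeriesFromCP(
      model, tensor, stats::setNames(truth$lifespans, truth$animals),
      censored = stats::setNames(truth$recordedDays < truth$lifespans,
                                 truth$animals),
      group = stats::setNames(truth$group, truth$animals))
  }
  if ("lifestages" %in% config$stages) {
    usage <- dailyUsageFromTensor(bundle$tensor,
                                  lightHours = config$sim$lightHours)
    ad <- animalDays(bundle$tensor)
    bundle$changePoints <- lapply(
      split(seq_len(nrow(ad)), ad$animal), function(rows) {
        rows <- rows[order(ad$age[rows])]
        detectChangePoints(usage[rows, , drop = FALSE],
                           penaltyScale = config$penaltyScale)
      })
    bundle$stageModel <- fitStageModel(bundle$ageSeries,
                                       KStages = config$KStages,
                                       seed = config$sim$seed)
    bundle$stageSummaries <- stageSummaries(bundle$stageModel, bundle$tensor)
  }
  if (!is.null(outDir)) writeBundle(bundle, outDir)
  bundle
}

#' @keywords internal
writeBundle <- function(bundle, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(bundle$provenance, file.path(outDir, "provenance.json"),
                       auto_unbox = TRUE)
  if (!is.null(bundle$track))
    writeKeypoints(bundle$track, file.path(outDir, "track.csv"))
  if (!is.null(bundle$ageSeries)) {
    utils::write.csv(data.frame(animal = bundle$ageSeries$animal,
                                age = bundle$ageSeries$age,
                                bundle$ageSeries$factors),
                     file.path(outDir, "age_factors.csv"), row.names = FALSE)
  }
  if (!is.null(bundle$cohort)) {
    tr <- bundle$cohort$truth
    utils::write.csv(data.frame(animal = tr$animals, lifespan = tr$lifespans,
                                group = tr$group,
                                recordedDays = tr$recordedDays),
                     file.path(outDir, "manifest.csv"), row.names = FALSE)
  }
  if (!is.null(bundle$changePoints)) {
    cp <- do.call(rbind, lapply(names(bundle$changePoints), function(a) {
      cps <- bundle$changePoints[[a]]$changePoints
      if (!length(cps)) return(NULL)
      data.frame(animal = a, changePointDay = cps)
    }))
    if (is.null(cp)) cp <- data.frame(animal = character(0),
                                      changePointDay = integer(0))
    utils::write.csv(cp, file.path(outDir, "change_points.csv"),
                     row.names = FALSE)
  }
  if (!is.null(bundle$stageModel)) {
    sl <- stageLabels(bundle$stageModel)
    df <- do.call(rbind, lapply(names(sl), function(a)
      data.frame(animal = a, day = seq_along(sl[[a]]), stage = sl[[a]])))
    utils::write.csv(df, file.path(outDir, "stage_labels.csv"),
                     row.names = FALSE)
  }
  invisible(outDir)
}
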