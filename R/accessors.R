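# Accessor generics and methods; user code should not reach into slots.

#' Number of frames in a track or feature matrix
#' @param x a KeypointTrack or PoseFeatures object.
#' @return integer frame count.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname nFrames
#' @export
setMethod("nFrames", "KeypointTrack", function(x) length(x@frame))

#' @rdname nFrames
#' @export
setMethod("nFrames", "PoseFeatures", function(x) nrow(x@features))

#' Keypoint coordinates of a track
#' @param x a KeypointTrack.
#' @param keypoint optional keypoint name; if given, returns an n x 2 matrix
#'   of that keypoint's (x, y), else the full coordinate matrix.
#' @export
setGeneric("keypointCoords", function(x, keypoint = NULL)
  standardGeneric("keypointCoords"))

#' @rdname keypointCoords
#' @export
setMethod("keypointCoords", "KeypointTrack", function(x, keypoint = NULL) {
  if (is.null(keypoint)) return(x@coords)
  stopifnot(keypoint %in% KEYPOINTS)
  m <- x@coords[, paste0(c("x_", "y_"), keypoint), drop = FALSE]
  colnames(m) <- c("x", "y")
  m
})

#' Timestamps of a track (seconds)
#' @param x a KeypointTrack.
#' @export
setGeneric("timestamps", function(x) standardGeneric("timestamps"))

#' @rdname timestamps
#' @export
setMethod("timestamps", "KeypointTrack", function(x) x@timestamp)

#' Keypoint visibility flags
#' @param x a KeypointTrack.
#' @export
setGeneric("keypointVisible", function(x) standardGeneric("keypointVisible"))

#' @rdname keypointVisible
#' @export
setMethod("keypointVisible", "KeypointTrack", function(x) x@visible)

#' Pose feature matrix (57 named columns)
#' @param x a PoseFeatures object.
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @rdname featureMatrix
#' @export
setMethod("featureMatrix", "PoseFeatures", function(x) x@features)

#' Smoothed principal-component scores
#' @param x a PoseFeatures object.
#' @export
setGeneric("pcScores", function(x) standardGeneric("pcScores"))

#' @rdname pcScores
#' @export
setMethod("pcScores", "PoseFeatures", function(x) x@pcs)

#' HMM parameter accessors
#' @param x a GaussianHMM.
#' @return `hmmStates`: state count; `startProbs`: initial distribution;
#'   `transitionMatrix`: K x K stochastic matrix; `emissionMeans`: K x D;
#'   `emissionCovs`: D x D x K.
#' @export
setGeneric("hmmStates", function(x) standardGeneric("hmmStates"))
#' @rdname hmmStates
#' @export
setMethod("hmmStates", "GaussianHMM", function(x) x@K)

#' @rdname hmmStates
#' @export
setGeneric("startProbs", function(x) standardGeneric("startProbs"))
#' @rdname hmmStates
#' @export
setMethod("startProbs", "GaussianHMM", function(x) x@pi)

#' @rdname hmmStates
#' @export
setGeneric("transitionMatrix", function(x) standardGeneric("transitionMatrix"))
#' @rdname hmmStates
#' @export
setMethod("transitionMatrix", "GaussianHMM", function(x) x@A)

#' @rdname hmmStates
#' @export
setGeneric("emissionMeans", function(x) standardGeneric("emissionMeans"))
#' @rdname hmmStates
#' @export
setMethod("emissionMeans", "GaussianHMM", function(x) x@mu)

#' @rdname hmmStates
#' @export
setGeneric("emissionCovs", function(x) standardGeneric("emissionCovs"))
#' @rdname hmmStates
#' @export
setMethod("emissionCovs", "GaussianHMM", function(x) x@Sigma)

#' Usage tensor accessors
#' @param x a UsageTensor.
#' @return `usageCounts`: the N x T x K integer count array;
#'   `usageNormalized`: the min-max scaled array (error if not yet
#'   normalized); `animalDays`: data.frame mapping slices to (animal, age).
#' @export
setGeneric("usageCounts", function(x) standardGeneric("usageCounts"))
#' @rdname usageCounts
#' @export
setMethod("usageCounts", "UsageTensor", function(x) x@counts)

#' @rdname usageCounts
#' @export
setGeneric("usageNormalized", function(x) standardGeneric("usageNormalized"))
#' @rdname usageCounts
#' @export
setMethod("usageNormalized", "UsageTensor", function(x) {
  if (length(dim(x@normalized)) != 3L)
    stop("tensor has not been normalized; call normalizeUsage() first")
  x@normalized
})

#' @rdname usageCounts
#' @export
setGeneric("animalDays", function(x) standardGeneric("animalDays"))
#' @rdname usageCounts
#' @export
setMethod("animalDays", "UsageTensor", function(x) x@animalDay)

#' CP factor accessors
#' @param x a CPModel.
#' @return `cpRank`: number of components; `syllableFactors`,
#'   `timeFactors`, `ageFactors`: the three factor matrices.
#' @export
setGeneric("cpRank", function(x) standardGeneric("cpRank"))
#' @rdname cpRank
#' @export
setMethod("cpRank", "CPModel", function(x) x@rank)

#' @rdname cpRank
#' @export
setGeneric("syllableFactors", function(x) standardGeneric("syllableFactors"))
#' @rdname cpRank
#' @export
setMethod("syllableFactors", "CPModel", function(x) x@syllable)

#' @rdname cpRank
#' @export
setGeneric("timeFactors", function(x) standardGeneric("timeFactors"))
#' @rdname cpRank
#' @export
setMethod("timeFactors", "CPModel", function(x) x@time)

#' @rdname cpRank
#' @export
setGeneric("ageFactors", function(x) standardGeneric("ageFactors"))
#' @rdname cpRank
#' @export
setMethod("ageFactors", "CPModel", function(x) x@age)

#' Stage model accessors
#' @param x a StageModel.
#' @return `stageLabels`: named list of per-animal 0-based stage sequences;
#'   `stageHmm`: the underlying GaussianHMM.
#' @export
setGeneric("stageLabels", function(x) standardGeneric("stageLabels"))
#' @rdname stageLabels
#' @export
setMethod("stageLabels", "StageModel", function(x) {
  stats::setNames(x@labels, x@animals)
})

#' @rdname stageLabels
#' @export
setGeneric("stageHmm", function(x) standardGeneric("stageHmm"))
#' @rdname stageLabels
#' @export
setMethod("stageHmm", "StageModel", function(x) x@hmm)
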