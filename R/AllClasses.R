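# Central S4 data containers.

KEYPOINTS <- c("snout", "midbody", "endbody", "tail", "fan", "sidebody")
# keypoints with coordinates used as pose features (sidebody is counted only)
COORD_KEYPOINTS <- c("snout", "midbody", "endbody", "tail", "fan")

#' KeypointTrack: per-frame 2-D keypoint coordinates for one animal
#'
#' Holds one animal's tracked body keypoints (snout, midbody, endbody, tail,
#' fan, sidebody) in tank coordinates with the origin at the bottom-left
#' corner of the tank. Coordinates of invisible keypoints are NA and flagged
#' in `visible`.
#'
#' @slot frame integer frame indices.
#' @slot timestamp numeric seconds, strictly increasing.
#' @slot coords numeric matrix, one row per frame, columns
#'   `x_<keypoint>`/`y_<keypoint>` for the six keypoints.
#' @slot visible logical matrix, one column per keypoint.
#' @slot tankSize numeric length-2 (width, height) in pixels.
#' @slot fps numeric frames per second of the recording.
#' @slot meta list of free-form provenance (seeds, program, drop counts).
#' @exportClass KeypointTrack
setClass("KeypointTrack",
  representation(
    frame = "integer", timestamp = "numeric", coords = "matrix",
    visible = "matrix", tankSize = "numeric", fps = "numeric", meta = "list"
  )
)

setValidity("KeypointTrack", function(object) {
  n <- length(object@frame)
  msg <- character()
  if (length(object@timestamp) != n) msg <- c(msg, "timestamp length mismatch")
  if (n > 1 && any(diff(object@timestamp) <= 0))
    msg <- c(msg, "timestamps must be strictly increasing")
  if (nrow(object@coords) != n) msg <- c(msg, "coords row mismatch")
  if (ncol(object@coords) != 2L * length(KEYPOINTS))
    msg <- c(msg, "coords must have x/y for the 6 keypoints")
  if (!identical(dim(object@visible), c(n, length(KEYPOINTS))) && n > 0)
    msg <- c(msg, "visible must be frames x 6")
  if (length(object@tankSize) != 2L || any(object@tankSize <= 0))
    msg <- c(msg, "tankSize must be two positive numbers")
  if (length(msg)) msg else TRUE
})

#' PoseFeatures: per-frame pose feature matrix and its PC reduction
#'
#' @slot features numeric matrix, one row per frame, 57 named columns.
#' @slot pcs numeric matrix of smoothed principal-component scores.
#' @slot loadings orthonormal loading matrix (features x PCs).
#' @slot center,scale z-scoring statistics of the feature columns.
#' @slot explainedVar explained-variance ratios of retained PCs.
#' @slot dropped names of constant feature columns excluded from the PCA.
#' @exportClass PoseFeatures
setClass("PoseFeatures",
  representation(
    features = "matrix", pcs = "matrix", loadings = "matrix",
    center = "numeric", scale = "numeric", explainedVar = "numeric",
    dropped = "character"
  )
)

setValidity("PoseFeatures", function(object) {
  msg <- character()
  if (nrow(object@pcs) > 0 && nrow(object@pcs) != nrow(object@features))
    msg <- c(msg, "pcs rows must align 1:1 with feature rows")
  if (length(object@explainedVar) > 1 &&
      any(diff(object@explainedVar) > 1e-8))
    msg <- c(msg, "explained-variance ratios must be non-increasing")
  if (length(msg)) msg else TRUE
})

#' GaussianHMM: parameters of a K-state Gaussian hidden Markov model
#'
#' @slot K number of hidden states.
#' @slot pi initial state probabilities.
#' @slot A K x K transition matrix (rows sum to 1).
#' @slot mu K x D matrix of emission means.
#' @slot Sigma D x D x K array of emission covariances.
#' @slot meta list of fitting metadata (seed, schedule, feature schema hash).
#' @exportClass GaussianHMM
setClass("GaussianHMM",
  representation(
    K = "integer", pi = "numeric", A = "matrix", mu = "matrix",
    Sigma = "array", meta = "list"
  )
)

setValidity("GaussianHMM", function(object) {
  msg <- character()
  K <- object@K
  if (length(object@pi) != K) msg <- c(msg, "pi length != K")
  if (abs(sum(object@pi) - 1) > 1e-8) msg <- c(msg, "pi must sum to 1")
  if (!identical(dim(object@A), c(K, K))) msg <- c(msg, "A must be K x K")
  else if (any(abs(rowSums(object@A) - 1) > 1e-8))
    msg <- c(msg, "rows of A must sum to 1")
  if (nrow(object@mu) != K) msg <- c(msg, "mu must have K rows")
  D <- ncol(object@mu)
  if (!identical(dim(object@Sigma), c(D, D, K)))
    msg <- c(msg, "Sigma must be D x D x K")
  else {
    for (k in seq_len(K)) {
      S <- object@Sigma[, , k, drop = TRUE]
      S <- matrix(S, D, D)
      if (max(abs(S - t(S))) > 1e-6) {
        msg <- c(msg, sprintf("Sigma[,,%d] not symmetric", k)); break
      }
      ev <- tryCatch(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values),
                     error = function(e) -Inf)
      if (ev <= 0) { msg <- c(msg, sprintf("Sigma[,,%d] not positive definite", k)); break }
    }
  }
  if (length(msg)) msg else TRUE
})

#' UsageTensor: syllable x time-of-day-bin x animal-day usage counts
#'
#' @slot counts integer array N x T x K of syllable frame counts per bin.
#' @slot normalized numeric array of per-syllable min-max scaled usage, or a
#'   zero-length array before normalization.
#' @slot sylRange N x 2 matrix of the (min, max) used in normalization.
#' @slot animalDay data.frame with one row per slice: animal id, age (days).
#' @slot framesPerBin nominal frames recorded per bin.
#' @exportClass UsageTensor
setClass("UsageTensor",
  representation(
    counts = "array", normalized = "array", sylRange = "matrix",
    animalDay = "data.frame", framesPerBin = "numeric"
  )
)

setValidity("UsageTensor", function(object) {
  msg <- character()
  d <- dim(object@counts)
  if (length(d) != 3L) msg <- c(msg, "counts must be a 3-way array")
  if (any(object@counts < 0)) msg <- c(msg, "counts must be non-negative")
  if (length(dim(object@normalized)) == 3L) {
    if (!identical(dim(object@normalized), d))
      msg <- c(msg, "normalized shape mismatch")
    else if (min(object@normalized) < -1e-12 || max(object@normalized) > 1 + 1e-12)
      msg <- c(msg, "normalized values must lie in [0, 1]")
  }
  if (!is.null(d) && nrow(object@animalDay) != d[3])
    msg <- c(msg, "animalDay must have one row per slice")
  if (length(msg)) msg else TRUE
})

#' CPModel: non-negative canonical polyadic decomposition of a usage tensor
#'
#' Reconstruction is the sum over components of
#' outer(syllable_r, time_r, age_r); time and syllable factor columns have
#' unit Euclidean norm with all magnitude absorbed into the age factors, and
#' components are ordered by reconstruction contribution.
#'
#' @slot rank number of components.
#' @slot syllable N x R non-negative syllable factors.
#' @slot time T x R non-negative time-of-day factors.
#' @slot age K x R non-negative age factors (per animal-day amplitudes).
#' @slot trainError normalized reconstruction error on the fitted entries.
#' @slot converged logical convergence flag.
#' @slot meta list (seed, restarts, iterations).
#' @exportClass CPModel
setClass("CPModel",
  representation(
    rank = "integer", syllable = "matrix", time = "matrix", age = "matrix",
    trainError = "numeric", converged = "logical", meta = "list"
  )
)

setValidity("CPModel", function(object) {
  msg <- character()
  R <- object@rank
  if (ncol(object@syllable) != R || ncol(object@time) != R ||
      ncol(object@age) != R)
    msg <- c(msg, "all factor matrices must have `rank` columns")
  if (min(object@syllable) < 0 || min(object@time) < 0 || min(object@age) < 0)
    msg <- c(msg, "factors must be non-negative")
  if (length(msg)) msg else TRUE
})

#' StageModel: life-stage Gaussian HMM over daily age factors
#'
#' @slot hmm fitted GaussianHMM over smoothed, z-scored age factors; states
#'   are relabeled so stage ids increase with the mean age of member days.
#' @slot labels list of per-animal integer stage sequences (0-based ids).
#' @slot animals character vector of animal ids, parallel to `labels`.
#' @slot meta list (seed, K grid diagnostics, smoothing sigma).
#' @exportClass StageModel
setClass("StageModel",
  representation(
    hmm = "GaussianHMM", labels = "list", animals = "character", meta = "list"
  )
)

setValidity("StageModel", function(object) {
  msg <- character()
  if (length(object@labels) != length(object@animals))
    msg <- c(msg, "labels and animals must be parallel")
  K <- object@hmm@K
  bad <- vapply(object@labels, function(l) any(l < 0 | l >= K), logical(1))
  if (any(bad)) msg <- c(msg, "stage labels must lie in [0, K)")
  if (length(msg)) msg else TRUE
})

# ---- show methods -----------------------------------------------------------

setMethod("show", "KeypointTrack", function(object) {
  cat("KeypointTrack:", length(object@frame), "frames at",
      object@fps, "fps;", "tank", paste(object@tankSize, collapse = " x "),
      "px\n")
  vis <- if (length(object@frame)) round(100 * colMeans(object@visible)) else rep(NA, 6)
  cat("  visibility (%):", paste(sprintf("%s=%s", KEYPOINTS, vis), collapse = ", "),
      "\n")
})

setMethod("show", "PoseFeatures", function(object) {
  cat("PoseFeatures:", nrow(object@features), "frames x",
      ncol(object@features), "features;", ncol(object@pcs), "PCs")
  if (length(object@explainedVar))
    cat(sprintf(" (%.1f%% variance)", 100 * sum(object@explainedVar)))
  cat("\n")
})

setMethod("show", "GaussianHMM", function(object) {
  cat("GaussianHMM:", object@K, "states,", ncol(object@mu),
      "dimensional Gaussian emissions\n")
})

setMethod("show", "UsageTensor", function(object) {
  d <- dim(object@counts)
  cat("UsageTensor:", d[1], "syllables x", d[2], "bins x", d[3],
      "animal-days;", object@framesPerBin, "frames/bin",
      if (length(dim(object@normalized)) == 3L) "(normalized)" else "", "\n")
})

setMethod("show", "CPModel", function(object) {
  cat("CPModel: rank", object@rank,
      sprintf("; train error %.4f", object@trainError),
      if (!object@converged) "(not converged)" else "", "\n")
})

setMethod("show", "StageModel", function(object) {
  cat("StageModel:", object@hmm@K, "stages over", length(object@animals),
      "animals\n")
})
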