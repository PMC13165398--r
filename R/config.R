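# Configuration constructors. Plain validated lists: configs are arguments,
# not data, so they stay lightweight.

#' Simulation configuration
#'
#' World constants for the synthetic generators. Defaults mirror the
#' recording design: 20 frames per second, a 12 h light / 12 h dark cycle,
#' and 144 ten-minute time-of-day bins per day.
#'
#' @param fps frames per second (> 0).
#' @param tankSize (width, height) of the tank in pixels.
#' @param jitterSd keypoint localization noise, pixels (isotropic Gaussian).
#' @param lightHours hours of light per day.
#' @param nBinsPerDay number of equal time-of-day bins spanning 24 h.
#' @param nSyllables syllable alphabet size.
#' @param seed RNG seed; identical seed and config give identical output.
#' @return a list of class `SimConfig`.
#' @export
simConfig <- function(fps = 20, tankSize = c(400, 250), jitterSd = 0.5,
                      lightHours = 12, nBinsPerDay = 144L, nSyllables = 100L,
                      seed = 1L) {
  stopifnot(fps > 0, length(tankSize) == 2L, all(tankSize > 0),
            jitterSd >= 0, lightHours > 0, lightHours < 24,
            nBinsPerDay >= 1L, 86400 %% round(86400 / nBinsPerDay) == 0,
            nSyllables >= 1L)
  structure(list(
    fps = fps, tankSize = as.numeric(tankSize), jitterSd = jitterSd,
    lightHours = lightHours, nBinsPerDay = as.integer(nBinsPerDay),
    nSyllables = as.integer(nSyllables), seed = as.integer(seed)
  ), class = "SimConfig")
}

#' Pose feature configuration
#'
#' @param rollingWindow frames for rolling mean/sd feature statistics.
#' @param dispersionWindow frames for the trailing dispersion window
#'   (default 40 frames = 2 s at 20 fps).
#' @param sleepDispersionThreshold dispersion area below which a frame is
#'   inactive (same units as the computed circle area).
#' @param sleepMinDuration minimum inactive-run duration, seconds, for the
#'   run to be labeled sleep.
#' @param filterB numerator coefficients of the causal FIR jitter filter
#'   applied to coordinates before differentiating.
#' @param smoothWindow frames of moving-average smoothing applied to PC
#'   scores.
#' @param nPcs retained principal components.
#' @return a list of class `PoseConfig`.
#' @export
poseConfig <- function(rollingWindow = 10L, dispersionWindow = 40L,
                       sleepDispersionThreshold = 50,
                       sleepMinDuration = 60,
                       filterB = rep(0.2, 5), smoothWindow = 10L,
                       nPcs = 15L) {
  stopifnot(rollingWindow >= 1L, dispersionWindow >= 1L,
            sleepDispersionThreshold > 0, sleepMinDuration > 0,
            length(filterB) >= 1, abs(sum(filterB) - 1) < 1e-8,
            nPcs >= 1L)
  structure(list(
    rollingWindow = as.integer(rollingWindow),
    dispersionWindow = as.integer(dispersionWindow),
    sleepDispersionThreshold = sleepDispersionThreshold,
    sleepMinDuration = sleepMinDuration,
    filterB = filterB, smoothWindow = as.integer(smoothWindow),
    nPcs = as.integer(nPcs)
  ), class = "PoseConfig")
}

#' Stochastic EM schedule
#'
#' Robbins-Monro step sizes for batch-wise sufficient-statistic blending.
#' The first step is forced to 1 so the first update adopts the first
#' batch's optimal statistics; later steps follow `(t + 2)^(-decay)`, which
#' satisfies the Robbins-Monro conditions for `decay` in (0.5, 1].
#'
#' @param batchSize frames per contiguous batch.
#' @param maxEpochs passes over the batched data.
#' @param decay step-size decay exponent.
#' @param seed seed controlling the batch shuffle and initialization.
#' @return a list of class `EMSchedule`.
#' @export
emSchedule <- function(batchSize = 5000L, maxEpochs = 5L, decay = 0.6,
                       seed = 1L) {
  stopifnot(batchSize >= 1L, maxEpochs >= 1L, decay > 0.5, decay <= 1)
  structure(list(
    batchSize = as.integer(batchSize), maxEpochs = as.integer(maxEpochs),
    decay = decay, seed = as.integer(seed),
    rho = function(t) if (t <= 1) 1 else (t + 2)^(-decay)
  ), class = "EMSchedule")
}
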