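# Synthetic ground-truth generators: short keypoint tracks for the pose /
# syllable layers, and lifelong daily usage tensors for the tensor, clock,
# and life-stage layers. Everything is seeded and deterministic.

#' Evaluate an expression under a temporary RNG seed
#' @keywords internal
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# kinematic rules per behavioral mode: speed in px/frame, heading turn SD in
# rad/frame. Modes mirror the canonical swim repertoire: rest/sleep, slow
# drift, steady cruise, fast burst, backward reversal, wall-following.
MODE_DEFAULTS <- list(
  rest       = list(speed = 0,   turnSd = 0),
  drift      = list(speed = 0.5, turnSd = 0.2),
  cruise     = list(speed = 5,   turnSd = 0),
  burst      = list(speed = 15,  turnSd = 0.1),
  reversal   = list(speed = 3,   turnSd = 0),
  glass_surf = list(speed = 4,   turnSd = 0)
)

# straight-body segment lengths (px): snout-midbody, midbody-endbody,
# endbody-tail, tail-fan
BODY_SEGMENTS <- c(10, 8, 6, 4)

#' Construct a behavior program
#'
#' A behavior program is an ordered list of (mode, duration, parameters)
#' segments describing the scripted kinematics of one simulated swim bout.
#'
#' @param ... segments created by [programSegment()].
#' @return a list of class `BehaviorProgram`.
#' @examples
#' prog <- behaviorProgram(
#'   programSegment("rest", 30),
#'   programSegment("cruise", 10, speed = 5)
#' )
#' @export
behaviorProgram <- function(...) {
  segments <- list(...)
  stopifnot(length(segments) >= 1)
  for (s in segments) {
    if (!is.list(s) || is.null(s$mode) || is.null(s$duration))
      stop("each segment needs a mode and a duration; use programSegment()")
    if (s$duration <= 0) stop("segment durations must be positive")
    if (!s$mode %in% names(MODE_DEFAULTS))
      stop("unknown behavior mode: ", s$mode)
  }
  structure(list(segments = segments), class = "BehaviorProgram")
}

#' @rdname behaviorProgram
#' @param mode one of "rest", "drift", "cruise", "burst", "reversal",
#'   "glass_surf".
#' @param duration segment duration in seconds.
#' @param speed displacement per frame in pixels (mode default if NULL).
#' @param turnSd per-frame heading random-walk SD in radians.
#' @export
programSegment <- function(mode, duration, speed = NULL, turnSd = NULL) {
  list(mode = mode, duration = duration, speed = speed, turnSd = turnSd)
}

#' Simulate a 6-keypoint track from a behavior program
#'
#' Plays the program's kinematic script at `config$fps`, laying the body
#' keypoints along a straight body of fixed segment lengths behind the snout
#' (oriented by heading), then adds i.i.d. isotropic Gaussian localization
#' jitter. The sidebody keypoint is rarely visible, exercising missing-data
#' paths downstream. Reversal segments move the animal anti-parallel to its
#' heading; glass-surf segments clamp motion to the nearest tank wall.
#'
#' @param program a [behaviorProgram()].
#' @param config a [simConfig()].
#' @return a [KeypointTrack-class] object.
#' @export
simulateTrack <- function(program, config = simConfig()) {
  stopifnot(inherits(program, "BehaviorProgram"), inherits(config, "SimConfig"))
  total <- sum(vapply(program$segments, `[[`, numeric(1), "duration"))
  if (total > 86400) stop("program durations must total at most 24 h")
  withSeed(config$seed, {
    fps <- config$fps
    tank <- config$tankSize
    bodyLen <- sum(BODY_SEGMENTS)
    margin <- bodyLen + 2
    # initial pose: center of tank, heading +x
    pos <- tank / 2
    ang <- 0
    snout <- list()
    headings <- list()
    modes <- character(0)
    for (seg in program$segments) {
      p <- MODE_DEFAULTS[[seg$mode]]
      speed <- if (is.null(seg$speed)) p$speed else seg$speed
      turnSd <- if (is.null(seg$turnSd)) p$turnSd else seg$turnSd
      nf <- round(seg$duration * fps)
      if (seg$mode == "glass_surf") {
        # snap to nearest wall and travel along it
        dWall <- c(pos[1], tank[1] - pos[1], pos[2], tank[2] - pos[2])
        wall <- which.min(dWall)
        if (wall == 1L) { pos[1] <- margin; ang <- pi / 2 }
        if (wall == 2L) { pos[1] <- tank[1] - margin; ang <- -pi / 2 }
        if (wall == 3L) { pos[2] <- margin; ang <- 0 }
        if (wall == 4L) { pos[2] <- tank[2] - margin; ang <- pi }
      }
      for (i in seq_len(nf)) {
        if (turnSd > 0) ang <- ang + stats::rnorm(1, 0, turnSd)
        h <- c(cos(ang), sin(ang))
        step <- if (seg$mode == "reversal") -speed * h else speed * h
        cand <- pos + step
        # reflect at walls, keeping the whole body inside the tank
        for (d in 1:2) {
          if (cand[d] < margin) { cand[d] <- 2 * margin - cand[d]; ang <- if (d == 1) pi - ang else -ang }
          if (cand[d] > tank[d] - margin) { cand[d] <- 2 * (tank[d] - margin) - cand[d]; ang <- if (d == 1) pi - ang else -ang }
        }
        pos <- cand
        h <- c(cos(ang), sin(ang))
        snout[[length(snout) + 1L]] <- pos
        headings[[length(headings) + 1L]] <- h
        modes <- c(modes, seg$mode)
      }
    }
    n <- length(snout)
    sn <- do.call(rbind, snout)
    hd <- do.call(rbind, headings)
    d <- cumsum(BODY_SEGMENTS)
    coords <- matrix(NA_real_, n, 12)
    colnames(coords) <- as.vector(rbind(paste0("x_", KEYPOINTS),
                                        paste0("y_", KEYPOINTS)))
    put <- function(name, xy) {
      coords[, paste0("x_", name)] <<- xy[, 1]
      coords[, paste0("y_", name)] <<- xy[, 2]
    }
    put("snout", sn)
    put("midbody", sn - d[1] * hd)
    put("endbody", sn - d[2] * hd)
    put("tail", sn - d[3] * hd)
    put("fan", sn - d[4] * hd)
    # sidebody sits beside the midbody, offset to the animal's left
    perp <- cbind(-hd[, 2], hd[, 1])
    put("sidebody", sn - d[1] * hd + 3 * perp)
    if (config$jitterSd > 0)
      coords <- coords + matrix(stats::rnorm(length(coords), 0, config$jitterSd),
                                n, ncol(coords))
    visible <- matrix(TRUE, n, length(KEYPOINTS),
                      dimnames = list(NULL, KEYPOINTS))
    visible[, "sidebody"] <- stats::runif(n) < 0.05
    coords[, "x_sidebody"][!visible[, "sidebody"]] <- NA_real_
    coords[, "y_sidebody"][!visible[, "sidebody"]] <- NA_real_
    methods::new("KeypointTrack",
      frame = seq_len(n) - 1L,
      timestamp = (seq_len(n) - 1) / fps,
      coords = coords, visible = visible,
      tankSize = tank, fps = fps,
      meta = list(modes = modes, seed = config$seed,
                  jitterSd = config$jitterSd, spawn = tank / 2)
    )
  })
}

#' Cohort truth specification
#'
#' Parameters of the stated synthetic world: a bimodal lifespan mixture
#' (two Gaussians truncated at 30 days), forward-only life stages with
#' shifted-geometric dwell times, and per-stage circadian usage templates
#' with seven feeding-time activity peaks during the light phase. Long- and
#' short-lived groups differ in day-time inactivity and in the weight of
#' peak-activity syllables.
#'
#' @param nStages number of forward-progressing life stages.
#' @param longMean,shortMean,lifespanSd means and shared SD (days) of the
#'   long-lived / short-lived lifespan mixture components.
#' @param probLong mixing weight of the long-lived component.
#' @param minLifespan truncation lower bound, days.
#' @param dwellMeans per-stage mean dwell in days (last stage absorbs).
#' @param separation multiplier on between-stage template differences;
#'   1 is the default world, larger values separate stages more.
#' @return a list of class `CohortSpec`.
#' @export
cohortSpec <- function(nStages = 3L, longMean = 250, shortMean = 150,
                       lifespanSd = 30, probLong = 0.5, minLifespan = 30,
                       dwellMeans = NULL, separation = 1) {
  if (is.null(dwellMeans)) dwellMeans <- rep(60, nStages)
  stopifnot(nStages >= 1L, length(dwellMeans) == nStages,
            all(dwellMeans > 0), probLong >= 0, probLong <= 1,
            separation > 0)
  structure(list(
    nStages = as.integer(nStages), longMean = longMean,
    shortMean = shortMean, lifespanSd = lifespanSd, probLong = probLong,
    minLifespan = minLifespan, dwellMeans = dwellMeans,
    separation = separation
  ), class = "CohortSpec")
}

#' Build per-stage, per-group syllable x bin count templates
#'
#' Templates are integer count matrices: each time-of-day bin's counts sum
#' exactly to the frames recorded per bin, so the noise-free limit of the
#' generator reproduces them verbatim.
#' @keywords internal
buildStageTemplates <- function(spec, config) {
  N <- config$nSyllables
  T_ <- config$nBinsPerDay
  framesPerBin <- config$fps * 86400 / T_
  lightBins <- round(T_ * config$lightHours / 24)
  # syllable classes: rest block, locomotion block, burst/feeding block
  nRest <- max(1L, round(0.3 * N))
  nLoco <- max(1L, round(0.4 * N))
  nBurst <- N - nRest - nLoco
  restIdx <- seq_len(nRest)
  locoIdx <- nRest + seq_len(nLoco)
  burstIdx <- nRest + nLoco + seq_len(nBurst)
  # seven feeding peaks at fixed bins inside the light phase
  feedBins <- round(seq(lightBins * 0.12, lightBins * 0.88, length.out = 7))
  feedBump <- rep(0, T_)
  for (b in feedBins)
    feedBump <- feedBump + exp(-((seq_len(T_) - b)^2) / (2 * 1.5^2))
  isLight <- seq_len(T_) <= lightBins
  templates <- list(long = vector("list", spec$nStages),
                    short = vector("list", spec$nStages))
  for (g in c("long", "short")) {
    # short-lived animals are more inactive in the light phase and put less
    # weight on peak-activity syllables
    dayRest <- if (g == "short") 0.45 else 0.25
    peakW <- if (g == "short") 0.6 else 1.0
    for (s in seq_len(spec$nStages)) {
      # activity declines with stage; each stage prefers a rotated subset of
      # syllables within each class so stage templates are distinguishable
      act <- max(0.15, 1 - spec$separation * 0.35 * (s - 1))
      pref <- function(idx, shift) {
        w <- rep(1, length(idx))
        sel <- ((seq_along(idx) + shift * ceiling(length(idx) / spec$nStages)) %%
                  length(idx)) < ceiling(length(idx) / 3)
        w[sel] <- 1 + 5 * spec$separation
        w / sum(w)
      }
      wRest <- pref(restIdx, s - 1)
      wLoco <- pref(locoIdx, s - 1)
      wBurst <- pref(burstIdx, s - 1)
      tmpl <- matrix(0, N, T_)
      for (t in seq_len(T_)) {
        restMass <- if (isLight[t]) dayRest + (1 - act) * 0.4 else 0.85
        feedMass <- if (isLight[t]) peakW * act * 0.25 * feedBump[t] else 0
        locoMass <- max(0, 1 - restMass) * act
        burstMass <- max(0, 1 - restMass) * (1 - act) * 0.3 + feedMass
        p <- numeric(N)
        p[restIdx] <- restMass * wRest
        p[locoIdx] <- locoMass * wLoco
        p[burstIdx] <- burstMass * wBurst
        p <- p / sum(p)
        # largest-remainder rounding to integer counts summing to framesPerBin
        raw <- p * framesPerBin
        cnt <- floor(raw)
        short <- framesPerBin - sum(cnt)
        if (short > 0) {
          ord <- order(raw - cnt, decreasing = TRUE)
          cnt[ord[seq_len(short)]] <- cnt[ord[seq_len(short)]] + 1
        }
        tmpl[, t] <- cnt
      }
      templates[[g]][[s]] <- tmpl
    }
  }
  templates
}

#' Simulate a lifelong syllable-usage cohort with ground truth
#'
#' For each animal a lifespan is drawn from the long/short Gaussian mixture
#' (truncated at the minimum lifespan), days are assigned to forward-only
#' life stages with shifted-geometric dwell times, and each 10-minute bin's
#' syllable counts are drawn multinomially from the animal's current stage
#' template, so every bin's counts sum exactly to the frames recorded per
#' bin (12,000 at 20 fps).
#'
#' @param nAnimals number of animals (>= 2).
#' @param spec a [cohortSpec()]; also accepts a list with a `templates`
#'   element (per-group lists of syllable x bin count matrices) to impose
#'   explicit stage templates.
#' @param config a [simConfig()].
#' @param noise "multinomial" (default) or "none" (counts equal the template
#'   exactly; the zero-noise limit).
#' @param maxDaysPerAnimal optional cap on recorded days per animal (animals
#'   surviving past the cap are right-censored in the recording, but their
#'   true lifespan is still returned in the truth object).
#' @return a list with elements `tensor` (a [UsageTensor-class]) and `truth`
#'   (class `CohortTruth`: lifespans, group labels, per-day stage sequences,
#'   change-point days, templates, recordedDays).
#' @export
simulateSyllableCohort <- function(nAnimals, spec = cohortSpec(),
                                   config = simConfig(),
                                   noise = c("multinomial", "none"),
                                   maxDaysPerAnimal = Inf) {
  noise <- match.arg(noise)
  stopifnot(nAnimals >= 2, inherits(config, "SimConfig"))
  N <- config$nSyllables
  T_ <- config$nBinsPerDay
  framesPerBin <- config$fps * 86400 / T_
  withSeed(config$seed, {
    if (!is.null(spec$templates)) {
      templates <- spec$templates
    } else {
      templates <- buildStageTemplates(spec, config)
    }
    nStages <- length(templates[[1]])
    for (g in names(templates)) for (s in seq_along(templates[[g]])) {
      tm <- templates[[g]][[s]]
      if (any(tm < 0)) stop("templates with negative entries rejected")
      if (nrow(tm) != N)
        stop("template syllable count (", nrow(tm),
             ") does not match config nSyllables (", N, ")")
      if (ncol(tm) != T_) stop("template bin count mismatch")
    }
    # lifespans from the truncated two-component mixture
    isLong <- stats::runif(nAnimals) < spec$probLong
    lifespans <- numeric(nAnimals)
    for (i in seq_len(nAnimals)) {
      m <- if (isLong[i]) spec$longMean else spec$shortMean
      repeat {
        l <- stats::rnorm(1, m, spec$lifespanSd)
        if (l >= spec$minLifespan) break
      }
      lifespans[i] <- round(l)
    }
    group <- ifelse(isLong, "long", "short")
    animals <- sprintf("fish%03d", seq_len(nAnimals))
    stageSeq <- vector("list", nAnimals)
    changePoints <- vector("list", nAnimals)
    recordedDays <- pmin(lifespans, maxDaysPerAnimal)
    for (i in seq_len(nAnimals)) {
      L <- lifespans[i]
      seqi <- integer(0)
      s <- 1L
      while (length(seqi) < L && s < nStages) {
        dwell <- 1L + stats::rgeom(1, 1 / spec$dwellMeans[s])
        dwell <- min(dwell, L - length(seqi))
        seqi <- c(seqi, rep(s, dwell))
        s <- s + 1L
      }
      if (length(seqi) < L) seqi <- c(seqi, rep(s, L - length(seqi)))
      seqi <- seqi[seq_len(min(L, recordedDays[i]))]
      stageSeq[[i]] <- seqi
      changePoints[[i]] <- which(diff(seqi) != 0) + 1L
    }
    totalDays <- sum(recordedDays)
    counts <- array(0L, dim = c(N, T_, totalDays))
    animalDay <- data.frame(
      animal = rep(animals, recordedDays),
      age = unlist(lapply(recordedDays, seq_len)),
      stringsAsFactors = FALSE
    )
    sliceStage <- unlist(stageSeq)
    sliceGroup <- rep(group, recordedDays)
    # draw all same-template slices of a bin at once for speed
    for (g in c("long", "short")) for (s in seq_len(nStages)) {
      sel <- which(sliceGroup == g & sliceStage == s)
      if (!length(sel)) next
      tmpl <- templates[[g]][[s]]
      if (noise == "none") {
        for (k in sel) counts[, , k] <- as.integer(tmpl)
      } else {
        for (t in seq_len(T_)) {
          p <- tmpl[, t] / sum(tmpl[, t])
          counts[, t, sel] <- stats::rmultinom(length(sel), framesPerBin, p)
        }
      }
    }
    tensor <- methods::new("UsageTensor",
      counts = counts, normalized = array(numeric(0)),
      sylRange = matrix(numeric(0), 0, 2), animalDay = animalDay,
      framesPerBin = framesPerBin
    )
    truth <- structure(list(
      animals = animals, lifespans = lifespans, group = group,
      stageSequence = stats::setNames(stageSeq, animals),
      changePoints = stats::setNames(changePoints, animals),
      templates = templates, recordedDays = recordedDays,
      seed = config$seed
    ), class = "CohortTruth")
    list(tensor = tensor, truth = truth)
  })
}

#' Sample observations and latent states from a Gaussian HMM
#'
#' Exact ancestral sampling from the generative model; returns both the
#' emissions and the latent state path so estimators can be scored against
#' truth.
#'
#' @param hmm a [GaussianHMM-class] object.
#' @param nFrames number of frames to sample.
#' @param seed RNG seed.
#' @return list with `observations` (nFrames x D matrix) and `states`
#'   (0-based integer vector).
#' @export
simulateHmmData <- function(hmm, nFrames, seed = 1L) {
  stopifnot(is(hmm, "GaussianHMM"), nFrames >= 1)
  methods::validObject(hmm)
  if (any(abs(rowSums(hmm@A) - 1) > 1e-8))
    stop("non-stochastic transition rows rejected")
  K <- hmm@K
  D <- ncol(hmm@mu)
  withSeed(seed, {
    chols <- lapply(seq_len(K), function(k) chol(matrix(hmm@Sigma[, , k], D, D)))
    states <- integer(nFrames)
    states[1] <- sample.int(K, 1, prob = hmm@pi)
    if (nFrames > 1) {
      for (t in 2:nFrames)
        states[t] <- sample.int(K, 1, prob = hmm@A[states[t - 1], ])
    }
    z <- matrix(stats::rnorm(nFrames * D), nFrames, D)
    obs <- matrix(0, nFrames, D)
    for (k in seq_len(K)) {
      sel <- states == k
      if (any(sel))
        obs[sel, ] <- sweep(z[sel, , drop = FALSE] %*% chols[[k]], 2,
                            hmm@mu[k, ], "+")
    }
    list(observations = obs, states = states - 1L)
  })
}
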