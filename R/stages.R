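# Life-stage analyses: daily light/dark usage vectors, symmetrized
# Kullback-Leibler divergences (discrete and Gaussian closed form),
# day-by-day divergence matrices, Gaussian-kernel penalized change-point
# detection, the forward-progressing life-stage HMM, and its summaries.

#' Daily light/dark syllable usage vector
#'
#' Sums the frames spent in each syllable during the light period and during
#' the dark period of one day, producing a 2N-element vector (200 entries
#' for the default 100-syllable alphabet): light-period counts first, then
#' dark-period counts.
#'
#' @param syllables per-frame 0-based syllable ids for one day, in frame
#'   order starting at lights-on.
#' @param nSyllables alphabet size N.
#' @param fps frames per second.
#' @param lightHours hours of light at the start of the day.
#' @return list with `counts` (length 2N) and `distribution` (counts
#'   normalized to sum to 1).
#' @export
dailyUsage <- function(syllables, nSyllables = 100L, fps = 20,
                       lightHours = 12) {
  nDay <- fps * 86400
  if (length(syllables) > nDay)
    stop("sequence longer than one day of frames rejected")
  if (any(syllables < 0 | syllables >= nSyllables, na.rm = TRUE))
    stop("syllable ids must be in [0, nSyllables)")
  nLight <- round(fps * lightHours * 3600)
  isLight <- seq_along(syllables) <= nLight
  cnt <- function(s) as.integer(table(factor(s + 1L,
                                             levels = seq_len(nSyllables))))
  counts <- c(cnt(syllables[isLight & !is.na(syllables)]),
              cnt(syllables[!isLight & !is.na(syllables)]))
  names(counts) <- c(paste0("light_s", seq_len(nSyllables) - 1L),
                     paste0("dark_s", seq_len(nSyllables) - 1L))
  list(counts = counts, distribution = counts / sum(counts))
}

#' Daily light/dark usage vectors from a usage tensor
#'
#' Collapses the time-of-day bins of each animal-day slice into the light
#' and dark photoperiods (day starts at lights-on), giving one 2N-element
#' count vector per slice.
#'
#' @param tensor a [UsageTensor-class].
#' @param lightHours hours of light at the start of the day.
#' @return slices x 2N matrix of counts (same slice order as
#'   [animalDays()]).
#' @export
dailyUsageFromTensor <- function(tensor, lightHours = 12) {
  x <- usageCounts(tensor)
  d <- dim(x)
  lightBins <- round(d[2] * lightHours / 24)
  light <- apply(x[, seq_len(lightBins), , drop = FALSE], c(1, 3), sum)
  dark <- apply(x[, setdiff(seq_len(d[2]), seq_len(lightBins)), ,
                  drop = FALSE], c(1, 3), sum)
  out <- t(rbind(light, dark))
  colnames(out) <- c(paste0("light_s", seq_len(d[1]) - 1L),
                     paste0("dark_s", seq_len(d[1]) - 1L))
  out
}

#' Symmetrized Kullback-Leibler divergence of two discrete distributions
#'
#' Adds the pseudocount to every entry, renormalizes, and returns
#' 0.5 KL(p||q) + 0.5 KL(q||p) in nats. Symmetric, non-negative, and zero
#' iff the smoothed distributions coincide.
#'
#' @param p,q non-negative vectors of equal length (counts or
#'   probabilities).
#' @param pseudocount value added to every entry before normalization
#'   (default 1 count; keeps the divergence finite when one day never uses
#'   a syllable the other day uses).
#' @return divergence in nats.
#' @export
symmetrizedDkl <- function(p, q, pseudocount = 1) {
  stopifnot(length(p) == length(q), all(p >= 0), all(q >= 0))
  if (sum(p) == 0 || sum(q) == 0) stop("all-zero vector rejected")
  p <- p + pseudocount
  q <- q + pseudocount
  p <- p / sum(p)
  q <- q / sum(q)
  sup <- p > 0 | q > 0
  kl <- function(a, b) {
    s <- a > 0
    sum(a[s] * log(a[s] / b[s]))
  }
  0.5 * kl(p[sup], q[sup]) + 0.5 * kl(q[sup], p[sup])
}

#' Symmetrized KL divergence of two multivariate Gaussians (closed form)
#'
#' KL(N1||N2) = 0.5 [tr(S2^-1 S1) + (m2-m1)' S2^-1 (m2-m1) - d +
#' ln(det S2 / det S1)], symmetrized as the average of the two directions.
#'
#' @param mu1,mu2 mean vectors.
#' @param Sigma1,Sigma2 positive-definite covariance matrices.
#' @return divergence in nats.
#' @export
symmetrizedDklGaussian <- function(mu1, Sigma1, mu2, Sigma2) {
  d <- length(mu1)
  Sigma1 <- as.matrix(Sigma1); Sigma2 <- as.matrix(Sigma2)
  ch1 <- tryCatch(chol(Sigma1), error = function(e) NULL)
  ch2 <- tryCatch(chol(Sigma2), error = function(e) NULL)
  if (is.null(ch1) || is.null(ch2))
    stop("non-positive-definite covariance rejected")
  logdet <- function(ch) 2 * sum(log(diag(ch)))
  dm <- mu2 - mu1
  ld1 <- logdet(ch1); ld2 <- logdet(ch2)
  inv1 <- chol2inv(ch1); inv2 <- chol2inv(ch2)
  kl12 <- 0.5 * (sum(inv2 * Sigma1) + drop(t(dm) %*% inv2 %*% dm) - d +
                   ld2 - ld1)
  kl21 <- 0.5 * (sum(inv1 * Sigma2) + drop(t(dm) %*% inv1 %*% dm) - d +
                   ld1 - ld2)
  0.5 * (kl12 + kl21)
}

#' Day-by-day divergence matrix for one animal
#'
#' Pairwise symmetrized divergence between every pair of daily usage
#' distributions, plus the adjacent-day series used for change-point
#' display.
#'
#' @param usage days x P matrix of daily usage counts (e.g. the 200-element
#'   light/dark vectors).
#' @param pseudocount passed to [symmetrizedDkl()].
#' @return list with `matrix` (symmetric, zero diagonal) and
#'   `adjacent` (length days-1 series of consecutive-day divergences).
#' @export
dayMatrix <- function(usage, pseudocount = 1) {
  usage <- as.matrix(usage)
  L <- nrow(usage)
  stopifnot(L >= 2)
  dm <- matrix(0, L, L)
  for (i in seq_len(L - 1)) for (j in (i + 1):L) {
    dm[i, j] <- dm[j, i] <- symmetrizedDkl(usage[i, ], usage[j, ],
                                           pseudocount)
  }
  list(matrix = dm, adjacent = dm[cbind(seq_len(L - 1), 2:L)])
}

#' Gaussian-kernel change-point detection on daily usage
#'
#' Daily usage is smoothed along age (Gaussian, sigma in days), z-scored
#' per dimension, and segmented by exact penalized kernel change-point
#' detection with a Gaussian (RBF) kernel: dynamic programming minimizes
#' the within-segment kernel scatter plus `penaltyScale * ln(L)` per
#' segment, where L is the number of recorded days — so the penalty scales
#' identically with the natural log of lifespan across animals.
#'
#' @param usage days x P matrix of daily usage counts for one animal.
#' @param penaltyScale the constant c multiplying ln(L).
#' @param sigma smoothing SD along days.
#' @param bandwidth RBF bandwidth; NULL uses the median-heuristic.
#' @return list of class `ChangePointSet`: `changePoints` (first day of
#'   each new segment, strictly increasing), `penalty`, `nSegments`,
#'   `segments` (per-segment first/last day and mean usage summary).
#' @export
detectChangePoints <- function(usage, penaltyScale = 1, sigma = 1,
                               bandwidth = NULL) {
  usage <- as.matrix(usage)
  L <- nrow(usage)
  if (L < 3) {
    return(structure(list(changePoints = integer(0),
                          penalty = NA_real_, nSegments = 1L,
                          segments = NULL), class = "ChangePointSet"))
  }
  sm <- apply(usage, 2, gaussSmooth1d, sigma = sigma)
  z <- zscoreCols(sm)
  z[is.na(z)] <- 0
  sq <- rowSums(z^2)
  D2 <- outer(sq, sq, "+") - 2 * tcrossprod(z)
  D2[D2 < 0] <- 0
  if (is.null(bandwidth)) {
    med <- stats::median(D2[upper.tri(D2)])
    bandwidth <- if (is.finite(med) && med > 0) med else 1
  }
  Kg <- exp(-D2 / (2 * bandwidth))
  # segment cost: sum_i K_ii - (1/m) * block-sum(K)  (kernel scatter)
  CS <- apply(apply(Kg, 2, cumsum), 1, cumsum)   # CS[j, i] = sum K[1:i,1:j]
  CS <- t(CS)
  diagCum <- cumsum(diag(Kg))
  blockSum <- function(a, b) {
    CS[b, b] - (if (a > 1) CS[a - 1, b] + CS[b, a - 1] else 0) +
      (if (a > 1) CS[a - 1, a - 1] else 0)
  }
  segCost <- function(a, b) {
    m <- b - a + 1
    (diagCum[b] - (if (a > 1) diagCum[a - 1] else 0)) - blockSum(a, b) / m
  }
  pen <- penaltyScale * log(L)
  F <- c(0, rep(Inf, L))
  prev <- integer(L)
  for (t in seq_len(L)) {
    for (s in 0:(t - 1)) {
      v <- F[s + 1] + segCost(s + 1, t) + pen
      if (v < F[t + 1]) { F[t + 1] <- v; prev[t] <- s }
    }
  }
  bounds <- integer(0)
  t <- L
  while (t > 0) { bounds <- c(prev[t], bounds); t <- prev[t] }
  changePoints <- bounds[bounds > 0] + 1L    # first day of each new segment
  segStarts <- c(1L, changePoints)
  segEnds <- c(changePoints - 1L, L)
  segments <- data.frame(
    start = segStarts, end = segEnds,
    meanUsage = vapply(seq_along(segStarts), function(i)
      mean(usage[segStarts[i]:segEnds[i], ]), numeric(1)))
  structure(list(changePoints = changePoints, penalty = pen,
                 nSegments = length(segStarts), segments = segments),
            class = "ChangePointSet")
}

#' Preprocess age factors for the life-stage model
#'
#' Gaussian-smooths each factor along age within each animal (sigma = 1 day
#' by default), then z-scores globally across all animal-days.
#' @keywords internal
stagePreprocess <- function(series, sigma = 1) {
  ids <- unique(series$animal)
  mats <- lapply(ids, function(a) {
    rows <- which(series$animal == a)
    rows <- rows[order(series$age[rows])]
    m <- series$factors[rows, , drop = FALSE]
    if (sigma > 0 && nrow(m) > 2) m <- apply(m, 2, gaussSmooth1d, sigma = sigma)
    m
  })
  all_ <- do.call(rbind, mats)
  z <- zscoreCols(all_)
  splits <- rep(seq_along(ids), vapply(mats, nrow, integer(1)))
  list(ids = ids,
       mats = lapply(seq_along(ids), function(i)
         z[splits == i, , drop = FALSE]))
}

#' Fit the life-stage hidden Markov model
#'
#' Smooths and z-scores the per-animal daily age factors, then fits a
#' K-state full-covariance Gaussian HMM by multi-sequence EM (k-means
#' initialization, a fixed 20 iterations by default), treating each animal
#' as one observation sequence of days. Days are labeled by posterior mode
#' and stages are renumbered so ids increase with the mean age of their
#' member days ("forward" is well-defined for reporting).
#'
#' @param series an [ageFactorSeries()].
#' @param KStages number of life stages (default 6).
#' @param seed RNG seed (k-means initialization).
#' @param nIter EM iterations.
#' @param sigma smoothing SD along age, days.
#' @return a [StageModel-class].
#' @export
fitStageModel <- function(series, KStages = 6L, seed = 1L, nIter = 20L,
                          sigma = 1) {
  pp <- stagePreprocess(series, sigma)
  keep <- vapply(pp$mats, nrow, integer(1)) >= 2
  if (any(!keep))
    warning("excluding animals with < 2 days: ",
            paste(pp$ids[!keep], collapse = ", "))
  mats <- pp$mats[keep]
  ids <- pp$ids[keep]
  hmm <- fitHmmEMMulti(mats, KStages, nIter = nIter, seed = seed)
  labels0 <- lapply(mats, function(m)
    decodeSyllables(m, hmm, method = "posterior")$labels)
  # order stages by mean age of member days so stage ids progress forward
  ages <- lapply(seq_along(mats), function(i) {
    rows <- which(series$animal == ids[i])
    sort(series$age[rows])
  })
  meanAge <- vapply(0:(KStages - 1), function(s) {
    a <- unlist(lapply(seq_along(labels0), function(i)
      ages[[i]][labels0[[i]] == s]))
    if (length(a)) mean(a) else Inf
  }, numeric(1))
  ord <- order(meanAge)                  # ord[newId] = oldId
  remap <- integer(KStages)
  remap[ord] <- seq_len(KStages)         # remap[oldId] = newId
  labels <- lapply(labels0, function(l) remap[l + 1L] - 1L)
  hmmOrd <- gaussianHMM(hmm@pi[ord], hmm@A[ord, ord, drop = FALSE],
                        hmm@mu[ord, , drop = FALSE],
                        hmm@Sigma[, , ord, drop = FALSE], meta = hmm@meta)
  methods::new("StageModel", hmm = hmmOrd,
               labels = labels, animals = ids,
               meta = list(seed = seed, nIter = nIter, sigma = sigma,
                           KStages = KStages))
}

#' Held-out selection of the number of life stages
#'
#' Fits the stage HMM on training animals for each candidate K and scores
#' held-out animals' per-day log probability; the plateau rule picks the
#' smallest K within `tol` of the maximum.
#'
#' @param series an [ageFactorSeries()].
#' @param Ks candidate stage counts.
#' @param holdoutAnimals animal ids used only for scoring.
#' @param tol plateau tolerance in nats/day; the default 0.1 sits above
#'   the small held-out gains that extra states earn by modeling
#'   smoothing-induced boundary days, and well below the gain of a true
#'   stage.
#' @param ... passed to [fitStageModel()] internals (seed, nIter, sigma).
#' @return list with `table` (K, heldOutLogLik per day) and `selected`.
#' @export
selectNumStages <- function(series, Ks, holdoutAnimals, tol = 0.1,
                            seed = 1L, nIter = 20L, sigma = 1) {
  pp <- stagePreprocess(series, sigma)
  hold <- pp$ids %in% holdoutAnimals
  if (!any(hold) || all(hold)) stop("need non-empty train and holdout sets")
  trainMats <- pp$mats[!hold]
  valMats <- pp$mats[hold]
  nDays <- sum(vapply(valMats, nrow, integer(1)))
  ll <- vapply(Ks, function(K) {
    m <- fitHmmEMMulti(trainMats, K, nIter = nIter, seed = seed)
    sum(vapply(valMats, function(v) forwardBackward(v, m)$logLik,
               numeric(1))) / nDays
  }, numeric(1))
  sel <- Ks[min(which(ll >= max(ll) - tol))]
  list(table = data.frame(K = Ks, heldOutLogLik = ll), selected = sel)
}

#' Summaries of a fitted life-stage model
#'
#' Empirical state-to-state transition matrix (self-transitions included,
#' rows normalized over observed transitions), bout duration distributions
#' in days, per-stage median daily syllable usage profiles from the binned
#' tensor, and the stage emission divergence matrix (Gaussian closed form).
#'
#' @param model a [StageModel-class].
#' @param tensor optional [UsageTensor-class] whose slices match the
#'   model's animal-days; enables the per-stage usage profiles.
#' @return list with `transitionMatrix`, `transitionCounts`,
#'   `boutDurations` (data.frame stage, duration), `medianDuration`,
#'   `usageProfiles` (stage x syllable x bin median array or NULL),
#'   `emissionDivergence` (K x K symmetric matrix).
#' @export
stageSummaries <- function(model, tensor = NULL) {
  K <- model@hmm@K
  counts <- matrix(0, K, K)
  bouts <- list()
  for (l in model@labels) {
    if (length(l) > 1) {
      for (t in seq_len(length(l) - 1))
        counts[l[t] + 1L, l[t + 1L] + 1L] <-
          counts[l[t] + 1L, l[t + 1L] + 1L] + 1
    }
    b <- boutLengths(l)
    bouts[[length(bouts) + 1L]] <- b
  }
  rs <- rowSums(counts)
  trans <- counts / ifelse(rs == 0, NA, rs)
  boutDurations <- do.call(rbind, bouts)
  names(boutDurations) <- c("stage", "duration")
  medianDuration <- stats::aggregate(duration ~ stage, boutDurations,
                                     stats::median)
  usageProfiles <- NULL
  if (!is.null(tensor)) {
    ad <- animalDays(tensor)
    x <- usageCounts(tensor)
    sliceStage <- rep(NA_integer_, nrow(ad))
    for (i in seq_along(model@animals)) {
      a <- model@animals[i]
      rows <- which(ad$animal == a)
      rows <- rows[order(ad$age[rows])]
      n <- min(length(rows), length(model@labels[[i]]))
      sliceStage[rows[seq_len(n)]] <- model@labels[[i]][seq_len(n)]
    }
    d <- dim(x)
    usageProfiles <- array(NA_real_, c(K, d[1], d[2]))
    for (s in 0:(K - 1)) {
      sel <- which(sliceStage == s)
      if (length(sel))
        usageProfiles[s + 1L, , ] <- apply(x[, , sel, drop = FALSE], c(1, 2),
                                           stats::median)
    }
  }
  D <- ncol(model@hmm@mu)
  dv <- matrix(0, K, K)
  for (i in seq_len(K)) for (j in seq_len(K)) {
    if (j <= i) next
    dv[i, j] <- dv[j, i] <- symmetrizedDklGaussian(
      model@hmm@mu[i, ], matrix(model@hmm@Sigma[, , i], D, D),
      model@hmm@mu[j, ], matrix(model@hmm@Sigma[, , j], D, D))
  }
  list(transitionMatrix = trans, transitionCounts = counts,
       boutDurations = boutDurations, medianDuration = medianDuration,
       usageProfiles = usageProfiles, emissionDivergence = dv)
}
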