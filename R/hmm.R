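# Gaussian hidden Markov machinery: scaled forward-backward, full-batch and
# memory-bounded stochastic EM, syllable decoding, state-count selection,
# and emission-divergence clustering of the fitted syllables.

#' Construct a GaussianHMM parameter object
#'
#' @param pi initial state probabilities (length K).
#' @param A K x K transition matrix with stochastic rows.
#' @param mu K x D matrix of emission means.
#' @param Sigma emission covariances: a D x D x K array or a list of K
#'   D x D matrices.
#' @param meta optional list of metadata.
#' @return a validated [GaussianHMM-class].
#' @export
gaussianHMM <- function(pi, A, mu, Sigma, meta = list()) {
  mu <- as.matrix(mu)
  K <- nrow(mu)
  D <- ncol(mu)
  if (is.list(Sigma)) {
    arr <- array(0, c(D, D, K))
    for (k in seq_len(K)) arr[, , k] <- Sigma[[k]]
    Sigma <- arr
  }
  obj <- methods::new("GaussianHMM", K = as.integer(K), pi = as.numeric(pi),
                      A = as.matrix(A), mu = mu, Sigma = Sigma, meta = meta)
  methods::validObject(obj)
  obj
}

#' @keywords internal
emissionLogLik <- function(obs, hmm) {
  K <- hmm@K
  D <- ncol(hmm@mu)
  out <- matrix(0, nrow(obs), K)
  for (k in seq_len(K))
    out[, k] <- mvnLogDensity(obs, hmm@mu[k, ],
                              matrix(hmm@Sigma[, , k], D, D))
  out
}

#' Forward-backward inference for a Gaussian HMM
#'
#' Scaled (per-frame normalized) implementation, so sequences of millions of
#' frames run without underflow. Returns per-frame state posteriors, the
#' summed pairwise transition posteriors, and the data log likelihood.
#'
#' @param observations T x D matrix of emissions.
#' @param hmm a [GaussianHMM-class].
#' @return list with `gamma` (T x K posteriors, rows sum to 1), `xiSum`
#'   (K x K summed pairwise posteriors), `logLik`, and `alpha`/`beta`
#'   scaled messages.
#' @export
forwardBackward <- function(observations, hmm) {
  obs <- as.matrix(observations)
  stopifnot(all(is.finite(obs)))
  if (ncol(obs) != ncol(hmm@mu))
    stop("observation dimension does not match emission dimension")
  Tn <- nrow(obs)
  K <- hmm@K
  logB <- emissionLogLik(obs, hmm)
  # per-frame max-shifted scaling keeps everything in the linear domain
  bmax <- apply(logB, 1, max)
  B <- exp(logB - bmax)
  alpha <- matrix(0, Tn, K)
  cvec <- numeric(Tn)
  a <- hmm@pi * B[1, ]
  cvec[1] <- sum(a)
  alpha[1, ] <- a / cvec[1]
  if (Tn > 1) {
    tA <- t(hmm@A)
    for (t in 2:Tn) {
      a <- drop(tA %*% alpha[t - 1, ]) * B[t, ]
      cvec[t] <- sum(a)
      alpha[t, ] <- a / cvec[t]
    }
  }
  beta <- matrix(0, Tn, K)
  beta[Tn, ] <- 1
  xiSum <- matrix(0, K, K)
  if (Tn > 1) {
    for (t in (Tn - 1):1) {
      bb <- B[t + 1, ] * beta[t + 1, ]
      xi <- hmm@A * outer(alpha[t, ], bb)
      xiSum <- xiSum + xi / sum(xi)
      beta[t, ] <- drop(hmm@A %*% bb) / cvec[t + 1]
    }
  }
  gamma <- alpha * beta
  gamma <- gamma / rowSums(gamma)
  list(gamma = gamma, xiSum = xiSum,
       logLik = sum(log(cvec)) + sum(bmax),
       alpha = alpha, beta = beta)
}

#' Expected sufficient statistics of one contiguous batch
#' @keywords internal
batchStats <- function(obs, hmm) {
  fb <- forwardBackward(obs, hmm)
  g <- fb$gamma
  Nk <- colSums(g)
  Mk <- t(obs) %*% g                       # D x K
  D <- ncol(obs)
  K <- hmm@K
  Sk <- array(0, c(D, D, K))
  for (k in seq_len(K))
    Sk[, , k] <- crossprod(obs * sqrt(g[, k]))
  list(n = nrow(obs), gamma1 = g[1, ], xiSum = fb$xiSum, Nk = Nk,
       Mk = Mk, Sk = Sk, logLik = fb$logLik)
}

#' Closed-form M-step from (possibly blended) sufficient statistics
#' @keywords internal
statsToParams <- function(st, D, K, ridge = 1e-6, globalCov = NULL,
                          globalMean = NULL, countScale = 1) {
  pi <- st$gamma1 / sum(st$gamma1)
  A <- st$xiSum
  rs <- rowSums(A)
  zero <- rs == 0
  A[zero, ] <- 1 / K
  A[!zero, ] <- A[!zero, , drop = FALSE] / rs[!zero]
  mu <- matrix(0, K, D)
  Sigma <- array(0, c(D, D, K))
  starved <- st$Nk * countScale < 1        # expected count below one frame
  for (k in seq_len(K)) {
    if (st$Nk[k] <= 0 || (starved[k] && !is.null(globalCov))) {
      mu[k, ] <- if (is.null(globalMean)) 0 else globalMean
      Sigma[, , k] <- if (is.null(globalCov)) diag(D) else globalCov
      if (starved[k]) message("state ", k,
                              " starved; covariance reset to global")
      next
    }
    mu[k, ] <- st$Mk[, k] / st$Nk[k]
    S <- st$Sk[, , k] / st$Nk[k] - tcrossprod(mu[k, ])
    S <- (S + t(S)) / 2
    Sigma[, , k] <- S + ridge * diag(D)
  }
  gaussianHMM(pi, A, mu, Sigma)
}

#' k-means initialization for HMM fitting
#'
#' Means from k-means on a subsample, shared diagonal covariance from the
#' pooled data, uniform start distribution, and a sticky transition matrix.
#' @keywords internal
kmeansInit <- function(obs, K, seed = 1L, subsample = 10000L,
                       stickiness = 0.95) {
  withSeed(seed, {
    n <- nrow(obs)
    idx <- if (n > subsample) sample.int(n, subsample) else seq_len(n)
    km <- suppressWarnings(
      stats::kmeans(obs[idx, , drop = FALSE], centers = K, nstart = 5,
                    iter.max = 50))
    D <- ncol(obs)
    v <- apply(obs, 2, stats::var)
    v[v == 0] <- 1e-6
    Sigma <- array(0, c(D, D, K))
    for (k in seq_len(K)) Sigma[, , k] <- diag(v, D)
    A <- matrix((1 - stickiness) / max(1, K - 1), K, K)
    diag(A) <- if (K == 1) 1 else stickiness
    gaussianHMM(rep(1 / K, K), A, km$centers, Sigma)
  })
}

#' Fit a Gaussian HMM by memory-bounded stochastic EM
#'
#' The observation stream is split into contiguous batches of
#' `schedule$batchSize` frames and visited in a seed-determined shuffled
#' order each epoch. After the E-step (forward-backward) on a batch, the
#' batch-optimal expected sufficient statistics (normalized per frame) are
#' blended into the running statistics by a convex combination with
#' Robbins-Monro step sizes, and the parameters are re-derived in closed
#' form — so transition rows stay stochastic and covariances stay positive
#' semi-definite by construction. Peak memory is bounded by the batch, not
#' by the stream length. With a single batch covering all data and step
#' size 1 throughout, the iterates coincide exactly with full-batch
#' Baum-Welch from the same initialization.
#'
#' @param observations T x D matrix (one contiguous stream).
#' @param K number of hidden states.
#' @param schedule an [emSchedule()].
#' @param init optional [GaussianHMM-class] initialization; defaults to
#'   k-means on a subsample with shared diagonal covariance.
#' @param ridge diagonal regularization added to every covariance update.
#' @return a fitted [GaussianHMM-class]; `meta` carries the per-update
#'   held-in log-likelihood trace (per frame), the schedule, and the seed.
#' @export
stochasticEMFit <- function(observations, K, schedule = emSchedule(),
                            init = NULL, ridge = 1e-6) {
  obs <- as.matrix(observations)
  Tn <- nrow(obs)
  stopifnot(K >= 1, Tn >= 2)
  if (is.null(init)) init <- kmeansInit(obs, K, seed = schedule$seed)
  D <- ncol(obs)
  starts <- seq(1L, Tn, by = schedule$batchSize)
  batches <- lapply(starts, function(s) s:min(s + schedule$batchSize - 1L, Tn))
  if (length(batches[[length(batches)]]) < 2L && length(batches) > 1L) {
    # merge a trailing 1-frame stub into the previous batch
    nb <- length(batches)
    batches[[nb - 1L]] <- c(batches[[nb - 1L]], batches[[nb]])
    batches <- batches[-nb]
  }
  hmm <- init
  blended <- NULL
  trace <- numeric(0)
  globalMean <- colMeans(obs)
  globalCov <- stats::cov(obs) + ridge * diag(D)
  tUpd <- 0L
  withSeed(schedule$seed, {
    for (epoch in seq_len(schedule$maxEpochs)) {
      order_ <- if (length(batches) > 1L) sample(length(batches)) else 1L
      for (bi in order_) {
        idx <- batches[[bi]]
        if (!length(idx)) stop("empty batch")
        st <- batchStats(obs[idx, , drop = FALSE], hmm)
        tUpd <- tUpd + 1L
        rho <- schedule$rho(tUpd)
        per <- list(gamma1 = st$gamma1, xiSum = st$xiSum / st$n,
                    Nk = st$Nk / st$n, Mk = st$Mk / st$n, Sk = st$Sk / st$n,
                    n = st$n)
        if (is.null(blended)) blended <- per
        else {
          for (f in c("gamma1", "xiSum", "Nk", "Mk", "Sk"))
            blended[[f]] <- (1 - rho) * blended[[f]] + rho * per[[f]]
          blended$n <- st$n
        }
        hmm <- statsToParams(blended, D, K, ridge = ridge,
                             globalCov = globalCov, globalMean = globalMean,
                             countScale = st$n)
        trace <- c(trace, st$logLik / st$n)
      }
    }
  })
  hmm@meta <- list(trace = trace, schedule = schedule[
    c("batchSize", "maxEpochs", "decay", "seed")],
    K = K, ridge = ridge, init = "kmeans")
  hmm
}

#' Decode per-frame behavioral syllables
#'
#' Labels each frame by the posterior mode (default) or by the Viterbi path,
#' and summarizes bout run lengths per syllable.
#'
#' @param observations T x D matrix.
#' @param hmm a fitted [GaussianHMM-class].
#' @param method "posterior" or "viterbi".
#' @return list of class `SyllableSequence`: `labels` (0-based ids),
#'   `posteriorMax` (per-frame winning posterior), and `boutStats`
#'   (data.frame with per-syllable mean, 5th and 95th percentile bout
#'   durations in frames).
#' @export
decodeSyllables <- function(observations, hmm,
                            method = c("posterior", "viterbi")) {
  method <- match.arg(method)
  obs <- as.matrix(observations)
  if (ncol(obs) != ncol(hmm@mu))
    stop("observation dimension does not match emission dimension")
  if (method == "posterior") {
    fb <- forwardBackward(obs, hmm)
    labels <- max.col(fb$gamma, ties.method = "first") - 1L
    pmax_ <- fb$gamma[cbind(seq_len(nrow(obs)), labels + 1L)]
  } else {
    labels <- viterbiPath(obs, hmm)
    pmax_ <- rep(NA_real_, nrow(obs))
  }
  bouts <- boutLengths(labels)
  boutStats <- do.call(rbind, lapply(sort(unique(bouts$state)), function(s) {
    d <- bouts$length[bouts$state == s]
    data.frame(syllable = s, meanDuration = mean(d),
               p5 = unname(stats::quantile(d, 0.05)),
               p95 = unname(stats::quantile(d, 0.95)),
               nBouts = length(d))
  }))
  structure(list(labels = labels, posteriorMax = pmax_,
                 boutStats = boutStats, method = method),
            class = "SyllableSequence")
}

#' @keywords internal
viterbiPath <- function(obs, hmm) {
  Tn <- nrow(obs)
  K <- hmm@K
  logB <- emissionLogLik(obs, hmm)
  logA <- log(hmm@A + .Machine$double.xmin)
  delta <- log(hmm@pi + .Machine$double.xmin) + logB[1, ]
  psi <- matrix(0L, Tn, K)
  if (Tn > 1) {
    for (t in 2:Tn) {
      cand <- delta + logA                 # K x K: prev state x next state
      psi[t, ] <- max.col(t(cand), ties.method = "first")
      delta <- cand[cbind(psi[t, ], seq_len(K))] + logB[t, ]
    }
  }
  path <- integer(Tn)
  path[Tn] <- which.max(delta)
  if (Tn > 1) for (t in (Tn - 1):1) path[t] <- psi[t + 1, path[t + 1]]
  path - 1L
}

#' Full-batch EM over multiple observation sequences
#'
#' Classic Baum-Welch accumulating expected sufficient statistics across
#' sequences; used by the life-stage model where each animal is one short
#' sequence.
#' @keywords internal
fitHmmEMMulti <- function(obsList, K, nIter = 20L, init = NULL, seed = 1L,
                          ridge = 1e-6) {
  obsAll <- do.call(rbind, obsList)
  D <- ncol(obsAll)
  if (is.null(init)) init <- kmeansInit(obsAll, K, seed = seed)
  hmm <- init
  globalMean <- colMeans(obsAll)
  globalCov <- stats::cov(obsAll) + ridge * diag(D)
  trace <- numeric(nIter)
  for (it in seq_len(nIter)) {
    acc <- NULL
    ll <- 0
    for (obs in obsList) {
      st <- batchStats(as.matrix(obs), hmm)
      ll <- ll + st$logLik
      if (is.null(acc)) acc <- st
      else {
        for (f in c("gamma1", "xiSum", "Nk", "Mk", "Sk"))
          acc[[f]] <- acc[[f]] + st[[f]]
        acc$n <- acc$n + st$n
      }
    }
    hmm <- statsToParams(acc, D, K, ridge = ridge, globalCov = globalCov,
                         globalMean = globalMean)
    trace[it] <- ll
  }
  hmm@meta <- list(trace = trace, nIter = nIter, seed = seed, ridge = ridge)
  hmm
}

#' Select the number of hidden states by held-out log likelihood
#'
#' Fits one model per candidate K on the training sequences and scores the
#' held-out validation sequences; training and validation animals must be
#' disjoint. The plateau rule selects the smallest K whose per-frame
#' held-out log likelihood is within `tol` of the maximum.
#'
#' @param train named list of training observation matrices (names are
#'   animal ids).
#' @param validation named list of validation observation matrices.
#' @param Ks integer grid of state counts.
#' @param schedule an [emSchedule()] used for every fit.
#' @param tol plateau tolerance in nats/frame.
#' @return list with `table` (data.frame of K and held-out log likelihood
#'   per frame), `selected`, and `models`.
#' @export
selectNumStates <- function(train, validation, Ks, schedule = emSchedule(),
                            tol = 0.02) {
  stopifnot(length(Ks) >= 1)
  if (length(intersect(names(train), names(validation))))
    stop("training and validation animals must be disjoint")
  trObs <- do.call(rbind, train)
  valFrames <- sum(vapply(validation, nrow, integer(1)))
  models <- list()
  ll <- numeric(length(Ks))
  for (i in seq_along(Ks)) {
    m <- stochasticEMFit(trObs, Ks[i], schedule)
    models[[i]] <- m
    ll[i] <- sum(vapply(validation, function(v)
      forwardBackward(as.matrix(v), m)$logLik, numeric(1))) / valFrames
  }
  sel <- Ks[min(which(ll >= max(ll) - tol))]
  list(table = data.frame(K = Ks, heldOutLogLik = ll), selected = sel,
       models = models)
}

#' Hierarchically cluster syllables by emission divergence
#'
#' Pairwise symmetrized Kullback-Leibler divergence between the Gaussian
#' emission distributions (closed form), average-linkage agglomerative
#' clustering, and a display leaf order.
#'
#' @param hmm a fitted [GaussianHMM-class].
#' @return list with `distance` (K x K symmetric matrix, zero diagonal),
#'   `hclust`, and `order`.
#' @export
clusterSyllables <- function(hmm) {
  K <- hmm@K
  D <- ncol(hmm@mu)
  dm <- matrix(0, K, K)
  for (i in seq_len(K)) for (j in seq_len(K)) {
    if (j <= i) next
    dm[i, j] <- dm[j, i] <- symmetrizedDklGaussian(
      hmm@mu[i, ], matrix(hmm@Sigma[, , i], D, D),
      hmm@mu[j, ], matrix(hmm@Sigma[, , j], D, D))
  }
  hc <- stats::hclust(stats::as.dist(dm), method = "average")
  list(distance = dm, hclust = hc, order = hc$order)
}
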