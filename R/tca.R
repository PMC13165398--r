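# Usage tensor construction and non-negative canonical polyadic (tensor
# component) decomposition: binning, per-syllable normalization, masked
# HALS fitting, normalized reconstruction error, and held-out-bin rank
# cross-validation.

#' Bin decoded syllables into a usage tensor
#'
#' Counts the frames spent in each syllable within each time-of-day bin for
#' every animal-day: counts[n, t, k] is the number of frames of syllable n
#' in bin t of slice k. At 20 fps with 144 ten-minute bins, a complete bin
#' holds 12,000 frames.
#'
#' @param sequences list of per-animal-day integer syllable vectors
#'   (0-based ids, one entry per frame, frames aligned to the day clock).
#' @param animalDay data.frame with one row per sequence: `animal`, `age`.
#' @param nSyllables syllable alphabet size N (ids must be < N).
#' @param nBins time-of-day bins per day.
#' @param fps frames per second.
#' @return a [UsageTensor-class]; bins with missing frames simply sum lower.
#' @export
binUsage <- function(sequences, animalDay, nSyllables = 100L,
                     nBins = 144L, fps = 20) {
  stopifnot(length(sequences) == nrow(animalDay))
  if (anyDuplicated(animalDay[, c("animal", "age")]))
    stop("overlapping day slices for one animal rejected")
  framesPerBin <- fps * 86400 / nBins
  K <- length(sequences)
  counts <- array(0L, c(nSyllables, nBins, K))
  for (k in seq_len(K)) {
    s <- sequences[[k]]
    if (any(s < 0 | s >= nSyllables, na.rm = TRUE))
      stop("syllable ids must be in [0, nSyllables)")
    bin <- pmin(nBins, floor((seq_along(s) - 1) / framesPerBin) + 1L)
    ok <- !is.na(s)
    tab <- table(factor(s[ok] + 1L, levels = seq_len(nSyllables)),
                 factor(bin[ok], levels = seq_len(nBins)))
    counts[, , k] <- as.integer(tab)
  }
  methods::new("UsageTensor",
    counts = counts, normalized = array(numeric(0)),
    sylRange = matrix(numeric(0), 0, 2),
    animalDay = animalDay, framesPerBin = framesPerBin)
}

#' Min-max normalize usage per syllable
#'
#' Each syllable's usage trace is scaled to [0, 1] across all bins and
#' animal-days, preventing highly used syllables from dominating the tensor
#' fit. Constant syllables map to 0 and are flagged.
#'
#' @param tensor a [UsageTensor-class].
#' @param zeroMin force the normalization minimum to 0 instead of the
#'   empirical minimum.
#' @return the tensor with `normalized` and `sylRange` filled in;
#'   `attr(, "constant")` lists flagged syllables.
#' @export
normalizeUsage <- function(tensor, zeroMin = FALSE) {
  x <- tensor@counts
  N <- dim(x)[1]
  lo <- apply(x, 1, min)
  hi <- apply(x, 1, max)
  if (zeroMin) lo <- rep(0, N)
  rng <- hi - lo
  constant <- rng == 0
  rng[constant] <- 1
  norm <- sweep(sweep(x, 1, lo, "-"), 1, rng, "/")
  norm[constant, , ] <- 0
  out <- tensor
  out@normalized <- norm
  out@sylRange <- cbind(min = lo, max = hi)
  methods::validObject(out)
  attr(out, "constant") <- which(constant)
  out
}

# ---- small tensor algebra helpers ------------------------------------------

#' Mode-n unfolding of a 3-way array
#' @keywords internal
unfold3 <- function(x, mode) {
  d <- dim(x)
  perm <- switch(mode, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  matrix(aperm(x, perm), d[mode], prod(d[-mode]))
}

#' Reconstruct a 3-way tensor from CP factors
#' @keywords internal
cpReconstruct <- function(U1, U2, U3) {
  d <- c(nrow(U1), nrow(U2), nrow(U3))
  out <- array(0, d)
  for (r in seq_len(ncol(U1)))
    out <- out + outer(outer(U1[, r], U2[, r]), U3[, r])
  out
}

#' Fit a non-negative CP model by HALS
#'
#' Hierarchical alternating least squares on the (optionally masked) squared
#' error, with multiple random restarts; the best restart is kept. Held-out
#' entries marked by `mask` are excluded from the objective via
#' expectation-style imputation: each sweep replaces them with the current
#' reconstruction, so they never influence the fitted factors. After
#' fitting, time and syllable factor columns are rescaled to unit norm with
#' magnitudes absorbed into the age factors, and components are ordered by
#' reconstruction contribution.
#'
#' @param tensor a normalized [UsageTensor-class] or a plain non-negative
#'   3-way array (syllable x time x animal-day).
#' @param R rank (number of components).
#' @param seed RNG seed for the restarts.
#' @param mask optional logical array of the tensor's shape; TRUE entries
#'   are held out of the fit.
#' @param nRestarts random restarts.
#' @param maxIter HALS sweeps per restart.
#' @param tol relative objective change declaring convergence.
#' @return a [CPModel-class].
#' @export
fitNonnegCP <- function(tensor, R, seed = 1L, mask = NULL, nRestarts = 3L,
                        maxIter = 200L, tol = 1e-7) {
  X <- if (is(tensor, "UsageTensor")) usageNormalized(tensor) else tensor
  stopifnot(R >= 1, length(dim(X)) == 3L, min(X) >= 0)
  if (!is.null(mask)) {
    stopifnot(identical(dim(mask), dim(X)))
    if (all(mask)) stop("mask holds out every entry; nothing to fit")
  }
  d <- dim(X)
  best <- NULL
  withSeed(seed, {
    for (rs in seq_len(nRestarts)) {
      U <- lapply(d, function(n) matrix(stats::runif(n * R), n, R))
      Xw <- X
      if (!is.null(mask)) {
        Xhat <- cpReconstruct(U[[1]], U[[2]], U[[3]])
        Xw[mask] <- Xhat[mask]
      }
      prev <- Inf
      converged <- FALSE
      for (it in seq_len(maxIter)) {
        for (m in 1:3) {
          others <- setdiff(1:3, m)
          # gram of the excluded factors and the MTTKRP for this mode
          G <- crossprod(U[[others[1]]]) * crossprod(U[[others[2]]])
          Xm <- unfold3(Xw, m)
          # khatri-rao of (first-varying = higher mode index ordering)
          a <- others[1]; b <- others[2]
          KR <- matrix(0, d[a] * d[b], R)
          for (r in seq_len(R))
            KR[, r] <- as.vector(outer(U[[a]][, r], U[[b]][, r]))
          W <- Xm %*% KR                  # d[m] x R
          for (r in seq_len(R)) {
            g <- G[r, r]
            if (g <= 0) { U[[m]][, r] <- 0; next }
            u <- U[[m]][, r] + (W[, r] - U[[m]] %*% G[, r]) / g
            U[[m]][, r] <- pmax(u, 0)
          }
        }
        if (!is.null(mask) || it %% 10 == 0 || it == maxIter) {
          Xhat <- cpReconstruct(U[[1]], U[[2]], U[[3]])
          if (!is.null(mask)) Xw[mask] <- Xhat[mask]
          err <- sum((Xw - Xhat)^2)
          if (is.finite(prev) && prev - err <= tol * max(prev, 1e-300)) {
            converged <- TRUE
            break
          }
          prev <- err
        }
      }
      Xhat <- cpReconstruct(U[[1]], U[[2]], U[[3]])
      fitErr <- if (is.null(mask)) sum((X - Xhat)^2) else
        sum(((X - Xhat)[!mask])^2)
      if (is.null(best) || fitErr < best$err)
        best <- list(U = U, err = fitErr, converged = converged)
    }
  })
  U <- best$U
  # unit-norm time and syllable columns, magnitude into the age factors
  for (m in 1:2) {
    nrm <- sqrt(colSums(U[[m]]^2))
    nrm[nrm == 0] <- 1
    U[[m]] <- sweep(U[[m]], 2, nrm, "/")
    U[[3]] <- sweep(U[[3]], 2, nrm, "*")
  }
  contrib <- colSums(U[[3]]^2)
  ord <- order(contrib, decreasing = TRUE)
  U <- lapply(U, function(u) u[, ord, drop = FALSE])
  denom <- if (is.null(mask)) sum(X^2) else sum((X[!mask])^2)
  model <- methods::new("CPModel",
    rank = as.integer(R), syllable = U[[1]], time = U[[2]], age = U[[3]],
    trainError = if (denom > 0) best$err / denom else 0,
    converged = best$converged,
    meta = list(seed = seed, nRestarts = nRestarts, maxIter = maxIter))
  methods::validObject(model)
  model
}

#' Normalized reconstruction error of a CP model
#'
#' Squared Frobenius norm of the (masked) residual divided by the squared
#' Frobenius norm of the (masked) data — 0 for a perfect reconstruction, 1
#' for the all-zero model, analogous to the fraction of unexplained
#' variance.
#'
#' @param tensor a normalized [UsageTensor-class] or 3-way array.
#' @param model a [CPModel-class].
#' @param mask optional logical array selecting the entries to score
#'   (TRUE = score this entry). NULL scores everything.
#' @return value in [0, 1] (can exceed 1 for a worse-than-zero model).
#' @export
normalizedError <- function(tensor, model, mask = NULL) {
  X <- if (is(tensor, "UsageTensor")) usageNormalized(tensor) else tensor
  Xhat <- cpReconstruct(model@syllable, model@time, model@age)
  if (!identical(dim(X), dim(Xhat))) stop("tensor and model shapes differ")
  if (is.null(mask)) return(sum((X - Xhat)^2) / sum(X^2))
  stopifnot(identical(dim(mask), dim(X)))
  if (!any(mask)) stop("empty mask rejected")
  sum(((X - Xhat)[mask])^2) / sum((X[mask])^2)
}

#' Cross-validate the CP rank by held-out time bins
#'
#' Holds out a fraction of (time-bin, animal-day) fibers, fits each
#' candidate rank on the remaining entries, and reports train/test
#' normalized errors. The selected rank is the smallest one whose relative
#' test-error improvement over the previous grid point falls below `tol`
#' (the "improvement becomes marginal" elbow rule; relative improvement is
#' used because the error metric is itself normalized).
#'
#' @param tensor a normalized [UsageTensor-class] or 3-way array.
#' @param Rs increasing integer grid of candidate ranks.
#' @param holdoutFraction fraction of time-bin fibers held out (default 0.5).
#' @param seed RNG seed for the mask and the fits.
#' @param tol elbow tolerance on the relative test-error improvement.
#' @param ... passed on to [fitNonnegCP()].
#' @return list with `table` (data.frame R, trainError, testError),
#'   `selected`, `mask`, and `models`.
#' @export
crossValidateRank <- function(tensor, Rs, holdoutFraction = 0.5, seed = 1L,
                              tol = 0.1, ...) {
  stopifnot(length(Rs) >= 1, !is.unsorted(Rs))
  X <- if (is(tensor, "UsageTensor")) usageNormalized(tensor) else tensor
  d <- dim(X)
  mask <- withSeed(seed, {
    fibers <- matrix(FALSE, d[2], d[3])
    nHold <- round(holdoutFraction * length(fibers))
    fibers[sample.int(length(fibers), nHold)] <- TRUE
    aperm(array(rep(fibers, each = d[1]), d), c(1, 2, 3))
  })
  models <- list()
  trainErr <- testErr <- numeric(length(Rs))
  for (i in seq_along(Rs)) {
    m <- fitNonnegCP(X, Rs[i], seed = seed + i, mask = mask, ...)
    models[[i]] <- m
    trainErr[i] <- normalizedError(X, m, mask = !mask)
    testErr[i] <- normalizedError(X, m, mask = mask)
  }
  selected <- Rs[length(Rs)]
  if (length(Rs) > 1) {
    relImprovement <- c(Inf, -diff(testErr) / pmax(testErr[-length(testErr)],
                                                  1e-12))
    flat <- which(relImprovement < tol)
    if (length(flat)) selected <- Rs[min(flat) - 1L]
  }
  list(table = data.frame(R = Rs, trainError = trainErr, testError = testErr),
       selected = selected, mask = mask, models = models)
}
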