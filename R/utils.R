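# Internal numerical helpers shared across modules.

#' Trailing rolling mean with missing-value tolerance
#'
#' Windows are trailing (frame t uses frames t-w+1..t) and truncated at the
#' start of the recording. A window's value is missing unless at least half
#' of its (nominal) frames are present.
#'
#' @param x numeric vector, may contain NA.
#' @param w window length in frames.
#' @param min_frac minimum fraction of non-missing frames required.
#' @return numeric vector the same length as `x`.
#' @keywords internal
rollMean <- function(x, w, min_frac = 0.5) {
  n <- length(x)
  if (w <= 1L) return(x)
  ok <- !is.na(x)
  xz <- ifelse(ok, x, 0)
  cs <- cumsum(xz)
  cn <- cumsum(as.numeric(ok))
  idx <- seq_len(n)
  lo <- pmax(idx - w, 0L)
  s <- cs - c(0, cs)[lo + 1L]
  k <- cn - c(0, cn)[lo + 1L]
  eff <- pmin(idx, w)            # nominal window size after truncation
  out <- s / k
  out[k < pmax(1, ceiling(min_frac * eff))] <- NA_real_
  out
}

#' Trailing rolling standard deviation (same window rules as rollMean)
#' @keywords internal
rollSd <- function(x, w, min_frac = 0.5) {
  n <- length(x)
  ok <- !is.na(x)
  xz <- ifelse(ok, x, 0)
  cs <- cumsum(xz)
  cs2 <- cumsum(xz^2)
  cn <- cumsum(as.numeric(ok))
  idx <- seq_len(n)
  lo <- pmax(idx - w, 0L)
  s <- cs - c(0, cs)[lo + 1L]
  s2 <- cs2 - c(0, cs2)[lo + 1L]
  k <- cn - c(0, cn)[lo + 1L]
  eff <- pmin(idx, w)
  v <- (s2 - s^2 / k) / (k - 1)
  v[v < 0] <- 0                  # guard tiny negative round-off
  out <- sqrt(v)
  out[k < 2 | k < pmax(1, ceiling(min_frac * eff))] <- NA_real_
  out
}

#' Causal linear FIR filter
#'
#' y[t] = sum_k b[k] x[t-k+1]. Pre-history samples (before the first frame)
#' are taken equal to the first value, so a constant signal is a fixed point
#' of the filter and no startup ramp is introduced.
#' @keywords internal
lfilterFIR <- function(x, b) {
  n <- length(x)
  if (n == 0L) return(x)
  init <- x[1]
  out <- numeric(n)
  for (k in seq_along(b)) {
    if (k == 1L) out <- out + b[k] * x
    else {
      shifted <- c(rep(init, k - 1L), x[seq_len(n - k + 1L)])
      out <- out + b[k] * shifted
    }
  }
  out
}

#' 1-D Gaussian smoothing with reflected boundaries
#'
#' Discrete Gaussian kernel truncated at 4 sigma, boundary handled by
#' reflection, matching common image-filter conventions.
#' @keywords internal
gaussSmooth1d <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  n <- length(x)
  # reflect edges ('reflect' mode: abcd -> dcba|abcd|dcba)
  pad <- c(rev(x[seq_len(min(r, n))]), x, rev(x[seq.int(max(1L, n - r + 1L), n)]))
  if (length(pad) < n + 2L * r) { # short series: keep reflecting
    while (length(pad) < n + 2L * r) pad <- c(pad[1], pad, pad[length(pad)])
  }
  out <- stats::filter(pad, k, sides = 2)
  as.numeric(out[(r + 1L):(r + n)])
}

#' Column z-scoring that tolerates constant columns
#'
#' Constant columns map to 0 rather than NaN; attributes record the centers
#' and scales used.
#' @keywords internal
zscoreCols <- function(x, center = NULL, scale = NULL) {
  x <- as.matrix(x)
  if (is.null(center)) center <- colMeans(x, na.rm = TRUE)
  if (is.null(scale)) scale <- apply(x, 2, stats::sd, na.rm = TRUE)
  scale2 <- ifelse(is.na(scale) | scale == 0, 1, scale)
  out <- sweep(sweep(x, 2, center, "-"), 2, scale2, "/")
  attr(out, "center") <- center
  attr(out, "scale") <- scale
  out
}

#' log-sum-exp over a vector
#' @keywords internal
logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Multivariate normal log density for a matrix of observations
#'
#' @param x T x D matrix.
#' @param mu length-D mean.
#' @param Sigma D x D covariance (positive definite).
#' @keywords internal
mvnLogDensity <- function(x, mu, Sigma) {
  x <- as.matrix(x)
  d <- ncol(x)
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch)) {
    warning("singular covariance regularized with ridge")
    ch <- chol(Sigma + diag(1e-6 * mean(diag(Sigma)) + 1e-12, d))
  }
  z <- backsolve(ch, t(x) - mu, transpose = TRUE)   # solves t(ch) %*% z = centered
  -0.5 * colSums(z^2) - sum(log(diag(ch))) - 0.5 * d * log(2 * pi)
}

#' Area under the ROC curve from scores
#'
#' Rank-based (equivalent to the Mann-Whitney statistic), ties handled by
#' midranks.
#' @keywords internal
rocAuc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Run-length encode integer labels into (value, length) bouts
#' @keywords internal
boutLengths <- function(labels) {
  r <- rle(as.integer(labels))
  data.frame(state = r$values, length = r$lengths)
}

#' Align estimated labels to truth by best permutation (Hungarian-free greedy
#' over all permutations for small K)
#' @keywords internal
bestPermutationAccuracy <- function(est, truth, K) {
  perms <- permutationsOf(K)
  best <- 0
  for (i in seq_len(nrow(perms))) {
    acc <- mean(perms[i, est + 1L] - 1L == truth)
    if (acc > best) best <- acc
  }
  best
}

#' All permutations of 1..n (n small)
#' @keywords internal
permutationsOf <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- permutationsOf(n - 1L)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    out <- rbind(out, cbind(i, sub + (sub >= i)))
  }
  out
}

#' Stable small hash of a serialized R object (provenance tagging)
#' @keywords internal
configHash <- function(x) {
  # functions are hashed by their source, not their closure environment,
  # so the hash is stable across load mechanisms and sessions
  sanitize <- function(v) {
    if (is.function(v)) return(paste(deparse(v), collapse = "\n"))
    if (is.list(v)) return(lapply(v, sanitize))
    v
  }
  raw <- as.integer(serialize(sanitize(x), NULL, version = 2))
  # polynomial rolling hash; enough for provenance tagging, not crypto
  h <- 0
  for (b in raw) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
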