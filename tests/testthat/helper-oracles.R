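# Independent oracles used to validate the package's implementations.
# These deliberately use different algorithms from the code under test.

# Brute-force HMM inference: enumerate all K^T hidden paths.
enumerateHMM <- function(obs, startProb, A, mu, Sigma) {
  obs <- as.matrix(obs)
  Tn <- nrow(obs)
  K <- length(startProb)
  dens <- function(x, k) {
    d <- length(x)
    S <- as.matrix(Sigma[[k]])
    exp(-0.5 * drop(t(x - mu[k, ]) %*% solve(S) %*% (x - mu[k, ]))) /
      sqrt((2 * pi)^d * det(S))
  }
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), Tn)))
  probs <- apply(paths, 1, function(z) {
    p <- startProb[z[1]] * dens(obs[1, ], z[1])
    if (Tn > 1) for (t in 2:Tn)
      p <- p * A[z[t - 1], z[t]] * dens(obs[t, ], z[t])
    p
  })
  lik <- sum(probs)
  gamma <- matrix(0, Tn, K)
  for (t in seq_len(Tn)) for (k in seq_len(K))
    gamma[t, k] <- sum(probs[paths[, t] == k]) / lik
  list(gamma = gamma, logLik = log(lik))
}

# Independent full-batch Baum-Welch in log space (no scaling, logsumexp),
# mirroring the declared M-step (ridge included) but via a separate route.
referenceBaumWelch <- function(obs, init, nIter, ridge = 1e-6) {
  obs <- as.matrix(obs)
  Tn <- nrow(obs)
  D <- ncol(obs)
  K <- length(init$pi)
  lse <- function(x) { m <- max(x); m + log(sum(exp(x - m))) }
  ldens <- function(mu, S) {
    ch <- chol(S)
    z <- backsolve(ch, t(obs) - mu, transpose = TRUE)
    -0.5 * colSums(z^2) - sum(log(diag(ch))) - 0.5 * D * log(2 * pi)
  }
  pi_ <- init$pi; A <- init$A; mu <- init$mu; Sig <- init$Sigma
  for (iter in seq_len(nIter)) {
    logB <- sapply(seq_len(K), function(k)
      ldens(mu[k, ], as.matrix(Sig[, , k])))
    la <- matrix(-Inf, Tn, K)
    la[1, ] <- log(pi_) + logB[1, ]
    for (t in 2:Tn) for (k in seq_len(K))
      la[t, k] <- lse(la[t - 1, ] + log(A[, k])) + logB[t, k]
    lb <- matrix(0, Tn, K)
    for (t in (Tn - 1):1) for (k in seq_len(K))
      lb[t, k] <- lse(log(A[k, ]) + logB[t + 1, ] + lb[t + 1, ])
    ll <- lse(la[Tn, ])
    lg <- la + lb - ll
    g <- exp(lg)
    xi <- matrix(0, K, K)
    for (t in seq_len(Tn - 1)) {
      lx <- outer(la[t, ], logB[t + 1, ] + lb[t + 1, ], "+") + log(A)
      xi <- xi + exp(lx - lse(as.vector(lx)))
    }
    pi_ <- g[1, ] / sum(g[1, ])
    A <- xi / rowSums(xi)
    Nk <- colSums(g)
    for (k in seq_len(K)) {
      mu[k, ] <- colSums(obs * g[, k]) / Nk[k]
      ctr <- sweep(obs, 2, mu[k, ])
      S <- crossprod(ctr * sqrt(g[, k])) / Nk[k]
      Sig[, , k] <- (S + t(S)) / 2 + ridge * diag(D)
    }
  }
  list(pi = pi_, A = A, mu = mu, Sigma = Sig)
}

# Exact minimum enclosing circle by brute force over pairs and triples.
minEnclosingCircleArea <- function(pts) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  contains <- function(c, r2) all(rowSums(sweep(pts, 2, c)^2) <= r2 + 1e-9)
  best <- Inf
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    c <- (pts[i, ] + pts[j, ]) / 2
    r2 <- sum((pts[i, ] - c)^2)
    if (r2 < best && contains(c, r2)) best <- r2
  }
  if (n >= 3) for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    p1 <- pts[i, ]; p2 <- pts[j, ]; p3 <- pts[k, ]
    dmat <- 2 * (p1[1] * (p2[2] - p3[2]) + p2[1] * (p3[2] - p1[2]) +
                   p3[1] * (p1[2] - p2[2]))
    if (abs(dmat) < 1e-12) next
    ux <- (sum(p1^2) * (p2[2] - p3[2]) + sum(p2^2) * (p3[2] - p1[2]) +
             sum(p3^2) * (p1[2] - p2[2])) / dmat
    uy <- (sum(p1^2) * (p3[1] - p2[1]) + sum(p2^2) * (p1[1] - p3[1]) +
             sum(p3^2) * (p2[1] - p1[1])) / dmat
    c <- c(ux, uy)
    r2 <- sum((p1 - c)^2)
    if (r2 < best && contains(c, r2)) best <- r2
  }
  if (n == 1) best <- 0
  pi * best
}

# Direct-summation symmetrized KL on already-normalized distributions.
directSymmetrizedDkl <- function(p, q) {
  kl <- function(a, b) sum(ifelse(a > 0, a * log(a / b), 0))
  0.5 * kl(p, q) + 0.5 * kl(q, p)
}

# Best-permutation factor congruence between two factor triples.
factorCongruence <- function(est, truth) {
  R <- ncol(est[[1]])
  perms <- behaviorome:::permutationsOf(R)
  colcos <- function(a, b) {
    na <- sqrt(colSums(a^2)); nb <- sqrt(colSums(b^2))
    colSums(a * b) / (na * nb)
  }
  best <- -Inf
  for (i in seq_len(nrow(perms))) {
    pm <- perms[i, ]
    sc <- sapply(1:3, function(m)
      colcos(est[[m]][, pm, drop = FALSE], truth[[m]]))
    best <- max(best, mean(sc))
  }
  best
}

# Exhaustive single-split search of the kernel change-point objective,
# sharing only the published cost definition.
bestSingleSplit <- function(z, bandwidth = NULL) {
  z <- as.matrix(z)
  L <- nrow(z)
  sq <- rowSums(z^2)
  D2 <- outer(sq, sq, "+") - 2 * tcrossprod(z)
  D2[D2 < 0] <- 0
  if (is.null(bandwidth)) bandwidth <- stats::median(D2[upper.tri(D2)])
  Kg <- exp(-D2 / (2 * bandwidth))
  cost <- function(a, b) {
    idx <- a:b
    sum(diag(Kg)[idx]) - sum(Kg[idx, idx]) / length(idx)
  }
  costs <- vapply(2:L, function(s) cost(1, s - 1) + cost(s, L), numeric(1))
  (2:L)[which.min(costs)]
}
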