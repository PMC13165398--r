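# Minimal bagged regression trees (CART, variance impurity, per-node
# feature subsampling) used for the behavioral clock and the lifespan
# classifier. For 0/1 labels variance impurity is Gini/2, so the same
# machinery serves as a probability forest for classification.

#' Fit one CART regression tree
#'
#' Recursive binary splitting minimizing within-node sum of squares, with
#' `mtry` features considered per node. Returns the tree as a flat
#' data.frame of nodes plus the per-feature impurity decrease.
#' @keywords internal
fitTreeReg <- function(X, y, mtry, minSplit = 5L, minBucket = 2L,
                       maxDepth = 25L) {
  p <- ncol(X)
  nodes <- new.env(parent = emptyenv())
  nodes$tab <- list()
  nodes$importance <- numeric(p)
  addNode <- function(rec) {
    id <- length(nodes$tab) + 1L
    nodes$tab[[id]] <- rec
    id
  }
  build <- function(idx, depth) {
    n <- length(idx)
    yi <- y[idx]
    mu <- mean(yi)
    sse <- sum((yi - mu)^2)
    if (n < minSplit || depth >= maxDepth || sse <= 1e-12) {
      return(addNode(list(leaf = TRUE, value = mu)))
    }
    feats <- if (mtry < p) sample.int(p, mtry) else seq_len(p)
    bestDec <- 0; bestJ <- NA_integer_; bestCut <- NA_real_
    for (j in feats) {
      xj <- X[idx, j]
      o <- order(xj)
      xs <- xj[o]; ys <- yi[o]
      cs <- cumsum(ys); cs2 <- cumsum(ys^2)
      nl <- seq_len(n - 1L)
      valid <- xs[nl] < xs[nl + 1L] & nl >= minBucket & (n - nl) >= minBucket
      if (!any(valid)) next
      sseL <- cs2[nl] - cs[nl]^2 / nl
      sseR <- (cs2[n] - cs2[nl]) - (cs[n] - cs[nl])^2 / (n - nl)
      dec <- sse - (sseL + sseR)
      dec[!valid] <- -Inf
      jBest <- which.max(dec)
      if (dec[jBest] > bestDec) {
        bestDec <- dec[jBest]; bestJ <- j
        bestCut <- (xs[jBest] + xs[jBest + 1L]) / 2
      }
    }
    if (is.na(bestJ)) return(addNode(list(leaf = TRUE, value = mu)))
    nodes$importance[bestJ] <- nodes$importance[bestJ] + bestDec
    id <- addNode(list(leaf = FALSE, feature = bestJ, cut = bestCut))
    left <- idx[X[idx, bestJ] <= bestCut]
    right <- idx[X[idx, bestJ] > bestCut]
    leftId <- build(left, depth + 1L)
    rightId <- build(right, depth + 1L)
    rec <- nodes$tab[[id]]
    rec$left <- leftId
    rec$right <- rightId
    nodes$tab[[id]] <- rec
    id
  }
  root <- build(seq_len(nrow(X)), 0L)
  list(nodes = nodes$tab, root = root, importance = nodes$importance)
}

#' @keywords internal
predictTreeReg <- function(tree, X) {
  out <- numeric(nrow(X))
  walk <- function(id, idx) {
    node <- tree$nodes[[id]]
    if (isTRUE(node$leaf)) { out[idx] <<- node$value; return(invisible()) }
    go <- X[idx, node$feature] <= node$cut
    if (any(go)) walk(node$left, idx[go])
    if (any(!go)) walk(node$right, idx[!go])
  }
  walk(tree$root, seq_len(nrow(X)))
  out
}

#' Bagged regression forest
#'
#' @param X numeric matrix of features.
#' @param y numeric response (0/1 for classification use).
#' @param nTrees number of bootstrap trees.
#' @param mtry features tried per split; defaults to p/3 (regression
#'   convention), at least 1.
#' @param seed RNG seed.
#' @return list of class `bagForest` with trees and normalized
#'   mean-decrease-in-impurity feature importances.
#' @keywords internal
bagForest <- function(X, y, nTrees = 100L, mtry = NULL, minSplit = 5L,
                      seed = 1L) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (is.null(mtry)) mtry <- max(1L, floor(p / 3))
  withSeed(seed, {
    trees <- vector("list", nTrees)
    imp <- numeric(p)
    n <- nrow(X)
    for (b in seq_len(nTrees)) {
      idx <- sample.int(n, n, replace = TRUE)
      trees[[b]] <- fitTreeReg(X[idx, , drop = FALSE], y[idx], mtry = mtry,
                               minSplit = minSplit)
      imp <- imp + trees[[b]]$importance
    }
    impN <- if (sum(imp) > 0) imp / sum(imp) else rep(1 / p, p)
    structure(list(trees = trees, importance = impN, mtry = mtry,
                   featureNames = colnames(X)),
              class = "bagForest")
  })
}

#' @keywords internal
predictForest <- function(forest, X) {
  X <- as.matrix(X)
  preds <- lapply(forest$trees, function(tr) predictTreeReg(tr, X))
  rowMeans(do.call(cbind, preds))
}
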