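# Minimal linear max-margin classifier (squared hinge loss, L2 penalty),
# used only for the linear-separability metric. Fit by L-BFGS with an
# analytic gradient; no kernel machinery is needed for a linear boundary.

#' @keywords internal
svmLinearFit <- function(X, y, lambda = 1e-3, maxit = 200) {
  X <- as.matrix(X)
  stopifnot(all(y %in% c(-1, 1)))
  Xa <- cbind(X, 1)                       # absorb the intercept
  p <- ncol(Xa)
  obj <- function(w) {
    m <- 1 - y * drop(Xa %*% w)
    h <- pmax(m, 0)
    mean(h^2) + lambda / 2 * sum(w[-p]^2)
  }
  grd <- function(w) {
    m <- 1 - y * drop(Xa %*% w)
    act <- m > 0
    g <- -2 * colMeans(Xa * (y * m * act))
    g[-p] <- g[-p] + lambda * w[-p]
    g
  }
  fit <- stats::optim(rep(0, p), obj, grd, method = "L-BFGS-B",
                      control = list(maxit = maxit))
  structure(list(w = fit$par[-p], b = fit$par[p]), class = "svmLinear")
}

#' @keywords internal
svmLinearPredict <- function(model, X) {
  s <- drop(as.matrix(X) %*% model$w) + model$b
  ifelse(s >= 0, 1, -1)
}
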