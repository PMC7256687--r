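#' Linear 2-norm soft-margin SVM
#'
#' Trains the linear 2-norm soft-margin support vector machine
#' \deqn{\min_{w,b} \tfrac12 \|w\|^2 + \sum_i c_i \max(0, 1 - y_i (w^T
#' x_i + b))^2} by the finite-Newton active-set method: for the current
#' set of margin violators the piecewise-quadratic objective is an exact
#' quadratic whose minimizer is found by one linear solve; backtracking
#' on the objective guarantees monotone convergence. The squared hinge
#' makes every zero-loss point irrelevant to the solution, so removing a
#' non-support vector leaves the decision function unchanged.
#'
#' @param x numeric matrix, rows = samples, columns = features.
#' @param y labels, coded 0/1 (or -1/+1).
#' @param cost soft-margin cost C (per-sample weight \eqn{c_i = C} or
#'   class-weighted).
#' @param classWeights logical; when TRUE, \eqn{c_i = C \cdot n/(2
#'   n_{y_i})} (inverse class frequency), addressing class imbalance.
#' @param maxIter iteration cap.
#' @param tol convergence tolerance on the relative objective decrease.
#' @return object of class \code{l2svm} with elements \code{w},
#'   \code{b}, \code{cost}.
#' @seealso [predict.l2svm()]
#' @export
l2svm <- function(x, y, cost = 1, classWeights = FALSE,
                  maxIter = 100L, tol = 1e-10) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (all(y %in% c(0, 1))) y <- 2 * y - 1
  if (!all(y %in% c(-1, 1))) stop("labels must be 0/1 or -1/+1")
  if (length(unique(y)) < 2L)
    stop("training data contain a single class")
  n <- nrow(x)
  d <- ncol(x)
  ci <- rep(cost, n)
  if (classWeights) {
    npos <- sum(y > 0)
    ci <- cost * ifelse(y > 0, n / (2 * npos), n / (2 * (n - npos)))
  }
  X1 <- cbind(x, 1)
  theta <- numeric(d + 1L)
  reg <- c(rep(1, d), 0)   # bias unregularized

  obj <- function(th) {
    f <- drop(X1 %*% th)
    viol <- pmax(0, 1 - y * f)
    0.5 * sum(reg * th^2) + sum(ci * viol^2)
  }

  fcur <- obj(theta)
  for (it in seq_len(maxIter)) {
    f <- drop(X1 %*% theta)
    active <- which(y * f < 1)
    if (!length(active)) break
    XA <- X1[active, , drop = FALSE]
    cA <- ci[active]
    H <- diag(reg, d + 1L) + 2 * crossprod(XA, XA * cA)
    rhs <- 2 * crossprod(XA, cA * y[active])
    thetaStar <- drop(solve(H, rhs))
    # backtracking line search from theta toward thetaStar
    step <- 1
    repeat {
      cand <- theta + step * (thetaStar - theta)
      fc <- obj(cand)
      if (fc <= fcur + 1e-12 || step < 1e-4) break
      step <- step / 2
    }
    if (abs(fcur - fc) <= tol * max(1, fcur) && step == 1) {
      theta <- cand
      fcur <- fc
      break
    }
    theta <- cand
    fcur <- fc
  }
  structure(list(w = theta[seq_len(d)], b = theta[d + 1L], cost = cost),
            class = "l2svm")
}

#' Decision values and class predictions of a fitted linear SVM
#'
#' @param object an \code{l2svm} fit.
#' @param newdata numeric matrix of samples.
#' @param ... unused.
#' @return data.frame with \code{decision} (signed distance score) and
#'   \code{predicted} (0/1; decision > 0 maps to 1).
#' @export
predict.l2svm <- function(object, newdata, ...) {
  dec <- drop(as.matrix(newdata) %*% object$w) + object$b
  data.frame(decision = dec, predicted = as.integer(dec > 0))
}
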