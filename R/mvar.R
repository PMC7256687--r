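#' Simulate a stable MVAR process
#'
#' Draws a realization of the multivariate autoregressive process
#' \eqn{x_t = \sum_k A_k x_{t-k} + e_t} with Gaussian innovations
#' \eqn{e_t \sim N(0, \Sigma)}. Used by the synthetic EEG generator and
#' by estimator tests.
#'
#' @param A coefficient array channels x channels x order (or a matrix for
#'   order 1).
#' @param Sigma innovation covariance (default identity).
#' @param n number of samples to return.
#' @param burnin samples discarded to remove the transient.
#' @param seed integer seed.
#' @return numeric matrix channels x n.
#' @export
simulateMVAR <- function(A, Sigma = NULL, n, burnin = 1000L, seed = 1L) {
  if (is.matrix(A)) A <- array(A, dim = c(dim(A), 1L))
  m <- dim(A)[1]
  p <- dim(A)[3]
  if (is.null(Sigma)) Sigma <- diag(m)
  rad <- companionRadius(A)
  if (rad >= 1)
    stop(sprintf(
      "MVAR coefficients are unstable (companion spectral radius %.4f >= 1)",
      rad))
  L <- t(chol(Sigma))
  set.seed(seed)
  ntot <- n + burnin
  e <- L %*% matrix(rnorm(m * ntot), m, ntot)
  x <- matrix(0, m, ntot)
  for (t in seq_len(ntot)) {
    acc <- e[, t]
    kmax <- min(p, t - 1L)
    for (k in seq_len(kmax)) acc <- acc + A[, , k] %*% x[, t - k]
    x[, t] <- acc
  }
  x[, burnin + seq_len(n), drop = FALSE]
}

#' Spectral radius of the MVAR companion matrix
#'
#' The process is (asymptotically) stationary iff this is below 1.
#'
#' @param A coefficient array channels x channels x order.
#' @return largest eigenvalue modulus of the companion form.
#' @export
companionRadius <- function(A) {
  if (is.matrix(A)) A <- array(A, dim = c(dim(A), 1L))
  m <- dim(A)[1]
  p <- dim(A)[3]
  C <- matrix(0, m * p, m * p)
  for (k in seq_len(p)) C[seq_len(m), (k - 1L) * m + seq_len(m)] <- A[, , k]
  if (p > 1L)
    C[m + seq_len(m * (p - 1L)), seq_len(m * (p - 1L))] <-
      diag(m * (p - 1L))
  max(Mod(eigen(C, only.values = TRUE)$values))
}

#' Fit an MVAR model by the Vieira-Morf lattice algorithm
#'
#' Multichannel lattice (partial-correlation) estimator with the
#' geometric-mean normalization of Vieira and Morf and unbiased
#' (1/(N - lag)) covariance scaling. The residual covariance is computed
#' by filtering the data through the fitted coefficients, so that
#' \code{Sigma} is exactly the covariance of the empirical residuals.
#'
#' @param x a \linkS4class{Segment}, or a numeric matrix channels x
#'   samples.
#' @param order model order p (default 10).
#' @param fs sampling rate for plain-matrix input (a
#'   \linkS4class{Segment} carries its own); default 500 Hz.
#' @return an \linkS4class{MVARModel}.
#' @export
fitMVAR <- function(x, order = 10L, fs = NULL) {
  if (is(x, "Segment")) {
    fs <- x@fs
    ch <- x@channelNames
    x <- x@data
  } else {
    fs <- fs %||% attr(x, "fs") %||% 500
    ch <- rownames(x) %||% paste0("ch", seq_len(nrow(x)))
  }
  order <- as.integer(order)
  m <- nrow(x)
  N <- ncol(x)
  if (N <= order)
    stop("need more samples than the model order")
  v <- apply(x, 1L, stats::var)
  if (any(v < .Machine$double.eps * 100))
    stop(sprintf("channel(s) %s are constant: rank-deficient data",
                 paste(ch[v < .Machine$double.eps * 100], collapse = ", ")))
  x <- x - rowMeans(x)

  f <- x            # forward prediction error, time-aligned at t
  b <- x            # backward prediction error, aligned at its own t
  ARF <- vector("list", order)
  ARB <- vector("list", order)
  for (k in seq_len(order)) {
    idxF <- (k + 1L):N
    Fm <- f[, idxF, drop = FALSE]
    Bm <- b[, idxF - 1L, drop = FALSE]
    sc <- 1 / (N - k)                      # unbiased covariance scaling
    Pf <- tcrossprod(Fm) * sc
    Pb <- tcrossprod(Bm) * sc
    Pfb <- tcrossprod(Fm, Bm) * sc
    Lf <- t(chol(Pf))
    Lb <- t(chol(Pb))
    # geometric-mean normalized partial correlation, singular values <= 1
    rho <- forwardsolve(Lf, Pfb)
    rho <- t(forwardsolve(Lb, t(rho)))
    Kf <- Lf %*% rho %*% solve(Lb)
    Kb <- Lb %*% t(rho) %*% solve(Lf)
    newF <- Fm - Kf %*% Bm
    newB <- Bm - Kb %*% Fm
    f[, idxF] <- newF
    b[, idxF] <- newB
    # Levinson-Whittle coefficient update
    newARF <- vector("list", k)
    newARB <- vector("list", k)
    newARF[[k]] <- Kf
    newARB[[k]] <- Kb
    if (k > 1L) {
      for (j in seq_len(k - 1L)) {
        newARF[[j]] <- ARF[[j]] - Kf %*% ARB[[k - j]]
        newARB[[j]] <- ARB[[j]] - Kb %*% ARF[[k - j]]
      }
    }
    ARF[seq_len(k)] <- newARF
    ARB[seq_len(k)] <- newARB
  }

  A <- array(0, dim = c(m, m, order))
  for (k in seq_len(order)) A[, , k] <- ARF[[k]]

  # residuals of the fitted one-step predictor
  idx <- (order + 1L):N
  res <- x[, idx, drop = FALSE]
  for (k in seq_len(order)) res <- res - A[, , k] %*% x[, idx - k, drop = FALSE]
  Sigma <- tcrossprod(res) / (length(idx) - 1L)
  Sigma <- (Sigma + t(Sigma)) / 2

  new("MVARModel", A = A, Sigma = Sigma, fs = as.numeric(fs),
      order = order, stable = companionRadius(A) < 1,
      channelNames = ch)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate the MVAR model in the frequency domain
#'
#' Computes the coefficient polynomial \eqn{\bar A(f) = I - \sum_k A_k
#' e^{-i2\pi f k/f_s}}, the transfer function \eqn{H(f) = \bar A(f)^{-1}}
#' and the cross-spectral matrix \eqn{S(f) = H(f)\Sigma H(f)^H} on a
#' frequency grid, by default 1 Hz steps from 2 to 125 Hz (124 points).
#'
#' @param model an \linkS4class{MVARModel}.
#' @param freqs frequency grid in Hz.
#' @return a \linkS4class{SpectralSet}.
#' @export
spectralSet <- function(model, freqs = 2:125) {
  stopifnot(is(model, "MVARModel"))
  A <- model@A
  m <- dim(A)[1]
  p <- dim(A)[3]
  fs <- model@fs
  if (!is.finite(fs) || fs <= 0)
    stop("model has no valid sampling rate")
  nf <- length(freqs)
  Abar <- array(complex(real = 0), dim = c(m, m, nf))
  H <- Abar
  S <- Abar
  I <- diag(m)
  for (fi in seq_len(nf)) {
    f <- freqs[fi]
    Af <- I + 0i
    for (k in seq_len(p)) Af <- Af - A[, , k] * exp(-2i * pi * f * k / fs)
    Hf <- tryCatch(solve(Af), error = function(e)
      stop(sprintf("coefficient polynomial singular at %g Hz", f)))
    Abar[, , fi] <- Af
    H[, , fi] <- Hf
    S[, , fi] <- Hf %*% model@Sigma %*% Conj(t(Hf))
  }
  ch <- model@channelNames
  if (length(ch) != m) ch <- paste0("ch", seq_len(m))
  new("SpectralSet", freqs = as.numeric(freqs), Abar = Abar, H = H, S = S,
      Sigma = model@Sigma, channelNames = ch)
}
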