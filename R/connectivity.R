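#' @name connectivity
#' @title Frequency-domain interaction measures from an MVAR fit
#'
#' @description
#' From the spectral set of a fitted MVAR model the package derives the
#' classical frequency-domain interaction measures: auto/cross spectrum,
#' complex/real/imaginary coherence, partial coherence (pCOH), the partial
#' directed coherence family (PDC, PDCF, gPDC), the directed transfer
#' function family (DTF, ffDTF, dDTF), Geweke-Granger causality (GGC),
#' the transfer function and the coefficient polynomial. Directed tensors
#' are indexed \code{[f, i, j]} = influence of source j on target i.
NULL

#' Supported interaction measure names
#' @export
connectivityMeasures <- function() {
  c("spectrum", "coherence_complex", "coherence_real", "coherence_imag",
    "pCOH", "PDC", "PDCF", "gPDC", "DTF", "dDTF", "ffDTF", "GGC",
    "direct_causality", "transfer_function", "tf_polynomial")
}

#' Classical EEG frequency bands
#'
#' Closed integer bands (Hz): delta 2-4, theta 5-7, alpha 8-13,
#' beta 14-30, gamma 31-80, high_gamma 81-125.
#' @export
classicalBands <- function() {
  list(delta = 2:4, theta = 5:7, alpha = 8:13, beta = 14:30,
       gamma = 31:80, high_gamma = 81:125)
}

# which measures are symmetric (undirected), and whether the diagonal
# belongs in the feature vector
measureSymmetry <- function(measure) {
  switch(measure,
    spectrum = list(symmetric = TRUE, diagonal = TRUE),
    coherence_complex = ,
    coherence_real = ,
    coherence_imag = ,
    pCOH = list(symmetric = TRUE, diagonal = FALSE),
    list(symmetric = FALSE, diagonal = FALSE))
}

#' Compute one interaction measure on the frequency grid
#'
#' @param spec a \linkS4class{SpectralSet}.
#' @param measure one of [connectivityMeasures()].
#' @param ridge ridge factor used if the cross-spectral matrix is
#'   numerically singular when inverted for partial coherence.
#' @return array \code{length(freqs) x channels x channels}; complex for
#'   \code{coherence_complex}, real otherwise. Directed measures are
#'   stored as \code{[f, target, source]}.
#' @export
computeMeasure <- function(spec, measure = connectivityMeasures(),
                           ridge = 1e-10) {
  measure <- match.arg(measure)
  stopifnot(is(spec, "SpectralSet"))
  m <- dim(spec@S)[1]
  nf <- length(spec@freqs)
  S <- spec@S
  H <- spec@H
  Abar <- spec@Abar
  Sigma <- spec@Sigma

  out <- array(if (measure == "coherence_complex") complex(real = 0) else 0,
               dim = c(nf, m, m))

  pcohAt <- function(fi) {
    Sf <- S[, , fi]
    P <- tryCatch(solve(Sf), error = function(e) {
      eps <- ridge * mean(Re(diag(Sf)))
      message(sprintf(
        "cross-spectral matrix singular at %g Hz: ridge eps = %g",
        spec@freqs[fi], eps))
      solve(Sf + eps * diag(m))
    })
    d <- sqrt(abs(Re(diag(P))))
    -P / tcrossprod(d)
  }

  if (measure %in% c("dDTF", "ffDTF", "direct_causality")) {
    # full-frequency row normalization: sum over grid and targets per row
    denom <- sqrt(apply(Mod(H)^2, 1L, sum))   # per target row i
  }

  for (fi in seq_len(nf)) {
    Sf <- S[, , fi]
    Hf <- H[, , fi]
    Af <- Abar[, , fi]
    val <- switch(measure,
      spectrum = Mod(Sf),
      coherence_complex = ,
      coherence_real = ,
      coherence_imag = {
        d <- sqrt(Re(diag(Sf)))
        C <- Sf / tcrossprod(d)
        switch(measure,
          coherence_complex = C,
          coherence_real = Re(C),
          coherence_imag = Im(C))
      },
      pCOH = Mod(pcohAt(fi)),
      PDC = {
        cd <- sqrt(colSums(Mod(Af)^2))
        sweep(Mod(Af), 2L, cd, "/")
      },
      PDCF = {
        Si <- solve(Sigma)
        cd <- sqrt(abs(Re(colSums(Conj(Af) * (Si %*% Af)))))
        sweep(Mod(Af), 2L, cd, "/")
      },
      gPDC = {
        s <- sqrt(diag(Sigma))
        num <- Mod(Af) / s                      # rows scaled by 1/sigma_i
        cd <- sqrt(colSums((Mod(Af) / s)^2))
        sweep(num, 2L, cd, "/")
      },
      DTF = {
        rd <- sqrt(rowSums(Mod(Hf)^2))
        Mod(Hf) / rd
      },
      ffDTF = Mod(Hf) / denom,
      dDTF = (Mod(Hf) / denom) * Mod(pcohAt(fi)),
      GGC = {
        Sii <- Re(diag(Sf))
        G <- matrix(0, m, m)
        for (j in seq_len(m)) {
          sig2 <- Sigma[j, j] - Sigma[, j]^2 / diag(Sigma)  # per target i
          rem <- Sii - sig2 * Mod(Hf[, j])^2
          rem <- pmax(rem, Sii * 1e-12)
          G[, j] <- log(Sii / rem)
        }
        diag(G) <- 0
        pmax(G, 0)
      },
      direct_causality = (Mod(Hf) / denom) * Mod(pcohAt(fi)),
      transfer_function = Mod(Hf),
      tf_polynomial = Mod(Af)
    )
    out[fi, , ] <- val
  }
  dimnames(out) <- list(NULL, spec@channelNames, spec@channelNames)
  attr(out, "freqs") <- spec@freqs
  attr(out, "measure") <- measure
  out
}

#' Average a frequency-resolved tensor into frequency bands
#'
#' Arithmetic mean over the integer frequencies of each closed band.
#' Complex tensors are averaged componentwise (real and imaginary parts
#' separately); real tensors as-is.
#'
#' @param tensor array freq x i x j as returned by [computeMeasure()].
#' @param bands named list of integer frequency vectors
#'   (default [classicalBands()]).
#' @param freqs the frequency grid of \code{tensor} (taken from its
#'   attribute when absent).
#' @return array bands x i x j with band dimnames.
#' @export
bandAverage <- function(tensor, bands = classicalBands(),
                        freqs = attr(tensor, "freqs")) {
  if (is.null(freqs)) stop("frequency grid unknown; pass freqs")
  if (!all(unlist(bands) %in% freqs))
    stop("frequency grid does not cover all requested bands")
  m <- dim(tensor)[2]
  out <- array(if (is.complex(tensor)) complex(real = 0) else 0,
               dim = c(length(bands), m, m))
  for (b in seq_along(bands)) {
    sel <- which(freqs %in% bands[[b]])
    sl <- tensor[sel, , , drop = FALSE]
    out[b, , ] <- apply(sl, c(2L, 3L), mean)
  }
  dimnames(out) <- list(names(bands), dimnames(tensor)[[2]],
                        dimnames(tensor)[[3]])
  attr(out, "measure") <- attr(tensor, "measure")
  out
}

#' Flatten a banded tensor to its nonredundant feature vector
#'
#' Symmetric measures keep the upper triangle (the spectrum also keeps
#' its diagonal); directed measures keep all ordered off-diagonal pairs.
#' Complex values are stored as (real, imaginary) feature pairs. Feature
#' identifiers follow \code{"measure:band:source->target"} for directed
#' and \code{"measure:band:chA~chB"} (A before B in channel order) for
#' undirected entries, with \code{":re"}/\code{":im"} suffixes for
#' complex pairs, in a fixed documented order: bands outer, pairs inner
#' (column-major over the matrix).
#'
#' @param bandTensor array bands x i x j from [bandAverage()].
#' @param measure measure name (taken from the attribute when absent).
#' @return named numeric vector.
#' @export
vectorizeMeasure <- function(bandTensor,
                             measure = attr(bandTensor, "measure")) {
  if (is.null(measure)) stop("measure name unknown")
  sym <- measureSymmetry(measure)
  bands <- dimnames(bandTensor)[[1]]
  ch <- dimnames(bandTensor)[[2]]
  m <- length(ch)
  vals <- c()
  ids <- c()
  for (b in seq_along(bands)) {
    M <- bandTensor[b, , ]
    if (sym$symmetric) {
      idx <- which(upper.tri(M, diag = sym$diagonal), arr.ind = TRUE)
      v <- M[idx]
      id <- paste0(measure, ":", bands[b], ":",
                   ch[idx[, 1]], "~", ch[idx[, 2]])
    } else {
      idx <- which(row(M) != col(M), arr.ind = TRUE)
      # order column-major: source j outer is the column
      v <- M[idx]
      id <- paste0(measure, ":", bands[b], ":",
                   ch[idx[, 2]], "->", ch[idx[, 1]])
    }
    if (is.complex(v)) {
      vals <- c(vals, as.vector(rbind(Re(v), Im(v))))
      ids <- c(ids, as.vector(rbind(paste0(id, ":re"), paste0(id, ":im"))))
    } else {
      vals <- c(vals, v)
      ids <- c(ids, id)
    }
  }
  names(vals) <- ids
  vals
}

#' One-call connectivity feature vector for a segment
#'
#' Fits the MVAR model, evaluates the spectral set on the 2-125 Hz grid,
#' computes the requested measures, band-averages them and concatenates
#' the nonredundant values into one named feature vector.
#'
#' @param x a \linkS4class{Segment}, matrix (channels x samples), or an
#'   already fitted \linkS4class{MVARModel}.
#' @param measures character vector of measure names.
#' @param bands band definition list.
#' @param freqs frequency grid.
#' @param order MVAR model order (default 10).
#' @return named numeric feature vector.
#' @export
connectivityFeatures <- function(x, measures = c("pCOH", "coherence_imag",
                                                 "PDC", "PDCF", "DTF"),
                                 bands = classicalBands(),
                                 freqs = 2:125, order = 10L) {
  measures <- match.arg(measures, connectivityMeasures(),
                        several.ok = TRUE)
  model <- if (is(x, "MVARModel")) x else fitMVAR(x, order = order)
  spec <- spectralSet(model, freqs = freqs)
  unlist(lapply(measures, function(ms) {
    vectorizeMeasure(bandAverage(computeMeasure(spec, ms), bands = bands,
                                 freqs = freqs))
  }))
}
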