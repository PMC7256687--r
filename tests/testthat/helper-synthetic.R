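# Shared fixture builders and independent oracles, all generated in code.

# analytic spectral quantities of an MVAR process from its TRUE
# coefficients: direct evaluation of the closed forms, independent of
# the package's SpectralSet path
analyticSpectral <- function(A, Sigma, f, fs) {
  m <- dim(A)[1]
  Af <- diag(m) + 0i
  for (k in seq_len(dim(A)[3]))
    Af <- Af - A[, , k] * exp(-2i * pi * f * k / fs)
  H <- solve(Af)
  S <- H %*% Sigma %*% Conj(t(H))
  list(Abar = Af, H = H, S = S,
       coh = Mod(S[1, 2]) / sqrt(Re(S[1, 1]) * Re(S[2, 2])),
       dtf21 = Mod(H[2, 1]) / sqrt(sum(Mod(H[2, ])^2)))
}

# bivariate test system: channel 1 is a 10 Hz oscillator driving
# channel 2 at lag 1
bivariateSystem <- function(strength = 0.25, r = 0.9, f0 = 10,
                            fs = 500) {
  A <- array(0, c(2, 2, 2))
  A[1, 1, 1] <- 2 * r * cos(2 * pi * f0 / fs)
  A[1, 1, 2] <- -r^2
  A[2, 2, 1] <- 0.5
  A[2, 1, 1] <- strength
  A
}

# random stable MVAR model object for measure identity checks
randomStableModel <- function(m = 5L, p = 3L, seed = 1L, fs = 500) {
  set.seed(seed)
  repeat {
    A <- array(rnorm(m * m * p, sd = 0.25 / p), c(m, m, p))
    if (companionRadius(A) < 0.95) break
  }
  L <- matrix(rnorm(m * m, sd = 0.3), m, m)
  Sigma <- crossprod(L) + diag(m)
  new("MVARModel", A = A, Sigma = Sigma, fs = fs, order = as.integer(p),
      stable = TRUE, channelNames = paste0("ch", seq_len(m)))
}

# brute-force per-voxel three-plane LBP oracle (double loop, no
# vectorization); mirrors the documented bit order E, NE, N, NW, W,
# SW, S, SE with ">=" comparison
lbpOracle <- function(intensity, labels, regionIds) {
  d <- dim(intensity)
  offs <- list(c(1, 0), c(1, 1), c(0, 1), c(-1, 1),
               c(-1, 0), c(-1, -1), c(0, -1), c(1, -1))
  planes <- list(xy = c(1, 2), xz = c(1, 3), yz = c(2, 3))
  out <- lapply(regionIds, function(i)
    stats::setNames(numeric(768),
                    paste0(rep(names(planes), each = 256), ":", 0:255)))
  names(out) <- as.character(regionIds)
  for (pi in seq_along(planes)) {
    ax <- planes[[pi]]
    hist <- matrix(0, length(regionIds), 256)
    for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
      pos <- c(x, y, z)
      if (pos[ax[1]] < 2 || pos[ax[1]] > d[ax[1]] - 1) next
      if (pos[ax[2]] < 2 || pos[ax[2]] > d[ax[2]] - 1) next
      lab <- labels[x, y, z]
      ri <- match(lab, regionIds)
      if (is.na(ri)) next
      code <- 0L
      for (b in seq_along(offs)) {
        np <- pos
        np[ax[1]] <- np[ax[1]] + offs[[b]][1]
        np[ax[2]] <- np[ax[2]] + offs[[b]][2]
        if (intensity[np[1], np[2], np[3]] >=
            intensity[x, y, z])
          code <- code + 2L^(b - 1L)
      }
      hist[ri, code + 1L] <- hist[ri, code + 1L] + 1
    }
    for (ri in seq_along(regionIds)) {
      h <- hist[ri, ]
      if (sum(h) > 0) h <- h / sum(h)
      out[[ri]][(pi - 1L) * 256L + 1:256] <- h
    }
  }
  out
}

# draw n samples from a generalized Gaussian with scale alpha, shape
# beta via the gamma representation
rggd <- function(n, alpha, beta) {
  g <- rgamma(n, shape = 1 / beta, rate = 1)
  alpha * g^(1 / beta) * sample(c(-1, 1), n, replace = TRUE)
}

# minimal decline assignment table for the neuropsych generator
makeAssign <- function(n, decliners = integer(0), domain = "executive") {
  a <- data.frame(participant_id = sprintf("P%03d", seq_len(n)),
                  group = "HC", executive = 0L,
                  visual_verbal_memory = 0L, divided_attention = 0L,
                  depression = 0L)
  a[[domain]][decliners] <- 1L
  a
}

# small participant-level sample table with planted informative
# features among Gaussian noise
plantedTable <- function(nPer = 10L, nNoise = 20L, nInf = 2L,
                         effect = 3, seed = 1L) {
  set.seed(seed)
  n <- 2L * nPer
  lab <- rep(c(1L, 0L), each = nPer)
  x <- matrix(rnorm(n * (nNoise + nInf)), n)
  colnames(x) <- c(paste0("inf", seq_len(nInf)),
                   paste0("noise", seq_len(nNoise)))
  x[, seq_len(nInf)] <- x[, seq_len(nInf)] + effect * lab
  rownames(x) <- sprintf("P%03d", seq_len(n))
  labels <- data.frame(participant_id = rownames(x), label = lab)
  assembleSamples(psyFeatures = x, labels = labels)
}
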