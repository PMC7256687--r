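#' Construct a labeled volume
#'
#' @param intensity 3D numeric array.
#' @param labels 3D integer array of the same shape, 0 = background.
#' @param voxelSize voxel edge lengths in mm.
#' @param labelDict named character vector mapping label id (name) to
#'   region name; defaults to "region<k>" for every nonzero label found.
#' @return a \linkS4class{LabeledVolume}.
#' @export
labeledVolume <- function(intensity, labels, voxelSize = c(1, 1, 1),
                          labelDict = NULL) {
  storage.mode(labels) <- "integer"
  if (is.null(labelDict)) {
    ids <- sort(unique(as.integer(labels)))
    ids <- ids[ids > 0L]
    labelDict <- stats::setNames(paste0("region", ids), ids)
  }
  new("LabeledVolume", intensity = intensity, labels = labels,
      voxelSize = as.numeric(voxelSize), labelDict = labelDict)
}

#' Normalized region volumetry
#'
#' Fraction of the total segmented (nonzero-label) volume occupied by
#' each region: the normalizer is global brain volume, i.e. the sum of
#' all segmented region volumes, not total intracranial volume.
#'
#' @param volume a \linkS4class{LabeledVolume}.
#' @return named numeric vector (region names), summing to 1.
#' @export
normalizedVolumetry <- function(volume) {
  stopifnot(is(volume, "LabeledVolume"))
  ids <- as.integer(names(volume@labelDict))
  if (!length(ids) || !any(volume@labels > 0L))
    stop("labeling is empty: no nonzero labels")
  counts <- tabulate(volume@labels[volume@labels > 0L], nbins = max(ids))
  counts <- counts[ids]
  tot <- sum(counts)
  stats::setNames(counts / tot, unname(volume@labelDict))
}

# code array for one plane: for every voxel with all 8 in-plane
# neighbors inside the volume, the 8-bit comparison code. Neighbor bit
# order (least significant first): E, NE, N, NW, W, SW, S, SE in the
# (first axis, second axis) coordinates of the plane.
lbpPlaneCodes <- function(intensity, axes) {
  d <- dim(intensity)
  offs <- list(c(1, 0), c(1, 1), c(0, 1), c(-1, 1),
               c(-1, 0), c(-1, -1), c(0, -1), c(1, -1))
  idx <- lapply(1:3, function(a) seq_len(d[a]))
  inner <- idx
  inner[[axes[1]]] <- 2:(d[axes[1]] - 1L)
  inner[[axes[2]]] <- 2:(d[axes[2]] - 1L)
  center <- intensity[inner[[1]], inner[[2]], inner[[3]], drop = FALSE]
  code <- array(0L, dim = dim(center))
  for (b in seq_along(offs)) {
    sh <- inner
    sh[[axes[1]]] <- inner[[axes[1]]] + offs[[b]][1]
    sh[[axes[2]]] <- inner[[axes[2]]] + offs[[b]][2]
    nb <- intensity[sh[[1]], sh[[2]], sh[[3]], drop = FALSE]
    code <- code + bitwShiftL(1L, b - 1L) * (nb >= center)
  }
  list(code = code, inner = inner)
}

#' Region-based three-plane 3D local binary patterns
#'
#' For each voxel, plain (non-uniform) 8-neighbor radius-1 LBP codes are
#' computed on the three orthogonal planes (xy, xz, yz) through that
#' voxel. Per region, the three 256-bin code histograms over voxels whose
#' center lies in the region mask are normalized to frequencies and
#' concatenated, giving 768 values per region. Voxels whose in-plane
#' neighborhood leaves the volume do not contribute to that plane's
#' histogram; a region with no valid voxels on a plane yields a zero
#' histogram with a warning.
#'
#' @param volume a \linkS4class{LabeledVolume} (at least 3 voxels per
#'   axis).
#' @return named list: region name -> named length-768 numeric vector
#'   (names "xy:0".."yz:255").
#' @export
lbp3dRegion <- function(volume) {
  stopifnot(is(volume, "LabeledVolume"))
  if (any(dim(volume@intensity) < 3L))
    stop("volume must be at least 3 voxels along every axis")
  planes <- list(xy = c(1L, 2L), xz = c(1L, 3L), yz = c(2L, 3L))
  ids <- as.integer(names(volume@labelDict))
  out <- lapply(ids, function(i)
    stats::setNames(numeric(768),
                    paste0(rep(names(planes), each = 256), ":", 0:255)))
  names(out) <- unname(volume@labelDict)
  for (pi in seq_along(planes)) {
    pc <- lbpPlaneCodes(volume@intensity, planes[[pi]])
    lab <- volume@labels[pc$inner[[1]], pc$inner[[2]], pc$inner[[3]],
                         drop = FALSE]
    for (k in seq_along(ids)) {
      sel <- lab == ids[k]
      cnt <- tabulate(pc$code[sel] + 1L, nbins = 256L)
      tot <- sum(cnt)
      if (tot == 0L) {
        warning(sprintf(
          "region %s has no valid %s-plane neighborhoods: zero histogram",
          names(out)[k], names(planes)[pi]))
      } else {
        cnt <- cnt / tot
      }
      out[[k]][(pi - 1L) * 256L + seq_len(256L)] <- cnt
    }
  }
  out
}

# circular shift of a 3D array along one axis: result[t] = x[t - d]
shiftAxis <- function(x, axis, d) {
  n <- dim(x)[axis]
  ord <- ((seq_len(n) - 1L - d) %% n) + 1L
  idx <- lapply(dim(x), seq_len)
  idx[[axis]] <- ord
  x[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

# one undecimated Haar analysis step along one axis with dilation d:
# low  = (x + shift(x, d)) / sqrt(2)
# high = (x - shift(x, d)) / sqrt(2)
# Perfect reconstruction: x = (low + high) / sqrt(2).
swtStep <- function(x, axis, d) {
  s <- shiftAxis(x, axis, d)
  list(L = (x + s) / sqrt(2), H = (x - s) / sqrt(2))
}

#' 3D stationary (undecimated) Haar wavelet transform
#'
#' Separable a-trous decomposition: at level l the Haar pair is applied
#' along x, y and z with dilation 2^(l-1), producing the 8 low/high
#' combinations per level; deeper levels decompose the previous level's
#' all-lowpass (LLL) subband. Periodic boundary handling; each level is
#' perfectly reconstructable from its 8 subbands.
#'
#' @param x 3D numeric array with every dimension >= 2^levels.
#' @param levels decomposition depth (default 2).
#' @return named list of subband arrays, names "l<level>_<XYZ>" with
#'   X,Y,Z in \{L,H\} (e.g. "l1_LLL", "l2_HLH"), 8 per level.
#' @export
swt3dHaar <- function(x, levels = 2L) {
  stopifnot(length(dim(x)) == 3L)
  if (any(dim(x) < 2^levels))
    stop("volume dimensions must be at least 2^levels")
  out <- list()
  approx <- x
  for (l in seq_len(levels)) {
    d <- 2L^(l - 1L)
    sx <- swtStep(approx, 1L, d)
    for (cx in c("L", "H")) {
      sy <- swtStep(sx[[cx]], 2L, d)
      for (cy in c("L", "H")) {
        sz <- swtStep(sy[[cy]], 3L, d)
        for (cz in c("L", "H"))
          out[[sprintf("l%d_%s%s%s", l, cx, cy, cz)]] <- sz[[cz]]
      }
    }
    approx <- out[[sprintf("l%d_LLL", l)]]
  }
  out
}

#' Fit a generalized Gaussian density by moment matching
#'
#' Zero-mean GGD with scale \eqn{\alpha} and shape \eqn{\beta}:
#' with \eqn{m_1 = E|x|} and \eqn{m_2 = E x^2}, the shape solves
#' \eqn{\Gamma(2/\beta)^2 / (\Gamma(1/\beta)\Gamma(3/\beta)) = m_1^2/m_2}
#' by monotone root finding on \eqn{\beta \in [0.05, 20]}, and
#' \eqn{\alpha = m_1 \Gamma(1/\beta)/\Gamma(2/\beta)}. \eqn{\beta = 2}
#' is Gaussian, \eqn{\beta = 1} Laplacian.
#'
#' @param samples numeric vector with at least 2 distinct values.
#' @return named numeric c(alpha, beta); attribute \code{flag} is set to
#'   "boundary" when the moment ratio falls outside the solvable range
#'   and the boundary shape is returned.
#' @export
fitGeneralizedGaussian <- function(samples) {
  samples <- samples[is.finite(samples)]
  if (length(unique(samples)) < 2L)
    stop("degenerate sample: need at least 2 distinct values")
  m1 <- mean(abs(samples))
  m2 <- mean(samples^2)
  r <- m1^2 / m2
  gfun <- function(b) exp(2 * lgamma(2 / b) - lgamma(1 / b) - lgamma(3 / b))
  lo <- 0.05
  hi <- 20
  flag <- NULL
  if (r <= gfun(lo)) {
    beta <- lo
    flag <- "boundary"
  } else if (r >= gfun(hi)) {
    beta <- hi
    flag <- "boundary"
  } else {
    beta <- stats::uniroot(function(b) gfun(b) - r, c(lo, hi),
                           tol = 1e-10)$root
  }
  alpha <- m1 * exp(lgamma(1 / beta) - lgamma(2 / beta))
  out <- c(alpha = alpha, beta = beta)
  if (!is.null(flag)) attr(out, "flag") <- flag
  out
}

#' Per-region stationary-wavelet GGD texture features
#'
#' Decomposes the intensity volume with [swt3dHaar()] and, for every
#' region x subband, fits a zero-mean generalized Gaussian to the
#' coefficients under the region mask. All-lowpass (LLL) subbands are
#' mean-centered per region before fitting; detail subbands are fitted
#' as-is. Regions with fewer than \code{minVoxels} voxels are kept but
#' flagged unreliable via a message.
#'
#' @param volume a \linkS4class{LabeledVolume}.
#' @param levels SWT depth (default 2, giving 16 subbands and 32
#'   parameters per region).
#' @param minVoxels reliability floor for the per-region fits.
#' @return named list: region name -> named numeric vector
#'   ("l1_LLL:alpha", "l1_LLL:beta", ...).
#' @export
swtRegionFeatures <- function(volume, levels = 2L, minVoxels = 30L) {
  stopifnot(is(volume, "LabeledVolume"))
  sub <- swt3dHaar(volume@intensity, levels = levels)
  ids <- as.integer(names(volume@labelDict))
  regions <- unname(volume@labelDict)
  masks <- lapply(ids, function(i) volume@labels == i)
  small <- vapply(masks, sum, 0L) < minVoxels
  if (any(small))
    message(sprintf("region(s) %s have < %d voxels: GGD fits unreliable",
                    paste(regions[small], collapse = ", "), minVoxels))
  out <- vector("list", length(ids))
  names(out) <- regions
  for (k in seq_along(ids)) {
    v <- numeric(0)
    for (sb in names(sub)) {
      x <- sub[[sb]][masks[[k]]]
      if (grepl("_LLL$", sb)) x <- x - mean(x)
      par <- tryCatch(fitGeneralizedGaussian(x),
                      error = function(e) c(alpha = NA_real_,
                                            beta = NA_real_))
      v <- c(v, stats::setNames(as.numeric(par),
                                paste0(sb, ":", c("alpha", "beta"))))
    }
    out[[k]] <- v
  }
  out
}

#' Flat MRI feature vector for one participant
#'
#' Concatenates the requested per-region descriptor families into one
#' named vector with identifiers \code{"vol:<region>"},
#' \code{"lbp:<region>:<plane>:<code>"} and
#' \code{"swt:<region>:<subband>:<param>"}.
#'
#' @param volume a \linkS4class{LabeledVolume}.
#' @param types subset of c("volumetry", "lbp", "swt").
#' @param levels SWT depth.
#' @return named numeric vector.
#' @export
mriFeatureVector <- function(volume,
                             types = c("volumetry", "lbp", "swt"),
                             levels = 2L) {
  types <- match.arg(types, several.ok = TRUE)
  out <- numeric(0)
  if ("volumetry" %in% types) {
    v <- normalizedVolumetry(volume)
    out <- c(out, stats::setNames(as.numeric(v), paste0("vol:", names(v))))
  }
  if ("lbp" %in% types) {
    h <- lbp3dRegion(volume)
    for (r in names(h))
      out <- c(out, stats::setNames(as.numeric(h[[r]]),
                                    paste0("lbp:", r, ":", names(h[[r]]))))
  }
  if ("swt" %in% types) {
    s <- swtRegionFeatures(volume, levels = levels)
    for (r in names(s))
      out <- c(out, stats::setNames(as.numeric(s[[r]]),
                                    paste0("swt:", r, ":", names(s[[r]]))))
  }
  out
}
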