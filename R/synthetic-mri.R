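#' MRI generator settings
#'
#' @param dims volume dimensions in voxels (>= 16 each).
#' @param nRegions number of labeled regions (default 83).
#' @param grid number of parcel cells per axis; \code{prod(grid)} must be
#'   >= nRegions.
#' @param semiAxisFrac ellipsoid semi-axes as a fraction of the cell
#'   size.
#' @param jitterFrac center jitter as a fraction of the cell size;
#'   \code{semiAxisFrac + jitterFrac} must stay below 0.5 so parcels
#'   cannot overlap.
#' @param baseIntensity mean tissue intensity.
#' @param regionMeanSD SD of per-region mean intensity offsets.
#' @param noiseSD voxelwise Gaussian noise SD.
#' @param textureContrast amplitude of the per-region oriented grating.
#' @param volumePerturbSD participant-level fractional jitter of region
#'   semi-axes.
#' @return list of settings for [generateLabeledVolume()].
#' @export
mriSpec <- function(dims = c(48L, 48L, 48L), nRegions = 83L,
                    grid = c(5L, 5L, 4L), semiAxisFrac = 0.35,
                    jitterFrac = 0.1, baseIntensity = 100,
                    regionMeanSD = 15, noiseSD = 4,
                    textureContrast = 6, volumePerturbSD = 0.04) {
  if (any(dims < 16L)) stop("volume dimensions must be >= 16 voxels")
  list(dims = dims, nRegions = nRegions, grid = grid,
       semiAxisFrac = semiAxisFrac, jitterFrac = jitterFrac,
       baseIntensity = baseIntensity, regionMeanSD = regionMeanSD,
       noiseSD = noiseSD, textureContrast = textureContrast,
       volumePerturbSD = volumePerturbSD)
}

#' Generate a synthetic labeled intensity volume
#'
#' Regions are ellipsoidal parcels on a jittered grid packed into the
#' field of view; real atlas geometry is irrelevant to the feature math,
#' which only sees label-masked statistics. Each region gets its own
#' mean intensity, an oriented sinusoidal grating texture and Gaussian
#' noise. A participant effect can scale designated region volumes and
#' shift their texture contrast (the planted decline signature).
#'
#' The parcel geometry (cell assignment, jitter, orientation) is drawn
#' from an atlas-level seed so that all participants share one parcel
#' layout; sizes, intensities and noise vary per participant.
#'
#' @param spec settings from [mriSpec()].
#' @param participantEffect optional list with \code{volumeScale} and/or
#'   \code{textureShift}: named numeric vectors keyed by region id
#'   (integer as character), a multiplicative semi-axis factor and an
#'   additive grating amplitude respectively.
#' @param seed participant-level seed.
#' @param atlasSeed seed fixing the shared parcel layout.
#' @return a \linkS4class{LabeledVolume}.
#' @export
generateLabeledVolume <- function(spec = mriSpec(),
                                  participantEffect = NULL, seed = 1L,
                                  atlasSeed = 99L) {
  if (spec$nRegions < 1L) stop("label set must be nonempty")
  nCells <- prod(spec$grid)
  if (spec$nRegions > nCells)
    stop(sprintf(
      "cannot pack regions %s: only %d grid cells for %d regions",
      paste(seq(nCells + 1L, spec$nRegions), collapse = ", "),
      nCells, spec$nRegions))
  if (spec$semiAxisFrac + spec$jitterFrac >= 0.5)
    stop("semiAxisFrac + jitterFrac must be < 0.5 to avoid parcel overlap")
  dims <- spec$dims
  cell <- dims / spec$grid

  # shared atlas layout
  set.seed(deriveSeed(atlasSeed, 1L))
  cells <- as.matrix(expand.grid(seq_len(spec$grid[1]),
                                 seq_len(spec$grid[2]),
                                 seq_len(spec$grid[3])))
  cells <- cells[sample(nCells, spec$nRegions), , drop = FALSE]
  centers <- sweep(cells - 0.5, 2L, cell, "*") +
    matrix(runif(spec$nRegions * 3L, -spec$jitterFrac, spec$jitterFrac),
           ncol = 3L) %*% diag(cell)
  baseAxes <- matrix(rep(cell * spec$semiAxisFrac, each = spec$nRegions),
                     ncol = 3L) *
    matrix(runif(spec$nRegions * 3L, 0.8, 1), ncol = 3L)
  orient <- matrix(rnorm(spec$nRegions * 3L), ncol = 3L)
  orient <- orient / sqrt(rowSums(orient^2))
  gratingFreq <- runif(spec$nRegions, 0.5, 1.2)   # cycles per voxel * 2pi
  regionMean <- rnorm(spec$nRegions, 0, spec$regionMeanSD)

  # participant-level variation
  set.seed(deriveSeed(seed, 2L))
  axScale <- 1 + rnorm(spec$nRegions, 0, spec$volumePerturbSD)
  contrast <- rep(spec$textureContrast, spec$nRegions)
  if (!is.null(participantEffect)) {
    vs <- participantEffect$volumeScale
    if (!is.null(vs)) {
      i <- as.integer(names(vs))
      axScale[i] <- axScale[i] * as.numeric(vs)
    }
    ts <- participantEffect$textureShift
    if (!is.null(ts)) {
      i <- as.integer(names(ts))
      contrast[i] <- contrast[i] + as.numeric(ts)
    }
  }

  labels <- array(0L, dim = dims)
  intensity <- array(rnorm(prod(dims), spec$baseIntensity, spec$noiseSD),
                     dim = dims)
  for (rgn in seq_len(spec$nRegions)) {
    ax <- baseAxes[rgn, ] * axScale[rgn]
    lo <- pmax(floor(centers[rgn, ] - ax), 1)
    hi <- pmin(ceiling(centers[rgn, ] + ax), dims)
    xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
    # voxel coordinates over the bounding box
    co <- expand.grid(x = xs, y = ys, z = zs)
    dd <- ((co$x - centers[rgn, 1]) / ax[1])^2 +
          ((co$y - centers[rgn, 2]) / ax[2])^2 +
          ((co$z - centers[rgn, 3]) / ax[3])^2
    inside <- dd <= 1
    if (!any(inside)) next
    sel <- cbind(co$x, co$y, co$z)[inside, , drop = FALSE]
    labels[sel] <- rgn
    phase <- gratingFreq[rgn] *
      (sel %*% orient[rgn, ])
    intensity[sel] <- intensity[sel] + regionMean[rgn] +
      contrast[rgn] * sin(phase)
  }
  labeledVolume(intensity, labels,
                labelDict = stats::setNames(
                  paste0("region", seq_len(spec$nRegions)),
                  seq_len(spec$nRegions)))
}
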