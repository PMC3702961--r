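## Seed-based confidence-connected region growing: the coarse
## structure-of-interest segmentation driven by a single click. The goal is
## not anatomical accuracy but a bone-dominated voxel sample for the rigid
## fit, so parameters are deliberately conservative and growth is clamped
## to a box around the seed.

#' GrowParams: region-growing parameters
#'
#' Defaults follow the interactive prototype's settings: multiplier 1,
#' one statistics-refresh iteration, a 2-voxel initial spherical
#' neighborhood, a 10 cm box (half-width 50 mm) around the seed, and a
#' replace value equal to the data maximum (used only when exporting the
#' mask as a volume).
#'
#' @slot multiplier acceptance half-width in standard deviations (> 0).
#' @slot nIterations statistics-refresh passes after the initial growth (>= 0).
#' @slot initialRadius seed neighborhood radius in voxels (>= 1).
#' @slot boxHalfWidth half-width of the clamping box, mm (> 0).
#' @slot replaceValue foreground value for mask export (`NA` = data maximum).
#' @seealso [growParams()], [confidenceConnected()]
#' @export
setClass("GrowParams",
  representation(multiplier = "numeric", nIterations = "integer",
                 initialRadius = "numeric", boxHalfWidth = "numeric",
                 replaceValue = "numeric"))

setValidity("GrowParams", function(object) {
  msg <- character()
  if (object@multiplier <= 0) msg <- c(msg, "multiplier must be > 0")
  if (object@nIterations < 0L) msg <- c(msg, "nIterations must be >= 0")
  if (object@initialRadius < 1) msg <- c(msg, "initialRadius must be >= 1")
  if (object@boxHalfWidth <= 0) msg <- c(msg, "boxHalfWidth must be > 0")
  if (length(msg)) msg else TRUE
})

#' @rdname GrowParams-class
#' @param multiplier,nIterations,initialRadius,boxHalfWidth,replaceValue
#'   see slots above.
#' @return A [GrowParams-class] object.
#' @export
growParams <- function(multiplier = 1, nIterations = 1L, initialRadius = 2,
                       boxHalfWidth = 50, replaceValue = NA_real_) {
  new("GrowParams", multiplier = as.numeric(multiplier),
      nIterations = as.integer(nIterations),
      initialRadius = as.numeric(initialRadius),
      boxHalfWidth = as.numeric(boxHalfWidth),
      replaceValue = as.numeric(replaceValue))
}

## vectorized frontier flood fill, 6-connectivity, over a 3D logical
## acceptance array; the seed voxel is always included and expanded from,
## neighbours are admitted only when accepted
floodFill6 <- function(accept, seedIdx1) {
  d <- dim(accept)
  nx <- d[1L]; nxy <- d[1L] * d[2L]
  visited <- array(FALSE, d)
  seedLin <- seedIdx1[1L] + nx * (seedIdx1[2L] - 1L) + nxy * (seedIdx1[3L] - 1L)
  visited[seedLin] <- TRUE
  frontier <- seedLin
  while (length(frontier)) {
    f0 <- frontier - 1L
    i <- f0 %% nx
    j <- (f0 %/% nx) %% d[2L]
    k <- f0 %/% nxy
    cand <- c(frontier[i > 0L] - 1L, frontier[i < nx - 1L] + 1L,
              frontier[j > 0L] - nx, frontier[j < d[2L] - 1L] + nx,
              frontier[k > 0L] - nxy, frontier[k < d[3L] - 1L] + nxy)
    cand <- unique(cand)
    cand <- cand[accept[cand] & !visited[cand]]
    visited[cand] <- TRUE
    frontier <- cand
  }
  visited   # contains only accepted reachable voxels, plus always the seed
}

## unbiased sample standard deviation, 0 for n = 1
sampleSd <- function(x) if (length(x) < 2L) 0 else stats::sd(x)

#' Confidence-connected region growing from a seed point
#'
#' Implements the one-click segmentation stage, following the reference
#' ITK semantics of the algorithm voxel-for-voxel: (1) clamp computation
#' to the axis-aligned box of half-width `boxHalfWidth` mm centred on the
#' seed (clipped at volume borders); (2) estimate mean and (unbiased)
#' standard deviation of the intensities in the cubic
#' `(2 * initialRadius + 1)^3` neighborhood around the seed; (3) widen the
#' acceptance interval `[mu - multiplier * sigma, mu + multiplier * sigma]`
#' so it contains the seed's own intensity (plus an absolute epsilon of
#' 1e-6 so a zero-variance neighborhood still accepts exactly-equal float
#' intensities); (4) flood-fill with 6-connectivity from the seed;
#' (5) `nIterations` times, recompute mu and sigma over the current mask
#' and regrow from scratch from the seed, again with a seed-inclusive
#' interval. The returned mask lives on the full grid (false outside the
#' box) and always contains the seed voxel.
#'
#' @param volume an [ImageVolume-class].
#' @param seed seed point, world mm; must lie inside the volume.
#' @param params a [GrowParams-class].
#' @return A [MaskVolume-class] on `volume`'s grid.
#' @examples
#' vol <- generatePhantom(phantomSpec(gridShape = c(32, 32, 48),
#'                                    noiseSigma = 0))@baseline
#' seed <- origin(vol) + spacing(vol) * c(9, 16, 24)
#' mask <- confidenceConnected(vol, seed)
#' @export
confidenceConnected <- function(volume, seed, params = growParams()) {
  d <- dim(volume@data)
  seedIdx <- round(worldToIndex(volume, seed))[1L, ]
  if (any(seedIdx < 0) || any(seedIdx > d - 1L))
    stop("SeedOutsideVolume: seed (", paste(seed, collapse = ", "),
         ") mm is outside the volume extent")

  ## box bounds in 0-based indices, voxel centres within the world box
  lo <- pmax(0, ceiling((as.numeric(seed) - params@boxHalfWidth -
                         volume@origin) / volume@spacing - 1e-9))
  hi <- pmin(d - 1L, floor((as.numeric(seed) + params@boxHalfWidth -
                            volume@origin) / volume@spacing + 1e-9))
  lo <- pmin(lo, seedIdx); hi <- pmax(hi, seedIdx)
  sub <- volume@data[(lo[1L] + 1L):(hi[1L] + 1L),
                     (lo[2L] + 1L):(hi[2L] + 1L),
                     (lo[3L] + 1L):(hi[3L] + 1L), drop = FALSE]
  subSeed <- as.integer(seedIdx - lo + 1L)   # 1-based within crop
  sd3 <- dim(sub)

  ## cubic seed neighborhood of radius `initialRadius` voxels, box-clipped
  ri <- floor(params@initialRadius)
  offs <- as.matrix(expand.grid(i = -ri:ri, j = -ri:ri, k = -ri:ri))
  nb <- sweep(offs, 2L, subSeed, "+")
  ok <- nb[, 1L] >= 1L & nb[, 1L] <= sd3[1L] &
        nb[, 2L] >= 1L & nb[, 2L] <= sd3[2L] &
        nb[, 3L] >= 1L & nb[, 3L] <= sd3[3L]
  nbVals <- sub[nb[ok, , drop = FALSE]]

  eps <- 1e-6
  seedVal <- sub[subSeed[1L], subSeed[2L], subSeed[3L]]
  seedInterval <- function(mu, sigma) {
    c(min(mu - params@multiplier * sigma, seedVal) - eps,
      max(mu + params@multiplier * sigma, seedVal) + eps)
  }
  iv <- seedInterval(mean(nbVals), sampleSd(nbVals))
  mask <- floodFill6(sub >= iv[1L] & sub <= iv[2L], subSeed)
  for (it in seq_len(params@nIterations)) {
    vals <- sub[mask]
    iv <- seedInterval(mean(vals), sampleSd(vals))
    mask <- floodFill6(sub >= iv[1L] & sub <= iv[2L], subSeed)
  }

  full <- array(FALSE, d)
  full[(lo[1L] + 1L):(hi[1L] + 1L), (lo[2L] + 1L):(hi[2L] + 1L),
       (lo[3L] + 1L):(hi[3L] + 1L)] <- mask
  maskVolume(full, volume@spacing, volume@origin)
}

#' Dice similarity coefficient between two masks
#'
#' @param a,b [MaskVolume-class] objects on the same grid.
#' @return `2 |A intersect B| / (|A| + |B|)`, in `[0, 1]`.
#' @export
diceCoefficient <- function(a, b) {
  if (!identical(dim(a@data), dim(b@data)))
    stop("GridMismatch: masks must share grid shape")
  2 * sum(a@data & b@data) / (sum(a@data) + sum(b@data))
}
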