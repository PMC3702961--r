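## The one-click pipeline core: mask voxels -> point pairs through the
## deformation field -> closed-form unit-quaternion rigid fit -> rigid
## resampling of the follow-up onto the baseline grid.

sameGridGeom <- function(aDim, aSp, aOr, bDim, bSp, bOr) {
  identical(as.integer(aDim), as.integer(bDim)) &&
    max(abs(aSp - bSp)) < 1e-9 && max(abs(aOr - bOr)) < 1e-6
}

#' Extract baseline/follow-up point pairs from a mask and field
#'
#' For every foreground voxel with world centre `x`, pairs `x` with
#' `x + d(x)` using the on-grid field value at that voxel (mask voxels are
#' grid points, so no interpolation is involved).
#'
#' @param mask a [MaskVolume-class] on the field's grid.
#' @param field a [DeformationField-class].
#' @return A [PointPairs-class] with one pair per foreground voxel.
#' @export
extractPointPairs <- function(mask, field) {
  if (!sameGridGeom(dim(mask@data), mask@spacing, mask@origin,
                    dim(field@vectors)[1:3], field@spacing, field@origin))
    stop("GridMismatch: mask and field must share grid shape, spacing, origin")
  lin <- which(mask@data)
  if (length(lin) == 0L) stop("EmptyMask: mask has no foreground voxels")
  idx0 <- arrayInd(lin, dim(mask@data)) - 1L
  base <- indexToWorld(mask, idx0)
  nvox <- prod(dim(mask@data))
  disp <- cbind(field@vectors[lin], field@vectors[lin + nvox],
                field@vectors[lin + 2L * nvox])
  pointPairs(base, base + disp)
}

#' Closed-form least-squares rigid fit between paired point sets
#'
#' The landmark (absolute-orientation) transform: finds the proper rigid
#' transform (rotation + translation, no scaling, no reflection)
#' minimizing `sum_i || followup_i - (R baseline_i + t) ||^2`,
#' non-iteratively via the unit-quaternion eigen-decomposition: centroids
#' are subtracted, the 3 x 3 cross-covariance accumulated, the symmetric
#' 4 x 4 quaternion matrix assembled, the rotation taken as the
#' eigenvector of its largest eigenvalue, and
#' `t = followup centroid - R * baseline centroid`.
#'
#' Errors: `TooFewPoints` for N < 3; `DegenerateGeometry` when the
#' baseline points are (numerically) collinear, or when the two largest
#' eigenvalues tie (a 180-degree ambiguity), since the rotation is then
#' unidentifiable.
#'
#' @param pairs a [PointPairs-class].
#' @return A [RigidTransform-class] with non-negative quaternion w.
#' @examples
#' p <- matrix(rnorm(30), 10)
#' tr <- rigidAboutPoint(c(0, 0, 1), 30, shift = c(5, -2, 1))
#' estimateRigid(pointPairs(p, transformPoints(tr, p)))
#' @export
estimateRigid <- function(pairs) {
  P <- pairs@baselinePoints
  Q <- pairs@followupPoints
  n <- nrow(P)
  if (n < 3L)
    stop("TooFewPoints: rigid estimation needs at least 3 point pairs, got ", n)
  pc <- colMeans(P); qc <- colMeans(Q)
  Pc <- sweep(P, 2L, pc); Qc <- sweep(Q, 2L, qc)
  sv <- svd(Pc, nu = 0L, nv = 0L)$d
  if (sv[2L] < 1e-9 * max(sv[1L], 1))
    stop("DegenerateGeometry: baseline points are collinear; ",
         "rotation about the line is unidentifiable")
  S <- crossprod(Pc, Qc)   # S[i, j] = sum_k Pc[k, i] * Qc[k, j]
  N <- matrix(c(
    S[1,1] + S[2,2] + S[3,3], S[2,3] - S[3,2], S[3,1] - S[1,3], S[1,2] - S[2,1],
    S[2,3] - S[3,2], S[1,1] - S[2,2] - S[3,3], S[1,2] + S[2,1], S[3,1] + S[1,3],
    S[3,1] - S[1,3], S[1,2] + S[2,1], -S[1,1] + S[2,2] - S[3,3], S[2,3] + S[3,2],
    S[1,2] - S[2,1], S[3,1] + S[1,3], S[2,3] + S[3,2], -S[1,1] - S[2,2] + S[3,3]),
    nrow = 4L, byrow = TRUE)
  e <- eigen(N, symmetric = TRUE)
  scaleN <- max(abs(e$values), 1)
  if (e$values[1L] - e$values[2L] < 1e-9 * scaleN)
    stop("DegenerateGeometry: tied largest eigenvalues ",
         "(180-degree rotation ambiguity)")
  q <- e$vectors[, 1L]
  R <- quaternionToMatrix(q)
  rigidTransform(q, qc - as.vector(R %*% pc))
}

#' RMS residual of point pairs under a rigid transform
#'
#' @param pairs a [PointPairs-class].
#' @param transform a [RigidTransform-class] (identity by default, giving
#'   the raw baseline/follow-up RMS discrepancy).
#' @return RMS of `|| followup_i - (R baseline_i + t) ||` in mm.
#' @export
rmsResidual <- function(pairs, transform = rigidTransform()) {
  pred <- transformPoints(transform, pairs@baselinePoints)
  sqrt(mean(rowSums((pairs@followupPoints - pred)^2)))
}

#' Resample the follow-up volume through a rigid transform
#'
#' Pull-back sampling: for every voxel centre `x` of the target grid the
#' output takes `followup(T(x))` by trilinear interpolation, so the
#' follow-up appears aligned to the baseline after one interpolation pass
#' with no hole-filling.
#'
#' @param followup the follow-up [ImageVolume-class].
#' @param transform the baseline-to-follow-up [RigidTransform-class].
#' @param targetGrid geometry of the output grid (default: the follow-up's
#'   own grid; normally the baseline volume is passed).
#' @param background intensity used outside the follow-up extent.
#' @return An [ImageVolume-class] on `targetGrid`'s geometry.
#' @export
applyRigidResample <- function(followup, transform, targetGrid = followup,
                               background = 0) {
  pts <- gridPoints(targetGrid)
  vals <- sampleTrilinear(followup, transformPoints(transform, pts),
                          background)
  imageVolume(array(vals, dim(targetGrid)), spacing(targetGrid),
              origin(targetGrid))
}

withStage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", stage, "': ", conditionMessage(e), call. = FALSE))
}

#' One-click locally rigid match at a seed point
#'
#' Runs the full pipeline: confidence-connected region growing around the
#' seed, point-pair extraction through the deformation field, the
#' closed-form rigid fit, and rigid resampling of the follow-up volume
#' onto the baseline grid. Records the RMS point-pair discrepancy before
#' (`rmsBefore`) and after (`rmsAfter`) removing the fitted rigid
#' component; the least-squares property guarantees
#' `rmsAfter <= rmsBefore`. Stage errors are propagated with the failing
#' stage named.
#'
#' @param bundle a [DatasetBundle-class].
#' @param seed point of interest, world mm, inside the baseline extent.
#' @param params a [GrowParams-class].
#' @return A [MatchResult-class].
#' @examples
#' truth <- generatePhantom(phantomSpec(gridShape = c(32, 32, 48)))
#' seed <- with(truth@spec@bones[[1]], (a + b) / 2)
#' res <- matchAtPoint(phantomBundle(truth), seed)
#' res
#' @export
matchAtPoint <- function(bundle, seed, params = growParams()) {
  mask <- withStage("segmentation",
                    confidenceConnected(bundle@baseline, seed, params))
  pairs <- withStage("point matching", extractPointPairs(mask, bundle@field))
  transform <- withStage("rigid estimation", estimateRigid(pairs))
  resampled <- withStage("resampling",
                         applyRigidResample(bundle@followup, transform,
                                            bundle@baseline))
  new("MatchResult", mask = mask, transform = transform,
      resampledFollowup = resampled,
      rmsBefore = rmsResidual(pairs), rmsAfter = rmsResidual(pairs, transform),
      nPoints = nrow(pairs@baselinePoints))
}
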