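#' @import methods
NULL

setClassUnion("ImageVolumeOrNULL", "NULL")
setClassUnion("RigidTransformOrNULL", "NULL")

#' ImageVolume: a 3D scalar grid in world millimetres
#'
#' The basic unit every pipeline stage operates on: a 3D array of scalar
#' intensities on an axis-aligned grid with positive per-axis spacing (mm)
#' and a world origin (mm) at the centre of voxel index (0,0,0), so that
#' `world = origin + index * spacing` element-wise (indices are 0-based and
#' continuous). Oblique (non-identity direction) grids are not represented;
#' readers reject them.
#'
#' @slot data 3D numeric array of intensities (arbitrary units).
#' @slot spacing Numeric length-3, mm per voxel along each axis; all > 0.
#' @slot origin Numeric length-3, world coordinate (mm) of voxel (0,0,0).
#'
#' @seealso [imageVolume()], [worldToIndex()], [sampleTrilinear()]
#' @export
setClass("ImageVolume",
  representation(data = "array", spacing = "numeric", origin = "numeric"))

setValidity("ImageVolume", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, "data must be a 3D array")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 finite positive values")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be 3 finite values")
  if (length(dim(object@data)) == 3L && any(dim(object@data) < 1L))
    msg <- c(msg, "all dimensions must be >= 1")
  if (length(msg)) msg else TRUE
})

setIs("ImageVolume", "ImageVolumeOrNULL")

#' Construct an ImageVolume
#'
#' @param data 3D numeric array.
#' @param spacing mm per voxel (length 3, or scalar recycled).
#' @param origin world mm of voxel (0,0,0) (length 3, or scalar recycled).
#' @return An [ImageVolume-class] object.
#' @examples
#' vol <- imageVolume(array(0, c(8, 8, 8)), spacing = 1.5)
#' dim(vol)
#' @export
imageVolume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  new("ImageVolume", data = data, spacing = rep_len(as.numeric(spacing), 3L),
      origin = rep_len(as.numeric(origin), 3L))
}

#' DeformationField: dense per-voxel displacement (mm) on the baseline grid
#'
#' Stores one 3-vector per voxel; the field maps a baseline world point `x`
#' to the corresponding follow-up world point `x + d(x)` (the fixed-to-moving
#' convention of the deformable registration that produced it).
#'
#' @slot vectors 4D numeric array, dims `c(nx, ny, nz, 3)`, displacement mm.
#' @slot spacing,origin Grid geometry as for [ImageVolume-class].
#'
#' @seealso [deformationField()], [sampleField()]
#' @export
setClass("DeformationField",
  representation(vectors = "array", spacing = "numeric", origin = "numeric"))

setValidity("DeformationField", function(object) {
  msg <- character()
  d <- dim(object@vectors)
  if (length(d) != 4L || d[4L] != 3L)
    msg <- c(msg, "vectors must be a 4D array with 3 components per voxel")
  if (any(!is.finite(object@vectors)))
    msg <- c(msg, "displacements must be finite")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive values")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be 3 finite values")
  if (length(msg)) msg else TRUE
})

#' Construct a DeformationField
#'
#' @param vectors 4D array `c(nx, ny, nz, 3)` of displacements in mm.
#' @param spacing,origin grid geometry (as [imageVolume()]).
#' @return A [DeformationField-class] object.
#' @export
deformationField <- function(vectors, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  new("DeformationField", vectors = vectors,
      spacing = rep_len(as.numeric(spacing), 3L),
      origin = rep_len(as.numeric(origin), 3L))
}

#' MaskVolume: a boolean volume on its source grid
#'
#' Output of region growing, input to point-pair extraction. Shares the grid
#' (shape, spacing, origin) of the volume it was grown on.
#'
#' @slot data 3D logical array.
#' @slot spacing,origin Grid geometry as for [ImageVolume-class].
#' @export
setClass("MaskVolume",
  representation(data = "array", spacing = "numeric", origin = "numeric"))

setValidity("MaskVolume", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3L || !is.logical(object@data))
    msg <- c(msg, "data must be a 3D logical array")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive values")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be 3 finite values")
  if (length(msg)) msg else TRUE
})

#' Construct a MaskVolume
#'
#' @param data 3D logical array.
#' @param spacing,origin grid geometry of the source volume.
#' @return A [MaskVolume-class] object.
#' @export
maskVolume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  storage.mode(data) <- "logical"
  new("MaskVolume", data = data, spacing = rep_len(as.numeric(spacing), 3L),
      origin = rep_len(as.numeric(origin), 3L))
}

#' RigidTransform: unit quaternion + translation
#'
#' Maps baseline world coordinates into follow-up world coordinates as
#' `x' = R x + t`, with `R` the rotation encoded by a unit quaternion
#' `(w, x, y, z)` and `t` a translation in mm. Only proper rotations
#' (det R = +1, no scaling, no reflection) are representable. The stored
#' quaternion is normalized and has non-negative `w` (q and -q encode the
#' same rotation).
#'
#' @slot quaternion Numeric length-4 `(w, x, y, z)`, unit norm.
#' @slot translation Numeric length-3, mm.
#'
#' @seealso [rigidTransform()], [transformPoints()], [estimateRigid()]
#' @export
setClass("RigidTransform",
  representation(quaternion = "numeric", translation = "numeric"))

setValidity("RigidTransform", function(object) {
  msg <- character()
  q <- object@quaternion
  if (length(q) != 4L || any(!is.finite(q)))
    msg <- c(msg, "quaternion must be 4 finite values")
  else if (abs(sqrt(sum(q^2)) - 1) > 1e-9)
    msg <- c(msg, "quaternion must have unit norm (within 1e-9)")
  if (length(object@translation) != 3L || any(!is.finite(object@translation)))
    msg <- c(msg, "translation must be 3 finite values")
  if (length(msg)) msg else TRUE
})

setIs("RigidTransform", "RigidTransformOrNULL")

#' Construct a RigidTransform
#'
#' The quaternion is normalized and sign-fixed (w >= 0) on construction.
#'
#' @param quaternion length-4 `(w, x, y, z)`; need not be pre-normalized
#'   (but must be non-zero).
#' @param translation length-3 mm.
#' @return A [RigidTransform-class] object.
#' @examples
#' identityRigid <- rigidTransform()
#' quarterTurnZ <- rigidTransform(c(cos(pi / 4), 0, 0, sin(pi / 4)))
#' @export
rigidTransform <- function(quaternion = c(1, 0, 0, 0), translation = c(0, 0, 0)) {
  q <- as.numeric(quaternion)
  n <- sqrt(sum(q^2))
  if (!is.finite(n) || n < 1e-12)
    stop("quaternion must be non-zero")
  q <- q / n
  if (q[1L] < 0) q <- -q
  new("RigidTransform", quaternion = q,
      translation = rep_len(as.numeric(translation), 3L))
}

#' PointPairs: paired baseline / follow-up world coordinates
#'
#' The landmark set for the rigid fit: row i of `baselinePoints` corresponds
#' to row i of `followupPoints`.
#'
#' @slot baselinePoints,followupPoints N x 3 numeric matrices, world mm.
#' @seealso [extractPointPairs()], [estimateRigid()]
#' @export
setClass("PointPairs",
  representation(baselinePoints = "matrix", followupPoints = "matrix"))

setValidity("PointPairs", function(object) {
  msg <- character()
  b <- object@baselinePoints; f <- object@followupPoints
  if (ncol(b) != 3L || ncol(f) != 3L)
    msg <- c(msg, "point matrices must have 3 columns")
  if (nrow(b) != nrow(f))
    msg <- c(msg, "baseline and follow-up point counts must match")
  if (any(!is.finite(b)) || any(!is.finite(f)))
    msg <- c(msg, "points must be finite")
  if (length(msg)) msg else TRUE
})

#' Construct a PointPairs object
#' @param baselinePoints,followupPoints N x 3 matrices of world coordinates (mm).
#' @return A [PointPairs-class] object.
#' @export
pointPairs <- function(baselinePoints, followupPoints) {
  new("PointPairs", baselinePoints = baselinePoints,
      followupPoints = followupPoints)
}

#' DatasetBundle: the volumes and field of one baseline/follow-up comparison
#'
#' Baseline and follow-up primary (T1W-like) volumes, the dense deformation
#' field on the baseline grid, and optional secondary (STIR-like) channels
#' per timepoint.
#'
#' @slot baseline,followup [ImageVolume-class] objects.
#' @slot field [DeformationField-class] on the baseline grid.
#' @slot baselineSecondary,followupSecondary Optional [ImageVolume-class] or NULL.
#' @seealso [datasetBundle()], [readBundle()], [matchAtPoint()]
#' @export
setClass("DatasetBundle",
  representation(baseline = "ImageVolume", followup = "ImageVolume",
                 field = "DeformationField",
                 baselineSecondary = "ImageVolumeOrNULL",
                 followupSecondary = "ImageVolumeOrNULL"))

setValidity("DatasetBundle", function(object) {
  msg <- character()
  b <- object@baseline
  sameGrid <- function(dimA, spA, orA, dimB, spB, orB)
    identical(dimA, dimB) && max(abs(spA - spB)) < 1e-9 &&
      max(abs(orA - orB)) < 1e-6
  if (!sameGrid(dim(b@data), b@spacing, b@origin,
                dim(object@field@vectors)[1:3], object@field@spacing,
                object@field@origin))
    msg <- c(msg, "baseline and field must share grid shape, spacing, origin")
  if (!is.null(object@baselineSecondary) &&
      !sameGrid(dim(b@data), b@spacing, b@origin,
                dim(object@baselineSecondary@data),
                object@baselineSecondary@spacing,
                object@baselineSecondary@origin))
    msg <- c(msg, "baseline secondary channel must share the baseline grid")
  f <- object@followup
  if (!is.null(object@followupSecondary) &&
      !sameGrid(dim(f@data), f@spacing, f@origin,
                dim(object@followupSecondary@data),
                object@followupSecondary@spacing,
                object@followupSecondary@origin))
    msg <- c(msg, "follow-up secondary channel must share the follow-up grid")
  if (length(msg)) msg else TRUE
})

#' Construct a DatasetBundle
#'
#' @param baseline,followup [ImageVolume-class] objects.
#' @param field [DeformationField-class] on the baseline grid.
#' @param baselineSecondary,followupSecondary optional secondary channels.
#' @return A [DatasetBundle-class] object.
#' @export
datasetBundle <- function(baseline, followup, field,
                          baselineSecondary = NULL, followupSecondary = NULL) {
  new("DatasetBundle", baseline = baseline, followup = followup, field = field,
      baselineSecondary = baselineSecondary,
      followupSecondary = followupSecondary)
}

#' MatchResult: output of the one-click locally rigid match
#'
#' @slot mask The grown [MaskVolume-class] region of interest.
#' @slot transform The fitted [RigidTransform-class] (baseline to follow-up).
#' @slot resampledFollowup Follow-up volume resampled onto the baseline grid
#'   through the fitted transform.
#' @slot rmsBefore,rmsAfter RMS point-pair discrepancy (mm) before and after
#'   removing the rigid component; `rmsAfter <= rmsBefore` always.
#' @slot nPoints Number of point pairs used for the fit.
#' @seealso [matchAtPoint()]
#' @export
setClass("MatchResult",
  representation(mask = "MaskVolume", transform = "RigidTransform",
                 resampledFollowup = "ImageVolume",
                 rmsBefore = "numeric", rmsAfter = "numeric",
                 nPoints = "integer"))

setValidity("MatchResult", function(object) {
  if (object@rmsAfter > object@rmsBefore + 1e-9)
    "rmsAfter must not exceed rmsBefore"
  else TRUE
})

## ---- accessors ----

#' Grid and transform accessors
#'
#' `spacing`, `origin` return grid geometry; `volumeData` the raw array;
#' `quaternion`, `translation`, `rotationMatrix` the transform parameters.
#'
#' @param object an object of one of the package's S4 classes.
#' @return `spacing`/`origin`: numeric length-3. `volumeData`: the array.
#'   `quaternion`: numeric length-4 `(w,x,y,z)`. `translation`: length-3 mm.
#'   `rotationMatrix`: 3 x 3 orthonormal matrix with determinant +1.
#' @name accessors
#' @aliases spacing origin volumeData quaternion translation rotationMatrix
#' @examples
#' spacing(imageVolume(array(0, c(4, 4, 4)), spacing = 1.5))
#' rotationMatrix(rigidTransform(c(1, 0, 0, 1)))  # 90 degrees about z
NULL

#' @rdname accessors
#' @export
setGeneric("spacing", function(object) standardGeneric("spacing"))
#' @rdname accessors
#' @export
setGeneric("origin", function(object) standardGeneric("origin"))
#' @rdname accessors
#' @export
setGeneric("volumeData", function(object) standardGeneric("volumeData"))
#' @rdname accessors
#' @export
setGeneric("quaternion", function(object) standardGeneric("quaternion"))
#' @rdname accessors
#' @export
setGeneric("translation", function(object) standardGeneric("translation"))
#' @rdname accessors
#' @export
setGeneric("rotationMatrix", function(object) standardGeneric("rotationMatrix"))

#' @rdname accessors
setMethod("spacing", "ImageVolume", function(object) object@spacing)
#' @rdname accessors
setMethod("spacing", "DeformationField", function(object) object@spacing)
#' @rdname accessors
setMethod("spacing", "MaskVolume", function(object) object@spacing)
#' @rdname accessors
setMethod("origin", "ImageVolume", function(object) object@origin)
#' @rdname accessors
setMethod("origin", "DeformationField", function(object) object@origin)
#' @rdname accessors
setMethod("origin", "MaskVolume", function(object) object@origin)
#' @rdname accessors
setMethod("volumeData", "ImageVolume", function(object) object@data)
#' @rdname accessors
setMethod("volumeData", "MaskVolume", function(object) object@data)
#' @rdname accessors
setMethod("volumeData", "DeformationField", function(object) object@vectors)
#' @rdname accessors
setMethod("quaternion", "RigidTransform", function(object) object@quaternion)
#' @rdname accessors
setMethod("translation", "RigidTransform", function(object) object@translation)
#' @rdname accessors
setMethod("rotationMatrix", "RigidTransform",
          function(object) quaternionToMatrix(object@quaternion))

#' @rdname accessors
#' @param x an `ImageVolume`, `MaskVolume` or `DeformationField`.
#' @export
setMethod("dim", "ImageVolume", function(x) dim(x@data))
#' @rdname accessors
setMethod("dim", "MaskVolume", function(x) dim(x@data))
#' @rdname accessors
setMethod("dim", "DeformationField", function(x) dim(x@vectors)[1:3])

## ---- show methods ----

setMethod("show", "ImageVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("ImageVolume %d x %d x %d voxels, spacing (%g, %g, %g) mm\n",
              d[1], d[2], d[3], object@spacing[1], object@spacing[2],
              object@spacing[3]))
  cat(sprintf("  origin (%g, %g, %g) mm; intensity range [%g, %g]\n",
              object@origin[1], object@origin[2], object@origin[3],
              min(object@data), max(object@data)))
})

setMethod("show", "DeformationField", function(object) {
  d <- dim(object@vectors)
  mag <- sqrt(rowSums(matrix(object@vectors, ncol = 3L)^2))
  cat(sprintf("DeformationField %d x %d x %d voxels, spacing (%g, %g, %g) mm\n",
              d[1], d[2], d[3], object@spacing[1], object@spacing[2],
              object@spacing[3]))
  cat(sprintf("  |d| range [%.3g, %.3g] mm, mean %.3g mm\n",
              min(mag), max(mag), mean(mag)))
})

setMethod("show", "MaskVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("MaskVolume %d x %d x %d voxels, %d foreground (%.2f%%)\n",
              d[1], d[2], d[3], sum(object@data),
              100 * mean(object@data)))
})

setMethod("show", "RigidTransform", function(object) {
  q <- object@quaternion; t <- object@translation
  cat(sprintf("RigidTransform: rotation %.3f deg, quaternion (%.5f, %.5f, %.5f, %.5f)\n",
              rotationAngle(object), q[1], q[2], q[3], q[4]))
  cat(sprintf("  translation (%.3f, %.3f, %.3f) mm\n", t[1], t[2], t[3]))
})

setMethod("show", "PointPairs", function(object) {
  d <- object@followupPoints - object@baselinePoints
  mag <- sqrt(rowSums(d^2))
  cat(sprintf("PointPairs: %d pairs, displacement %.3g-%.3g mm (mean %.3g)\n",
              nrow(object@baselinePoints), min(mag), max(mag), mean(mag)))
})

setMethod("show", "MatchResult", function(object) {
  cat("Locally rigid match\n")
  cat(sprintf("  %d point pairs from a %d-voxel region\n", object@nPoints,
              sum(object@mask@data)))
  show(object@transform)
  cat(sprintf("  RMS discrepancy: %.4f mm before -> %.4f mm after rigid removal\n",
              object@rmsBefore, object@rmsAfter))
})

setMethod("show", "DatasetBundle", function(object) {
  d <- dim(object@baseline@data)
  cat(sprintf("DatasetBundle: %d x %d x %d baseline grid%s%s\n", d[1], d[2], d[3],
              if (!is.null(object@baselineSecondary)) " + secondary" else "",
              ""))
})
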