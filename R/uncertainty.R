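## Where is the locally rigid approximation trustworthy? The error field
## measures the absolute difference between the deformable mapping and its
## rigid approximation; radial iso-contours and the deformation-sphere
## residual cloud turn it into glanceable feedback around the point of
## interest.

#' UncertaintyContours: radial iso-contours of the rigid-approximation error
#'
#' For each of `nRays` equally spaced in-plane angles, `radii[ray, k]`
#' holds the first radius (mm) at which the error reaches
#' `thresholds[k]`, or `NA` when the ray stays below the threshold within
#' `maxRadius` ("open"). First crossings are monotone in the threshold,
#' so the contours nest by construction.
#'
#' @slot center contour centre, world mm.
#' @slot thresholds strictly increasing error levels, mm.
#' @slot angles ray angles, radians.
#' @slot radii `nRays x length(thresholds)` matrix of first-crossing radii.
#' @slot polylines per threshold, a list of 2-column matrices of in-plane
#'   (u, v) coordinates connecting consecutive non-open rays.
#' @slot axisU,axisV orthonormal in-plane axes.
#' @slot step,maxRadius ray-march discretization, mm.
#' @seealso [radialContours()]
#' @export
setClass("UncertaintyContours",
  representation(center = "numeric", thresholds = "numeric",
                 angles = "numeric", radii = "matrix", polylines = "list",
                 axisU = "numeric", axisV = "numeric", step = "numeric",
                 maxRadius = "numeric"))

setMethod("show", "UncertaintyContours", function(object) {
  cat(sprintf("UncertaintyContours at (%g, %g, %g) mm, %d rays\n",
              object@center[1], object@center[2], object@center[3],
              length(object@angles)))
  for (k in seq_along(object@thresholds)) {
    r <- object@radii[, k]
    cat(sprintf("  %g mm: %d/%d rays crossed, radius %s mm\n",
                object@thresholds[k], sum(!is.na(r)), length(r),
                if (all(is.na(r))) "-" else
                  sprintf("%.1f-%.1f", min(r, na.rm = TRUE),
                          max(r, na.rm = TRUE))))
  }
})

#' SphereSample: a deformation-sphere point cloud
#'
#' Points on a sphere in the baseline coordinate system, their positions
#' after warping through the deformation field, and the residual vectors
#' (after removing a rigid transform when one is supplied). Long residuals
#' mark genuinely non-rigid change.
#'
#' @slot baselinePoints,warpedPoints,residuals `n x 3` matrices, mm.
#' @slot center,radius sphere definition, mm.
#' @seealso [deformationSphere()]
#' @export
setClass("SphereSample",
  representation(baselinePoints = "matrix", warpedPoints = "matrix",
                 residuals = "matrix", center = "numeric",
                 radius = "numeric"))

setMethod("show", "SphereSample", function(object) {
  mag <- sqrt(rowSums(object@residuals^2))
  cat(sprintf("SphereSample: %d points, radius %g mm; residuals %.3g-%.3g mm (mean %.3g)\n",
              nrow(object@baselinePoints), object@radius, min(mag), max(mag),
              mean(mag)))
})

#' Rigid-approximation error field
#'
#' Per voxel `x` of `region`, the absolute difference (mm) between the
#' deformable mapping and its rigid approximation:
#' `e(x) = || (x + d(x)) - (R x + t) ||`. Zero wherever the field is
#' explained exactly by the transform.
#'
#' @param field a [DeformationField-class].
#' @param transform a [RigidTransform-class].
#' @param region grid geometry to evaluate on (default: the field's own
#'   grid); must lie within the field extent.
#' @return A scalar [ImageVolume-class] of errors in mm.
#' @export
errorField <- function(field, transform, region = NULL) {
  if (is.null(region)) {
    pts <- gridPoints(field)
    d <- matrix(field@vectors, ncol = 3L)
    geomDim <- dim(field@vectors)[1:3]
    sp <- field@spacing; or <- field@origin
  } else {
    pts <- gridPoints(region)
    d <- sampleField(field, pts)   # errors OutOfDomain beyond the field
    geomDim <- dim(region)
    sp <- spacing(region); or <- origin(region)
  }
  pred <- transformPoints(transform, pts)
  e <- sqrt(rowSums((pts + d - pred)^2))
  imageVolume(array(e, geomDim), sp, or)
}

#' Radial uncertainty iso-contours around a point
#'
#' Marches outward from `center` along `nRays` equally spaced angles in
#' the plane spanned by `axisU`/`axisV`, interpolating the error volume in
#' steps of `step` mm, and records per threshold the first radius at which
#' the error reaches it (independently per threshold, so the contours nest
#' even for non-monotone error profiles). Rays that never reach a
#' threshold within `maxRadius` (or that leave the error volume first) are
#' "open". Defaults: 360 rays (1 degree), 0.5 mm steps, 150 mm reach and
#' the 3 / 6 / 9 mm error levels used for reading follow-up alignment.
#'
#' @param error scalar error [ImageVolume-class] (see [errorField()]).
#' @param center contour centre, world mm, inside the error volume.
#' @param thresholds strictly increasing error levels, mm.
#' @param nRays number of rays.
#' @param step march step, mm.
#' @param maxRadius maximum search radius, mm.
#' @param axisU,axisV orthonormal plane axes (default axial).
#' @return An [UncertaintyContours-class].
#' @export
radialContours <- function(error, center, thresholds = c(3, 6, 9),
                           nRays = 360L, step = 0.5, maxRadius = 150,
                           axisU = c(1, 0, 0), axisV = c(0, 1, 0)) {
  if (any(diff(thresholds) <= 0) || length(thresholds) < 1L)
    stop("thresholds must be strictly increasing")
  if (abs(sum(axisU * axisV)) > 1e-9 ||
      abs(sqrt(sum(axisU^2)) - 1) > 1e-9 || abs(sqrt(sum(axisV^2)) - 1) > 1e-9)
    stop("InvalidPlane: axisU and axisV must be orthonormal")
  angles <- 2 * pi * (seq_len(nRays) - 1L) / nRays
  rs <- seq(step, maxRadius, by = step)
  dirU <- cos(angles); dirV <- sin(angles)
  ## nRays x nSteps sample lattice, flattened ray-major
  uu <- outer(dirU, rs); vv <- outer(dirV, rs)
  pts <- cbind(center[1L] + as.vector(uu) * axisU[1L] + as.vector(vv) * axisV[1L],
               center[2L] + as.vector(uu) * axisU[2L] + as.vector(vv) * axisV[2L],
               center[3L] + as.vector(uu) * axisU[3L] + as.vector(vv) * axisV[3L])
  vals <- matrix(sampleTrilinear(error, pts, background = NA_real_),
                 nrow = nRays)
  ## once a ray leaves the volume it stops: blank everything after first NA
  offGrid <- t(apply(is.na(vals), 1L, cummax)) > 0
  vals[offGrid] <- -Inf
  radii <- matrix(NA_real_, nRays, length(thresholds))
  for (k in seq_along(thresholds)) {
    hit <- vals >= thresholds[k]
    idx <- apply(hit, 1L, function(h) if (any(h)) which(h)[1L] else NA_integer_)
    radii[, k] <- rs[idx]
  }
  polylines <- lapply(seq_along(thresholds), function(k) {
    closed <- which(!is.na(radii[, k]))
    if (length(closed) == 0L) return(list())
    runs <- split(closed, cumsum(c(1L, diff(closed) != 1L)))
    lapply(unname(runs), function(ix)
      cbind(u = radii[ix, k] * dirU[ix], v = radii[ix, k] * dirV[ix]))
  })
  new("UncertaintyContours", center = as.numeric(center),
      thresholds = as.numeric(thresholds), angles = angles, radii = radii,
      polylines = polylines, axisU = as.numeric(axisU),
      axisV = as.numeric(axisV), step = step, maxRadius = maxRadius)
}

#' Deformation sphere: warp a spherical point cloud through the field
#'
#' Places `nPoints` points on a sphere around `center` by a deterministic
#' Fibonacci lattice (uniform without randomness), warps each through the
#' deformation field (`warped = p + d(p)`), and computes residual vectors:
#' `warped - (R p + t)` when a rigid transform is supplied (showing only
#' the deformation the rigid transform does not explain), else
#' `warped - p`.
#'
#' @param field a [DeformationField-class].
#' @param center sphere centre, world mm.
#' @param radius sphere radius, mm (default 20).
#' @param nPoints number of lattice points (default 200).
#' @param transform optional [RigidTransform-class] to remove.
#' @return A [SphereSample-class].
#' @export
deformationSphere <- function(field, center, radius = 20, nPoints = 200L,
                              transform = NULL) {
  i <- seq_len(nPoints) - 1L
  z <- 1 - (2 * i + 1) / nPoints
  phi <- i * pi * (3 - sqrt(5))
  s <- sqrt(pmax(0, 1 - z^2))
  p <- cbind(center[1L] + radius * s * cos(phi),
             center[2L] + radius * s * sin(phi),
             center[3L] + radius * z)
  warped <- p + sampleField(field, p)
  pred <- if (is.null(transform)) p else transformPoints(transform, p)
  new("SphereSample", baselinePoints = p, warpedPoints = warped,
      residuals = warped - pred, center = as.numeric(center),
      radius = as.numeric(radius))
}
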