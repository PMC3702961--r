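## Grid geometry, interpolation and rigid-transform algebra shared by all
## stages. Points are row vectors or N x 3 matrices of world coordinates (mm);
## continuous voxel indices are 0-based, voxel (0,0,0) centred at the origin.

asPointMatrix <- function(points) {
  if (is.matrix(points)) {
    if (ncol(points) != 3L) stop("points must have 3 columns")
    points
  } else {
    if (length(points) != 3L) stop("a point must have 3 components")
    matrix(as.numeric(points), nrow = 1L)
  }
}

#' Convert between world coordinates and continuous voxel indices
#'
#' `worldToIndex` maps world mm to continuous 0-based voxel indices via
#' `(point - origin) / spacing`; `indexToWorld` is its exact inverse.
#' Out-of-grid indices are returned as-is; callers bound-check.
#'
#' @param volume an [ImageVolume-class], [MaskVolume-class] or
#'   [DeformationField-class] supplying the grid geometry.
#' @param points a length-3 vector or N x 3 matrix.
#' @return A matrix of the same shape as `points` (a 1 x 3 matrix for a
#'   single point).
#' @examples
#' vol <- imageVolume(array(0, c(10, 10, 10)), spacing = 2, origin = c(10, 0, 0))
#' worldToIndex(vol, c(10, 0, 0))   # (0, 0, 0)
#' indexToWorld(vol, c(1, 1, 1))    # (12, 2, 2)
#' @export
worldToIndex <- function(volume, points) {
  p <- asPointMatrix(points)
  or <- origin(volume); sp <- spacing(volume)
  cbind((p[, 1L] - or[1L]) / sp[1L], (p[, 2L] - or[2L]) / sp[2L],
        (p[, 3L] - or[3L]) / sp[3L])
}

#' @rdname worldToIndex
#' @export
indexToWorld <- function(volume, points) {
  p <- asPointMatrix(points)
  or <- origin(volume); sp <- spacing(volume)
  cbind(p[, 1L] * sp[1L] + or[1L], p[, 2L] * sp[2L] + or[2L],
        p[, 3L] * sp[3L] + or[3L])
}

## Trilinear interpolation of a 3D array at continuous 0-based indices.
## Returns `background` wherever any of the 8 support voxels is off-grid.
## At the top lattice plane the support cell is shifted down one voxel
## (fraction 1) so lattice points reproduce stored values exactly.
trilinearAtIndex <- function(data, idx, background = 0) {
  d <- dim(data)
  n <- nrow(idx)
  inb <- idx[, 1L] >= 0 & idx[, 1L] <= d[1L] - 1L &
         idx[, 2L] >= 0 & idx[, 2L] <= d[2L] - 1L &
         idx[, 3L] >= 0 & idx[, 3L] <= d[3L] - 1L
  inb[is.na(inb)] <- FALSE
  out <- rep(as.numeric(background), n)
  if (!any(inb)) return(out)
  ix <- idx[inb, , drop = FALSE]
  i0 <- pmin(floor(ix[, 1L]), d[1L] - 2L)
  j0 <- pmin(floor(ix[, 2L]), d[2L] - 2L)
  k0 <- pmin(floor(ix[, 3L]), d[3L] - 2L)
  # degenerate single-slab axes: collapse to the only plane, fraction 0
  if (d[1L] == 1L) i0 <- rep(0, nrow(ix))
  if (d[2L] == 1L) j0 <- rep(0, nrow(ix))
  if (d[3L] == 1L) k0 <- rep(0, nrow(ix))
  fx <- ix[, 1L] - i0; fy <- ix[, 2L] - j0; fz <- ix[, 3L] - k0
  nx <- d[1L]; nxy <- d[1L] * d[2L]
  base <- i0 + nx * j0 + nxy * k0 + 1
  sx <- if (d[1L] > 1L) 1L else 0L
  sy <- if (d[2L] > 1L) nx else 0L
  sz <- if (d[3L] > 1L) nxy else 0L
  v000 <- data[base];           v100 <- data[base + sx]
  v010 <- data[base + sy];      v110 <- data[base + sx + sy]
  v001 <- data[base + sz];      v101 <- data[base + sx + sz]
  v011 <- data[base + sy + sz]; v111 <- data[base + sx + sy + sz]
  c00 <- v000 * (1 - fx) + v100 * fx
  c10 <- v010 * (1 - fx) + v110 * fx
  c01 <- v001 * (1 - fx) + v101 * fx
  c11 <- v011 * (1 - fx) + v111 * fx
  c0 <- c00 * (1 - fy) + c10 * fy
  c1 <- c01 * (1 - fy) + c11 * fy
  out[inb] <- c0 * (1 - fz) + c1 * fz
  out
}

#' Sample a volume by trilinear interpolation at world points
#'
#' Interpolates the volume at continuous positions. Points whose 8-voxel
#' interpolation support falls (even partly) outside the grid return the
#' caller-supplied `background` value.
#'
#' @param volume an [ImageVolume-class] (or [MaskVolume-class], sampled as 0/1).
#' @param points world-mm point (length 3) or N x 3 matrix.
#' @param background value returned off-grid (default 0).
#' @return Numeric vector of length N.
#' @examples
#' vol <- imageVolume(array(7, c(5, 5, 5)))
#' sampleTrilinear(vol, c(2.3, 1.7, 0.5))      # 7
#' sampleTrilinear(vol, c(1000, 0, 0), -1)     # -1 (off grid)
#' @export
sampleTrilinear <- function(volume, points, background = 0) {
  dat <- volumeData(volume)
  if (is.logical(dat)) storage.mode(dat) <- "double"
  trilinearAtIndex(dat, worldToIndex(volume, points), background)
}

#' Sample a volume by nearest-neighbour interpolation (masks)
#'
#' Rounds the continuous index to the nearest voxel. Intended for masks,
#' where averaging labels is meaningless.
#'
#' @inheritParams sampleTrilinear
#' @return Numeric vector of length N (`background` off-grid).
#' @export
sampleNearest <- function(volume, points, background = 0) {
  dat <- volumeData(volume)
  if (is.logical(dat)) storage.mode(dat) <- "double"
  d <- dim(dat)
  idx <- round(worldToIndex(volume, points))
  n <- nrow(idx)
  inb <- idx[, 1L] >= 0 & idx[, 1L] <= d[1L] - 1L &
         idx[, 2L] >= 0 & idx[, 2L] <= d[2L] - 1L &
         idx[, 3L] >= 0 & idx[, 3L] <= d[3L] - 1L
  inb[is.na(inb)] <- FALSE
  out <- rep(as.numeric(background), n)
  lin <- idx[inb, 1L] + d[1L] * idx[inb, 2L] + d[1L] * d[2L] * idx[inb, 3L] + 1
  out[inb] <- dat[lin]
  out
}

#' Sample a deformation field at world points
#'
#' Component-wise trilinear interpolation of the displacement vectors.
#' Unlike volume sampling there is no background fallback: a fabricated
#' displacement would corrupt the rigid fit, so out-of-domain points are an
#' error.
#'
#' @param field a [DeformationField-class].
#' @param points world-mm point or N x 3 matrix; must lie within the field
#'   grid (continuous index in `[0, dim - 1]` on every axis).
#' @return N x 3 matrix of displacements (mm).
#' @examples
#' f <- deformationField(array(rep(c(1, -2, 3), each = 64), c(4, 4, 4, 3)))
#' sampleField(f, c(1.5, 1.5, 1.5))  # (1, -2, 3)
#' @export
sampleField <- function(field, points) {
  idx <- worldToIndex(field, points)
  d <- dim(field@vectors)[1:3]
  bad <- idx[, 1L] < 0 | idx[, 1L] > d[1L] - 1L |
         idx[, 2L] < 0 | idx[, 2L] > d[2L] - 1L |
         idx[, 3L] < 0 | idx[, 3L] > d[3L] - 1L
  if (any(bad | is.na(bad)))
    stop(sprintf("OutOfDomain: %d point(s) outside the deformation field grid",
                 sum(bad | is.na(bad))))
  cbind(trilinearAtIndex(field@vectors[, , , 1L, drop = TRUE], idx),
        trilinearAtIndex(field@vectors[, , , 2L, drop = TRUE], idx),
        trilinearAtIndex(field@vectors[, , , 3L, drop = TRUE], idx))
}

## ---- quaternion / rigid algebra ----

#' Quaternion rotation utilities
#'
#' `quaternionToMatrix` converts a unit quaternion `(w, x, y, z)` to its
#' 3 x 3 rotation matrix; `matrixToQuaternion` inverts that (returning the
#' representative with non-negative w); `axisAngleQuaternion` builds the
#' quaternion for a rotation of `angleDeg` degrees about `axis`.
#'
#' @param q length-4 quaternion `(w, x, y, z)`.
#' @param R 3 x 3 proper rotation matrix.
#' @param axis length-3 rotation axis (need not be normalized).
#' @param angleDeg rotation angle in degrees.
#' @return A 3 x 3 matrix, or a length-4 unit quaternion.
#' @examples
#' quaternionToMatrix(axisAngleQuaternion(c(0, 0, 1), 90))
#' @export
quaternionToMatrix <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3L)  # column-major: columns are images of the basis vectors
}

#' @rdname quaternionToMatrix
#' @export
matrixToQuaternion <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] >= R[2, 2] && R[1, 1] >= R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] >= R[3, 3]) {
    s <- sqrt(1 - R[1, 1] + R[2, 2] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, 0.25 * s,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 - R[1, 1] - R[2, 2] + R[3, 3]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  q <- q / sqrt(sum(q^2))
  if (q[1L] < 0) q <- -q
  q
}

#' @rdname quaternionToMatrix
#' @export
axisAngleQuaternion <- function(axis, angleDeg) {
  a <- axis / sqrt(sum(axis^2))
  h <- angleDeg * pi / 360
  c(cos(h), sin(h) * a)
}

#' Apply, compose and invert rigid transforms
#'
#' `transformPoints` maps points through `x' = R x + t`; `composeRigid(a, b)`
#' returns the transform applying `b` first, then `a`; `invertRigid` the
#' inverse transform; `rotationAngle` the rotation angle in degrees.
#'
#' @param transform,a,b [RigidTransform-class] objects.
#' @param points world-mm point or N x 3 matrix.
#' @return `transformPoints`: N x 3 matrix; `composeRigid`, `invertRigid`:
#'   a [RigidTransform-class]; `rotationAngle`: degrees in `[0, 180]`.
#' @examples
#' t90 <- rigidTransform(axisAngleQuaternion(c(0, 0, 1), 90))
#' transformPoints(t90, c(1, 0, 0))  # (0, 1, 0)
#' rotationAngle(composeRigid(t90, invertRigid(t90)))  # 0
#' @export
transformPoints <- function(transform, points) {
  p <- asPointMatrix(points)
  R <- quaternionToMatrix(transform@quaternion)
  q <- p %*% t(R)
  t3 <- transform@translation
  q[, 1L] <- q[, 1L] + t3[1L]
  q[, 2L] <- q[, 2L] + t3[2L]
  q[, 3L] <- q[, 3L] + t3[3L]
  q
}

#' @rdname transformPoints
#' @export
composeRigid <- function(a, b) {
  qa <- a@quaternion; qb <- b@quaternion
  q <- c(qa[1] * qb[1] - qa[2] * qb[2] - qa[3] * qb[3] - qa[4] * qb[4],
         qa[1] * qb[2] + qa[2] * qb[1] + qa[3] * qb[4] - qa[4] * qb[3],
         qa[1] * qb[3] - qa[2] * qb[4] + qa[3] * qb[1] + qa[4] * qb[2],
         qa[1] * qb[4] + qa[2] * qb[3] - qa[3] * qb[2] + qa[4] * qb[1])
  Ra <- quaternionToMatrix(qa)
  rigidTransform(q, as.vector(Ra %*% b@translation) + a@translation)
}

#' @rdname transformPoints
#' @export
invertRigid <- function(transform) {
  qi <- transform@quaternion * c(1, -1, -1, -1)
  Ri <- quaternionToMatrix(qi)
  rigidTransform(qi, -as.vector(Ri %*% transform@translation))
}

#' @rdname transformPoints
#' @export
rotationAngle <- function(transform) {
  q <- transform@quaternion
  # atan2 form: numerically exact near 0 and 180 degrees, unlike acos(w)
  2 * atan2(sqrt(sum(q[2:4]^2)), abs(q[1L])) * 180 / pi
}

#' Rigid rotation about a pivot point
#'
#' Convenience constructor: rotate by `angleDeg` about `axis` through the
#' world point `center`, then translate by `shift`. Useful for articulating
#' phantom bones about their own centres.
#'
#' @param axis rotation axis (length 3).
#' @param angleDeg angle in degrees.
#' @param center pivot point, world mm.
#' @param shift extra translation, mm.
#' @return A [RigidTransform-class].
#' @export
rigidAboutPoint <- function(axis, angleDeg, center = c(0, 0, 0),
                            shift = c(0, 0, 0)) {
  q <- axisAngleQuaternion(axis, angleDeg)
  R <- quaternionToMatrix(q)
  rigidTransform(q, center - as.vector(R %*% center) + shift)
}

## angular separation between two transforms' rotations, degrees
rotationDiscrepancy <- function(a, b) {
  rotationAngle(composeRigid(a, invertRigid(b)))
}

## world coordinates of every voxel centre, N x 3, x fastest
gridPoints <- function(geometry) {
  d <- dim(geometry)
  sp <- spacing(geometry); or <- origin(geometry)
  xs <- or[1L] + sp[1L] * (seq_len(d[1L]) - 1)
  ys <- or[2L] + sp[2L] * (seq_len(d[2L]) - 1)
  zs <- or[3L] + sp[3L] * (seq_len(d[3L]) - 1)
  cbind(rep(xs, times = d[2L] * d[3L]),
        rep(rep(ys, each = d[1L]), times = d[3L]),
        rep(zs, each = d[1L] * d[2L]))
}
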