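## Slice extraction and the comparison renderings: side-by-side triptych,
## orange-blue color fusion, magic-lens composite of the secondary (STIR)
## channel, and grayscale ROI context. All "follows the mouse" behaviours
## of the interactive prototype become explicit center parameters; output
## is static images.

#' SlicePlane: a 2D sampling plane through a volume
#'
#' @slot origin world mm of pixel (1, 1).
#' @slot axisU,axisV orthonormal in-plane direction vectors.
#' @slot width,height image size in pixels.
#' @slot pixelSpacing mm per pixel.
#' @seealso [slicePlane()], [canonicalPlane()], [extractSlice()]
#' @export
setClass("SlicePlane",
  representation(origin = "numeric", axisU = "numeric", axisV = "numeric",
                 width = "integer", height = "integer",
                 pixelSpacing = "numeric"))

setValidity("SlicePlane", function(object) {
  msg <- character()
  if (abs(sqrt(sum(object@axisU^2)) - 1) > 1e-9 ||
      abs(sqrt(sum(object@axisV^2)) - 1) > 1e-9)
    msg <- c(msg, "InvalidPlane: axes must be unit length")
  if (abs(sum(object@axisU * object@axisV)) > 1e-9)
    msg <- c(msg, "InvalidPlane: axes must be orthogonal")
  if (object@width < 1L || object@height < 1L)
    msg <- c(msg, "InvalidPlane: width and height must be >= 1")
  if (object@pixelSpacing <= 0)
    msg <- c(msg, "InvalidPlane: pixelSpacing must be > 0")
  if (length(msg)) msg else TRUE
})

#' @rdname SlicePlane-class
#' @param origin,axisU,axisV,width,height,pixelSpacing see slots.
#' @return A [SlicePlane-class].
#' @export
slicePlane <- function(origin, axisU, axisV, width, height, pixelSpacing = 1) {
  new("SlicePlane", origin = as.numeric(origin), axisU = as.numeric(axisU),
      axisV = as.numeric(axisV), width = as.integer(width),
      height = as.integer(height), pixelSpacing = as.numeric(pixelSpacing))
}

#' Canonical slice plane through a world point
#'
#' Builds an axial (xy), coronal (xz) or sagittal (yz) plane through
#' `through`, covering the volume's full in-plane extent at the volume's
#' (minimum) spacing.
#'
#' @param volume an [ImageVolume-class] (geometry source).
#' @param orientation `"axial"`, `"coronal"` or `"sagittal"`.
#' @param through world point the plane must contain (default: volume
#'   centre).
#' @param pixelSpacing mm per pixel (default `min(spacing(volume))`).
#' @return A [SlicePlane-class].
#' @export
canonicalPlane <- function(volume, orientation = c("axial", "coronal",
                                                   "sagittal"),
                           through = NULL, pixelSpacing = NULL) {
  orientation <- match.arg(orientation)
  d <- dim(volume); sp <- spacing(volume); or <- origin(volume)
  if (is.null(through)) through <- or + sp * (d - 1) / 2
  if (is.null(pixelSpacing)) pixelSpacing <- min(sp)
  ax <- switch(orientation,
    axial = list(u = c(1, 0, 0), v = c(0, 1, 0), iu = 1L, iv = 2L, k = 3L),
    coronal = list(u = c(1, 0, 0), v = c(0, 0, 1), iu = 1L, iv = 3L, k = 2L),
    sagittal = list(u = c(0, 1, 0), v = c(0, 0, 1), iu = 2L, iv = 3L, k = 1L))
  extentU <- sp[ax$iu] * (d[ax$iu] - 1)
  extentV <- sp[ax$iv] * (d[ax$iv] - 1)
  o <- or
  o[ax$k] <- through[ax$k]
  slicePlane(o, ax$u, ax$v, floor(extentU / pixelSpacing) + 1L,
             floor(extentV / pixelSpacing) + 1L, pixelSpacing)
}

planePixelCenters <- function(plane) {
  i <- seq_len(plane@width) - 1L
  j <- seq_len(plane@height) - 1L
  uu <- rep(i, times = plane@height) * plane@pixelSpacing
  vv <- rep(j, each = plane@width) * plane@pixelSpacing
  cbind(plane@origin[1L] + uu * plane@axisU[1L] + vv * plane@axisV[1L],
        plane@origin[2L] + uu * plane@axisU[2L] + vv * plane@axisV[2L],
        plane@origin[3L] + uu * plane@axisU[3L] + vv * plane@axisV[3L])
}

#' Extract a 2D slice from a volume
#'
#' Pixel `(i, j)` samples the volume trilinearly at
#' `origin + (i-1) ps axisU + (j-1) ps axisV`. Arbitrary oblique planes
#' are supported.
#'
#' @param volume an [ImageVolume-class].
#' @param plane a [SlicePlane-class].
#' @param background value used outside the volume.
#' @return A `width x height` numeric matrix.
#' @export
extractSlice <- function(volume, plane, background = 0) {
  validObject(plane)
  vals <- sampleTrilinear(volume, planePixelCenters(plane), background)
  matrix(vals, plane@width, plane@height)
}

#' Intensity window for display normalization
#'
#' `windowLevel` stores the `[low, high)` intensity window mapped to
#' `[0, 1]`; `volumeWindow` derives it from a volume's intensity
#' percentiles (default 1st-99th), the package's standard display window.
#'
#' @param low,high window bounds (low < high).
#' @param volume an [ImageVolume-class].
#' @param probs two percentiles in `[0, 1]`.
#' @return A list of class `"windowLevel"`.
#' @export
windowLevel <- function(low, high) {
  if (!is.finite(low) || !is.finite(high) || low >= high)
    stop("window requires low < high")
  structure(list(low = low, high = high), class = "windowLevel")
}

#' @rdname windowLevel
#' @export
volumeWindow <- function(volume, probs = c(0.01, 0.99)) {
  q <- stats::quantile(volume@data, probs, names = FALSE)
  if (q[2L] <= q[1L]) q[2L] <- q[1L] + 1   # constant volume: avoid 0 width
  windowLevel(q[1L], q[2L])
}

#' Normalize an image into [0, 1] through an intensity window
#'
#' Values are clipped to the window then mapped linearly: `low -> 0`,
#' `high -> 1`.
#'
#' @param image numeric matrix or array.
#' @param wl a [windowLevel()].
#' @return Same shape as `image`, values in `[0, 1]`.
#' @export
normalizeWindow <- function(image, wl) {
  out <- (image - wl$low) / (wl$high - wl$low)
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

#' Orange-blue color fusion of baseline and follow-up
#'
#' Each pixel mixes baseline intensity in orange `(1, 0.5, 0)` and
#' follow-up intensity in light blue `(0, 0.5, 1)`. The two hues are
#' exactly complementary (they sum to white), so where the intensities
#' agree the result is neutral gray; a local intensity decrease turns
#' orange, an increase turns blue.
#'
#' @param baseNorm,followNorm equal-shape matrices in `[0, 1]`.
#' @return `width x height x 3` RGB array, clipped to `[0, 1]`.
#' @examples
#' colorFuse(matrix(1), matrix(1))[1, 1, ]  # white
#' colorFuse(matrix(1), matrix(0))[1, 1, ]  # orange
#' @export
colorFuse <- function(baseNorm, followNorm) {
  if (!identical(dim(baseNorm), dim(followNorm)))
    stop("ShapeMismatch: fused images must share shape")
  rgb <- array(0, c(dim(baseNorm), 3L))
  rgb[, , 1L] <- baseNorm
  rgb[, , 2L] <- 0.5 * baseNorm + 0.5 * followNorm
  rgb[, , 3L] <- followNorm
  rgb[rgb < 0] <- 0
  rgb[rgb > 1] <- 1
  rgb
}

grayToRGB <- function(image) {
  if (length(dim(image)) == 3L) return(image)
  array(rep(image, 3L), c(dim(image), 3L))
}

#' Magic-lens composite of a co-located secondary image
#'
#' Pixels closer than `radiusPx` to `center` (in pixel units, 1-based
#' pixel indices) come from `secondary`, the rest from `primary`; a 1-px
#' white ring optionally marks the boundary. The composite is idempotent.
#'
#' @param primary,secondary images sharing geometry (gray matrices or RGB
#'   arrays).
#' @param center lens centre `(i, j)` in pixel coordinates.
#' @param radiusPx lens radius in pixels.
#' @param ring draw the white boundary circle?
#' @return An RGB array.
#' @export
magicLensComposite <- function(primary, secondary, center, radiusPx,
                               ring = TRUE) {
  p <- grayToRGB(primary); s <- grayToRGB(secondary)
  if (!identical(dim(p), dim(s)))
    stop("ShapeMismatch: lens images must share geometry")
  d <- dim(p)
  dist <- sqrt(outer((seq_len(d[1L]) - center[1L])^2,
                     (seq_len(d[2L]) - center[2L])^2, "+"))
  inside <- dist < radiusPx
  out <- p
  for (c_ in 1:3) {
    ch <- out[, , c_]; ch[inside] <- s[, , c_][inside]
    if (ring) ch[abs(dist - radiusPx) <= 0.5 & radiusPx > 0] <- 1
    out[, , c_] <- ch
  }
  out
}

#' Grayscale context outside a region of interest
#'
#' Converts pixels outside the ROI to luma gray
#' (`0.299 R + 0.587 G + 0.114 B` replicated over channels), keeping the
#' ROI in color -- the "surrounding area converted to grayscale" reading
#' aid.
#'
#' @param fused RGB array.
#' @param roiMaskSlice logical matrix, `TRUE` inside the ROI.
#' @return An RGB array.
#' @export
roiContextGray <- function(fused, roiMaskSlice) {
  if (!identical(dim(fused)[1:2], dim(roiMaskSlice)))
    stop("ShapeMismatch: mask must share the image shape")
  luma <- 0.299 * fused[, , 1L] + 0.587 * fused[, , 2L] + 0.114 * fused[, , 3L]
  out <- fused
  for (c_ in 1:3) {
    ch <- out[, , c_]; ch[!roiMaskSlice] <- luma[!roiMaskSlice]
    out[, , c_] <- ch
  }
  out
}

#' Render the three-view comparison (baseline | fusion | matched follow-up)
#'
#' The follow-up slice is taken through [applyRigidResample()] output so
#' all three views share the baseline plane; both timepoints are windowed
#' with the baseline's display window so intensity change stays visible.
#' When a lens is given (`list(center = c(i, j), radiusPx = r,
#' ring = TRUE)`) and the bundle carries secondary channels, the lens
#' composites the co-located secondary data into all three views at the
#' same position.
#'
#' @param bundle a [DatasetBundle-class].
#' @param transform the fitted [RigidTransform-class].
#' @param plane a [SlicePlane-class].
#' @param lens optional lens spec (see above).
#' @param window optional [windowLevel()] override.
#' @return Named list of RGB arrays: `baseline`, `fusion`, `followup`.
#' @export
renderTriptych <- function(bundle, transform, plane, lens = NULL,
                           window = NULL) {
  resampled <- applyRigidResample(bundle@followup, transform, bundle@baseline)
  wl <- if (is.null(window)) volumeWindow(bundle@baseline) else window
  bN <- normalizeWindow(extractSlice(bundle@baseline, plane), wl)
  fN <- normalizeWindow(extractSlice(resampled, plane), wl)
  views <- list(baseline = grayToRGB(bN), fusion = colorFuse(bN, fN),
                followup = grayToRGB(fN))
  if (!is.null(lens) && !is.null(bundle@baselineSecondary) &&
      !is.null(bundle@followupSecondary)) {
    wlS <- volumeWindow(bundle@baselineSecondary)
    sB <- normalizeWindow(extractSlice(bundle@baselineSecondary, plane), wlS)
    resampledSec <- applyRigidResample(bundle@followupSecondary, transform,
                                       bundle@baseline)
    sF <- normalizeWindow(extractSlice(resampledSec, plane), wlS)
    secViews <- list(baseline = grayToRGB(sB), fusion = colorFuse(sB, sF),
                     followup = grayToRGB(sF))
    ring <- if (is.null(lens$ring)) TRUE else lens$ring
    views <- Map(function(v, s) magicLensComposite(v, s, lens$center,
                                                   lens$radiusPx, ring),
                 views, secViews)
  }
  views
}

## rasterize a polyline (in-plane mm coordinates around `center`) onto an
## RGB image; used by the CLI's uncertainty overlay
drawPolyline <- function(image, plane, center, poly, color) {
  if (nrow(poly) < 1L) return(image)
  cuv <- c(sum((center - plane@origin) * plane@axisU),
           sum((center - plane@origin) * plane@axisV))
  px <- (cuv[1L] + poly[, 1L]) / plane@pixelSpacing + 1
  py <- (cuv[2L] + poly[, 2L]) / plane@pixelSpacing + 1
  d <- dim(image)
  stamp <- function(x, y) {
    x <- round(x); y <- round(y)
    ok <- x >= 1 & x <= d[1L] & y >= 1 & y <= d[2L]
    for (c_ in 1:3) {
      ch <- image[, , c_]
      ch[cbind(x[ok], y[ok])] <- color[c_]
      image[, , c_] <<- ch
    }
  }
  if (nrow(poly) == 1L) { stamp(px, py); return(image) }
  for (s in seq_len(nrow(poly) - 1L)) {
    n <- max(2L, ceiling(max(abs(px[s + 1L] - px[s]),
                             abs(py[s + 1L] - py[s])) * 3))
    t <- seq(0, 1, length.out = n)
    stamp(px[s] + t * (px[s + 1L] - px[s]), py[s] + t * (py[s + 1L] - py[s]))
  }
  image
}
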