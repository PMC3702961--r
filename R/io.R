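## Readers/writers for volumes, deformation fields, masks and rendered
## images. MetaImage (.mha/.mhd) is the primary dialect; NIfTI-1 (.nii,
## .nii.gz) is accepted for interoperability. Grids must have identity
## direction cosines; oblique files are rejected, never silently reoriented.

metaTypeInfo <- list(
  MET_UCHAR  = list(size = 1L, what = "integer", signed = FALSE),
  MET_CHAR   = list(size = 1L, what = "integer", signed = TRUE),
  MET_USHORT = list(size = 2L, what = "integer", signed = FALSE),
  MET_SHORT  = list(size = 2L, what = "integer", signed = TRUE),
  MET_UINT   = list(size = 4L, what = "integer", signed = TRUE),
  MET_INT    = list(size = 4L, what = "integer", signed = TRUE),
  MET_FLOAT  = list(size = 4L, what = "numeric", signed = TRUE),
  MET_DOUBLE = list(size = 8L, what = "numeric", signed = TRUE))

fileExt <- function(path) {
  p <- tolower(path)
  if (grepl("\\.nii\\.gz$", p)) "nii.gz"
  else sub(".*\\.", "", p)
}

parseMetaHeader <- function(path) {
  bytes <- readBin(path, "raw", file.info(path)$size)
  edfPos <- grepRaw("ElementDataFile", bytes)
  if (length(edfPos) == 0L)
    stop("UnsupportedFormat: no ElementDataFile key in MetaImage header: ", path)
  nlAfter <- grepRaw("\n", bytes, offset = edfPos[1L])
  hdrEnd <- if (length(nlAfter)) nlAfter[1L] else length(bytes)
  lines <- strsplit(rawToChar(bytes[seq_len(hdrEnd)]), "\n", fixed = TRUE)[[1L]]
  kv <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*?)\\s*$", ln))[[1L]]
    if (length(m) == 3L) kv[[m[2L]]] <- m[3L]
  }
  list(kv = kv, bytes = bytes, dataStart = hdrEnd + 1L)
}

readMetaImage <- function(path) {
  h <- parseMetaHeader(path)
  kv <- h$kv
  if (!identical(kv$NDims, "3"))
    stop("UnsupportedFormat: only 3D MetaImage supported (NDims = ",
         kv$NDims, ")")
  dims <- as.integer(strsplit(kv$DimSize, "\\s+")[[1L]])
  spacing <- if (!is.null(kv$ElementSpacing))
    as.numeric(strsplit(kv$ElementSpacing, "\\s+")[[1L]]) else c(1, 1, 1)
  offset <- if (!is.null(kv$Offset))
    as.numeric(strsplit(kv$Offset, "\\s+")[[1L]]) else c(0, 0, 0)
  if (!is.null(kv$TransformMatrix)) {
    tm <- as.numeric(strsplit(kv$TransformMatrix, "\\s+")[[1L]])
    if (max(abs(tm - c(1, 0, 0, 0, 1, 0, 0, 0, 1))) > 1e-6)
      stop("NonIdentityDirection: oblique grids are not supported: ", path)
  }
  if (identical(toupper(kv$CompressedData), "TRUE"))
    stop("UnsupportedFormat: compressed MetaImage not supported: ", path)
  channels <- if (!is.null(kv$ElementNumberOfChannels))
    as.integer(kv$ElementNumberOfChannels) else 1L
  ti <- metaTypeInfo[[kv$ElementType]]
  if (is.null(ti))
    stop("UnsupportedFormat: ElementType ", kv$ElementType)
  msb <- identical(toupper(kv$BinaryDataByteOrderMSB), "TRUE") ||
         identical(toupper(kv$ElementByteOrderMSB), "TRUE")
  endian <- if (msb) "big" else "little"
  n <- prod(dims) * channels
  edf <- kv$ElementDataFile
  raw <- if (identical(edf, "LOCAL")) {
    h$bytes[seq(h$dataStart, length.out = n * ti$size)]
  } else {
    rawPath <- file.path(dirname(path), edf)
    readBin(rawPath, "raw", n * ti$size)
  }
  vals <- readBin(raw, ti$what, n = n, size = ti$size, signed = ti$signed,
                  endian = endian)
  if (ti$what == "integer") vals <- as.numeric(vals)
  list(vals = vals, dims = dims, spacing = spacing, origin = offset,
       channels = channels)
}

writeMetaImage <- function(vals, dims, spacing, origin, channels, metType,
                           path) {
  ti <- metaTypeInfo[[metType]]
  local <- fileExt(path) == "mha"
  dataFile <- if (local) "LOCAL" else
    paste0(sub("\\.mhd$", "", basename(path), ignore.case = TRUE), ".raw")
  hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
           paste0("BinaryDataByteOrderMSB = ",
                  if (.Platform$endian == "big") "True" else "False"),
           "CompressedData = False",
           "TransformMatrix = 1 0 0 0 1 0 0 0 1",
           paste("Offset =", paste(format(origin, digits = 17), collapse = " ")),
           "CenterOfRotation = 0 0 0",
           paste("ElementSpacing =",
                 paste(format(spacing, digits = 17), collapse = " ")),
           paste("DimSize =", paste(dims, collapse = " ")))
  if (channels > 1L)
    hdr <- c(hdr, paste("ElementNumberOfChannels =", channels))
  hdr <- c(hdr, paste("ElementType =", metType),
           paste("ElementDataFile =", dataFile))
  writeValues <- function(con) {
    if (ti$what == "integer") {
      v <- as.numeric(vals)
      if (metType == "MET_USHORT") v <- v - 65536 * (v > 32767)
      if (metType == "MET_UCHAR") v <- v - 256 * (v > 127)
      writeBin(as.integer(round(v)), con, size = ti$size,
               endian = .Platform$endian)
    } else {
      writeBin(as.numeric(vals), con, size = ti$size,
               endian = .Platform$endian)
    }
  }
  if (local) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(paste0(paste(hdr, collapse = "\n"), "\n"), con, eos = NULL)
    writeValues(con)
  } else {
    writeLines(hdr, path)
    con <- file(file.path(dirname(path), dataFile), "wb")
    on.exit(close(con))
    writeValues(con)
  }
  invisible(NULL)
}

niftiGeometry <- function(img, path) {
  pd <- RNifti::pixdim(img)[1:3]
  x <- RNifti::xform(img)
  M <- x[1:3, 1:3]
  if (max(abs(M - diag(pd))) > 1e-4 * max(pd))
    stop("NonIdentityDirection: oblique or flipped NIfTI grids are not supported: ",
         path)
  list(spacing = pd, origin = x[1:3, 4])
}

writeNiftiArray <- function(arr, spacing, origin, datatype, path) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(spacing, rep(1, length(dim(arr)) - 3L))
  m <- diag(4)
  m[1:3, 1:3] <- diag(spacing, 3L)
  m[1:3, 4] <- origin
  img <- RNifti::`sform<-`(img, structure(m, code = 2L))
  img <- RNifti::`qform<-`(img, structure(m, code = 2L))
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(NULL)
}

#' Read a 3D scalar volume (MetaImage or NIfTI)
#'
#' Supported containers: MetaImage (`.mha` embedded-raw, `.mhd` + `.raw`)
#' and NIfTI-1 (`.nii`, `.nii.gz`). Integer intensities are preserved
#' bit-exactly. Files with more than one component per voxel are rejected
#' (use [readField()]); oblique direction cosines are rejected.
#'
#' @param path file path.
#' @return An [ImageVolume-class].
#' @export
readVolume <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  ext <- fileExt(path)
  if (ext %in% c("mha", "mhd")) {
    m <- readMetaImage(path)
    if (m$channels != 1L)
      stop("VectorPixelWhereScalarExpected: ", m$channels,
           " components per voxel in ", path)
    imageVolume(array(m$vals, m$dims), m$spacing, m$origin)
  } else if (ext %in% c("nii", "nii.gz")) {
    img <- RNifti::readNifti(path)
    d <- dim(img)
    if (length(d) != 3L)
      stop("VectorPixelWhereScalarExpected: ", length(d), "D NIfTI in ", path)
    g <- niftiGeometry(img, path)
    imageVolume(array(as.numeric(img), d), g$spacing, g$origin)
  } else {
    stop("UnsupportedFormat: cannot read '.", ext, "' (use .mha/.mhd/.nii/.nii.gz)")
  }
}

#' Write a 3D scalar volume
#'
#' 16-bit unsigned is the canonical on-disk scalar type: with
#' `type = "auto"` integral data in `[0, 65535]` are written as uint16 and
#' anything else as 32-bit float. MetaImage is written with embedded raw
#' data (`.mha`) or a sidecar `.raw` (`.mhd`) in local byte order, recorded
#' in the header.
#'
#' @param volume an [ImageVolume-class].
#' @param path output path (`.mha`, `.mhd`, `.nii`, `.nii.gz`).
#' @param type `"auto"`, `"uint16"`, `"float"` or `"double"`.
#' @return `path`, invisibly.
#' @export
writeVolume <- function(volume, path, type = c("auto", "uint16", "float",
                                               "double")) {
  type <- match.arg(type)
  dat <- volume@data
  if (type == "auto") {
    type <- if (all(dat == round(dat)) && min(dat) >= 0 && max(dat) <= 65535)
      "uint16" else "float"
  }
  ext <- fileExt(path)
  if (ext %in% c("mha", "mhd")) {
    metType <- c(uint16 = "MET_USHORT", float = "MET_FLOAT",
                 double = "MET_DOUBLE")[[type]]
    writeMetaImage(as.vector(dat), dim(dat), volume@spacing, volume@origin,
                   1L, metType, path)
  } else if (ext %in% c("nii", "nii.gz")) {
    writeNiftiArray(dat, volume@spacing, volume@origin, type, path)
  } else {
    stop("UnsupportedFormat: cannot write '.", ext, "'")
  }
  invisible(path)
}

#' Read / write a dense deformation field
#'
#' Fields are 3-component 32-bit float vector images (12 bytes per voxel on
#' disk plus header): MetaImage with `ElementNumberOfChannels = 3`
#' (channel-interleaved, the ITK layout) or a 4D NIfTI with a 3-long fourth
#' dimension. Files with a different component count are rejected.
#'
#' @param path file path.
#' @param field a [DeformationField-class].
#' @return `readField`: a [DeformationField-class]; `writeField`: `path`,
#'   invisibly.
#' @export
readField <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  ext <- fileExt(path)
  if (ext %in% c("mha", "mhd")) {
    m <- readMetaImage(path)
    if (m$channels != 3L)
      stop("WrongComponentCount: expected 3 components per voxel, found ",
           m$channels, " in ", path)
    vec <- aperm(array(m$vals, c(3L, m$dims)), c(2L, 3L, 4L, 1L))
    deformationField(vec, m$spacing, m$origin)
  } else if (ext %in% c("nii", "nii.gz")) {
    img <- RNifti::readNifti(path)
    d <- dim(img)
    if (length(d) != 4L || d[4L] != 3L)
      stop("WrongComponentCount: expected a 4D NIfTI with 3 components, found dims ",
           paste(d, collapse = "x"), " in ", path)
    g <- niftiGeometry(img, path)
    deformationField(array(as.numeric(img), d), g$spacing, g$origin)
  } else {
    stop("UnsupportedFormat: cannot read '.", ext, "'")
  }
}

#' @rdname readField
#' @export
writeField <- function(field, path) {
  ext <- fileExt(path)
  if (ext %in% c("mha", "mhd")) {
    vec <- aperm(field@vectors, c(4L, 1L, 2L, 3L))  # channel-interleaved
    writeMetaImage(as.vector(vec), dim(field@vectors)[1:3], field@spacing,
                   field@origin, 3L, "MET_FLOAT", path)
  } else if (ext %in% c("nii", "nii.gz")) {
    writeNiftiArray(field@vectors, field@spacing, field@origin, "float", path)
  } else {
    stop("UnsupportedFormat: cannot write '.", ext, "'")
  }
  invisible(path)
}

#' Render a mask as a writable volume
#'
#' Foreground voxels take `replaceValue`, background 0, mirroring the
#' exported segmentations of the interactive prototype.
#'
#' @param mask a [MaskVolume-class].
#' @param replaceValue foreground intensity.
#' @return An [ImageVolume-class].
#' @export
maskAsVolume <- function(mask, replaceValue = 1) {
  dat <- array(0, dim(mask@data))
  dat[mask@data] <- replaceValue
  imageVolume(dat, mask@spacing, mask@origin)
}

#' Read a volume as a boolean mask
#'
#' Nonzero voxels become foreground.
#'
#' @param path file path of a scalar volume.
#' @return A [MaskVolume-class].
#' @export
readMask <- function(path) {
  v <- readVolume(path)
  maskVolume(v@data != 0, v@spacing, v@origin)
}

#' Write an RGB image as 8-bit PNG
#'
#' Channel values must be in `[0, 1]` and are quantized as `round(255 * v)`.
#' The image uses screen-free axes: `image[i, j, ]` is the pixel at
#' horizontal position i, vertical position j (row 1 of the PNG is j = 1).
#' Output is deterministic: identical inputs give byte-identical files.
#'
#' @param image numeric array `c(width, height, 3)` in `[0, 1]` (a 2D matrix
#'   is written as grayscale).
#' @param path output `.png` path.
#' @return `path`, invisibly.
#' @export
writeRGBImage <- function(image, path) {
  if (any(!is.finite(image)) || min(image) < 0 || max(image) > 1)
    stop("ValueOutOfRange: image values must be finite and in [0, 1]")
  q <- round(255 * image) / 255
  out <- if (length(dim(q)) == 3L) aperm(q, c(2L, 1L, 3L)) else t(q)
  png::writePNG(out, path)
  invisible(path)
}

#' @rdname writeRGBImage
#' @export
readRGBImage <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) aperm(img, c(2L, 1L, 3L)) else t(img)
}

#' Read a dataset bundle from a YAML config
#'
#' The YAML file names the files of one baseline/follow-up comparison:
#' keys `baseline`, `followup`, `field` (required), `baseline_secondary`,
#' `followup_secondary` (optional). Relative paths are resolved against the
#' config file's directory.
#'
#' @param path YAML file path.
#' @return A [DatasetBundle-class].
#' @export
readBundle <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  cfg <- yaml::read_yaml(path)
  root <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    full <- if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(root, p)
    if (!file.exists(full)) stop("file does not exist: ", full)
    full
  }
  for (key in c("baseline", "followup", "field"))
    if (is.null(cfg[[key]])) stop("bundle config is missing key '", key, "'")
  readSec <- function(p) if (is.null(p)) NULL else readVolume(p)
  datasetBundle(
    baseline = readVolume(resolve(cfg$baseline)),
    followup = readVolume(resolve(cfg$followup)),
    field = readField(resolve(cfg$field)),
    baselineSecondary = readSec(resolve(cfg$baseline_secondary)),
    followupSecondary = readSec(resolve(cfg$followup_secondary)))
}
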