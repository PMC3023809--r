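#' @include AllClasses.R AllGenerics.R
NULL

#' Construct an in-memory image volume
#'
#' @param data 3D numeric or integer array.
#' @param voxelSize numeric(3), mm per voxel (default 1,1,1).
#' @param origin numeric(3), world position (mm) of the center of voxel
#'   (1,1,1) (default 0,0,0).
#' @param axisLabels character(3) orientation codes (default x, y, z).
#' @return an \linkS4class{ImageVolume}.
#' @examples
#' v <- imageVolume(array(0, c(4, 5, 6)))
#' volumeDims(v)
#' @export
imageVolume <- function(data, voxelSize = c(1, 1, 1), origin = c(0, 0, 0),
                        axisLabels = c("x", "y", "z")) {
  if (is.null(dim(data))) atkStop("validation", "data must be a 3D array")
  if (length(dim(data)) == 2L) dim(data) <- c(dim(data), 1L)
  rng <- suppressWarnings(range(data, finite = TRUE))
  new("ImageVolume", data = data, voxelSize = as.numeric(voxelSize),
      origin = as.numeric(origin), axisLabels = as.character(axisLabels),
      valueRange = rng)
}

#' @rdname volumeDims
#' @export
setMethod("volumeDims", "ImageVolume", function(x) dim(x@data))
#' @rdname voxelSize
#' @export
setMethod("voxelSize", "ImageVolume", function(x) x@voxelSize)
#' @rdname worldOrigin
#' @export
setMethod("worldOrigin", "ImageVolume", function(x) x@origin)
#' @rdname axisLabels
#' @export
setMethod("axisLabels", "ImageVolume", function(x) x@axisLabels)
#' @rdname valueRange
#' @export
setMethod("valueRange", "ImageVolume", function(x) x@valueRange)

#' Raw voxel data of a volume
#' @param x an \linkS4class{ImageVolume}.
#' @return the 3D array.
#' @export
volumeData <- function(x) x@data

setMethod("show", "ImageVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("ImageVolume %dx%dx%d (%s), voxel %s mm, origin (%s), range [%g, %g]\n",
              d[1], d[2], d[3], typeof(object@data),
              paste(signif(object@voxelSize, 4), collapse = "x"),
              paste(signif(object@origin, 4), collapse = ", "),
              object@valueRange[1], object@valueRange[2]))
})

.niftiExt <- function(path) grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)
.analyzeExt <- function(path) grepl("\\.(hdr|img)(\\.gz)?$", path, ignore.case = TRUE)

#' Read a 3D volume from NIfTI-1 or Analyze 7.5
#'
#' NIfTI files (.nii, .nii.gz) are read with \pkg{RNifti}; Analyze pairs
#' (.hdr/.img) with \pkg{oro.nifti}. Voxel size and origin come from the
#' NIfTI xform when present (only its diagonal/permutation part is honored;
#' oblique affines are not resampled) or from pixdim otherwise. Integer and
#' floating input types are preserved.
#'
#' @param path path to a .nii, .nii.gz, .hdr or .img file.
#' @return an \linkS4class{ImageVolume}.
#' @export
readVolume <- function(path) {
  if (!file.exists(path)) atkStop("not_found", "volume file not found: %s", path)
  if (.niftiExt(path)) {
    img <- tryCatch(RNifti::readNifti(path),
                    error = function(e) atkStop("format",
                      "not a readable NIfTI file: %s (%s)", path, conditionMessage(e)))
    arr <- as.array(img)
    attributes(arr) <- list(dim = dim(arr))   # plain array, native type
    if (length(dim(arr)) > 3L) dim(arr) <- dim(arr)[1:3]
    if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
    xf <- try(RNifti::xform(img), silent = TRUE)
    if (!inherits(xf, "try-error") && is.matrix(xf) &&
        isTRUE(attr(xf, "code") > 0)) {
      vs <- sqrt(colSums(xf[1:3, 1:3]^2))
      vs[vs == 0] <- 1
      org <- as.numeric(xf[1:3, 4])
    } else {
      vs <- RNifti::pixdim(img)[1:3]
      vs[!is.finite(vs) | vs <= 0] <- 1
      org <- c(0, 0, 0)
    }
    return(imageVolume(arr, voxelSize = vs, origin = org))
  }
  if (.analyzeExt(path)) {
    stub <- sub("\\.(hdr|img)(\\.gz)?$", "", path, ignore.case = TRUE)
    if (!file.exists(paste0(stub, ".hdr")) && !file.exists(paste0(stub, ".hdr.gz")))
      atkStop("not_found", "Analyze header not found for: %s", path)
    img <- tryCatch(oro.nifti::readANALYZE(stub),
                    error = function(e) atkStop("format",
                      "not a readable Analyze file: %s (%s)", path, conditionMessage(e)))
    arr <- img@.Data
    if (length(dim(arr)) > 3L) dim(arr) <- dim(arr)[1:3]
    dt <- img@datatype
    if (dt %in% c(2L, 4L, 8L)) storage.mode(arr) <- "integer"
    vs <- img@pixdim[2:4]
    vs[!is.finite(vs) | vs <= 0] <- 1
    return(imageVolume(arr, voxelSize = vs))
  }
  atkStop("format", "unrecognized volume format: %s", path)
}

#' Write a volume to NIfTI-1 or Analyze 7.5
#'
#' Round-trips with \code{\link{readVolume}} exactly: integer arrays are
#' stored as int32 and numeric arrays as float64 in both formats. NIfTI
#' output carries voxel size and origin in the sform; Analyze 7.5 has no
#' origin field, so the origin is not preserved by that format.
#'
#' @param volume an \linkS4class{ImageVolume}.
#' @param path output path. For Analyze, the .hdr/.img pair is derived from
#'   the path stub.
#' @param format "nifti" or "analyze"; default inferred from the extension.
#' @return the path, invisibly.
#' @export
writeVolume <- function(volume, path, format = c("auto", "nifti", "analyze")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (.analyzeExt(path)) "analyze" else "nifti"
  }
  dir <- dirname(path)
  if (!dir.exists(dir)) atkStop("io", "output directory does not exist: %s", dir)
  if (format == "nifti") {
    img <- RNifti::asNifti(volume@data)
    m <- diag(4)
    m[cbind(1:3, 1:3)] <- volume@voxelSize
    m[1:3, 4] <- volume@origin
    img <- RNifti::`sform<-`(img, structure(m, code = 2L))
    RNifti::writeNifti(img, path)
  } else {
    stub <- sub("\\.(hdr|img)$", "", path, ignore.case = TRUE)
    isInt <- is.integer(volume@data)
    dat <- volume@data
    storage.mode(dat) <- if (isInt) "integer" else "double"
    an <- oro.nifti::anlz(dat, datatype = if (isInt) 8L else 64L)
    an@bitpix <- if (isInt) 32L else 64L
    an@pixdim <- c(0, volume@voxelSize, 1, 1, 1, 1)
    oro.nifti::writeANALYZE(an, stub, gzipped = FALSE)
  }
  invisible(path)
}

#' @rdname extractSlice
#' @export
setMethod("extractSlice", "ImageVolume", function(volume, axis, index,
                                                  normalize = TRUE) {
  d <- dim(volume@data)
  .checkSlice(axis, index, d)
  plane <- switch(axis,
                  volume@data[index, , , drop = TRUE],
                  volume@data[, index, , drop = TRUE],
                  volume@data[, , index, drop = TRUE])
  plane <- as.matrix(plane)
  if (!normalize) return(plane)
  rng <- volume@valueRange
  px <- if (diff(rng) > 0) (plane - rng[1]) / diff(rng) else plane * 0
  image2d(px, pixelSize = volume@voxelSize[-axis])
})

.checkSlice <- function(axis, index, dims) {
  if (!axis %in% 1:3) atkStop("validation", "axis must be 1, 2 or 3")
  if (index < 1L || index > dims[axis]) {
    atkStop("bounds", "slice index %d out of range for axis %d (1..%d)",
            index, axis, dims[axis])
  }
}

#' Reorient a volume by axis permutation and flips
#'
#' Permutes the data axes and optionally reverses them; voxel size and axis
#' labels are permuted consistently. \code{flips} applies to the output axes
#' after permutation.
#'
#' @param volume an \linkS4class{ImageVolume}.
#' @param perm a permutation of 1:3; output axis i is input axis perm[i].
#' @param flips logical(3); reverse the corresponding output axis.
#' @return the reoriented \linkS4class{ImageVolume}.
#' @export
reorientVolume <- function(volume, perm, flips = c(FALSE, FALSE, FALSE)) {
  if (length(perm) != 3L || !setequal(perm, 1:3)) {
    atkStop("validation", "perm must be a permutation of 1:3")
  }
  dat <- aperm(volume@data, perm)
  d <- dim(dat)
  idx <- lapply(1:3, function(a) if (flips[a]) d[a]:1 else seq_len(d[a]))
  dat <- dat[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  imageVolume(dat, voxelSize = volume@voxelSize[perm],
              origin = volume@origin[perm],
              axisLabels = volume@axisLabels[perm])
}

#' Voxel to world coordinate conversion
#'
#' World coordinates follow the voxel-center convention:
#' \code{xyz = origin + (ijk - 1) * voxelSize} with 1-based voxel indices.
#'
#' @param volume a volume object.
#' @param ijk numeric(3) or n x 3 matrix of 1-based voxel indices.
#' @return numeric(3) or n x 3 matrix of world coordinates (mm).
#' @export
voxelToWorld <- function(volume, ijk) {
  vs <- voxelSize(volume); org <- worldOrigin(volume)
  if (is.matrix(ijk)) {
    sweep(sweep(ijk - 1, 2, vs, "*"), 2, org, "+")
  } else {
    org + (as.numeric(ijk) - 1) * vs
  }
}

#' World to voxel coordinate conversion
#'
#' Inverse of \code{\link{voxelToWorld}}, rounding to the nearest voxel.
#' Out-of-grid world points are allowed; the result carries an
#' \code{"inGrid"} attribute flagging whether the rounded voxel lies inside
#' the volume.
#'
#' @param volume a volume object.
#' @param xyz numeric(3) world coordinates (mm).
#' @return integer(3) voxel indices with attribute \code{inGrid}.
#' @export
worldToVoxel <- function(volume, xyz) {
  vs <- voxelSize(volume); org <- worldOrigin(volume)
  ijk <- as.integer(round((as.numeric(xyz) - org) / vs + 1))
  d <- volumeDims(volume)
  structure(ijk, inGrid = all(ijk >= 1L & ijk <= d))
}
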