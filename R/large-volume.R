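#' @include AllClasses.R AllGenerics.R volume-io.R
NULL

# On-disk scalar types supported by the raw large-volume layout.
.dtypeInfo <- function(dtype) {
  switch(dtype,
    uint8   = list(what = "integer", size = 1L, signed = FALSE, mode = "integer"),
    int16   = list(what = "integer", size = 2L, signed = TRUE,  mode = "integer"),
    int32   = list(what = "integer", size = 4L, signed = TRUE,  mode = "integer"),
    float32 = list(what = "numeric", size = 4L, signed = TRUE,  mode = "double"),
    float64 = list(what = "numeric", size = 8L, signed = TRUE,  mode = "double"),
    atkStop("format", "unsupported dtype: %s", dtype))
}

.niftiDtypeName <- function(code) {
  switch(as.character(code),
    "2" = "uint8", "4" = "int16", "8" = "int32",
    "16" = "float32", "64" = "float64",
    atkStop("format", "unsupported NIfTI datatype code %s for streaming", code))
}

#' Write a raw large-volume descriptor
#'
#' The descriptor is a small YAML text header naming the data file, its
#' scalar type, dimensions and spatial metadata. The paired data file holds
#' the voxels in native array order (first index fastest), little-endian.
#'
#' @param path output .lhdr path.
#' @param datafile name of the data file (relative to the header).
#' @param dims integer(3).
#' @param dtype one of uint8, int16, int32, float32, float64.
#' @param voxelSize,origin spatial metadata.
#' @param valueRange global intensity range of the data (used for display
#'   normalization without a full scan).
#' @return the path, invisibly.
#' @export
writeLargeVolumeHeader <- function(path, datafile, dims, dtype,
                                   voxelSize = c(1, 1, 1),
                                   origin = c(0, 0, 0),
                                   valueRange = NULL) {
  hdr <- list(datafile = datafile, dims = as.integer(dims), dtype = dtype,
              offset = 0L, voxel_size = as.numeric(voxelSize),
              origin = as.numeric(origin))
  if (!is.null(valueRange)) hdr$value_range <- as.numeric(valueRange)
  yaml::write_yaml(hdr, path, precision = 17L)  # range must survive verbatim
  invisible(path)
}

#' Open a disk-backed volume for on-demand slice streaming
#'
#' Supported layouts are the package's raw descriptor (.lhdr, see
#' \code{\link{writeLargeVolumeHeader}}) and uncompressed NIfTI-1 (.nii).
#' Voxel data are read plane by plane along the file's fastest-varying plane
#' (fixed third index) into a slice-granular LRU cache; any read returns
#' values bit-identical to an in-memory load of the same file, and the
#' resident cache never exceeds \code{cacheBudget} bytes (accounted at
#' on-disk slice size).
#'
#' @param path a .lhdr or uncompressed .nii file.
#' @param cacheBudget cache capacity in bytes; must hold at least one slice.
#' @return an \linkS4class{OutOfCoreVolume}.
#' @export
openLargeVolume <- function(path, cacheBudget) {
  if (!file.exists(path)) atkStop("not_found", "file not found: %s", path)
  if (grepl("\\.lhdr$", path, ignore.case = TRUE)) {
    hdr <- yaml::read_yaml(path)
    datafile <- file.path(dirname(path), hdr$datafile)
    if (!file.exists(datafile)) {
      atkStop("not_found", "data file not found: %s", datafile)
    }
    dims <- as.integer(hdr$dims); dtype <- hdr$dtype
    offset <- as.numeric(hdr$offset %||% 0)
    vs <- as.numeric(hdr$voxel_size %||% c(1, 1, 1))
    org <- as.numeric(hdr$origin %||% c(0, 0, 0))
    vr <- as.numeric(hdr$value_range %||% c(NA_real_, NA_real_))
  } else if (grepl("\\.nii$", path, ignore.case = TRUE)) {
    nh <- RNifti::niftiHeader(path)
    dims <- as.integer(nh$dim[2:4]); dtype <- .niftiDtypeName(nh$datatype)
    offset <- as.numeric(nh$vox_offset)
    vs <- as.numeric(nh$pixdim[2:4]); vs[!is.finite(vs) | vs <= 0] <- 1
    org <- c(0, 0, 0)
    sr <- rbind(nh$srow_x, nh$srow_y, nh$srow_z)
    if (isTRUE(nh$sform_code > 0)) org <- as.numeric(sr[, 4])
    vr <- c(NA_real_, NA_real_)
    datafile <- path
  } else if (grepl("\\.nii\\.gz$", path, ignore.case = TRUE)) {
    atkStop("format", "compressed NIfTI cannot be streamed; gunzip first: %s", path)
  } else {
    atkStop("format", "unsupported large-volume layout: %s", path)
  }
  info <- .dtypeInfo(dtype)
  sliceBytes <- as.numeric(dims[1]) * dims[2] * info$size
  if (cacheBudget < sliceBytes) {
    atkStop("config",
            "cache budget %g bytes is smaller than one slice (%g bytes)",
            cacheBudget, sliceBytes)
  }
  st <- new.env(parent = emptyenv())
  st$cache <- list()        # key "k" -> numeric/integer plane vector
  st$lru <- character(0)    # keys, least recent first
  st$diskReads <- 0L
  st$cacheHits <- 0L
  st$residentBytes <- 0
  new("OutOfCoreVolume", path = datafile, dims = dims, dtype = dtype,
      dataOffset = offset, voxelSize = vs, origin = org,
      axisLabels = c("x", "y", "z"), valueRange = vr,
      cacheBudget = as.numeric(cacheBudget), state = st)
}

#' @rdname volumeDims
#' @export
setMethod("volumeDims", "OutOfCoreVolume", function(x) x@dims)
#' @rdname voxelSize
#' @export
setMethod("voxelSize", "OutOfCoreVolume", function(x) x@voxelSize)
#' @rdname worldOrigin
#' @export
setMethod("worldOrigin", "OutOfCoreVolume", function(x) x@origin)
#' @rdname axisLabels
#' @export
setMethod("axisLabels", "OutOfCoreVolume", function(x) x@axisLabels)

#' @rdname valueRange
#' @export
setMethod("valueRange", "OutOfCoreVolume", function(x) {
  if (all(is.finite(x@valueRange))) return(x@valueRange)
  if (!is.null(x@state$scannedRange)) return(x@state$scannedRange)
  # one streaming pass outside the LRU cache so counters stay meaningful
  info <- .dtypeInfo(x@dtype)
  con <- file(x@path, "rb"); on.exit(close(con))
  seek(con, x@dataOffset)
  n <- as.numeric(x@dims[1]) * x@dims[2]
  rng <- c(Inf, -Inf)
  for (k in seq_len(x@dims[3])) {
    v <- readBin(con, info$what, n = n, size = info$size,
                 signed = info$signed, endian = "little")
    rng <- range(rng, v)
  }
  x@state$scannedRange <- rng
  rng
})

setMethod("show", "OutOfCoreVolume", function(object) {
  cat(sprintf("OutOfCoreVolume %s [%s] %s, budget %g bytes (%d reads, %d hits)\n",
              basename(object@path), paste(object@dims, collapse = "x"),
              object@dtype, object@cacheBudget,
              object@state$diskReads, object@state$cacheHits))
})

# Fetch plane k (third index fixed) through the LRU cache.
.oocPlane <- function(x, k) {
  st <- x@state
  key <- as.character(k)
  hit <- st$cache[[key]]
  if (!is.null(hit)) {
    st$cacheHits <- st$cacheHits + 1L
    st$lru <- c(setdiff(st$lru, key), key)
    return(hit)
  }
  info <- .dtypeInfo(x@dtype)
  n <- as.numeric(x@dims[1]) * x@dims[2]
  sliceBytes <- n * info$size
  con <- file(x@path, "rb")
  seek(con, x@dataOffset + (k - 1) * sliceBytes)
  v <- readBin(con, info$what, n = n, size = info$size,
               signed = info$signed, endian = "little")
  close(con)
  st$diskReads <- st$diskReads + 1L
  st$cache[[key]] <- v
  st$lru <- c(st$lru, key)
  st$residentBytes <- st$residentBytes + sliceBytes
  while (st$residentBytes > x@cacheBudget && length(st$lru) > 1L) {
    drop <- st$lru[1L]
    st$lru <- st$lru[-1L]
    st$cache[[drop]] <- NULL
    st$residentBytes <- st$residentBytes - sliceBytes
  }
  v
}

#' Cache access statistics of an out-of-core volume
#'
#' @param x an \linkS4class{OutOfCoreVolume}.
#' @return list with \code{diskReads}, \code{cacheHits},
#'   \code{residentSlices}, \code{residentBytes}.
#' @export
cacheStats <- function(x) {
  st <- x@state
  list(diskReads = st$diskReads, cacheHits = st$cacheHits,
       residentSlices = length(st$lru), residentBytes = st$residentBytes)
}

#' @rdname extractSlice
#' @export
setMethod("extractSlice", "OutOfCoreVolume", function(volume, axis, index,
                                                      normalize = TRUE) {
  d <- volume@dims
  .checkSlice(axis, index, d)
  if (axis == 3L) {
    plane <- matrix(.oocPlane(volume, index), d[1], d[2])
  } else {
    plane <- matrix(0, if (axis == 1L) d[2] else d[1], d[3])
    if (is.integer(.oocPlane(volume, 1L))) storage.mode(plane) <- "integer"
    for (k in seq_len(d[3])) {
      pk <- matrix(.oocPlane(volume, k), d[1], d[2])
      plane[, k] <- if (axis == 1L) pk[index, ] else pk[, index]
    }
  }
  if (!normalize) return(plane)
  rng <- valueRange(volume)
  px <- if (diff(rng) > 0) (plane - rng[1]) / diff(rng) else plane * 0
  image2d(px, pixelSize = volume@voxelSize[-axis])
})

#' Load a large-volume file fully into memory
#'
#' The in-memory twin of \code{\link{openLargeVolume}}; used as the oracle
#' that streamed reads are bit-identical.
#'
#' @param path a .lhdr or .nii file.
#' @return an \linkS4class{ImageVolume}.
#' @export
loadLargeVolumeInMemory <- function(path) {
  ooc <- openLargeVolume(path, cacheBudget = Inf)
  info <- .dtypeInfo(ooc@dtype)
  con <- file(ooc@path, "rb"); on.exit(close(con))
  seek(con, ooc@dataOffset)
  v <- readBin(con, info$what, n = prod(as.numeric(ooc@dims)),
               size = info$size, signed = info$signed, endian = "little")
  imageVolume(array(v, ooc@dims), voxelSize = ooc@voxelSize,
              origin = ooc@origin)
}
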