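#' @include AllClasses.R
NULL

#' Extract an orthogonal slice from a volume
#'
#' Returns the axis-orthogonal plane at \code{index} as an
#' \linkS4class{Image2D}, with intensities rescaled to [0,1] by the volume's
#' global value range (so stepping through slices does not flicker) and pixel
#' size equal to the two remaining voxel-size components.
#'
#' @param volume an \linkS4class{ImageVolume} or \linkS4class{OutOfCoreVolume}.
#' @param axis array axis orthogonal to the slice, 1, 2 or 3.
#' @param index 1-based slice index along \code{axis}.
#' @param normalize rescale intensities to [0,1] by the volume value range
#'   (default TRUE); with FALSE the raw plane is returned as a plain matrix.
#' @return an \linkS4class{Image2D} (or matrix when \code{normalize = FALSE}).
#' @export
setGeneric("extractSlice", function(volume, axis, index, normalize = TRUE)
  standardGeneric("extractSlice"))

#' Volume dimensions
#' @param x a volume object.
#' @return integer(3).
#' @export
setGeneric("volumeDims", function(x) standardGeneric("volumeDims"))

#' Voxel size accessor
#' @param x a volume object.
#' @return numeric(3), mm per voxel.
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' World origin accessor (center of voxel (1,1,1))
#' @param x a volume object.
#' @return numeric(3), mm.
#' @export
setGeneric("worldOrigin", function(x) standardGeneric("worldOrigin"))

#' Axis orientation labels
#' @param x a volume object.
#' @return character(3).
#' @export
setGeneric("axisLabels", function(x) standardGeneric("axisLabels"))

#' Intensity range accessor
#' @param x a volume or image object.
#' @return numeric(2), the actual data min/max.
#' @export
setGeneric("valueRange", function(x) standardGeneric("valueRange"))
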