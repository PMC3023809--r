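#' @import methods
NULL

# ---------------------------------------------------------------------------
# Volumes and 2D images
# ---------------------------------------------------------------------------

#' ImageVolume: an in-memory 3D scalar volume
#'
#' A plain 3D array of intensities plus the spatial metadata needed to place
#' it in world coordinates: per-axis voxel size (mm), the world position of
#' the center of voxel (1,1,1), and orientation codes for the three array
#' axes. The intensity range is kept alongside the data and recomputed by the
#' constructor so that display normalization is stable across slices.
#'
#' @slot data 3D numeric or integer array, all dimensions >= 1.
#' @slot voxelSize numeric(3), positive, mm per voxel along each array axis.
#' @slot origin numeric(3), world coordinates (mm) of the center of voxel
#'   (1,1,1).
#' @slot axisLabels character(3) orientation codes for the array axes.
#' @slot valueRange numeric(2), the actual min/max of \code{data}.
#' @exportClass ImageVolume
setClass("ImageVolume", representation(
  data = "array",
  voxelSize = "numeric",
  origin = "numeric",
  axisLabels = "character",
  valueRange = "numeric"
))

setValidity("ImageVolume", function(object) {
  d <- dim(object@data)
  if (length(d) != 3L) return("data must be a 3D array")
  if (any(d < 1L)) return("all three dimensions must be >= 1")
  if (length(object@voxelSize) != 3L || any(!is.finite(object@voxelSize)) ||
      any(object@voxelSize <= 0)) {
    return("voxelSize must be 3 positive finite numbers")
  }
  if (length(object@origin) != 3L) return("origin must have length 3")
  if (length(object@axisLabels) != 3L) return("axisLabels must have length 3")
  rng <- suppressWarnings(range(object@data, finite = TRUE))
  if (!isTRUE(all.equal(rng, object@valueRange))) {
    return("valueRange does not match the data range")
  }
  TRUE
})

#' Image2D: a 2D raster with grayscale or RGB(A) channels in [0,1]
#'
#' @slot pixels matrix (grayscale) or 3D array with 3rd dimension 3 (RGB) or
#'   4 (RGBA); values in [0,1].
#' @slot pixelSize numeric(2), positive, physical size of a pixel.
#' @exportClass Image2D
setClass("Image2D", representation(
  pixels = "array",
  pixelSize = "numeric"
))

setValidity("Image2D", function(object) {
  d <- dim(object@pixels)
  if (!(length(d) == 2L || (length(d) == 3L && d[3L] %in% c(1L, 3L, 4L)))) {
    return("pixels must be 2D or have 1, 3 or 4 channels")
  }
  if (length(object@pixelSize) != 2L || any(object@pixelSize <= 0)) {
    return("pixelSize must be 2 positive numbers")
  }
  rng <- suppressWarnings(range(object@pixels, finite = TRUE))
  if (is.finite(rng[1L]) && (rng[1L] < -1e-9 || rng[2L] > 1 + 1e-9)) {
    return("pixel values must lie in [0,1]")
  }
  TRUE
})

#' ImageSeries: an ordered stack of same-sized 2D frames
#'
#' @slot frames list of \linkS4class{Image2D}, all with identical dimensions.
#' @slot currentIndex integer, 1-based index of the current frame.
#' @exportClass ImageSeries
setClass("ImageSeries", representation(
  frames = "list",
  currentIndex = "integer"
))

setValidity("ImageSeries", function(object) {
  if (!length(object@frames)) return("series must contain at least one frame")
  if (!all(vapply(object@frames, is, logical(1), "Image2D"))) {
    return("all frames must be Image2D")
  }
  dims <- lapply(object@frames, function(f) dim(f@pixels)[1:2])
  if (!all(vapply(dims, identical, logical(1), dims[[1L]]))) {
    return("all frames must share the same dimensions")
  }
  if (object@currentIndex < 1L || object@currentIndex > length(object@frames)) {
    return("currentIndex out of range")
  }
  TRUE
})

#' OutOfCoreVolume: a disk-backed volume streamed slice by slice
#'
#' Header metadata plus a slice-granular LRU cache; the voxel data stay on
#' disk and are read plane-by-plane along the file's fastest-varying plane
#' (fixed third index). Reads are bit-identical to an in-memory load of the
#' same file and the resident cache never exceeds \code{cacheBudget} bytes.
#'
#' @slot path path of the data file.
#' @slot dims integer(3) volume dimensions.
#' @slot dtype storage type on disk (\code{"float32"}, \code{"float64"},
#'   \code{"int16"}, \code{"int32"}, \code{"uint8"}).
#' @slot dataOffset byte offset of the first voxel in the file.
#' @slot voxelSize,origin,axisLabels spatial metadata as for
#'   \linkS4class{ImageVolume}.
#' @slot valueRange numeric(2) global intensity range (from the header, used
#'   for display normalization).
#' @slot cacheBudget cache capacity in bytes (on-disk slice size accounting).
#' @slot state environment holding the LRU cache and access counters.
#' @exportClass OutOfCoreVolume
setClass("OutOfCoreVolume", representation(
  path = "character",
  dims = "integer",
  dtype = "character",
  dataOffset = "numeric",
  voxelSize = "numeric",
  origin = "numeric",
  axisLabels = "character",
  valueRange = "numeric",
  cacheBudget = "numeric",
  state = "environment"
))

# ---------------------------------------------------------------------------
# Label hierarchies
# ---------------------------------------------------------------------------

#' LabelSet: a single-parent hierarchy of labels
#'
#' Stores the tree in a node table whose row order is the file/DFS order;
#' sibling order is row order among rows sharing a parent. Each node carries
#' a non-negative integer id (unique within the set), an abbreviation, a full
#' name and an RGB color.
#'
#' @slot setName context name of the label set (e.g. anatomic, functional).
#' @slot nodes data.frame with columns \code{id}, \code{abbrev}, \code{name},
#'   \code{r}, \code{g}, \code{b}, \code{parent} (\code{NA} for roots).
#' @slot notes character vector of parse-time warnings (e.g. dropped
#'   multi-parent edges when reducing an OBO graph to a tree).
#' @exportClass LabelSet
setClass("LabelSet", representation(
  setName = "character",
  nodes = "data.frame",
  notes = "character"
))

setValidity("LabelSet", function(object) {
  n <- object@nodes
  need <- c("id", "abbrev", "name", "r", "g", "b", "parent")
  if (!all(need %in% names(n))) {
    return(paste("nodes must have columns", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(n$id)) {
    return(sprintf("duplicate label id %s", n$id[duplicated(n$id)][1L]))
  }
  if (any(n$id < 0)) return("label ids must be non-negative")
  bad <- !is.na(n$parent) & !(n$parent %in% n$id)
  if (any(bad)) {
    return(sprintf("node %d references missing parent %d",
                   n$id[bad][1L], n$parent[bad][1L]))
  }
  rgb <- c(n$r, n$g, n$b)
  if (any(is.na(rgb)) || any(rgb < 0) || any(rgb > 255)) {
    return("colors must be integers in 0..255")
  }
  # cycle check: every node must reach a root
  idx <- match(n$parent, n$id)
  for (i in seq_len(nrow(n))) {
    seen <- integer(0)
    j <- i
    while (!is.na(idx[j])) {
      if (j %in% seen) return(sprintf("cycle involving label id %d", n$id[j]))
      seen <- c(seen, j)
      j <- idx[j]
    }
  }
  TRUE
})

# ---------------------------------------------------------------------------
# Atlas
# ---------------------------------------------------------------------------

#' LabelLayer: an integer label volume paired with its label set
#'
#' @slot ids 3D non-negative integer array; 0 is background.
#' @slot labelSet the \linkS4class{LabelSet} giving meaning to the ids.
#' @exportClass LabelLayer
setClass("LabelLayer", representation(
  ids = "array",
  labelSet = "LabelSet"
))

setValidity("LabelLayer", function(object) {
  if (length(dim(object@ids)) != 3L) return("ids must be a 3D array")
  if (any(object@ids < 0L)) return("label ids must be non-negative")
  TRUE
})

#' Atlas: a reference volume with one or more label layers
#'
#' An atlas may carry several label layers over the same voxel grid, each a
#' different labelling context (anatomic, functional, ...) with its own label
#' volume and hierarchy. One layer is active at a time; label lookups report
#' the active layer first.
#'
#' @slot reference optional \linkS4class{ImageVolume} (may be NULL).
#' @slot layers list of \linkS4class{LabelLayer}, length >= 1, all sharing
#'   the reference grid.
#' @slot activeIndex 1-based index of the active label layer.
#' @slot notes load-time warnings (e.g. label ids present in a volume but
#'   absent from its hierarchy).
#' @exportClass Atlas
setClass("Atlas", representation(
  reference = "ANY",
  layers = "list",
  activeIndex = "integer",
  notes = "character"
))

setValidity("Atlas", function(object) {
  if (!length(object@layers)) return("atlas needs at least one label layer")
  if (!all(vapply(object@layers, is, logical(1), "LabelLayer"))) {
    return("layers must all be LabelLayer")
  }
  dims <- lapply(object@layers, function(l) dim(l@ids))
  if (!all(vapply(dims, identical, logical(1), dims[[1L]]))) {
    return("all label layers must share the same grid")
  }
  if (!is.null(object@reference)) {
    if (!is(object@reference, "ImageVolume")) {
      return("reference must be an ImageVolume or NULL")
    }
    if (!identical(dim(object@reference@data), dims[[1L]])) {
      return("reference grid does not match the label layers")
    }
  }
  if (object@activeIndex < 1L || object@activeIndex > length(object@layers)) {
    return("activeIndex out of range")
  }
  TRUE
})

#' SelectionState: per-layer selected and expanded label ids
#'
#' @slot selected list (one integer vector per layer) of selected label ids.
#' @slot expanded list (one integer vector per layer) of expanded graph nodes.
#' @exportClass SelectionState
setClass("SelectionState", representation(
  selected = "list",
  expanded = "list"
))

# ---------------------------------------------------------------------------
# Compositor
# ---------------------------------------------------------------------------

#' Layer: a transformable, adjustable image layer
#'
#' @slot id layer identifier, unique within a canvas.
#' @slot content an \linkS4class{Image2D} or \linkS4class{ImageSeries}.
#' @slot transform list with \code{pan} (numeric(2), canvas px),
#'   \code{rotation} (degrees, about the image center) and \code{scale}
#'   (positive). Applied as scale, then rotation, then pan.
#' @slot opacity alpha in [0,1].
#' @slot brightness additive offset in [-1,1].
#' @slot contrast positive gain about mid-gray.
#' @slot lut optional 256x3 color lookup table in [0,1] rows, or NULL.
#' @slot visible logical.
#' @slot linkGroup link-group id (NA when unlinked).
#' @slot linkMaster TRUE if this layer is the master of its link group.
#' @exportClass Layer
setClass("Layer", representation(
  id = "character",
  content = "ANY",
  transform = "list",
  opacity = "numeric",
  brightness = "numeric",
  contrast = "numeric",
  lut = "ANY",
  visible = "logical",
  linkGroup = "character",
  linkMaster = "logical"
))

setValidity("Layer", function(object) {
  tr <- object@transform
  if (!all(c("pan", "rotation", "scale") %in% names(tr))) {
    return("transform must have pan, rotation, scale")
  }
  if (tr$scale <= 0) return("scale must be positive")
  if (object@opacity < 0 || object@opacity > 1) return("opacity must be in [0,1]")
  if (object@contrast <= 0) return("contrast must be positive")
  if (!is.null(object@lut) &&
      !(is.matrix(object@lut) && all(dim(object@lut) == c(256L, 3L)))) {
    return("lut must be a 256x3 matrix or NULL")
  }
  TRUE
})

#' Canvas: an ordered stack of layers composited bottom to top
#'
#' @slot layers list of \linkS4class{Layer}, bottom first.
#' @slot size integer(2), canvas width and height in px.
#' @slot backgroundColor numeric(3) RGB in [0,1].
#' @slot backgroundAlpha background coverage in [0,1] (1 = opaque canvas).
#' @slot zoom canvas-level uniform scale about the canvas center.
#' @exportClass Canvas
setClass("Canvas", representation(
  layers = "list",
  size = "integer",
  backgroundColor = "numeric",
  backgroundAlpha = "numeric",
  zoom = "numeric"
))

setValidity("Canvas", function(object) {
  if (length(object@size) != 2L || any(object@size < 1L)) {
    return("size must be two positive integers")
  }
  if (object@zoom <= 0) return("zoom must be positive")
  ids <- vapply(object@layers, function(l) l@id, character(1))
  if (anyDuplicated(ids)) return("layer ids must be unique")
  TRUE
})

# ---------------------------------------------------------------------------
# Registration
# ---------------------------------------------------------------------------

#' TransformModel: a fitted 2D spatial mapping
#'
#' Rigid models store a rotation matrix and translation; affine models a 2x3
#' matrix; thin-plate splines the affine part, per-landmark kernel weights,
#' the landmark anchors and the smoothing parameter lambda. Fitted models map
#' source coordinates to template coordinates.
#'
#' @slot kind one of \code{"rigid"}, \code{"affine"}, \code{"tps"}.
#' @slot params model parameters (see Details).
#' @exportClass TransformModel
setClass("TransformModel", representation(
  kind = "character",
  params = "list"
))

setValidity("TransformModel", function(object) {
  if (!object@kind %in% c("rigid", "affine", "tps")) {
    return("kind must be rigid, affine or tps")
  }
  if (object@kind == "rigid") {
    R <- object@params$R
    if (!isTRUE(all.equal(crossprod(R), diag(2), tolerance = 1e-6)) ||
        det(R) < 0) {
      return("rigid rotation block must be orthonormal with determinant +1")
    }
  }
  if (object@kind == "tps") {
    P <- cbind(1, object@params$anchors)
    side <- crossprod(P, object@params$weights)
    if (max(abs(side)) > 1e-6 * max(1, max(abs(object@params$weights)))) {
      return("TPS weights must satisfy the side conditions")
    }
  }
  TRUE
})

# ---------------------------------------------------------------------------
# Federated search
# ---------------------------------------------------------------------------

#' Query: a federated search request
#'
#' @slot keywords character vector of free-text keywords (AND semantics).
#' @slot terms data.frame with columns \code{field}, \code{value}.
#' @slot sources names of the data sources to query.
#' @exportClass Query
setClass("Query", representation(
  keywords = "character",
  terms = "data.frame",
  sources = "character"
))

setValidity("Query", function(object) {
  if (!length(object@keywords) && !nrow(object@terms)) {
    return("query needs at least one keyword or term")
  }
  if (!length(object@sources)) return("query must select at least one source")
  TRUE
})

#' DataSource: the pluggable search backend contract
#'
#' A data source declares which search types it supports and which data types
#' it returns, and provides an \code{execute} function mapping a
#' \linkS4class{Query} to a list of \linkS4class{ResultRecord}. The engine
#' imposes nothing about how the source stores or accesses its data.
#'
#' @slot name unique source name.
#' @slot searchTypes subset of \code{c("keyword", "query_term")}.
#' @slot dataTypes data types this source can return.
#' @slot execute function(query) -> list of ResultRecord.
#' @exportClass DataSource
setClass("DataSource", representation(
  name = "character",
  searchTypes = "character",
  dataTypes = "character",
  execute = "function"
))

setValidity("DataSource", function(object) {
  if (!length(object@searchTypes) ||
      !all(object@searchTypes %in% c("keyword", "query_term"))) {
    return("searchTypes must be a non-empty subset of keyword, query_term")
  }
  TRUE
})

#' ResultRecord: one annotated search result
#'
#' @slot source name of the source that produced the record.
#' @slot dataType the record's data type (e.g. "2D Image").
#' @slot annotations named list of annotation values (text, number or URL);
#'   names unique.
#' @slot thumbnailRef optional preview locator (character or NULL).
#' @slot payloadRef optional data locator (character or NULL).
#' @exportClass ResultRecord
setClass("ResultRecord", representation(
  source = "character",
  dataType = "character",
  annotations = "list",
  thumbnailRef = "ANY",
  payloadRef = "ANY"
))

setValidity("ResultRecord", function(object) {
  if (length(object@annotations) && anyDuplicated(names(object@annotations))) {
    return("annotation names must be unique")
  }
  TRUE
})

#' ResultTable: query results grouped by (source, data type)
#'
#' @slot groups named list (key "source/dataType") of record lists.
#' @slot columnState per-group view state: \code{order}, \code{visible},
#'   \code{sortKey}, \code{sortDecreasing}, \code{expanded}.
#' @slot status named character, per selected source: "ok", "failed" or
#'   "skipped".
#' @slot messages named character, per-source status detail.
#' @exportClass ResultTable
setClass("ResultTable", representation(
  groups = "list",
  columnState = "list",
  status = "character",
  messages = "character"
))

#' Cart: the global container carrying results between workspaces
#'
#' @slot items list of \linkS4class{ResultRecord} in insertion (FIFO) order.
#' @slot duplicate logical vector flagging items equal to an earlier item.
#' @exportClass Cart
setClass("Cart", representation(
  items = "list",
  duplicate = "logical"
))
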