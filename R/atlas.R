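#' @include AllClasses.R volume-io.R hierarchy.R
NULL

#' Construct a label layer
#'
#' @param ids 3D non-negative integer array of label ids (0 = background).
#' @param labelSet the \linkS4class{LabelSet} for this layer.
#' @return a \linkS4class{LabelLayer}.
#' @export
labelLayer <- function(ids, labelSet) {
  storage.mode(ids) <- "integer"
  new("LabelLayer", ids = ids, labelSet = labelSet)
}

#' Construct an atlas
#'
#' Every nonzero id occurring in a layer's label volume should resolve in
#' that layer's label set; violations are reported in the atlas notes (not
#' fatal, matching a viewer that loads what it can and warns).
#'
#' @param layers list of \linkS4class{LabelLayer} (length >= 1).
#' @param reference optional \linkS4class{ImageVolume} on the same grid.
#' @param activeIndex 1-based active layer (default 1).
#' @return an \linkS4class{Atlas}.
#' @export
newAtlas <- function(layers, reference = NULL, activeIndex = 1L) {
  if (is(layers, "LabelLayer")) layers <- list(layers)
  notes <- character(0)
  for (i in seq_along(layers)) {
    lay <- layers[[i]]
    present <- setdiff(sort(unique(as.integer(lay@ids))), 0L)
    missing <- setdiff(present, lay@labelSet@nodes$id)
    if (length(missing)) {
      notes <- c(notes, sprintf(
        "layer %d ('%s'): label id(s) %s present in volume but absent from hierarchy",
        i, lay@labelSet@setName, paste(missing, collapse = ", ")))
    }
  }
  new("Atlas", reference = reference, layers = layers,
      activeIndex = as.integer(activeIndex), notes = notes)
}

#' Active layer index of an atlas
#' @param atlas an \linkS4class{Atlas}.
#' @return integer.
#' @export
activeIndex <- function(atlas) atlas@activeIndex

#' Set the active layer of an atlas
#' @param atlas an \linkS4class{Atlas}.
#' @param value new 1-based layer index.
#' @return the updated atlas.
#' @export
`activeIndex<-` <- function(atlas, value) {
  atlas@activeIndex <- as.integer(value)
  validObject(atlas)
  atlas
}

#' Label layers of an atlas
#' @param atlas an \linkS4class{Atlas}.
#' @return list of \linkS4class{LabelLayer}.
#' @export
atlasLayers <- function(atlas) atlas@layers

#' Reference volume of an atlas
#' @param atlas an \linkS4class{Atlas}.
#' @return an \linkS4class{ImageVolume} or NULL.
#' @export
atlasReference <- function(atlas) atlas@reference

#' Load-time notes of an atlas
#' @param atlas an \linkS4class{Atlas}.
#' @return character vector of warnings collected while validating layers.
#' @export
atlasNotes <- function(atlas) atlas@notes

setMethod("show", "Atlas", function(object) {
  d <- dim(object@layers[[1]]@ids)
  cat(sprintf("Atlas %dx%dx%d: %d label layer(s) [%s], active %d, %s reference\n",
              d[1], d[2], d[3], length(object@layers),
              paste(vapply(object@layers, function(l) l@labelSet@setName,
                           character(1)), collapse = ", "),
              object@activeIndex,
              if (is.null(object@reference)) "no" else "with"))
  if (length(object@notes)) cat(" ", paste(object@notes, collapse = "\n  "), "\n")
})

# ---------------------------------------------------------------------------
# .atlas bundle
# ---------------------------------------------------------------------------

#' Save an atlas as a bundle directory
#'
#' The bundle is a directory with a YAML manifest (\code{manifest.atlas})
#' naming the reference volume and, per layer, the label volume, the
#' hierarchy file and the set name; volumes are written as NIfTI and
#' hierarchies as ILF-dialect XML.
#'
#' @param atlas an \linkS4class{Atlas}.
#' @param path bundle directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
saveAtlas <- function(atlas, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(atlas = basename(path), layers = list())
  if (!is.null(atlas@reference)) {
    writeVolume(atlas@reference, file.path(path, "reference.nii"))
    manifest$reference <- "reference.nii"
  }
  for (i in seq_along(atlas@layers)) {
    lay <- atlas@layers[[i]]
    nm <- lay@labelSet@setName
    safe <- gsub("[^A-Za-z0-9_.-]", "_", nm)
    labFile <- sprintf("labels_%02d_%s.nii", i, safe)
    ilfFile <- sprintf("hierarchy_%02d_%s.ilf", i, safe)
    writeVolume(imageVolume(lay@ids), file.path(path, labFile))
    writeIlf(lay@labelSet, file.path(path, ilfFile))
    manifest$layers[[i]] <- list(name = nm, labels = labFile,
                                 hierarchy = ilfFile)
  }
  manifest$active <- atlas@activeIndex
  mf <- file.path(path, "manifest.atlas")
  yaml::write_yaml(manifest, mf)
  invisible(mf)
}

#' Load an atlas bundle
#'
#' @param path the bundle directory or its \code{manifest.atlas} file.
#' @return an \linkS4class{Atlas}; unresolvable label ids are reported in
#'   \code{\link{atlasNotes}}.
#' @export
loadAtlas <- function(path) {
  mf <- if (dir.exists(path)) file.path(path, "manifest.atlas") else path
  if (!file.exists(mf)) atkStop("not_found", "atlas manifest not found: %s", mf)
  root <- dirname(mf)
  manifest <- yaml::read_yaml(mf)
  reference <- NULL
  if (!is.null(manifest$reference)) {
    rf <- file.path(root, manifest$reference)
    if (!file.exists(rf)) atkStop("not_found", "reference volume not found: %s", rf)
    reference <- readVolume(rf)
  }
  if (!length(manifest$layers)) atkStop("format", "manifest lists no layers: %s", mf)
  layers <- lapply(manifest$layers, function(ly) {
    lf <- file.path(root, ly$labels); hf <- file.path(root, ly$hierarchy)
    if (!file.exists(lf)) atkStop("not_found", "label volume not found: %s", lf)
    if (!file.exists(hf)) atkStop("not_found", "hierarchy not found: %s", hf)
    ls <- parseIlf(hf)
    ls@setName <- ly$name %||% ls@setName
    labelLayer(volumeData(readVolume(lf)), ls)
  })
  newAtlas(layers, reference = reference,
           activeIndex = manifest$active %||% 1L)
}

# ---------------------------------------------------------------------------
# Lookup, selection, masking, overlay
# ---------------------------------------------------------------------------

.checkIjk <- function(ijk, dims) {
  ijk <- as.integer(ijk)
  if (length(ijk) != 3L || any(ijk < 1L) || any(ijk > dims)) {
    atkStop("bounds", "voxel (%s) outside grid %s",
            paste(ijk, collapse = ","), paste(dims, collapse = "x"))
  }
  ijk
}

#' All labels at a voxel, active set first
#'
#' One entry is returned per label layer whose id at the voxel is nonzero
#' and resolvable in that layer's label set; the active layer's entry comes
#' first and the rest follow in layer order. A background-only voxel yields
#' an empty table.
#'
#' @param atlas an \linkS4class{Atlas}.
#' @param ijk integer(3) voxel index.
#' @return data.frame (setName, id, abbrev, name, r, g, b), zero rows if the
#'   voxel is background everywhere.
#' @export
labelsAt <- function(atlas, ijk) {
  ijk <- .checkIjk(ijk, dim(atlas@layers[[1]]@ids))
  ord <- c(atlas@activeIndex, setdiff(seq_along(atlas@layers), atlas@activeIndex))
  rows <- list()
  for (li in ord) {
    lay <- atlas@layers[[li]]
    id <- lay@ids[ijk[1], ijk[2], ijk[3]]
    if (id == 0L || !id %in% lay@labelSet@nodes$id) next
    info <- labelInfo(lay@labelSet, id)
    rows[[length(rows) + 1L]] <- data.frame(
      setName = lay@labelSet@setName, id = info$id, abbrev = info$abbrev,
      name = info$name, r = info$r, g = info$g, b = info$b,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(setName = character(0), id = integer(0),
                      abbrev = character(0), name = character(0),
                      r = integer(0), g = integer(0), b = integer(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Create an empty selection state for an atlas
#'
#' @param atlas an \linkS4class{Atlas}.
#' @return a \linkS4class{SelectionState} with nothing selected or expanded.
#' @export
selectionState <- function(atlas) {
  empty <- replicate(length(atlas@layers), integer(0), simplify = FALSE)
  new("SelectionState", selected = empty, expanded = empty)
}

#' Selected ids of a layer
#' @param state a \linkS4class{SelectionState}.
#' @param layerIndex 1-based layer index.
#' @return sorted integer vector.
#' @export
selectedIds <- function(state, layerIndex = 1L) {
  sort(state@selected[[layerIndex]])
}

#' Toggle the label under a voxel in the active layer
#'
#' The active layer's id at the voxel flips its membership in the selection;
#' toggling a background voxel is a no-op (with a message).
#'
#' @param state a \linkS4class{SelectionState}.
#' @param atlas an \linkS4class{Atlas}.
#' @param ijk integer(3) voxel index.
#' @return the updated \linkS4class{SelectionState}.
#' @export
toggleLabel <- function(state, atlas, ijk) {
  ijk <- .checkIjk(ijk, dim(atlas@layers[[1]]@ids))
  li <- atlas@activeIndex
  id <- atlas@layers[[li]]@ids[ijk[1], ijk[2], ijk[3]]
  if (id == 0L) {
    message(sprintf("voxel (%s) is background in the active layer; nothing toggled",
                    paste(ijk, collapse = ",")))
    return(state)
  }
  sel <- state@selected[[li]]
  state@selected[[li]] <- if (id %in% sel) setdiff(sel, id) else c(sel, id)
  state
}

#' Select a node and all of its substructures
#'
#' Adds the node and every descendant in the layer's hierarchy to the
#' selection; idempotent and monotone (never removes ids).
#'
#' @param state a \linkS4class{SelectionState}.
#' @param atlas an \linkS4class{Atlas}.
#' @param layerIndex 1-based layer index.
#' @param nodeId label id of the subtree root.
#' @return the updated \linkS4class{SelectionState}.
#' @export
selectSubtree <- function(state, atlas, layerIndex, nodeId) {
  ls <- atlas@layers[[layerIndex]]@labelSet
  ids <- descendants(ls, nodeId)
  state@selected[[layerIndex]] <- sort(union(state@selected[[layerIndex]], ids))
  state
}

#' Deselect a node and all of its substructures
#'
#' @inheritParams selectSubtree
#' @return the updated \linkS4class{SelectionState}.
#' @export
deselectSubtree <- function(state, atlas, layerIndex, nodeId) {
  ls <- atlas@layers[[layerIndex]]@labelSet
  ids <- descendants(ls, nodeId)
  state@selected[[layerIndex]] <- sort(setdiff(state@selected[[layerIndex]], ids))
  state
}

#' Binary mask of a set of label ids
#'
#' @param atlas an \linkS4class{Atlas}.
#' @param layerIndex 1-based layer index.
#' @param ids label ids to include (empty set gives an all-FALSE mask).
#' @return logical 3D array, TRUE where the layer's label id is in
#'   \code{ids}.
#' @export
regionMask <- function(atlas, layerIndex, ids) {
  lay <- atlas@layers[[layerIndex]]
  array(lay@ids %in% as.integer(ids), dim(lay@ids))
}

#' Zero the reference outside the labeled foreground
#'
#' Returns a copy of the reference volume with intensity set to 0 wherever
#' the active label volume is background.
#'
#' @param atlas an \linkS4class{Atlas} with a reference volume.
#' @return an \linkS4class{ImageVolume}.
#' @export
maskBackground <- function(atlas) {
  if (is.null(atlas@reference)) {
    atkStop("state", "atlas has no reference volume to mask")
  }
  ref <- atlas@reference
  dat <- ref@data
  dat[atlas@layers[[atlas@activeIndex]]@ids == 0L] <- 0
  imageVolume(dat, voxelSize = ref@voxelSize, origin = ref@origin,
              axisLabels = ref@axisLabels)
}

#' Render the colored label overlay for a slice
#'
#' Per pixel: if the active layer's label id is nonzero and either nothing
#' is selected (an untouched atlas shows all delineations) or the id lies in
#' the selection or below a selected node, the output takes that label's
#' color with alpha = opacity; otherwise the pixel is fully transparent.
#'
#' @param atlas an \linkS4class{Atlas}.
#' @param state a \linkS4class{SelectionState} (NULL = empty selection).
#' @param axis,index slice specification (see \code{\link{extractSlice}}).
#' @param opacity overlay alpha in [0,1].
#' @return an RGBA \linkS4class{Image2D}.
#' @export
renderLabelOverlay <- function(atlas, state = NULL, axis, index, opacity = 0.5) {
  if (opacity < 0 || opacity > 1) {
    atkStop("validation", "opacity must be in [0,1]")
  }
  li <- atlas@activeIndex
  lay <- atlas@layers[[li]]
  d <- dim(lay@ids)
  .checkSlice(axis, index, d)
  plane <- switch(axis,
                  lay@ids[index, , , drop = TRUE],
                  lay@ids[, index, , drop = TRUE],
                  lay@ids[, , index, drop = TRUE])
  plane <- as.matrix(plane)
  n <- lay@labelSet@nodes
  sel <- if (is.null(state)) integer(0) else state@selected[[li]]
  visible <- if (length(sel)) {
    sort(unique(unlist(lapply(sel, function(s)
      if (s %in% n$id) descendants(lay@labelSet, s) else integer(0)))))
  } else {
    n$id
  }
  idx <- match(plane, n$id)           # NA for background/unresolvable
  on <- !is.na(idx) & plane != 0L & (plane %in% visible)
  h <- nrow(plane); w <- ncol(plane)
  out <- array(0, c(h, w, 4))
  ii <- which(on)
  if (length(ii)) {
    out[ii] <- n$r[idx[ii]] / 255
    out[ii + h * w] <- n$g[idx[ii]] / 255
    out[ii + 2 * h * w] <- n$b[idx[ii]] / 255
    out[ii + 3 * h * w] <- opacity
  }
  ps <- if (!is.null(atlas@reference)) atlas@reference@voxelSize[-axis] else c(1, 1)
  image2d(out, pixelSize = ps)
}
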