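#' @include atlas.R
NULL

# The event bus is reference-semantic (an environment) because publishers
# and subscribers on both sides of the atlas/graph link mutate shared state.

#' Create an event bus
#'
#' Events are delivered synchronously in FIFO order per publisher through a
#' queue, which makes delivery re-entrant safe: a handler that publishes
#' while an event is being dispatched only appends to the queue. An event
#' identical (kind, layer, payload) to one currently in flight is suppressed,
#' which prevents infinite select/highlight echo loops between linked views.
#' A handler error is caught and logged and does not block other handlers.
#'
#' @return an event bus object.
#' @export
eventBus <- function() {
  bus <- new.env(parent = emptyenv())
  bus$handlers <- list()
  bus$queue <- list()
  bus$inflight <- list()
  bus$dispatching <- FALSE
  bus$log <- list()
  class(bus) <- "EventBus"
  bus
}

#' Build an atlas event
#'
#' @param kind one of select, deselect, expand, collapse,
#'   send_names_to_search, send_location_to_search.
#' @param layerIndex 1-based label layer the event refers to.
#' @param payload label ids, structure names or a voxel index, depending on
#'   \code{kind}.
#' @return an immutable event (a plain list).
#' @export
atlasEvent <- function(kind, layerIndex = 1L, payload = NULL) {
  kinds <- c("select", "deselect", "expand", "collapse",
             "send_names_to_search", "send_location_to_search")
  if (!kind %in% kinds) {
    atkStop("validation", "unknown event kind '%s'", kind)
  }
  list(kind = kind, layerIndex = as.integer(layerIndex), payload = payload)
}

#' Subscribe a handler to a bus
#'
#' @param bus an event bus.
#' @param handler function(event) called for every published event.
#' @param name optional handler name (used in the error log).
#' @return the handler name, invisibly.
#' @export
subscribe <- function(bus, handler, name = NULL) {
  name <- name %||% sprintf("handler%d", length(bus$handlers) + 1L)
  bus$handlers[[name]] <- handler
  invisible(name)
}

#' Publish an event on a bus
#'
#' @param bus an event bus.
#' @param event an event from \code{\link{atlasEvent}}.
#' @return invisibly, TRUE if the event was queued and FALSE if it was
#'   suppressed as an echo of an event currently being processed.
#' @export
publish <- function(bus, event) {
  key <- list(event$kind, event$layerIndex, event$payload)
  echo <- any(vapply(bus$inflight, identical, logical(1), key))
  bus$log[[length(bus$log) + 1L]] <- list(event = event, suppressed = echo)
  if (echo) return(invisible(FALSE))
  bus$queue[[length(bus$queue) + 1L]] <- event
  if (!bus$dispatching) {
    bus$dispatching <- TRUE
    on.exit(bus$dispatching <- FALSE)
    while (length(bus$queue)) {
      ev <- bus$queue[[1L]]
      bus$queue <- bus$queue[-1L]
      k <- list(ev$kind, ev$layerIndex, ev$payload)
      bus$inflight[[length(bus$inflight) + 1L]] <- k
      for (nm in names(bus$handlers)) {
        tryCatch(bus$handlers[[nm]](ev), error = function(e) {
          bus$log[[length(bus$log) + 1L]] <<-
            list(handlerError = nm, message = conditionMessage(e))
        })
      }
      bus$inflight <- bus$inflight[-length(bus$inflight)]
    }
  }
  invisible(TRUE)
}

#' Event log of a bus
#' @param bus an event bus.
#' @return list of log entries (published/suppressed events, handler errors).
#' @export
busLog <- function(bus) bus$log

# ---------------------------------------------------------------------------
# Atlas <-> graph viewer <-> search synchronization
# ---------------------------------------------------------------------------

#' Link an atlas, a graph viewer and a search outbox over one event bus
#'
#' Models the synchronized trio of views: selection events from either the
#' atlas side (double-clicking a region) or the graph side (clicking a node,
#' which acts on the whole subtree) flow through the bus, and at quiescence
#' the atlas selection and the graph highlight set are identical. Send-to-
#' search events capture the selected structure names, or the world
#' coordinate of a voxel, into the link's search outbox.
#'
#' @param atlas an \linkS4class{Atlas}.
#' @return a link object (environment) with fields \code{bus}, \code{atlas},
#'   \code{state} (a \linkS4class{SelectionState}), \code{highlights}
#'   (per-layer highlighted ids), \code{searchKeywords} and
#'   \code{searchLocation}.
#' @export
atlasGraphLink <- function(atlas) {
  link <- new.env(parent = emptyenv())
  link$bus <- eventBus()
  link$atlas <- atlas
  link$state <- selectionState(atlas)
  link$highlights <- replicate(length(atlas@layers), integer(0),
                               simplify = FALSE)
  link$searchKeywords <- character(0)
  link$searchLocation <- NULL
  class(link) <- "AtlasGraphLink"

  subscribe(link$bus, function(ev) {      # atlas side
    li <- ev$layerIndex
    if (ev$kind == "select") {
      link$state@selected[[li]] <-
        sort(union(link$state@selected[[li]], ev$payload))
    } else if (ev$kind == "deselect") {
      link$state@selected[[li]] <-
        sort(setdiff(link$state@selected[[li]], ev$payload))
    }
  }, "atlasView")

  subscribe(link$bus, function(ev) {      # graph viewer side
    li <- ev$layerIndex
    if (ev$kind == "select") {
      link$highlights[[li]] <- sort(union(link$highlights[[li]], ev$payload))
    } else if (ev$kind == "deselect") {
      link$highlights[[li]] <- sort(setdiff(link$highlights[[li]], ev$payload))
    } else if (ev$kind == "expand") {
      link$state@expanded[[li]] <-
        sort(union(link$state@expanded[[li]], ev$payload))
    } else if (ev$kind == "collapse") {
      link$state@expanded[[li]] <-
        sort(setdiff(link$state@expanded[[li]], ev$payload))
    }
  }, "graphView")

  subscribe(link$bus, function(ev) {      # search workspace side
    if (ev$kind == "send_names_to_search") {
      li <- ev$layerIndex
      ls <- link$atlas@layers[[li]]@labelSet
      sel <- link$state@selected[[li]]
      link$searchKeywords <-
        ls@nodes$name[match(sel, ls@nodes$id)][sel %in% ls@nodes$id]
    } else if (ev$kind == "send_location_to_search") {
      ref <- link$atlas@reference
      link$searchLocation <- if (!is.null(ref)) {
        voxelToWorld(ref, ev$payload)
      } else {
        as.numeric(ev$payload) - 1   # unit geometry fallback
      }
    }
  }, "searchOutbox")

  link
}

#' Toggle a label from the atlas side of a link
#'
#' Publishes a select or deselect event for the active layer's id under the
#' voxel, as a double-click in the atlas view would.
#'
#' @param link an \code{\link{atlasGraphLink}}.
#' @param ijk integer(3) voxel index.
#' @return the id acted on (0 for a background voxel), invisibly.
#' @export
linkToggleAtlas <- function(link, ijk) {
  atlas <- link$atlas
  ijk <- .checkIjk(ijk, dim(atlas@layers[[1]]@ids))
  li <- atlas@activeIndex
  id <- atlas@layers[[li]]@ids[ijk[1], ijk[2], ijk[3]]
  if (id == 0L) return(invisible(0L))
  kind <- if (id %in% link$state@selected[[li]]) "deselect" else "select"
  publish(link$bus, atlasEvent(kind, li, id))
  invisible(id)
}

#' Select or deselect a subtree from the graph side of a link
#'
#' Clicking a node in the graph viewer acts on the node and all of its
#' substructures.
#'
#' @param link an \code{\link{atlasGraphLink}}.
#' @param layerIndex 1-based layer index.
#' @param nodeId label id of the clicked node.
#' @param select TRUE to select (default), FALSE to deselect.
#' @return the resolved id set, invisibly.
#' @export
linkGraphSelect <- function(link, layerIndex, nodeId, select = TRUE) {
  ls <- link$atlas@layers[[layerIndex]]@labelSet
  ids <- descendants(ls, nodeId)
  publish(link$bus,
          atlasEvent(if (select) "select" else "deselect", layerIndex, ids))
  invisible(ids)
}

#' Send the selected structure names to the search outbox
#' @param link an \code{\link{atlasGraphLink}}.
#' @param layerIndex 1-based layer index.
#' @return the captured keywords, invisibly.
#' @export
sendNamesToSearch <- function(link, layerIndex = NULL) {
  li <- layerIndex %||% link$atlas@activeIndex
  publish(link$bus, atlasEvent("send_names_to_search", li))
  invisible(link$searchKeywords)
}

#' Send a voxel's world location to the search outbox
#' @param link an \code{\link{atlasGraphLink}}.
#' @param ijk integer(3) voxel index.
#' @return the captured world coordinate, invisibly.
#' @export
sendLocationToSearch <- function(link, ijk) {
  publish(link$bus,
          atlasEvent("send_location_to_search", link$atlas@activeIndex, ijk))
  invisible(link$searchLocation)
}

#' Current atlas selection of a link
#' @param link an \code{\link{atlasGraphLink}}.
#' @param layerIndex 1-based layer index.
#' @return sorted integer vector.
#' @export
atlasSelection <- function(link, layerIndex = 1L) {
  sort(link$state@selected[[layerIndex]])
}

#' Current graph highlight set of a link
#' @param link an \code{\link{atlasGraphLink}}.
#' @param layerIndex 1-based layer index.
#' @return sorted integer vector.
#' @export
graphHighlights <- function(link, layerIndex = 1L) {
  sort(link$highlights[[layerIndex]])
}
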