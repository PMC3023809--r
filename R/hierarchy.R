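#' @include AllClasses.R
NULL

#' Construct a label set from a node table
#'
#' @param nodes data.frame with columns \code{id}, \code{abbrev},
#'   \code{name}, \code{r}, \code{g}, \code{b}, \code{parent} (NA for
#'   roots); row order is sibling/file order.
#' @param setName context name of the set.
#' @param notes optional parse warnings to carry along.
#' @return a \linkS4class{LabelSet}.
#' @export
labelSet <- function(nodes, setName = "labels", notes = character(0)) {
  nodes$id <- as.integer(nodes$id)
  nodes$parent <- as.integer(nodes$parent)
  for (col in c("r", "g", "b")) nodes[[col]] <- as.integer(nodes[[col]])
  nodes$abbrev <- as.character(nodes$abbrev)
  nodes$name <- as.character(nodes$name)
  # normalize to depth-first pre-order (sibling order = input row order) so
  # that structurally equal sets compare equal regardless of input row order;
  # skipped for malformed tables, which validity rejects with a clear message
  if (nrow(nodes) && !anyDuplicated(nodes$id) &&
      all(is.na(nodes$parent) | nodes$parent %in% nodes$id)) {
    ord <- integer(0)
    visit <- function(rows) {
      for (i in rows) {
        ord <<- c(ord, i)
        visit(which(!is.na(nodes$parent) & nodes$parent == nodes$id[i]))
      }
    }
    visit(which(is.na(nodes$parent)))
    if (length(ord) == nrow(nodes)) nodes <- nodes[ord, , drop = FALSE]
  }
  rownames(nodes) <- NULL
  new("LabelSet", setName = setName, nodes = nodes, notes = notes)
}

#' Number of labels in a set
#' @param x a \linkS4class{LabelSet}.
#' @return integer.
#' @export
nLabels <- function(x) nrow(x@nodes)

#' All label ids in a set
#' @param x a \linkS4class{LabelSet}.
#' @return integer vector in file order.
#' @export
labelIds <- function(x) x@nodes$id

#' Context name of a label set
#' @param x a \linkS4class{LabelSet}.
#' @return character.
#' @export
setName <- function(x) x@setName

#' Node table of a label set
#' @param x a \linkS4class{LabelSet}.
#' @return the nodes data.frame.
#' @export
labelNodes <- function(x) x@nodes

#' Look up one label
#' @param x a \linkS4class{LabelSet}.
#' @param id label id.
#' @return one-row data.frame (id, abbrev, name, r, g, b, parent).
#' @export
labelInfo <- function(x, id) {
  i <- match(as.integer(id), x@nodes$id)
  if (is.na(i)) atkStop("key", "unknown label id %s in set '%s'", id, x@setName)
  x@nodes[i, , drop = FALSE]
}

setMethod("show", "LabelSet", function(object) {
  roots <- sum(is.na(object@nodes$parent))
  cat(sprintf("LabelSet '%s': %d labels, %d root(s)\n",
              object@setName, nrow(object@nodes), roots))
  if (length(object@notes)) {
    cat(sprintf("  %d note(s), e.g.: %s\n", length(object@notes),
                object@notes[1]))
  }
})

# ---------------------------------------------------------------------------
# ILF-dialect XML
# ---------------------------------------------------------------------------

.attrOr <- function(node, attr, default) {
  v <- xml2::xml_attr(node, attr)
  if (is.na(v)) default else v
}

.parseColor <- function(s, context) {
  if (is.na(s)) atkStop("format", "missing color%s", context)
  parts <- suppressWarnings(as.integer(strsplit(s, ",")[[1]]))
  if (length(parts) != 3L || any(is.na(parts)) ||
      any(parts < 0L) || any(parts > 255L)) {
    atkStop("format", "malformed color \"%s\"%s", s, context)
  }
  parts
}

#' Parse a label hierarchy from ILF-dialect XML
#'
#' The dialect is an XML document whose root element \code{labelset} carries
#' a \code{name} attribute and contains nested \code{label} elements with
#' attributes \code{id}, \code{abbrev}, \code{name} and \code{color="R,G,B"};
#' element nesting encodes parentage and document order is sibling order.
#'
#' @param path path to the .ilf file.
#' @return a \linkS4class{LabelSet}.
#' @export
parseIlf <- function(path) {
  if (!file.exists(path)) atkStop("not_found", "hierarchy file not found: %s", path)
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) atkStop("format", "not valid XML: %s (%s)",
                                              path, conditionMessage(e)))
  root <- doc
  if (xml2::xml_name(root) != "labelset") {
    atkStop("format", "expected <labelset> root in %s", path)
  }
  lines <- readLines(path, warn = FALSE)
  rows <- list()
  walk <- function(node, parent) {
    for (child in xml2::xml_children(node)) {
      if (xml2::xml_name(child) != "label") next
      id <- suppressWarnings(as.integer(xml2::xml_attr(child, "id")))
      if (is.na(id)) atkStop("format", "label with missing or bad id in %s", path)
      colorStr <- xml2::xml_attr(child, "color")
      lineno <- if (is.na(colorStr)) NA_integer_ else
        grep(sprintf('color="%s"', colorStr), lines, fixed = TRUE)[1]
      ctx <- if (!is.na(lineno)) sprintf(" at line %d of %s", lineno, path)
             else sprintf(" in %s", path)
      col <- .parseColor(colorStr, ctx)
      rows[[length(rows) + 1L]] <<- data.frame(
        id = id,
        abbrev = .attrOr(child, "abbrev", ""),
        name = .attrOr(child, "name", ""),
        r = col[1], g = col[2], b = col[3],
        parent = if (is.na(parent)) NA_integer_ else parent,
        stringsAsFactors = FALSE)
      walk(child, id)
    }
  }
  walk(root, NA_integer_)
  nodes <- do.call(rbind, rows)
  if (is.null(nodes) || !nrow(nodes)) {
    atkStop("format", "no labels found in %s", path)
  }
  if (anyDuplicated(nodes$id)) {
    atkStop("validation", "duplicate label id %d in %s",
            nodes$id[duplicated(nodes$id)][1L], path)
  }
  labelSet(nodes, setName = .attrOr(root, "name", "labels"))
}

#' Write a label set as ILF-dialect XML
#'
#' Inverse of \code{\link{parseIlf}}: write then parse reproduces the set
#' (ids, names, abbreviations, colors, child order).
#'
#' @param labelset a \linkS4class{LabelSet}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeIlf <- function(labelset, path) {
  doc <- xml2::xml_new_root("labelset", name = labelset@setName)
  n <- labelset@nodes
  addChildren <- function(node, parent) {
    rows <- which(if (is.na(parent)) is.na(n$parent) else !is.na(n$parent) & n$parent == parent)
    for (i in rows) {
      el <- xml2::xml_add_child(node, "label",
        id = as.character(n$id[i]), abbrev = n$abbrev[i], name = n$name[i],
        color = sprintf("%d,%d,%d", n$r[i], n$g[i], n$b[i]))
      addChildren(el, n$id[i])
    }
  }
  addChildren(doc, NA_integer_)
  xml2::write_xml(doc, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# OBO 1.2
# ---------------------------------------------------------------------------

#' Parse an OBO 1.2 ontology into a label set
#'
#' Term stanzas with \code{is_a} edges are reduced to a single-parent tree:
#' a term with several \code{is_a} parents keeps the lexically first one and
#' a note recording the dropped edge(s) is attached to the result. Term ids
#' are mapped to integer label ids either through optional
#' \code{id-mapping: TERM <int>} header lines or, failing that, sequentially
#' in file order. Node colors are assigned deterministically around the hue
#' wheel. Cyclic \code{is_a} chains are an error naming one cycle.
#'
#' @param path path to the .obo file.
#' @param setName context name for the resulting set (default the ontology
#'   name from the header, or the file name).
#' @return a \linkS4class{LabelSet}.
#' @export
parseObo <- function(path, setName = NULL) {
  if (!file.exists(path)) atkStop("not_found", "OBO file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  idmap <- integer(0)
  ontName <- NULL
  inTerm <- FALSE
  terms <- list()
  cur <- NULL
  flush <- function() {
    if (!is.null(cur) && !is.null(cur$id)) terms[[length(terms) + 1L]] <<- cur
    cur <<- NULL
  }
  for (ln in lines) {
    ln <- sub("!.*$", "", ln)
    ln <- trimws(ln)
    if (ln == "") next
    if (grepl("^\\[", ln)) {
      flush()
      inTerm <- identical(ln, "[Term]")
      if (inTerm) cur <- list(isa = character(0))
      next
    }
    kv <- regmatches(ln, regexec("^([A-Za-z_-]+):\\s*(.*)$", ln))[[1]]
    if (length(kv) != 3L) next
    key <- kv[2]; val <- trimws(kv[3])
    if (!inTerm) {
      if (key == "ontology") ontName <- val
      if (key == "id-mapping") {
        parts <- strsplit(val, "\\s+")[[1]]
        if (length(parts) == 2L) idmap[parts[1]] <- as.integer(parts[2])
      }
      next
    }
    if (key == "id") cur$id <- val
    if (key == "name") cur$name <- val
    if (key == "is_a") cur$isa <- c(cur$isa, sub("\\s*\\{.*\\}$", "", val))
  }
  flush()
  if (!length(terms)) atkStop("format", "no [Term] stanzas in %s", path)
  termIds <- vapply(terms, function(t) t$id, character(1))
  if (anyDuplicated(termIds)) {
    atkStop("validation", "duplicate term id %s in %s",
            termIds[duplicated(termIds)][1L], path)
  }
  notes <- character(0)
  parents <- character(length(terms))
  for (i in seq_along(terms)) {
    isa <- intersect(sort(terms[[i]]$isa), termIds)
    parents[i] <- if (length(isa)) isa[1L] else NA_character_
    if (length(isa) > 1L) {
      notes <- c(notes, sprintf(
        "term %s: kept is_a parent %s, dropped %s", termIds[i], isa[1L],
        paste(isa[-1L], collapse = ", ")))
    }
  }
  # cycle check on the reduced parent map
  pidx <- match(parents, termIds)
  for (i in seq_along(terms)) {
    seen <- integer(0); j <- i
    while (!is.na(pidx[j])) {
      if (j %in% seen) {
        cyc <- termIds[c(seen[which(seen == j):length(seen)], j)]
        atkStop("validation", "cyclic is_a chain: %s",
                paste(unique(cyc), collapse = " -> "))
      }
      seen <- c(seen, j); j <- pidx[j]
    }
  }
  ids <- if (length(idmap)) {
    miss <- setdiff(termIds, names(idmap))
    nxt <- if (length(idmap)) max(idmap) else 0L
    extra <- seq_along(miss) + nxt
    names(extra) <- miss
    unname(c(idmap, extra)[termIds])
  } else {
    seq_along(termIds)
  }
  hue <- (seq_along(termIds) - 1) / max(1L, length(termIds))
  cols <- t(grDevices::col2rgb(grDevices::hsv(hue, 0.65, 0.95)))
  nodes <- data.frame(
    id = as.integer(ids),
    abbrev = termIds,
    name = vapply(terms, function(t) t$name %||% t$id, character(1)),
    r = cols[, 1], g = cols[, 2], b = cols[, 3],
    parent = as.integer(ids[pidx]),
    stringsAsFactors = FALSE)
  labelSet(nodes, setName = setName %||% ontName %||%
             tools::file_path_sans_ext(basename(path)),
           notes = notes)
}

# ---------------------------------------------------------------------------
# Traversal and search
# ---------------------------------------------------------------------------

#' Descendant ids of a node (inclusive)
#'
#' Returns the query id together with every id strictly below it, matching
#' atlas selection semantics: selecting a parent structure selects the
#' structure itself and all of its substructures.
#'
#' @param labelset a \linkS4class{LabelSet}.
#' @param id query label id.
#' @return sorted integer vector of ids.
#' @export
descendants <- function(labelset, id) {
  n <- labelset@nodes
  id <- as.integer(id)
  if (!id %in% n$id) atkStop("key", "unknown label id %d", id)
  acc <- id
  frontier <- id
  repeat {
    kids <- n$id[!is.na(n$parent) & n$parent %in% frontier]
    kids <- setdiff(kids, acc)
    if (!length(kids)) break
    acc <- c(acc, kids)
    frontier <- kids
  }
  sort(acc)
}

#' Depth of every node (root = 0)
#' @param labelset a \linkS4class{LabelSet}.
#' @return named integer vector, names are label ids.
#' @export
labelDepths <- function(labelset) {
  n <- labelset@nodes
  pidx <- match(n$parent, n$id)
  depth <- integer(nrow(n))
  for (i in seq_len(nrow(n))) {
    d <- 0L; j <- i
    while (!is.na(pidx[j])) { d <- d + 1L; j <- pidx[j] }
    depth[i] <- d
  }
  names(depth) <- n$id
  depth
}

#' Search labels by text pattern
#'
#' Case-insensitive plain substring match against the abbreviation or full
#' name of each label.
#'
#' @param labelset a \linkS4class{LabelSet}.
#' @param pattern non-empty substring to look for.
#' @return integer vector of matching ids (file order).
#' @export
searchLabels <- function(labelset, pattern) {
  if (!is.character(pattern) || length(pattern) != 1L || !nzchar(pattern)) {
    atkStop("validation", "search pattern must be a non-empty string")
  }
  n <- labelset@nodes
  pat <- tolower(pattern)
  hit <- grepl(pat, tolower(n$abbrev), fixed = TRUE) |
         grepl(pat, tolower(n$name), fixed = TRUE)
  n$id[hit]
}

# ---------------------------------------------------------------------------
# Graph layouts
# ---------------------------------------------------------------------------

# children row indices per node, in file (sibling) order
.childIndex <- function(n) {
  lapply(n$id, function(id) which(!is.na(n$parent) & n$parent == id))
}

# number of leaves under each node (itself if leaf)
.leafCounts <- function(n, childIdx) {
  counts <- rep(NA_real_, nrow(n))
  count <- function(i) {
    if (!is.na(counts[i])) return(counts[i])
    kids <- childIdx[[i]]
    counts[i] <<- if (!length(kids)) 1 else sum(vapply(kids, count, numeric(1)))
    counts[i]
  }
  for (i in seq_len(nrow(n))) count(i)
  counts
}

#' Radial graph layout: generations on concentric circles
#'
#' Each depth-g node is placed on the circle of radius g * ringSpacing, with
#' roots at the origin. Children occupy disjoint angular sectors nested
#' within their parent's sector, sized proportionally to leaf counts with
#' ties broken by file order; a node sits at the midpoint of its sector.
#' Positions are deterministic for a fixed input.
#'
#' @param labelset a non-empty \linkS4class{LabelSet}.
#' @param ringSpacing radial distance between generations (default 1).
#' @return data.frame (id, x, y, depth) with attribute \code{style} set to
#'   \code{"radial"}.
#' @export
layoutRadial <- function(labelset, ringSpacing = 1) {
  n <- labelset@nodes
  childIdx <- .childIndex(n)
  leaves <- .leafCounts(n, childIdx)
  depth <- unname(labelDepths(labelset))
  a0 <- a1 <- numeric(nrow(n))
  assign_ <- function(i, lo, hi) {
    a0[i] <<- lo; a1[i] <<- hi
    kids <- childIdx[[i]]
    if (!length(kids)) return(invisible())
    w <- leaves[kids] / sum(leaves[kids])
    cuts <- lo + c(0, cumsum(w)) * (hi - lo)
    for (j in seq_along(kids)) assign_(kids[j], cuts[j], cuts[j + 1])
  }
  roots <- which(is.na(n$parent))
  w <- leaves[roots] / sum(leaves[roots])
  cuts <- c(0, cumsum(w)) * 2 * pi
  for (j in seq_along(roots)) assign_(roots[j], cuts[j], cuts[j + 1])
  ang <- (a0 + a1) / 2
  r <- depth * ringSpacing
  out <- data.frame(id = n$id, x = r * cos(ang), y = r * sin(ang),
                    depth = depth)
  out$x[depth == 0] <- 0; out$y[depth == 0] <- 0
  attr(out, "style") <- "radial"
  attr(out, "sector") <- cbind(a0, a1)
  out
}

#' Linear graph layout: generations left to right
#'
#' Every node sits at x = depth * columnSpacing. Leaves get consecutive
#' integer y (0, 1, 2, ...) in depth-first file order; each internal node is
#' centered at the mean y of its children.
#'
#' @param labelset a non-empty \linkS4class{LabelSet}.
#' @param columnSpacing horizontal distance between generations (default 1).
#' @return data.frame (id, x, y, depth) with attribute \code{style} set to
#'   \code{"linear"}.
#' @export
layoutLinear <- function(labelset, columnSpacing = 1) {
  n <- labelset@nodes
  childIdx <- .childIndex(n)
  depth <- unname(labelDepths(labelset))
  y <- rep(NA_real_, nrow(n))
  nextLeaf <- 0
  place <- function(i) {
    kids <- childIdx[[i]]
    if (!length(kids)) {
      y[i] <<- nextLeaf
      nextLeaf <<- nextLeaf + 1
    } else {
      for (k in kids) place(k)
      y[i] <<- mean(y[kids])
    }
  }
  for (rt in which(is.na(n$parent))) place(rt)
  out <- data.frame(id = n$id, x = depth * columnSpacing, y = y,
                    depth = depth)
  attr(out, "style") <- "linear"
  out
}
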