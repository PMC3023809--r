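#' @include AllClasses.R
NULL

#' Construct a federated search query
#'
#' @param keywords character vector of free-text keywords. A record matches
#'   when every keyword occurs (case-insensitive) somewhere in its text —
#'   AND semantics across keywords.
#' @param terms named character vector or data.frame (field, value) of
#'   field-targeted query terms.
#' @param sources names of the data sources to query.
#' @return a \linkS4class{Query}.
#' @export
newQuery <- function(keywords = character(0), terms = NULL, sources) {
  if (is.null(terms)) {
    terms <- data.frame(field = character(0), value = character(0))
  } else if (!is.data.frame(terms)) {
    terms <- data.frame(field = names(terms), value = as.character(terms))
  }
  q <- new("Query", keywords = as.character(keywords), terms = terms,
           sources = as.character(sources))
  q
}

#' Keywords of a query
#' @param query a \linkS4class{Query}.
#' @return character vector.
#' @export
queryKeywords <- function(query) query@keywords

#' Terms of a query
#' @param query a \linkS4class{Query}.
#' @return data.frame (field, value).
#' @export
queryTerms <- function(query) query@terms

#' Construct a result record
#'
#' @param source producing source name.
#' @param dataType the record's data type.
#' @param annotations named list of text/number/URL annotation values.
#' @param thumbnailRef,payloadRef optional locators.
#' @return a \linkS4class{ResultRecord}.
#' @export
resultRecord <- function(source, dataType, annotations = list(),
                         thumbnailRef = NULL, payloadRef = NULL) {
  new("ResultRecord", source = source, dataType = dataType,
      annotations = annotations, thumbnailRef = thumbnailRef,
      payloadRef = payloadRef)
}

#' Annotations of a record
#' @param record a \linkS4class{ResultRecord}.
#' @return named list.
#' @export
recordAnnotations <- function(record) record@annotations

setMethod("show", "ResultRecord", function(object) {
  cat(sprintf("ResultRecord [%s | %s]: %s\n", object@source, object@dataType,
              paste(sprintf("%s=%s", names(object@annotations),
                            vapply(object@annotations, format, character(1))),
                    collapse = ", ")))
})

#' Construct a data source
#'
#' @param name unique source name.
#' @param searchTypes subset of \code{c("keyword", "query_term")}.
#' @param dataTypes data types the source returns.
#' @param execute function(query) -> list of \linkS4class{ResultRecord}.
#' @return a \linkS4class{DataSource}.
#' @export
dataSource <- function(name, searchTypes, dataTypes, execute) {
  new("DataSource", name = name, searchTypes = searchTypes,
      dataTypes = dataTypes, execute = execute)
}

setMethod("show", "DataSource", function(object) {
  cat(sprintf("DataSource '%s' [%s] -> %s\n", object@name,
              paste(object@searchTypes, collapse = ", "),
              paste(object@dataTypes, collapse = ", ")))
})

# ---------------------------------------------------------------------------
# Source registry
# ---------------------------------------------------------------------------

#' Create an empty data-source registry
#' @return a registry (environment keyed by source name).
#' @export
sourceRegistry <- function() {
  reg <- new.env(parent = emptyenv())
  class(reg) <- "SourceRegistry"
  reg
}

#' Register a data source
#' @param registry a \code{\link{sourceRegistry}}.
#' @param source a \linkS4class{DataSource}.
#' @return the source name, invisibly.
#' @export
registerSource <- function(registry, source) {
  if (source@name %in% ls(registry)) {
    atkStop("registration", "source '%s' is already registered", source@name)
  }
  assign(source@name, source, envir = registry)
  invisible(source@name)
}

#' Names of registered sources
#' @param registry a \code{\link{sourceRegistry}}.
#' @return sorted character vector.
#' @export
listSources <- function(registry) sort(ls(registry))

# ---------------------------------------------------------------------------
# Query execution
# ---------------------------------------------------------------------------

.groupKey <- function(source, dataType) paste(source, dataType, sep = "/")

#' Run a query against every selected source
#'
#' The query is fanned out source by source, each source receiving only the
#' search types it declares (a keyword-only source gets keywords, a term
#' source gets terms); a source given nothing it understands is skipped with
#' status "skipped". A source that throws yields status "failed" and does
#' not affect the other sources' groups. Results are grouped by (source,
#' data type), groups ordered by source name then data type, records in
#' source-returned order.
#'
#' @param query a \linkS4class{Query}.
#' @param registry the \code{\link{sourceRegistry}} holding the selected
#'   sources.
#' @return a \linkS4class{ResultTable}.
#' @export
runQuery <- function(query, registry) {
  validObject(query)
  missing <- setdiff(query@sources, ls(registry))
  if (length(missing)) {
    atkStop("config", "unregistered source(s): %s",
            paste(missing, collapse = ", "))
  }
  status <- character(0); messages <- character(0)
  records <- list()
  for (nm in sort(query@sources)) {
    src <- get(nm, envir = registry)
    kw <- if ("keyword" %in% src@searchTypes) query@keywords else character(0)
    tm <- if ("query_term" %in% src@searchTypes) query@terms else
      data.frame(field = character(0), value = character(0))
    if (!length(kw) && !nrow(tm)) {
      status[nm] <- "skipped"
      messages[nm] <- "unsupported search type"
      next
    }
    sub <- new("Query", keywords = kw, terms = tm, sources = nm)
    res <- tryCatch(list(ok = TRUE, records = src@execute(sub)),
                    error = function(e) list(ok = FALSE,
                                             msg = conditionMessage(e)))
    if (!res$ok) {
      status[nm] <- "failed"
      messages[nm] <- res$msg
      next
    }
    status[nm] <- "ok"
    messages[nm] <- ""
    records <- c(records, res$records)
  }
  groups <- list()
  for (rec in records) {
    key <- .groupKey(rec@source, rec@dataType)
    groups[[key]] <- append(groups[[key]] %||% list(), list(rec))
  }
  groups <- groups[order(names(groups), method = "radix")]
  columnState <- lapply(groups, function(recs) {
    cols <- unique(unlist(lapply(recs, function(r) names(r@annotations))))
    list(order = cols, visible = cols, sortKey = NA_character_,
         sortDecreasing = FALSE, expanded = TRUE)
  })
  new("ResultTable", groups = groups, columnState = columnState,
      status = status, messages = messages)
}

#' Group keys of a result table
#' @param table a \linkS4class{ResultTable}.
#' @return character vector "source/dataType".
#' @export
resultGroups <- function(table) names(table@groups)

#' Records of one group
#' @param table a \linkS4class{ResultTable}.
#' @param group a group key from \code{\link{resultGroups}}.
#' @return list of \linkS4class{ResultRecord}.
#' @export
groupRecords <- function(table, group) {
  if (!group %in% names(table@groups)) {
    atkStop("key", "unknown group '%s'", group)
  }
  table@groups[[group]]
}

#' Per-source status of a result table
#' @param table a \linkS4class{ResultTable}.
#' @return named character ("ok", "failed", "skipped").
#' @export
sourceStatus <- function(table) table@status

setMethod("show", "ResultTable", function(object) {
  cat(sprintf("ResultTable: %d group(s), %d record(s)\n",
              length(object@groups),
              sum(vapply(object@groups, length, integer(1)))))
  for (key in names(object@groups)) {
    cat(sprintf("  %s: %d record(s)\n", key, length(object@groups[[key]])))
  }
  bad <- object@status != "ok"
  if (any(bad)) {
    cat(sprintf("  [%s: %s]\n", names(object@status)[bad],
                paste(object@status[bad], object@messages[bad])), sep = "")
  }
})

# ---------------------------------------------------------------------------
# Table view operations (content-preserving)
# ---------------------------------------------------------------------------

.checkColumn <- function(table, group, column) {
  st <- table@columnState[[group]]
  if (is.null(st)) atkStop("key", "unknown group '%s'", group)
  if (!column %in% st$order) {
    atkStop("key", "unknown column '%s' in group '%s'", column, group)
  }
  st
}

#' Sort a group by an annotation column
#'
#' Stable sort; records missing the annotation sort last in either
#' direction. Numeric-looking columns sort numerically.
#'
#' @param table a \linkS4class{ResultTable}.
#' @param group group key.
#' @param column annotation column name.
#' @param decreasing sort direction (default increasing).
#' @return the updated table; record content is untouched.
#' @export
sortBy <- function(table, group, column, decreasing = FALSE) {
  .checkColumn(table, group, column)
  recs <- table@groups[[group]]
  vals <- vapply(recs, function(r) {
    v <- r@annotations[[column]]
    if (is.null(v)) NA_character_ else as.character(v)
  }, character(1))
  num <- suppressWarnings(as.numeric(vals))
  key <- if (all(is.na(num) == is.na(vals))) num else vals
  rk <- xtfrm(key)
  if (decreasing) rk <- -rk
  ord <- order(is.na(vals), rk, method = "radix")
  table@groups[[group]] <- recs[ord]
  table@columnState[[group]]$sortKey <- column
  table@columnState[[group]]$sortDecreasing <- decreasing
  table
}

#' Show or hide an annotation column
#' @param table a \linkS4class{ResultTable}.
#' @param group group key.
#' @param column column name.
#' @param visible TRUE to show, FALSE to hide.
#' @return the updated table.
#' @export
setColumnVisible <- function(table, group, column, visible) {
  st <- .checkColumn(table, group, column)
  vis <- setdiff(st$visible, column)
  if (visible) {
    # restore at the column's position in the full order
    vis <- intersect(st$order, c(vis, column))
  }
  table@columnState[[group]]$visible <- vis
  table
}

#' Reorder the annotation columns of a group
#' @param table a \linkS4class{ResultTable}.
#' @param group group key.
#' @param newOrder permutation of the group's column names.
#' @return the updated table.
#' @export
reorderColumns <- function(table, group, newOrder) {
  st <- table@columnState[[group]]
  if (is.null(st)) atkStop("key", "unknown group '%s'", group)
  if (!setequal(newOrder, st$order) || length(newOrder) != length(st$order)) {
    atkStop("validation", "newOrder must be a permutation of the group's columns")
  }
  table@columnState[[group]]$order <- newOrder
  table@columnState[[group]]$visible <- intersect(newOrder, st$visible)
  table
}

#' Expand or collapse a group
#' @param table a \linkS4class{ResultTable}.
#' @param group group key.
#' @param expanded logical.
#' @return the updated table.
#' @export
setGroupExpanded <- function(table, group, expanded) {
  if (!group %in% names(table@groups)) atkStop("key", "unknown group '%s'", group)
  table@columnState[[group]]$expanded <- expanded
  table
}

# ---------------------------------------------------------------------------
# Cart
# ---------------------------------------------------------------------------

#' Create an empty cart
#' @return a \linkS4class{Cart}.
#' @export
newCart <- function() new("Cart", items = list(), duplicate = logical(0))

#' Add a record to the cart
#'
#' Duplicates are allowed but flagged.
#'
#' @param cart a \linkS4class{Cart}.
#' @param record a \linkS4class{ResultRecord}.
#' @return the updated cart.
#' @export
cartAdd <- function(cart, record) {
  dup <- any(vapply(cart@items, function(it)
    identical(it@source, record@source) &&
      identical(it@dataType, record@dataType) &&
      identical(it@annotations, record@annotations), logical(1)))
  cart@items[[length(cart@items) + 1L]] <- record
  cart@duplicate <- c(cart@duplicate, dup)
  cart
}

#' Remove a cart item by position
#' @param cart a \linkS4class{Cart}.
#' @param index 1-based position; later items shift down.
#' @return the updated cart.
#' @export
cartRemove <- function(cart, index) {
  if (index < 1L || index > length(cart@items)) {
    atkStop("bounds", "cart index %d out of range (1..%d)", index,
            length(cart@items))
  }
  cart@items <- cart@items[-index]
  cart@duplicate <- cart@duplicate[-index]
  cart
}

#' Items of the cart, in FIFO order
#' @param cart a \linkS4class{Cart}.
#' @return list of \linkS4class{ResultRecord}.
#' @export
cartItems <- function(cart) cart@items

setMethod("show", "Cart", function(object) {
  cat(sprintf("Cart with %d item(s)%s\n", length(object@items),
              if (any(object@duplicate)) sprintf(" (%d duplicate)",
                                                 sum(object@duplicate)) else ""))
})

#' Serialize the cart to JSON
#' @param cart a \linkS4class{Cart}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
saveCart <- function(cart, path) {
  items <- lapply(cart@items, function(r) list(
    source = r@source, dataType = r@dataType, annotations = r@annotations,
    thumbnailRef = r@thumbnailRef, payloadRef = r@payloadRef))
  jsonlite::write_json(items, path, auto_unbox = TRUE, null = "null",
                       digits = NA)
  invisible(path)
}

#' Load a cart from JSON
#' @param path a file written by \code{\link{saveCart}}.
#' @return a \linkS4class{Cart}.
#' @export
loadCart <- function(path) {
  if (!file.exists(path)) atkStop("not_found", "cart file not found: %s", path)
  items <- jsonlite::read_json(path)
  cart <- newCart()
  for (it in items) {
    cart <- cartAdd(cart, resultRecord(
      it$source, it$dataType, it$annotations,
      thumbnailRef = it$thumbnailRef, payloadRef = it$payloadRef))
  }
  cart
}

# ---------------------------------------------------------------------------
# Built-in sources
# ---------------------------------------------------------------------------

.matchesKeywords <- function(text, keywords) {
  hay <- tolower(text)
  all(vapply(keywords, function(k)
    any(grepl(tolower(k), hay, fixed = TRUE)), logical(1)))
}

#' A keyword-searchable data source over a directory of images
#'
#' Matches keywords (AND, case-insensitive) against file names and the
#' values of optional sidecar annotation files (\code{<image>.txt} with
#' \code{key: value} lines). Returns one "2D Image" record per matching
#' file, with the file path as payload and thumbnail locator.
#'
#' @param path directory of .png/.tif/.jpg images.
#' @param name source name (default "local_images").
#' @return a \linkS4class{DataSource} supporting keyword search.
#' @export
directoryImageSource <- function(path, name = "local_images") {
  if (!dir.exists(path)) {
    atkStop("not_found", "image directory not found: %s", path)
  }
  dataSource(name, "keyword", "2D Image", function(query) {
    files <- sort(list.files(path, pattern = "\\.(png|tiff?|jpe?g)$",
                             ignore.case = TRUE))
    out <- list()
    for (f in files) {
      ann <- list(file = f)
      sidecar <- file.path(path, paste0(f, ".txt"))
      if (file.exists(sidecar)) {
        for (ln in readLines(sidecar, warn = FALSE)) {
          kv <- regmatches(ln, regexec("^([^:]+):\\s*(.*)$", ln))[[1]]
          if (length(kv) == 3L) ann[[trimws(kv[2])]] <- trimws(kv[3])
        }
      }
      hay <- c(f, unlist(ann, use.names = FALSE))
      if (.matchesKeywords(hay, query@keywords)) {
        out[[length(out) + 1L]] <- resultRecord(
          name, "2D Image", ann,
          thumbnailRef = file.path(path, f),
          payloadRef = file.path(path, f))
      }
    }
    out
  })
}

#' A query-term data source over a delimited table
#'
#' Each query term (field, value) filters rows by case-insensitive equality
#' on the named column; all terms must match (AND). Each matching row
#' becomes one record whose annotations are the row's columns.
#'
#' @param path a .tsv or .csv file with a header row.
#' @param name source name (default the file name).
#' @param dataType data type reported for the records (default "Tabular").
#' @return a \linkS4class{DataSource} supporting query_term search.
#' @export
tableSource <- function(path, name = NULL,
                        dataType = "Tabular") {
  if (!file.exists(path)) atkStop("not_found", "table file not found: %s", path)
  name <- name %||% tools::file_path_sans_ext(basename(path))
  tab <- if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  } else {
    utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  }
  dataSource(name, "query_term", dataType, function(query) {
    keep <- rep(TRUE, nrow(tab))
    for (i in seq_len(nrow(query@terms))) {
      fld <- query@terms$field[i]; val <- query@terms$value[i]
      if (!fld %in% names(tab)) {
        atkStop("key", "source '%s' has no column '%s'", name, fld)
      }
      keep <- keep & (tolower(as.character(tab[[fld]])) == tolower(val))
    }
    lapply(which(keep), function(r) {
      resultRecord(name, dataType, as.list(tab[r, , drop = FALSE]),
                   payloadRef = sprintf("%s#row%d", path, r))
    })
  })
}

#' A deterministic in-memory literature source
#'
#' Keyword search (AND, case-insensitive) over the text annotations of a
#' fixed record list; useful as a literature-source stand-in and in tests.
#'
#' @param records list of \linkS4class{ResultRecord}.
#' @param name source name (default "literature").
#' @return a \linkS4class{DataSource} supporting keyword search.
#' @export
mockLiteratureSource <- function(records, name = "literature") {
  dataSource(name, "keyword", "Publication", function(query) {
    Filter(function(r) {
      hay <- vapply(r@annotations, function(a) paste(format(a), collapse = " "),
                    character(1))
      .matchesKeywords(hay, query@keywords)
    }, records)
  })
}

# ---------------------------------------------------------------------------
# Atlas -> query bridge
# ---------------------------------------------------------------------------

.formatCoord <- function(x) {
  s <- format(x, trim = TRUE, digits = 7)
  ifelse(grepl("^-?[0-9]+$", s), paste0(s, ".0"), s)
}

#' Build a query from an atlas selection or location
#'
#' Selected structure names become keywords; a world location becomes a
#' query term \code{("location", "x,y,z")}.
#'
#' @param selection character vector of selected structure names.
#' @param location optional numeric(3) world coordinate (mm).
#' @param sources data sources the query should target.
#' @param extraKeywords additional keywords to refine the search (e.g. a
#'   gene name).
#' @return a \linkS4class{Query}.
#' @export
queryFromAtlas <- function(selection = character(0), location = NULL,
                           sources, extraKeywords = character(0)) {
  if (!length(selection) && is.null(location)) {
    atkStop("validation", "need a non-empty selection or a location")
  }
  terms <- NULL
  if (!is.null(location)) {
    terms <- c(location = paste(.formatCoord(as.numeric(location)),
                                collapse = ","))
  }
  newQuery(keywords = c(selection, extraKeywords), terms = terms,
           sources = sources)
}
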