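#' @include atlas.R registration.R search.R large-volume.R
NULL

# All generators are pure functions of their FixtureSpec: the global seed is
# threaded through with a fixed per-generator offset so the sub-streams are
# independent but reproducible.

#' Specification for the synthetic-fixture generators
#'
#' @param seed integer master seed; identical specs yield bit-identical
#'   fixtures.
#' @param volumeShape integer(3) voxel grid (default 16^3; the large-volume
#'   generator defaults to 64^3 independently).
#' @param nStructures number of labeled structures (default 7).
#' @param hierarchyDepth maximum tree depth below the root (default 3).
#' @param noiseSigma noise level added by generators that take noise
#'   (default 0.05).
#' @return a FixtureSpec (plain list).
#' @export
fixtureSpec <- function(seed = 1L, volumeShape = c(16L, 16L, 16L),
                        nStructures = 7L, hierarchyDepth = 3L,
                        noiseSigma = 0.05) {
  structure(list(seed = as.integer(seed),
                 volumeShape = as.integer(volumeShape),
                 nStructures = as.integer(nStructures),
                 hierarchyDepth = as.integer(hierarchyDepth),
                 noiseSigma = noiseSigma),
            class = "FixtureSpec")
}

.withSeed <- function(seed, offset, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed((seed + offset) %% .Machine$integer.max)
  force(expr)
}

# Deterministic tree: node 1 is the root; each further node attaches to a
# uniformly drawn existing node whose depth is below the limit. Arity is
# capped at 3 so the nested-box geometry always has room to subdivide.
.randomTree <- function(n, maxDepth) {
  parent <- rep(NA_integer_, n)
  depth <- integer(n)
  nkids <- integer(n)
  for (i in seq_len(n)[-1]) {
    ok <- which(depth[seq_len(i - 1)] < maxDepth & nkids[seq_len(i - 1)] < 3L)
    if (!length(ok)) ok <- which(depth[seq_len(i - 1)] < maxDepth)
    p <- ok[sample.int(length(ok), 1L)]
    parent[i] <- p
    depth[i] <- depth[p] + 1L
    nkids[p] <- nkids[p] + 1L
  }
  list(parent = parent, depth = depth)
}

# Nested axis-aligned boxes matching the tree: each child box lies strictly
# inside its parent with a 1-voxel margin, siblings split the parent's
# interior along its longest axis.
.assignBoxes <- function(parent, shape) {
  n <- length(parent)
  lo <- matrix(NA_integer_, n, 3)
  hi <- matrix(NA_integer_, n, 3)
  childrenOf <- function(i) which(!is.na(parent) & parent == i)
  recurse <- function(i, l, h) {
    lo[i, ] <<- l; hi[i, ] <<- h
    kids <- childrenOf(i)
    if (!length(kids)) return(invisible())
    # interior: pull in by one voxel on every axis wide enough, so the split
    # axis (and any roomy axis) leaves the parent label visible around the
    # children while thin axes are not shrunk to nothing
    roomy <- (h - l + 1L) >= 3L
    il <- l + as.integer(roomy); ih <- h - as.integer(roomy)
    ax <- which.max(ih - il)
    width <- ih[ax] - il[ax] + 1L
    k <- length(kids)
    avail <- width - (k - 1L)               # 1-voxel gaps between siblings
    base <- avail %/% k
    if (base < 1L) {
      atkStop("validation",
              "structures do not fit: node %d needs %d slots on axis %d (width %d)",
              i, k, ax, width)
    }
    sw <- rep(base, k)
    extra <- avail - base * k
    if (extra > 0L) sw[seq_len(extra)] <- sw[seq_len(extra)] + 1L
    pos <- il[ax]
    for (j in seq_len(k)) {
      cl <- il; ch <- ih
      cl[ax] <- pos
      ch[ax] <- pos + sw[j] - 1L
      pos <- pos + sw[j] + 1L
      recurse(kids[j], cl, ch)
    }
  }
  roots <- which(is.na(parent))
  for (rt in roots) recurse(rt, rep(2L, 3), shape - 1L)
  list(lo = lo, hi = hi)
}

#' Generate a synthetic atlas bundle
#'
#' Builds a deterministic atlas whose label volume is a set of nested
#' axis-aligned boxes mirroring a random hierarchy tree (every child box
#' strictly inside its parent), an ILF hierarchy with distinct colors, and
#' a smooth sinusoidal reference volume. With \code{functionalLayer} a
#' second, coarser "functional" partition (a 3-node hierarchy splitting the
#' foreground in two) is added to exercise multi-label-set lookup.
#'
#' @param spec a \code{\link{fixtureSpec}}.
#' @param path optional bundle directory; when given, the atlas is saved
#'   there with \code{\link{saveAtlas}}.
#' @param functionalLayer add the second label layer (default TRUE).
#' @return the \linkS4class{Atlas} (invisibly if written to disk).
#' @export
makeAtlas <- function(spec, path = NULL, functionalLayer = TRUE) {
  if (spec$nStructures < 1L) atkStop("validation", "need nStructures >= 1")
  shape <- spec$volumeShape
  tree <- .withSeed(spec$seed, 101L, .randomTree(spec$nStructures,
                                                 spec$hierarchyDepth))
  boxes <- .assignBoxes(tree$parent, shape)
  ids3d <- array(0L, shape)
  ord <- order(tree$depth)                 # parents first, children overwrite
  for (i in ord) {
    ids3d[boxes$lo[i, 1]:boxes$hi[i, 1],
          boxes$lo[i, 2]:boxes$hi[i, 2],
          boxes$lo[i, 3]:boxes$hi[i, 3]] <- i
  }
  hue <- (seq_len(spec$nStructures) - 1) / spec$nStructures
  cols <- t(grDevices::col2rgb(grDevices::hsv(hue, 0.7, 1)))
  anatomicNames <- sprintf("structure %02d", seq_len(spec$nStructures))
  nodes <- data.frame(
    id = seq_len(spec$nStructures),
    abbrev = sprintf("S%02d", seq_len(spec$nStructures)),
    name = anatomicNames,
    r = cols[, 1], g = cols[, 2], b = cols[, 3],
    parent = tree$parent)
  anatomic <- labelSet(nodes, setName = "anatomic")
  layers <- list(labelLayer(ids3d, anatomic))

  if (functionalLayer) {
    half <- shape[1] %/% 2L
    fun3d <- array(0L, shape)
    fg <- ids3d != 0L
    left <- array(FALSE, shape); left[seq_len(half), , ] <- TRUE
    fun3d[fg & left] <- 2L
    fun3d[fg & !left] <- 3L
    funNodes <- data.frame(
      id = 1:3,
      abbrev = c("FN", "FA", "FB"),
      name = c("functional root", "functional zone A", "functional zone B"),
      r = c(128L, 255L, 0L), g = c(128L, 128L, 192L), b = c(128L, 0L, 255L),
      parent = c(NA_integer_, 1L, 1L))
    layers <- c(layers, labelLayer(fun3d, labelSet(funNodes,
                                                   setName = "functional")))
  }

  g <- expand.grid(i = seq_len(shape[1]), j = seq_len(shape[2]),
                   k = seq_len(shape[3]))
  ref <- 0.5 + 0.2 * sin(2 * pi * g$i / shape[1]) +
    0.15 * cos(2 * pi * g$j / shape[2]) + 0.1 * sin(2 * pi * g$k / shape[3])
  noise <- .withSeed(spec$seed, 102L, stats::rnorm(nrow(g), 0, spec$noiseSigma))
  reference <- imageVolume(array(ref + noise, shape))
  atlas <- newAtlas(layers, reference = reference)
  if (!is.null(path)) {
    saveAtlas(atlas, path)
    return(invisible(atlas))
  }
  atlas
}

#' Generate a (source, template) image pair with known ground truth
#'
#' The template is a deterministic smooth asymmetric pattern; the source is
#' the template pushed through a known transform of the requested kind, with
#' magnitude controlling the rotation angle (degrees, rigid), shear
#' (affine) or control-point displacement in px (tps). Landmarks are exact
#' correspondences sampled on a grid: source point p and template point
#' M(p), where M is the returned true model mapping source to template
#' coordinates. Magnitude 0 yields identical images and an identity truth.
#'
#' @param spec a \code{\link{fixtureSpec}}.
#' @param modelKind "rigid", "affine" or "tps".
#' @param magnitude transform strength (see Details).
#' @param size image side length in px (default 64).
#' @return list with \code{source}, \code{template} (\linkS4class{Image2D}),
#'   \code{landmarks} (data.frame xs, ys, xt, yt) and \code{truth} (the true
#'   \linkS4class{TransformModel}).
#' @export
makeWarpedPair <- function(spec, modelKind = c("rigid", "affine", "tps"),
                           magnitude = 10, size = 64L) {
  modelKind <- match.arg(modelKind)
  size <- as.integer(size)
  g <- expand.grid(x = seq_len(size), y = seq_len(size))
  blobs <- .withSeed(spec$seed, 201L,
                     cbind(stats::runif(4, 0.2, 0.8) * size,
                           stats::runif(4, 0.2, 0.8) * size,
                           stats::runif(4, 4, 10)))
  tpx <- 0.15 + 0.2 * g$x / size + 0.1 * g$y / size
  for (b in seq_len(nrow(blobs))) {
    tpx <- tpx + 0.6 * exp(-((g$x - blobs[b, 1])^2 + (g$y - blobs[b, 2])^2) /
                             (2 * blobs[b, 3]^2)) / b
  }
  # g varies x fastest; pixels are [y, x], so transpose the column-major fill
  template <- image2d(t(matrix(pmin(tpx, 1), size, size)))
  ctr <- (size + 1) / 2
  truth <- switch(modelKind,
    rigid = {
      th <- magnitude * pi / 180
      R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
      t <- c(ctr, ctr) - as.numeric(R %*% c(ctr, ctr)) +
        c(magnitude / 5, -magnitude / 7)
      new("TransformModel", kind = "rigid",
          params = list(R = R, t = t, angle = magnitude))
    },
    affine = {
      M <- diag(2) + magnitude / 100 * matrix(c(0, 0.3, 1, -0.5), 2, 2)
      t <- c(ctr, ctr) - as.numeric(M %*% c(ctr, ctr)) + c(magnitude / 10, 0)
      new("TransformModel", kind = "affine", params = list(A = cbind(M, t)))
    },
    tps = {
      anchors <- as.matrix(expand.grid(
        x = seq(0.15, 0.85, length.out = 3) * size,
        y = seq(0.15, 0.85, length.out = 3) * size))
      disp <- .withSeed(spec$seed, 202L,
                        matrix(stats::runif(18, -1, 1) * magnitude, 9, 2))
      lmx <- data.frame(xs = anchors[, 1], ys = anchors[, 2],
                        xt = anchors[, 1] + disp[, 1],
                        yt = anchors[, 2] + disp[, 2])
      fitTps(lmx, 0)
    })
  # landmarks: source grid points and their images under the truth
  lmGrid <- as.matrix(expand.grid(
    x = seq(0.2, 0.8, length.out = if (modelKind == "tps") 3 else 4) * size,
    y = seq(0.2, 0.8, length.out = if (modelKind == "tps") 3 else 4) * size))
  mapped <- transformPoints(truth, lmGrid)
  landmarks <- data.frame(xs = lmGrid[, 1], ys = lmGrid[, 2],
                          xt = mapped[, 1], yt = mapped[, 2])
  # source image: source(p) = template(truth(p)), sampled bilinearly
  pts <- cbind(g$x, g$y)
  tp <- transformPoints(truth, pts)
  tpxm <- template@pixels
  vals <- .sampleImageAt(tpxm, matrix(tp[, 1], size, size),
                         matrix(tp[, 2], size, size), "bilinear")
  source <- image2d(t(matrix(vals, size, size)))
  list(source = source, template = template, landmarks = landmarks,
       truth = truth)
}

#' Generate a deterministic mock source registry
#'
#' Builds \code{n} keyword-searchable mock sources with controlled record
#' counts and annotation schemas, plus (optionally) one fault injector that
#' throws on execution — the harness for failure-isolation tests.
#'
#' @param spec a \code{\link{fixtureSpec}}.
#' @param counts integer vector of record counts per source (default
#'   rep(3, n)).
#' @param n number of sources (default length of counts, or 3).
#' @param faultIndex index of the source configured to fail, or 0 for none.
#' @return a \code{\link{sourceRegistry}} with sources named
#'   \code{mock1..mockN}.
#' @export
makeMockRegistry <- function(spec, counts = NULL, n = NULL, faultIndex = 0L) {
  if (is.null(n)) n <- if (!is.null(counts)) length(counts) else 3L
  if (is.null(counts)) counts <- rep(3L, n)
  if (n < 1L) atkStop("validation", "need at least one source")
  reg <- sourceRegistry()
  for (s in seq_len(n)) {
    nm <- sprintf("mock%d", s)
    if (s == faultIndex) {
      registerSource(reg, dataSource(nm, "keyword", "2D Image",
        function(query) stop("simulated source failure")))
      next
    }
    recs <- lapply(seq_len(counts[s]), function(r) {
      rid <- spec$seed * 10000L + s * 100L + r
      resultRecord(nm, if (r %% 2L) "2D Image" else "3D Volume",
                   list(id = rid,
                        title = sprintf("record %d from %s", r, nm),
                        score = round(((rid * 2654435761) %% 1000) / 10, 1),
                        url = sprintf("file:///mock/%s/%d", nm, r)))
    })
    registerSource(reg, dataSource(nm, "keyword", c("2D Image", "3D Volume"),
      local({
        recs0 <- recs
        function(query) Filter(function(r) {
          hay <- vapply(r@annotations, function(a) paste(format(a), collapse = " "),
                        character(1))
          .matchesKeywords(hay, query@keywords)
        }, recs0)
      })))
  }
  reg
}

#' Generate an on-disk large volume with its descriptor
#'
#' Writes a float32 raw data file plus a .lhdr descriptor. The voxel value
#' at (i, j, k) (1-based) is the ramp
#' \code{(i-1) + nx*(j-1) + nx*ny*(k-1)}, scaled into [0,1], plus Gaussian
#' noise of sd \code{noiseSigma}; a different seed changes the noise but not
#' the header.
#'
#' @param spec a \code{\link{fixtureSpec}}; \code{volumeShape} sets the
#'   dimensions (use c(64,64,64) for a ~1 MiB file).
#' @param path output stub; \code{<path>.lhdr} and \code{<path>.dat} are
#'   written.
#' @return the .lhdr path.
#' @export
makeLargeVolume <- function(spec, path) {
  dims <- spec$volumeShape
  n <- prod(as.numeric(dims))
  ramp <- (seq_len(n) - 1) / (n - 1)
  noise <- .withSeed(spec$seed, 301L, stats::rnorm(n, 0, spec$noiseSigma))
  vals <- ramp + noise
  dat <- paste0(path, ".dat")
  con <- file(dat, "wb")
  writeBin(vals, con, size = 4L, endian = "little")
  close(con)
  # re-read so the header range matches the stored float32 values exactly
  con <- file(dat, "rb")
  stored <- readBin(con, "numeric", n = n, size = 4L, endian = "little")
  close(con)
  hdr <- paste0(path, ".lhdr")
  writeLargeVolumeHeader(hdr, basename(dat), dims, "float32",
                         valueRange = range(stored))
  hdr
}
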