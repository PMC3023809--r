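#' @include AllClasses.R image2d.R
NULL

#' Construct a canvas layer
#'
#' @param content an \linkS4class{Image2D} or \linkS4class{ImageSeries}.
#' @param id layer id (unique within a canvas).
#' @param pan numeric(2) translation in canvas px.
#' @param rotation degrees, counter-clockwise about the image center.
#' @param scale positive per-layer scale factor.
#' @param opacity alpha in [0,1].
#' @param brightness additive offset in [-1,1].
#' @param contrast positive gain about mid-gray.
#' @param lut optional 256x3 lookup table ([0,1] entries) applied to
#'   grayscale content.
#' @param visible logical.
#' @param linkGroup optional link-group id.
#' @param linkMaster TRUE if this layer drives its link group.
#' @return a \linkS4class{Layer}.
#' @export
imageLayer <- function(content, id, pan = c(0, 0), rotation = 0, scale = 1,
                       opacity = 1, brightness = 0, contrast = 1,
                       lut = NULL, visible = TRUE, linkGroup = NA_character_,
                       linkMaster = FALSE) {
  new("Layer", id = id, content = content,
      transform = list(pan = as.numeric(pan), rotation = as.numeric(rotation),
                       scale = as.numeric(scale)),
      opacity = opacity, brightness = brightness, contrast = contrast,
      lut = lut, visible = visible, linkGroup = as.character(linkGroup),
      linkMaster = linkMaster)
}

#' Construct a canvas
#'
#' @param width,height canvas size in px.
#' @param backgroundColor numeric(3) RGB in [0,1] (default black).
#' @param backgroundAlpha background coverage (default 1, an opaque canvas).
#' @param zoom canvas-level uniform scale about the canvas center.
#' @return a \linkS4class{Canvas} with no layers.
#' @export
newCanvas <- function(width, height, backgroundColor = c(0, 0, 0),
                      backgroundAlpha = 1, zoom = 1) {
  new("Canvas", layers = list(), size = as.integer(c(width, height)),
      backgroundColor = as.numeric(backgroundColor),
      backgroundAlpha = backgroundAlpha, zoom = zoom)
}

#' Add a layer on top of a canvas
#' @param canvas a \linkS4class{Canvas}.
#' @param layer a \linkS4class{Layer}.
#' @return the updated canvas.
#' @export
addLayer <- function(canvas, layer) {
  canvas@layers[[length(canvas@layers) + 1L]] <- layer
  validObject(canvas)
  canvas
}

.layerPos <- function(canvas, id) {
  ids <- vapply(canvas@layers, function(l) l@id, character(1))
  i <- match(id, ids)
  if (is.na(i)) atkStop("key", "unknown layer id '%s'", id)
  i
}

#' Get a layer by id
#' @param canvas a \linkS4class{Canvas}.
#' @param id layer id.
#' @return the \linkS4class{Layer}.
#' @export
getLayer <- function(canvas, id) canvas@layers[[.layerPos(canvas, id)]]

setMethod("show", "Canvas", function(object) {
  cat(sprintf("Canvas %dx%d, %d layer(s), zoom %g\n", object@size[1],
              object@size[2], length(object@layers), object@zoom))
})

# ---------------------------------------------------------------------------
# Photometry and LUTs
# ---------------------------------------------------------------------------

#' Adjust brightness and contrast of an image
#'
#' Applies \code{out = clamp(contrast * (in - 0.5) + 0.5 + brightness, 0, 1)}
#' per channel: contrast is a gain pivoted at mid-gray and brightness an
#' additive offset, so a neutral setting (0, 1) leaves the image unchanged.
#'
#' @param image an \linkS4class{Image2D} or numeric array in [0,1].
#' @param brightness additive offset in [-1,1].
#' @param contrast positive gain.
#' @return the adjusted image, same type as the input.
#' @export
adjustPhotometry <- function(image, brightness = 0, contrast = 1) {
  if (contrast <= 0) atkStop("validation", "contrast must be positive")
  px <- if (is(image, "Image2D")) image@pixels else image
  d <- dim(px)
  if (length(d) == 3L && d[3L] == 4L) {
    rgbpart <- px[, , 1:3, drop = FALSE]
    rgbpart <- pmin(pmax(contrast * (rgbpart - 0.5) + 0.5 + brightness, 0), 1)
    px[, , 1:3] <- rgbpart
  } else {
    px <- pmin(pmax(contrast * (px - 0.5) + 0.5 + brightness, 0), 1)
  }
  if (is(image, "Image2D")) image2d(px, pixelSize = image@pixelSize) else px
}

#' The identity grayscale lookup table
#' @return 256x3 matrix mapping gray value v to (v,v,v)/255.
#' @export
identityLut <- function() {
  v <- (0:255) / 255
  cbind(v, v, v, deparse.level = 0)
}

#' Apply a 256-entry color lookup table to a grayscale image
#'
#' Gray value v maps to \code{lut[round(v*255) + 1, ]}.
#'
#' @param image a grayscale \linkS4class{Image2D} or matrix in [0,1].
#' @param lut 256x3 matrix of RGB entries in [0,1].
#' @return an RGB \linkS4class{Image2D} (or array for matrix input).
#' @export
applyLut <- function(image, lut) {
  if (!is.matrix(lut) || !all(dim(lut) == c(256L, 3L))) {
    atkStop("validation", "lut must be a 256x3 matrix")
  }
  px <- if (is(image, "Image2D")) image@pixels else image
  if (length(dim(px)) != 2L) {
    atkStop("validation", "lut applies to grayscale images only")
  }
  idx <- round(px * 255) + 1L
  out <- array(0, c(dim(px), 3L))
  out[, , 1] <- lut[idx, 1]
  out[, , 2] <- lut[idx, 2]
  out[, , 3] <- lut[idx, 3]
  ps <- if (is(image, "Image2D")) image@pixelSize else c(1, 1)
  if (is(image, "Image2D")) image2d(out, pixelSize = ps) else out
}

# ---------------------------------------------------------------------------
# Transforms and linking
# ---------------------------------------------------------------------------

#' Apply a transform delta to a layer or its link group
#'
#' The delta is applied to the target layer. If the target is the master of
#' a link group, the identical delta is mirrored by every other member of
#' the group (the slaves); a delta applied to a slave moves only the slave.
#' Pan deltas add, rotation deltas add (degrees), scale deltas multiply.
#'
#' @param canvas a \linkS4class{Canvas}.
#' @param id id of the layer receiving the delta.
#' @param pan optional numeric(2) pan increment (canvas px).
#' @param rotation optional rotation increment (degrees).
#' @param scale optional scale factor (multiplied onto the current scale).
#' @return the updated canvas.
#' @export
transformLayer <- function(canvas, id, pan = NULL, rotation = NULL,
                           scale = NULL) {
  i <- .layerPos(canvas, id)
  target <- canvas@layers[[i]]
  targets <- i
  if (!is.na(target@linkGroup) && target@linkMaster) {
    members <- vapply(canvas@layers, function(l)
      identical(l@linkGroup, target@linkGroup), logical(1))
    targets <- which(members)
  }
  for (j in targets) {
    tr <- canvas@layers[[j]]@transform
    if (!is.null(pan)) tr$pan <- tr$pan + as.numeric(pan)
    if (!is.null(rotation)) tr$rotation <- tr$rotation + rotation
    if (!is.null(scale)) tr$scale <- tr$scale * scale
    canvas@layers[[j]]@transform <- tr
  }
  canvas
}

#' Step the current frame of a series layer
#'
#' Advances the frame index by \code{delta}, clamped to the valid range (no
#' wrap-around, so sweeping forward then backward returns to the start).
#'
#' @param layer a \linkS4class{Layer} whose content is an
#'   \linkS4class{ImageSeries}.
#' @param delta signed frame increment.
#' @return the updated layer.
#' @export
stepCine <- function(layer, delta) {
  if (!is(layer@content, "ImageSeries")) {
    atkStop("validation", "layer '%s' does not hold an image series", layer@id)
  }
  s <- layer@content
  s@currentIndex <- max(1L, min(length(s@frames),
                                s@currentIndex + as.integer(delta)))
  layer@content <- s
  layer
}

# ---------------------------------------------------------------------------
# Compositing
# ---------------------------------------------------------------------------

# Current straight-color image of a layer with photometry + LUT applied.
# Returns list(r, g, b, a) of h x w matrices (a = NULL means fully opaque).
.layerImage <- function(layer) {
  img <- layer@content
  if (is(img, "ImageSeries")) img <- img@frames[[img@currentIndex]]
  px <- img@pixels
  a <- NULL
  d <- dim(px)
  if (length(d) == 3L && d[3L] == 4L) {
    a <- px[, , 4L]
    px <- px[, , 1:3, drop = FALSE]
  }
  if (layer@brightness != 0 || layer@contrast != 1) {
    px <- pmin(pmax(layer@contrast * (px - 0.5) + 0.5 + layer@brightness, 0), 1)
  }
  if (length(dim(px)) == 2L || dim(px)[3L] == 1L) {
    g <- if (length(dim(px)) == 2L) px else px[, , 1L]
    if (!is.null(layer@lut)) {
      idx <- round(g * 255) + 1L
      r <- matrix(layer@lut[idx, 1], nrow(g), ncol(g))
      gg <- matrix(layer@lut[idx, 2], nrow(g), ncol(g))
      b <- matrix(layer@lut[idx, 3], nrow(g), ncol(g))
      return(list(r = r, g = gg, b = b, a = a))
    }
    return(list(r = g, g = g, b = g, a = a))
  }
  list(r = px[, , 1L], g = px[, , 2L], b = px[, , 3L], a = a)
}

# Inverse-map canvas pixel centers to layer image coordinates.
# Forward model: p_canvas = zoom * R(theta) * scale * (p_img - c_img) + c_canvas + pan
.canvasToImage <- function(canvas, layer, w, h, imgDim) {
  xc <- matrix(rep(seq_len(w), each = h), h, w)
  yc <- matrix(rep(seq_len(h), times = w), h, w)
  tr <- layer@transform
  ccx <- (w + 1) / 2; ccy <- (h + 1) / 2
  cix <- (imgDim[2] + 1) / 2; ciy <- (imgDim[1] + 1) / 2
  dx <- (xc - ccx - tr$pan[1]) / (canvas@zoom * tr$scale)
  dy <- (yc - ccy - tr$pan[2]) / (canvas@zoom * tr$scale)
  th <- -tr$rotation * pi / 180
  xs <- cos(th) * dx - sin(th) * dy + cix
  ys <- sin(th) * dx + cos(th) * dy + ciy
  list(x = xs, y = ys)
}

# Bilinear sample of straight-color channels; returns premultiplied color
# plus alpha. Out-of-bounds neighbors contribute nothing (transparent).
.sampleBilinear <- function(ch, xs, ys) {
  h <- nrow(ch$r); w <- ncol(ch$r)
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0; fy <- ys - y0
  alpha <- ch$a
  acc <- list(r = 0, g = 0, b = 0, a = 0)
  for (oy in 0:1) for (ox in 0:1) {
    xi <- x0 + ox; yi <- y0 + oy
    wgt <- (ox * fx + (1 - ox) * (1 - fx)) * (oy * fy + (1 - oy) * (1 - fy))
    valid <- xi >= 1 & xi <= w & yi >= 1 & yi <= h & wgt > 0
    if (!any(valid)) next
    idx <- cbind(as.vector(pmin(pmax(yi, 1), h)), as.vector(pmin(pmax(xi, 1), w)))
    av <- if (is.null(alpha)) 1 else alpha[idx]
    wa <- ifelse(valid, wgt * av, 0)
    acc$r <- acc$r + wa * ch$r[idx]
    acc$g <- acc$g + wa * ch$g[idx]
    acc$b <- acc$b + wa * ch$b[idx]
    acc$a <- acc$a + ifelse(valid, wgt * av, 0)
  }
  acc
}

#' Composite a canvas to an RGBA raster
#'
#' Starting from the background, every visible layer is resampled into
#' canvas space (inverse-mapped bilinear sampling under its transform, with
#' transparent out-of-bounds) and blended bottom-to-top with the straight-
#' alpha over operator, the effective alpha being the layer opacity times
#' the sampled coverage. Rendering is a pure function of canvas state: the
#' same state always yields a bit-identical raster.
#'
#' @param canvas a \linkS4class{Canvas}.
#' @return h x w x 4 numeric array (straight RGB + alpha) in [0,1].
#' @export
compositeCanvas <- function(canvas) {
  w <- canvas@size[1]; h <- canvas@size[2]
  A <- matrix(canvas@backgroundAlpha, h, w)
  P <- list(r = matrix(canvas@backgroundColor[1] * canvas@backgroundAlpha, h, w),
            g = matrix(canvas@backgroundColor[2] * canvas@backgroundAlpha, h, w),
            b = matrix(canvas@backgroundColor[3] * canvas@backgroundAlpha, h, w))
  for (layer in canvas@layers) {
    if (!layer@visible || layer@opacity <= 0) next
    ch <- .layerImage(layer)
    co <- .canvasToImage(canvas, layer, w, h, dim(ch$r))
    s <- .sampleBilinear(ch, co$x, co$y)
    aEff <- layer@opacity * s$a
    keep <- 1 - aEff
    P$r <- layer@opacity * s$r + P$r * keep
    P$g <- layer@opacity * s$g + P$g * keep
    P$b <- layer@opacity * s$b + P$b * keep
    A <- aEff + A * keep
  }
  out <- array(0, c(h, w, 4))
  nz <- A > 0
  out[, , 1][nz] <- P$r[nz] / A[nz]
  out[, , 2][nz] <- P$g[nz] / A[nz]
  out[, , 3][nz] <- P$b[nz] / A[nz]
  out[, , 4] <- A
  out[] <- pmin(pmax(out, 0), 1)
  out
}

#' Render two layer subsets side by side
#'
#' Composites the left and right layer subsets independently, each onto a
#' half-width canvas sharing the parent canvas's background and zoom, and
#' juxtaposes the halves.
#'
#' @param canvas a \linkS4class{Canvas}.
#' @param leftIds,rightIds disjoint character vectors of layer ids.
#' @return h x (2 * floor(w/2)) x 4 RGBA array.
#' @export
dualView <- function(canvas, leftIds, rightIds) {
  if (length(intersect(leftIds, rightIds))) {
    atkStop("validation", "left and right layer sets overlap: %s",
            paste(intersect(leftIds, rightIds), collapse = ", "))
  }
  half <- function(ids) {
    sub <- canvas
    sub@size <- as.integer(c(canvas@size[1] %/% 2L, canvas@size[2]))
    sub@layers <- canvas@layers[vapply(canvas@layers,
                                       function(l) l@id %in% ids, logical(1))]
    compositeCanvas(sub)
  }
  left <- half(leftIds)
  right <- half(rightIds)
  out <- array(0, c(dim(left)[1], dim(left)[2] + dim(right)[2], 4))
  out[, seq_len(dim(left)[2]), ] <- left
  out[, dim(left)[2] + seq_len(dim(right)[2]), ] <- right
  out
}

# ---------------------------------------------------------------------------
# Scene files
# ---------------------------------------------------------------------------

#' Save a canvas as a reproducible scene file
#'
#' The scene is a YAML document recording the canvas geometry and, for each
#' layer, its adjustments, transform and content. Content that was loaded
#' from a file (\code{src} attribute) is referenced by path; otherwise the
#' frame is written as a PNG sidecar next to the scene.
#'
#' @param canvas a \linkS4class{Canvas}.
#' @param path output .yaml scene path.
#' @return the path, invisibly.
#' @export
saveScene <- function(canvas, path) {
  layers <- lapply(canvas@layers, function(l) {
    src <- attr(l@content, "src")
    if (is.null(src)) {
      src <- file.path(dirname(path), paste0(l@id, "_content.png"))
      img <- l@content
      if (is(img, "ImageSeries")) img <- img@frames[[img@currentIndex]]
      writeImage2d(img, src)
    }
    list(id = l@id, src = src, pan = l@transform$pan,
         rotation = l@transform$rotation, scale = l@transform$scale,
         opacity = l@opacity, brightness = l@brightness,
         contrast = l@contrast, visible = l@visible,
         linkGroup = if (is.na(l@linkGroup)) NULL else l@linkGroup,
         linkMaster = l@linkMaster)
  })
  yaml::write_yaml(list(
    size = canvas@size, background = canvas@backgroundColor,
    backgroundAlpha = canvas@backgroundAlpha, zoom = canvas@zoom,
    layers = layers), path)
  invisible(path)
}

#' Load a canvas from a scene file
#'
#' @param path a scene written by \code{\link{saveScene}}.
#' @return a \linkS4class{Canvas}.
#' @export
loadScene <- function(path) {
  if (!file.exists(path)) atkStop("not_found", "scene file not found: %s", path)
  sc <- yaml::read_yaml(path)
  canvas <- newCanvas(sc$size[1], sc$size[2],
                      backgroundColor = as.numeric(sc$background),
                      backgroundAlpha = sc$backgroundAlpha %||% 1,
                      zoom = sc$zoom %||% 1)
  for (ly in sc$layers) {
    content <- readImage2d(ly$src)
    attr(content, "src") <- ly$src
    canvas <- addLayer(canvas, imageLayer(
      content, id = ly$id, pan = as.numeric(ly$pan),
      rotation = ly$rotation, scale = ly$scale, opacity = ly$opacity,
      brightness = ly$brightness, contrast = ly$contrast,
      visible = ly$visible, linkGroup = ly$linkGroup %||% NA_character_,
      linkMaster = isTRUE(ly$linkMaster)))
  }
  canvas
}
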