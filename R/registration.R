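#' @include AllClasses.R image2d.R
NULL

#' Read landmark pairs from a plain-text table
#'
#' One pair per line, \code{xs ys xt yt} (source point then template point,
#' image pixel coordinates); \code{#} starts a comment.
#'
#' @param path path to the landmark file.
#' @return data.frame with columns xs, ys, xt, yt.
#' @export
readLandmarks <- function(path) {
  if (!file.exists(path)) atkStop("not_found", "landmark file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  vals <- lapply(lines, function(l)
    as.numeric(strsplit(l, "[,[:space:]]+")[[1]]))
  if (!length(vals) || any(vapply(vals, length, integer(1)) != 4L) ||
      anyNA(unlist(vals))) {
    atkStop("format", "landmark lines must be 'xs ys xt yt': %s", path)
  }
  m <- do.call(rbind, vals)
  data.frame(xs = m[, 1], ys = m[, 2], xt = m[, 3], yt = m[, 4])
}

#' Write landmark pairs
#' @param landmarks data.frame with columns xs, ys, xt, yt.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeLandmarks <- function(landmarks, path) {
  writeLines(c("# xs ys xt yt",
               sprintf("%.10g %.10g %.10g %.10g", landmarks$xs, landmarks$ys,
                       landmarks$xt, landmarks$yt)), path)
  invisible(path)
}

.lmCheck <- function(landmarks, minPairs) {
  need <- c("xs", "ys", "xt", "yt")
  if (!all(need %in% names(landmarks))) {
    atkStop("validation", "landmarks need columns xs, ys, xt, yt")
  }
  if (nrow(landmarks) < minPairs) {
    atkStop("validation", "at least %d landmark pairs required, got %d",
            minPairs, nrow(landmarks))
  }
  landmarks
}

#' Fit a rigid (rotation + translation) landmark transform
#'
#' Closed-form least squares: the rotation comes from the SVD of the
#' centered cross-covariance between source and template points (with the
#' reflection corrected so the determinant is +1), and the translation maps
#' the source centroid onto the template centroid. Minimizes
#' sum ||R s_i + t - t_i||^2.
#'
#' @param landmarks data.frame with columns xs, ys, xt, yt (>= 2 rows).
#' @return a \linkS4class{TransformModel} of kind "rigid" mapping source to
#'   template coordinates.
#' @export
fitRigid <- function(landmarks) {
  lm <- .lmCheck(landmarks, 2L)
  S <- cbind(lm$xs, lm$ys); Tm <- cbind(lm$xt, lm$yt)
  if (max(dist(S)) < .Machine$double.eps^0.5) {
    atkStop("degenerate", "all source landmarks coincide")
  }
  sc <- colMeans(S); tc <- colMeans(Tm)
  H <- crossprod(sweep(S, 2, sc), sweep(Tm, 2, tc))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, d)) %*% t(sv$u)
  t <- tc - as.numeric(R %*% sc)
  new("TransformModel", kind = "rigid",
      params = list(R = R, t = t, angle = atan2(R[2, 1], R[1, 1]) * 180 / pi))
}

#' Fit an affine landmark transform
#'
#' Least-squares 2x3 matrix; exact when the pairs were generated by an
#' affine map.
#'
#' @param landmarks data.frame with columns xs, ys, xt, yt (>= 3
#'   non-collinear rows).
#' @return a \linkS4class{TransformModel} of kind "affine".
#' @export
fitAffine <- function(landmarks) {
  lm <- .lmCheck(landmarks, 3L)
  X <- cbind(1, lm$xs, lm$ys)
  if (qr(X)$rank < 3L) {
    atkStop("degenerate", "source landmarks are collinear; affine fit is rank-deficient")
  }
  B <- qr.coef(qr(X), cbind(lm$xt, lm$yt))   # 3 x 2: intercept, x, y
  A <- cbind(t(B[2:3, , drop = FALSE]), B[1, ])  # 2x3 [linear | translation]
  new("TransformModel", kind = "affine", params = list(A = A))
}

# TPS radial kernel U(r) = r^2 log(r^2), U(0) = 0.
.tpsKernel <- function(r2) ifelse(r2 > 0, r2 * log(r2), 0)

.tpsDistance2 <- function(P, Q) {
  outer(rowSums(P^2), rep(1, nrow(Q))) +
    outer(rep(1, nrow(P)), rowSums(Q^2)) - 2 * tcrossprod(P, Q)
}

#' Fit a thin-plate-spline landmark transform
#'
#' Standard 2D thin-plate spline with kernel U(r) = r^2 log(r^2): solves the
#' dense bordered system [[K + lambda I, P], [P', 0]] for the kernel weights
#' and affine part per output coordinate. The side conditions (weights
#' orthogonal to constants and coordinates) hold by construction. With
#' lambda = 0 the spline interpolates the landmarks exactly; increasing
#' lambda smooths towards the least-squares affine.
#'
#' @param landmarks data.frame with columns xs, ys, xt, yt (>= 3 rows,
#'   distinct source points).
#' @param lambda smoothing parameter >= 0 (default 0, exact interpolation).
#' @return a \linkS4class{TransformModel} of kind "tps".
#' @export
fitTps <- function(landmarks, lambda = 0) {
  lm <- .lmCheck(landmarks, 3L)
  if (lambda < 0) atkStop("validation", "lambda must be >= 0")
  S <- cbind(lm$xs, lm$ys)
  n <- nrow(S)
  D2 <- .tpsDistance2(S, S)
  if (any(D2[upper.tri(D2)] < .Machine$double.eps)) {
    atkStop("singular", "duplicate source landmarks make the TPS system singular")
  }
  K <- .tpsKernel(pmax(D2, 0))
  P <- cbind(1, S)
  L <- rbind(cbind(K + lambda * diag(n), P),
             cbind(t(P), matrix(0, 3, 3)))
  V <- rbind(cbind(lm$xt, lm$yt), matrix(0, 3, 2))
  sol <- tryCatch(solve(L, V), error = function(e)
    atkStop("singular", "TPS system is singular: %s", conditionMessage(e)))
  new("TransformModel", kind = "tps",
      params = list(weights = sol[seq_len(n), , drop = FALSE],
                    affine = sol[n + 1:3, , drop = FALSE],
                    anchors = S, lambda = lambda))
}

#' Map points through a transform model
#'
#' @param model a \linkS4class{TransformModel}.
#' @param pts n x 2 matrix (or length-2 vector) of (x, y) points.
#' @return n x 2 matrix of mapped points.
#' @export
transformPoints <- function(model, pts) {
  if (!is.matrix(pts)) pts <- matrix(pts, ncol = 2)
  switch(model@kind,
    rigid = sweep(pts %*% t(model@params$R), 2, model@params$t, "+"),
    affine = {
      A <- model@params$A
      sweep(pts %*% t(A[, 1:2]), 2, A[, 3], "+")
    },
    tps = {
      p <- model@params
      U <- .tpsKernel(pmax(.tpsDistance2(pts, p$anchors), 0))
      cbind(1, pts) %*% p$affine + U %*% p$weights
    })
}

#' Root-mean-square landmark residual of a fitted model
#' @param model a \linkS4class{TransformModel}.
#' @param landmarks the landmark pairs the model was fitted to.
#' @return RMS of the distances between mapped source and template points.
#' @export
transformResidual <- function(model, landmarks) {
  pred <- transformPoints(model, cbind(landmarks$xs, landmarks$ys))
  sqrt(mean(rowSums((pred - cbind(landmarks$xt, landmarks$yt))^2)))
}

setMethod("show", "TransformModel", function(object) {
  cat(sprintf("TransformModel (%s)", object@kind))
  if (object@kind == "rigid") {
    cat(sprintf(": angle %.3f deg, t = (%.3f, %.3f)",
                object@params$angle, object@params$t[1], object@params$t[2]))
  }
  if (object@kind == "tps") {
    cat(sprintf(": %d anchors, lambda %g", nrow(object@params$anchors),
                object@params$lambda))
  }
  cat("\n")
})

# Sample an image at arbitrary (x, y) points, per channel.
.sampleImageAt <- function(px, xs, ys, interpolation) {
  h <- nrow(px); w <- ncol(px)
  if (interpolation == "nearest") {
    xi <- round(xs); yi <- round(ys)
    valid <- xi >= 1 & xi <= w & yi >= 1 & yi <= h
    idx <- cbind(as.vector(pmin(pmax(yi, 1), h)), as.vector(pmin(pmax(xi, 1), w)))
    out <- ifelse(valid, px[idx], 0)
  } else {
    x0 <- floor(xs); y0 <- floor(ys)
    fx <- xs - x0; fy <- ys - y0
    out <- 0
    for (oy in 0:1) for (ox in 0:1) {
      xi <- x0 + ox; yi <- y0 + oy
      wgt <- (ox * fx + (1 - ox) * (1 - fx)) * (oy * fy + (1 - oy) * (1 - fy))
      valid <- xi >= 1 & xi <= w & yi >= 1 & yi <= h & wgt > 0
      idx <- cbind(as.vector(pmin(pmax(yi, 1), h)), as.vector(pmin(pmax(xi, 1), w)))
      out <- out + ifelse(valid, wgt * px[idx], 0)
    }
  }
  out
}

# Invert a linear (rigid/affine) model.
.invertLinear <- function(model) {
  if (model@kind == "rigid") {
    R <- model@params$R; t <- model@params$t
    list(A = t(R), t = -as.numeric(t(R) %*% t))
  } else {
    A <- model@params$A
    M <- A[, 1:2]
    if (abs(det(M)) < .Machine$double.eps) {
      atkStop("singular", "affine transform is not invertible")
    }
    Mi <- solve(M)
    list(A = Mi, t = -as.numeric(Mi %*% A[, 3]))
  }
}

#' Resample an image through a transform
#'
#' Output pixel p is sampled from the source image at the source-space
#' position of p: for rigid and affine models (which map source to template)
#' that position is transform^-1(p); for a TPS model the given spline must
#' itself map template space to source space, so the resampling is a direct
#' evaluation (warp inversion is not closed-form; fit the reverse-direction
#' spline, as \code{\link{registerImages}} does).
#'
#' @param image the source \linkS4class{Image2D}.
#' @param model a \linkS4class{TransformModel}.
#' @param outputShape integer(2) rows, cols of the output (default the input
#'   shape).
#' @param interpolation "bilinear" (default) or "nearest".
#' @return the resampled \linkS4class{Image2D}.
#' @export
applyTransform <- function(image, model, outputShape = NULL,
                           interpolation = c("bilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  px <- image@pixels
  d <- dim(px)
  outputShape <- as.integer(outputShape %||% d[1:2])
  h <- outputShape[1]; w <- outputShape[2]
  xg <- matrix(rep(seq_len(w), each = h), h, w)
  yg <- matrix(rep(seq_len(h), times = w), h, w)
  pts <- cbind(as.numeric(xg), as.numeric(yg))
  src <- if (model@kind == "tps") {
    transformPoints(model, pts)
  } else {
    inv <- .invertLinear(model)
    sweep(pts %*% t(inv$A), 2, inv$t, "+")
  }
  xs <- matrix(src[, 1], h, w); ys <- matrix(src[, 2], h, w)
  if (length(d) == 2L) {
    out <- matrix(.sampleImageAt(px, xs, ys, interpolation), h, w)
  } else {
    out <- array(0, c(h, w, d[3]))
    for (c in seq_len(d[3])) {
      out[, , c] <- .sampleImageAt(px[, , c], xs, ys, interpolation)
    }
  }
  image2d(out, pixelSize = image@pixelSize)
}

#' Landmark-based registration of a source image to a template
#'
#' Fits the requested model to the landmark pairs and resamples the source
#' into the template geometry. For rigid and affine models the fitted
#' forward map is inverted analytically; for TPS the reverse-direction
#' spline (template to source) is fitted for resampling, since a TPS warp
#' has no closed-form inverse. For 2D-to-3D use, pick the template slice
#' with \code{\link{extractSlice}} first.
#'
#' @param source,template \linkS4class{Image2D} objects.
#' @param landmarks data.frame (xs, ys, xt, yt): source point, template
#'   point per row.
#' @param model "rigid", "affine" or "tps".
#' @param lambda TPS smoothing (default 0).
#' @param interpolation "bilinear" or "nearest".
#' @return list with \code{model} (the forward \linkS4class{TransformModel}),
#'   \code{aligned} (the resampled \linkS4class{Image2D} in template
#'   geometry), \code{residual} (RMS landmark residual of the forward fit)
#'   and \code{nLandmarks}.
#' @export
registerImages <- function(source, template, landmarks,
                           model = c("rigid", "affine", "tps"), lambda = 0,
                           interpolation = c("bilinear", "nearest")) {
  model <- match.arg(model)
  interpolation <- match.arg(interpolation)
  fwd <- switch(model,
                rigid = fitRigid(landmarks),
                affine = fitAffine(landmarks),
                tps = fitTps(landmarks, lambda))
  resampler <- if (model == "tps") {
    rev <- landmarks
    names(rev) <- c("xt", "yt", "xs", "ys")
    fitTps(rev, lambda)
  } else {
    fwd
  }
  aligned <- applyTransform(source, resampler,
                            outputShape = dim(template@pixels)[1:2],
                            interpolation = interpolation)
  list(model = fwd, aligned = aligned,
       residual = transformResidual(fwd, landmarks),
       nLandmarks = nrow(landmarks), modelKind = model)
}

# ---------------------------------------------------------------------------
# Registration backend registry
# ---------------------------------------------------------------------------

.atkEnv <- new.env(parent = emptyenv())
.atkEnv$backends <- list()

#' Register a registration backend
#'
#' A backend is a named function \code{function(source, template, options)}
#' returning at least \code{list(model = ..., aligned = ...)}. The core
#' imposes only this input/output contract; anything may happen behind it.
#'
#' @param name unique backend name.
#' @param fun the backend function.
#' @param overwrite allow replacing an existing backend (default FALSE).
#' @return the name, invisibly.
#' @export
registerBackend <- function(name, fun, overwrite = FALSE) {
  if (!overwrite && name %in% names(.atkEnv$backends)) {
    atkStop("registration", "backend '%s' is already registered", name)
  }
  .atkEnv$backends[[name]] <- fun
  invisible(name)
}

#' List registered registration backends
#' @return sorted character vector of backend names.
#' @export
listBackends <- function() sort(names(.atkEnv$backends))

#' Remove a registration backend from the registry
#' @param name backend name; unknown names are ignored.
#' @return invisibly, TRUE if a backend was removed.
#' @export
unregisterBackend <- function(name) {
  had <- name %in% names(.atkEnv$backends)
  .atkEnv$backends[[name]] <- NULL
  invisible(had)
}

#' Invoke a registration backend by name
#'
#' A backend that fails internally is reported as a backend failure naming
#' the backend; the registry itself is unaffected.
#'
#' @param name backend name.
#' @param source,template \linkS4class{Image2D} objects.
#' @param options named list passed to the backend (for the built-in
#'   \code{landmark_warp} backend: \code{landmarks}, \code{model},
#'   \code{lambda}, \code{interpolation}).
#' @return the backend's result list.
#' @export
invokeBackend <- function(name, source, template, options = list()) {
  fun <- .atkEnv$backends[[name]]
  if (is.null(fun)) {
    atkStop("not_found", "unknown backend '%s'; available: %s", name,
            paste(listBackends(), collapse = ", "))
  }
  tryCatch(fun(source, template, options), error = function(e) {
    atkStop("backend", "backend '%s' failed: %s", name, conditionMessage(e))
  })
}

.landmarkWarpBackend <- function(source, template, options) {
  lms <- options$landmarks
  if (is.character(lms)) lms <- readLandmarks(lms)
  if (is.null(lms)) atkStop("validation", "landmark_warp needs options$landmarks")
  registerImages(source, template, lms,
                 model = options$model %||% "tps",
                 lambda = options$lambda %||% 0,
                 interpolation = options$interpolation %||% "bilinear")
}
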