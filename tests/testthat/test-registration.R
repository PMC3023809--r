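rot2 <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
}

randomPoints <- function(n, lo = 0, hi = 50) {
  cbind(runif(n, lo, hi), runif(n, lo, hi))
}

test_that("rigid fit recovers generated transforms exactly and rejects degeneracy", {
  idpairs <- data.frame(xs = c(0, 4, 1), ys = c(0, 0, 3),
                        xt = c(0, 4, 1), yt = c(0, 0, 3))
  fit <- fitRigid(idpairs)
  expect_equal(fit@params$R, diag(2), tolerance = 1e-12)
  expect_equal(fit@params$t, c(0, 0), tolerance = 1e-12)

  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  R90 <- rot2(90)
  tq <- sq %*% t(R90)
  fit90 <- fitRigid(data.frame(xs = sq[, 1], ys = sq[, 2],
                               xt = tq[, 1], yt = tq[, 2]))
  expect_equal(fit90@params$angle, 90, tolerance = 1e-9)
  expect_lt(transformResidual(fit90, data.frame(xs = sq[, 1], ys = sq[, 2],
                                                xt = tq[, 1], yt = tq[, 2])),
            1e-9)

  set.seed(100)
  for (i in 1:100) {
    n <- sample(3:12, 1)
    S <- randomPoints(n)
    ang <- runif(1, -180, 180); tr <- runif(2, -20, 20)
    Tp <- sweep(S %*% t(rot2(ang)), 2, tr, "+")
    fit <- fitRigid(data.frame(xs = S[, 1], ys = S[, 2],
                               xt = Tp[, 1], yt = Tp[, 2]))
    pred <- transformPoints(fit, S)
    expect_lt(max(abs(pred - Tp)), 1e-9)
  }

  expect_error(fitRigid(idpairs[1, ]), class = "atk_validation")
  same <- data.frame(xs = c(1, 1, 1), ys = c(2, 2, 2),
                     xt = c(0, 1, 2), yt = c(0, 1, 2))
  expect_error(fitRigid(same), class = "atk_degenerate")
})

test_that("noisy rigid fit is within a degree and beats a grid search", {
  set.seed(5)
  n <- 20
  S <- randomPoints(n)
  truth <- rot2(30)
  Tp <- sweep(S %*% t(truth), 2, c(3, -2), "+") + matrix(rnorm(2 * n, 0, 0.1),
                                                         n, 2)
  lms <- data.frame(xs = S[, 1], ys = S[, 2], xt = Tp[, 1], yt = Tp[, 2])
  fit <- fitRigid(lms)
  expect_lt(abs(fit@params$angle - 30), 1)

  # brute-force grid over angles (translation optimal given the angle)
  gridBest <- Inf
  sc <- colMeans(S); tc <- colMeans(Tp)
  for (ang in seq(25, 35, by = 0.1)) {
    R <- rot2(ang)
    t0 <- tc - as.numeric(R %*% sc)
    res <- sqrt(mean(rowSums((sweep(S %*% t(R), 2, t0, "+") - Tp)^2)))
    gridBest <- min(gridBest, res)
  }
  expect_lte(transformResidual(fit, lms), gridBest + 1e-12)
})

test_that("affine fit is exact on affine data and locally optimal under noise", {
  idp <- data.frame(xs = c(0, 5, 2, 7), ys = c(0, 1, 6, 4),
                    xt = c(0, 5, 2, 7), yt = c(0, 1, 6, 4))
  A <- fitAffine(idp)@params$A
  expect_equal(A, cbind(diag(2), c(0, 0)), tolerance = 1e-12)

  shear <- matrix(c(1, 0, 0.5, 1), 2, 2)
  set.seed(7)
  for (i in 1:100) {
    S <- randomPoints(sample(3:10, 1))
    if (qr(cbind(1, S))$rank < 3) next
    M <- matrix(runif(4, -2, 2), 2, 2)
    if (abs(det(M)) < 0.1) next
    off <- runif(2, -10, 10)
    Tp <- sweep(S %*% t(M), 2, off, "+")
    fit <- fitAffine(data.frame(xs = S[, 1], ys = S[, 2],
                                xt = Tp[, 1], yt = Tp[, 2]))
    expect_lt(max(abs(fit@params$A - cbind(M, off))), 1e-9)
  }
  S <- randomPoints(5)
  Tp <- sweep(S %*% t(shear), 2, c(0, 0), "+")
  fitS <- fitAffine(data.frame(xs = S[, 1], ys = S[, 2],
                               xt = Tp[, 1], yt = Tp[, 2]))
  expect_lt(max(abs(fitS@params$A[, 1:2] - shear)), 1e-9)

  # overdetermined noisy system: no random perturbation does better
  set.seed(12)
  S <- randomPoints(15)
  Tp <- sweep(S %*% t(shear), 2, c(1, 2), "+") + matrix(rnorm(30, 0, 0.3),
                                                        15, 2)
  lms <- data.frame(xs = S[, 1], ys = S[, 2], xt = Tp[, 1], yt = Tp[, 2])
  best <- fitAffine(lms)
  bestRes <- transformResidual(best, lms)
  for (i in 1:1000) {
    pert <- best
    pert@params$A <- best@params$A + matrix(rnorm(6, 0, 0.01), 2, 3)
    expect_gte(transformResidual(pert, lms), bestRes - 1e-12)
  }

  coll <- data.frame(xs = c(0, 1, 2), ys = c(0, 1, 2),
                     xt = c(0, 1, 2), yt = c(0, 2, 4))
  expect_error(fitAffine(coll), class = "atk_degenerate")
})

test_that("rigid residual never beats affine residual on the same landmarks", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(4:12, 1)
    S <- randomPoints(n)
    Tp <- randomPoints(n)
    lms <- data.frame(xs = S[, 1], ys = S[, 2], xt = Tp[, 1], yt = Tp[, 2])
    if (qr(cbind(1, S))$rank < 3) next
    expect_gte(transformResidual(fitRigid(lms), lms),
               transformResidual(fitAffine(lms), lms) - 1e-9)
  }
})

test_that("TPS interpolates at lambda 0, collapses to affine on affine data, and smooths with lambda", {
  set.seed(9)
  S <- randomPoints(9, 5, 45)
  Tp <- S + matrix(runif(18, -3, 3), 9, 2)
  lms <- data.frame(xs = S[, 1], ys = S[, 2], xt = Tp[, 1], yt = Tp[, 2])
  tps <- fitTps(lms, 0)
  expect_lt(max(abs(transformPoints(tps, S) - Tp)), 1e-6)
  # side conditions
  P <- cbind(1, S)
  expect_lt(max(abs(crossprod(P, tps@params$weights))), 1e-6)

  M <- matrix(c(1.2, 0.3, -0.4, 0.9), 2, 2)
  Ta <- sweep(S %*% t(M), 2, c(2, -1), "+")
  lmsA <- data.frame(xs = S[, 1], ys = S[, 2], xt = Ta[, 1], yt = Ta[, 2])
  tpsA <- fitTps(lmsA, 0)
  expect_lt(sqrt(sum(tpsA@params$weights^2)), 1e-6)
  aff <- fitAffine(lmsA)
  grid <- as.matrix(expand.grid(seq(0, 50, 10), seq(0, 50, 10)))
  expect_lt(max(abs(transformPoints(tpsA, grid) - transformPoints(aff, grid))),
            1e-6)

  # increasing lambda pulls the warp towards the least-squares affine
  set.seed(10)
  Tn <- Ta + matrix(rnorm(18, 0, 1.5), 9, 2)
  lmsN <- data.frame(xs = S[, 1], ys = S[, 2], xt = Tn[, 1], yt = Tn[, 2])
  affN <- fitAffine(lmsN)
  sup <- vapply(c(0.1, 10, 1000), function(lam) {
    max(abs(transformPoints(fitTps(lmsN, lam), grid) -
              transformPoints(affN, grid)))
  }, numeric(1))
  expect_true(all(diff(sup) < 0))

  dupl <- lms; dupl$xs[2] <- dupl$xs[1]; dupl$ys[2] <- dupl$ys[1]
  expect_error(fitTps(dupl, 0), class = "atk_singular")
  expect_error(fitTps(lms, -1), class = "atk_validation")
})

test_that("applyTransform matches per-pixel remapping oracles", {
  set.seed(15)
  img <- image2d(matrix(runif(25), 5, 5))
  ident <- fitAffine(data.frame(xs = c(1, 5, 3), ys = c(1, 2, 5),
                                xt = c(1, 5, 3), yt = c(1, 2, 5)))
  expect_equal(imagePixels(applyTransform(img, ident)), imagePixels(img))

  shift <- new("TransformModel", kind = "affine",
               params = list(A = cbind(diag(2), c(3, 0))))
  out <- applyTransform(img, shift, interpolation = "nearest")
  px <- imagePixels(img); o <- imagePixels(out)
  expect_identical(o[, 4:5], px[, 1:2])
  expect_true(all(o[, 1:3] == 0))

  # 90-degree rotation about the image center vs a brute-force remap
  ctr <- 3
  R <- rot2(90)
  t90 <- c(ctr, ctr) - as.numeric(R %*% c(ctr, ctr))
  rot <- new("TransformModel", kind = "rigid",
             params = list(R = R, t = t90, angle = 90))
  o2 <- imagePixels(applyTransform(img, rot, interpolation = "nearest"))
  expected <- matrix(0, 5, 5)
  for (y in 1:5) for (x in 1:5) {
    src <- as.numeric(t(R) %*% (c(x, y) - t90))   # inverse map
    sx <- round(src[1]); sy <- round(src[2])
    if (sx >= 1 && sx <= 5 && sy >= 1 && sy <= 5) {
      expected[y, x] <- px[sy, sx]
    }
  }
  expect_equal(o2, expected)

  sing <- new("TransformModel", kind = "affine",
              params = list(A = cbind(matrix(0, 2, 2), c(0, 0))))
  expect_error(applyTransform(img, sing), class = "atk_singular")
})

test_that("registerImages aligns synthetic pairs within tolerance", {
  spec <- fixtureSpec(seed = 6L)

  idp <- makeWarpedPair(spec, "rigid", magnitude = 0)
  regId <- registerImages(idp$source, idp$template, idp$landmarks, "rigid")
  expect_equal(imagePixels(regId$aligned), imagePixels(idp$source),
               tolerance = 1e-12)

  # pure integer translation with 4 corner landmarks: interpolation-exact
  set.seed(44)
  base <- matrix(runif(32 * 32), 32, 32)
  tmplA <- image2d(base)
  srcA <- image2d(rbind(base[4:32, ], matrix(0, 3, 32)))  # content shifted up
  corners <- data.frame(xs = c(5, 28, 5, 28), ys = c(5, 5, 25, 25))
  corners$xt <- corners$xs; corners$yt <- corners$ys + 3
  regT <- registerImages(srcA, tmplA, corners, "rigid")
  inner <- 5:28
  expect_lt(mean(abs(imagePixels(regT$aligned)[inner, inner] -
                       imagePixels(tmplA)[inner, inner])), 0.01)

  warped <- makeWarpedPair(spec, "tps", magnitude = 2)
  regW <- registerImages(warped$source, warped$template, warped$landmarks,
                         "tps", lambda = 0)
  expect_lt(regW$residual, 0.5)
  expect_identical(regW$nLandmarks, nrow(warped$landmarks))
  expect_identical(dim(imagePixels(regW$aligned)),
                   dim(imagePixels(warped$template)))
})

test_that("the backend registry routes, lists, and wraps failures", {
  expect_true("landmark_warp" %in% listBackends())

  echo <- function(source, template, options) list(model = NULL,
                                                   aligned = source)
  registerBackend("echo_test", echo)
  on.exit(unregisterBackend("echo_test"), add = TRUE)
  img <- image2d(matrix(0.5, 3, 3))
  res <- invokeBackend("echo_test", img, img)
  expect_identical(imagePixels(res$aligned), imagePixels(img))
  expect_error(registerBackend("echo_test", echo), class = "atk_registration")

  registerBackend("crashy_test", function(s, t, o) stop("inner explosion"))
  on.exit(unregisterBackend("crashy_test"), add = TRUE)
  err <- tryCatch(invokeBackend("crashy_test", img, img),
                  error = function(e) e)
  expect_s3_class(err, "atk_backend")
  expect_match(conditionMessage(err), "crashy_test")
  expect_true("landmark_warp" %in% listBackends())   # registry unaffected

  err2 <- tryCatch(invokeBackend("no_such_backend", img, img),
                   error = function(e) conditionMessage(e))
  expect_match(err2, "landmark_warp")                # lists what exists

  spec <- fixtureSpec(seed = 2L)
  pair <- makeWarpedPair(spec, "rigid", magnitude = 8)
  viaBackend <- invokeBackend("landmark_warp", pair$source, pair$template,
                              list(landmarks = pair$landmarks,
                                   model = "rigid"))
  direct <- registerImages(pair$source, pair$template, pair$landmarks,
                           "rigid")
  expect_identical(imagePixels(viaBackend$aligned),
                   imagePixels(direct$aligned))
})

test_that("landmark files round-trip and reject malformed rows", {
  lms <- data.frame(xs = c(1.5, 2), ys = c(3, 4.25), xt = c(5, 6),
                    yt = c(7, 8.5))
  f <- withr::local_tempfile(fileext = ".txt")
  writeLandmarks(lms, f)
  expect_equal(readLandmarks(f), lms)
  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# comment", "1 2 3"), bad)
  expect_error(readLandmarks(bad), class = "atk_format")
  expect_error(readLandmarks(tempfile()), class = "atk_not_found")
})
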