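# Moving-least-squares deformation: weights, closed forms, fields,
# fold-back prevention, image and contour warping.

test_that("weights follow the inverse-distance power law", {
  p <- rbind(c(0, 1), c(0, -1))
  expect_equal(mlsWeights(c(0, 0), p, alpha = 2), c(1, 1))
  expect_equal(mlsWeights(c(2, 1), p, alpha = 2)[1], 1 / 16)
  # scaling all distances by s scales weights by s^(-2 alpha)
  p3 <- spreadPoints(6)
  v <- c(11, 17)
  w1 <- mlsWeights(v, p3, alpha = 2)
  for (s in c(2, 10)) {
    ws <- mlsWeights(s * v, s * p3, alpha = 2)
    expect_equal(ws, w1 * s^(-4), tolerance = 1e-12)
  }
  expect_error(mlsWeights(p[1, ], p, alpha = 2, eps = 1e-6), "coincides")
})

test_that("pointwise solves satisfy interpolation, identity and closed-form recovery", {
  p <- spreadPoints(8)
  vs <- withr::with_seed(11, matrix(runif(100, 0, 50), ncol = 2))
  for (mode in c("affine", "similarity", "rigid")) {
    cfg <- MLSConfig(mode = mode)
    # q = p  =>  f is the identity
    cpsI <- ControlPointSet(p, p)
    got <- t(apply(vs, 1, solvePoint, cps = cpsI, cfg = cfg))
    expect_equal(got, vs, tolerance = 1e-9)
    # pure translation is in all three families
    cpsT <- ControlPointSet(p, p + rep(1, 8) %o% c(3, -1))
    gotT <- t(apply(vs, 1, solvePoint, cps = cpsT, cfg = cfg))
    expect_equal(gotT, vs + rep(1, nrow(vs)) %o% c(3, -1), tolerance = 1e-9)
    # querying at a source point returns the matched target exactly
    expect_equal(solvePoint(p[3, ], cpsT, cfg), p[3, ] + c(3, -1))
  }
  # affine mode reproduces any exact affine correspondence everywhere
  errs <- vapply(1:50, function(s) {
    M <- withr::with_seed(100 + s, matrix(runif(4, -1, 1), 2, 2))
    if (abs(det(M)) < 0.1) M <- M + diag(2)
    Tv <- withr::with_seed(200 + s, runif(2, -5, 5))
    q <- p %*% M + rep(1, 8) %o% Tv
    got <- t(apply(vs[1:10, ], 1, solvePoint,
                   cps = ControlPointSet(p, q), cfg = MLSConfig()))
    max(abs(got - (vs[1:10, ] %*% M + rep(1, 10) %o% Tv)))
  }, numeric(1))
  expect_lt(max(errs), 1e-9)
  # rigid mode is an isometry when (p, q) are rotation + translation related
  R <- rotationMat(0.7)
  q <- p %*% R + rep(1, 8) %o% c(2, 9)
  pts <- withr::with_seed(12, matrix(runif(40, 0, 50), ncol = 2))
  gotR <- t(apply(pts, 1, solvePoint, cps = ControlPointSet(p, q),
                  cfg = MLSConfig(mode = "rigid")))
  expect_equal(as.vector(dist(gotR)), as.vector(dist(pts)),
               tolerance = 1e-9)
})

test_that("similarity and rigid transforms carry the promised matrix structure", {
  p <- spreadPoints(7, seed = 21)
  q <- p + withr::with_seed(22, matrix(rnorm(14, 0, 3), ncol = 2))
  v <- c(20, 25)
  Ms <- mlsTransform(v, ControlPointSet(p, q), MLSConfig(mode = "similarity"))@M
  # lambda R: orthogonal columns of equal norm
  expect_equal(sum(Ms[, 1] * Ms[, 2]), 0, tolerance = 1e-12)
  expect_equal(sum(Ms[, 1]^2), sum(Ms[, 2]^2), tolerance = 1e-12)
  Mr <- mlsTransform(v, ControlPointSet(p, q), MLSConfig(mode = "rigid"))@M
  expect_equal(det(Mr), 1, tolerance = 1e-12)
  expect_equal(crossprod(Mr), diag(2), tolerance = 1e-12)
  # f(x) = xM + T is consistent with solvePoint
  tr <- mlsTransform(v, ControlPointSet(p, q), MLSConfig())
  expect_equal(drop(v %*% tr@M + tr@T),
               solvePoint(v, ControlPointSet(p, q), MLSConfig()),
               tolerance = 1e-10)
})

test_that("mode nesting: residual is non-increasing from rigid to similarity to affine", {
  p <- spreadPoints(9, seed = 31)
  resid <- function(v, cps, mode) {
    cfg <- MLSConfig(mode = mode)
    w <- mlsWeights(v, srcPoints(cps), alpha = 2)
    tr <- mlsTransform(v, cps, cfg)
    f <- srcPoints(cps) %*% tr@M + rep(1, nPoints(cps)) %o% tr@T
    sum(w * rowSums((f - dstPoints(cps))^2))
  }
  for (s in 1:5) {
    q <- p + withr::with_seed(40 + s, matrix(rnorm(18, 0, 4), ncol = 2))
    cps <- ControlPointSet(p, q)
    v <- withr::with_seed(50 + s, runif(2, 5, 45))
    rr <- resid(v, cps, "rigid")
    rs <- resid(v, cps, "similarity")
    ra <- resid(v, cps, "affine")
    expect_lte(rs, rr + 1e-9)
    expect_lte(ra, rs + 1e-9)
  }
})

test_that("collinear sources in affine mode raise a degenerate-geometry error", {
  p <- cbind(seq(5, 45, length.out = 5), seq(5, 45, length.out = 5))
  q <- p + 1
  expect_error(solvePoint(c(10, 30), ControlPointSet(p, q), MLSConfig()),
               "similarity")
  # similarity mode handles the same geometry
  expect_silent(solvePoint(c(10, 30), ControlPointSet(p, q),
                           MLSConfig(mode = "similarity")))
})

test_that("dense fields sample the pointwise solves faithfully", {
  p <- spreadPoints(6, seed = 61)
  cfg <- MLSConfig(gridSpacing = 1)
  domain <- c(50, 50)
  fI <- buildField(ControlPointSet(p, p), domain, cfg)
  grid <- cbind(rep(fI@xs, times = length(fI@ys)),
                rep(fI@ys, each = length(fI@xs)))
  expect_equal(cbind(as.vector(fI@fx), as.vector(fI@fy)), grid,
               tolerance = 1e-9)
  fT <- buildField(ControlPointSet(p, p + rep(1, 6) %o% c(2, 5)), domain, cfg)
  expect_equal(as.vector(fT@fx) - grid[, 1], rep(2, nrow(grid)),
               tolerance = 1e-9)
  # off-grid bilinear evaluation tracks the direct solve on a smooth warp
  q <- p + withr::with_seed(62, matrix(rnorm(12, 0, 2), ncol = 2))
  fS <- buildField(ControlPointSet(p, q), domain, cfg)
  pts <- withr::with_seed(63, matrix(runif(60, 2, 48), ncol = 2))
  interp <- evalField(fS, pts)
  direct <- evalField(fS, pts, exact = TRUE)
  expect_lt(max(sqrt(rowSums((interp - direct)^2))), 0.5)
})

test_that("jacobian sign detection separates fold-free from folding fields", {
  p <- spreadPoints(6, seed = 71)
  cfg <- MLSConfig(gridSpacing = 1)
  fI <- buildField(ControlPointSet(p, p), c(40, 40), cfg)
  jI <- jacobianSignUniform(fI)
  expect_true(jI$uniform)
  expect_equal(jI$det, matrix(1, length(fI@xs), length(fI@ys)),
               tolerance = 1e-6)
  # pure rotation about the domain center: det = +1 everywhere
  ctr <- c(20, 20); R <- rotationMat(0.5)
  q <- sweep(sweep(p, 2, ctr) %*% R, 2, ctr, "+")
  jR <- jacobianSignUniform(buildField(ControlPointSet(p, q), c(40, 40),
                                       MLSConfig(mode = "rigid")))
  expect_true(jR$uniform)
  expect_equal(mean(jR$det), 1, tolerance = 1e-3)
  # two points swapping across a short gap folds the map
  pS <- rbind(c(18, 20), c(22, 20), c(5, 5), c(35, 5), c(20, 35))
  qS <- rbind(c(23, 21), c(17, 19), c(5, 5), c(35, 5), c(20, 35))
  jS <- jacobianSignUniform(buildField(ControlPointSet(pS, qS), c(40, 40), cfg))
  expect_false(jS$uniform)
  expect_true(any(jS$det < 0) && any(jS$det > 0))
  # a sub-3x3 grid cannot support the finite differences
  tiny <- buildField(ControlPointSet(p, p), c(2, 2), cfg)
  expect_error(jacobianSignUniform(tiny), "insufficient domain")
})

test_that("partial warps decompose folds and compose to the full warp", {
  cfg <- MLSConfig(gridSpacing = 1)
  domain <- c(50, 50)
  diag50 <- sqrt(sum(domain^2))
  # mild warp: accepted in a single step
  p <- spreadPoints(6, seed = 81)
  qMild <- p + withr::with_seed(82, matrix(rnorm(12, 0, 1.5), ncol = 2))
  wsM <- partialWarpSequence(ControlPointSet(p, qMild), domain, cfg)
  expect_identical(length(wsM), 1L)
  expect_lt(max(abs(warpPoints(wsM, p) - qMild)), 1e-6 * diag50)
  # staggered pass-by: needs several partial steps, still lands on q
  pX <- rbind(c(20, 20), c(24, 21), c(10, 40), c(40, 40), c(30, 5),
              c(5, 5), c(45, 20))
  qX <- rbind(c(27, 21), c(17, 20), c(10, 40), c(40, 40), c(30, 5),
              c(5, 5), c(45, 20))
  wsX <- partialWarpSequence(ControlPointSet(pX, qX), domain, cfg)
  expect_gte(length(wsX), 2L)
  expect_lt(max(abs(warpPoints(wsX, pX) - qX)), 1e-6 * diag50)
  expect_true(all(vapply(warpSteps(wsX),
                         function(f) isTRUE(f@jacobianSignUniform),
                         logical(1))))
  expect_equal(wsX@schedule[length(wsX@schedule)], 1)
  # q = p: single identity step, composed map is the identity
  wsI <- partialWarpSequence(ControlPointSet(p, p), domain, cfg)
  expect_identical(length(wsI), 1L)
  pts <- withr::with_seed(83, matrix(runif(200, 1, 49), ncol = 2))
  expect_equal(warpPoints(wsI, pts), pts, tolerance = 1e-9)
  # handles swapping exactly through each other cannot be decomposed
  pD <- rbind(c(20, 20), c(24, 20), c(5, 5), c(45, 5), c(25, 45))
  qD <- rbind(c(24, 20), c(20, 20), c(5, 5), c(45, 5), c(25, 45))
  expect_error(partialWarpSequence(ControlPointSet(pD, qD), domain,
                                   MLSConfig(maxBisections = 4)),
               "non-decomposable")
})

test_that("image warping honors identity, constancy and translation contracts", {
  img <- withr::with_seed(91, matrix(runif(64 * 64, 0, 100), 64, 64))
  p <- spreadPoints(5, size = 64, seed = 92)
  cfg <- MLSConfig(gridSpacing = 1)
  wsI <- partialWarpSequence(ControlPointSet(p, p), c(64, 64), cfg)
  expect_equal(warpImage(img, wsI), img, tolerance = 1e-9)
  # constant image stays constant in the interior under any mild sequence
  qs <- p + withr::with_seed(93, matrix(rnorm(10, 0, 2), ncol = 2))
  wsS <- partialWarpSequence(ControlPointSet(p, qs), c(64, 64), cfg)
  cst <- matrix(5, 64, 64)
  expect_equal(warpImage(cst, wsS, fill = 5)[10:54, 10:54],
               cst[10:54, 10:54], tolerance = 1e-9)
  # integer translation equals a direct index shift on the overlap
  qT <- p + rep(1, 5) %o% c(3, -2)
  wsT <- partialWarpSequence(ControlPointSet(p, qT), c(64, 64), cfg)
  wT <- warpImage(img, wsT, fill = 0)
  expect_equal(wT[4:64, 1:62], img[1:61, 3:64], tolerance = 1e-7)
})

test_that("contour warping preserves labels, closure and rigid-mode areas", {
  poly <- list(A = circlePoly(c(25, 25), 8), B = squarePoly(c(40, 12), 4))
  p <- spreadPoints(6, seed = 95)
  cfg <- MLSConfig(gridSpacing = 1)
  wsI <- partialWarpSequence(ControlPointSet(p, p), c(50, 50), cfg)
  wI <- warpContours(poly, wsI)
  expect_identical(names(wI), c("A", "B"))
  expect_equal(wI$A, poly$A, tolerance = 1e-9)
  # translation preserves areas exactly
  wsT <- partialWarpSequence(
    ControlPointSet(p, p + rep(1, 6) %o% c(2, 1)), c(50, 50), cfg)
  wT <- warpContours(poly, wsT)
  expect_equal(polygonArea(wT$A), polygonArea(poly$A), tolerance = 1e-9)
  # rigid-mode rotation preserves area to < 0.1 %
  ctr <- c(25, 25); R <- rotationMat(25 * pi / 180)
  pr <- circlePoly(ctr, 12, 10)
  qr <- sweep(sweep(pr, 2, ctr) %*% R, 2, ctr, "+")
  wsR <- partialWarpSequence(ControlPointSet(pr, qr), c(50, 50),
                             MLSConfig(mode = "rigid"))
  wR <- warpContours(poly["A"], wsR)
  expect_lt(abs(polygonArea(wR$A) / polygonArea(poly$A) - 1), 0.001)
  # out-of-domain vertices are clamped with a warning
  far <- list(C = squarePoly(c(49, 49), 3))
  expect_warning(warpContours(far, wsI), "clamped")
})
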