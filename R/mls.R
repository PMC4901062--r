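## Moving-least-squares (MLS) 2D deformation.
##
## For each query point v the method solves for its own affine map
## f(x) = xM + T (row-vector convention) minimizing
##     sum_i w_i |f(p_i) - q_i|^2,   w_i = 1 / |p_i - v|^(2 alpha),
## so that f(p_i) = q_i in the limit, f is smooth in v, and f is the
## identity whenever q = p. The weighted-centroid closed forms: with
## weighted centroids p*, q* and centered coordinates phat_i = p_i - p*,
## qhat_i = q_i - q*,
##   affine:     M = A^-1 B,  A = sum w phat' phat,  B = sum w phat' qhat
##   similarity: M = [[a, b], [-b, a]] / mu,  a = tr(B), b = B12 - B21,
##               mu = sum w |phat|^2   (the unconstrained lambda * rotation)
##   rigid:      M = [[c, s], [-s, c]],  (c, s) = (a, b) / sqrt(a^2 + b^2)
##               (weighted Procrustes rotation, det(M) = +1)
## and always T = q* - p* M.

# Vectorized MLS solve: V is P x 2 query points. Returns the mapped points
# and, when `transform = TRUE` (single query), the local M and T.
mlsSolve <- function(V, p, q, mode, alpha, eps, transform = FALSE) {
  V <- matrix(as.numeric(V), ncol = 2)
  px <- p[, 1]; py <- p[, 2]; qx <- q[, 1]; qy <- q[, 2]
  P <- nrow(V)
  Dx <- outer(V[, 1], px, "-"); Dy <- outer(V[, 2], py, "-")
  D2 <- Dx * Dx + Dy * Dy
  hit <- D2 < eps^2
  hitRow <- rowSums(hit) > 0
  D2[hit] <- eps^2                       # placeholder; rows overwritten below
  W <- D2^(-alpha)
  sw <- rowSums(W)
  psx <- (W %*% px)[, 1] / sw; psy <- (W %*% py)[, 1] / sw
  qsx <- (W %*% qx)[, 1] / sw; qsy <- (W %*% qy)[, 1] / sw
  vhx <- V[, 1] - psx; vhy <- V[, 2] - psy
  # centered moments (phat = p - p*, qhat = q - q* per query row): immune
  # to the cancellation that raw-moment sums suffer when one weight
  # dominates near a source point
  Phx <- vhx - Dx; Phy <- vhy - Dy
  ones <- rep(1, P)
  Qhx <- ones %o% qx - qsx; Qhy <- ones %o% qy - qsy
  a11 <- rowSums(W * Phx * Phx)
  a12 <- rowSums(W * Phx * Phy)
  a22 <- rowSums(W * Phy * Phy)
  b11 <- rowSums(W * Phx * Qhx)
  b12 <- rowSums(W * Phx * Qhy)
  b21 <- rowSums(W * Phy * Qhx)
  b22 <- rowSums(W * Phy * Qhy)
  if (mode == "affine") {
    det <- a11 * a22 - a12 * a12
    bad <- det <= 1e-12 * (a11 + a22)^2
    bad[hitRow] <- FALSE                 # coincident rows are mapped directly
    if (any(bad))
      stop(paste("degenerate geometry: source control points are collinear,",
                 "the affine moment matrix is singular; use similarity mode"))
    M11 <- (a22 * b11 - a12 * b21) / det
    M21 <- (a11 * b21 - a12 * b11) / det
    M12 <- (a22 * b12 - a12 * b22) / det
    M22 <- (a11 * b22 - a12 * b12) / det
  } else {
    a <- b11 + b22; b <- b12 - b21
    if (mode == "similarity") {
      mu <- a11 + a22
      cc <- a / mu; ss <- b / mu
    } else {                             # rigid
      r <- sqrt(a * a + b * b)
      cc <- ifelse(r > 0, a / r, 1)
      ss <- ifelse(r > 0, b / r, 0)
    }
    M11 <- cc; M22 <- cc; M12 <- ss; M21 <- -ss
  }
  fx <- vhx * M11 + vhy * M21 + qsx
  fy <- vhx * M12 + vhy * M22 + qsy
  # queries coincident with a source point map to the matched target exactly
  if (any(hitRow)) {
    idx <- apply(hit[hitRow, , drop = FALSE], 1, which.max)
    fx[hitRow] <- qx[idx]; fy[hitRow] <- qy[idx]
  }
  out <- cbind(as.numeric(fx), as.numeric(fy))
  dimnames(out) <- NULL
  if (transform) {
    if (P != 1L) stop("transform extraction requires a single query point")
    list(f = out,
         M = matrix(c(M11[1], M12[1], M21[1], M22[1]), 2, 2, byrow = TRUE),
         T = c(qsx[1] - (psx[1] * M11[1] + psy[1] * M21[1]),
               qsy[1] - (psx[1] * M12[1] + psy[1] * M22[1])))
  } else out
}

# coincidence threshold: explicit config value, else 1e-9 x domain diagonal
epsFor <- function(cfg, domain = NULL, cps = NULL) {
  if (!is.na(cfg@epsilonDistance)) return(cfg@epsilonDistance)
  if (!is.null(domain)) return(1e-9 * sqrt(sum(domain^2)))
  ext <- apply(rbind(srcPoints(cps), dstPoints(cps)), 2,
               function(z) diff(range(z)))
  1e-9 * max(sqrt(sum(ext^2)), 1)
}

checkModeArity <- function(cps, mode) {
  n <- nPoints(cps)
  need <- if (mode == "affine") 3L else 2L
  if (n < need)
    stop(sprintf("%s mode needs at least %d control-point pairs, got %d",
                 mode, need, n))
}

#' MLS weights at a query point
#'
#' \eqn{w_i = 1 / |p_i - v|^{2\alpha}}. All weights are positive and finite
#' away from the source points; a query within \code{eps} of a source point
#' signals coincidence (the caller should return the matched target
#' directly).
#'
#' @param v length-2 query point
#' @param p n x 2 matrix of source points
#' @param alpha positive weight exponent (default 2)
#' @param eps coincidence threshold
#' @return numeric vector of n weights
#' @export
mlsWeights <- function(v, p, alpha = 2, eps = 1e-9) {
  d2 <- (p[, 1] - v[1])^2 + (p[, 2] - v[2])^2
  if (any(d2 < eps^2))
    stop(sprintf("query point coincides with source point %d",
                 which.min(d2)))
  d2^(-alpha)
}

#' Solve the local MLS transform at one point
#'
#' Returns the mapped location of \code{v} under the mode-constrained
#' weighted least-squares transform. Interpolation (\code{f(p_i) = q_i}),
#' identity (\code{q = p} implies \code{f(v) = v}) and smoothness in
#' \code{v} all hold by construction.
#'
#' @param v length-2 query point
#' @param cps a \code{\link{ControlPointSet}}
#' @param cfg an \code{\link{MLSConfig}}
#' @return length-2 mapped point
#' @seealso \code{\link{mlsTransform}} for the local M and T
#' @export
solvePoint <- function(v, cps, cfg = MLSConfig()) {
  checkModeArity(cps, cfg@mode)
  eps <- epsFor(cfg, cps = cps)
  drop(mlsSolve(matrix(v, 1, 2), srcPoints(cps), dstPoints(cps),
                cfg@mode, cfg@alpha, eps))
}

#' Local transform (M, T) at one point
#'
#' @inheritParams solvePoint
#' @return a \code{\link{PointTransform}} with \code{f(x) = xM + T}
#' @export
mlsTransform <- function(v, cps, cfg = MLSConfig()) {
  checkModeArity(cps, cfg@mode)
  eps <- epsFor(cfg, cps = cps)
  res <- mlsSolve(matrix(v, 1, 2), srcPoints(cps), dstPoints(cps),
                  cfg@mode, cfg@alpha, eps, transform = TRUE)
  new("PointTransform", M = res$M, T = res$T, mode = cfg@mode)
}

#' Build a dense deformation field
#'
#' Samples the per-pixel MLS map on a regular grid over the rectangular
#' domain (origin lower-left, pixel centers at half-integers times the grid
#' spacing) and records the Jacobian-sign verdict.
#'
#' @param cps a \code{\link{ControlPointSet}}
#' @param domain length-2 numeric, domain width and height in px
#' @param cfg an \code{\link{MLSConfig}}
#' @param stepFraction fraction of a full warp this field carries (metadata)
#' @return a \code{\link{DeformationField}}
#' @export
buildField <- function(cps, domain, cfg = MLSConfig(), stepFraction = 1) {
  if (any(domain <= 0)) stop("domain must be non-empty")
  checkModeArity(cps, cfg@mode)
  gs <- cfg@gridSpacing
  xs <- seq(gs / 2, domain[1] - gs / 2 + 1e-12, by = gs)
  ys <- seq(gs / 2, domain[2] - gs / 2 + 1e-12, by = gs)
  grid <- cbind(rep(xs, times = length(ys)), rep(ys, each = length(xs)))
  eps <- epsFor(cfg, domain = domain)
  f <- tryCatch(
    mlsSolve(grid, srcPoints(cps), dstPoints(cps), cfg@mode, cfg@alpha, eps),
    error = function(e) stop(sprintf(
      "field solve failed over %g x %g domain: %s",
      domain[1], domain[2], conditionMessage(e)), call. = FALSE))
  fld <- new("DeformationField",
             fx = matrix(f[, 1], length(xs), length(ys)),
             fy = matrix(f[, 2], length(xs), length(ys)),
             xs = xs, ys = ys, cps = cps, mode = cfg@mode,
             alpha = cfg@alpha, jacobianSignUniform = NA,
             stepFraction = stepFraction)
  fld@jacobianSignUniform <-
    if (length(xs) >= 3 && length(ys) >= 3)
      jacobianSignUniform(fld)$uniform else NA
  fld
}

#' Evaluate a deformation field at arbitrary points
#'
#' Bilinear interpolation of the sampled field; with \code{exact = TRUE}
#' the MLS system is re-solved at the query points instead (used where the
#' control-point interpolation contract must hold to machine precision).
#'
#' @param field a \code{\link{DeformationField}}
#' @param pts n x 2 matrix of query points
#' @param exact re-solve instead of interpolating
#' @return n x 2 matrix of mapped points
#' @export
evalField <- function(field, pts, exact = FALSE) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  if (exact) {
    eps <- 1e-9 * sqrt(sum(c(max(field@xs), max(field@ys))^2))
    return(mlsSolve(pts, field@cps@p, field@cps@q, field@mode,
                    field@alpha, eps))
  }
  gs <- field@xs[2] - field@xs[1]
  ix <- (pts[, 1] - field@xs[1]) / gs + 0.5
  iy <- (pts[, 2] - field@ys[1]) / gs + 0.5
  cbind(bilinearSample(field@fx, ix, iy, fill = NA),
        bilinearSample(field@fy, ix, iy, fill = NA))
}

#' Jacobian-determinant sign check
#'
#' Central finite differences of the mapped coordinates at interior grid
#' nodes (one-sided at the boundary) give a signed Jacobian determinant
#' grid. The field is fold-free iff all determinants share one sign: a sign
#' change means the map folds the image back on itself.
#'
#' @param field a \code{\link{DeformationField}}
#' @return list with \code{uniform} (logical) and \code{det} (matrix)
#' @export
jacobianSignUniform <- function(field) {
  nx <- length(field@xs); ny <- length(field@ys)
  if (nx < 3 || ny < 3)
    stop(sprintf("insufficient domain: %d x %d grid, need at least 3 x 3",
                 nx, ny))
  h <- field@xs[2] - field@xs[1]
  dX <- function(m) {                    # d/dx along rows
    out <- m
    out[2:(nx - 1), ] <- (m[3:nx, ] - m[1:(nx - 2), ]) / (2 * h)
    out[1, ] <- (m[2, ] - m[1, ]) / h
    out[nx, ] <- (m[nx, ] - m[nx - 1, ]) / h
    out
  }
  dY <- function(m) {
    out <- m
    out[, 2:(ny - 1)] <- (m[, 3:ny] - m[, 1:(ny - 2)]) / (2 * h)
    out[, 1] <- (m[, 2] - m[, 1]) / h
    out[, ny] <- (m[, ny] - m[, ny - 1]) / h
    out
  }
  det <- dX(field@fx) * dY(field@fy) - dY(field@fx) * dX(field@fy)
  list(uniform = all(det > 0) || all(det < 0), det = det)
}

#' Decompose a warp into fold-free partial deformations
#'
#' Large deformations can flip the sign of the Jacobian of the per-pixel
#' map. The warp is therefore broken into a series of smaller partial
#' deformations along the straight-line handle schedule
#' \eqn{p_i(t) = p_i + t (q_i - p_i)}: each step attempts the remaining
#' fraction, halving it on fold detection, and the moved handles become the
#' next step's sources until the cumulative t reaches 1 and every control
#' point constraint \eqn{f(p_i) = q_i} is satisfied.
#'
#' @param cps a \code{\link{ControlPointSet}}
#' @param domain length-2 numeric domain size in px
#' @param cfg an \code{\link{MLSConfig}}; \code{maxBisections} bounds the
#'   step search
#' @return a \code{\link{WarpSequence}}
#' @export
partialWarpSequence <- function(cps, domain, cfg = MLSConfig()) {
  checkModeArity(cps, cfg@mode)
  p0 <- srcPoints(cps); q1 <- dstPoints(cps)
  tDone <- 0; src <- p0
  steps <- list(); schedule <- numeric()
  while (tDone < 1 - 1e-12) {
    tTry <- 1 - tDone
    bis <- 0L
    repeat {
      tgt <- p0 + (tDone + tTry) * (q1 - p0)
      # intermediate handles that (nearly) coincide would make the next
      # step's sources degenerate: treat like a fold and bisect
      dmin <- min(stats::dist(tgt))
      ok <- dmin > epsFor(cfg, domain = domain)
      if (ok) {
        fld <- buildField(ControlPointSet(src, tgt), domain, cfg,
                          stepFraction = tTry)
        if (isTRUE(fld@jacobianSignUniform) || is.na(fld@jacobianSignUniform))
          break
      }
      bis <- bis + 1L
      if (bis > cfg@maxBisections)
        stop(sprintf(paste(
          "non-decomposable warp: no fold-free step found after %d",
          "bisections at t = %.4g (fold within the %g x %g domain)"),
          cfg@maxBisections, tDone, domain[1], domain[2]))
      tTry <- tTry / 2
    }
    steps[[length(steps) + 1L]] <- fld
    tDone <- tDone + tTry
    schedule <- c(schedule, tDone)
    src <- tgt
  }
  if (length(steps) == 0L) {             # q identical to p: single identity
    steps <- list(buildField(cps, domain, cfg, stepFraction = 1))
    schedule <- 1
  }
  new("WarpSequence", steps = steps, cps = cps, domain = as.numeric(domain),
      schedule = schedule)
}

#' Map points forward through a warp sequence
#'
#' Applies each partial deformation in order with exact (re-solved) MLS
#' evaluation, so the composition carries every source control point to its
#' target within tolerance.
#'
#' @param seq a \code{\link{WarpSequence}}
#' @param pts n x 2 matrix of points
#' @return n x 2 matrix of warped points
#' @export
warpPoints <- function(seq, pts) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  for (fld in seq@steps) pts <- evalField(fld, pts, exact = TRUE)
  pts
}

#' Warp an image through a fold-free sequence
#'
#' Backward resampling per step: for every output pixel the MLS system is
#' solved with the roles of p and q swapped to find the source location,
#' which is sampled with bilinear interpolation (out-of-domain pixels take
#' \code{fill}). The partially warped image of each stage is the input of
#' the next.
#'
#' @param image 2D numeric matrix, pixel \code{[i, j]} centered at
#'   (i - 0.5, j - 0.5)
#' @param seq a \code{\link{WarpSequence}}
#' @param fill value for pixels mapped outside the image
#' @return warped matrix of the same size
#' @export
warpImage <- function(image, seq, fill = 0) {
  if (length(seq@steps) == 0L) return(image)
  nx <- nrow(image); ny <- ncol(image)
  centers <- cbind(rep(seq_len(nx) - 0.5, times = ny),
                   rep(seq_len(ny) - 0.5, each = nx))
  eps <- 1e-9 * sqrt(sum(seq@domain^2))
  out <- image
  for (fld in seq@steps) {
    src <- mlsSolve(centers, fld@cps@q, fld@cps@p, fld@mode, fld@alpha, eps)
    out <- matrix(bilinearSample(out, src[, 1], src[, 2], fill = fill),
                  nx, ny)
  }
  out
}

#' Warp labeled contours through a sequence
#'
#' Forward-maps every polygon vertex through the composed sequence; labels
#' are preserved and closed polygons stay closed. Vertices outside the
#' domain are clamped to it with a warning.
#'
#' @param polygons named list of n x 2 vertex matrices, or an
#'   \code{\link{AtlasPlate}}
#' @param seq a \code{\link{WarpSequence}}
#' @return object of the same shape with warped vertices
#' @export
warpContours <- function(polygons, seq) {
  plate <- NULL
  if (is(polygons, "AtlasPlate")) { plate <- polygons; polygons <- plate@contours }
  clamped <- FALSE
  warped <- lapply(polygons, function(poly) {
    out <- pmin(pmax(poly, 0), rep(seq@domain, each = nrow(poly)))
    if (any(out != poly)) clamped <<- TRUE
    warpPoints(seq, out)
  })
  if (clamped) warning("contour vertices outside the domain were clamped")
  names(warped) <- names(polygons)
  if (!is.null(plate))
    return(AtlasPlate(plate@plateId, plate@apPosition, warped))
  warped
}
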