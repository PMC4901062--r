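## Internal numerical helpers: seeded evaluation, bilinear/trilinear
## sampling, even-odd polygon rasterization. Pixel centers sit at
## half-integers; matrix element [i, j] covers (i-1, i) x (j-1, j).

# Evaluate `expr` under a temporary RNG seed, restoring global RNG state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Bilinear sampling of matrix `img` at continuous coordinates (x, y);
# out-of-domain points take `fill`.
bilinearSample <- function(img, x, y, fill = 0) {
  nx <- nrow(img); ny <- ncol(img)
  fx <- x + 0.5; fy <- y + 0.5          # continuous index space
  i0 <- floor(fx); j0 <- floor(fy)
  tx <- fx - i0; ty <- fy - j0
  out <- rep(fill, length(x))
  # clamp the four neighbours into range; points whose *clamped* support
  # leaves the image get the fill value
  ok <- fx >= 0.5 & fx <= nx + 0.5 & fy >= 0.5 & fy <= ny + 0.5
  i0c <- pmin(pmax(i0, 1L), nx); i1c <- pmin(i0c + 1L, nx)
  j0c <- pmin(pmax(j0, 1L), ny); j1c <- pmin(j0c + 1L, ny)
  txc <- ifelse(i0 < 1, 0, ifelse(i0 >= nx, 1, tx))
  tyc <- ifelse(j0 < 1, 0, ifelse(j0 >= ny, 1, ty))
  # when i0 >= nx the support collapses to column nx, weight on i0c
  i0c2 <- ifelse(i0 >= nx, nx, i0c); i1c2 <- ifelse(i0 >= nx, nx, i1c)
  v00 <- img[cbind(i0c2, j0c)]; v10 <- img[cbind(i1c2, j0c)]
  v01 <- img[cbind(i0c2, j1c)]; v11 <- img[cbind(i1c2, j1c)]
  val <- (1 - txc) * (1 - tyc) * v00 + txc * (1 - tyc) * v10 +
         (1 - txc) * tyc * v01 + txc * tyc * v11
  out[ok] <- val[ok]
  out
}

# Trilinear sampling of 3D array `arr` at continuous voxel-index coordinates
# (center of voxel (i,j,k) is at index (i-0.5, j-0.5, k-0.5) + 0.5 = i,...).
# `pts` is n x 3 in *continuous index* units where voxel centers are at
# integer indices 1..n (i.e. already divided by voxel size and shifted).
trilinearSample <- function(arr, pts, fill = 0) {
  d <- dim(arr)
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
  out <- rep(fill, nrow(pts))
  ok <- x >= 1 & x <= d[1] & y >= 1 & y <= d[2] & z >= 1 & z <= d[3]
  if (!any(ok)) return(out)
  x <- x[ok]; y <- y[ok]; z <- z[ok]
  i0 <- pmin(floor(x), d[1] - 1L); j0 <- pmin(floor(y), d[2] - 1L)
  k0 <- pmin(floor(z), d[3] - 1L)
  i0 <- pmax(i0, 1L); j0 <- pmax(j0, 1L); k0 <- pmax(k0, 1L)
  tx <- x - i0; ty <- y - j0; tz <- z - k0
  g <- function(di, dj, dk) arr[cbind(i0 + di, j0 + dj, k0 + dk)]
  val <-
    (1 - tx) * (1 - ty) * (1 - tz) * g(0L, 0L, 0L) +
    tx * (1 - ty) * (1 - tz) * g(1L, 0L, 0L) +
    (1 - tx) * ty * (1 - tz) * g(0L, 1L, 0L) +
    (1 - tx) * (1 - ty) * tz * g(0L, 0L, 1L) +
    tx * ty * (1 - tz) * g(1L, 1L, 0L) +
    tx * (1 - ty) * tz * g(1L, 0L, 1L) +
    (1 - tx) * ty * tz * g(0L, 1L, 1L) +
    tx * ty * tz * g(1L, 1L, 1L)
  out[ok] <- val
  out
}

#' Even-odd polygon rasterization
#'
#' Crossing-number (even-odd) scan of one closed polygon onto an
#' \code{nx x ny} pixel grid with centers at
#' \code{((i - 0.5), (j - 0.5)) * spacing + origin}. Vertices on edges
#' resolve by the half-open crossing rule; the result is invariant under
#' vertex-order reversal.
#'
#' @param poly n x 2 vertex matrix (closed implicitly)
#' @param nx,ny grid size in pixels
#' @param spacing pixel size
#' @param origin lower-left corner of the grid
#' @return logical \code{nx x ny} matrix of interior pixels
#' @export
rasterizePolygon <- function(poly, nx, ny, spacing = 1, origin = c(0, 0)) {
  xs <- (seq_len(nx) - 0.5) * spacing + origin[1]
  ys <- (seq_len(ny) - 0.5) * spacing + origin[2]
  px <- poly[, 1]; py <- poly[, 2]
  n <- length(px)
  if (px[1] == px[n] && py[1] == py[n]) { px <- px[-n]; py <- py[-n]; n <- n - 1 }
  inside <- matrix(FALSE, nx, ny)
  X <- matrix(xs, nx, ny)
  for (a in seq_len(n)) {
    b <- if (a == n) 1L else a + 1L
    y1 <- py[a]; y2 <- py[b]
    if (y1 == y2) next
    x1 <- px[a]; x2 <- px[b]
    for (j in seq_len(ny)) {
      yc <- ys[j]
      if ((y1 > yc) != (y2 > yc)) {
        xint <- x1 + (yc - y1) / (y2 - y1) * (x2 - x1)
        inside[, j] <- xor(inside[, j], xs < xint)
      }
    }
  }
  inside
}

#' Shoelace area of a closed polygon
#'
#' @param poly n x 2 vertex matrix (closed implicitly)
#' @return absolute enclosed area
#' @export
polygonArea <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- length(x)
  if (x[1] == x[n] && y[1] == y[n]) { x <- x[-n]; y <- y[-n]; n <- n - 1 }
  i2 <- c(2:n, 1)
  abs(sum(x * y[i2] - x[i2] * y)) / 2
}

# 3D cross product
cross3 <- function(u, v)
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])

unitVec <- function(v) v / sqrt(sum(v^2))
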