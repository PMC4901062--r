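## Atlas-to-subject pipeline: AC-PC reslicing, Talairach-style proportional
## slice matching, global rigid + local affine plate registration, MLS
## refinement, and lofting of warped contours into 3D label volumes.

#' Reslice a volume into serial coronal sections in AC-PC space
#'
#' Builds an orthonormal frame from the AC-PC line (AP axis, positive
#' posterior) and the midsagittal point (dorsal axis), then resamples
#' coronal sections orthogonal to the AC-PC line by trilinear
#' interpolation. AP coordinate 0 lies at the AC; slice pixel (i, j) maps
#' to (left-right, dorsal-ventral) offsets centered on the AC-PC line.
#'
#' @param volume an \code{\link{MRVolume}} (magnitude, SWI, ...)
#' @param frame an \code{\link{AcpcFrame}} in mm volume coordinates
#' @param outSpacing in-plane and between-slice spacing in mm
#' @param apRange length-2 numeric, AP extent in mm from AC (default spans
#'   0 to the AC-PC length)
#' @param planeSize length-2 numeric, in-plane width and height in mm
#'   (default: the volume's largest extent)
#' @param fill value for samples outside the volume
#' @return a \code{\link{SliceSeries}}
#' @export
acpcReslice <- function(volume, frame, outSpacing,
                        apRange = NULL, planeSize = NULL, fill = 0) {
  stopifnot(is(volume, "MRVolume"), is(frame, "AcpcFrame"))
  validObject(frame)
  eAP <- unitVec(frame@pc - frame@ac)
  v <- frame@midsagittal - frame@ac
  vPerp <- v - sum(v * eAP) * eAP
  if (sqrt(sum(vPerp^2)) < 1e-9) stop("frame points are collinear")
  eDV <- unitVec(vPerp)                  # dorsal within the midsagittal plane
  eLR <- cross3(eAP, eDV)                # completes a right-handed frame
  if (is.null(apRange))
    apRange <- c(0, sqrt(sum((frame@pc - frame@ac)^2)))
  if (is.null(planeSize)) {
    ext <- dim(volume@data) * volume@voxelSize
    planeSize <- c(max(ext), max(ext))
  }
  aps <- seq(apRange[1], apRange[2], by = outSpacing)
  us <- seq(-planeSize[1] / 2 + outSpacing / 2, planeSize[1] / 2,
            by = outSpacing)
  ws <- seq(-planeSize[2] / 2 + outSpacing / 2, planeSize[2] / 2,
            by = outSpacing)
  nu <- length(us); nw <- length(ws)
  slices <- array(fill, c(nu, nw, length(aps)))
  uu <- rep(us, times = nw); ww <- rep(ws, each = nu)
  for (k in seq_along(aps)) {
    world <- cbind(frame@ac[1] + aps[k] * eAP[1] + uu * eLR[1] + ww * eDV[1],
                   frame@ac[2] + aps[k] * eAP[2] + uu * eLR[2] + ww * eDV[2],
                   frame@ac[3] + aps[k] * eAP[3] + uu * eLR[3] + ww * eDV[3])
    idx <- sweep(world, 2, volume@voxelSize, "/") + 0.5
    slices[, , k] <- matrix(trilinearSample(volume@data, idx, fill = fill),
                            nu, nw)
  }
  SliceSeries(slices, apPositions = aps,
              pixelSpacing = c(outSpacing, outSpacing))
}

#' Proportional-grid matching of atlas plates to subject slices
#'
#' Talairach-style proportional scaling: plate AP positions are multiplied
#' by the ratio of the subject's AC-PC length to the atlas' AC-PC
#' reference length, then each plate is assigned the nearest slice (ties
#' break toward the anterior slice). The mean distance between consecutive
#' matched plate positions is the derived spacing, and 10 further slice
#' positions are generated posterior to the PC at that spacing.
#'
#' @param plates list of \code{\link{AtlasPlate}}, ordered by AP position
#' @param series a \code{\link{SliceSeries}} spanning AC to PC
#' @param atlasAcPc atlas AC-PC reference length in mm
#' @param subjectAcPc subject AC-PC length in mm
#' @param nPosterior number of interpolated posterior slices (default 10)
#' @return list with \code{pairs} (data.frame plate_id, ap_atlas,
#'   ap_scaled, slice_index), \code{scale}, \code{spacingUsed},
#'   \code{posteriorPositions} and \code{interpolatedPosteriorCount}
#' @export
proportionalMatch <- function(plates, series, atlasAcPc, subjectAcPc,
                              nPosterior = 10L) {
  stopifnot(length(plates) >= 1, is(series, "SliceSeries"))
  apsAtlas <- vapply(plates, apPosition, numeric(1))
  if (is.unsorted(apsAtlas, strictly = TRUE))
    stop("plates must be strictly ordered by AP position")
  scale <- subjectAcPc / atlasAcPc
  scaled <- apsAtlas * scale
  apSlices <- series@apPositions
  lo <- min(apSlices) - 1e-9; hi <- max(apSlices) + 1e-9
  miss <- scaled < lo | scaled > hi
  if (any(miss))
    stop(sprintf("slice series does not cover scaled plate position(s): %s",
                 paste(vapply(plates[miss], function(p) p@plateId,
                              character(1)), collapse = ", ")))
  sliceIdx <- vapply(scaled, function(a) {
    d <- abs(apSlices - a)
    cand <- which(d < min(d) + 1e-9)
    cand[1L]                             # tie -> anterior (smaller AP)
  }, integer(1))
  spacingUsed <- if (length(scaled) > 1) mean(diff(scaled)) else
    mean(diff(apSlices))
  posterior <- subjectAcPc + seq_len(nPosterior) * spacingUsed
  list(pairs = data.frame(
         plate_id = vapply(plates, function(p) p@plateId, character(1)),
         ap_atlas = apsAtlas, ap_scaled = scaled, slice_index = sliceIdx),
       scale = scale, spacingUsed = spacingUsed,
       posteriorPositions = posterior,
       interpolatedPosteriorCount = as.integer(nPosterior))
}

#' Global rigid + local affine landmark registration
#'
#' Stage 1 fits the least-squares rigid transform (rotation + translation,
#' no scaling) carrying the plate landmarks onto the slice landmarks; stage
#' 2 fits a full affine map on the rigid stage's output by least squares.
#' The composition aligns cortical outlines and the inter-hemispheric
#' fissure before nonlinear refinement.
#'
#' @param p n x 2 plate landmarks (>= 2 for rigid, >= 3 non-collinear for
#'   the affine stage)
#' @param q n x 2 matched slice landmarks
#' @param affine fit the local affine stage (default TRUE)
#' @return a \code{\link{GlobalTransform}}
#' @export
globalRegister <- function(p, q, affine = TRUE) {
  p <- matrix(as.numeric(p), ncol = 2); q <- matrix(as.numeric(q), ncol = 2)
  n <- nrow(p)
  if (n < 2 || nrow(q) != n) stop("need >= 2 matched landmark pairs")
  pm <- colMeans(p); qm <- colMeans(q)
  ph <- sweep(p, 2, pm); qh <- sweep(q, 2, qm)
  a <- sum(ph[, 1] * qh[, 1] + ph[, 2] * qh[, 2])
  b <- sum(ph[, 1] * qh[, 2] - ph[, 2] * qh[, 1])
  theta <- atan2(b, a)
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)),
              2, 2, byrow = TRUE)       # row-vector rotation
  shift <- qm - drop(pm %*% R)
  pr <- p %*% R + rep(1, n) %o% shift   # rigid-stage output
  A <- diag(2); t2 <- c(0, 0)
  if (affine) {
    if (n < 3) stop("the affine stage needs >= 3 landmark pairs")
    X <- cbind(pr, 1)
    xtx <- crossprod(X)
    if (abs(det(xtx)) < 1e-10 * max(abs(xtx))^3)
      stop(paste("landmarks are collinear: the affine stage is degenerate;",
                 "re-run with affine = FALSE for the rigid-only fit"))
    beta <- solve(xtx, crossprod(X, q))
    A <- beta[1:2, ]; t2 <- beta[3, ]
  }
  fitted <- pr %*% A + rep(1, n) %o% t2
  rms <- sqrt(mean(rowSums((fitted - q)^2)))
  new("GlobalTransform", angle = theta, rigidShift = shift,
      affineM = A, affineShift = t2, residualRMS = rms)
}

#' Apply a global transform to points or a plate
#'
#' @param gt a \code{\link{GlobalTransform}}
#' @param x n x 2 point matrix or an \code{\link{AtlasPlate}}
#' @return object of the same shape, transformed
#' @export
applyGlobalTransform <- function(gt, x) {
  f <- function(m) {
    R <- matrix(c(cos(gt@angle), sin(gt@angle),
                  -sin(gt@angle), cos(gt@angle)), 2, 2, byrow = TRUE)
    pr <- m %*% R + rep(1, nrow(m)) %o% gt@rigidShift
    pr %*% gt@affineM + rep(1, nrow(m)) %o% gt@affineShift
  }
  if (is(x, "AtlasPlate"))
    return(AtlasPlate(x@plateId, x@apPosition, lapply(x@contours, f)))
  f(matrix(as.numeric(x), ncol = 2))
}

#' Nonlinear MLS refinement of a globally aligned plate
#'
#' Delegates to the fold-free partial-warp machinery: fits a
#' \code{\link{WarpSequence}} from the control points and forward-maps the
#' plate contours through it. With no control points the plate is returned
#' unchanged.
#'
#' @param plate a globally aligned \code{\link{AtlasPlate}} in slice
#'   coordinates
#' @param cps a \code{\link{ControlPointSet}} in slice coordinates, or NULL
#' @param domain length-2 slice domain size in px
#' @param cfg an \code{\link{MLSConfig}}
#' @return list with \code{plate} (warped) and \code{sequence}
#' @export
refinePlate <- function(plate, cps, domain, cfg = MLSConfig()) {
  stopifnot(is(plate, "AtlasPlate"))
  if (is.null(cps) || nPoints(cps) == 0)
    return(list(plate = plate, sequence = NULL))
  seq <- partialWarpSequence(cps, domain, cfg)
  list(plate = warpContours(plate, seq), sequence = seq)
}

#' Loft warped plates into a 3D label volume
#'
#' Rasterizes each plate's polygon interiors onto the slice grid (even-odd
#' rule, pixel centers at half-integers) and stacks the slices at the slice
#' spacing. Overlapping labels on one slice resolve by the declared label
#' order (earlier wins) with a warning. Per-label volumes in mm^3 are
#' attached to the label table.
#'
#' @param plates list of \code{\link{AtlasPlate}} (one per slice, in order)
#' @param planeSize length-2 in-plane domain size in mm
#' @param pixelSpacing in-plane pixel size in mm
#' @param sliceSpacing distance between consecutive plates in mm
#' @param labelOrder label precedence; default: order of first appearance
#' @return a \code{\link{LabelVolume}} whose label table carries
#'   \code{voxels} and \code{volume_mm3} columns
#' @export
loftLabels <- function(plates, planeSize, pixelSpacing = 1, sliceSpacing,
                       labelOrder = NULL) {
  nx <- round(planeSize[1] / pixelSpacing)
  ny <- round(planeSize[2] / pixelSpacing)
  if (length(plates) == 0)
    return(LabelVolume(array(0L, c(nx, ny, 0)),
                       c(pixelSpacing, pixelSpacing, sliceSpacing)))
  allLabels <- unique(unlist(lapply(plates, function(p) names(p@contours))))
  if (is.null(labelOrder)) labelOrder <- allLabels
  if (!all(allLabels %in% labelOrder))
    stop("labelOrder must contain every label present in the plates")
  codes <- seq_along(labelOrder)
  vol <- array(0L, c(nx, ny, length(plates)))
  for (k in seq_along(plates)) {
    img <- matrix(0L, nx, ny)
    for (li in seq_along(labelOrder)) {
      nm <- labelOrder[li]
      poly <- plates[[k]]@contours[[nm]]
      if (is.null(poly)) next
      m <- rasterizePolygon(poly, nx, ny, spacing = pixelSpacing)
      if (any(m & img != 0L))
        warning(sprintf(
          "plate %s: label '%s' overlaps an earlier label; keeping the earlier",
          plates[[k]]@plateId, nm))
      img[m & img == 0L] <- codes[li]
    }
    vol[, , k] <- img
  }
  counts <- vapply(codes, function(cd) sum(vol == cd), numeric(1))
  vmm3 <- counts * pixelSpacing^2 * sliceSpacing
  LabelVolume(vol, c(pixelSpacing, pixelSpacing, sliceSpacing),
              labelTable = data.frame(code = codes, name = labelOrder,
                                      voxels = counts, volume_mm3 = vmm3))
}
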