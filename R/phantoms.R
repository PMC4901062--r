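## Seeded generators for every input the pipeline consumes: magnitude/phase
## volume phantoms with regionally varying susceptibility-induced phase,
## plate/subject image pairs related by a known smooth deformation, and
## multi-subject cohorts with a known age trend. All generators are pure
## functions of (spec, seed) and return their ground truth alongside the
## data.

#' Phantom volume specification
#'
#' Regions are ellipsoids with a label, a magnitude level and a phase
#' offset in \eqn{[-\pi, 0]} (iron-like tissue shifts phase negative).
#' Noise: additive Gaussian on magnitude (truncated at 0) and wrapped
#' Gaussian on phase (wrapped into \eqn{[-\pi, \pi]}), so the type
#' invariants hold by construction.
#'
#' @param dim length-3 volume dimensions in voxels
#' @param voxelSize length-3 mm per axis
#' @param regions list of lists with fields \code{label}, \code{center}
#'   (voxel units), \code{semiaxes} (voxel units), \code{magnitude},
#'   \code{phase}
#' @param background background magnitude level
#' @param magnitudeNoiseSD additive Gaussian SD on magnitude
#' @param phaseNoiseSD wrapped Gaussian SD on phase (radians)
#' @return a validated spec list
#' @export
phantomSpec <- function(dim = c(48, 48, 24), voxelSize = c(0.4, 0.4, 0.4),
                        regions = defaultPhantomRegions(),
                        background = 100,
                        magnitudeNoiseSD = 0, phaseNoiseSD = 0) {
  stopifnot(length(dim) == 3, all(dim >= 4),
            magnitudeNoiseSD >= 0, phaseNoiseSD >= 0, background >= 0)
  for (r in regions) {
    stopifnot(all(c("label", "center", "semiaxes", "magnitude", "phase")
                  %in% names(r)))
    if (r$phase < -pi || r$phase > 0)
      stop(sprintf("region '%s': phase offset must lie in [-pi, 0]", r$label))
    if (any(r$center - r$semiaxes < 0) || any(r$center + r$semiaxes > dim))
      stop(sprintf("region '%s' extends outside the volume", r$label))
  }
  list(dim = as.integer(dim), voxelSize = as.numeric(voxelSize),
       regions = regions, background = background,
       magnitudeNoiseSD = magnitudeNoiseSD, phaseNoiseSD = phaseNoiseSD)
}

#' @describeIn phantomSpec default regions: an iso-intense ventral-like
#'   ellipsoid (zero phase) and two hypointense posterior
#'   pulvinar/MGN-like ellipsoids with negative phase offsets
#' @export
defaultPhantomRegions <- function() {
  list(
    list(label = "ventral",  center = c(14, 24, 12), semiaxes = c(7, 8, 6),
         magnitude = 100, phase = 0),
    list(label = "pulvinar", center = c(32, 28, 12), semiaxes = c(6, 7, 6),
         magnitude = 100, phase = -pi / 2),
    list(label = "MGN",      center = c(34, 12, 12), semiaxes = c(4, 4, 4),
         magnitude = 100, phase = -pi / 3))
}

#' Generate a magnitude/phase phantom with ground-truth labels
#'
#' Deterministic for a fixed seed. Overlapping regions resolve by list
#' order (earlier wins) with a warning.
#'
#' @param spec a \code{\link{phantomSpec}}
#' @param seed RNG seed
#' @return list with \code{magnitude}, \code{phase}, \code{labels}
#'   (\code{\link{LabelVolume}}) and \code{truth} (the spec plus per-region
#'   expected SWI attenuation at m = 4)
#' @examples
#' ph <- makePhantom(phantomSpec(), seed = 1)
#' swi <- combineSWI(ph$magnitude, ph$phase)
#' @export
makePhantom <- function(spec, seed = 1) {
  d <- spec$dim
  mag <- array(spec$background, d)
  phs <- array(0, d)
  lab <- array(0L, d)
  ii <- rep(seq_len(d[1]) - 0.5, times = d[2] * d[3])
  jj <- rep(rep(seq_len(d[2]) - 0.5, each = d[1]), times = d[3])
  kk <- rep(seq_len(d[3]) - 0.5, each = d[1] * d[2])
  for (ri in seq_along(spec$regions)) {
    r <- spec$regions[[ri]]
    inside <- ((ii - r$center[1]) / r$semiaxes[1])^2 +
              ((jj - r$center[2]) / r$semiaxes[2])^2 +
              ((kk - r$center[3]) / r$semiaxes[3])^2 <= 1
    clash <- inside & (lab != 0L)
    if (any(clash))
      warning(sprintf("region '%s' overlaps an earlier region; keeping earlier",
                      r$label))
    inside <- inside & lab == 0L
    mag[inside] <- r$magnitude
    phs[inside] <- r$phase
    lab[inside] <- ri
  }
  withSeed(seed, {
    if (spec$magnitudeNoiseSD > 0)
      mag <- pmax(mag + stats::rnorm(length(mag), 0, spec$magnitudeNoiseSD), 0)
    if (spec$phaseNoiseSD > 0) {
      phs <- phs + stats::rnorm(length(phs), 0, spec$phaseNoiseSD)
      phs <- ((phs + pi) %% (2 * pi)) - pi
    }
  })
  labelTable <- data.frame(
    code = seq_along(spec$regions),
    name = vapply(spec$regions, function(r) r$label, character(1)))
  truth <- list(spec = spec,
                swiAttenuation = vapply(spec$regions, function(r) {
                  m <- if (r$phase >= 0) 1 else 1 + r$phase / pi
                  m^4
                }, numeric(1)))
  list(magnitude = MagnitudeVolume(mag, spec$voxelSize),
       phase = PhaseVolume(array(phs, d), spec$voxelSize),
       labels = LabelVolume(lab, spec$voxelSize, labelTable),
       truth = truth)
}

## ---------------------------------------------------- deformation phantoms

# Closed-form invertible smooth deformations of the plane. "sinusoid" is
# the composition of a horizontal and a vertical sinusoidal shear, each
# unit-Jacobian and exactly invertible; "affine" is x %*% M + T.
deformationMaps <- function(deformation) {
  type <- deformation$type
  if (type == "sinusoid") {
    ax <- deformation$amplitude[1]; ay <- deformation$amplitude[2]
    lx <- deformation$period[1]; ly <- deformation$period[2]
    fwd <- function(pts) {
      x1 <- pts[, 1] + ax * sin(2 * pi * pts[, 2] / ly)
      y1 <- pts[, 2] + ay * sin(2 * pi * x1 / lx)
      matrix(c(x1, y1), ncol = 2)
    }
    inv <- function(pts) {
      y0 <- pts[, 2] - ay * sin(2 * pi * pts[, 1] / lx)
      x0 <- pts[, 1] - ax * sin(2 * pi * y0 / ly)
      matrix(c(x0, y0), ncol = 2)
    }
    list(forward = fwd, inverse = inv)
  } else if (type == "affine") {
    M <- deformation$M; Tv <- deformation$T
    dt <- M[1, 1] * M[2, 2] - M[1, 2] * M[2, 1]
    if (dt <= 0)
      stop(sprintf(
        "requested deformation folds: affine Jacobian determinant %.4g <= 0",
        dt))
    Minv <- matrix(c(M[2, 2], -M[1, 2], -M[2, 1], M[1, 1]), 2, 2,
                   byrow = TRUE) / dt
    list(forward = function(pts) pts %*% M + rep(1, nrow(pts)) %o% Tv,
         inverse = function(pts)
           (pts - rep(1, nrow(pts)) %o% Tv) %*% Minv)
  } else stop("deformation$type must be 'sinusoid' or 'affine'")
}

#' Render plate contours to an intensity image
#'
#' Rasterizes each labeled polygon (even-odd rule) onto a background level,
#' assigning one intensity level per label; a stand-in for the MR slice
#' appearance the warp operates on.
#'
#' @param plate an \code{\link{AtlasPlate}}
#' @param width,height image size in px
#' @param background background intensity
#' @param levels named intensity per label (default 40, 80, ... in contour
#'   order)
#' @return numeric matrix [width x height]
#' @export
renderPlate <- function(plate, width, height, background = 10,
                        levels = NULL) {
  img <- matrix(background, width, height)
  nms <- names(plate@contours)
  if (is.null(levels))
    levels <- stats::setNames(40 * seq_along(nms), nms)
  for (nm in nms) {
    m <- rasterizePolygon(plate@contours[[nm]], width, height)
    img[m] <- levels[[nm]]
  }
  img
}

#' Generate a plate/subject image pair under a known deformation
#'
#' Renders the plate, deforms it with a closed-form invertible smooth
#' field, and samples control points on the structure boundaries (as
#' manual landmarks are placed on cortical and thalamic borders), giving
#' p on the source, q = f(p) on the target. The target image is produced
#' by exact backward sampling through the field's inverse, so image,
#' control points and ground-truth field are mutually consistent.
#'
#' @param plate an \code{\link{AtlasPlate}} in px coordinates
#' @param deformation list: either \code{list(type = "sinusoid", amplitude
#'   = c(ax, ay), period = c(lx, ly))} or \code{list(type = "affine", M =
#'   2x2, T = c(tx, ty))}; an orientation-reversing affine is rejected
#'   with its Jacobian determinant
#' @param imageSize length-2 image size in px
#' @param nControl approximate number of control points to sample
#' @param jitterSD Gaussian placement jitter on q in px (default 0)
#' @param seed RNG seed (used only when jitterSD > 0)
#' @return list with \code{source}, \code{target} (matrices),
#'   \code{forward}, \code{inverse} (vectorized point maps), \code{cps}
#'   (\code{\link{ControlPointSet}}) and \code{plate}
#' @export
makeDeformedPair <- function(plate, deformation, imageSize = c(64, 64),
                             nControl = 40, jitterSD = 0, seed = 1) {
  maps <- deformationMaps(deformation)
  src <- renderPlate(plate, imageSize[1], imageSize[2])
  nx <- imageSize[1]; ny <- imageSize[2]
  centers <- cbind(rep(seq_len(nx) - 0.5, times = ny),
                   rep(seq_len(ny) - 0.5, each = nx))
  back <- maps$inverse(centers)
  tgt <- matrix(bilinearSample(src, back[, 1], back[, 2], fill = 0), nx, ny)
  verts <- do.call(rbind, unname(plate@contours))
  stride <- max(1L, floor(nrow(verts) / nControl))
  p <- verts[seq(1, nrow(verts), by = stride), , drop = FALSE]
  q <- maps$forward(p)
  if (jitterSD > 0)
    q <- q + withSeed(seed,
                      matrix(stats::rnorm(length(q), 0, jitterSD), ncol = 2))
  list(source = src, target = tgt, forward = maps$forward,
       inverse = maps$inverse, cps = ControlPointSet(p, q), plate = plate)
}

## ------------------------------------------------------- cohort generator

#' Cohort specification
#'
#' Per-nucleus linear age model: subject mean intensity = intercept +
#' slope * age + Gaussian noise. Negative slopes emulate iron accumulation
#' (deeper hypointensity) with age in posterior nuclei.
#'
#' @param ages subject ages in years (length >= 3)
#' @param nuclei data.frame with columns \code{nucleus}, \code{intercept},
#'   \code{slope}
#' @param noiseSD between-subject noise SD on the nucleus means
#' @param withinSD within-nucleus SD reported per subject (constant)
#' @return a validated spec list
#' @export
cohortSpec <- function(ages = c(22, 22, 14, 13, 10, 9, 4),
                       nuclei = data.frame(
                         nucleus = c("anterior", "posterior"),
                         intercept = c(1.3, 1.5),
                         slope = c(0, -0.04)),
                       noiseSD = 0.1, withinSD = 0.2) {
  stopifnot(length(ages) >= 3, all(ages > 0), noiseSD >= 0,
            all(c("nucleus", "intercept", "slope") %in% names(nuclei)))
  list(ages = as.numeric(ages), nuclei = nuclei,
       noiseSD = noiseSD, withinSD = withinSD)
}

#' Generate a synthetic cohort with a known age trend
#'
#' @param spec a \code{\link{cohortSpec}}
#' @param seed RNG seed
#' @return list with \code{cohort} (a \code{\link{CohortTable}}) and
#'   \code{truth} (the generating parameters)
#' @examples
#' co <- makeCohort(cohortSpec(noiseSD = 0), seed = 1)
#' ageCorrelation(co$cohort, "posterior")$r   # exactly -1
#' @export
makeCohort <- function(spec, seed = 1) {
  n <- length(spec$ages)
  subjects <- data.frame(subject = seq_len(n), age = spec$ages)
  intensity <- withSeed(seed, {
    do.call(rbind, lapply(seq_len(nrow(spec$nuclei)), function(i) {
      mu <- spec$nuclei$intercept[i] + spec$nuclei$slope[i] * spec$ages
      data.frame(subject = seq_len(n),
                 nucleus = spec$nuclei$nucleus[i],
                 mean = mu + stats::rnorm(n, 0, spec$noiseSD),
                 sd = spec$withinSD)
    }))
  })
  list(cohort = CohortTable(subjects, intensity),
       truth = list(spec = spec))
}
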