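## S4 containers for the SWI reconstruction / atlas warping pipeline.
## Coordinate conventions (enforced throughout):
##   * 2D plate/slice coordinates are continuous, origin at the lower-left
##     corner, x rightward, y upward, pixel centers at half-integers.
##   * 3D volume coordinates: voxel (i,j,k) has its center at
##     ((i,j,k) - 0.5) * voxelSize mm.

setClass("MRVolume",
  representation("VIRTUAL", data = "array", voxelSize = "numeric"),
  validity = function(object) {
    if (length(dim(object@data)) != 3L)
      return("data must be a 3D array")
    if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
      return("voxelSize must be three positive numbers (mm)")
    TRUE
  })

#' Magnitude volume
#'
#' A 3D gradient-echo magnitude image. Values are non-negative arbitrary
#' intensity units.
#'
#' @param data 3D numeric array, all values >= 0 (NaN allowed)
#' @param voxelSize length-3 numeric, mm per axis
#' @return a \code{MagnitudeVolume}
#' @export MagnitudeVolume
#' @exportClass MagnitudeVolume
#' @examples
#' mag <- MagnitudeVolume(array(100, c(4, 4, 4)), c(0.4, 0.4, 0.4))
setClass("MagnitudeVolume", contains = "MRVolume",
  validity = function(object) {
    v <- object@data
    if (any(v < 0, na.rm = TRUE)) return("magnitude values must be >= 0")
    TRUE
  })
MagnitudeVolume <- function(data, voxelSize = c(1, 1, 1))
  new("MagnitudeVolume", data = data, voxelSize = as.numeric(voxelSize))

#' Phase volume
#'
#' A 3D reconstructed phase image in radians; values must lie in
#' \eqn{[-\pi, \pi]}. Susceptibility-induced field shifts appear as negative
#' phase in iron-rich tissue.
#'
#' @param data 3D numeric array of phase values (radians)
#' @param voxelSize length-3 numeric, mm per axis
#' @return a \code{PhaseVolume}
#' @export PhaseVolume
#' @exportClass PhaseVolume
setClass("PhaseVolume", contains = "MRVolume",
  validity = function(object) {
    bad <- which(object@data < -pi - 1e-12 | object@data > pi + 1e-12)
    if (length(bad) > 0) {
      ijk <- arrayInd(bad[1L], dim(object@data))
      return(sprintf(
        "phase value %.6g at voxel (%d,%d,%d) outside [-pi, pi]",
        object@data[bad[1L]], ijk[1], ijk[2], ijk[3]))
    }
    TRUE
  })
PhaseVolume <- function(data, voxelSize = c(1, 1, 1))
  new("PhaseVolume", data = data, voxelSize = as.numeric(voxelSize))

#' Phase mask
#'
#' Per-voxel multiplier in [0, 1] derived from the phase image: 1 where the
#' phase is non-negative, a linear ramp from 1 to 0 over \eqn{[0, -\pi]}.
#' \code{exponentApplied} records the power the mask has been raised to
#' (1 for the linear, pre-exponent mask).
#'
#' @param data 3D numeric array in [0, 1]
#' @param voxelSize length-3 numeric, mm per axis
#' @param exponentApplied integer power already applied
#' @return a \code{PhaseMask}
#' @export PhaseMask
#' @exportClass PhaseMask
setClass("PhaseMask", contains = "MRVolume",
  representation(exponentApplied = "integer"),
  validity = function(object) {
    v <- object@data
    if (any(v < -1e-12 | v > 1 + 1e-12, na.rm = TRUE))
      return("mask values must lie in [0, 1]")
    if (object@exponentApplied < 1L)
      return("exponentApplied must be >= 1")
    TRUE
  })
PhaseMask <- function(data, voxelSize = c(1, 1, 1), exponentApplied = 1L)
  new("PhaseMask", data = data, voxelSize = as.numeric(voxelSize),
      exponentApplied = as.integer(exponentApplied))

#' Susceptibility-weighted volume
#'
#' Product of a magnitude volume and a phase mask raised to a power; never
#' exceeds the magnitude at any voxel. \code{provenance} records the mask
#' exponent and any NaN bookkeeping.
#'
#' @param data 3D numeric array
#' @param voxelSize length-3 numeric, mm per axis
#' @param provenance list of reconstruction metadata
#' @return an \code{SWIVolume}
#' @export SWIVolume
#' @exportClass SWIVolume
setClass("SWIVolume", contains = "MRVolume",
  representation(provenance = "list"),
  validity = function(object) {
    if (any(object@data < -1e-9, na.rm = TRUE))
      return("SWI values must be >= 0")
    TRUE
  })
SWIVolume <- function(data, voxelSize = c(1, 1, 1), provenance = list())
  new("SWIVolume", data = data, voxelSize = as.numeric(voxelSize),
      provenance = provenance)

#' Label volume
#'
#' 3D integer grid of nucleus labels (background 0) plus a label table
#' mapping integer codes to nucleus names.
#'
#' @param data 3D integer array of label codes
#' @param voxelSize length-3 numeric, mm per axis
#' @param labelTable data.frame with columns \code{code}, \code{name}
#' @return a \code{LabelVolume}
#' @export LabelVolume
#' @exportClass LabelVolume
setClass("LabelVolume", contains = "MRVolume",
  representation(labelTable = "data.frame"),
  validity = function(object) {
    codes <- unique(as.vector(object@data))
    codes <- codes[codes != 0 & !is.na(codes)]
    if (!all(codes %in% object@labelTable$code))
      return("labels present in the grid but missing from the label table")
    TRUE
  })
LabelVolume <- function(data, voxelSize = c(1, 1, 1),
                        labelTable = data.frame(code = integer(),
                                                name = character())) {
  storage.mode(data) <- "integer"
  new("LabelVolume", data = data, voxelSize = as.numeric(voxelSize),
      labelTable = labelTable)
}

#' @rdname swiatlas-generics
#' @export
setMethod("volData", "MRVolume", function(object) object@data)
#' @rdname swiatlas-generics
#' @export
setMethod("voxelSize", "MRVolume", function(object) object@voxelSize)
#' @rdname swiatlas-generics
#' @export
setMethod("dim", "MRVolume", function(x) dim(x@data))

setMethod("show", "MRVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("%s: %d x %d x %d voxels, %.3g x %.3g x %.3g mm\n",
              class(object), d[1], d[2], d[3],
              object@voxelSize[1], object@voxelSize[2], object@voxelSize[3]))
  rng <- suppressWarnings(range(object@data, na.rm = TRUE))
  cat(sprintf("  value range: [%.4g, %.4g]\n", rng[1], rng[2]))
})

## ---------------------------------------------------------------- MLS types

#' Matched control points
#'
#' Landmark pairs (p_i, q_i) marking the same anatomical location on the
#' atlas plate (p, source) and the MR slice (q, target): cortical outline,
#' major sulci, ventricles and the thalamic border in practice.
#'
#' @param p n x 2 numeric matrix of source points
#' @param q n x 2 numeric matrix of matched target points
#' @return a \code{ControlPointSet}
#' @export ControlPointSet
#' @exportClass ControlPointSet
setClass("ControlPointSet", representation(p = "matrix", q = "matrix"),
  validity = function(object) {
    if (ncol(object@p) != 2L || ncol(object@q) != 2L)
      return("p and q must have two columns")
    if (nrow(object@p) != nrow(object@q))
      return("p and q must have the same number of points")
    if (nrow(object@p) < 2L)
      return("at least 2 control-point pairs are required")
    d <- as.matrix(stats::dist(object@p))
    diag(d) <- Inf
    if (any(d < 1e-12))
      return("duplicate points within p are not allowed")
    TRUE
  })
ControlPointSet <- function(p, q) {
  p <- matrix(as.numeric(p), ncol = 2)
  q <- matrix(as.numeric(q), ncol = 2)
  new("ControlPointSet", p = p, q = q)
}

#' @rdname swiatlas-generics
#' @export
setMethod("srcPoints", "ControlPointSet", function(object) object@p)
#' @rdname swiatlas-generics
#' @export
setMethod("dstPoints", "ControlPointSet", function(object) object@q)
#' @rdname swiatlas-generics
#' @export
setMethod("nPoints", "ControlPointSet", function(object) nrow(object@p))

setMethod("show", "ControlPointSet", function(object) {
  cat(sprintf("ControlPointSet: %d matched pairs\n", nrow(object@p)))
  cat(sprintf("  mean displacement: %.3g px\n",
              mean(sqrt(rowSums((object@q - object@p)^2)))))
})

#' Moving-least-squares configuration
#'
#' @param alpha positive weight exponent; weights decay as
#'   \eqn{1/|p_i - v|^{2\alpha}}. Default 2.
#' @param mode one of \code{"affine"}, \code{"similarity"}, \code{"rigid"}
#' @param gridSpacing field sampling interval in px, default 1
#' @param maxBisections bisection budget of the fold-free step search
#' @param epsilonDistance coincidence threshold in px; \code{NA} means
#'   1e-9 times the domain diagonal
#' @return an \code{MLSConfig}
#' @export MLSConfig
#' @exportClass MLSConfig
setClass("MLSConfig",
  representation(alpha = "numeric", mode = "character",
                 gridSpacing = "numeric", maxBisections = "integer",
                 epsilonDistance = "numeric"),
  validity = function(object) {
    if (object@alpha <= 0) return("alpha must be > 0")
    if (!object@mode %in% c("affine", "similarity", "rigid"))
      return("mode must be affine, similarity or rigid")
    if (object@gridSpacing <= 0) return("gridSpacing must be > 0")
    if (object@maxBisections < 1L) return("maxBisections must be >= 1")
    TRUE
  })
MLSConfig <- function(alpha = 2, mode = c("affine", "similarity", "rigid"),
                      gridSpacing = 1, maxBisections = 10L,
                      epsilonDistance = NA_real_) {
  mode <- match.arg(mode)
  new("MLSConfig", alpha = alpha, mode = mode, gridSpacing = gridSpacing,
      maxBisections = as.integer(maxBisections),
      epsilonDistance = epsilonDistance)
}

#' Pointwise affine transform
#'
#' The local transform \eqn{f(x) = xM + T} (row-vector convention) solved at
#' one query point. In similarity mode \eqn{M = \lambda R} with R a rotation;
#' in rigid mode M is a pure rotation with det +1.
#'
#' @export
#' @exportClass PointTransform
setClass("PointTransform",
  representation(M = "matrix", T = "numeric", mode = "character"))

#' Dense deformation field
#'
#' Mapped coordinates f(v) sampled on a regular grid over the domain, along
#' with the control points that generated it, the Jacobian-sign verdict and
#' the fraction of the full warp this step carries.
#'
#' @export
#' @exportClass DeformationField
setClass("DeformationField",
  representation(fx = "matrix", fy = "matrix", xs = "numeric", ys = "numeric",
                 cps = "ControlPointSet", mode = "character",
                 alpha = "numeric", jacobianSignUniform = "logical",
                 stepFraction = "numeric"))

setMethod("show", "DeformationField", function(object) {
  cat(sprintf(
    "DeformationField: %d x %d grid, mode %s, step %.3g, fold-free: %s\n",
    length(object@xs), length(object@ys), object@mode, object@stepFraction,
    object@jacobianSignUniform))
})

#' Fold-free warp sequence
#'
#' Ordered partial deformations whose composition carries every source
#' control point to its target while each step keeps a uniform Jacobian
#' sign (no fold-backs).
#'
#' @export
#' @exportClass WarpSequence
setClass("WarpSequence",
  representation(steps = "list", cps = "ControlPointSet",
                 domain = "numeric", schedule = "numeric"))

#' @rdname swiatlas-generics
#' @export
setMethod("warpSteps", "WarpSequence", function(object) object@steps)
setMethod("length", "WarpSequence", function(x) length(x@steps))

setMethod("show", "WarpSequence", function(object) {
  cat(sprintf("WarpSequence: %d step(s), schedule %s\n",
              length(object@steps),
              paste(signif(object@schedule, 3), collapse = " ")))
})

## -------------------------------------------------------------- atlas types

#' Atlas plate
#'
#' One coronal plate of a histological brain atlas: labeled closed polygons
#' (nucleus name to vertex matrix, mm) at an anterior-posterior position
#' relative to the anterior commissure (positive posterior).
#'
#' @param plateId character identifier
#' @param apPosition AP position in mm posterior to AC
#' @param contours named list of n x 2 vertex matrices (closed implicitly)
#' @return an \code{AtlasPlate}
#' @export AtlasPlate
#' @exportClass AtlasPlate
setClass("AtlasPlate",
  representation(plateId = "character", apPosition = "numeric",
                 contours = "list"),
  validity = function(object) {
    if (length(object@contours) > 0 && is.null(names(object@contours)))
      return("contours must be a named list (nucleus label -> vertices)")
    if (anyDuplicated(names(object@contours)))
      return("labels must be unique within a plate")
    for (nm in names(object@contours)) {
      m <- object@contours[[nm]]
      if (!is.matrix(m) || ncol(m) != 2L || nrow(m) < 3L)
        return(sprintf("contour '%s' must be an n x 2 matrix with n >= 3", nm))
    }
    TRUE
  })
AtlasPlate <- function(plateId, apPosition, contours = list())
  new("AtlasPlate", plateId = as.character(plateId),
      apPosition = as.numeric(apPosition), contours = contours)

#' @rdname swiatlas-generics
#' @export
setMethod("contours", "AtlasPlate", function(object) object@contours)
#' @rdname swiatlas-generics
#' @export
setMethod("apPosition", "AtlasPlate", function(object) object@apPosition)

setMethod("show", "AtlasPlate", function(object) {
  cat(sprintf("AtlasPlate '%s' at AP %+.2f mm: %d contour(s) [%s]\n",
              object@plateId, object@apPosition, length(object@contours),
              paste(names(object@contours), collapse = ", ")))
})

#' AC-PC reference frame
#'
#' Anterior commissure, posterior commissure and a third midsagittal point
#' (mm, volume coordinates); the three must be non-collinear so the frame
#' fixes roll about the AC-PC line.
#'
#' @param ac,pc,midsagittal length-3 numeric points in mm
#' @return an \code{AcpcFrame}
#' @export AcpcFrame
#' @exportClass AcpcFrame
setClass("AcpcFrame",
  representation(ac = "numeric", pc = "numeric", midsagittal = "numeric"),
  validity = function(object) {
    if (length(object@ac) != 3 || length(object@pc) != 3 ||
        length(object@midsagittal) != 3)
      return("ac, pc and midsagittal must be 3D points")
    u <- object@pc - object@ac
    if (sqrt(sum(u^2)) < 1e-9) return("ac and pc must differ")
    v <- object@midsagittal - object@ac
    cr <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
            u[1] * v[2] - u[2] * v[1])
    if (sqrt(sum(cr^2)) < 1e-9 * sqrt(sum(u^2)) * max(sqrt(sum(v^2)), 1e-12))
      return("the three frame points are collinear")
    TRUE
  })
AcpcFrame <- function(ac, pc, midsagittal)
  new("AcpcFrame", ac = as.numeric(ac), pc = as.numeric(pc),
      midsagittal = as.numeric(midsagittal))

#' Serial coronal slice series
#'
#' Ordered coronal sections resampled orthogonal to the AC-PC line, with AP
#' coordinates in mm from AC (positive posterior) and uniform spacing.
#'
#' @export SliceSeries
#' @exportClass SliceSeries
setClass("SliceSeries",
  representation(slices = "array", apPositions = "numeric",
                 pixelSpacing = "numeric"),
  validity = function(object) {
    if (length(dim(object@slices)) != 3L)
      return("slices must be a 3D array (x, y, slice)")
    if (dim(object@slices)[3] != length(object@apPositions))
      return("one AP position per slice is required")
    d <- diff(object@apPositions)
    if (length(d) > 0) {
      if (any(d <= 0)) return("AP positions must be strictly increasing")
      if (max(d) - min(d) > 1e-6 * max(abs(d)))
        return("slice spacing must be uniform")
    }
    TRUE
  })
SliceSeries <- function(slices, apPositions, pixelSpacing = c(1, 1))
  new("SliceSeries", slices = slices, apPositions = as.numeric(apPositions),
      pixelSpacing = as.numeric(pixelSpacing))

setMethod("show", "SliceSeries", function(object) {
  d <- dim(object@slices)
  cat(sprintf(
    "SliceSeries: %d coronal slices (%d x %d px), AP %.2f to %.2f mm\n",
    d[3], d[1], d[2], min(object@apPositions), max(object@apPositions)))
})

#' Global plate-to-slice transform
#'
#' A global rigid fit (rotation + translation) composed with a subsequent
#' local affine fit on the rigid residuals, as used to align cortical
#' outlines and the inter-hemispheric fissure before nonlinear refinement.
#'
#' @exportClass GlobalTransform
setClass("GlobalTransform",
  representation(angle = "numeric", rigidShift = "numeric",
                 affineM = "matrix", affineShift = "numeric",
                 residualRMS = "numeric"))

setMethod("show", "GlobalTransform", function(object) {
  cat(sprintf(
    "GlobalTransform: rotation %.3f deg, shift (%.3g, %.3g), residual RMS %.3g\n",
    object@angle * 180 / pi, object@rigidShift[1], object@rigidShift[2],
    object@residualRMS))
})

## -------------------------------------------------------------- cohort type

#' Cohort table
#'
#' Per-subject metadata (age in years, sex) together with per-nucleus
#' normalized-intensity summaries (mean, SD, voxel count per subject and
#' nucleus).
#'
#' @param subjects data.frame with columns \code{subject}, \code{age} and
#'   optionally \code{sex}
#' @param intensity data.frame with columns \code{subject}, \code{nucleus},
#'   \code{mean}, \code{sd} and optionally \code{voxels}
#' @return a \code{CohortTable}
#' @export CohortTable
#' @exportClass CohortTable
setClass("CohortTable",
  representation(subjects = "data.frame", intensity = "data.frame"),
  validity = function(object) {
    if (!all(c("subject", "age") %in% names(object@subjects)))
      return("subjects needs columns subject, age")
    if (any(object@subjects$age <= 0)) return("ages must be positive")
    if (!all(c("subject", "nucleus", "mean") %in% names(object@intensity)))
      return("intensity needs columns subject, nucleus, mean")
    if (!all(object@intensity$subject %in% object@subjects$subject))
      return("intensity rows refer to unknown subjects")
    if (nrow(object@subjects) < 3)
      return("at least 3 subjects are required")
    TRUE
  })
CohortTable <- function(subjects, intensity)
  new("CohortTable", subjects = subjects, intensity = intensity)

#' @describeIn CohortTable subject ages, named by subject id
#' @param object a \code{CohortTable}
#' @export
ages <- function(object) {
  stats::setNames(object@subjects$age, object@subjects$subject)
}

#' @describeIn CohortTable nucleus labels present in the table
#' @export
nucleusNames <- function(object) unique(object@intensity$nucleus)

#' @describeIn CohortTable per-subject mean intensities for one nucleus,
#'   ordered as the subjects table
#' @param nucleus nucleus label
#' @export
nucleusMeans <- function(object, nucleus) {
  rows <- object@intensity[object@intensity$nucleus == nucleus, ]
  idx <- match(object@subjects$subject, rows$subject)
  stats::setNames(rows$mean[idx], object@subjects$subject)
}

setMethod("show", "CohortTable", function(object) {
  cat(sprintf("CohortTable: %d subjects (ages %g-%g y), %d nuclei\n",
              nrow(object@subjects), min(object@subjects$age),
              max(object@subjects$age),
              length(nucleusNames(object))))
})
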