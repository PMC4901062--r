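#' @title Generics for swiatlas containers
#' @description Accessor generics shared by the volume, plate and
#'   control-point classes.
#' @param object a swiatlas object
#' @param x a swiatlas object
#' @name swiatlas-generics
NULL

#' @describeIn swiatlas-generics the raw data array of a volume
#' @export
setGeneric("volData", function(object) standardGeneric("volData"))

#' @describeIn swiatlas-generics voxel size in mm per axis
#' @export
setGeneric("voxelSize", function(object) standardGeneric("voxelSize"))

#' @describeIn swiatlas-generics source (p) landmark matrix
#' @export
setGeneric("srcPoints", function(object) standardGeneric("srcPoints"))

#' @describeIn swiatlas-generics target (q) landmark matrix
#' @export
setGeneric("dstPoints", function(object) standardGeneric("dstPoints"))

#' @describeIn swiatlas-generics labeled closed polygons of a plate
#' @export
setGeneric("contours", function(object) standardGeneric("contours"))

#' @describeIn swiatlas-generics anterior-posterior position (mm from AC)
#' @export
setGeneric("apPosition", function(object) standardGeneric("apPosition"))

#' @describeIn swiatlas-generics number of landmark pairs
#' @export
setGeneric("nPoints", function(object) standardGeneric("nPoints"))

#' @describeIn swiatlas-generics ordered deformation steps of a warp
#' @export
setGeneric("warpSteps", function(object) standardGeneric("warpSteps"))
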