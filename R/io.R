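## File interchange: NIfTI-1 volumes (RNifti), plate text files,
## control-point tables.

#' Read a NIfTI-1 volume
#'
#' @param path NIfTI file (.nii or .nii.gz)
#' @param type container class to return
#' @return an \code{\link{MRVolume}} of the requested class
#' @export
readVolume <- function(path,
                       type = c("magnitude", "phase", "swi", "label")) {
  type <- match.arg(type)
  img <- RNifti::readNifti(path)
  vs <- RNifti::pixdim(img)[1:3]
  arr <- array(as.numeric(img), dim(img)[1:3])
  if (type == "label") {
    lab <- array(as.integer(round(arr)), dim(arr))
    codes <- sort(unique(as.vector(lab)))
    codes <- codes[codes != 0]
    return(LabelVolume(lab, vs,
                       labelTable = data.frame(code = codes,
                                               name = as.character(codes))))
  }
  switch(type,
         magnitude = MagnitudeVolume(arr, vs),
         phase = PhaseVolume(arr, vs),
         swi = SWIVolume(arr, vs))
}

#' Write a volume as NIfTI-1
#'
#' @param volume an \code{\link{MRVolume}}
#' @param path output file (.nii or .nii.gz)
#' @return the path, invisibly
#' @export
writeVolume <- function(volume, path) {
  stopifnot(is(volume, "MRVolume"))
  img <- RNifti::asNifti(volume@data)
  RNifti::pixdim(img) <- volume@voxelSize
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read / write atlas plates as structured text
#'
#' One file per plate: a header with \code{plate_id} and
#' \code{ap_position_mm}, then per-label vertex blocks introduced by
#' \code{label: <name>} with one \code{x y} pair per line.
#'
#' @param path plate file
#' @return an \code{\link{AtlasPlate}}
#' @export
readAtlasPlate <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  grab <- function(key) {
    ln <- grep(paste0("^", key, ":"), lines, value = TRUE)
    if (length(ln) != 1) stop(sprintf("plate file needs one '%s:' line", key))
    trimws(sub(paste0("^", key, ":"), "", ln))
  }
  plateId <- grab("plate_id")
  ap <- as.numeric(grab("ap_position_mm"))
  labIdx <- grep("^label:", lines)
  contours <- list()
  bounds <- c(labIdx, length(lines) + 1L)
  for (i in seq_along(labIdx)) {
    nm <- trimws(sub("^label:", "", lines[labIdx[i]]))
    block <- lines[seq(labIdx[i] + 1L, bounds[i + 1L] - 1L)]
    block <- block[!grepl(":", block)]
    xy <- do.call(rbind, lapply(strsplit(block, "[ \t,]+"),
                                function(z) as.numeric(z[1:2])))
    contours[[nm]] <- xy
  }
  AtlasPlate(plateId, ap, contours)
}

#' @rdname readAtlasPlate
#' @param plate an \code{\link{AtlasPlate}}
#' @export
writeAtlasPlate <- function(plate, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("plate_id: %s", plate@plateId), con)
  writeLines(sprintf("ap_position_mm: %.6g", plate@apPosition), con)
  for (nm in names(plate@contours)) {
    writeLines(sprintf("label: %s", nm), con)
    m <- plate@contours[[nm]]
    writeLines(sprintf("%.8g %.8g", m[, 1], m[, 2]), con)
  }
  invisible(path)
}

#' Read / write control-point tables
#'
#' Delimited text with a required header and columns \code{slice_id},
#' \code{p_x}, \code{p_y}, \code{q_x}, \code{q_y}.
#'
#' @param path table file (tab- or comma-delimited)
#' @param sliceId optional filter on \code{slice_id}
#' @return a \code{\link{ControlPointSet}}
#' @export
readControlPoints <- function(path, sliceId = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = "",
                           stringsAsFactors = FALSE)
  need <- c("slice_id", "p_x", "p_y", "q_x", "q_y")
  if (!all(need %in% names(tab)))
    stop(sprintf("control-point table must have columns: %s",
                 paste(need, collapse = ", ")))
  if (!is.null(sliceId)) tab <- tab[tab$slice_id == sliceId, ]
  if (nrow(tab) == 0) stop("no control points for the requested slice")
  ControlPointSet(cbind(tab$p_x, tab$p_y), cbind(tab$q_x, tab$q_y))
}

#' @rdname readControlPoints
#' @param cps a \code{\link{ControlPointSet}}
#' @export
writeControlPoints <- function(cps, path, sliceId = "s1") {
  tab <- data.frame(slice_id = sliceId,
                    p_x = cps@p[, 1], p_y = cps@p[, 2],
                    q_x = cps@q[, 1], q_y = cps@q[, 2])
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
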