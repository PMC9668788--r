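#' Resample a volume or mask onto a target grid
#'
#' Interpolates the source field at the voxel centres of the target geometry.
#' Intensity volumes use interpolating cubic-spline (Catmull-Rom) resampling
#' (`mode = "spline"`), which reproduces linear fields exactly; masks always
#' use nearest-neighbour so labels are never interpolated. Target voxels
#' outside the source extent are filled with `fill` (default: the source
#' minimum, which is air-like for CT).
#'
#' @param source the [VolumeGrid-class], [BinaryMask-class] or
#'   [LabelledMask-class] to resample. Masks force `mode = "nearest"`.
#' @param target a grid-carrying object supplying the output geometry.
#' @param mode `"spline"` (cubic) or `"nearest"`.
#' @param fill value for voxels outside the source extent; default
#'   `min(source)` for volumes, background for masks.
#' @return An object of the same class as `source` on the target geometry.
#' @examples
#' src <- VolumeGrid(array(seq_len(8), c(8, 1, 1)), spacing = c(2, 2, 2))
#' tgt <- VolumeGrid(array(0, c(15, 1, 1)), spacing = c(1, 2, 2))
#' v <- resampleToGrid(src, tgt)   # linear ramp is reproduced exactly
#' @export
setGeneric("resampleToGrid",
           function(source, target, mode = c("spline", "nearest"),
                    fill = NULL) standardGeneric("resampleToGrid"))

checkTargetGrid <- function(target) {
    if (any(gridShape(target) < 1L) || any(gridSpacing(target) <= 0))
        stop("degenerate target grid", call. = FALSE)
}

resampleArray <- function(values, sspacing, sorigin, target, mode, fill) {
    checkTargetGrid(target)
    tdim <- as.integer(gridShape(target))
    out <- .resampleGrid(src = as.numeric(values), sdim = dim(values),
                         sspacing = as.numeric(sspacing),
                         sorigin = as.numeric(sorigin), tdim = tdim,
                         tspacing = as.numeric(gridSpacing(target)),
                         torigin = as.numeric(gridOrigin(target)),
                         mode = if (mode == "nearest") 0L else 1L,
                         fill = fill)
    array(out, dim = tdim)
}

#' @rdname resampleToGrid
#' @export
setMethod("resampleToGrid", signature(source = "VolumeGrid"),
          function(source, target, mode = c("spline", "nearest"),
                   fill = NULL) {
    mode <- match.arg(mode)
    if (is.null(fill)) fill <- min(source@values)
    vals <- resampleArray(source@values, source@spacing, source@origin,
                          target, mode, fill)
    VolumeGrid(vals, spacing = gridSpacing(target),
               origin = gridOrigin(target))
})

#' @rdname resampleToGrid
#' @export
setMethod("resampleToGrid", signature(source = "BinaryMask"),
          function(source, target, mode = c("spline", "nearest"),
                   fill = NULL) {
    vals <- resampleArray(source@membership + 0, source@spacing,
                          source@origin, target, "nearest", 0)
    BinaryMask(vals != 0, spacing = gridSpacing(target),
               origin = gridOrigin(target))
})

#' @rdname resampleToGrid
#' @export
setMethod("resampleToGrid", signature(source = "LabelledMask"),
          function(source, target, mode = c("spline", "nearest"),
                   fill = NULL) {
    vals <- resampleArray(source@labels + 0, source@spacing, source@origin,
                          target, "nearest", 0)
    LabelledMask(array(as.integer(round(vals)), dim = dim(vals)),
                 siteByLabel = source@siteByLabel,
                 spacing = gridSpacing(target), origin = gridOrigin(target))
})
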