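#' Grid geometry accessors
#'
#' `gridShape`, `gridSpacing` and `gridOrigin` return the voxel dimensions,
#' voxel spacing (mm) and world origin (mm) of any grid-carrying object
#' ([VolumeGrid-class], [BinaryMask-class], [LabelledMask-class]).
#' `voxelVolume` returns the volume of a single voxel in cm^3
#' (`prod(spacing) / 1000`).
#'
#' @param x a grid-carrying object.
#' @return `gridShape`: integer(3); `gridSpacing`, `gridOrigin`: numeric(3);
#'   `voxelVolume`: a single positive number in cm^3.
#' @examples
#' g <- VolumeGrid(array(0, c(2, 2, 2)), spacing = c(4.07, 4.07, 2))
#' voxelVolume(g)  # 0.0331298 cm^3
#' @name grid-accessors
#' @export
setGeneric("gridShape", function(x) standardGeneric("gridShape"))

#' @rdname grid-accessors
#' @export
setGeneric("gridSpacing", function(x) standardGeneric("gridSpacing"))

#' @rdname grid-accessors
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))

#' @rdname grid-accessors
#' @export
setGeneric("voxelVolume", function(x) standardGeneric("voxelVolume"))

#' @rdname grid-accessors
#' @export
setMethod("gridShape", "VolumeGrid", function(x) dim(x@values))
#' @rdname grid-accessors
#' @export
setMethod("gridShape", "BinaryMask", function(x) dim(x@membership))
#' @rdname grid-accessors
#' @export
setMethod("gridShape", "LabelledMask", function(x) dim(x@labels))

setMethod("gridSpacing", "ANY", function(x) x@spacing)
setMethod("gridOrigin", "ANY", function(x) x@origin)
setMethod("voxelVolume", "ANY", function(x) prod(gridSpacing(x)) / 1000)

#' Voxel payload accessors
#'
#' `voxelValues` extracts the scalar 3D array of a [VolumeGrid-class];
#' `maskMembership` the logical array of a [BinaryMask-class]; `maskLabels`
#' the integer array of a [LabelledMask-class]; `siteByLabel` its label-to-site
#' map; `labelIds` the sorted vector of nonzero labels present.
#'
#' @param x the object.
#' @return the corresponding array / vector.
#' @name voxel-accessors
#' @export
setGeneric("voxelValues", function(x) standardGeneric("voxelValues"))
#' @rdname voxel-accessors
#' @export
setMethod("voxelValues", "VolumeGrid", function(x) x@values)

#' @rdname voxel-accessors
#' @export
setGeneric("maskMembership", function(x) standardGeneric("maskMembership"))
#' @rdname voxel-accessors
#' @export
setMethod("maskMembership", "BinaryMask", function(x) x@membership)
#' @rdname voxel-accessors
#' @export
setMethod("maskMembership", "LabelledMask", function(x) x@labels > 0L)

#' @rdname voxel-accessors
#' @export
setGeneric("maskLabels", function(x) standardGeneric("maskLabels"))
#' @rdname voxel-accessors
#' @export
setMethod("maskLabels", "LabelledMask", function(x) x@labels)

#' @rdname voxel-accessors
#' @export
setGeneric("siteByLabel", function(x) standardGeneric("siteByLabel"))
#' @rdname voxel-accessors
#' @export
setMethod("siteByLabel", "LabelledMask", function(x) x@siteByLabel)

#' @rdname voxel-accessors
#' @export
setGeneric("labelIds", function(x) standardGeneric("labelIds"))
#' @rdname voxel-accessors
#' @export
setMethod("labelIds", "LabelledMask",
          function(x) sort(unique(x@labels[x@labels > 0L])))

#' Coerce a labelled mask to its binary foreground
#'
#' @param x a [LabelledMask-class] (a [BinaryMask-class] passes through).
#' @return A [BinaryMask-class] whose foreground is every nonzero label.
#' @export
setGeneric("asBinaryMask", function(x) standardGeneric("asBinaryMask"))
#' @rdname asBinaryMask
#' @export
setMethod("asBinaryMask", "LabelledMask", function(x) {
    m <- x@labels > 0L
    dim(m) <- dim(x@labels)
    new("BinaryMask", membership = m, spacing = x@spacing, origin = x@origin)
})
#' @rdname asBinaryMask
#' @export
setMethod("asBinaryMask", "BinaryMask", function(x) x)

# Geometry compatibility: identical shape, spacing within 1e-6 mm, origin
# within 1e-6 mm.
sameGeometry <- function(a, b, tol = 1e-6) {
    identical(as.integer(gridShape(a)), as.integer(gridShape(b))) &&
        all(abs(gridSpacing(a) - gridSpacing(b)) <= tol) &&
        all(abs(gridOrigin(a) - gridOrigin(b)) <= tol)
}

stopIfGridMismatch <- function(a, b, what = "inputs") {
    if (!sameGeometry(a, b))
        stop(what, " must share the same grid (shape, spacing, origin)",
             call. = FALSE)
    invisible(TRUE)
}
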