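#' @useDynLib psmapet, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
NULL

LESION_SITES <- c("local_prostate", "regional_nodal", "distant_nodal",
                  "osseous", "visceral")

validGeometry <- function(shape, spacing, origin) {
    if (length(shape) != 3L || any(shape < 1L))
        return("shape must be three strictly positive integers")
    if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
        return("spacing must be three strictly positive values (mm)")
    if (length(origin) != 3L || any(!is.finite(origin)))
        return("origin must be three finite values (mm)")
    TRUE
}

#' VolumeGrid: a 3D scalar field on a regular axis-aligned grid
#'
#' The central image container: a 3D array of voxel values (PET SUV, CT
#' Hounsfield units, or raw activity concentration in Bq/mL) together with its
#' voxel spacing (mm) and world-space origin (mm). Voxel `(i, j, k)` (0-based)
#' has its centre at `origin + c(i, j, k) * spacing`; orientation is fixed
#' axis-aligned.
#'
#' @slot values 3D numeric array of voxel values.
#' @slot spacing numeric(3), voxel edge lengths in mm, strictly positive.
#' @slot origin numeric(3), world position of the first voxel centre, in mm.
#' @aliases VolumeGrid
#' @exportClass VolumeGrid
setClass("VolumeGrid",
         representation(values = "array", spacing = "numeric",
                        origin = "numeric"),
         validity = function(object) {
             if (length(dim(object@values)) != 3L)
                 return("values must be a 3D array")
             validGeometry(dim(object@values), object@spacing, object@origin)
         })

#' Construct a VolumeGrid
#'
#' @param values 3D numeric array.
#' @param spacing numeric(3) voxel spacing in mm (default 1 mm isotropic).
#' @param origin numeric(3) world position of the first voxel centre in mm.
#' @return A [VolumeGrid-class] object.
#' @examples
#' g <- VolumeGrid(array(0, c(4, 4, 4)), spacing = c(4.07, 4.07, 2))
#' voxelVolume(g)
#' @export
VolumeGrid <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
    storage.mode(values) <- "double"
    new("VolumeGrid", values = values, spacing = as.numeric(spacing),
        origin = as.numeric(origin))
}

#' BinaryMask: voxel membership on a grid
#'
#' A logical 3D array sharing the geometry (shape, spacing, origin) of the
#' volume it annotates. Used for predicted lesion masks, ground-truth
#' foreground, and physiologic-uptake regions.
#'
#' @slot membership 3D logical array.
#' @slot spacing numeric(3) mm.
#' @slot origin numeric(3) mm.
#' @aliases BinaryMask
#' @exportClass BinaryMask
setClass("BinaryMask",
         representation(membership = "array", spacing = "numeric",
                        origin = "numeric"),
         validity = function(object) {
             if (length(dim(object@membership)) != 3L ||
                 !is.logical(object@membership))
                 return("membership must be a 3D logical array")
             validGeometry(dim(object@membership), object@spacing,
                           object@origin)
         })

#' Construct a BinaryMask
#'
#' @param membership 3D logical array (numeric input is coerced via `!= 0`).
#' @param grid optional [VolumeGrid-class] (or other mask) supplying geometry.
#' @param spacing,origin geometry used when `grid` is missing.
#' @return A [BinaryMask-class].
#' @export
BinaryMask <- function(membership, grid = NULL, spacing = c(1, 1, 1),
                       origin = c(0, 0, 0)) {
    if (!is.logical(membership)) {
        dm <- dim(membership)
        membership <- membership != 0
        dim(membership) <- dm
    }
    if (!is.null(grid)) {
        spacing <- gridSpacing(grid)
        origin <- gridOrigin(grid)
    }
    new("BinaryMask", membership = membership, spacing = as.numeric(spacing),
        origin = as.numeric(origin))
}

#' LabelledMask: integer lesion labels with anatomical site annotations
#'
#' A 3D integer array in which 0 is background and each positive label is one
#' lesion (a contiguous voxel cluster). `siteByLabel` maps each label to an
#' anatomical site category (`local_prostate`, `regional_nodal`,
#' `distant_nodal`, `osseous`, `visceral`), or `NA` when sites are unset (for
#' example straight out of [connectedComponents()]).
#'
#' @slot labels 3D integer array, 0 = background.
#' @slot spacing numeric(3) mm.
#' @slot origin numeric(3) mm.
#' @slot siteByLabel named character vector, names `"1"`, `"2"`, ... per label.
#' @aliases LabelledMask
#' @exportClass LabelledMask
setClass("LabelledMask",
         representation(labels = "array", spacing = "numeric",
                        origin = "numeric", siteByLabel = "character"),
         validity = function(object) {
             if (length(dim(object@labels)) != 3L ||
                 !is.integer(object@labels))
                 return("labels must be a 3D integer array")
             v <- validGeometry(dim(object@labels), object@spacing,
                                object@origin)
             if (!isTRUE(v)) return(v)
             present <- sort(unique(object@labels[object@labels > 0L]))
             if (!all(as.character(present) %in% names(object@siteByLabel)))
                 return("every nonzero label must appear in siteByLabel")
             known <- stats::na.omit(object@siteByLabel)
             if (length(known) && !all(known %in% LESION_SITES))
                 return(paste("site categories must be one of:",
                              paste(LESION_SITES, collapse = ", ")))
             TRUE
         })

#' Construct a LabelledMask
#'
#' @param labels 3D integer array (numeric is coerced), 0 = background.
#' @param siteByLabel named character vector of site categories; defaults to
#'   `NA` (unset) for every label present.
#' @param grid optional geometry source.
#' @param spacing,origin geometry used when `grid` is missing.
#' @return A [LabelledMask-class].
#' @export
LabelledMask <- function(labels, siteByLabel = NULL, grid = NULL,
                         spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
    storage.mode(labels) <- "integer"
    if (!is.null(grid)) {
        spacing <- gridSpacing(grid)
        origin <- gridOrigin(grid)
    }
    if (is.null(siteByLabel)) {
        present <- sort(unique(labels[labels > 0L]))
        siteByLabel <- stats::setNames(rep(NA_character_, length(present)),
                                       as.character(present))
    }
    new("LabelledMask", labels = labels, spacing = as.numeric(spacing),
        origin = as.numeric(origin), siteByLabel = siteByLabel)
}

setMethod("show", "VolumeGrid", function(object) {
    d <- dim(object@values)
    cat(sprintf("VolumeGrid: %d x %d x %d voxels @ %.3g x %.3g x %.3g mm\n",
                d[1], d[2], d[3], object@spacing[1], object@spacing[2],
                object@spacing[3]))
    cat(sprintf("  origin (mm): [%.3g, %.3g, %.3g]; value range [%.4g, %.4g]\n",
                object@origin[1], object@origin[2], object@origin[3],
                min(object@values), max(object@values)))
})

setMethod("show", "BinaryMask", function(object) {
    d <- dim(object@membership)
    cat(sprintf("BinaryMask: %d x %d x %d voxels, %d foreground (%.3g%%)\n",
                d[1], d[2], d[3], sum(object@membership),
                100 * mean(object@membership)))
})

setMethod("show", "LabelledMask", function(object) {
    d <- dim(object@labels)
    k <- length(labelIds(object))
    cat(sprintf("LabelledMask: %d x %d x %d voxels, %d lesion label%s\n",
                d[1], d[2], d[3], k, if (k == 1) "" else "s"))
    if (k > 0) {
        tab <- table(factor(object@siteByLabel, levels = LESION_SITES),
                     useNA = "ifany")
        tab <- tab[tab > 0]
        if (length(tab))
            cat("  sites:", paste(names(tab), tab, sep = "=", collapse = ", "),
                "\n")
    }
})
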