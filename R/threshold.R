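#' Global SUV-threshold baseline segmentation
#'
#' The automated counterpart of threshold-based ground-truth bootstrapping on
#' PSMA PET: every voxel with SUV_bw strictly greater than `suv_threshold`
#' (default 3, strict `>`) is foreground; clusters smaller than
#' `min_cluster_size` voxels are removed. Physiologic-uptake regions
#' (bladder, kidneys, liver, ...) are removed afterwards with
#' [excludePhysiologic()] given an explicit physiologic mask.
#'
#' @param pet a [VolumeGrid-class] in SUV_bw units, finite and non-negative.
#' @param suv_threshold SUV_bw cutoff, strict inequality; default 3.
#' @param connectivity cluster connectivity for the minimum-size filter.
#' @param min_cluster_size smallest retained cluster, in voxels; default 1
#'   (no filtering).
#' @return A [BinaryMask-class] of supra-threshold voxels.
#' @examples
#' pet <- VolumeGrid(array(3, c(3, 3, 3)))
#' sum(maskMembership(globalThresholdSegment(pet)))  # 0: strict >
#' @export
globalThresholdSegment <- function(pet, suv_threshold = 3,
                                   connectivity = 26, min_cluster_size = 1) {
    stopifnot(is(pet, "VolumeGrid"))
    if (!is.finite(suv_threshold) || suv_threshold <= 0)
        stop("suv_threshold must be > 0", call. = FALSE)
    if (min_cluster_size < 1)
        stop("min_cluster_size must be >= 1", call. = FALSE)
    vals <- pet@values
    if (any(!is.finite(vals)) || any(vals < 0))
        stop("PET volume must contain finite, non-negative SUV values",
             call. = FALSE)
    m <- vals > suv_threshold
    dim(m) <- dim(vals)
    mask <- BinaryMask(m, grid = pet)
    if (min_cluster_size > 1 && any(m)) {
        cc <- connectedComponents(mask, connectivity)
        sizes <- tabulate(cc@labels[cc@labels > 0L])
        keep <- which(sizes >= min_cluster_size)
        m <- array(cc@labels %in% keep, dim = dim(vals))
        mask <- BinaryMask(m, grid = pet)
    }
    mask
}

#' Remove physiologic-uptake regions from a segmentation
#'
#' Computes `mask AND NOT physiologic`: the automated stand-in for the manual
#' discarding of physiologic tracer uptake (bladder, kidneys, salivary glands,
#' liver, ...) after global thresholding. Idempotent.
#'
#' @param mask a [BinaryMask-class] segmentation.
#' @param physiologic a [BinaryMask-class] of physiologic-uptake voxels on the
#'   same grid.
#' @return A [BinaryMask-class].
#' @export
excludePhysiologic <- function(mask, physiologic) {
    stopifnot(is(mask, "BinaryMask"), is(physiologic, "BinaryMask"))
    stopIfGridMismatch(mask, physiologic, "mask and physiologic mask")
    m <- mask@membership & !physiologic@membership
    dim(m) <- dim(mask@membership)
    BinaryMask(m, grid = mask)
}
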