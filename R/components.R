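#' Label connected voxel clusters
#'
#' Partitions the foreground of a binary mask into maximal connected clusters
#' under 6- (face), 18- (face+edge) or 26- (face+edge+corner) connectivity.
#' Labels `1..K` are assigned in raster-scan order of each cluster's minimum
#' linear index, so the labelling is deterministic. Site categories are left
#' unset (`NA`).
#'
#' @param mask a [BinaryMask-class].
#' @param connectivity 6, 18 or 26 (default 26, the most inclusive reading of
#'   voxel contiguity).
#' @return A [LabelledMask-class] with one label per cluster (0 labels for an
#'   empty mask).
#' @examples
#' m <- array(FALSE, c(2, 2, 2)); m[1, 1, 1] <- m[2, 2, 2] <- TRUE
#' length(labelIds(connectedComponents(BinaryMask(m), 26)))  # 1
#' length(labelIds(connectedComponents(BinaryMask(m), 6)))   # 2
#' @export
connectedComponents <- function(mask, connectivity = 26) {
    stopifnot(is(mask, "BinaryMask"))
    connectivity <- as.integer(connectivity)
    if (!connectivity %in% c(6L, 18L, 26L))
        stop("connectivity must be 6, 18 or 26", call. = FALSE)
    d <- dim(mask@membership)
    lab <- .ccLabel(as.logical(mask@membership), as.integer(d), connectivity)
    k <- attr(lab, "maxLabel")
    attributes(lab) <- list(dim = d)
    LabelledMask(lab,
                 siteByLabel = stats::setNames(
                     rep(NA_character_, k),
                     if (k > 0) as.character(seq_len(k)) else character(0)),
                 spacing = mask@spacing, origin = mask@origin)
}

# Binary morphology with the face-connected structuring element, repeated
# `radius` times; radius > 0 dilates, < 0 erodes, 0 is the identity.
morphMask <- function(membership, radius) {
    radius <- as.integer(round(radius))
    if (radius == 0L) return(membership)
    d <- dim(membership)
    m <- as.logical(membership)
    for (i in seq_len(abs(radius)))
        m <- .morphStep(m, as.integer(d), radius > 0L)
    dim(m) <- d
    m
}
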