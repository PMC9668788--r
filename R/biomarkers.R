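#' Whole-body tumour-burden biomarkers
#'
#' `computeTLV` returns the total lesional volume in cm^3: the number of
#' positive voxels times the voxel volume. `computeTLU` returns the total
#' lesional uptake: the plain (unweighted) sum of SUV_bw over the positive
#' voxels, unitless. `totalLesionActivity` is the explicitly named
#' volume-weighted alternative (`sum(SUV) * voxel volume`, in SUV * cm^3),
#' provided for comparison but never the default.
#'
#' @param mask a [BinaryMask-class] (or [LabelledMask-class]) of lesion voxels.
#' @param pet a [VolumeGrid-class] of SUV_bw on the same grid.
#' @return A single non-negative number.
#' @examples
#' m <- array(FALSE, c(4, 4, 4)); m[1:12] <- TRUE
#' computeTLV(BinaryMask(m, spacing = c(4.07, 4.07, 2)))  # 0.3975576 cm^3
#' @export
computeTLV <- function(mask) {
    mask <- asBinaryMask(mask)
    sum(mask@membership) * voxelVolume(mask)
}

#' @rdname computeTLV
#' @export
computeTLU <- function(mask, pet) {
    mask <- asBinaryMask(mask)
    stopifnot(is(pet, "VolumeGrid"))
    stopIfGridMismatch(mask, pet, "mask and PET volume")
    sum(pet@values[mask@membership])
}

#' @rdname computeTLV
#' @export
totalLesionActivity <- function(mask, pet) {
    computeTLU(mask, pet) * voxelVolume(asBinaryMask(mask))
}

#' Build a biomarker record row
#'
#' @param scan_id scan identifier.
#' @param mask lesion [BinaryMask-class]/[LabelledMask-class].
#' @param pet SUV_bw [VolumeGrid-class].
#' @param source `"auto"` (model prediction) or `"manual"` (reference
#'   delineation).
#' @return one-row data.frame with `scan_id`, `source`, `tlv_cm3`, `tlu`.
#' @export
biomarkerRecord <- function(scan_id, mask, pet, source = c("auto", "manual")) {
    source <- match.arg(source)
    data.frame(scan_id = as.character(scan_id), source = source,
               tlv_cm3 = computeTLV(mask), tlu = computeTLU(mask, pet),
               stringsAsFactors = FALSE)
}

#' Compare automated against manual biomarker sets
#'
#' Pairs automated and manual biomarker records by `scan_id` and, for each
#' biomarker (`tlv_cm3`, `tlu`), reports the paired medians, a two-sided
#' Wilcoxon signed-rank p-value on the paired differences, and the Spearman
#' rank correlation with its p-value. Also returns identity-line scatter data
#' (optionally log1p-transformed, as used for display of heavily skewed
#' burden distributions).
#'
#' @param auto,manual data.frames as returned by [biomarkerRecord()] (columns
#'   `scan_id`, `tlv_cm3`, `tlu`); the same scan ids must appear in both,
#'   n >= 5.
#' @param log_scatter logical; return `log1p`-transformed scatter coordinates.
#' @return list with one element per biomarker: `median_auto`,
#'   `median_manual`, `wilcoxon_p`, `degenerate`, `spearman_rho`,
#'   `spearman_p`, and a `scatter` data.frame (`scan_id`, `auto`, `manual`).
#' @export
compareBiomarkers <- function(auto, manual, log_scatter = FALSE) {
    stopifnot(is.data.frame(auto), is.data.frame(manual))
    if (!setequal(auto$scan_id, manual$scan_id) ||
        anyDuplicated(auto$scan_id) || anyDuplicated(manual$scan_id))
        stop("scan ids must pair one-to-one between auto and manual records",
             call. = FALSE)
    if (nrow(auto) < 5)
        stop("need at least 5 paired scans", call. = FALSE)
    manual <- manual[match(auto$scan_id, manual$scan_id), , drop = FALSE]
    out <- lapply(c(tlv_cm3 = "tlv_cm3", tlu = "tlu"), function(col) {
        x <- auto[[col]]
        y <- manual[[col]]
        d <- x - y
        degenerate <- all(d == 0)
        sp <- spearmanCorrelation(x, y)
        sc <- data.frame(scan_id = auto$scan_id,
                         auto = if (log_scatter) log1p(x) else x,
                         manual = if (log_scatter) log1p(y) else y,
                         stringsAsFactors = FALSE)
        list(median_auto = stats::median(x), median_manual = stats::median(y),
             wilcoxon_p = if (degenerate) 1 else wilcoxonSignedRank(d)$p_value,
             degenerate = degenerate,
             spearman_rho = sp$rho, spearman_p = sp$p_value, scatter = sc)
    })
    out
}
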