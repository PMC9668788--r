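#' Read and write volumes and masks as NIfTI
#'
#' `readVolume` loads a 3D NIfTI image into a [VolumeGrid-class]; `writeVolume`
#' stores one. `readMask`/`writeMask` do the same for lesion masks, stored as
#' unsigned integer labels that are never interpolated. Only 3D, axis-aligned
#' images are supported; spacing is taken from the NIfTI `pixdim` and the
#' origin from the qform/sform translation.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `readVolume`: a [VolumeGrid-class]. `readMask`: a
#'   [LabelledMask-class] when `labelled = TRUE` (default), otherwise a
#'   [BinaryMask-class].
#' @examples
#' g <- VolumeGrid(array(rnorm(8), c(2, 2, 2)), spacing = c(4.07, 4.07, 2))
#' f <- tempfile(fileext = ".nii.gz")
#' writeVolume(g, f)
#' g2 <- readVolume(f)
#' stopifnot(all.equal(voxelValues(g), voxelValues(g2)))
#' @export
readVolume <- function(path) {
    hdr <- readNiftiChecked(path)
    VolumeGrid(hdr$values, spacing = hdr$spacing, origin = hdr$origin)
}

#' @rdname readVolume
#' @param labelled logical; read the mask as integer labels (`TRUE`) or binary
#'   membership (`FALSE`).
#' @export
readMask <- function(path, labelled = TRUE) {
    hdr <- readNiftiChecked(path)
    vals <- hdr$values
    if (any(vals < 0) || any(vals != round(vals)))
        stop("mask file contains non-integer or negative values: ", path,
             call. = FALSE)
    if (labelled) {
        lab <- array(as.integer(round(vals)), dim = dim(vals))
        LabelledMask(lab, spacing = hdr$spacing, origin = hdr$origin)
    } else {
        BinaryMask(vals != 0, spacing = hdr$spacing, origin = hdr$origin)
    }
}

#' @rdname readVolume
#' @param grid a [VolumeGrid-class] to write.
#' @export
writeVolume <- function(grid, path) {
    stopifnot(is(grid, "VolumeGrid"))
    if (any(!is.finite(grid@values)))
        stop("refusing to write non-finite voxel values", call. = FALSE)
    writeNiftiGrid(grid@values, grid@spacing, grid@origin, path,
                   datatype = "double")
    invisible(path)
}

#' @rdname readVolume
#' @param mask a [BinaryMask-class] or [LabelledMask-class] to write.
#' @export
writeMask <- function(mask, path) {
    if (is(mask, "BinaryMask")) {
        vals <- array(as.integer(mask@membership), dim = dim(mask@membership))
    } else if (is(mask, "LabelledMask")) {
        vals <- mask@labels
    } else stop("mask must be a BinaryMask or LabelledMask", call. = FALSE)
    writeNiftiGrid(vals, gridSpacing(mask), gridOrigin(mask), path,
                   datatype = "uint16")
    invisible(path)
}

readNiftiChecked <- function(path) {
    if (!file.exists(path))
        stop("file not found: ", path, call. = FALSE)
    img <- RNifti::readNifti(path)
    d <- dim(img)
    if (length(d) != 3L)
        stop("expected a 3D NIfTI image, got ", length(d), "D: ", path,
             call. = FALSE)
    spacing <- RNifti::pixdim(img)
    if (length(spacing) != 3L || any(spacing <= 0))
        stop("non-positive voxel spacing in NIfTI header: ", path,
             call. = FALSE)
    x <- RNifti::xform(img)
    rot <- x[1:3, 1:3]
    offdiag <- rot - diag(diag(rot))
    if (any(abs(offdiag) > 1e-4 * max(abs(diag(rot)))))
        stop("oblique or rotated NIfTI orientations are not supported: ", path,
             call. = FALSE)
    vals <- as.array(img)
    storage.mode(vals) <- "double"
    attributes(vals) <- list(dim = d)
    list(values = vals, spacing = as.numeric(spacing),
         origin = as.numeric(x[1:3, 4]))
}

writeNiftiGrid <- function(values, spacing, origin, path, datatype) {
    img <- RNifti::asNifti(values)
    RNifti::pixdim(img) <- spacing
    m <- rbind(cbind(diag(spacing), origin), c(0, 0, 0, 1))
    RNifti::qform(img) <- structure(m, code = 2L)
    RNifti::writeNifti(img, path, datatype = datatype)
}

#' Read and write per-scan metadata tables
#'
#' The scan metadata CSV has columns `patient_id`, `timepoint`
#' (`baseline`/`followup`), `body_weight_kg`, `injected_activity_MBq`,
#' `delay_min`, `psma_status` (`positive`/`negative`).
#'
#' @param path CSV file path.
#' @return `readScanMeta`: a data.frame with the columns above, validated.
#' @export
readScanMeta <- function(path) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("patient_id", "timepoint", "body_weight_kg",
              "injected_activity_MBq", "delay_min", "psma_status")
    miss <- setdiff(need, names(df))
    if (length(miss))
        stop("scan metadata is missing columns: ",
             paste(miss, collapse = ", "), call. = FALSE)
    for (i in seq_len(nrow(df)))
        scanMeta(df$patient_id[i], df$timepoint[i], df$body_weight_kg[i],
                 df$injected_activity_MBq[i], df$delay_min[i],
                 df$psma_status[i])
    df
}

#' @rdname readScanMeta
#' @param meta data.frame of scan metadata rows.
#' @export
writeScanMeta <- function(meta, path) {
    utils::write.csv(meta, path, row.names = FALSE)
    invisible(path)
}
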