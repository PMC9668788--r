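#' Round half-up to one decimal, for display of percentages
#'
#' Printed metrics use conventional half-up rounding at one decimal
#' (`94.55 -> 94.6`); machine-readable outputs keep full precision.
#'
#' @param x numeric.
#' @param digits decimal places (default 1).
#' @return numeric, rounded half-up.
#' @export
roundHalfUp <- function(x, digits = 1) {
    p <- 10^digits
    sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Metrics from a 2x2 confusion table
#'
#' Standard ratios from true/false positive/negative counts, as percentages at
#' full precision; a metric whose denominator is zero is `NA` (undefined).
#'
#' @param tp,fp,tn,fn non-negative integer counts. `tp` may also be a
#'   `ConfusionCounts` list with those fields.
#' @return A list of class `MetricSet` with `accuracy`, `sensitivity`, `ppv`,
#'   `specificity`, `npv`, `f1` (percent, full precision) and the `counts`.
#' @examples
#' m <- confusionMetrics(tp = 70, fp = 2, tn = 51, fn = 5)
#' roundHalfUp(m$accuracy)  # 94.5
#' @export
confusionMetrics <- function(tp, fp = NULL, tn = NULL, fn = NULL) {
    if (is.list(tp)) {
        c0 <- tp; tp <- c0$tp; fp <- c0$fp; tn <- c0$tn; fn <- c0$fn
    }
    counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
    if (any(!is.finite(counts)) || any(counts < 0) ||
        any(counts != round(counts)))
        stop("confusion counts must be non-negative integers", call. = FALSE)
    rate <- function(num, den) if (den > 0) 100 * num / den else NA_real_
    sens <- rate(tp, tp + fn)
    ppv <- rate(tp, tp + fp)
    out <- list(accuracy = rate(tp + tn, sum(counts)),
                sensitivity = sens,
                ppv = ppv,
                specificity = rate(tn, tn + fp),
                npv = rate(tn, tn + fn),
                f1 = if (!is.na(sens) && !is.na(ppv) && (sens + ppv) > 0)
                    f1Score(ppv, sens) else NA_real_,
                counts = as.list(counts))
    class(out) <- "MetricSet"
    out
}

#' F1 score as the harmonic mean of PPV and sensitivity
#'
#' @param ppv,sensitivity percentages in \[0, 100\], not both zero.
#' @return The F1 score in percent, full precision.
#' @examples
#' roundHalfUp(f1Score(88.2, 73.0))  # 79.9
#' @export
f1Score <- function(ppv, sensitivity) {
    if (any(!is.finite(c(ppv, sensitivity))) ||
        any(c(ppv, sensitivity) < 0) || any(c(ppv, sensitivity) > 100))
        stop("ppv and sensitivity must be percentages in [0, 100]",
             call. = FALSE)
    if (ppv + sensitivity == 0)
        stop("F1 is undefined when PPV and sensitivity are both zero",
             call. = FALSE)
    2 * ppv * sensitivity / (ppv + sensitivity)
}

#' Voxel-level segmentation metrics
#'
#' Dice similarity coefficient, sensitivity, positive predictive value and
#' specificity between a ground-truth foreground `A` and a prediction `B`:
#' `DSC = 2|A.B| / (|A| + |B|)`, `sensitivity = |A.B| / |A|`,
#' `PPV = |A.B| / |B|`, specificity over all grid voxels. All in percent.
#' The ground truth must be non-empty (voxel metrics are computed on
#' PSMA-positive scans only); an empty prediction yields PPV 0 with
#' `ppv_defined = FALSE`.
#'
#' @param gt ground truth, a [BinaryMask-class] or [LabelledMask-class].
#' @param pred predicted [BinaryMask-class] on the same grid.
#' @return list with `dsc`, `sensitivity`, `ppv`, `specificity` (percent) and
#'   `ppv_defined`.
#' @export
voxelMetrics <- function(gt, pred) {
    gtm <- asBinaryMask(gt)
    stopifnot(is(pred, "BinaryMask"))
    stopIfGridMismatch(gtm, pred, "ground truth and prediction")
    A <- gtm@membership
    B <- pred@membership
    a <- sum(A)
    if (a == 0)
        stop("DSC is undefined on an empty ground truth ",
             "(exclude negative scans from voxel-level metrics)",
             call. = FALSE)
    b <- sum(B)
    i <- sum(A & B)
    n <- length(A)
    list(dsc = 200 * i / (a + b),
         sensitivity = 100 * i / a,
         ppv = if (b > 0) 100 * i / b else 0,
         ppv_defined = b > 0,
         specificity = 100 * (n - a - b + i) / (n - a))
}

#' Match predicted voxels against ground-truth lesions
#'
#' The lesion-level detection rule: a ground-truth lesion is detected when the
#' predicted mask covers at least a fraction `tau` (default 0.10, inclusive)
#' of the lesion's voxels. The overlap denominator is the ground-truth lesion
#' volume, and the overlap is computed against the whole predicted mask, so a
#' single predicted cluster may detect several lesions. A false-positive
#' cluster is a connected component of the prediction whose intersection with
#' the ground-truth foreground is empty; predicted clusters that touch a
#' lesion without triggering a detection are neither true nor false positives.
#'
#' @param gt a [LabelledMask-class] of ground-truth lesions.
#' @param pred a [BinaryMask-class] prediction on the same grid.
#' @param tau detection threshold in (0, 1], inclusive; default 0.10.
#' @param connectivity connectivity for false-positive cluster extraction.
#' @return A list of class `DetectionReport`: `lesions` (data.frame with
#'   `label`, `site`, `volume_voxels`, `overlap_voxels`, `overlap_fraction`,
#'   `detected`), `fp_cluster_count`, `n_detected`, `n_lesions`, `tau`,
#'   `connectivity`, and percent `sensitivity`, `ppv`, `f1` (`NA` when
#'   undefined).
#' @examples
#' lab <- array(0L, c(4, 4, 4)); lab[1:2, 1, 1] <- 1L
#' gt <- LabelledMask(lab)
#' rep <- matchLesions(gt, asBinaryMask(gt))
#' rep$sensitivity  # 100
#' @export
matchLesions <- function(gt, pred, tau = 0.10, connectivity = 26) {
    stopifnot(is(gt, "LabelledMask"), is(pred, "BinaryMask"))
    stopIfGridMismatch(gt, pred, "ground truth and prediction")
    if (!is.finite(tau) || tau <= 0 || tau > 1)
        stop("tau must be in (0, 1]", call. = FALSE)
    labs <- labelIds(gt)
    k <- length(labs)
    predm <- pred@membership
    if (k > 0) {
        maxl <- max(labs)
        vol <- tabulate(gt@labels, nbins = maxl)[labs]
        ov <- tabulate(gt@labels[predm], nbins = maxl)[labs]
    } else {
        vol <- ov <- integer(0)
    }
    frac <- ifelse(vol > 0, ov / vol, 0)
    detected <- frac >= tau
    lesions <- data.frame(
        label = labs,
        site = if (k > 0) unname(gt@siteByLabel[as.character(labs)])
               else character(0),
        volume_voxels = vol, overlap_voxels = ov, overlap_fraction = frac,
        detected = detected, stringsAsFactors = FALSE)
    # false-positive clusters: predicted components disjoint from GT foreground
    fp <- 0L
    if (any(predm)) {
        cc <- connectedComponents(pred, connectivity)
        npc <- length(labelIds(cc))
        hit <- unique(cc@labels[gt@labels > 0L & predm])
        fp <- npc - length(hit[hit > 0L])
    }
    nd <- sum(detected)
    sens <- if (k > 0) 100 * nd / k else NA_real_
    ppv <- if (nd + fp > 0) 100 * nd / (nd + fp) else NA_real_
    out <- list(lesions = lesions, fp_cluster_count = fp,
                n_detected = nd, n_lesions = k, tau = tau,
                connectivity = connectivity,
                sensitivity = sens, ppv = ppv,
                f1 = if (!is.na(sens) && !is.na(ppv) && sens + ppv > 0)
                    f1Score(ppv, sens) else NA_real_)
    class(out) <- "DetectionReport"
    out
}

#' Patient-level scan classification
#'
#' Classifies one scan from its ground truth and prediction: a PSMA-positive
#' scan (ground truth has at least one lesion) is a true positive when at
#' least one lesion is detected at overlap threshold `tau`, otherwise a false
#' negative; a PSMA-negative scan is a true negative only when the prediction
#' contains not a single positive voxel, otherwise a false positive.
#'
#' @inheritParams matchLesions
#' @return list with `gt_status` (`"positive"`/`"negative"`), `call` (one of
#'   `"tp"`, `"fp"`, `"tn"`, `"fn"`), `n_detected`, `n_lesions`,
#'   `n_pred_voxels`.
#' @export
classifyScan <- function(gt, pred, tau = 0.10, connectivity = 26) {
    stopifnot(is(gt, "LabelledMask"), is(pred, "BinaryMask"))
    stopIfGridMismatch(gt, pred, "ground truth and prediction")
    npred <- sum(pred@membership)
    if (length(labelIds(gt)) == 0L) {
        return(list(gt_status = "negative",
                    call = if (npred == 0L) "tn" else "fp",
                    n_detected = 0L, n_lesions = 0L, n_pred_voxels = npred))
    }
    rep <- matchLesions(gt, pred, tau = tau, connectivity = connectivity)
    list(gt_status = "positive",
         call = if (rep$n_detected >= 1L) "tp" else "fn",
         n_detected = rep$n_detected, n_lesions = rep$n_lesions,
         n_pred_voxels = npred)
}

#' Sweep the lesion-detection overlap threshold
#'
#' Recomputes patient-level and lesion-level metrics as the true-positive
#' overlap threshold `tau` is varied. Overlap fractions and false-positive
#' cluster counts do not depend on `tau`, so they are computed once per scan.
#' Lesion sensitivity is non-increasing in `tau`.
#'
#' @param gt a [LabelledMask-class] or a list of them (cohort mode).
#' @param pred a [BinaryMask-class] or a list matching `gt`.
#' @param tau_grid numeric vector of thresholds in (0, 1].
#' @param connectivity cluster connectivity.
#' @return data.frame with one row per `tau`: lesion-level `lesion_sensitivity`,
#'   `lesion_ppv`, `lesion_f1` and patient-level `patient_accuracy`,
#'   `patient_sensitivity`, `patient_ppv`, `patient_specificity`,
#'   `patient_npv` (percent; `NA` when undefined).
#' @export
thresholdSweep <- function(gt, pred, tau_grid, connectivity = 26) {
    if (length(tau_grid) == 0)
        stop("tau_grid must be non-empty", call. = FALSE)
    if (any(!is.finite(tau_grid)) || any(tau_grid <= 0) || any(tau_grid > 1))
        stop("tau_grid values must be in (0, 1]", call. = FALSE)
    if (!is.list(gt)) gt <- list(gt)
    if (!is.list(pred)) pred <- list(pred)
    stopifnot(length(gt) == length(pred))
    base <- lapply(seq_along(gt), function(i)
        matchLesions(gt[[i]], pred[[i]], tau = min(tau_grid),
                     connectivity = connectivity))
    npred <- vapply(pred, function(p) sum(p@membership), numeric(1))
    do.call(rbind, lapply(tau_grid, function(tau) {
        det <- vapply(base, function(r)
            sum(r$lesions$overlap_fraction >= tau), numeric(1))
        nles <- vapply(base, function(r) r$n_lesions, numeric(1))
        fp <- vapply(base, function(r) r$fp_cluster_count, numeric(1))
        pos <- nles > 0
        cls <- confusionMetrics(tp = sum(pos & det >= 1),
                                fn = sum(pos & det == 0),
                                tn = sum(!pos & npred == 0),
                                fp = sum(!pos & npred > 0))
        nd <- sum(det)
        sens <- if (sum(nles) > 0) 100 * nd / sum(nles) else NA_real_
        ppv <- if (nd + sum(fp) > 0) 100 * nd / (nd + sum(fp)) else NA_real_
        data.frame(tau = tau,
                   lesion_sensitivity = sens, lesion_ppv = ppv,
                   lesion_f1 = if (!is.na(sens) && !is.na(ppv) &&
                                   sens + ppv > 0) f1Score(ppv, sens)
                               else NA_real_,
                   patient_accuracy = cls$accuracy,
                   patient_sensitivity = cls$sensitivity,
                   patient_ppv = cls$ppv,
                   patient_specificity = cls$specificity,
                   patient_npv = cls$npv)
    }))
}

#' Per-site lesion detection sensitivity
#'
#' Aggregates detection reports into a per-anatomical-site sensitivity table
#' (detected / total per site category), plus an `overall` row. Sites absent
#' from the cohort are omitted rather than reported as 0/0.
#'
#' @param reports a `DetectionReport` or a list of them.
#' @return data.frame with `site`, `detected`, `total`, `sensitivity`
#'   (percent).
#' @export
subgroupSensitivity <- function(reports) {
    if (inherits(reports, "DetectionReport")) reports <- list(reports)
    les <- do.call(rbind, lapply(reports, function(r) r$lesions))
    if (is.null(les) || nrow(les) == 0)
        return(data.frame(site = character(0), detected = integer(0),
                          total = integer(0), sensitivity = numeric(0),
                          stringsAsFactors = FALSE))
    site <- factor(les$site, levels = LESION_SITES)
    det <- tapply(les$detected, site, sum)
    tot <- tapply(rep(1L, nrow(les)), site, sum)
    keep <- !is.na(tot) & tot > 0
    out <- data.frame(site = names(tot)[keep],
                      detected = as.integer(det[keep]),
                      total = as.integer(tot[keep]),
                      stringsAsFactors = FALSE)
    out <- rbind(out, data.frame(site = "overall",
                                 detected = sum(les$detected),
                                 total = nrow(les),
                                 stringsAsFactors = FALSE))
    out$sensitivity <- 100 * out$detected / out$total
    out
}

#' Compare paired per-scan metrics between two raters or models
#'
#' For scans assessed by two sources (for example an automated model and a
#' second human observer, both scored against the same reference), reports
#' per-metric medians and a two-sided Wilcoxon signed-rank p-value on the
#' paired per-scan differences. Pairs with zero difference are dropped by the
#' signed-rank test; when every difference is zero the comparison is flagged
#' degenerate and p = 1.
#'
#' @param a,b data.frames with a `scan_id` column and one column per metric;
#'   the same scan ids must be present in both (order-free), n >= 5.
#' @return data.frame with `metric`, `median_a`, `median_b`, `p_value`,
#'   `degenerate`.
#' @export
pairedObserverComparison <- function(a, b) {
    stopifnot(is.data.frame(a), is.data.frame(b),
              "scan_id" %in% names(a), "scan_id" %in% names(b))
    if (!setequal(a$scan_id, b$scan_id) || anyDuplicated(a$scan_id) ||
        anyDuplicated(b$scan_id))
        stop("scan ids must pair one-to-one between the two sets",
             call. = FALSE)
    if (nrow(a) < 5)
        stop("need at least 5 paired scans", call. = FALSE)
    b <- b[match(a$scan_id, b$scan_id), , drop = FALSE]
    metrics <- intersect(setdiff(names(a), "scan_id"),
                         setdiff(names(b), "scan_id"))
    do.call(rbind, lapply(metrics, function(mname) {
        d <- a[[mname]] - b[[mname]]
        degenerate <- all(d == 0)
        p <- if (degenerate) 1 else wilcoxonSignedRank(d)$p_value
        data.frame(metric = mname,
                   median_a = stats::median(a[[mname]]),
                   median_b = stats::median(b[[mname]]),
                   p_value = p, degenerate = degenerate,
                   stringsAsFactors = FALSE)
    }))
}
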