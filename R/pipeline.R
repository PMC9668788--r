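#' End-to-end run configuration
#'
#' Bundles the stage configurations for a full simulate - predict - evaluate -
#' biomarkers - survival run. A single master seed fans out deterministically
#' to per-stage and per-scan sub-seeds. The prediction source is either the
#' corruption model applied to the ground truth (`predictor = "corruption"`,
#' the controlled-error mode) or the bundled SUV-threshold baseline segmenter
#' with physiologic exclusion (`predictor = "threshold"`).
#'
#' @param phantom a [phantomConfig()].
#' @param corruption a [corruptionConfig()].
#' @param survival_sim a [survivalSimConfig()].
#' @param n_scans cohort size (default 128, with the configured negative
#'   fraction).
#' @param tau lesion-detection overlap threshold (default 0.10).
#' @param connectivity cluster connectivity (default 26).
#' @param suv_threshold SUV threshold of the baseline segmenter.
#' @param predictor `"corruption"` or `"threshold"`.
#' @param tau_grid thresholds for the detection sweep table.
#' @param seed master seed.
#' @return list of class `RunConfig`.
#' @export
runConfig <- function(phantom = phantomConfig(),
                      corruption = corruptionConfig(),
                      survival_sim = survivalSimConfig(),
                      n_scans = 128, tau = 0.10, connectivity = 26,
                      suv_threshold = 3,
                      predictor = c("corruption", "threshold"),
                      tau_grid = seq(0.05, 0.95, by = 0.05),
                      seed = 1) {
    predictor <- match.arg(predictor)
    stopifnot(inherits(phantom, "PhantomConfig"),
              inherits(corruption, "CorruptionConfig"),
              inherits(survival_sim, "SurvivalSimConfig"),
              n_scans >= 2, tau > 0, tau <= 1)
    structure(list(phantom = phantom, corruption = corruption,
                   survival_sim = survival_sim, n_scans = n_scans,
                   tau = tau, connectivity = connectivity,
                   suv_threshold = suv_threshold, predictor = predictor,
                   tau_grid = tau_grid, seed = seed),
              class = "RunConfig")
}

#' Run the full assessment pipeline on a synthetic cohort
#'
#' Generates the phantom cohort scan by scan, produces a prediction for each
#' (corrupted ground truth or threshold baseline), evaluates at the patient,
#' lesion and voxel levels, computes TLV/TLU biomarkers from both the
#' prediction ("auto") and the ground truth ("manual" stand-in), simulates
#' survival tied to the ground-truth burden, and stratifies survival by the
#' automated biomarkers. Writes machine-readable CSV/JSON results to
#' `out_dir` and returns them. Identical config + seed gives identical
#' outputs.
#'
#' @param config a [runConfig()].
#' @param out_dir output directory (created); `NULL` skips writing.
#' @param verbose print stage progress.
#' @return list with `manifest`, `scan_table` (per-scan calls and voxel
#'   metrics), `lesion_table` (per-lesion matches), `patient_metrics`,
#'   `lesion_metrics`, `subgroup`, `voxel_summary`, `biomarkers`,
#'   `biomarker_comparison`, `survival` (records + stratifications),
#'   `sweep`, `fp_per_scan`.
#' @export
runPipeline <- function(config, out_dir = NULL, verbose = FALSE) {
    stopifnot(inherits(config, "RunConfig"))
    say <- function(...) if (verbose) message(...)
    plan <- cohortPlan(config$phantom, config$n_scans, config$seed)

    scan_rows <- list()
    lesion_rows <- list()
    bio_auto <- list()
    bio_manual <- list()
    say("stage simulate+evaluate: ", nrow(plan), " scans")
    for (i in seq_len(nrow(plan))) {
        sc <- generateScan(config$phantom, positive = plan$positive[i],
                           seed = plan$seed_scan[i],
                           patient_id = plan$patient_id[i])
        pred <- switch(config$predictor,
            corruption = corruptPrediction(sc$gt, config$corruption,
                                           seed = plan$seed_corrupt[i]),
            threshold = excludePhysiologic(
                globalThresholdSegment(sc$pet, config$suv_threshold,
                                       config$connectivity),
                sc$physiologic))
        cls <- classifyScan(sc$gt, pred, tau = config$tau,
                            connectivity = config$connectivity)
        rep <- matchLesions(sc$gt, pred, tau = config$tau,
                            connectivity = config$connectivity)
        vox <- if (cls$gt_status == "positive")
            voxelMetrics(sc$gt, pred) else NULL
        scan_rows[[i]] <- data.frame(
            scan_id = plan$scan_id[i], patient_id = plan$patient_id[i],
            psma_status = cls$gt_status, call = cls$call,
            n_lesions = rep$n_lesions, n_detected = rep$n_detected,
            fp_clusters = rep$fp_cluster_count,
            n_pred_voxels = cls$n_pred_voxels,
            dsc = if (is.null(vox)) NA_real_ else vox$dsc,
            vox_sensitivity = if (is.null(vox)) NA_real_
                              else vox$sensitivity,
            vox_ppv = if (is.null(vox)) NA_real_ else vox$ppv,
            vox_specificity = if (is.null(vox)) NA_real_
                              else vox$specificity,
            stringsAsFactors = FALSE)
        if (nrow(rep$lesions))
            lesion_rows[[i]] <- cbind(scan_id = plan$scan_id[i],
                                      rep$lesions,
                                      stringsAsFactors = FALSE)
        bio_auto[[i]] <- cbind(biomarkerRecord(plan$scan_id[i], pred,
                                               sc$pet, "auto"),
                               patient_id = plan$patient_id[i],
                               psma_status = cls$gt_status,
                               stringsAsFactors = FALSE)
        bio_manual[[i]] <- cbind(biomarkerRecord(plan$scan_id[i], sc$gt,
                                                 sc$pet, "manual"),
                                 patient_id = plan$patient_id[i],
                                 psma_status = cls$gt_status,
                                 stringsAsFactors = FALSE)
    }
    scan_table <- do.call(rbind, scan_rows)
    lesion_table <- do.call(rbind, lesion_rows)
    if (is.null(lesion_table))
        lesion_table <- data.frame(scan_id = character(0))
    auto <- do.call(rbind, bio_auto)
    manual <- do.call(rbind, bio_manual)

    say("stage summarise")
    calls <- table(factor(scan_table$call, levels = c("tp", "fp", "tn",
                                                      "fn")))
    patient_metrics <- confusionMetrics(tp = calls[["tp"]],
                                        fp = calls[["fp"]],
                                        tn = calls[["tn"]],
                                        fn = calls[["fn"]])
    nles <- sum(scan_table$n_lesions)
    ndet <- sum(scan_table$n_detected)
    nfp <- sum(scan_table$fp_clusters)
    lesion_metrics <- list(
        sensitivity = if (nles > 0) 100 * ndet / nles else NA_real_,
        ppv = if (ndet + nfp > 0) 100 * ndet / (ndet + nfp) else NA_real_,
        n_lesions = nles, n_detected = ndet, fp_clusters = nfp)
    lesion_metrics$f1 <- if (!is.na(lesion_metrics$sensitivity) &&
                             !is.na(lesion_metrics$ppv) &&
                             lesion_metrics$sensitivity +
                             lesion_metrics$ppv > 0)
        f1Score(lesion_metrics$ppv, lesion_metrics$sensitivity) else NA_real_

    pos <- scan_table$psma_status == "positive"
    fp_per_scan <- list(
        all = nfp / nrow(scan_table),
        positive = if (any(pos)) sum(scan_table$fp_clusters[pos]) / sum(pos)
                   else NA_real_,
        negative = if (any(!pos))
            sum(scan_table$fp_clusters[!pos]) / sum(!pos) else NA_real_)

    vox_cols <- c("dsc", "vox_sensitivity", "vox_ppv", "vox_specificity")
    vm <- scan_table[pos, vox_cols, drop = FALSE]
    voxel_summary <- data.frame(
        metric = vox_cols,
        mean = vapply(vm, mean, numeric(1), na.rm = TRUE),
        sd = vapply(vm, stats::sd, numeric(1)),
        median = vapply(vm, stats::median, numeric(1), na.rm = TRUE),
        row.names = NULL)

    subgroup <- if (nrow(lesion_table) > 0) {
        reports <- list(list(lesions = lesion_table))
        class(reports[[1]]) <- "DetectionReport"
        subgroupSensitivity(reports)
    } else data.frame()

    biomarker_comparison <- compareBiomarkers(
        auto[, c("scan_id", "tlv_cm3", "tlu")],
        manual[, c("scan_id", "tlv_cm3", "tlu")])

    say("stage survival")
    surv_records <- simulateSurvival(
        data.frame(patient_id = manual$patient_id,
                   tlv_cm3 = manual$tlv_cm3, tlu = manual$tlu,
                   psma_status = manual$psma_status,
                   stringsAsFactors = FALSE),
        config$survival_sim, seed = subSeed(config$seed, 999983))
    # stratify on the automated biomarkers
    strat_records <- surv_records
    strat_records$tlv_cm3 <- auto$tlv_cm3
    strat_records$tlu <- auto$tlu
    ticks <- seq(0, config$survival_sim$horizon_months, by = 20)
    strat <- list(
        tlu_median_all = tryStratify(strat_records, "tlu", "median_split",
                                     "all", ticks),
        tlv_median_all = tryStratify(strat_records, "tlv", "median_split",
                                     "all", ticks),
        tlu_q1q4_pos = tryStratify(strat_records, "tlu", "q1_vs_q4",
                                   "psma_positive", ticks),
        tlv_q1q4_pos = tryStratify(strat_records, "tlv", "q1_vs_q4",
                                   "psma_positive", ticks))

    say("stage sweep")
    sweep <- sweepFromTables(scan_table, lesion_table, config$tau_grid)

    results <- list(manifest = plan, scan_table = scan_table,
                    lesion_table = lesion_table,
                    patient_metrics = patient_metrics,
                    lesion_metrics = lesion_metrics,
                    subgroup = subgroup, voxel_summary = voxel_summary,
                    biomarkers = rbind(auto, manual),
                    biomarker_comparison = biomarker_comparison,
                    survival = list(records = surv_records,
                                    stratifications = strat),
                    sweep = sweep, fp_per_scan = fp_per_scan,
                    config_digest = configDigest(config))
    if (!is.null(out_dir)) writeRunDir(results, out_dir)
    results
}

tryStratify <- function(records, biomarker, rule, subset, ticks) {
    tryCatch(stratifySurvival(records, biomarker, rule, subset, ticks),
             error = function(e) structure(list(error = conditionMessage(e)),
                                           class = "StratifiedComparison"))
}

# Recompute the tau sweep from stored per-scan/per-lesion tables: overlap
# fractions and FP counts do not depend on tau.
sweepFromTables <- function(scan_table, lesion_table, tau_grid) {
    do.call(rbind, lapply(tau_grid, function(tau) {
        if (nrow(lesion_table) > 0) {
            det_by_scan <- tapply(lesion_table$overlap_fraction >= tau,
                                  lesion_table$scan_id, sum)
            ndet <- sum(lesion_table$overlap_fraction >= tau)
            nles <- nrow(lesion_table)
        } else {
            det_by_scan <- integer(0)
            ndet <- 0
            nles <- 0
        }
        det <- rep(0, nrow(scan_table))
        names(det) <- scan_table$scan_id
        det[names(det_by_scan)] <- det_by_scan
        pos <- scan_table$psma_status == "positive"
        nfp <- sum(scan_table$fp_clusters)
        cm <- confusionMetrics(
            tp = sum(pos & det >= 1), fn = sum(pos & det == 0),
            tn = sum(!pos & scan_table$n_pred_voxels == 0),
            fp = sum(!pos & scan_table$n_pred_voxels > 0))
        sens <- if (nles > 0) 100 * ndet / nles else NA_real_
        ppv <- if (ndet + nfp > 0) 100 * ndet / (ndet + nfp) else NA_real_
        data.frame(tau = tau, lesion_sensitivity = sens, lesion_ppv = ppv,
                   lesion_f1 = if (!is.na(sens) && !is.na(ppv) &&
                                   sens + ppv > 0) f1Score(ppv, sens)
                               else NA_real_,
                   patient_accuracy = cm$accuracy,
                   patient_sensitivity = cm$sensitivity,
                   patient_ppv = cm$ppv,
                   patient_specificity = cm$specificity,
                   patient_npv = cm$npv)
    }))
}

configDigest <- function(config) {
    # order-stable flat rendering of the configuration tree
    flat <- unlist(config, use.names = TRUE)
    paste0("n=", length(flat), ";",
           paste(names(flat), vapply(flat, function(v)
               format(v, digits = 15), character(1)),
               sep = "=", collapse = ";"))
}

writeRunDir <- function(results, out_dir) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wcsv <- function(df, name)
        utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
    wcsv(results$manifest, "manifest.csv")
    wcsv(results$scan_table, "scan_metrics.csv")
    if (nrow(results$lesion_table)) wcsv(results$lesion_table,
                                         "lesion_matches.csv")
    wcsv(results$voxel_summary, "voxel_summary.csv")
    if (nrow(results$subgroup)) wcsv(results$subgroup,
                                     "subgroup_sensitivity.csv")
    wcsv(results$biomarkers, "biomarkers.csv")
    wcsv(results$survival$records, "survival_records.csv")
    wcsv(results$sweep, "sweep.csv")
    summ <- list(
        patient_level = results$patient_metrics[
            c("accuracy", "sensitivity", "ppv", "specificity", "npv")],
        patient_counts = results$patient_metrics$counts,
        lesion_level = results$lesion_metrics,
        fp_per_scan = results$fp_per_scan,
        stratifications = lapply(results$survival$stratifications,
                                 function(s) {
            if (!is.null(s$error)) return(list(error = s$error))
            list(biomarker = s$biomarker, rule = s$rule, subset = s$subset,
                 chisq = s$chisq, p_value = s$p_value,
                 p_display = s$p_display,
                 group_sizes = as.list(s$group_sizes))
        }),
        config_digest = results$config_digest)
    jsonlite::write_json(summ, file.path(out_dir, "cohort_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(out_dir)
}

#' Format a metric with its raw counts
#'
#' Renders a percentage alongside the counts it was computed from in the
#' conventional `"93.3 (70/75)"` form (half-up rounding to one decimal).
#'
#' @param num,den numerator and denominator counts.
#' @return character.
#' @examples
#' formatCountPct(70, 75)  # "93.3 (70/75)"
#' @export
formatCountPct <- function(num, den) {
    if (den == 0) return(sprintf("NA (%d/%d)", num, den))
    sprintf("%.1f (%d/%d)", roundHalfUp(100 * num / den, 1), num, den)
}

#' Summary tables for a completed run
#'
#' Reads a run directory written by [runPipeline()] and renders the
#' three-level performance summary (patient-level classification, lesion-level
#' detection with per-site sub-groups, voxel-level segmentation) with counts
#' printed alongside percentages, plus the tidy detection-threshold sweep
#' table (one row per tau, level, metric).
#'
#' @param run_dir a directory written by [runPipeline()].
#' @return list with `performance` (data.frame `task`, `metric`, `value`) and
#'   `sweep_tidy` (data.frame `tau`, `level`, `metric`, `value`).
#' @export
reportTables <- function(run_dir) {
    need <- c("scan_metrics.csv", "cohort_summary.json", "sweep.csv")
    for (f in need)
        if (!file.exists(file.path(run_dir, f)))
            stop("incomplete run directory: missing ", f, call. = FALSE)
    summ <- jsonlite::read_json(file.path(run_dir, "cohort_summary.json"),
                                simplifyVector = TRUE)
    if (length(summ$patient_counts) == 0 ||
        sum(unlist(summ$patient_counts)) == 0)
        stop("empty cohort", call. = FALSE)
    cc <- summ$patient_counts
    lm <- summ$lesion_level
    rows <- list(
        c("Patient-level classification", "Accuracy (%)",
          formatCountPct(cc$tp + cc$tn, cc$tp + cc$tn + cc$fp + cc$fn)),
        c("Patient-level classification", "Sensitivity (%)",
          formatCountPct(cc$tp, cc$tp + cc$fn)),
        c("Patient-level classification", "PPV (%)",
          formatCountPct(cc$tp, cc$tp + cc$fp)),
        c("Patient-level classification", "Specificity (%)",
          formatCountPct(cc$tn, cc$tn + cc$fp)),
        c("Patient-level classification", "NPV (%)",
          formatCountPct(cc$tn, cc$tn + cc$fn)),
        c("Lesion-level detection", "PPV (%)",
          formatCountPct(lm$n_detected, lm$n_detected + lm$fp_clusters)),
        c("Lesion-level detection", "Sensitivity (%)",
          formatCountPct(lm$n_detected, lm$n_lesions)),
        c("Lesion-level detection", "F1 score (%)",
          sprintf("%.1f", roundHalfUp(lm$f1, 1))))
    sg_path <- file.path(run_dir, "subgroup_sensitivity.csv")
    if (file.exists(sg_path)) {
        sg <- utils::read.csv(sg_path, stringsAsFactors = FALSE)
        sg <- sg[sg$site != "overall", , drop = FALSE]
        for (i in seq_len(nrow(sg)))
            rows[[length(rows) + 1]] <-
                c("Lesion sub-groups detection",
                  paste0(sg$site[i], " sensitivity (%)"),
                  formatCountPct(sg$detected[i], sg$total[i]))
    }
    vs <- utils::read.csv(file.path(run_dir, "voxel_summary.csv"),
                          stringsAsFactors = FALSE)
    lab <- c(dsc = "DSC", vox_sensitivity = "Sensitivity",
             vox_ppv = "PPV", vox_specificity = "Specificity")
    for (i in seq_len(nrow(vs)))
        rows[[length(rows) + 1]] <-
            c("Voxel-level segmentation",
              paste0(lab[[vs$metric[i]]], " (mean ± SD)"),
              sprintf("%.1f ± %.1f", roundHalfUp(vs$mean[i], 1),
                      roundHalfUp(vs$sd[i], 1)))
    performance <- as.data.frame(do.call(rbind, rows),
                                 stringsAsFactors = FALSE)
    names(performance) <- c("task", "metric", "value")

    sweep <- utils::read.csv(file.path(run_dir, "sweep.csv"),
                             stringsAsFactors = FALSE)
    long <- do.call(rbind, lapply(setdiff(names(sweep), "tau"),
                                  function(mn) {
        level <- if (startsWith(mn, "lesion")) "lesion" else "patient"
        data.frame(tau = sweep$tau, level = level,
                   metric = sub("^(lesion|patient)_", "", mn),
                   value = sweep[[mn]], stringsAsFactors = FALSE)
    }))
    list(performance = performance, sweep_tidy = long)
}
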