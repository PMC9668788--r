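# Toy fixture: 16^3 grid, lesion A = 3x3x3 = 27 voxels, lesion B = 4x4x4 =
# 64 voxels, prediction covering 3/27 of A and 40/64 of B plus a 5-voxel
# cluster disjoint from both.
toyTwoLesion <- function() {
    lab <- array(0L, c(16, 16, 16))
    lab[2:4, 2:4, 2:4] <- 1L
    lab[9:12, 9:12, 9:12] <- 2L
    pred <- array(FALSE, c(16, 16, 16))
    pred[2:4, 2, 2] <- TRUE                      # 3 voxels inside A
    pred[9:12, 9:12, 9:11] <- TRUE               # 48 -> trim to 40
    pred[9:12, 9:10, 11] <- FALSE                # now 40 voxels inside B
    pred[14:16, 2, 14] <- TRUE; pred[14:15, 3, 14] <- TRUE  # 5-voxel FP
    gt <- LabelledMask(lab, siteByLabel = c("1" = "local_prostate",
                                            "2" = "osseous"))
    list(gt = gt, pred = BinaryMask(pred))
}

test_that("perfect prediction detects everything with no FP clusters", {
    t <- toyTwoLesion()
    rep <- matchLesions(t$gt, asBinaryMask(t$gt))
    expect_true(all(rep$lesions$detected))
    expect_equal(rep$fp_cluster_count, 0)
    expect_equal(rep$sensitivity, 100)
})

test_that("the 10%-overlap detection boundary is inclusive", {
    lab <- array(0L, c(20, 20, 20))
    lab[1:10, 1:10, 1:10] <- 1L                  # 1000-voxel lesion
    gt <- LabelledMask(lab)
    pred <- array(FALSE, c(20, 20, 20))
    pred[1:10, 1:10, 1] <- TRUE                  # 100 interior voxels
    pm <- BinaryMask(pred)
    r10 <- matchLesions(gt, pm, tau = 0.10)
    expect_equal(r10$lesions$overlap_fraction, 0.100)
    expect_true(r10$lesions$detected)
    r101 <- matchLesions(gt, pm, tau = 0.101)
    expect_false(r101$lesions$detected)
    expect_error(matchLesions(gt, pm, tau = 0), "tau")
})

test_that("two-lesion toy example reproduces brute-force set arithmetic", {
    t <- toyTwoLesion()
    rep <- matchLesions(t$gt, t$pred, tau = 0.10)
    expect_equal(rep$lesions$overlap_fraction, c(3 / 27, 40 / 64))
    expect_identical(rep$lesions$detected, c(TRUE, TRUE))
    rep2 <- matchLesions(t$gt, t$pred, tau = 0.2)
    expect_identical(rep2$lesions$detected, c(FALSE, TRUE))
    expect_equal(rep2$fp_cluster_count, 1)
    expect_equal(rep2$sensitivity, 50)
    expect_equal(rep2$ppv, 100 * 1 / (1 + 1))
    # against the exhaustive oracle
    br <- bruteMatch(maskLabels(t$gt), maskMembership(t$pred), 0.2, 26)
    expect_equal(rep2$lesions$overlap_fraction, br$frac)
    expect_equal(rep2$fp_cluster_count, br$fp)
})

test_that("scan classification follows the single-voxel negative rule", {
    empty <- LabelledMask(array(0L, c(8, 8, 8)))
    one_voxel <- array(FALSE, c(8, 8, 8)); one_voxel[4, 4, 4] <- TRUE
    expect_equal(classifyScan(empty, BinaryMask(one_voxel))$call, "fp")
    expect_equal(classifyScan(empty,
                              BinaryMask(array(FALSE, c(8, 8, 8))))$call,
                 "tn")
    # positive scan, prediction non-empty but every overlap below tau -> fn
    lab <- array(0L, c(8, 8, 8)); lab[1:5, 1:5, 1:5] <- 1L   # 125 voxels
    gt <- LabelledMask(lab)
    pred <- array(FALSE, c(8, 8, 8))
    pred[1:3, 1, 1] <- TRUE; pred[8, 8, 8] <- TRUE           # 3/125 < 10%
    expect_equal(classifyScan(gt, BinaryMask(pred))$call, "fn")
    expect_equal(classifyScan(gt, asBinaryMask(gt))$call, "tp")
})

test_that("voxel metrics implement the DSC/sensitivity/PPV formulas", {
    A <- array(FALSE, c(6, 6, 6)); A[1:6] <- TRUE
    gt <- BinaryMask(A)
    expect_equal(voxelMetrics(gt, gt)$dsc, 100)
    B <- array(FALSE, c(6, 6, 6)); B[20:23] <- TRUE
    expect_equal(voxelMetrics(gt, BinaryMask(B))$dsc, 0)
    # |A|=6, |B|=4, |A.B|=3
    B2 <- array(FALSE, c(6, 6, 6)); B2[4:7] <- TRUE
    vm <- voxelMetrics(gt, BinaryMask(B2))
    expect_equal(vm$dsc, 60)
    expect_equal(vm$sensitivity, 50)
    expect_equal(vm$ppv, 75)
    expect_error(voxelMetrics(BinaryMask(array(FALSE, c(6, 6, 6))),
                              BinaryMask(B2)), "empty ground truth")
    # DSC is symmetric
    for (seed in 1:3) {
        x <- BinaryMask(randomMask(c(7, 7, 7), 0.3, seed))
        y <- BinaryMask(randomMask(c(7, 7, 7), 0.3, seed + 50))
        expect_equal(voxelMetrics(x, y)$dsc, voxelMetrics(y, x)$dsc)
    }
})

test_that("confusion metrics reproduce printed test-set percentages from
           raw counts", {
    pm <- confusionMetrics(tp = 70, fn = 5, tn = 51, fp = 2)
    expect_equal(roundHalfUp(pm$accuracy), 94.5)
    expect_equal(roundHalfUp(pm$sensitivity), 93.3)
    expect_equal(roundHalfUp(pm$ppv), 97.2)
    expect_equal(roundHalfUp(pm$specificity), 96.2)
    expect_equal(roundHalfUp(pm$npv), 91.1)
    lm <- confusionMetrics(tp = 224, fn = 307 - 224, fp = 254 - 224, tn = 0)
    expect_equal(roundHalfUp(lm$sensitivity), 73.0)
    expect_equal(roundHalfUp(lm$ppv), 88.2)
    all1 <- confusionMetrics(tp = 1, fn = 0, tn = 1, fp = 0)
    expect_equal(all1$accuracy, 100)
    expect_equal(all1$sensitivity, 100)
    expect_equal(all1$npv, 100)
    und <- confusionMetrics(tp = 0, fn = 0, tn = 3, fp = 1)
    expect_true(is.na(und$sensitivity))   # no positives to detect
    expect_error(confusionMetrics(tp = -1, fn = 0, tn = 0, fp = 0),
                 "non-negative")
})

test_that("F1 is the harmonic mean of PPV and sensitivity", {
    expect_equal(roundHalfUp(f1Score(88.2, 73.0)), 79.9)
    expect_equal(roundHalfUp(f1Score(91.7, 71.7)), 80.5)
    for (x in c(5, 50, 99.5)) expect_equal(f1Score(x, x), x)
    expect_error(f1Score(0, 0), "undefined")
    expect_error(f1Score(101, 50), "\\[0, 100\\]")
})

test_that("threshold sweep matches single-tau evaluation and is monotone", {
    t <- toyTwoLesion()
    sw <- thresholdSweep(t$gt, t$pred, tau_grid = 0.10)
    r <- matchLesions(t$gt, t$pred, tau = 0.10)
    expect_equal(sw$lesion_sensitivity, r$sensitivity)
    expect_equal(sw$lesion_ppv, r$ppv)
    # overlap fractions are 3/27 ~ 0.111 and 40/64 = 0.625
    sw2 <- thresholdSweep(t$gt, t$pred, tau_grid = c(0.05, 0.70))
    expect_equal(sw2$lesion_sensitivity, c(100, 0))
    grid <- seq(0.01, 1, length.out = 100)
    sw3 <- thresholdSweep(t$gt, t$pred, tau_grid = grid)
    expect_true(all(diff(sw3$lesion_sensitivity) <= 1e-12))
    expect_error(thresholdSweep(t$gt, t$pred, numeric(0)), "non-empty")
})

test_that("per-site sensitivity aggregates detections and omits absent
           sites", {
    t <- toyTwoLesion()
    all_det <- matchLesions(t$gt, asBinaryMask(t$gt))
    tab <- subgroupSensitivity(all_det)
    expect_true(all(tab$sensitivity == 100))
    expect_setequal(tab$site, c("local_prostate", "osseous", "overall"))
    expect_false("visceral" %in% tab$site)
    part <- matchLesions(t$gt, t$pred, tau = 0.2)  # A missed, B detected
    tab2 <- subgroupSensitivity(part)
    expect_equal(tab2$sensitivity[tab2$site == "local_prostate"], 0)
    expect_equal(tab2$sensitivity[tab2$site == "osseous"], 100)
    expect_equal(tab2$sensitivity[tab2$site == "overall"], 50)
})

test_that("paired observer comparison: degenerate equality, real shift,
           pairing errors", {
    a <- data.frame(scan_id = sprintf("s%02d", 1:20),
                    dsc = seq(30, 68, by = 2))
    expect_equal(pairedObserverComparison(a, a)$p_value, 1)
    expect_true(pairedObserverComparison(a, a)$degenerate)
    b <- a; b$dsc <- b$dsc - 5     # constant positive shift on 20 scans
    res <- pairedObserverComparison(a, b)
    expect_lt(res$p_value, 0.005)
    expect_equal(res$median_a - res$median_b, 5)
    bad <- b; bad$scan_id[1] <- "zz"
    expect_error(pairedObserverComparison(a, bad), "pair")
})
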