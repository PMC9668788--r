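test_that("negative scans have empty ground truth but hot physiologic
           organs", {
    sc <- generateScan(smallPhantom(), positive = FALSE, seed = 5)
    expect_length(labelIds(sc$gt), 0)
    expect_gt(sum(maskMembership(sc$physiologic)), 0)
    expect_equal(sc$meta$psma_status, "negative")
    # physiologic organs are genuinely hot (SUV in [5, 30])
    pv <- voxelValues(sc$pet)[maskMembership(sc$physiologic)]
    expect_gt(stats::median(pv), 4)
})

test_that("a fixed lesion count yields exactly that many labelled,
           site-tagged lesions with peak SUV above threshold", {
    sc <- generateScan(smallPhantom(lesions_fixed = 3), positive = TRUE,
                       seed = 9)
    expect_length(labelIds(sc$gt), 3)
    expect_length(stats::na.omit(siteByLabel(sc$gt)), 3)
    expect_equal(nrow(sc$lesion_table), 3)
    expect_true(all(sc$lesion_table$peak_suv > 3))
    # lesion voxels never overlap physiologic organs
    expect_equal(sum(maskMembership(sc$gt) &
                     maskMembership(sc$physiologic)), 0)
})

test_that("generation is bit-identical under a fixed seed", {
    cfg <- smallPhantom()
    a <- generateScan(cfg, positive = TRUE, seed = 42)
    b <- generateScan(cfg, positive = TRUE, seed = 42)
    expect_identical(voxelValues(a$pet), voxelValues(b$pet))
    expect_identical(maskLabels(a$gt), maskLabels(b$gt))
    expect_identical(a$lesion_table, b$lesion_table)
    expect_identical(a$meta, b$meta)
    c <- generateScan(cfg, positive = TRUE, seed = 43)
    expect_false(identical(voxelValues(a$pet), voxelValues(c$pet)))
})

test_that("osseous lesions sit in high-HU bone voxels", {
    cfg <- smallPhantom(lesions_fixed = 6)
    found <- 0
    for (seed in 1:6) {
        sc <- generateScan(cfg, positive = TRUE, seed = seed)
        oss <- sc$lesion_table[sc$lesion_table$site == "osseous", ]
        if (nrow(oss) == 0) next
        found <- found + nrow(oss)
        for (l in oss$label) {
            hu <- voxelValues(sc$ct)[maskLabels(sc$gt) == l]
            expect_gte(stats::median(hu), 700)
        }
    }
    expect_gt(found, 0)
})

test_that("CT on its own coarser grid resamples consistently onto PET", {
    cfg <- smallPhantom(ct_spacing = c(1.52, 1.52, 5) * 2)
    sc <- generateScan(cfg, positive = FALSE, seed = 13)
    expect_false(identical(gridShape(sc$ct), gridShape(sc$pet)))
    ct_on_pet <- resampleToGrid(sc$ct, sc$pet, mode = "nearest")
    expect_identical(gridShape(ct_on_pet), gridShape(sc$pet))
    expect_setequal(unique(as.vector(voxelValues(ct_on_pet))),
                    c(-1000, 40, 700))
})

test_that("corruption: identity, total miss, and exact partial overlap", {
    sc <- generateScan(smallPhantom(lesions_fixed = 4), positive = TRUE,
                       seed = 17)
    ident <- corruptPrediction(sc$gt, corruptionConfig(), seed = 1)
    expect_identical(maskMembership(ident), maskMembership(sc$gt))
    gone <- corruptPrediction(sc$gt, corruptionConfig(drop_prob = 1),
                              seed = 1)
    expect_equal(sum(maskMembership(gone)), 0)
    expect_error(corruptionConfig(overlap_fraction = 1.2), "<= 1")
    # exact ceil(f * volume) voxels, all inside the lesion, contiguous
    lab <- array(0L, c(20, 20, 20)); lab[6:15, 6:15, 6:15] <- 1L  # 1000
    gt1 <- LabelledMask(lab)
    part <- corruptPrediction(gt1,
                              corruptionConfig(overlap_fraction = 0.10),
                              seed = 2)
    expect_equal(sum(maskMembership(part)), 100)
    expect_equal(sum(maskMembership(part) & lab == 1L), 100)
    expect_length(labelIds(connectedComponents(part, 6)), 1)
    r <- matchLesions(gt1, part, tau = 0.10)
    expect_true(r$lesions$detected)
    expect_equal(r$lesions$overlap_fraction, 0.1)
})

test_that("injected FP clusters are disjoint from ground truth and
           Poisson-like in count", {
    sc <- generateScan(smallPhantom(lesions_fixed = 3), positive = TRUE,
                       seed = 23)
    counts <- integer(60)
    for (i in seq_along(counts)) {
        pred <- corruptPrediction(sc$gt,
                                  corruptionConfig(fp_rate = 1.0),
                                  seed = 1000 + i)
        rep <- matchLesions(sc$gt, pred)
        counts[i] <- rep$fp_cluster_count
        expect_equal(rep$sensitivity, 100)  # FP never eats the lesions
    }
    # mean within 3 SE of the configured rate
    expect_lt(abs(mean(counts) - 1.0), 3 * sqrt(1.0 / length(counts)))
})

test_that("boundary morphology erodes and dilates the prediction", {
    lab <- array(0L, c(16, 16, 16)); lab[5:12, 5:12, 5:12] <- 1L
    gt <- LabelledMask(lab)
    er <- corruptPrediction(gt, corruptionConfig(morph_radius = -1),
                            seed = 1)
    expect_equal(sum(maskMembership(er)), 6^3)
    di <- corruptPrediction(gt, corruptionConfig(morph_radius = 1), seed = 1)
    expect_equal(sum(maskMembership(di)), 8^3 + 6 * 8^2)
})

test_that("cohort plan: negative fraction, reproducibility, sub-seed
           fan-out", {
    cfg <- smallPhantom()
    plan <- cohortPlan(cfg, n_scans = 128, seed = 3)
    expect_equal(sum(!plan$positive), round(0.414 * 128))  # 53 negatives
    plan2 <- cohortPlan(cfg, n_scans = 128, seed = 3)
    expect_identical(plan, plan2)
    expect_false(identical(plan$positive,
                           cohortPlan(cfg, 128, seed = 4)$positive))
    expect_true(all(plan$seed_scan < 2^31))
    expect_false(anyDuplicated(c(plan$seed_scan, plan$seed_corrupt)) > 0)
})

test_that("site frequencies follow the configured anatomical mix", {
    cfg <- smallPhantom()
    sites <- character(0)
    for (i in 1:60) {
        sc <- generateScan(cfg, positive = TRUE, seed = 5000 + i)
        sites <- c(sites, sc$lesion_table$site)
    }
    n <- length(sites)
    expect_gt(n, 150)
    p <- cfg$site_probs
    obs <- table(factor(sites, levels = names(p))) / n
    for (s in names(p)) {
        se <- sqrt(p[[s]] * (1 - p[[s]]) / n)
        expect_lt(abs(obs[[s]] - p[[s]]), 3 * se + 1e-9)
    }
})

test_that("survival simulation: null independence, horizon censoring,
           burden effect", {
    bio <- data.frame(patient_id = sprintf("p%03d", 1:500),
                      tlv_cm3 = rlnorm(500, 1, 1))
    # beta = 0: survival unrelated to burden
    rec0 <- simulateSurvival(bio, survivalSimConfig(base_rate = 0.02,
                                                    beta = 0,
                                                    censor_rate = 0),
                             seed = 11)
    rho <- spearmanCorrelation(rec0$tlv_cm3, rec0$time_months)$rho
    expect_lt(abs(rho), 0.1)
    # only the administrative horizon censors: zero hazard -> all censored
    rech <- simulateSurvival(bio[1:20, , drop = FALSE],
                             survivalSimConfig(base_rate = 0, beta = 0,
                                               censor_rate = 0,
                                               horizon_months = 80),
                             seed = 12)
    expect_true(all(rech$time_months == 80))
    expect_true(all(rech$event == 0))
    # strong effect at n = 200: median split separates survival
    bio2 <- data.frame(patient_id = sprintf("q%03d", 1:200),
                       tlv_cm3 = rlnorm(200, 1.5, 1.2))
    rec2 <- simulateSurvival(bio2, survivalSimConfig(base_rate = 0.002,
                                                     beta = 1.5,
                                                     censor_rate = 0.005),
                             seed = 13)
    rec2$tlu <- rec2$tlv_cm3
    st <- stratifySurvival(rec2, "tlv", "median_split", "all")
    expect_lt(st$p_value, 0.05)
    expect_error(simulateSurvival(data.frame(tlv_cm3 = -1),
                                  survivalSimConfig(), 1), "non-negative")
})

test_that("lesion-level sensitivity of corrupted cohorts recovers
           1 - drop probability", {
    cfg <- smallPhantom()
    ccfg <- corruptionConfig(drop_prob = 0.3)
    total <- 0; detected <- 0
    i <- 0
    while (total < 220) {
        i <- i + 1
        sc <- generateScan(cfg, positive = TRUE, seed = 7000 + i)
        pred <- corruptPrediction(sc$gt, ccfg, seed = 8000 + i)
        rep <- matchLesions(sc$gt, pred)
        total <- total + rep$n_lesions
        detected <- detected + rep$n_detected
    }
    p <- detected / total
    se <- sqrt(0.7 * 0.3 / total)
    expect_lt(abs(p - 0.7), 3 * se)
})
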