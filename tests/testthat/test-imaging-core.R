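test_that("NIfTI volume round-trip preserves geometry and values", {
    set.seed(11)
    g <- VolumeGrid(array(rnorm(4 * 5 * 6), c(4, 5, 6)),
                    spacing = c(4.07, 4.07, 2), origin = c(10, -5, 3.5))
    f <- withr::local_tempfile(fileext = ".nii.gz")
    writeVolume(g, f)
    g2 <- readVolume(f)
    expect_identical(gridShape(g2), gridShape(g))
    expect_lt(max(abs(gridSpacing(g2) - c(4.07, 4.07, 2))), 1e-6)
    expect_lt(max(abs(gridOrigin(g2) - c(10, -5, 3.5))), 1e-6)
    expect_equal(voxelValues(g2), voxelValues(g))
})

test_that("non-3D and non-finite volumes are rejected", {
    f <- withr::local_tempfile(fileext = ".nii.gz")
    RNifti::writeNifti(RNifti::asNifti(array(1, c(2, 2, 2, 2))), f)
    expect_error(readVolume(f), "3D")
    expect_error(readVolume(file.path(tempdir(), "no_such_file.nii.gz")),
                 "not found")
    bad <- VolumeGrid(array(c(NaN, rep(1, 7)), c(2, 2, 2)))
    expect_error(writeVolume(bad, withr::local_tempfile(fileext = ".nii")),
                 "non-finite")
})

test_that("mask round-trips keep labels exact and never interpolate", {
    lab <- array(0L, c(5, 5, 5))
    lab[1:3] <- 1L; lab[30:35] <- 2L; lab[100:101] <- 3L
    lm <- LabelledMask(lab, spacing = c(4.07, 4.07, 2),
                       siteByLabel = c("1" = "osseous", "2" = "visceral",
                                       "3" = "local_prostate"))
    f <- withr::local_tempfile(fileext = ".nii.gz")
    writeMask(lm, f)
    lm2 <- readMask(f)
    expect_identical(maskLabels(lm2), maskLabels(lm))
    bin <- BinaryMask(lab > 0, spacing = c(4.07, 4.07, 2))
    writeMask(bin, f)
    b2 <- readMask(f, labelled = FALSE)
    expect_identical(maskMembership(b2), maskMembership(bin))
})

test_that("phantom scans carry the configured PET grid through file IO", {
    sc <- generateScan(phantomConfig(shape = c(16, 16, 24)), positive = FALSE,
                       seed = 3)
    f <- withr::local_tempfile(fileext = ".nii.gz")
    writeVolume(sc$pet, f)
    expect_lt(max(abs(gridSpacing(readVolume(f)) - c(4.07, 4.07, 2))), 1e-6)
})

test_that("SUV_bw conversion follows the decay-corrected body-weight formula", {
    m <- scanMeta("p1", "baseline", body_weight_kg = 70,
                  injected_activity_MBq = 140, delay_min = 0,
                  psma_status = "positive")
    act <- VolumeGrid(array(2000, c(3, 3, 3)))
    expect_equal(unique(as.vector(voxelValues(toSUVbw(act, m)))), 1.0)
    expect_equal(voxelValues(toSUVbw(VolumeGrid(array(0, c(2, 2, 2))), m)),
                 array(0, c(2, 2, 2)))
    # 60 min uptake delay scales the denominator by 2^(-60/67.71)
    m60 <- scanMeta("p1", "baseline", 70, 140, delay_min = 60)
    s60 <- toSUVbw(act, m60)
    expect_equal(unique(as.vector(voxelValues(s60))), 2^(60 / 67.71),
                 tolerance = 1e-12)
    # linearity in the activity
    set.seed(5)
    a <- VolumeGrid(array(runif(27, 0, 5000), c(3, 3, 3)))
    for (cc in c(0, 0.5, 3)) {
        ac <- VolumeGrid(voxelValues(a) * cc)
        expect_equal(voxelValues(toSUVbw(ac, m)),
                     cc * voxelValues(toSUVbw(a, m)), tolerance = 1e-12)
    }
    expect_error(scanMeta("p", "baseline", 0, 140, 0), "body_weight")
    expect_error(scanMeta("p", "baseline", 70, -1, 0), "injected")
})

test_that("voxel volume at the PET reconstruction spacing is 0.0331298 cm^3", {
    g <- VolumeGrid(array(0, c(2, 2, 2)), spacing = c(4.07, 4.07, 2))
    expect_equal(round(voxelVolume(g), 6), 0.033130)
    expect_equal(voxelVolume(g), 4.07 * 4.07 * 2 / 1000, tolerance = 1e-12)
})

test_that("resampling: identity, linear ramp exactness, mask labels", {
    set.seed(7)
    src <- VolumeGrid(array(rnorm(6 * 5 * 4), c(6, 5, 4)),
                      spacing = c(2, 3, 4))
    same <- resampleToGrid(src, src)
    expect_lt(max(abs(voxelValues(same) - voxelValues(src))), 1e-9)
    # cubic interpolation reproduces a linear field exactly at half spacing
    ramp <- VolumeGrid(array(rep(0:7 * 2, 9), c(8, 3, 3)),
                       spacing = c(2, 2, 2))
    tgt <- VolumeGrid(array(0, c(15, 3, 3)), spacing = c(1, 2, 2))
    out <- resampleToGrid(ramp, tgt, mode = "spline")
    expect_lt(max(abs(voxelValues(out)[, 2, 2] - seq(0, 14))), 1e-9)
    # nearest mode keeps masks binary and is idempotent on identity
    mk <- BinaryMask(randomMask(c(6, 5, 4), 0.3, 1), spacing = c(2, 3, 4))
    mr <- resampleToGrid(mk, tgt)
    expect_true(all(maskMembership(mr) %in% c(TRUE, FALSE)))
    twice <- resampleToGrid(resampleToGrid(mk, mk), mk)
    expect_identical(maskMembership(twice), maskMembership(mk))
    expect_error(resampleToGrid(src, VolumeGrid(array(0, c(2, 2, 2)),
                                                spacing = c(1, 1, 1)),
                                fill = 0), NA)
})

test_that("out-of-extent voxels are filled with the source minimum", {
    src <- VolumeGrid(array(5:12, c(2, 2, 2)), spacing = c(1, 1, 1))
    tgt <- VolumeGrid(array(0, c(6, 6, 6)), spacing = c(1, 1, 1),
                      origin = c(-2, -2, -2))
    out <- resampleToGrid(src, tgt, mode = "nearest")
    expect_equal(voxelValues(out)[1, 1, 1], 5)  # min(src)
    out2 <- resampleToGrid(src, tgt, mode = "nearest", fill = -7)
    expect_equal(voxelValues(out2)[1, 1, 1], -7)
})

test_that("connected components: contract cases and label determinism", {
    empty <- BinaryMask(array(FALSE, c(3, 3, 3)))
    expect_length(labelIds(connectedComponents(empty)), 0)
    # face-sharing pair is one cluster under every connectivity
    m <- array(FALSE, c(3, 3, 3)); m[1, 1, 1] <- m[2, 1, 1] <- TRUE
    for (conn in c(6, 18, 26))
        expect_length(labelIds(connectedComponents(BinaryMask(m), conn)), 1)
    # corner-sharing pair: split at 6, joined at 26
    m2 <- array(FALSE, c(2, 2, 2)); m2[1, 1, 1] <- m2[2, 2, 2] <- TRUE
    expect_length(labelIds(connectedComponents(BinaryMask(m2), 6)), 2)
    expect_length(labelIds(connectedComponents(BinaryMask(m2), 26)), 1)
    # edge-sharing pair: split at 6, joined at 18
    m3 <- array(FALSE, c(2, 2, 2)); m3[1, 1, 1] <- m3[2, 2, 1] <- TRUE
    expect_length(labelIds(connectedComponents(BinaryMask(m3), 6)), 2)
    expect_length(labelIds(connectedComponents(BinaryMask(m3), 18)), 1)
    # labels are ordered by the cluster's minimum linear index
    m4 <- array(FALSE, c(5, 1, 1)); m4[c(4, 5)] <- TRUE; m4[1] <- TRUE
    cc <- connectedComponents(BinaryMask(m4), 6)
    expect_identical(as.integer(maskLabels(cc)[c(1, 4, 5)]), c(1L, 2L, 2L))
})

test_that("connected components partition the foreground (property)", {
    for (seed in 1:5) {
        m <- randomMask(c(9, 8, 7), 0.25, seed)
        for (conn in c(6, 18, 26)) {
            cc <- connectedComponents(BinaryMask(m), conn)
            lab <- maskLabels(cc)
            expect_identical(lab > 0L, m)
            k <- length(labelIds(cc))
            if (k > 0)
                expect_identical(sort(unique(lab[lab > 0L])), seq_len(k))
        }
    }
})
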