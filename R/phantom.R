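# Whole-body PET/CT phantom cohorts with known ground truth, controlled
# prediction corruption, and survival times tied to lesion burden.

# Evaluate code under a transient RNG state seeded with `seed`, restoring the
# caller's stream afterwards. All generator randomness flows through this.
withSeed <- function(seed, code) {
    old <- if (exists(".Random.seed", envir = .GlobalEnv))
        get(".Random.seed", envir = .GlobalEnv) else NULL
    on.exit({
        if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
        else if (exists(".Random.seed", envir = .GlobalEnv))
            rm(".Random.seed", envir = .GlobalEnv)
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
    code
}

# Deterministic sub-seed fan-out, kept below 2^31.
subSeed <- function(seed, k) {
    as.integer((as.numeric(seed) * 7919 + as.numeric(k) * 104729 + 1) %%
               2147483629)
}

#' Phantom cohort configuration
#'
#' Defines the study conditions the synthetic whole-body phantoms emulate:
#' the PET reconstruction grid (default 96 x 96 x 256 voxels at
#' 4.07 x 4.07 x 2 mm), a lognormal soft-tissue background (median SUV 0.5,
#' sigma 0.3), physiologic hot organs (bladder, kidneys, liver; SUV in
#' \[5, 30\]), a truncated-Poisson lesion count per positive scan (mean 4.2,
#' >= 1), lesion radii 4-20 mm with peak SUV 3.5-25 and a smooth falloff to
#' background at the boundary, anatomical site frequencies
#' (local prostate 16.02%, regional nodal 21.70%, distant nodal 40.45%,
#' osseous 18.98%, visceral 2.84%; renormalised to sum exactly to 1), and a
#' 41.4% fraction of PSMA-negative scans in cohort generation.
#'
#' @param shape integer(3) PET grid dimensions.
#' @param spacing numeric(3) PET voxel spacing, mm.
#' @param background_median,background_sigma lognormal background SUV
#'   parameters (median, log-sd).
#' @param noise_sd additive Gaussian SUV noise (floored at 0).
#' @param lesions_mean mean of the truncated (>= 1) Poisson lesion count per
#'   positive scan.
#' @param lesions_fixed optional fixed lesion count overriding the Poisson
#'   draw.
#' @param lesion_radius_mm numeric(2) lesion radius range, mm.
#' @param lesion_peak_suv numeric(2) lesion peak SUV range.
#' @param site_probs named numeric(5) anatomical site probabilities
#'   (renormalised to sum to 1).
#' @param negative_fraction fraction of PSMA-negative scans in a cohort.
#' @param ct_spacing numeric(3) CT grid spacing (default: the PET grid).
#' @param max_retries placement retries before a generation error.
#' @return list of class `PhantomConfig`.
#' @export
phantomConfig <- function(shape = c(96, 96, 256),
                          spacing = c(4.07, 4.07, 2),
                          background_median = 0.5, background_sigma = 0.3,
                          noise_sd = 0.1,
                          lesions_mean = 4.2, lesions_fixed = NULL,
                          lesion_radius_mm = c(4, 20),
                          lesion_peak_suv = c(3.5, 25),
                          site_probs = c(local_prostate = 0.1602,
                                         regional_nodal = 0.2170,
                                         distant_nodal = 0.4045,
                                         osseous = 0.1898,
                                         visceral = 0.0284),
                          negative_fraction = 0.414,
                          ct_spacing = NULL,
                          max_retries = 200) {
    stopifnot(length(shape) == 3, all(shape >= 8),
              length(spacing) == 3, all(spacing > 0))
    if (any(diff(lesion_radius_mm) < 0) || any(lesion_radius_mm <= 0))
        stop("lesion_radius_mm must be positive and ordered", call. = FALSE)
    if (any(diff(lesion_peak_suv) < 0) || any(lesion_peak_suv <= 0))
        stop("lesion_peak_suv must be positive and ordered", call. = FALSE)
    if (!setequal(names(site_probs), LESION_SITES))
        stop("site_probs must be named by the five site categories",
             call. = FALSE)
    if (abs(sum(site_probs) - 1) > 1e-3)
        stop("site_probs must sum to 1 (within printed rounding)",
             call. = FALSE)
    site_probs <- site_probs[LESION_SITES] / sum(site_probs)
    if (negative_fraction < 0 || negative_fraction > 1)
        stop("negative_fraction must be in [0, 1]", call. = FALSE)
    structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                   background_median = background_median,
                   background_sigma = background_sigma, noise_sd = noise_sd,
                   lesions_mean = lesions_mean, lesions_fixed = lesions_fixed,
                   lesion_radius_mm = lesion_radius_mm,
                   lesion_peak_suv = lesion_peak_suv,
                   site_probs = site_probs,
                   negative_fraction = negative_fraction,
                   ct_spacing = ct_spacing, max_retries = max_retries),
              class = "PhantomConfig")
}

# Internal anatomy layout in world mm for a given config: body ellipse,
# physiologic organs, spine (bone) cylinder, and per-site placement zones as
# z-axis bands (pelvic / abdominal / thoracic).
phantomAnatomy <- function(config) {
    fov <- config$shape * config$spacing
    cx <- fov[1] / 2
    cy <- fov[2] / 2
    Lz <- fov[3]
    list(
        fov = fov, cx = cx, cy = cy, Lz = Lz,
        body_semi = c(0.40 * fov[1], 0.36 * fov[2]),
        spine = list(x = cx, y = cy + 0.22 * fov[2], r = 16,
                     z = c(0.05, 0.92) * Lz),
        organs = list(
            bladder = list(c = c(cx, cy - 0.08 * fov[2], 0.14 * Lz),
                           r = c(22, 22, 18), suv = 20),
            kidney_l = list(c = c(cx - 0.17 * fov[1], cy, 0.42 * Lz),
                            r = c(18, 14, 28), suv = 12),
            kidney_r = list(c = c(cx + 0.17 * fov[1], cy, 0.42 * Lz),
                            r = c(18, 14, 28), suv = 12),
            liver = list(c = c(cx + 0.15 * fov[1], cy - 0.05 * fov[2],
                               0.56 * Lz),
                         r = c(52, 38, 40), suv = 6)),
        zones = list(
            local_prostate = list(x = cx + c(-25, 25),
                                  y = cy - 0.08 * fov[2] + c(-30, 10),
                                  z = c(0.08, 0.15) * Lz),
            regional_nodal = list(x = cx + c(-1, 1) * 0.30 * fov[1],
                                  y = cy + c(-1, 1) * 0.25 * fov[2],
                                  z = c(0.06, 0.30) * Lz),
            distant_nodal = list(x = cx + c(-1, 1) * 0.30 * fov[1],
                                 y = cy + c(-1, 1) * 0.25 * fov[2],
                                 z = c(0.30, 0.88) * Lz),
            osseous = list(x = cx + c(-8, 8),
                           y = cy + 0.22 * fov[2] + c(-8, 8),
                           z = c(0.08, 0.88) * Lz),
            visceral = list(x = cx + c(-1, 1) * 0.30 * fov[1],
                            y = cy + c(-1, 1) * 0.20 * fov[2],
                            z = c(0.60, 0.86) * Lz)))
}

# World coordinates of voxel centres along each axis.
axisCoords <- function(shape, spacing, origin = c(0, 0, 0)) {
    lapply(1:3, function(a) origin[a] + (seq_len(shape[a]) - 1) * spacing[a])
}

# Linear indices of voxels inside an axis-aligned ellipsoid, plus the
# normalised radius rho of each. Restricted to a bounding box for speed.
ellipsoidVoxels <- function(shape, spacing, centre, radii) {
    lo <- pmax(1L, floor((centre - radii) / spacing) + 1L)
    hi <- pmin(shape, ceiling((centre + radii) / spacing) + 1L)
    if (any(lo > hi)) return(list(idx = integer(0), rho = numeric(0)))
    xs <- (seq(lo[1], hi[1]) - 1) * spacing[1]
    ys <- (seq(lo[2], hi[2]) - 1) * spacing[2]
    zs <- (seq(lo[3], hi[3]) - 1) * spacing[3]
    dx2 <- ((xs - centre[1]) / radii[1])^2
    dy2 <- ((ys - centre[2]) / radii[2])^2
    dz2 <- ((zs - centre[3]) / radii[3])^2
    rho2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
    inside <- which(rho2 <= 1)
    if (length(inside) == 0) return(list(idx = integer(0), rho = numeric(0)))
    arr <- arrayInd(inside, dim(rho2))
    ix <- (lo[1] - 1L + arr[, 1])
    iy <- (lo[2] - 1L + arr[, 2])
    iz <- (lo[3] - 1L + arr[, 3])
    idx <- ix + shape[1] * ((iy - 1L) + shape[2] * (iz - 1L))
    list(idx = as.integer(idx), rho = sqrt(rho2[inside]))
}

# Lesion radial SUV profile: flat core at the peak for rho <= 0.7, cosine
# taper to the background level at the boundary. The flat core guarantees
# that at least ~30% of any lesion's volume sits at its peak SUV, so every
# lesion with peak above an SUV threshold is detectable at the 10%-overlap
# rule by pure thresholding.
lesionTaper <- function(rho, core = 0.7) {
    ifelse(rho <= core, 1, 0.5 * (1 + cos(pi * (rho - core) / (1 - core))))
}

#' Generate one synthetic whole-body PET/CT scan
#'
#' Builds a PET SUV volume with lognormal soft-tissue background, physiologic
#' hot organs, and (for positive scans) spherical lesions with flat-core,
#' cosine-tapered SUV profiles; a CT volume with distinct Hounsfield bands for
#' air (-1000), soft tissue (40) and bone (700, a spine column in which
#' osseous lesions are placed); the ground-truth lesion mask with per-lesion
#' anatomical sites assigned by spatial zone; the physiologic-uptake mask; and
#' scan metadata. Identical `(config, positive, seed)` gives bit-identical
#' output. Lesions never overlap each other or physiologic organs; placement
#' failure after bounded retries raises a generation error.
#'
#' @param config a [phantomConfig()].
#' @param positive logical: does the scan carry lesions (PSMA-positive)?
#' @param seed integer seed for this scan.
#' @param patient_id,timepoint metadata fields.
#' @return list with `pet` ([VolumeGrid-class], SUV_bw), `ct`
#'   ([VolumeGrid-class], HU), `gt` ([LabelledMask-class]), `physiologic`
#'   ([BinaryMask-class]), `meta` ([scanMeta()]), and `lesion_table`
#'   (data.frame: `label`, `site`, `radius_mm`, `peak_suv`, `n_voxels`,
#'   `suv_sum` bookkeeping).
#' @export
generateScan <- function(config, positive = TRUE, seed = 1,
                         patient_id = "phantom", timepoint = "baseline") {
    stopifnot(inherits(config, "PhantomConfig"))
    withSeed(seed, {
        shape <- config$shape
        spacing <- config$spacing
        n <- prod(shape)
        anat <- phantomAnatomy(config)
        co <- axisCoords(shape, spacing)

        # body support as an elliptic cylinder
        bx <- ((co[[1]] - anat$cx) / anat$body_semi[1])^2
        by <- ((co[[2]] - anat$cy) / anat$body_semi[2])^2
        body2d <- outer(bx, by, "+") <= 1
        body <- array(body2d, dim = shape)  # recycled along z

        pet <- array(0, dim = shape)
        nb <- sum(body)
        pet[body] <- stats::rlnorm(nb, meanlog = log(config$background_median),
                                   sdlog = config$background_sigma)

        # physiologic organs
        phys <- array(FALSE, dim = shape)
        for (org in anat$organs) {
            ev <- ellipsoidVoxels(shape, spacing, org$c, org$r)
            pet[ev$idx] <- org$suv
            phys[ev$idx] <- TRUE
        }

        # CT: air / soft tissue / bone bands
        spine2d <- outer((co[[1]] - anat$spine$x)^2,
                         (co[[2]] - anat$spine$y)^2, "+") <= anat$spine$r^2
        zin <- co[[3]] >= anat$spine$z[1] & co[[3]] <= anat$spine$z[2]
        spine <- array(outer(spine2d, zin, "&"), dim = shape)
        ctv <- array(-1000, dim = shape)
        ctv[body] <- 40
        ctv[spine & body] <- 700
        ct <- makeCT(config, ctv, spacing)

        # lesions
        labels <- array(0L, dim = shape)
        sites <- character(0)
        tab <- NULL
        if (positive) {
            k <- if (!is.null(config$lesions_fixed)) config$lesions_fixed
                 else {
                     repeat {
                         k0 <- stats::rpois(1, config$lesions_mean)
                         if (k0 >= 1) break
                     }
                     k0
                 }
            occupied <- phys
            for (li in seq_len(k)) {
                site <- sample(LESION_SITES, 1, prob = config$site_probs)
                placed <- FALSE
                for (try in seq_len(config$max_retries)) {
                    r <- stats::runif(1, config$lesion_radius_mm[1],
                                      config$lesion_radius_mm[2])
                    if (site == "osseous") r <- min(r, 14)
                    zone <- anat$zones[[site]]
                    centre <- c(stats::runif(1, zone$x[1], zone$x[2]),
                                stats::runif(1, zone$y[1], zone$y[2]),
                                stats::runif(1, zone$z[1], zone$z[2]))
                    ev <- ellipsoidVoxels(shape, spacing, centre,
                                          rep(r, 3))
                    if (length(ev$idx) == 0) next
                    if (any(occupied[ev$idx])) next
                    peak <- stats::runif(1, config$lesion_peak_suv[1],
                                         config$lesion_peak_suv[2])
                    prof <- config$background_median +
                        (peak - config$background_median) *
                        lesionTaper(ev$rho)
                    pet[ev$idx] <- pmax(pet[ev$idx], prof)
                    labels[ev$idx] <- li
                    occupied[ev$idx] <- TRUE
                    if (site == "osseous") ctv[ev$idx] <- 700
                    sites <- c(sites, site)
                    tab <- rbind(tab, data.frame(
                        label = li, site = site,
                        centre_x = centre[1], centre_y = centre[2],
                        centre_z = centre[3], radius_mm = r, peak_suv = peak,
                        n_voxels = length(ev$idx),
                        stringsAsFactors = FALSE))
                    placed <- TRUE
                    break
                }
                if (!placed)
                    stop("lesion placement failed after ",
                         config$max_retries,
                         " retries (overcrowded phantom configuration)",
                         call. = FALSE)
            }
        }

        if (config$noise_sd > 0)
            pet <- pmax(pet + stats::rnorm(n, 0, config$noise_sd), 0)
        dim(pet) <- shape

        if (!is.null(tab))
            tab$suv_sum <- vapply(tab$label, function(l)
                sum(pet[labels == l]), numeric(1))
        else
            tab <- data.frame(label = integer(0), site = character(0),
                              centre_x = numeric(0), centre_y = numeric(0),
                              centre_z = numeric(0), radius_mm = numeric(0),
                              peak_suv = numeric(0), n_voxels = integer(0),
                              suv_sum = numeric(0), stringsAsFactors = FALSE)

        weight <- round(stats::runif(1, 60, 100), 1)
        meta <- scanMeta(patient_id, timepoint, body_weight_kg = weight,
                         injected_activity_MBq = 2 * weight,
                         delay_min = 60,
                         psma_status = if (positive) "positive"
                                       else "negative")
        list(pet = VolumeGrid(pet, spacing = spacing),
             ct = ct,
             gt = LabelledMask(labels,
                               siteByLabel = stats::setNames(
                                   sites,
                                   if (length(sites)) as.character(
                                       seq_along(sites)) else character(0)),
                               spacing = spacing),
             physiologic = BinaryMask(phys, spacing = spacing),
             meta = meta, lesion_table = tab)
    })
}

# Build the CT VolumeGrid, resampling the PET-grid HU field onto a coarser or
# finer CT grid when ct_spacing is configured.
makeCT <- function(config, ctv, spacing) {
    ctgrid <- VolumeGrid(ctv, spacing = spacing)
    if (is.null(config$ct_spacing)) return(ctgrid)
    fov <- config$shape * config$spacing
    tshape <- pmax(2L, as.integer(round(fov / config$ct_spacing)))
    target <- VolumeGrid(array(0, dim = tshape),
                         spacing = config$ct_spacing)
    resampleToGrid(ctgrid, target, mode = "nearest")
}

#' Prediction-corruption configuration
#'
#' Controlled error modes applied to a ground-truth mask to emulate an
#' imperfect segmenter: whole-lesion misses (`drop_prob`), boundary
#' over/under-segmentation (`morph_radius` voxels of face-connected dilation
#' for positive values, erosion for negative), partial coverage
#' (`overlap_fraction`: each retained lesion keeps exactly
#' `ceiling(f * volume)` contiguous interior voxels), and false-positive
#' clusters injected disjoint from the ground truth at a Poisson `fp_rate`
#' per scan.
#'
#' @param drop_prob per-lesion probability of a complete miss, in \[0, 1\].
#' @param morph_radius signed integer voxel radius (>0 dilate, <0 erode).
#' @param overlap_fraction optional target overlap fraction in (0, 1\];
#'   values > 1 are a parameter error.
#' @param fp_rate Poisson mean of injected false-positive clusters per scan.
#' @param fp_radius_vox numeric(2) radius range (in voxels) of the injected
#'   spherical false-positive clusters.
#' @return list of class `CorruptionConfig`.
#' @export
corruptionConfig <- function(drop_prob = 0, morph_radius = 0,
                             overlap_fraction = NULL, fp_rate = 0,
                             fp_radius_vox = c(1, 2.5)) {
    if (drop_prob < 0 || drop_prob > 1)
        stop("drop_prob must be in [0, 1]", call. = FALSE)
    if (!is.null(overlap_fraction)) {
        if (overlap_fraction > 1)
            stop("overlap_fraction must be <= 1", call. = FALSE)
        if (overlap_fraction <= 0)
            stop("overlap_fraction must be > 0", call. = FALSE)
    }
    if (fp_rate < 0) stop("fp_rate must be >= 0", call. = FALSE)
    structure(list(drop_prob = drop_prob, morph_radius = morph_radius,
                   overlap_fraction = overlap_fraction, fp_rate = fp_rate,
                   fp_radius_vox = fp_radius_vox),
              class = "CorruptionConfig")
}

#' Corrupt a ground-truth mask into a synthetic prediction
#'
#' Applies the error modes of a [corruptionConfig()] to a ground-truth
#' lesion mask, returning the "predicted" binary mask. Dropped lesions
#' contribute no voxels; with `overlap_fraction = f`, each retained lesion is
#' reduced to its `ceiling(f * volume)` voxels closest to the lesion centroid
#' (a contiguous interior core for the spherical phantom lesions); morphology
#' is applied to the retained foreground; injected false-positive clusters
#' are placed so that, even after 26-connected clustering, they are disjoint
#' from the ground-truth foreground and from the retained prediction.
#'
#' @param gt a [LabelledMask-class] ground truth.
#' @param cfg a [corruptionConfig()].
#' @param seed integer seed.
#' @return A [BinaryMask-class] prediction on the grid of `gt`.
#' @export
corruptPrediction <- function(gt, cfg, seed = 1) {
    stopifnot(is(gt, "LabelledMask"), inherits(cfg, "CorruptionConfig"))
    withSeed(seed, {
        shape <- dim(gt@labels)
        pred <- array(FALSE, dim = shape)
        gtfg <- gt@labels > 0L
        for (l in labelIds(gt)) {
            if (stats::runif(1) < cfg$drop_prob) next
            idx <- which(gt@labels == l)
            if (!is.null(cfg$overlap_fraction)) {
                k <- ceiling(cfg$overlap_fraction * length(idx))
                ai <- arrayInd(idx, shape)
                centroid <- colMeans(ai)
                d2 <- rowSums((t(t(ai) - centroid))^2)
                ord <- order(d2, idx)  # deterministic tie-break
                idx <- idx[ord[seq_len(k)]]
            }
            pred[idx] <- TRUE
        }
        if (cfg$morph_radius != 0)
            pred <- morphMask(pred, cfg$morph_radius)
        nfp <- if (cfg$fp_rate > 0) stats::rpois(1, cfg$fp_rate) else 0L
        if (nfp > 0) {
            for (i in seq_len(nfp)) {
                placed <- FALSE
                for (try in 1:100) {
                    c_idx <- stats::runif(3) * (shape - 1) + 1
                    r <- stats::runif(1, cfg$fp_radius_vox[1],
                                      cfg$fp_radius_vox[2])
                    ev <- ellipsoidVoxels(shape, c(1, 1, 1), c_idx - 1,
                                          rep(r, 3))
                    if (length(ev$idx) == 0) next
                    # guard band: the cluster, dilated by one voxel, must not
                    # touch the GT foreground or the current prediction
                    guard <- array(FALSE, dim = shape)
                    guard[ev$idx] <- TRUE
                    guard <- morphMask(guard, 1L)
                    if (any(gtfg[guard]) || any(pred[guard])) next
                    pred[ev$idx] <- TRUE
                    placed <- TRUE
                    break
                }
                if (!placed)
                    warning("false-positive cluster placement failed; ",
                            "injected ", i - 1L, " of ", nfp)
            }
        }
        BinaryMask(pred, grid = gt)
    })
}

#' Survival-simulation configuration
#'
#' Event times are exponential with a proportional-hazards rate
#' `base_rate * exp(beta * log1p(TLV))` per month; observed time is the
#' minimum of the event time, an independent exponential censoring time
#' (`censor_rate`), and an administrative horizon (default 80 months,
#' matching a follow-up range of roughly 21-80 months).
#'
#' @param base_rate baseline hazard per month, >= 0.
#' @param beta log-hazard coefficient on `log1p(TLV)`.
#' @param censor_rate independent censoring rate per month, >= 0.
#' @param horizon_months administrative censoring horizon, > 0.
#' @return list of class `SurvivalSimConfig`.
#' @export
survivalSimConfig <- function(base_rate = 0.002, beta = 0.5,
                              censor_rate = 0.005, horizon_months = 80) {
    if (base_rate < 0 || censor_rate < 0)
        stop("rates must be >= 0", call. = FALSE)
    if (horizon_months <= 0)
        stop("horizon_months must be > 0", call. = FALSE)
    structure(list(base_rate = base_rate, beta = beta,
                   censor_rate = censor_rate,
                   horizon_months = horizon_months),
              class = "SurvivalSimConfig")
}

#' Simulate survival records tied to lesion burden
#'
#' @param biomarkers data.frame with columns `patient_id` (or `scan_id`),
#'   `tlv_cm3` (>= 0), and optionally `tlu`, `psma_status`.
#' @param cfg a [survivalSimConfig()].
#' @param seed integer seed.
#' @return data.frame with `patient_id`, `time_months`, `event` (0/1),
#'   `tlv_cm3`, `tlu`, `psma_status`, `timepoint`.
#' @export
simulateSurvival <- function(biomarkers, cfg = survivalSimConfig(),
                             seed = 1) {
    stopifnot(is.data.frame(biomarkers), inherits(cfg, "SurvivalSimConfig"))
    tlv <- biomarkers$tlv_cm3
    if (is.null(tlv) || any(tlv < 0))
        stop("biomarkers must carry non-negative tlv_cm3", call. = FALSE)
    id <- if (!is.null(biomarkers$patient_id)) biomarkers$patient_id
          else biomarkers$scan_id
    withSeed(seed, {
        n <- nrow(biomarkers)
        rate <- cfg$base_rate * exp(cfg$beta * log1p(tlv))
        t_event <- ifelse(rate > 0, stats::rexp(n, pmax(rate, 1e-300)), Inf)
        t_cens <- if (cfg$censor_rate > 0) stats::rexp(n, cfg$censor_rate)
                  else rep(Inf, n)
        time <- pmin(t_event, t_cens, cfg$horizon_months)
        event <- as.integer(t_event <= pmin(t_cens, cfg$horizon_months))
        data.frame(patient_id = as.character(id),
                   time_months = time, event = event,
                   tlv_cm3 = tlv,
                   tlu = if (!is.null(biomarkers$tlu)) biomarkers$tlu
                         else NA_real_,
                   psma_status = if (!is.null(biomarkers$psma_status))
                       biomarkers$psma_status else "positive",
                   timepoint = "baseline",
                   stringsAsFactors = FALSE)
    })
}

#' Plan a phantom cohort
#'
#' Deterministically derives the per-scan positivity labels and sub-seeds for
#' a cohort of `n_scans`, with `round(negative_fraction * n_scans)` negative
#' scans in seeded random order.
#'
#' @param config a [phantomConfig()].
#' @param n_scans cohort size.
#' @param seed master seed; per-scan seeds are fanned out deterministically.
#' @return data.frame with `scan_id`, `patient_id`, `positive`, `seed_scan`,
#'   `seed_corrupt`.
#' @export
cohortPlan <- function(config, n_scans = 128, seed = 1) {
    stopifnot(inherits(config, "PhantomConfig"), n_scans >= 1)
    n_neg <- round(config$negative_fraction * n_scans)
    withSeed(subSeed(seed, 0), {
        positive <- sample(rep(c(FALSE, TRUE), c(n_neg, n_scans - n_neg)))
        data.frame(scan_id = sprintf("scan%03d", seq_len(n_scans)),
                   patient_id = sprintf("pt%03d", seq_len(n_scans)),
                   positive = positive,
                   seed_scan = vapply(seq_len(n_scans), function(i)
                       subSeed(seed, 2 * i), integer(1)),
                   seed_corrupt = vapply(seq_len(n_scans), function(i)
                       subSeed(seed, 2 * i + 1), integer(1)),
                   stringsAsFactors = FALSE)
    })
}

#' Write a phantom cohort to disk as NIfTI + CSV
#'
#' Materialises each scan of a [cohortPlan()] as NIfTI volumes/masks
#' (`<scan_id>_pet.nii.gz`, `_ct`, `_gt`, `_phys`, and `_pred` when a
#' corruption config is given) plus a cohort manifest CSV.
#'
#' @param config a [phantomConfig()].
#' @param dir output directory (created).
#' @param n_scans,seed cohort plan parameters.
#' @param corruption optional [corruptionConfig()] to emit predicted masks.
#' @return the manifest data.frame, invisibly.
#' @export
writeCohort <- function(config, dir, n_scans = 8, seed = 1,
                        corruption = NULL) {
    plan <- cohortPlan(config, n_scans, seed)
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_len(nrow(plan))) {
        sc <- generateScan(config, positive = plan$positive[i],
                           seed = plan$seed_scan[i],
                           patient_id = plan$patient_id[i])
        pre <- file.path(dir, plan$scan_id[i])
        writeVolume(sc$pet, paste0(pre, "_pet.nii.gz"))
        writeVolume(sc$ct, paste0(pre, "_ct.nii.gz"))
        writeMask(sc$gt, paste0(pre, "_gt.nii.gz"))
        writeMask(sc$physiologic, paste0(pre, "_phys.nii.gz"))
        if (!is.null(corruption))
            writeMask(corruptPrediction(sc$gt, corruption,
                                        seed = plan$seed_corrupt[i]),
                      paste0(pre, "_pred.nii.gz"))
    }
    manifest <- cbind(plan,
                      psma_status = ifelse(plan$positive, "positive",
                                           "negative"))
    utils::write.csv(manifest, file.path(dir, "cohort.csv"),
                     row.names = FALSE)
    invisible(manifest)
}
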