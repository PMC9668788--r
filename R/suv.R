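#' Half-life of gallium-68 in minutes
#'
#' Used for decay correction of the injected activity in body-weight SUV
#' conversion of [68Ga]Ga-PSMA-11 PET.
#' @export
GA68_HALF_LIFE_MIN <- 67.71

#' Per-scan acquisition metadata
#'
#' Validated record of the quantities needed for body-weight SUV conversion
#' and cohort bookkeeping.
#'
#' @param patient_id opaque string identifier.
#' @param timepoint `"baseline"` or `"followup"`.
#' @param body_weight_kg patient body weight in kg, > 0.
#' @param injected_activity_MBq tracer activity at injection time, MBq, > 0.
#' @param delay_min minutes between injection and scan start, >= 0
#'   (the acquisition protocol targets about 60 min).
#' @param psma_status ground-truth scan label, `"positive"` or `"negative"`.
#' @return A named list of class `ScanMeta`.
#' @examples
#' m <- scanMeta("p1", "baseline", 70, 140, 0, "positive")
#' @export
scanMeta <- function(patient_id, timepoint = "baseline", body_weight_kg,
                     injected_activity_MBq, delay_min = 60,
                     psma_status = "positive") {
    timepoint <- match.arg(timepoint, c("baseline", "followup"))
    psma_status <- match.arg(psma_status, c("positive", "negative"))
    if (!is.finite(body_weight_kg) || body_weight_kg <= 0)
        stop("body_weight_kg must be > 0", call. = FALSE)
    if (!is.finite(injected_activity_MBq) || injected_activity_MBq <= 0)
        stop("injected_activity_MBq must be > 0", call. = FALSE)
    if (!is.finite(delay_min) || delay_min < 0)
        stop("delay_min must be >= 0", call. = FALSE)
    structure(list(patient_id = as.character(patient_id),
                   timepoint = timepoint,
                   body_weight_kg = as.numeric(body_weight_kg),
                   injected_activity_MBq = as.numeric(injected_activity_MBq),
                   delay_min = as.numeric(delay_min),
                   psma_status = psma_status),
              class = "ScanMeta")
}

#' Convert an activity-concentration volume to body-weight SUV
#'
#' Applies the standard body-weight standardised uptake value definition:
#' `SUV_bw(v) = C(v) * m / A_0`, where `C(v)` is the activity concentration in
#' Bq/mL, `m` the body mass in grams, and `A_0` the injected activity in Bq
#' decay-corrected to scan start: `A_0 = A_inj * 2^(-delay / half_life)`.
#' The result is unitless (g/mL cancels against the ~1 g/mL tissue density
#' convention).
#'
#' @param activity a [VolumeGrid-class] of non-negative activity concentration
#'   in Bq/mL.
#' @param meta a [scanMeta()] record.
#' @param half_life_min radionuclide half-life in minutes; default
#'   [GA68_HALF_LIFE_MIN] (67.71 min for 68Ga).
#' @return A [VolumeGrid-class] of unitless SUV_bw on the same geometry.
#' @examples
#' act <- VolumeGrid(array(2000, c(2, 2, 2)))
#' m <- scanMeta("p1", "baseline", 70, 140, 0, "positive")
#' range(voxelValues(toSUVbw(act, m)))  # 1 1
#' @export
toSUVbw <- function(activity, meta, half_life_min = GA68_HALF_LIFE_MIN) {
    stopifnot(is(activity, "VolumeGrid"), inherits(meta, "ScanMeta"))
    if (!is.finite(half_life_min) || half_life_min <= 0)
        stop("half_life_min must be > 0", call. = FALSE)
    vals <- activity@values
    if (any(!is.finite(vals)) || any(vals < 0))
        stop("activity volume must be finite and non-negative", call. = FALSE)
    decayed_Bq <- meta$injected_activity_MBq * 1e6 *
        2^(-meta$delay_min / half_life_min)
    suv <- vals * (meta$body_weight_kg * 1000) / decayed_Bq
    VolumeGrid(suv, spacing = activity@spacing, origin = activity@origin)
}
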