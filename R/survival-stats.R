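#' Kaplan-Meier product-limit estimate
#'
#' Wraps [survival::survfit()] to return the product-limit curve
#' `S(t) = prod_{t_i <= t} (1 - d_i / n_i)` over the distinct event times,
#' with subjects censored at an event time counted in the risk set at that
#' time, plus at-risk counts at requested tick times (patients that have
#' neither experienced the event nor been censored before the tick).
#'
#' @param time follow-up times in months, > 0.
#' @param event logical/0-1 event indicator (death = 1, censored = 0).
#' @param ticks optional times at which to report the number still at risk.
#' @return list of class `KMCurve`: `curve` (data.frame `time`, `n_risk`,
#'   `n_event`, `n_censor`, `surv`), `at_risk` (data.frame `time`, `n_risk`;
#'   `NULL` when no ticks requested), `n`.
#' @examples
#' km <- kmEstimate(c(1, 2, 3), c(1, 0, 1))
#' kmSurvivalAt(km, 2.5)  # 2/3
#' @export
kmEstimate <- function(time, event, ticks = NULL) {
    if (length(time) < 1 || any(!is.finite(time)) || any(time <= 0))
        stop("follow-up times must be positive", call. = FALSE)
    event <- as.integer(as.logical(event))
    fit <- survival::survfit(survival::Surv(time, event) ~ 1)
    curve <- data.frame(time = fit$time, n_risk = fit$n.risk,
                        n_event = fit$n.event, n_censor = fit$n.censor,
                        surv = fit$surv)
    at_risk <- NULL
    if (!is.null(ticks))
        at_risk <- data.frame(time = ticks,
                              n_risk = vapply(ticks, function(t)
                                  sum(time >= t), numeric(1)))
    structure(list(curve = curve, at_risk = at_risk, n = length(time)),
              class = "KMCurve")
}

#' @rdname kmEstimate
#' @param km a `KMCurve`.
#' @param t time(s) at which to evaluate the step function.
#' @return `kmSurvivalAt`: survival probability S(t), right-continuous.
#' @export
kmSurvivalAt <- function(km, t) {
    stopifnot(inherits(km, "KMCurve"))
    steps <- km$curve[km$curve$n_event > 0, , drop = FALSE]
    vapply(t, function(tt) {
        i <- which(steps$time <= tt)
        if (length(i) == 0) 1 else steps$surv[max(i)]
    }, numeric(1))
}

#' Two-group log-rank test
#'
#' Unweighted (Mantel-Haenszel) log-rank test comparing the survival curves of
#' two groups, via [survival::survdiff()]; the p-value comes from a chi-square
#' distribution with 1 degree of freedom.
#'
#' @param timeA,eventA follow-up times and event indicators for group A.
#' @param timeB,eventB the same for group B.
#' @return list with `chisq`, `df` (= 1), `p_value`, `n` per group and
#'   observed/expected event counts.
#' @export
logrankTest <- function(timeA, eventA, timeB, eventB) {
    if (length(timeA) == 0 || length(timeB) == 0)
        stop("both groups must be non-empty", call. = FALSE)
    eventA <- as.integer(as.logical(eventA))
    eventB <- as.integer(as.logical(eventB))
    if (sum(eventA) + sum(eventB) == 0)
        stop("log-rank test is undefined with zero events", call. = FALSE)
    time <- c(timeA, timeB)
    event <- c(eventA, eventB)
    grp <- factor(rep(c("A", "B"), c(length(timeA), length(timeB))))
    sd <- survival::survdiff(survival::Surv(time, event) ~ grp)
    list(chisq = unname(sd$chisq), df = 1L,
         p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
         n = unname(sd$n), observed = unname(sd$obs),
         expected = unname(sd$exp))
}

#' Stratify survival by a tumour-burden biomarker
#'
#' Splits baseline-scan patients into two groups on a biomarker (TLV or TLU)
#' and compares overall survival with the log-rank test, attaching the
#' Kaplan-Meier curve of each group. `median_split` assigns values less than
#' or equal to the median to the low group; `q1_vs_q4` compares the lowest
#' against the highest quartile, with quartile boundaries from
#' linear-interpolation quantiles ([stats::quantile()] type 7) on the selected
#' subset. Only baseline records enter the analysis; `subset =
#' "psma_positive"` further restricts to PSMA-positive scans.
#'
#' @param records data.frame with columns `patient_id`, `time_months`,
#'   `event`, `tlv_cm3`, `tlu`, `psma_status`, and optionally `timepoint`
#'   (rows other than `"baseline"` are dropped).
#' @param biomarker `"tlv"` or `"tlu"`.
#' @param rule `"median_split"` or `"q1_vs_q4"`.
#' @param subset `"all"` or `"psma_positive"`.
#' @param ticks optional at-risk tick times passed to [kmEstimate()].
#' @return list of class `StratifiedComparison`: `biomarker`, `rule`,
#'   `subset`, `cutpoints`, `group_sizes`, `chisq`, `p_value`, `p_display`,
#'   `km` (list `low`/`high` of `KMCurve`).
#' @export
stratifySurvival <- function(records, biomarker = c("tlv", "tlu"),
                             rule = c("median_split", "q1_vs_q4"),
                             subset = c("all", "psma_positive"),
                             ticks = NULL) {
    biomarker <- match.arg(biomarker)
    rule <- match.arg(rule)
    subset <- match.arg(subset)
    stopifnot(is.data.frame(records))
    if ("timepoint" %in% names(records))
        records <- records[records$timepoint == "baseline", , drop = FALSE]
    if (subset == "psma_positive")
        records <- records[records$psma_status == "positive", , drop = FALSE]
    col <- if (biomarker == "tlv") "tlv_cm3" else "tlu"
    v <- records[[col]]
    if (length(v) < 4)
        stop("too few baseline records to stratify", call. = FALSE)
    if (max(v) == min(v))
        stop("degenerate split: all biomarker values identical",
             call. = FALSE)
    if (rule == "median_split") {
        cut <- stats::median(v)
        low <- v <= cut
        high <- !low
        cutpoints <- c(median = cut)
    } else {
        q <- stats::quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
        low <- v <= q[1]
        high <- v >= q[2]
        cutpoints <- c(q1 = q[1], q3 = q[2])
    }
    if (sum(low) < 2 || sum(high) < 2)
        stop("fewer than 2 patients in a stratum", call. = FALSE)
    lr <- logrankTest(records$time_months[low], records$event[low],
                      records$time_months[high], records$event[high])
    structure(list(
        biomarker = biomarker, rule = rule, subset = subset,
        cutpoints = cutpoints,
        group_sizes = c(low = sum(low), high = sum(high)),
        chisq = lr$chisq, p_value = lr$p_value,
        p_display = pValueDisplay(lr$p_value),
        km = list(low = kmEstimate(records$time_months[low],
                                   records$event[low], ticks),
                  high = kmEstimate(records$time_months[high],
                                    records$event[high], ticks))),
        class = "StratifiedComparison")
}

#' Display convention for small p-values
#'
#' Values below 0.005 are printed as `"< 0.005"`; the exact value is always
#' retained in machine-readable fields.
#'
#' @param p a p-value.
#' @return character.
#' @export
pValueDisplay <- function(p) {
    if (p < 0.005) "< 0.005" else sprintf("%.3g", p)
}

#' Wilcoxon signed-rank test on paired differences
#'
#' Two-sided signed-rank test via [stats::wilcox.test()]: zero differences are
#' dropped, tied absolute differences are mid-ranked, the exact null
#' distribution is used for n <= 25 without ties, and the normal approximation
#' with continuity correction otherwise.
#'
#' @param d paired differences, or the first sample when `y` is given.
#' @param y optional second sample; then the test runs on `d - y`.
#' @return list with `statistic` (V, sum of positive ranks), `p_value`,
#'   `n_nonzero`, `exact`.
#' @export
wilcoxonSignedRank <- function(d, y = NULL) {
    if (!is.null(y)) d <- d - y
    d <- d[is.finite(d)]
    nz <- d[d != 0]
    if (length(nz) == 0)
        stop("all paired differences are zero: signed-rank test is undefined",
             call. = FALSE)
    exact <- length(nz) <= 25 && !anyDuplicated(abs(nz))
    wt <- suppressWarnings(stats::wilcox.test(nz, exact = exact,
                                              correct = TRUE))
    list(statistic = unname(wt$statistic), p_value = wt$p.value,
         n_nonzero = length(nz), exact = exact)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks, with a two-sided p-value from the
#' t-approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2 degrees
#' of freedom (p = 0 at rho = +-1).
#'
#' @param x,y numeric vectors, finite, n >= 4.
#' @return list with `rho`, `p_value`, `n`.
#' @examples
#' spearmanCorrelation(1:5, c(1, 3, 2, 5, 4))$rho  # 0.8
#' @export
spearmanCorrelation <- function(x, y) {
    stopifnot(length(x) == length(y))
    if (length(x) < 4 || any(!is.finite(x)) || any(!is.finite(y)))
        stop("need >= 4 finite paired observations", call. = FALSE)
    rx <- rank(x)
    ry <- rank(y)
    if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
        stop("zero variance in ranks", call. = FALSE)
    rho <- stats::cor(rx, ry)
    n <- length(x)
    if (abs(rho) >= 1) {
        p <- 0
    } else {
        t <- rho * sqrt((n - 2) / (1 - rho^2))
        p <- 2 * stats::pt(-abs(t), df = n - 2)
    }
    list(rho = rho, p_value = p, n = n)
}

#' One-way analysis of variance
#'
#' Classical fixed-effects ANOVA: between/within mean-square F statistic with
#' (k - 1, N - k) degrees of freedom, via [stats::oneway.test()] with equal
#' variances.
#'
#' @param groups list of numeric vectors, at least 2 groups of n >= 2 each.
#' @return list with `F`, `df1`, `df2`, `p_value`.
#' @examples
#' anovaOneway(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))$F  # 3
#' @export
anovaOneway <- function(groups) {
    stopifnot(is.list(groups))
    if (length(groups) < 2 || any(lengths(groups) < 2))
        stop("need >= 2 groups with >= 2 observations each", call. = FALSE)
    if (all(vapply(groups, function(g) stats::var(g) == 0, logical(1))))
        stop("zero within-group variance everywhere: F is undefined",
             call. = FALSE)
    values <- unlist(groups, use.names = FALSE)
    g <- factor(rep(seq_along(groups), lengths(groups)))
    ow <- stats::oneway.test(values ~ g, var.equal = TRUE)
    list(F = unname(ow$statistic), df1 = unname(ow$parameter[1]),
         df2 = unname(ow$parameter[2]), p_value = ow$p.value)
}

#' Read survival records from CSV
#'
#' Expected columns: `patient_id`, `time_months`, `event`, `tlv_cm3`, `tlu`,
#' `psma_status`, `timepoint`.
#'
#' @param path CSV file path.
#' @return data.frame.
#' @export
readSurvivalRecords <- function(path) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("patient_id", "time_months", "event", "tlv_cm3", "tlu",
              "psma_status")
    miss <- setdiff(need, names(df))
    if (length(miss))
        stop("survival records are missing columns: ",
             paste(miss, collapse = ", "), call. = FALSE)
    df
}
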