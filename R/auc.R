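#' @include AllClasses.R AllGenerics.R rk.R
NULL

.trapz <- function(x, y) sum((y[-1] + y[-length(y)]) / 2 * diff(x))

#' Area under the normalized intensity curve
#'
#' The pipeline's scalar transparency statistic: the trapezoidal integral of
#' normalized intensity over normalized depth, a dimensionless number in
#' [0, 1]. High values mean signal survives deep into the tissue. The default
#' route integrates the reproducing-kernel curve on the 201-point grid; the
#' method for [NormalizedProfile-class] integrates the raw profile instead
#' (a sensitivity-check variant selected by \code{auc.source = "raw"} in the
#' pipeline).
#'
#' @param x a [SampledCurve-class] or a [NormalizedProfile-class].
#' @return one-row data.frame: \code{experiment_id, group, specimen, region,
#'   channel, auc}.
#' @examples
#' cv <- new("SampledCurve", values = 1 - curveGrid(),
#'           labels = experimentLabels())
#' computeAUC(cv)$auc                       # 0.5
#' @export
setGeneric("computeAUC", function(x) standardGeneric("computeAUC"))

.aucRecord <- function(labels, auc) {
    data.frame(experiment_id = labels[["experiment"]],
               group = labels[["group"]], specimen = labels[["specimen"]],
               region = labels[["region"]], channel = labels[["channel"]],
               auc = auc)
}

#' @rdname computeAUC
setMethod("computeAUC", "SampledCurve", function(x) {
    v <- curveValues(x)
    if (anyNA(v)) .err("clearquant_bad_values", "curve contains NaN")
    .aucRecord(expLabels(x), .trapz(curveGrid(), v))
})

#' @rdname computeAUC
setMethod("computeAUC", "NormalizedProfile", function(x) {
    .aucRecord(expLabels(x), .trapz(normDepths(x), normIntensities(x)))
})

#' Group-average curves with pointwise spread
#'
#' Averages all experiments of a group (and channel) pointwise on the common
#' 201-point grid -- the group-averaged normalized intensity curve -- and
#' attaches the pointwise sample SD (NA where a group has a single curve).
#'
#' @param curves non-empty list of [SampledCurve-class], all on the common
#'   grid.
#' @return data.frame with columns \code{group, channel, u, mean, sd, n},
#'   ordered by group, channel, u.
#' @section Errors: \code{clearquant_empty_input}.
#' @export
groupAverageCurve <- function(curves) {
    if (length(curves) == 0L)
        .err("clearquant_empty_input", "no curves given")
    key <- vapply(curves, function(cv)
        paste(expLabels(cv)[c("group", "channel")], collapse = "\r"), "")
    out <- lapply(split(curves, key), function(cs) {
        V <- vapply(cs, curveValues, numeric(.GRID_N))   # 201 x n
        lb <- expLabels(cs[[1L]])
        n <- length(cs)
        data.frame(group = lb[["group"]], channel = lb[["channel"]],
                   u = curveGrid(), mean = rowMeans(V),
                   sd = if (n >= 2L) apply(V, 1L, stats::sd) else NA_real_,
                   n = n)
    })
    df <- do.call(rbind, out)
    rownames(df) <- NULL
    df[order(df$group, df$channel, df$u), ]
}

#' Summarize AUC records per group
#'
#' Produces one summary row per (group, channel) -- n, mean, sample SD,
#' median, and quartiles Q1/Q3 by linear interpolation between order
#' statistics -- plus the full record table sorted by group, specimen,
#' region and AUC value (the convention used for reporting).
#'
#' @param records data.frame of AUC records as produced by [computeAUC()]
#'   (rows may be concatenated with \code{rbind}).
#' @return list with elements \code{summaries} (data.frame: group, channel,
#'   n, mean, sd, median, q1, q3) and \code{table} (the sorted records).
#'   \code{sd} is 0 when n = 1 (flagged by the n column).
#' @export
summarizeGroups <- function(records) {
    if (is.null(records) || nrow(records) == 0L)
        .err("clearquant_empty_input", "no AUC records given")
    key <- paste(records$group, records$channel, sep = "\r")
    summaries <- do.call(rbind, lapply(split(records, key), function(d) {
        q <- stats::quantile(d$auc, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
        data.frame(group = d$group[1L], channel = d$channel[1L], n = nrow(d),
                   mean = mean(d$auc),
                   sd = if (nrow(d) >= 2L) stats::sd(d$auc) else 0,
                   median = q[2L], q1 = q[1L], q3 = q[3L])
    }))
    rownames(summaries) <- NULL
    summaries <- summaries[order(summaries$group, summaries$channel), ]
    tab <- records[order(records$group, records$specimen, records$region,
                         records$auc), ]
    rownames(tab) <- NULL
    list(summaries = summaries, table = tab)
}
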