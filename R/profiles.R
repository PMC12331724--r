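#' @include AllClasses.R AllGenerics.R stack-io.R
NULL

#' Extract a depth-intensity profile from a z-stack
#'
#' The per-slice statistic is the arithmetic mean over the frame, or over a
#' pixel ROI mask if one is supplied (the usual z-axis-profile convention).
#' Depth of slice \eqn{k} is \eqn{(k-1)\,\Delta z}.
#'
#' @param stack a [ZStack-class].
#' @param roi optional logical matrix matching the slice dimensions; only
#'   \code{TRUE} pixels enter the mean. Must select at least one pixel.
#' @return a [DepthProfile-class] carrying the stack's labels.
#' @section Errors: \code{clearquant_bad_roi} for an empty or mis-shaped ROI.
#' @examples
#' st <- new("ZStack", voxels = array(100, c(5, 4, 4)), zStep = 1,
#'           labels = experimentLabels())
#' depths(extractProfile(st))
#' @export
extractProfile <- function(stack, roi = NULL) {
    stopifnot(is(stack, "ZStack"))
    v <- voxels(stack)
    if (!is.null(roi)) {
        if (!is.logical(roi) || !identical(dim(roi), dim(v)[2:3]))
            .err("clearquant_bad_roi",
                 "roi must be a logical matrix of dimensions %d x %d",
                 dim(v)[2L], dim(v)[3L])
        if (!any(roi))
            .err("clearquant_bad_roi", "roi selects no pixels")
        int <- apply(v, 1L, function(sl) mean(sl[roi]))
    } else {
        int <- apply(v, 1L, mean)
    }
    new("DepthProfile", z = depths(stack), intensity = int,
        labels = expLabels(stack))
}

#' Normalize a depth profile onto the unit square
#'
#' Depths are divided by the profile's maximum available imaging depth
#' \eqn{z_{max}} and intensities by the 8-bit ceiling 255, putting every
#' experiment on a common \eqn{[0,1]^2} scale. \eqn{z_{max}} is the deepest
#' acquired plane of that stack, not an estimate of tissue thickness.
#'
#' @param profile a [DepthProfile-class] with max depth > 0.
#' @return a [NormalizedProfile-class].
#' @section Errors: \code{clearquant_zero_depth} if max depth is 0.
#' @examples
#' p <- new("DepthProfile", z = c(0, 50, 100), intensity = c(255, 127.5, 0),
#'          labels = experimentLabels())
#' normDepths(normalizeProfile(p))
#' @export
normalizeProfile <- function(profile) {
    stopifnot(is(profile, "DepthProfile"))
    zm <- max(depths(profile))
    if (zm <= 0)
        .err("clearquant_zero_depth",
             "profile has non-positive maximum depth")
    new("NormalizedProfile", u = depths(profile) / zm,
        y = intensities(profile) / 255, zMax = zm,
        labels = expLabels(profile))
}

#' Estimate tissue thickness from a depth profile
#'
#' A simple threshold rule: thickness is the deepest plane whose intensity is
#' still at least \code{relThreshold} of the profile's peak intensity. If the
#' signal never falls below the threshold, the full imaging depth is
#' returned. For a pure Beer-Lambert decay this inverts to
#' \eqn{-\ln(\mathrm{relThreshold}) / \mu_{\mathrm{eff}}} (per-micrometre
#' \eqn{\mu}), to within one z-step.
#'
#' @param profile a [DepthProfile-class] with a nonzero intensity somewhere.
#' @param relThreshold fraction of peak intensity in (0, 1), default 0.05.
#' @return thickness in micrometres.
#' @section Errors: \code{clearquant_zero_signal} for an all-zero profile;
#'   \code{clearquant_bad_threshold} for a threshold outside (0, 1).
#' @export
estimateThickness <- function(profile, relThreshold = 0.05) {
    stopifnot(is(profile, "DepthProfile"))
    if (length(relThreshold) != 1L || relThreshold <= 0 || relThreshold >= 1)
        .err("clearquant_bad_threshold",
             "relThreshold must lie strictly between 0 and 1")
    int <- intensities(profile)
    if (max(int) <= 0)
        .err("clearquant_zero_signal",
             "cannot estimate thickness of an all-zero profile")
    keep <- int >= relThreshold * max(int)
    max(depths(profile)[keep])
}
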