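#' @include AllClasses.R
NULL

#' Accessors for ClearQuant objects
#'
#' Small accessor layer over the S4 slots: \code{voxels()} and \code{zStep()}
#' for [ZStack-class]; \code{depths()} and \code{intensities()} for
#' [DepthProfile-class]; \code{normDepths()}, \code{normIntensities()} and
#' \code{zMax()} for [NormalizedProfile-class]; \code{curveValues()} for
#' [SampledCurve-class]; \code{expLabels()} and \code{channel()} for all of
#' them.
#'
#' @param object a ClearQuant S4 object.
#' @return the slot contents (see each accessor).
#' @name accessors
#' @examples
#' p <- new("DepthProfile", z = c(0, 1), intensity = c(10, 5),
#'          labels = experimentLabels())
#' depths(p)
#' channel(p)
NULL

#' @rdname accessors
#' @export
setGeneric("voxels", function(object) standardGeneric("voxels"))
#' @rdname accessors
#' @export
setGeneric("zStep", function(object) standardGeneric("zStep"))
#' @rdname accessors
#' @export
setGeneric("depths", function(object) standardGeneric("depths"))
#' @rdname accessors
#' @export
setGeneric("intensities", function(object) standardGeneric("intensities"))
#' @rdname accessors
#' @export
setGeneric("normDepths", function(object) standardGeneric("normDepths"))
#' @rdname accessors
#' @export
setGeneric("normIntensities", function(object) standardGeneric("normIntensities"))
#' @rdname accessors
#' @export
setGeneric("zMax", function(object) standardGeneric("zMax"))
#' @rdname accessors
#' @export
setGeneric("curveValues", function(object) standardGeneric("curveValues"))
#' @rdname accessors
#' @export
setGeneric("expLabels", function(object) standardGeneric("expLabels"))
#' @rdname accessors
#' @export
setGeneric("channel", function(object) standardGeneric("channel"))

#' @rdname accessors
setMethod("voxels", "ZStack", function(object) object@voxels)
#' @rdname accessors
setMethod("zStep", "ZStack", function(object) object@zStep)
#' @rdname accessors
setMethod("depths", "ZStack",
    function(object) (seq_len(dim(object@voxels)[1L]) - 1L) * object@zStep)
#' @rdname accessors
setMethod("depths", "DepthProfile", function(object) object@z)
#' @rdname accessors
setMethod("intensities", "DepthProfile", function(object) object@intensity)
#' @rdname accessors
setMethod("normDepths", "NormalizedProfile", function(object) object@u)
#' @rdname accessors
setMethod("normIntensities", "NormalizedProfile", function(object) object@y)
#' @rdname accessors
setMethod("zMax", "NormalizedProfile", function(object) object@zMax)
#' @rdname accessors
setMethod("curveValues", "SampledCurve", function(object) object@values)

for (cls in c("ZStack", "DepthProfile", "NormalizedProfile", "RKModel",
              "SampledCurve")) {
    setMethod("expLabels", cls, function(object) object@labels)
    setMethod("channel", cls, function(object) object@labels[["channel"]])
}

setMethod("show", "ZStack", function(object) {
    d <- dim(object@voxels)
    cat(sprintf("ZStack: %d slices of %d x %d px, z-step %.3g um (%s)\n",
                d[1L], d[2L], d[3L], object@zStep,
                paste(object@labels[c("experiment", "group", "channel")],
                      collapse = " / ")))
})

setMethod("show", "DepthProfile", function(object) {
    cat(sprintf(
        "DepthProfile: %d points, depth 0..%.3g um, intensity %.3g..%.3g (%s)\n",
        length(object@z), max(object@z), min(object@intensity),
        max(object@intensity),
        paste(object@labels[c("experiment", "group", "channel")],
              collapse = " / ")))
})

setMethod("show", "NormalizedProfile", function(object) {
    cat(sprintf("NormalizedProfile: %d points, zMax %.3g um (%s)\n",
                length(object@u), object@zMax,
                paste(object@labels[c("experiment", "group", "channel")],
                      collapse = " / ")))
})

setMethod("show", "RKModel", function(object) {
    cat(sprintf(
        "RKModel: %d nodes, basis order %d, %s kernel, support %s\n",
        length(object@nodes), object@config@basisOrder, object@config@kernel,
        if (is.na(object@config@support)) "auto" else
            format(object@config@support)))
})

setMethod("show", "SampledCurve", function(object) {
    cat(sprintf("SampledCurve: 201-point grid, values %.4g..%.4g (%s)\n",
                min(object@values), max(object@values),
                paste(object@labels[c("experiment", "group", "channel")],
                      collapse = " / ")))
})

setMethod("show", "SyntheticSpec", function(object) {
    cat(sprintf(
        "SyntheticSpec: %d group/channel decays, %d specimens x %d regions, %d slices, noise %s(%.3g), seed %d\n",
        nrow(object@groups), object@nSpecimens, object@nRegions,
        object@nSlices, object@noise, object@noiseParam, object@seed))
})
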