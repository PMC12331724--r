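#' @import methods
NULL

.CHANNELS <- c("AF", "SHG")
.GRID_STEP <- 0.005
.GRID_N <- 201L

.validLabels <- function(labels) {
    need <- c("experiment", "group", "specimen", "region", "channel")
    if (!is.character(labels) || is.null(names(labels)) ||
        !all(need %in% names(labels)))
        return(sprintf("labels must be a named character vector with fields %s",
                       paste(need, collapse = ", ")))
    if (!labels[["channel"]] %in% .CHANNELS)
        return(sprintf("channel must be one of %s", paste(.CHANNELS, collapse = ", ")))
    TRUE
}

#' Construct the label set attached to every experiment-level object
#'
#' Every profile, curve and z-stack in the pipeline carries the same five
#' identifiers: the experiment it came from, the study group (e.g. a clearing
#' protocol), the specimen, the imaged region within the specimen, and the
#' detection channel (autofluorescence \code{"AF"} or second harmonic
#' generation \code{"SHG"}).
#'
#' @param experiment experiment identifier (unique per profile).
#' @param group study-group label, e.g. \code{"BABB"} or \code{"NC-F"}.
#' @param specimen specimen identifier.
#' @param region imaged region identifier within the specimen.
#' @param channel \code{"AF"} or \code{"SHG"}.
#' @return named character vector of length 5.
#' @examples
#' experimentLabels("e1", "BABB", "s1", "r1", "AF")
#' @export
experimentLabels <- function(experiment = "exp1", group = "group1",
                             specimen = "spec1", region = "reg1",
                             channel = "AF") {
    channel <- match.arg(channel, .CHANNELS)
    c(experiment = as.character(experiment), group = as.character(group),
      specimen = as.character(specimen), region = as.character(region),
      channel = channel)
}

#' ZStack: a multiphoton z-stack on the 8-bit intensity scale
#'
#' Holds the voxel data of one acquisition as a 3D array indexed
#' (slice, row, col), together with the axial step and the experiment labels.
#' Slice 1 is the shallowest plane (the tissue surface nearest the objective,
#' depth 0); slice \eqn{k} sits at depth \eqn{(k-1)\,\Delta z}.
#' Intensities live on the 0--255 scale regardless of the bit depth of the
#' source file.
#'
#' @slot voxels numeric 3D array (slice, row, col), values in [0, 255].
#' @slot zStep axial step in micrometres, > 0.
#' @slot labels named character vector from [experimentLabels()].
#' @aliases ZStack
#' @exportClass ZStack
setClass("ZStack",
    representation(voxels = "array", zStep = "numeric", labels = "character"))

setValidity("ZStack", function(object) {
    v <- object@voxels
    if (length(dim(v)) != 3L)
        return("voxels must be a 3D array (slice, row, col)")
    if (dim(v)[1L] < 2L)
        return("a z-stack needs at least 2 slices")
    if (anyNA(v) || min(v) < 0 || max(v) > 255)
        return("voxel intensities must be finite and within [0, 255]")
    if (length(object@zStep) != 1L || !is.finite(object@zStep) || object@zStep <= 0)
        return("zStep must be a single positive number (micrometres)")
    .validLabels(object@labels)
})

#' DepthProfile: depth versus mean signal intensity for one experiment
#'
#' The pipeline's central record: strictly increasing depths (micrometres,
#' surface = 0) paired with per-slice intensities on the 0--255 scale.
#'
#' @slot z numeric, strictly increasing depths in micrometres.
#' @slot intensity numeric, same length as \code{z}, values in [0, 255].
#' @slot labels named character vector from [experimentLabels()].
#' @aliases DepthProfile
#' @exportClass DepthProfile
setClass("DepthProfile",
    representation(z = "numeric", intensity = "numeric", labels = "character"))

setValidity("DepthProfile", function(object) {
    if (length(object@z) < 2L)
        return("a profile needs at least 2 points")
    if (length(object@z) != length(object@intensity))
        return("z and intensity must have equal length")
    if (anyNA(object@z) || any(diff(object@z) <= 0))
        return("depths must be finite and strictly increasing")
    if (anyNA(object@intensity) || min(object@intensity) < 0 ||
        max(object@intensity) > 255)
        return("intensities must be finite and within [0, 255]")
    .validLabels(object@labels)
})

#' NormalizedProfile: a depth profile on the unit square
#'
#' Depths divided by the maximum available imaging depth of the stack
#' (\code{zMax}) and intensities divided by the 8-bit ceiling 255, so every
#' experiment lives on \eqn{[0,1] \times [0,1]} and curves are comparable
#' across stacks of unequal depth.
#'
#' @slot u numeric, strictly increasing normalized depths with max(u) = 1.
#' @slot y numeric, normalized intensities in [0, 1].
#' @slot zMax the depth-normalization constant in micrometres.
#' @slot labels named character vector from [experimentLabels()].
#' @aliases NormalizedProfile
#' @exportClass NormalizedProfile
setClass("NormalizedProfile",
    representation(u = "numeric", y = "numeric", zMax = "numeric",
                   labels = "character"))

setValidity("NormalizedProfile", function(object) {
    if (length(object@u) < 2L || length(object@u) != length(object@y))
        return("u and y must have equal length >= 2")
    if (anyNA(object@u) || any(diff(object@u) <= 0))
        return("u must be strictly increasing")
    if (abs(max(object@u) - 1) > 1e-12 || min(object@u) < 0)
        return("u must lie in [0, 1] with max(u) = 1")
    if (anyNA(object@y) || min(object@y) < 0 || max(object@y) > 1)
        return("y must lie in [0, 1]")
    if (length(object@zMax) != 1L || !is.finite(object@zMax) || object@zMax <= 0)
        return("zMax must be a single positive number")
    .validLabels(object@labels)
})

#' RKConfig: reproducing-kernel approximation settings
#'
#' @slot basisOrder monomial basis order, 0 (constant), 1 (linear, default)
#'   or 2 (quadratic).
#' @slot kernel kernel window, \code{"cubic_bspline"} (default, compact
#'   support) or \code{"gaussian"} (truncated at the support radius).
#' @slot support kernel half-width on the normalized-depth axis; \code{NA}
#'   (default) means 2.5 times the median node spacing, chosen per profile.
#' @slot ridge non-negative regularization added to the moment-matrix
#'   diagonal (relative to its largest entry), default 1e-12.
#' @aliases RKConfig
#' @exportClass RKConfig
setClass("RKConfig",
    representation(basisOrder = "integer", kernel = "character",
                   support = "numeric", ridge = "numeric"))

setValidity("RKConfig", function(object) {
    if (!object@basisOrder %in% 0:2)
        return("basisOrder must be 0, 1 or 2")
    if (!object@kernel %in% c("cubic_bspline", "gaussian"))
        return("kernel must be 'cubic_bspline' or 'gaussian'")
    if (!is.na(object@support) && object@support <= 0)
        return("support must be positive (or NA for automatic)")
    if (object@ridge < 0)
        return("ridge must be >= 0")
    TRUE
})

#' Create a reproducing-kernel configuration
#'
#' @param basisOrder 0, 1 (default) or 2; order of the monomial basis the
#'   shape functions reproduce exactly.
#' @param kernel "cubic_bspline" (default) or "gaussian".
#' @param support kernel half-width in normalized-depth units; \code{NA}
#'   picks 2.5 times the median node spacing of each profile.
#' @param ridge relative diagonal regularization of the moment matrix.
#' @return an [RKConfig-class] object.
#' @examples
#' rkConfig(basisOrder = 1)
#' @export
rkConfig <- function(basisOrder = 1L, kernel = c("cubic_bspline", "gaussian"),
                     support = NA_real_, ridge = 1e-12) {
    new("RKConfig", basisOrder = as.integer(basisOrder),
        kernel = match.arg(kernel), support = as.numeric(support),
        ridge = as.numeric(ridge))
}

#' RKModel: a reproducing-kernel approximant of one normalized profile
#'
#' Stores the profile's normalized depths as nodes and normalized intensities
#' as nodal values; the approximant is
#' \eqn{y_h(u) = \sum_i \Psi_i(u)\, y_i} with the shape functions
#' \eqn{\Psi_i} built by [rkShapeFunctions()].
#'
#' @slot nodes strictly increasing normalized depths in [0, 1].
#' @slot nodeValues normalized intensities at the nodes.
#' @slot config an [RKConfig-class].
#' @slot labels experiment labels carried over from the profile.
#' @aliases RKModel
#' @exportClass RKModel
setClass("RKModel",
    representation(nodes = "numeric", nodeValues = "numeric",
                   config = "RKConfig", labels = "character"))

setValidity("RKModel", function(object) {
    n <- length(object@nodes)
    if (n != length(object@nodeValues))
        return("nodes and nodeValues must have equal length")
    if (n < object@config@basisOrder + 2L)
        return("need at least basisOrder + 2 nodes")
    if (anyNA(object@nodes) || any(diff(object@nodes) <= 0) ||
        min(object@nodes) < 0 || max(object@nodes) > 1)
        return("nodes must be strictly increasing within [0, 1]")
    if (anyNA(object@nodeValues))
        return("nodeValues must be finite")
    .validLabels(object@labels)
})

#' SampledCurve: an approximated profile on the common 0.005 grid
#'
#' Every experiment's smoothed curve is evaluated at the same 201 normalized
#' depths \eqn{u = 0, 0.005, \ldots, 1}, which makes group averaging and AUC
#' integration a fixed-grid operation.
#'
#' @slot values numeric of length 201, finite, in [0, 1].
#' @slot labels experiment labels carried over.
#' @aliases SampledCurve
#' @exportClass SampledCurve
setClass("SampledCurve",
    representation(values = "numeric", labels = "character"))

setValidity("SampledCurve", function(object) {
    if (length(object@values) != .GRID_N)
        return(sprintf("values must have exactly %d points (grid step %.3f)",
                       .GRID_N, .GRID_STEP))
    if (anyNA(object@values) || any(!is.finite(object@values)))
        return("curve values must be finite")
    .validLabels(object@labels)
})

#' The common normalized-depth evaluation grid
#'
#' @return numeric vector \code{seq(0, 1, by = 0.005)} (201 points).
#' @examples
#' length(curveGrid())
#' @export
curveGrid <- function() seq(0, 1, by = .GRID_STEP)

#' SyntheticSpec: parameterization of the Beer-Lambert study simulator
#'
#' Describes a full synthetic imaging study: one Beer-Lambert decay
#' \eqn{I(z) = I_0 e^{-\mu_{\mathrm{eff}} z / z_{max}}} per group and channel,
#' hierarchical specimen- and region-level variability, detector noise,
#' optional 8-bit quantization, and per-experiment stack geometry.
#' \eqn{\mu_{\mathrm{eff}}} is expressed per unit \emph{normalized} depth so
#' the closed-form noise-free AUC \eqn{(1 - e^{-\mu})/\mu} applies directly.
#'
#' @slot groups data.frame with columns \code{group}, \code{channel},
#'   \code{mu_eff} (> 0, per unit normalized depth) and \code{I0}
#'   (surface intensity, 0--255 scale).
#' @slot nSpecimens specimens per group.
#' @slot nRegions imaged regions per specimen (one experiment per region
#'   and channel).
#' @slot specimenSdLogMu SD of the specimen-level lognormal perturbation
#'   applied to \code{mu_eff}.
#' @slot regionSdI0 SD of the region-level Gaussian perturbation applied to
#'   \code{I0} (0--255 scale).
#' @slot noise \code{"gaussian"} (additive, SD \code{noiseParam}) or
#'   \code{"poisson"} (photon counting, gain \code{noiseParam}) or
#'   \code{"none"}.
#' @slot noiseParam noise SD (gaussian) or gain (poisson).
#' @slot nSlices slices per stack, >= 4.
#' @slot zMaxRange micrometre range (min, max) from which each experiment's
#'   maximum imaging depth is drawn uniformly.
#' @slot quantize round intensities to integers (8-bit detector), default TRUE.
#' @slot seed integer driving all randomness of the simulated study.
#' @aliases SyntheticSpec
#' @exportClass SyntheticSpec
setClass("SyntheticSpec",
    representation(groups = "data.frame", nSpecimens = "integer",
                   nRegions = "integer", specimenSdLogMu = "numeric",
                   regionSdI0 = "numeric", noise = "character",
                   noiseParam = "numeric", nSlices = "integer",
                   zMaxRange = "numeric", quantize = "logical",
                   seed = "integer"))

setValidity("SyntheticSpec", function(object) {
    g <- object@groups
    need <- c("group", "channel", "mu_eff", "I0")
    if (!all(need %in% names(g)) || nrow(g) < 1L)
        return("groups needs columns group, channel, mu_eff, I0 and >= 1 row")
    if (!all(g$channel %in% .CHANNELS))
        return("groups$channel entries must be 'AF' or 'SHG'")
    if (any(g$mu_eff <= 0))
        return("mu_eff must be > 0")
    if (any(g$I0 <= 0 | g$I0 > 255))
        return("I0 must lie in (0, 255]")
    if (anyDuplicated(g[c("group", "channel")]))
        return("one row per (group, channel)")
    if (object@nSpecimens < 1L || object@nRegions < 1L)
        return("nSpecimens and nRegions must be >= 1")
    if (object@specimenSdLogMu < 0 || object@regionSdI0 < 0)
        return("variability SDs must be >= 0")
    if (!object@noise %in% c("gaussian", "poisson", "none"))
        return("noise must be 'gaussian', 'poisson' or 'none'")
    if (object@noiseParam < 0)
        return("noiseParam must be >= 0")
    if (object@nSlices < 4L)
        return("nSlices must be >= 4")
    if (length(object@zMaxRange) != 2L || any(object@zMaxRange <= 0) ||
        object@zMaxRange[2L] < object@zMaxRange[1L])
        return("zMaxRange must be a positive increasing pair (min, max)")
    TRUE
})
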