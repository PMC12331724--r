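#' @include AllClasses.R AllGenerics.R stack-io.R
NULL

## kernel windows on the normalized distance z = |s| / a  (support z < 1)
.rkKernel <- function(z, kernel) {
    w <- numeric(length(z))
    if (kernel == "cubic_bspline") {
        lo <- z <= 0.5
        hi <- z > 0.5 & z < 1
        w[lo] <- 2 / 3 - 4 * z[lo]^2 + 4 * z[lo]^3
        w[hi] <- 4 / 3 * (1 - z[hi])^3
    } else {                                # truncated gaussian
        inside <- z < 1
        w[inside] <- exp(-4 * z[inside]^2)
    }
    w
}

.defaultSupport <- function(nodes) 2.5 * stats::median(diff(nodes))

## Shape-function weights at one evaluation point.
## The monomial basis is evaluated in support-scaled coordinates t = s / a so
## the moment matrix stays O(1)-conditioned; a diagonal congruence leaves the
## resulting shape functions unchanged. One iterative-refinement step against
## the unridged moment matrix removes the ridge perturbation from the solve.
.rkWeightsAt <- function(uEval, nodes, basisOrder, kernel, support, ridge) {
    n <- length(nodes)
    a <- support
    repeat {
        s <- uEval - nodes
        z <- abs(s) / a
        w <- .rkKernel(z, kernel)
        active <- which(w > 0)
        if (length(active) >= basisOrder + 1L) {
            t <- s[active] / a
            P <- outer(t, 0:basisOrder, `^`)           # m x (p+1)
            M <- crossprod(P * sqrt(w[active]))
            Mr <- M + diag(ridge * max(diag(M)), basisOrder + 1L)
            ## conditioning gate: kappa * eps bounds the partition-of-unity
            ## error, so demand kappa <~ 1e5 before accepting this support
            if (rcond(Mr) > 1e-5) {
                e1 <- c(1, numeric(basisOrder))
                cvec <- solve(Mr, e1)
                cvec <- cvec + solve(Mr, e1 - M %*% cvec)  # refinement
                cvec <- cvec + solve(Mr, e1 - M %*% cvec)
                psi <- numeric(n)
                psi[active] <- w[active] * drop(P %*% cvec)
                return(psi)
            }
        }
        a <- a * 1.5
        if (a > 8)
            .err("clearquant_singular_moment",
                 "moment matrix singular at u = %.4g even at support %.3g",
                 uEval, a)
    }
}

#' Reproducing-kernel shape functions at an evaluation point
#'
#' Builds the meshfree shape functions \eqn{\Psi_i(u)} of the reproducing
#' kernel particle construction: with the monomial basis
#' \eqn{H(s) = (1, s, \ldots, s^n)^T} and a compact kernel window
#' \eqn{\phi_a}, the moment matrix is
#' \deqn{M(u) = \sum_i H(u - u_i) H(u - u_i)^T \phi_a(u - u_i)}
#' and \eqn{\Psi_i(u) = H(0)^T M(u)^{-1} H(u - u_i)\, \phi_a(u - u_i)}.
#' By construction the weights form a partition of unity and reproduce
#' polynomials up to the basis order exactly:
#' \eqn{\sum_i \Psi_i(u) u_i^k = u^k} for \eqn{k \le n}.
#'
#' If fewer than \code{basisOrder + 1} nodes fall inside the kernel support of
#' \code{uEval}, or the moment matrix is ill-conditioned (as happens near the
#' profile edges), the support is widened adaptively until it is invertible.
#'
#' @param uEval evaluation point(s) in [0, 1].
#' @param nodes strictly increasing node locations in [0, 1].
#' @param config an [rkConfig()] object.
#' @return if \code{uEval} is scalar, a numeric weight vector (one weight per
#'   node); otherwise a \code{length(uEval) x length(nodes)} matrix of
#'   weights.
#' @section Errors: \code{clearquant_bad_eval_point} outside [0, 1];
#'   \code{clearquant_singular_moment} if widening cannot fix conditioning.
#' @examples
#' psi <- rkShapeFunctions(0.5, seq(0, 1, 0.1), rkConfig())
#' sum(psi)                                   # partition of unity
#' sum(psi * seq(0, 1, 0.1))                  # reproduces u exactly
#' @export
rkShapeFunctions <- function(uEval, nodes, config = rkConfig()) {
    stopifnot(is(config, "RKConfig"))
    if (anyNA(uEval) || any(uEval < 0 | uEval > 1))
        .err("clearquant_bad_eval_point",
             "evaluation points must lie within [0, 1]")
    if (length(nodes) < config@basisOrder + 2L)
        .err("clearquant_too_few_nodes",
             "need at least basisOrder + 2 = %d nodes, got %d",
             config@basisOrder + 2L, length(nodes))
    if (is.unsorted(nodes, strictly = TRUE))
        .err("clearquant_bad_nodes", "nodes must be strictly increasing")
    a <- if (is.na(config@support)) .defaultSupport(nodes) else config@support
    out <- vapply(uEval, .rkWeightsAt, numeric(length(nodes)),
                  nodes = nodes, basisOrder = config@basisOrder,
                  kernel = config@kernel, support = a, ridge = config@ridge)
    if (length(uEval) == 1L) drop(out) else t(out)
}

#' Fit a reproducing-kernel approximant to a normalized profile
#'
#' The profile's normalized depths become the nodes and its normalized
#' intensities the nodal values of the approximant
#' \eqn{y_h(u) = \sum_i \Psi_i(u)\, y_i}. Nothing is solved at fit time (the
#' construction is a quasi-interpolation, not a regression); the returned
#' model is evaluated lazily by [evaluateOnGrid()].
#'
#' @param profile a [NormalizedProfile-class] with at least
#'   \code{basisOrder + 2} points (4 or more recommended for moment-matrix
#'   conditioning).
#' @param config an [rkConfig()].
#' @return an [RKModel-class].
#' @section Errors: \code{clearquant_too_few_nodes};
#'   \code{clearquant_bad_values} for non-finite intensities.
#' @export
fitRK <- function(profile, config = rkConfig()) {
    stopifnot(is(profile, "NormalizedProfile"), is(config, "RKConfig"))
    u <- normDepths(profile)
    y <- normIntensities(profile)
    if (length(u) < config@basisOrder + 2L)
        .err("clearquant_too_few_nodes",
             "profile has %d points; need at least %d", length(u),
             config@basisOrder + 2L)
    if (anyNA(y) || any(!is.finite(y)))
        .err("clearquant_bad_values", "profile intensities contain NaN")
    new("RKModel", nodes = u, nodeValues = y, config = config,
        labels = expLabels(profile))
}

#' Evaluate a reproducing-kernel model on the common 0.005 grid
#'
#' Evaluates the approximant at the 201 normalized depths
#' \eqn{u = 0, 0.005, \ldots, 1} shared by every experiment, and clamps the
#' result to [0, 1]: kernel overshoot must not feed unphysical negative
#' intensities into the AUC.
#'
#' @param model an [RKModel-class].
#' @return a [SampledCurve-class].
#' @export
evaluateOnGrid <- function(model) {
    stopifnot(is(model, "RKModel"))
    W <- rkShapeFunctions(curveGrid(), model@nodes, model@config)
    vals <- drop(W %*% model@nodeValues)
    new("SampledCurve", values = pmin(pmax(vals, 0), 1),
        labels = expLabels(model))
}
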