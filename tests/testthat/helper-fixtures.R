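## shared fixture builders -- everything is generated in code at test time

labs <- function(experiment = "e1", group = "g1", specimen = "s1",
                 region = "r1", channel = "AF")
    experimentLabels(experiment, group, specimen, region, channel)

makeStack <- function(voxels, zStep = 1, ...)
    new("ZStack", voxels = voxels, zStep = zStep, labels = labs(...))

makeProfile <- function(z, intensity, ...)
    new("DepthProfile", z = z, intensity = intensity, labels = labs(...))

makeNorm <- function(u, y, zMax = 100, ...)
    new("NormalizedProfile", u = u, y = y, zMax = zMax, labels = labs(...))

makeCurve <- function(values, ...)
    new("SampledCurve", values = values, labels = labs(...))

## independent dense-matrix evaluation of the reproducing-kernel shape
## functions: unscaled monomials, explicit kernel, base solve() -- coded
## separately from the package's support-scaled implementation
oracleRkWeights <- function(uEval, nodes, order = 1L, a = NULL) {
    if (is.null(a)) a <- 2.5 * median(diff(nodes))
    phi <- function(s) {
        z <- abs(s) / a
        ifelse(z <= 0.5, 2 / 3 - 4 * z^2 + 4 * z^3,
               ifelse(z < 1, 4 / 3 * (1 - z)^3, 0))
    }
    s <- uEval - nodes
    w <- phi(s)
    H <- t(vapply(s, function(si) si^(0:order), numeric(order + 1L)))
    M <- matrix(0, order + 1L, order + 1L)
    for (i in seq_along(nodes))
        M <- M + w[i] * tcrossprod(H[i, ])
    c0 <- solve(M, c(1, numeric(order)))
    as.numeric(w * (H %*% c0))
}

## two-way factorial data with prescribed cell means (A rows, B cols)
factorialData <- function(cellMeans, n, noise = function(k) rnorm(k)) {
    A <- rownames(cellMeans); B <- colnames(cellMeans)
    do.call(rbind, lapply(seq_along(A), function(i)
        do.call(rbind, lapply(seq_along(B), function(j)
            data.frame(auc = cellMeans[i, j] + noise(n),
                       fA = A[i], fB = B[j])))))
}
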