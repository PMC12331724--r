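test_that("shape functions form a partition of unity and reproduce linears", {
    set.seed(5)
    for (i in 1:10) {
        nodes <- unique(c(0, sort(runif(sample(6:40, 1))), 1))
        W <- rkShapeFunctions(curveGrid(), nodes, rkConfig())
        expect_lt(max(abs(rowSums(W) - 1)), 1e-10)
        expect_lt(max(abs(drop(W %*% nodes) - curveGrid())), 1e-8)
    }
})

test_that("shape functions agree with an independent dense implementation", {
    set.seed(9)
    nodes <- seq(0, 1, length.out = 17)
    ue <- runif(50, 0.1, 0.9)      # interior, where no adaptive widening kicks in
    W <- rkShapeFunctions(ue, nodes, rkConfig())
    for (k in seq_along(ue))
        expect_lt(max(abs(W[k, ] - oracleRkWeights(ue[k], nodes))), 1e-9)
})

test_that("locality: evaluation at a node under small support loads that node", {
    nodes <- seq(0, 1, length.out = 11)
    psi <- rkShapeFunctions(0.5, nodes, rkConfig(support = 0.11))
    expect_gt(psi[6], 0.99)
    expect_equal(sum(psi), 1, tolerance = 1e-12)
})

test_that("fitRK reproduces linear and constant profiles exactly on the grid", {
    u <- seq(0, 1, length.out = 30)
    lin <- makeNorm(u, 0.3 - 0.2 * u)
    cv <- evaluateOnGrid(fitRK(lin))
    expect_lt(max(abs(curveValues(cv) - (0.3 - 0.2 * curveGrid()))), 1e-8)

    const <- makeNorm(u, rep(0.4, 30))
    expect_lt(max(abs(curveValues(evaluateOnGrid(fitRK(const))) - 0.4)),
              1e-10)
})

test_that("the evaluation grid contract holds: 201 points at spacing 0.005", {
    g <- curveGrid()
    expect_length(g, 201L)
    expect_true(all(abs(diff(g) - 0.005) < 1e-15))
    u <- seq(0, 1, length.out = 12)
    cv <- evaluateOnGrid(fitRK(makeNorm(u, exp(-2 * u))))
    expect_length(curveValues(cv), 201L)
    expect_true(all(is.finite(curveValues(cv))))
    expect_true(all(curveValues(cv) >= 0 & curveValues(cv) <= 1))
})

test_that("smoothing attenuates noise on an exponential profile", {
    set.seed(13)
    u <- seq(0, 1, length.out = 80)
    sdNoise <- 0.02
    truth <- 0.8 * exp(-3 * u)
    y <- pmin(pmax(truth + rnorm(80, 0, sdNoise), 0), 1)
    cv <- curveValues(evaluateOnGrid(fitRK(makeNorm(u, y))))
    rms <- sqrt(mean((cv - 0.8 * exp(-3 * curveGrid()))^2))
    expect_lt(rms, sdNoise * 1.5)
})

test_that("mirroring the profile mirrors the curve", {
    set.seed(17)
    u <- sort(runif(25)); u <- unique(c(0, u, 1))
    y <- runif(length(u), 0.2, 0.9)
    fwd <- curveValues(evaluateOnGrid(fitRK(makeNorm(u, y))))
    bwd <- curveValues(evaluateOnGrid(fitRK(makeNorm(rev(1 - u), rev(y)))))
    expect_equal(bwd, rev(fwd), tolerance = 1e-9)
})

test_that("as support shrinks toward node spacing the fit approaches the data", {
    u <- seq(0, 1, length.out = 10)
    y <- 0.9 * exp(-1.5 * u)
    h <- diff(u)[1]
    cvTight <- curveValues(evaluateOnGrid(fitRK(makeNorm(u, y),
                                                rkConfig(support = 1.05 * h))))
    interp <- approx(u, y, xout = curveGrid())$y
    expect_lt(max(abs(cvTight - interp)), 0.01)
})

test_that("degenerate inputs raise named errors", {
    expect_error(rkShapeFunctions(1.2, seq(0, 1, 0.1), rkConfig()),
                 class = "clearquant_bad_eval_point")
    expect_error(rkShapeFunctions(0.5, c(0, 1), rkConfig(basisOrder = 2)),
                 class = "clearquant_too_few_nodes")
    expect_error(fitRK(makeNorm(c(0, 1), c(1, 0))),
                 class = "clearquant_too_few_nodes")
    expect_error(rkConfig(basisOrder = 5))
})
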