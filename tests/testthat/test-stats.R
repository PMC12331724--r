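test_that("star labels follow the strict reporting thresholds", {
    expect_identical(starLabel(c(0.03, 0.0005, 0.05, 0.009, 0.2)),
                     c("*", "***", "N.S.", "**", "N.S."))
    expect_error(starLabel(1.2), class = "clearquant_bad_pvalue")
})

test_that("normality check returns Shapiro-Wilk W/p and usable Q-Q points", {
    ## inverse-normal scores are as normal as a sample can be
    scores <- qnorm(ppoints(50))
    nc <- normalityCheck(scores)
    expect_gt(nc$W, 0.99)
    ## Q-Q points of a standard normal sample hug the identity line
    set.seed(2)
    x <- rnorm(200)
    qq <- normalityCheck(x)$qq
    slope <- coef(lm(sample ~ theoretical, qq))[2]
    expect_true(slope > 0.9 && slope < 1.1)
    ## heavy tails are detected reliably
    set.seed(31)
    hits <- sum(replicate(200, normalityCheck(rt(500, df = 2))$p < 0.05))
    expect_gte(hits, 190)
    expect_error(normalityCheck(c(1, 2)), class = "clearquant_bad_sample_size")
    expect_error(normalityCheck(rep(3, 10)),
                 class = "clearquant_constant_input")
})

test_that("ANOVA matches hand-computed sums of squares on a balanced design", {
    set.seed(41)
    cm <- matrix(c(10, 12, 9, 14, 11, 13), 3, 2,
                 dimnames = list(c("a1", "a2", "a3"), c("b1", "b2")))
    d <- factorialData(cm, n = 5)
    res <- aucAnova(d, c("fA", "fB"))

    ## brute-force type-II-on-balanced = classic factorial sums of squares
    y <- d$auc; A <- factor(d$fA); B <- factor(d$fB)
    grand <- mean(y)
    ssA <- sum(tapply(y, A, function(v) length(v) * (mean(v) - grand)^2))
    ssB <- sum(tapply(y, B, function(v) length(v) * (mean(v) - grand)^2))
    cellm <- tapply(y, list(A, B), mean)
    ssCells <- 5 * sum((cellm - grand)^2)
    ssAB <- ssCells - ssA - ssB
    ssE <- sum((y - cellm[cbind(A, B)])^2)
    dfE <- length(y) - 6
    expect_equal(res$statistic[res$effect == "fA"],
                 (ssA / 2) / (ssE / dfE), tolerance = 1e-10)
    expect_equal(res$statistic[res$effect == "fB"],
                 (ssB / 1) / (ssE / dfE), tolerance = 1e-10)
    expect_equal(res$statistic[res$effect == "fA:fB"],
                 (ssAB / 2) / (ssE / dfE), tolerance = 1e-10)
    expect_equal(res$df2, rep(dfE, 3))
})

test_that("ANOVA finds a large shift and stays calm under the null mean pattern", {
    set.seed(55)
    d <- data.frame(auc = c(rnorm(10), rnorm(10, 5)),
                    g = rep(c("a", "b"), each = 10))
    expect_lt(aucAnova(d, "g")$p, 0.001)

    dnull <- data.frame(auc = c(1, 2, 3, 1, 2, 3), g = rep(c("a", "b"), 3))
    expect_lt(aucAnova(dnull, "g")$statistic, 1e-20)

    dtie <- data.frame(auc = rep(c(1, 2), each = 3),
                       g = rep(c("a", "b"), each = 3))
    expect_error(aucAnova(dtie, "g"), class = "clearquant_zero_variance")
})

test_that("ART isolates the effect it aligns for", {
    set.seed(77)
    cm <- matrix(0, 2, 3, dimnames = list(c("a1", "a2"), c("b1", "b2", "b3")))
    cm["a2", ] <- 3                      # pure A effect
    d <- factorialData(cm, n = 8, noise = function(k) rlnorm(k) - 1)
    res <- alignedRankTransform(d, c("fA", "fB"))
    expect_lt(res$p[res$effect == "fA"], 0.001)
    expect_gt(res$p[res$effect == "fB"], 0.05)
    expect_gt(res$p[res$effect == "fA:fB"], 0.05)
    ## algebraic alignment property: stripped effects vanish
    expect_lt(attr(res, "alignment_check"), 1e-10)
})

test_that("ART p-values are exactly invariant to affine response transforms", {
    set.seed(78)
    cm <- matrix(c(0, 1, 2, 0.5, 1.5, 0), 2, 3,
                 dimnames = list(c("a1", "a2"), c("b1", "b2", "b3")))
    d <- factorialData(cm, n = 6, noise = function(k) rlnorm(k))
    p1 <- alignedRankTransform(d, c("fA", "fB"))$p
    d2 <- d; d2$auc <- 7 * d$auc - 3
    expect_identical(p1, alignedRankTransform(d2, c("fA", "fB"))$p)
})

test_that("ART degenerates safely", {
    d <- data.frame(auc = rep(1, 12), fA = rep(c("x", "y"), 6),
                    fB = rep(c("u", "v"), each = 6))
    expect_error(alignedRankTransform(d, c("fA", "fB")),
                 class = "clearquant_constant_input")
    dsing <- data.frame(auc = rnorm(5), fA = c("x", "x", "y", "y", "y"),
                        fB = c("u", "v", "u", "v", "v"))
    expect_error(alignedRankTransform(dsing, c("fA", "fB")),
                 class = "clearquant_empty_cell")
})

test_that("pairwise post-hoc contrasts behave at both extremes", {
    set.seed(91)
    ## two cells holding literally the same values: contrast is exactly zero
    vals <- rnorm(10)
    d0 <- data.frame(auc = c(vals, vals), g = rep(c("a", "b"), each = 10))
    ph <- pairwisePosthoc(d0, "g")
    expect_gt(ph$p, 0.99)

    ## one outlying cell among six: exactly its five contrasts light up
    d6 <- do.call(rbind, lapply(1:6, function(g)
        data.frame(auc = rnorm(8, mean = ifelse(g == 4, 6, 0), sd = 0.5),
                   g = paste0("c", g))))
    ph6 <- pairwisePosthoc(d6, "g")
    hot <- grepl("c4", ph6$effect)
    expect_true(all(ph6$significant[hot]))
    expect_false(any(ph6$significant[!hot]))

    ph6r <- pairwisePosthoc(d6, "g", method = "art_contrasts_holm")
    hotr <- grepl("c4", ph6r$effect)
    expect_true(all(ph6r$significant[hotr]))
    expect_false(any(ph6r$significant[!hotr]))

    expect_error(pairwisePosthoc(d0, "g", method = "bonferroni"),
                 class = "clearquant_bad_method")
})
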