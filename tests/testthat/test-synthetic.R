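test_that("simulateProfile realizes the Beer-Lambert identities", {
    groups <- data.frame(group = c("flat", "half"), channel = "AF",
                         mu_eff = c(1e-9, log(2)), I0 = c(120, 200))
    spec <- syntheticSpec(groups = groups, noise = "none", quantize = FALSE,
                          specimenSdLogMu = 0, regionSdI0 = 0,
                          nSlices = 50L, seed = 7)
    flat <- simulateProfile(spec, "flat")
    expect_equal(intensities(flat), rep(120, 50), tolerance = 1e-6)

    half <- simulateProfile(spec, "half")
    expect_equal(intensities(half)[50], 100, tolerance = 1e-9)
    expect_equal(intensities(half)[1], 200)

    ## determinism: identical spec => bitwise-identical draws
    spec2 <- syntheticSpec(groups = groups, noise = "none", quantize = FALSE,
                           specimenSdLogMu = 0, regionSdI0 = 0,
                           nSlices = 50L, seed = 7)
    expect_identical(intensities(simulateProfile(spec2, "half")),
                     intensities(half))
    noisy <- syntheticSpec(seed = 12)
    expect_identical(intensities(simulateProfile(noisy, "BABB")),
                     intensities(simulateProfile(noisy, "BABB")))
    ## ...and specimen-level perturbation is shared across regions
    sA <- simulateProfile(noisy, "BABB", specimen = 2, region = 1)
    sB <- simulateProfile(noisy, "BABB", specimen = 2, region = 2)
    expect_equal(fitMuEff(sA)$muEffNorm, fitMuEff(sB)$muEffNorm,
                 tolerance = 0.05)
})

test_that("simulateStudy produces the full crossed layout and design table", {
    spec <- syntheticSpec(seed = 5)            # 6 groups x 2 channels
    study <- simulateStudy(spec)
    expect_length(study$profiles, 12 * 3 * 3)
    expect_equal(nrow(study$design), 12 * 3 * 3)
    expect_setequal(unique(study$design$group),
                    c("BABB", "BABB-F", "GLY", "GLY-F", "NC", "NC-F"))
    expect_setequal(unique(study$design$clearing), c("BABB", "GLY", "NC"))
    expect_setequal(unique(study$design$fixation), c("fixed", "unfixed"))
    expect_false(anyDuplicated(study$design$experiment_id) > 0)
})

test_that("fitMuEff inverts noise-free decays exactly", {
    groups <- data.frame(group = c("g3", "g0"), channel = "AF",
                         mu_eff = c(3, 1e-12), I0 = c(200, 200))
    spec <- syntheticSpec(groups = groups, noise = "none", quantize = FALSE,
                          specimenSdLogMu = 0, regionSdI0 = 0,
                          nSlices = 50L, zMaxRange = c(100, 100), seed = 2)
    est <- fitMuEff(simulateProfile(spec, "g3"))
    expect_equal(est$muEffNorm, 3, tolerance = 1e-6)
    expect_equal(est$muEffPerUm, 0.03, tolerance = 1e-6)
    expect_equal(est$I0, 200, tolerance = 1e-6)

    flat <- fitMuEff(simulateProfile(spec, "g0"))
    expect_lt(abs(flat$muEffNorm), 1e-8)

    expect_error(fitMuEff(makeProfile(c(0, 1, 2, 3), c(200, 0.5, 0.2, 0.1))),
                 class = "clearquant_too_few_points")
})

test_that("expected AUC decreases in mu and quantization bias stays small", {
    aucFor <- function(mu, quantize) {
        groups <- data.frame(group = "g", channel = "AF", mu_eff = mu,
                             I0 = 200)
        spec <- syntheticSpec(groups = groups, noise = "none",
                              quantize = quantize, specimenSdLogMu = 0,
                              regionSdI0 = 0, nSlices = 400L, seed = 1)
        np <- normalizeProfile(simulateProfile(spec, "g"))
        computeAUC(evaluateOnGrid(fitRK(np)))$auc
    }
    mus <- c(0.5, 1, 2, 5, 10)
    exact <- lapply(mus, aucFor, quantize = FALSE)
    expect_true(all(diff(unlist(exact)) < 0))
    for (i in seq_along(mus)) {
        closed <- (200 / 255) * (1 - exp(-mus[i])) / mus[i]
        expect_equal(exact[[i]], closed, tolerance = 5e-3)
        expect_lt(abs(aucFor(mus[i], TRUE) - closed), 0.005)
    }
})

test_that("group decay tables are internally consistent", {
    for (tab in list(clearingStudyGroups(), validationStudyGroups())) {
        expect_equal(nrow(tab), 12L)
        for (ch in c("AF", "SHG")) {
            mu <- setNames(tab$mu_eff[tab$channel == ch],
                           tab$group[tab$channel == ch])
            expect_true(mu[["NC"]] > mu[["GLY"]] &&
                        mu[["GLY"]] > mu[["BABB"]])
        }
    }
    ## the validation table's designed crossover: zero expected marginal
    ## fixation effect on the closed-form AUC scale
    v <- validationStudyGroups()
    f <- function(mu) (1 - exp(-mu)) / mu
    v$auc <- v$I0 / 255 * f(v$mu_eff)
    marg <- tapply(v$auc, list(v$fixation, v$channel), mean)
    expect_equal(marg["fixed", "AF"], marg["unfixed", "AF"],
                 tolerance = 2e-3)
    expect_equal(marg["fixed", "SHG"], marg["unfixed", "SHG"],
                 tolerance = 2e-3)
})
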