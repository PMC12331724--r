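#' @include AllClasses.R AllGenerics.R profiles.R
NULL

## deterministic sub-seed from the study seed and a label path, so specimen-
## level draws are shared across that specimen's regions and everything is
## reproducible from the single study seed (kept below 2^31)
.derivedSeed <- function(seed, ...) {
    h <- as.integer(seed) %% 2147483629L
    for (ch in utf8ToInt(paste(..., sep = "\r")))
        h <- (h * 31 + ch) %% 2147483629L
    as.integer(h)
}

.withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv())) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(rm(list = ".Random.seed", envir = globalenv()))
    }
    set.seed(seed)
    expr
}

#' Default group decay table: a six-group clearing-by-fixation study
#'
#' Beer-Lambert parameters for the canonical two-factor design: three
#' clearing conditions (BABB, glycerol, uncleared) crossed with formalin
#' fixation, observed in both channels. Effective attenuation (per unit
#' normalized depth) and surface intensity are calibrated so the noise-free
#' closed-form AUC \eqn{(I_0/255)(1-e^{-\mu})/\mu} matches the transparency
#' ranking typical of such studies: BABB clears best, glycerol moderately,
#' uncleared tissue barely, with fixation helping glycerol but hurting BABB,
#' and SHG everywhere dimmer than autofluorescence.
#'
#' @return data.frame with columns \code{group, channel, mu_eff, I0,
#'   clearing, fixation}; the extra factor columns propagate into the design
#'   table of [simulateStudy()].
#' @export
clearingStudyGroups <- function() {
    g <- expand.grid(clearing = c("BABB", "GLY", "NC"),
                     fixation = c("unfixed", "fixed"),
                     channel = c("AF", "SHG"),
                     stringsAsFactors = FALSE)
    g$group <- paste0(g$clearing, ifelse(g$fixation == "fixed", "-F", ""))
    key <- paste(g$group, g$channel)
    mu <- c("BABB AF" = 7.15, "BABB-F AF" = 11.98, "GLY AF" = 50.28,
            "GLY-F AF" = 15.83, "NC AF" = 89.64, "NC-F AF" = 63.03,
            "BABB SHG" = 43.57, "BABB-F SHG" = 78.43, "GLY SHG" = 117.65,
            "GLY-F SHG" = 98.04, "NC SHG" = 130.72, "NC-F SHG" = 89.13)
    I0 <- c("BABB AF" = 220, "BABB-F AF" = 220, "GLY AF" = 150,
            "GLY-F AF" = 180, "NC AF" = 80, "NC-F AF" = 90,
            "BABB SHG" = 80, "BABB-F SHG" = 70, "GLY SHG" = 15,
            "GLY-F SHG" = 20, "NC SHG" = 10, "NC-F SHG" = 25)
    g$mu_eff <- unname(mu[key])
    g$I0 <- unname(I0[key])
    g[c("group", "channel", "mu_eff", "I0", "clearing", "fixation")]
}

#' Crossover validation design: a fixation effect with no marginal component
#'
#' A variant of [clearingStudyGroups()] built for end-to-end validation of
#' the analysis chain. The clearing ordering is as in the default table
#' (\eqn{\mu_{NC} > \mu_{GLY} > \mu_{BABB}} in both channels), but two
#' properties are designed in. First, the fixation effect is a pure
#' crossover: fixation lowers the expected closed-form AUC of BABB-cleared
#' tissue and raises that of glycerol-cleared tissue by the same amount
#' (0.03 in AF, 0.003 in SHG) and leaves uncleared tissue untouched, so the
#' expected fixation \emph{main} effect is exactly zero while the
#' clearing-by-fixation interaction is strong. Second, the dynamic range of
#' the group means is compressed (about 2:1 instead of the 30:1 of the
#' default table) so that within-group spreads are comparable across groups:
#' with the multiplicative variability model, widely separated group means
#' make the aligned rank transform anti-conservative for the null effect
#' (rank displacement of the low-variance groups by the alignment-estimate
#' noise), which would confound the validation. A correct pipeline must
#' find the clearing effect and the interaction significant and the
#' fixation effect not.
#'
#' @return data.frame in the format of [clearingStudyGroups()].
#' @seealso [clearingStudyGroups()] for the realistically wide-range table.
#' @export
validationStudyGroups <- function() {
    g <- clearingStudyGroups()
    key <- paste(g$group, g$channel)
    ## expected closed-form AUCs: AF 0.12/0.09/0.08/0.11/0.055/0.055,
    ## SHG one tenth of that; I0 fixed at 200 (AF) and 50 (SHG)
    mu <- c("BABB AF" = 6.53, "BABB-F AF" = 8.71, "GLY AF" = 9.80,
            "GLY-F AF" = 7.12, "NC AF" = 14.26, "NC-F AF" = 14.26,
            "BABB SHG" = 16.34, "BABB-F SHG" = 21.79, "GLY SHG" = 24.51,
            "GLY-F SHG" = 17.83, "NC SHG" = 35.65, "NC-F SHG" = 35.65)
    g$mu_eff <- unname(mu[key])
    g$I0 <- ifelse(g$channel == "AF", 200, 50)
    g
}

#' The canonical end-to-end validation study
#'
#' Bundles [validationStudyGroups()] with the replication structure the
#' validation requires: 9 independent specimens per group with a single
#' region each, so every experiment is an independent draw (with several
#' regions per specimen the shared specimen-level attenuation draw makes
#' regions correlated, and the fixed-effects tests -- which treat
#' experiments as replicates -- would be anti-conservative by
#' pseudo-replication).
#'
#' @param seed integer seed for the simulated study.
#' @return a [SyntheticSpec-class].
#' @export
validationStudySpec <- function(seed = 1L) {
    syntheticSpec(groups = validationStudyGroups(), nSpecimens = 9L,
                  nRegions = 1L, specimenSdLogMu = 0.15, regionSdI0 = 5,
                  seed = seed)
}

#' Build a synthetic-study specification
#'
#' Parameterizes the Beer-Lambert z-stack simulator: per-group decay curves,
#' hierarchical variability (specimen-level lognormal perturbation of
#' \eqn{\mu_{\mathrm{eff}}} shared by all regions of a specimen; region-level
#' Gaussian perturbation of \eqn{I_0}), additive detector noise, unequal
#' per-experiment imaging depths, and 8-bit quantization. Defaults describe a
#' realistic six-group clearing-by-fixation study: 3 specimens x 3 regions
#' per group, ~20--25\% between-experiment AUC variability, Gaussian noise of
#' 2 grey levels, 400 slices over a 200--280 um deep stack.
#'
#' @param groups decay table as in [clearingStudyGroups()] (the default);
#'   extra columns are carried into the design table as factors.
#' @param nSpecimens,nRegions specimens per group and regions per specimen.
#' @param specimenSdLogMu SD of log-normal specimen perturbation on mu_eff.
#' @param regionSdI0 SD (grey levels) of Gaussian region perturbation on I0.
#' @param noise "gaussian", "poisson" or "none".
#' @param noiseParam Gaussian SD or Poisson gain, in grey levels.
#' @param nSlices slices per simulated stack.
#' @param zMaxRange range (um) for the per-experiment maximum imaging depth.
#' @param quantize round intensities to integer grey levels.
#' @param seed integer; the sole source of randomness.
#' @return a [SyntheticSpec-class].
#' @examples
#' sp <- syntheticSpec(seed = 1)
#' sp
#' @export
syntheticSpec <- function(groups = clearingStudyGroups(), nSpecimens = 3L,
                          nRegions = 3L, specimenSdLogMu = 0.2,
                          regionSdI0 = 15,
                          noise = c("gaussian", "poisson", "none"),
                          noiseParam = 2, nSlices = 400L,
                          zMaxRange = c(200, 280), quantize = TRUE,
                          seed = 1L) {
    new("SyntheticSpec", groups = groups, nSpecimens = as.integer(nSpecimens),
        nRegions = as.integer(nRegions), specimenSdLogMu = specimenSdLogMu,
        regionSdI0 = regionSdI0, noise = match.arg(noise),
        noiseParam = noiseParam, nSlices = as.integer(nSlices),
        zMaxRange = zMaxRange, quantize = quantize, seed = as.integer(seed))
}

#' Simulate one depth-intensity profile
#'
#' Draws the experiment for (group, specimen, region, channel) under the
#' spec's Beer-Lambert model
#' \eqn{I(z) = I_0' \exp(-\mu' z / z_{max}) + \epsilon}: the specimen-level
#' lognormal factor on \eqn{\mu_{\mathrm{eff}}} is derived from the study
#' seed and the specimen identity (so all regions of a specimen share it),
#' the region-level Gaussian shift on \eqn{I_0} from the region identity,
#' then detector noise is added, intensities are clamped to [0, 255] and,
#' if \code{quantize}, rounded to integer grey levels. Identical spec and
#' identities give a bitwise-identical profile.
#'
#' @param spec a [SyntheticSpec-class].
#' @param group group name present in \code{spec@groups}.
#' @param specimen,region 1-based indices (or labels) of specimen and region.
#' @param channelName "AF" or "SHG".
#' @return a [DepthProfile-class].
#' @export
simulateProfile <- function(spec, group, specimen = 1L, region = 1L,
                            channelName = "AF") {
    stopifnot(is(spec, "SyntheticSpec"))
    row <- spec@groups[spec@groups$group == group &
                       spec@groups$channel == channelName, ]
    if (nrow(row) != 1L)
        .err("clearquant_unknown_group",
             "no decay parameters for group '%s' channel '%s'", group,
             channelName)
    muP <- row$mu_eff * .withSeed(
        .derivedSeed(spec@seed, "specimen", group, specimen),
        exp(stats::rnorm(1L, 0, spec@specimenSdLogMu)))
    I0P <- .withSeed(
        .derivedSeed(spec@seed, "region", group, specimen, region,
                     channelName),
        row$I0 + stats::rnorm(1L, 0, spec@regionSdI0))
    I0P <- min(max(I0P, 1), 255)
    zmax <- .withSeed(.derivedSeed(spec@seed, "zmax", group, specimen, region),
                      stats::runif(1L, spec@zMaxRange[1L], spec@zMaxRange[2L]))
    z <- seq(0, zmax, length.out = spec@nSlices)
    I <- I0P * exp(-muP * z / zmax)
    I <- .withSeed(.derivedSeed(spec@seed, "noise", group, specimen, region,
                                channelName),
                   switch(spec@noise,
                          gaussian = I + stats::rnorm(length(I), 0,
                                                      spec@noiseParam),
                          poisson = if (spec@noiseParam > 0)
                              stats::rpois(length(I), I / spec@noiseParam) *
                                  spec@noiseParam else I,
                          none = I))
    I <- pmin(pmax(I, 0), 255)
    if (spec@quantize) I <- round(I)
    new("DepthProfile", z = z, intensity = I,
        labels = experimentLabels(
            experiment = paste(group, specimen, region, channelName,
                               sep = "_"),
            group = group, specimen = paste0("S", specimen),
            region = paste0("R", region), channel = channelName))
}

#' Simulate a full crossed imaging study
#'
#' Generates every (group x specimen x region x channel) experiment of the
#' spec and the matching design table for the statistics module. Extra
#' columns of \code{spec@groups} (e.g. \code{clearing}, \code{fixation})
#' are propagated into the design table as factor columns.
#'
#' @param spec a [SyntheticSpec-class] with >= 1 group.
#' @return list with \code{profiles} (list of [DepthProfile-class]) and
#'   \code{design} (data.frame: experiment_id, group, specimen, region,
#'   channel, plus any extra factor columns).
#' @export
simulateStudy <- function(spec) {
    stopifnot(is(spec, "SyntheticSpec"))
    g <- spec@groups
    extra <- setdiff(names(g), c("group", "channel", "mu_eff", "I0"))
    rows <- expand.grid(region = seq_len(spec@nRegions),
                        specimen = seq_len(spec@nSpecimens),
                        idx = seq_len(nrow(g)))
    profiles <- vector("list", nrow(rows))
    design <- vector("list", nrow(rows))
    for (i in seq_len(nrow(rows))) {
        gi <- rows$idx[i]
        p <- simulateProfile(spec, g$group[gi], rows$specimen[i],
                             rows$region[i], g$channel[gi])
        profiles[[i]] <- p
        lb <- expLabels(p)
        d <- data.frame(experiment_id = lb[["experiment"]],
                        group = lb[["group"]], specimen = lb[["specimen"]],
                        region = lb[["region"]], channel = lb[["channel"]])
        for (col in extra) d[[col]] <- g[[col]][gi]
        design[[i]] <- d
    }
    names(profiles) <- vapply(profiles, function(p)
        expLabels(p)[["experiment"]], "")
    list(profiles = profiles, design = do.call(rbind, design))
}

#' Estimate the effective attenuation coefficient of a profile
#'
#' Log-linear inversion of the Beer-Lambert decay: ordinary least squares of
#' \eqn{\ln I} on \eqn{z} over the leading run of points with intensity
#' >= 1 grey level -- the fit stops at the first sample that falls below 1,
#' because beyond that depth detector noise re-crossing the threshold would
#' otherwise contribute spurious flat points and bias the slope towards
#' zero. The slope magnitude is the effective attenuation; the intercept
#' recovers the surface intensity.
#'
#' @param profile a [DepthProfile-class] with at least 4 points of
#'   intensity >= 1.
#' @return list with \code{muEffPerUm} (per micrometre), \code{muEffNorm}
#'   (per unit normalized depth, i.e. scaled by the profile's max depth),
#'   \code{I0} (estimated surface intensity) and \code{nUsed}.
#' @section Errors: \code{clearquant_too_few_points}.
#' @examples
#' sp <- syntheticSpec(noise = "none", quantize = FALSE,
#'                     specimenSdLogMu = 0, regionSdI0 = 0)
#' fitMuEff(simulateProfile(sp, "BABB"))$muEffNorm   # ~7.15
#' @export
fitMuEff <- function(profile) {
    stopifnot(is(profile, "DepthProfile"))
    z <- depths(profile)
    I <- intensities(profile)
    below <- which(I < 1)
    keep <- seq_len(if (length(below)) below[1L] - 1L else length(I))
    if (length(keep) < 4L)
        .err("clearquant_too_few_points",
             "need >= 4 points with intensity >= 1, got %d", length(keep))
    fit <- stats::lm.fit(cbind(1, z[keep]), log(I[keep]))
    slope <- -fit$coefficients[2L]
    list(muEffPerUm = unname(slope),
         muEffNorm = unname(slope * max(z)),
         I0 = unname(exp(fit$coefficients[1L])), nUsed = length(keep))
}
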