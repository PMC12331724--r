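#' @include AllClasses.R AllGenerics.R stack-io.R
NULL

.statResult <- function(test, effect, statistic, df1, df2, p) {
    data.frame(test = test, effect = effect, statistic = statistic,
               df1 = df1, df2 = df2, p = p,
               significant = !is.na(p) & p < 0.05,
               stars = starLabel(p))
}

#' Significance star labels
#'
#' The reporting convention: \code{"***"} for p < 0.001, \code{"**"} for
#' p < 0.01, \code{"*"} for p < 0.05, \code{"N.S."} otherwise. Boundaries are
#' strict (p = 0.05 is not significant).
#'
#' @param p vector of p-values in [0, 1] (NA allowed, labelled NA).
#' @return character vector of labels.
#' @examples
#' starLabel(c(0.03, 0.0005, 0.05))
#' @export
starLabel <- function(p) {
    if (any(!is.na(p) & (p < 0 | p > 1)))
        .err("clearquant_bad_pvalue", "p-values must lie in [0, 1]")
    ifelse(is.na(p), NA_character_,
           ifelse(p < 0.001, "***",
                  ifelse(p < 0.01, "**",
                         ifelse(p < 0.05, "*", "N.S."))))
}

#' Shapiro-Wilk normality check with Q-Q points
#'
#' Runs the Shapiro-Wilk test and returns the paired (theoretical normal
#' quantile, sample quantile) points used for Q-Q inspection -- the two
#' normality diagnostics that gate the choice between parametric ANOVA and
#' the aligned rank transform.
#'
#' @param values numeric vector, 3 <= n <= 5000, non-constant.
#' @return list with \code{W}, \code{p} and \code{qq} (data.frame with
#'   columns \code{theoretical}, \code{sample}, sorted by sample value).
#' @section Errors: \code{clearquant_bad_sample_size},
#'   \code{clearquant_constant_input}.
#' @export
normalityCheck <- function(values) {
    values <- values[!is.na(values)]
    if (length(values) < 3L || length(values) > 5000L)
        .err("clearquant_bad_sample_size",
             "Shapiro-Wilk needs 3 to 5000 observations, got %d",
             length(values))
    if (diff(range(values)) == 0)
        .err("clearquant_constant_input",
             "normality check undefined for constant input")
    sw <- stats::shapiro.test(values)
    qq <- stats::qqnorm(values, plot.it = FALSE)
    ord <- order(qq$y)
    list(W = unname(sw$statistic), p = sw$p.value,
         qq = data.frame(theoretical = qq$x[ord], sample = qq$y[ord]))
}

.checkCells <- function(data, factors, minPerCell = 1L) {
    cells <- interaction(data[factors], drop = FALSE)
    counts <- table(cells)
    if (any(counts < minPerCell))
        .err("clearquant_empty_cell",
             "design cell(s) with fewer than %d observations: %s",
             minPerCell,
             paste(names(counts)[counts < minPerCell], collapse = ", "))
    invisible(counts)
}

#' Factorial ANOVA on AUC values
#'
#' One-way or two-way (with interaction) fixed-effects ANOVA. Two-way designs
#' use type-II sums of squares so unbalanced specimen/region counts across
#' groups are handled sensibly.
#'
#' @param data data.frame containing the response and factor columns.
#' @param factors one factor name (one-way) or two (two-way with
#'   interaction).
#' @param response response column name, default \code{"auc"}.
#' @return data.frame of results, one row per effect: \code{test, effect,
#'   statistic} (F), \code{df1, df2, p, significant, stars}.
#' @section Errors: \code{clearquant_empty_cell},
#'   \code{clearquant_zero_variance} when the residual variance is zero so F
#'   is undefined.
#' @examples
#' d <- data.frame(auc = c(1, 2, 3, 7, 8, 9),
#'                 g = rep(c("a", "b"), each = 3))
#' aucAnova(d, "g")
#' @export
aucAnova <- function(data, factors, response = "auc") {
    stopifnot(length(factors) %in% 1:2,
              all(c(response, factors) %in% names(data)))
    data[factors] <- lapply(data[factors], factor)
    .checkCells(data, factors)
    rhs <- paste(factors, collapse = " * ")
    fit <- stats::lm(stats::reformulate(rhs, response), data = data)
    if (stats::df.residual(fit) < 1L)
        .err("clearquant_empty_cell", "no residual degrees of freedom")
    if (sum(stats::residuals(fit)^2) <= .Machine$double.eps *
            sum(fit$fitted.values^2 + 1))
        .err("clearquant_zero_variance",
             "residual variance is zero; F is undefined")
    tab <- car::Anova(fit, type = 2)
    eff <- rownames(tab)
    keep <- eff != "Residuals"
    dfres <- tab[["Df"]][!keep]
    .statResult(test = if (length(factors) == 1L) "one-way ANOVA"
                       else "two-way ANOVA (type II)",
                effect = eff[keep], statistic = tab[["F value"]][keep],
                df1 = tab[["Df"]][keep], df2 = dfres,
                p = tab[["Pr(>F)"]][keep])
}

## unweighted effect estimates from cell means (the alignment currency)
.artEstimates <- function(data, fA, fB, response) {
    cm <- tapply(data[[response]], list(data[[fA]], data[[fB]]), mean)
    mA <- rowMeans(cm)                      # unweighted marginal means
    mB <- colMeans(cm)
    grand <- mean(cm)
    list(cellMean = cm, A = mA - grand, B = mB - grand,
         AB = sweep(sweep(cm, 1L, mA), 2L, mB) + grand, grand = grand)
}

#' Aligned rank transform for two-way factorial designs
#'
#' The nonparametric route for non-normal factorial data. For each effect
#' (both main effects and the interaction) the procedure (i) estimates all
#' cell and marginal means, (ii) aligns every response by stripping the
#' estimates of every \emph{other} effect -- leaving the residual plus the
#' effect of interest, (iii) assigns midranks to the aligned responses, and
#' (iv) runs the full factorial ANOVA on the ranks, reporting only the
#' effect the data were aligned for.
#'
#' A correctness diagnostic is attached as
#' \code{attr(result, "alignment_check")}: the largest absolute stripped-
#' effect estimate recomputed from the aligned (unranked) responses, which
#' must be ~0 if the alignment is correct.
#'
#' @param data data.frame with the response and two factor columns.
#' @param factors the two factor column names.
#' @param response response column name, default \code{"auc"}.
#' @return data.frame of results (one row per effect: A, B, A:B) as in
#'   [aucAnova()], with the alignment diagnostic attached as an attribute.
#' @section Errors: \code{clearquant_empty_cell} for singleton cells (the
#'   alignment is degenerate); \code{clearquant_constant_input} when all
#'   responses tie.
#' @references Wobbrock, J.O., Findlater, L., Gergle, D., Higgins, J.J.
#'   (2011) The aligned rank transform for nonparametric factorial analyses
#'   using only ANOVA procedures. Proc. CHI 2011.
#' @export
alignedRankTransform <- function(data, factors, response = "auc") {
    stopifnot(length(factors) == 2L,
              all(c(response, factors) %in% names(data)))
    fA <- factors[1L]; fB <- factors[2L]
    data[factors] <- lapply(data[factors], factor)
    if (nlevels(data[[fA]]) < 2L || nlevels(data[[fB]]) < 2L)
        .err("clearquant_empty_cell", "each factor needs >= 2 levels")
    .checkCells(data, factors, minPerCell = 2L)
    if (diff(range(data[[response]])) == 0)
        .err("clearquant_constant_input", "all responses are tied")
    est <- .artEstimates(data, fA, fB, response)
    iA <- as.integer(data[[fA]]); iB <- as.integer(data[[fB]])
    resid <- data[[response]] - est$cellMean[cbind(iA, iB)]
    effects <- list("A" = est$A[iA], "B" = est$B[iB],
                    "A:B" = est$AB[cbind(iA, iB)])
    names(effects) <- c(fA, fB, paste(fA, fB, sep = ":"))
    out <- vector("list", 3L)
    checks <- numeric(3L)
    scale <- max(abs(data[[response]]), 1)
    for (k in seq_along(effects)) {
        aligned <- resid + effects[[k]]
        ## diagnostic: stripped effects must vanish on the aligned responses
        d2 <- data; d2[[response]] <- aligned
        e2 <- .artEstimates(d2, fA, fB, response)
        others <- setdiff(c("A", "B", "AB"), c("A", "B", "AB")[k])
        checks[k] <- max(abs(unlist(e2[others]))) / scale
        d2[[response]] <- rank(aligned)                 # midranks
        fit <- stats::lm(stats::reformulate(paste(fA, fB, sep = " * "),
                                            response), data = d2)
        tab <- car::Anova(fit, type = 2)
        row <- which(rownames(tab) == names(effects)[k])
        dfres <- tab[["Df"]][rownames(tab) == "Residuals"]
        out[[k]] <- .statResult("aligned rank transform",
                                names(effects)[k], tab[["F value"]][row],
                                tab[["Df"]][row], dfres, tab[["Pr(>F)"]][row])
    }
    res <- do.call(rbind, out)
    attr(res, "alignment_check") <- max(checks)
    res
}

#' Pairwise post-hoc comparisons
#'
#' All pairwise contrasts between the cells of a grouping (a single factor,
#' or the cells of a factor combination), with multiplicity control:
#' \code{"tukey_hsd"} (the default after a parametric ANOVA) or
#' \code{"art_contrasts_holm"} -- pairwise t contrasts on the midranked
#' responses with Holm adjustment, the companion to the aligned rank
#' transform.
#'
#' @param data data.frame with the response and grouping column(s).
#' @param factors one or more factor names; multiple names are crossed into
#'   cells.
#' @param response response column name, default \code{"auc"}.
#' @param method \code{"tukey_hsd"} or \code{"art_contrasts_holm"}.
#' @return data.frame of results, one row per contrast (effect column
#'   \code{"cellA - cellB"}), with adjusted p-values.
#' @section Errors: \code{clearquant_bad_method};
#'   \code{clearquant_empty_cell} for cells with n < 2.
#' @export
pairwisePosthoc <- function(data, factors, response = "auc",
                            method = c("tukey_hsd", "art_contrasts_holm")) {
    method <- tryCatch(match.arg(method),
                       error = function(e) .err("clearquant_bad_method",
                                                "unknown post-hoc method"))
    stopifnot(all(c(response, factors) %in% names(data)))
    cell <- droplevels(interaction(data[factors], sep = ":"))
    if (nlevels(cell) < 2L)
        .err("clearquant_empty_cell", "need >= 2 cells for pairwise contrasts")
    if (any(table(cell) < 2L))
        .err("clearquant_empty_cell", "every cell needs n >= 2")
    d <- data.frame(y = data[[response]], cell = cell)
    if (method == "tukey_hsd") {
        hsd <- stats::TukeyHSD(stats::aov(y ~ cell, data = d))$cell
        .statResult("Tukey HSD", rownames(hsd), hsd[, "diff"],
                    NA_real_, NA_real_, hsd[, "p adj"])
    } else {
        d$r <- rank(d$y)
        pt <- stats::pairwise.t.test(d$r, d$cell, p.adjust.method = "holm")$p.value
        eff <- outer(rownames(pt), colnames(pt), paste, sep = " - ")
        keep <- !is.na(pt)
        .statResult("ART contrasts (Holm)", eff[keep],
                    NA_real_, NA_real_, NA_real_, pt[keep])
    }
}
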