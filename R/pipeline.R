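#' @include AllClasses.R AllGenerics.R stack-io.R profiles.R rk.R auc.R stats.R synthetic.R
NULL

.defaultConfig <- function() {
    list(mode = "profile_csv",
         input = NULL,                 # TIFF dir, profile CSV, or NULL
         design = NULL,                # design-table CSV path
         channel = NULL,               # NULL = analyze all channels
         rk = list(basis_order = 1L, kernel = "cubic_bspline",
                   support = NA, ridge = 1e-12),
         auc = list(source = "rk"),    # "rk" or "raw"
         stats = list(alpha = 0.05, factors = "group", route = "auto",
                      posthoc = "auto"),
         thickness = list(rel_threshold = 0.05),
         synthetic = list(),           # overrides for syntheticSpec()
         outdir = ".",
         seed = 1L,
         log_level = "info")
}

.mergeConfig <- function(base, over) {
    for (nm in names(over)) {
        base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]]))
            .mergeConfig(base[[nm]], over[[nm]]) else over[[nm]]
    }
    base
}

#' Assemble a pipeline run configuration
#'
#' Starts from the documented defaults, overlays a YAML file (if given), then
#' overlays named arguments. Every under-specified analysis choice (per-slice
#' statistic, RK kernel and support, AUC source, normality gate, post-hoc
#' method, thickness threshold) is an explicit key so a run is fully
#' auditable.
#'
#' @param path optional YAML config file.
#' @param ... named overrides (nested lists merge recursively).
#' @return the configuration list.
#' @examples
#' cfg <- runConfig(seed = 7, stats = list(alpha = 0.01))
#' cfg$stats$alpha
#' @export
runConfig <- function(path = NULL, ...) {
    cfg <- .defaultConfig()
    if (!is.null(path))
        cfg <- .mergeConfig(cfg, yaml::read_yaml(path))
    cfg <- .mergeConfig(cfg, list(...))
    if (!is.numeric(cfg$stats$alpha) || cfg$stats$alpha <= 0 ||
        cfg$stats$alpha >= 1)
        .err("clearquant_bad_config", "stats.alpha must lie in (0, 1)")
    if (!cfg$auc$source %in% c("rk", "raw"))
        .err("clearquant_bad_config", "auc.source must be 'rk' or 'raw'")
    cfg$seed <- as.integer(cfg$seed)
    cfg
}

## hash only the analysis-relevant keys: file-system locations and log
## chatter must not change the provenance stamp of otherwise identical runs
.configHash <- function(cfg) {
    cfg <- cfg[setdiff(names(cfg), c("input", "design", "outdir",
                                     "log_level"))]
    s <- utf8ToInt(paste(utils::capture.output(utils::str(cfg)),
                         collapse = "\n"))
    h <- 0
    for (ch in s) h <- (h * 31 + ch) %% 2147483629
    sprintf("%08x", as.integer(h))
}

.log <- function(cfg, fmt, ...) {
    if (identical(cfg$log_level, "quiet")) return(invisible())
    message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...)))
}

## every output CSV carries a provenance comment (version + config hash)
.writeCsvWithHeader <- function(df, path, cfg) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# ClearQuant %s config %s",
                       as.character(utils::packageVersion("ClearQuant")),
                       .configHash(cfg)), con)
    utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
    path
}

.rkConfigFrom <- function(cfg)
    rkConfig(basisOrder = cfg$rk$basis_order, kernel = cfg$rk$kernel,
             support = as.numeric(cfg$rk$support), ridge = cfg$rk$ridge)

#' Extract profiles from a directory of TIFF z-stacks
#'
#' Reads every stack listed in the design table (columns \code{file},
#' \code{experiment_id, group, specimen, region, channel, z_step_um}),
#' extracts the per-slice mean-intensity profile, and writes the unified
#' profile CSV to \code{outdir/profiles.csv}. Unreadable stacks are logged
#' and skipped; if none can be read the run fails.
#'
#' @param config from [runConfig()]: \code{input} is the TIFF directory,
#'   \code{design} the design-table CSV with per-file metadata.
#' @return path of the written profile CSV, invisibly.
#' @export
runExtract <- function(config) {
    if (is.null(config$input) || !dir.exists(config$input))
        .err("clearquant_bad_config", "config$input must be a directory")
    if (is.null(config$design))
        .err("clearquant_bad_config",
             "extraction needs a design table with per-file metadata")
    design <- utils::read.csv(config$design, stringsAsFactors = FALSE, comment.char = "#")
    need <- c("file", "experiment_id", "group", "specimen", "region",
              "channel", "z_step_um")
    if (!all(need %in% names(design)))
        .err("clearquant_missing_column", "design table needs columns: %s",
             paste(need, collapse = ", "))
    profiles <- list()
    for (i in seq_len(nrow(design))) {
        path <- file.path(config$input, design$file[i])
        p <- tryCatch({
            st <- readTiffStack(path, design$z_step_um[i],
                                experimentLabels(design$experiment_id[i],
                                                 design$group[i],
                                                 design$specimen[i],
                                                 design$region[i],
                                                 design$channel[i]))
            extractProfile(st)
        }, error = function(e) {
            .log(config, "skipping '%s': %s", path, conditionMessage(e))
            NULL
        })
        if (!is.null(p)) profiles[[length(profiles) + 1L]] <- p
    }
    if (length(profiles) == 0L)
        .err("clearquant_empty_input", "no stack could be read from '%s'",
             config$input)
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    out <- file.path(config$outdir, "profiles.csv")
    writeProfileCsv(profiles, out)
    .log(config, "extracted %d profiles -> %s", length(profiles), out)
    invisible(out)
}

## normality gate on pooled model residuals, overridable via stats.route
.chooseRoute <- function(auc, data, factors, cfg) {
    forced <- cfg$stats$route
    fml <- stats::reformulate(paste(factors, collapse = " * "), "auc")
    res <- stats::residuals(stats::lm(fml, data = cbind(auc = auc, data)))
    nc <- tryCatch(normalityCheck(res), error = function(e) NULL)
    route <- if (forced %in% c("anova", "art")) forced
             else if (is.null(nc) || nc$p >= cfg$stats$alpha) "anova"
             else "art"
    list(route = route, W = if (is.null(nc)) NA_real_ else nc$W,
         p = if (is.null(nc)) NA_real_ else nc$p)
}

.statsForChannel <- function(records, design, cfg) {
    factors <- cfg$stats$factors
    d <- merge(records, design[!duplicated(design$experiment_id), ],
               by = "experiment_id", suffixes = c("", ".design"))
    gate <- .chooseRoute(d$auc, d, factors, cfg)
    main <- if (gate$route == "art" && length(factors) == 2L) {
        alignedRankTransform(d, factors)
    } else if (gate$route == "art") {
        d$auc_rank <- rank(d$auc)
        r <- aucAnova(d, factors, response = "auc_rank")
        r$test <- "rank-transformed one-way ANOVA"
        r
    } else {
        aucAnova(d, factors)
    }
    method <- if (cfg$stats$posthoc != "auto") cfg$stats$posthoc
              else if (gate$route == "art") "art_contrasts_holm"
              else "tukey_hsd"
    posthoc <- tryCatch(pairwisePosthoc(d, factors, method = method),
                        error = function(e) NULL)
    list(gate = gate, main = main, posthoc = posthoc)
}

#' Run the full depth-intensity analysis
#'
#' Profile CSV in; four artifacts out, all written to \code{config$outdir}:
#' \describe{
#'   \item{auc.csv}{per-experiment AUC table sorted by group, specimen,
#'     region and AUC.}
#'   \item{group_summaries.csv}{per-(group, channel) n / mean / SD / median /
#'     Q1 / Q3 of AUC.}
#'   \item{curves.csv}{group-averaged curves with pointwise SD on the
#'     common 201-point grid.}
#'   \item{stats_report.csv + stats_report.txt}{the statistical battery per
#'     channel: normality gate (Shapiro-Wilk on pooled model residuals),
#'     ANOVA or aligned-rank-transform results, pairwise post-hoc
#'     contrasts, significance stars.}
#' }
#'
#' @param config from [runConfig()]: \code{input} is the profile CSV;
#'   \code{design} an optional design-table CSV adding factor columns
#'   (merged on \code{experiment_id}); \code{stats$factors} the factor
#'   column(s) to test (default \code{"group"}).
#' @return invisible list with the in-memory results (\code{records},
#'   \code{summaries}, \code{curves}, \code{stats}).
#' @export
runAnalyze <- function(config) {
    if (is.null(config$input) || !file.exists(config$input))
        .err("clearquant_bad_config", "config$input must be a profile CSV")
    profiles <- readProfileCsv(config$input)
    if (!is.null(config$channel))
        profiles <- Filter(function(p) channel(p) %in% config$channel,
                           profiles)
    if (length(profiles) == 0L)
        .err("clearquant_empty_input", "no profiles after channel filter")
    design <- if (!is.null(config$design))
        utils::read.csv(config$design, stringsAsFactors = FALSE, comment.char = "#")
    else do.call(rbind, lapply(profiles, function(p)
        as.data.frame(as.list(expLabels(p)[c("experiment", "group",
                                             "specimen", "region",
                                             "channel")]),
                      col.names = c("experiment_id", "group", "specimen",
                                    "region", "channel"))))
    missing <- setdiff(vapply(profiles, function(p)
        expLabels(p)[["experiment"]], ""), design$experiment_id)
    if (length(missing))
        .err("clearquant_unlabeled_experiment",
             "experiments absent from design table: %s",
             paste(missing, collapse = ", "))
    rkc <- .rkConfigFrom(config)
    normed <- lapply(profiles, normalizeProfile)
    curves <- lapply(normed, function(np) evaluateOnGrid(fitRK(np, rkc)))
    records <- do.call(rbind, lapply(
        if (config$auc$source == "rk") curves else normed, computeAUC))
    rownames(records) <- NULL
    if (length(unique(records$group)) < 2L)
        .err("clearquant_too_few_groups",
             "need >= 2 groups for a comparison")
    summ <- summarizeGroups(records)
    curveTab <- groupAverageCurve(curves)
    stats <- lapply(split(records, records$channel), .statsForChannel,
                    design = design, cfg = config)
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    .writeCsvWithHeader(summ$table, file.path(config$outdir, "auc.csv"),
                        config)
    .writeCsvWithHeader(summ$summaries,
                        file.path(config$outdir, "group_summaries.csv"),
                        config)
    .writeCsvWithHeader(curveTab, file.path(config$outdir, "curves.csv"),
                        config)
    statRows <- do.call(rbind, lapply(names(stats), function(ch) {
        s <- stats[[ch]]
        rbind(cbind(channel = ch, stage = "main", s$main),
              if (!is.null(s$posthoc))
                  cbind(channel = ch, stage = "posthoc", s$posthoc))
    }))
    .writeCsvWithHeader(statRows,
                        file.path(config$outdir, "stats_report.csv"), config)
    txt <- c(sprintf("ClearQuant statistics report (alpha = %g)",
                     config$stats$alpha))
    for (ch in names(stats)) {
        s <- stats[[ch]]
        txt <- c(txt, "",
                 sprintf("Channel %s: Shapiro-Wilk on model residuals W = %.4f, p = %.4g -> %s",
                         ch, s$gate$W, s$gate$p,
                         if (s$gate$route == "art")
                             "aligned rank transform" else "ANOVA"),
                 utils::capture.output(print(s$main, row.names = FALSE)),
                 if (!is.null(s$posthoc)) c("Pairwise contrasts:",
                     utils::capture.output(print(s$posthoc,
                                                 row.names = FALSE))))
    }
    writeLines(txt, file.path(config$outdir, "stats_report.txt"))
    .log(config, "analysis written to %s", config$outdir)
    invisible(list(records = records, summaries = summ$summaries,
                   table = summ$table, curves = curveTab, stats = stats))
}

#' Simulate a study and write it in pipeline interchange format
#'
#' Builds a [syntheticSpec()] from \code{config$synthetic} overrides (the
#' run seed always takes precedence), simulates the full crossed study, and
#' writes \code{profiles.csv} and \code{design.csv} to \code{config$outdir}.
#'
#' @param config from [runConfig()].
#' @return invisible list with \code{profiles}, \code{design} and the file
#'   paths.
#' @export
runSimulate <- function(config) {
    args <- config$synthetic
    args$seed <- config$seed
    spec <- do.call(syntheticSpec, args)
    study <- simulateStudy(spec)
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    pcsv <- file.path(config$outdir, "profiles.csv")
    dcsv <- file.path(config$outdir, "design.csv")
    writeProfileCsv(study$profiles, pcsv)
    .writeCsvWithHeader(study$design, dcsv, config)
    .log(config, "simulated %d profiles -> %s", length(study$profiles),
         config$outdir)
    invisible(list(profiles = study$profiles, design = study$design,
                   profile_csv = pcsv, design_csv = dcsv))
}
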