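#' @include AllClasses.R AllGenerics.R
NULL

## condition helper: every I/O failure mode gets its own condition class so
## callers can trap them individually
.err <- function(class, fmt, ...) {
    stop(structure(class = c(class, "error", "condition"),
                   list(message = sprintf(fmt, ...), call = sys.call(-1L))))
}

.PROFILE_COLS <- c("experiment_id", "group", "specimen", "region", "channel",
                   "z_um", "intensity")

#' Read a multi-page TIFF z-stack
#'
#' Each TIFF page becomes one slice; page 1 is the tissue surface (depth 0).
#' 8-bit files are read as-is. Files with more than 8 bits per sample are
#' brought onto the 0--255 scale by the fixed linear map value/257 (the exact
#' 16-bit-to-8-bit correspondence, 65535/257 = 255) and clamped, so intensity
#' stays on an absolute scale comparable across stacks -- a requirement for
#' normalizing by the fixed ceiling 255 downstream.
#'
#' @param path a readable TIFF file, all pages of equal dimensions, grayscale.
#' @param zStep axial step between pages in micrometres, > 0.
#' @param labels experiment labels from [experimentLabels()].
#' @return a [ZStack-class].
#' @section Errors: \code{clearquant_unreadable_file},
#'   \code{clearquant_empty_stack}, \code{clearquant_page_mismatch},
#'   \code{clearquant_bad_zstep} condition classes.
#' @seealso [writeTiffStack()], [extractProfile()]
#' @export
readTiffStack <- function(path, zStep, labels = experimentLabels()) {
    if (length(zStep) != 1L || !is.finite(zStep) || zStep <= 0)
        .err("clearquant_bad_zstep", "zStep must be a positive number, got %s",
             format(zStep))
    pages <- tryCatch(
        tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE),
        error = function(e) .err("clearquant_unreadable_file",
                                 "cannot read TIFF '%s': %s", path,
                                 conditionMessage(e)))
    if (length(pages) == 0L)
        .err("clearquant_empty_stack", "TIFF '%s' contains no pages", path)
    dims <- lapply(pages, dim)
    if (any(vapply(dims, length, 1L) != 2L))
        .err("clearquant_page_mismatch",
             "TIFF '%s' has non-grayscale (multi-sample) pages", path)
    if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
        .err("clearquant_page_mismatch",
             "TIFF '%s' pages differ in dimensions", path)
    vox <- vapply(pages, function(p) {
        bits <- attr(p, "bits.per.sample")
        p <- as.numeric(p)
        if (!is.null(bits) && bits > 8L) p <- p / 257
        pmin(pmax(p, 0), 255)
    }, numeric(prod(dims[[1L]])))
    vox <- aperm(array(vox, c(dims[[1L]], length(pages))), c(3L, 1L, 2L))
    new("ZStack", voxels = vox, zStep = zStep, labels = labels)
}

#' Write a z-stack as an 8-bit multi-page TIFF
#'
#' Voxels are rounded to integers and stored one page per slice. Round-trips
#' losslessly through [readTiffStack()] for integer-valued stacks.
#'
#' @param stack a [ZStack-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeTiffStack <- function(stack, path) {
    stopifnot(is(stack, "ZStack"))
    v <- round(voxels(stack))
    pages <- lapply(seq_len(dim(v)[1L]), function(k) v[k, , ] / 255)
    ok <- tryCatch(tiff::writeTIFF(pages, path, bits.per.sample = 8L),
                   error = function(e) .err("clearquant_unwritable_file",
                                            "cannot write TIFF '%s': %s", path,
                                            conditionMessage(e)))
    invisible(path)
}

#' Read per-experiment depth-intensity profiles from CSV
#'
#' The interchange schema has one row per (experiment, depth):
#' \code{experiment_id, group, specimen, region, channel, z_um, intensity}.
#' Rows may arrive in any order; depths are sorted per experiment. Intensities
#' are clamped to [0, 255].
#'
#' @param path CSV file with the schema above (comma separator, "." decimal,
#'   header required).
#' @return a list of [DepthProfile-class], one per distinct
#'   \code{experiment_id}, in order of first appearance.
#' @section Errors: \code{clearquant_missing_column},
#'   \code{clearquant_bad_numeric}, \code{clearquant_duplicate_depth}.
#' @seealso [writeProfileCsv()]
#' @export
readProfileCsv <- function(path) {
    df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#"),
                   error = function(e) .err("clearquant_unreadable_file",
                                            "cannot read CSV '%s': %s", path,
                                            conditionMessage(e)))
    miss <- setdiff(.PROFILE_COLS, names(df))
    if (length(miss))
        .err("clearquant_missing_column", "CSV '%s' lacks column(s): %s",
             path, paste(miss, collapse = ", "))
    z <- suppressWarnings(as.numeric(df$z_um))
    int <- suppressWarnings(as.numeric(df$intensity))
    if (anyNA(z) || anyNA(int))
        .err("clearquant_bad_numeric",
             "non-numeric z_um or intensity in '%s'", path)
    if (anyDuplicated(df[c("experiment_id", "z_um")]))
        .err("clearquant_duplicate_depth",
             "duplicate (experiment_id, z_um) pairs in '%s'", path)
    df$z_um <- z
    df$intensity <- pmin(pmax(int, 0), 255)
    lapply(split(df, factor(df$experiment_id, levels = unique(df$experiment_id))),
           function(d) {
               d <- d[order(d$z_um), ]
               new("DepthProfile", z = d$z_um, intensity = d$intensity,
                   labels = experimentLabels(d$experiment_id[1L], d$group[1L],
                                             d$specimen[1L], d$region[1L],
                                             d$channel[1L]))
           })
}

#' Write depth-intensity profiles to the interchange CSV
#'
#' Emits the same schema [readProfileCsv()] reads, with rows globally sorted
#' by (group, specimen, region, z_um) so each experiment's rows are
#' contiguous -- the same sort convention the AUC table uses.
#'
#' @param profiles non-empty list of [DepthProfile-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeProfileCsv <- function(profiles, path) {
    if (length(profiles) == 0L)
        .err("clearquant_empty_input", "no profiles to write")
    df <- do.call(rbind, lapply(profiles, function(p) {
        lb <- expLabels(p)
        data.frame(experiment_id = lb[["experiment"]], group = lb[["group"]],
                   specimen = lb[["specimen"]], region = lb[["region"]],
                   channel = lb[["channel"]], z_um = depths(p),
                   intensity = intensities(p))
    }))
    df <- df[order(df$group, df$specimen, df$region, df$z_um), ]
    ok <- tryCatch(utils::write.csv(df, path, row.names = FALSE,
                                    quote = FALSE),
                   error = function(e) .err("clearquant_unwritable_file",
                                            "cannot write CSV '%s': %s", path,
                                            conditionMessage(e)))
    invisible(path)
}

#' Pixel-wise maximum intensity projection
#'
#' Collapses the stack to a 2D image by taking each pixel's maximum across
#' slices, then applies a linear brightness/contrast display mapping: the
#' value \code{displayMin} maps to 0 and \code{displayMax} to 255, clamped.
#' The defaults (0, 255) leave intensities untouched.
#'
#' @param stack a [ZStack-class].
#' @param displayMin,displayMax display-range endpoints,
#'   \code{displayMin < displayMax}. Negative minima are allowed (a common
#'   brightness boost, e.g. a display range of (-39, 119)).
#' @return numeric matrix (rows x cols) with values in [0, 255].
#' @export
maxIntensityProjection <- function(stack, displayMin = 0, displayMax = 255) {
    stopifnot(is(stack, "ZStack"))
    if (displayMin >= displayMax)
        .err("clearquant_bad_display_range",
             "displayMin (%.3g) must be < displayMax (%.3g)",
             displayMin, displayMax)
    mip <- apply(voxels(stack), c(2L, 3L), max)
    mip <- (mip - displayMin) / (displayMax - displayMin) * 255
    pmin(pmax(mip, 0), 255)
}
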