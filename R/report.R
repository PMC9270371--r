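## Pipeline orchestration: read -> filter -> group -> validate ->
## optional cutoff / overlap / properties, with every output written to
## an output directory and a per-stage log.

#' Run the full validation report pipeline
#'
#' Executes the standard post-processing sequence on one or more
#' search-engine result files: read through the dialect layer, filter to
#' target crosslinks, optionally group to unique links, validate against
#' the library ground truth, optionally apply a post-score cutoff to a
#' target FDR, compare multiple inputs by overlap, and compute crosslink
#' properties. All tables are written as CSV and figures as PNG under
#' \code{outDir}; a run log records configuration and per-stage counts.
#' Every stage is deterministic, so identical configurations produce
#' identical CSV outputs.
#'
#' @param resultFiles Named character vector of result file paths; names
#'   label the sets in comparisons.
#' @param libraryFile Path to the library support file (or a
#'   [PeptideLibrary()] directly).
#' @param dialect One [engineDialect()] (or dialect YAML path) applied to
#'   all inputs, or a list of them, one per input.
#' @param level \code{"unique_link"} (default) or \code{"csm"}:
#'   validation level.
#' @param targetFdr Optional target FDR in (0, 1] for the post-score
#'   cutoff stage.
#' @param minShortPeptideLen Minimum shorter-peptide length passed to
#'   [filterTargets()].
#' @param mode Theoretical enumeration mode for the property comparison.
#' @param properties Compute crosslink property tables.
#' @param outDir Output directory (created if needed).
#' @return Invisibly, a list with the per-input
#'   \linkS4class{ValidationResult}s, the optional
#'   \linkS4class{CutoffResult}s and \linkS4class{OverlapResult}, and the
#'   paths written.
#' @export
runReport <- function(resultFiles, libraryFile,
                      dialect = canonicalDialect(),
                      level = c("unique_link", "csm"),
                      targetFdr = NULL, minShortPeptideLen = 1L,
                      mode = c("grouped", "pooled"), properties = FALSE,
                      outDir = ".") {
    level <- match.arg(level)
    mode <- match.arg(mode)
    if (!dir.exists(outDir))
        dir.create(outDir, recursive = TRUE)
    library <- if (is(libraryFile, "PeptideLibrary")) libraryFile
               else loadLibrary(libraryFile)
    if (is.null(names(resultFiles)))
        names(resultFiles) <- paste0("set", seq_along(resultFiles))
    if (!is.list(dialect))
        dialect <- rep(list(dialect), length(resultFiles))
    logLines <- c(sprintf("xlfdr %s run at %s",
                          as.character(utils::packageVersion("xlfdr")),
                          format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
                  sprintf("library: %s (%d peptides, %d groups)",
                          libraryId(library), nrow(peptides(library)),
                          length(unique(peptides(library)$group_id))),
                  sprintf("level: %s; min peptide length: %d",
                          level, minShortPeptideLen))
    validations <- list()
    cutoffs <- list()
    sets <- list()
    paths <- character(0)
    for (nm in names(resultFiles)) {
        csm <- readResults(resultFiles[[nm]],
                           dialect[[match(nm, names(resultFiles))]],
                           replicate = nm)
        filtered <- filterTargets(csm, minShortPeptideLen)
        rec <- if (level == "unique_link") groupToUniqueLinks(filtered)
               else filtered
        logLines <- c(logLines, sprintf(
            "%s: %d rows read, %d target crosslinks (%d removed), %d at %s level",
            nm, nrow(records(csm)), nrow(records(filtered)),
            nrow(records(csm)) - nrow(records(filtered)),
            nrow(records(rec)), level))
        v <- withCallingHandlers(
            validatedFdr(rec, library),
            warning = function(w) {
                logLines <<- c(logLines, paste("warning:",
                                               conditionMessage(w)))
                invokeRestart("muffleWarning")
            })
        validations[[nm]] <- v
        sets[[nm]] <- rec
        p <- file.path(outDir, paste0(nm, "_validated.csv"))
        utils::write.csv(annotated(v), p, row.names = FALSE)
        paths <- c(paths, p)
        if (nrow(records(rec))) {
            curve <- fdrScoreCurve(rec, library)
            p <- file.path(outDir, paste0(nm, "_fdr_curve.csv"))
            utils::write.csv(curve, p, row.names = FALSE)
            fig <- file.path(outDir, paste0(nm, "_fdr_curve.png"))
            plotFdrCurve(curve, file = fig, targetFdr = targetFdr)
            paths <- c(paths, p, fig)
        }
        logLines <- c(logLines, sprintf(
            "%s: validated FDR %s (%d cross-group + %d non-library of %d)",
            nm, formatFdrPercent(fdrValue(v)), v@nCrossGroup,
            v@nNonLibrary, v@nTotal))
        if (!is.null(targetFdr)) {
            co <- applyScoreCutoff(rec, library, targetFdr)
            cutoffs[[nm]] <- co
            p <- file.path(outDir, paste0(nm, "_cutoff.csv"))
            utils::write.csv(fdrCurve(co), p, row.names = FALSE)
            writeRecords(retained(co),
                         file.path(outDir, paste0(nm, "_retained.csv")))
            paths <- c(paths, p,
                       file.path(outDir, paste0(nm, "_retained.csv")))
            logLines <- c(logLines, sprintf(
                "%s: cutoff %.6g retains %d at FDR %s (target %s)",
                nm, co@threshold, co@nRetained,
                formatFdrPercent(if (co@nRetained) co@achievedFdr else 0),
                formatFdrPercent(targetFdr)))
        }
        if (properties && nrow(records(rec))) {
            p <- file.path(outDir, paste0(nm, "_properties.csv"))
            utils::write.csv(crosslinkProperties(rec), p, row.names = FALSE)
            paths <- c(paths, p)
            dc <- distributionComparison(rec, library, mode)
            p <- file.path(outDir, paste0(nm, "_aa_distribution.csv"))
            utils::write.csv(comparisonTable(dc), p, row.names = FALSE)
            paths <- c(paths, p)
            if (any(!is.na(records(rec)$site_a) |
                    !is.na(records(rec)$site_b))) {
                ppm <- ppmAroundSite(rec)
                p <- file.path(outDir, paste0(nm, "_ppm.csv"))
                utils::write.csv(data.frame(aa = aminoAcids(), probs(ppm),
                                            check.names = FALSE),
                                 p, row.names = FALSE)
                fig <- file.path(outDir, paste0(nm, "_ppm.png"))
                plotPpm(ppm, file = fig)
                paths <- c(paths, p, fig)
            }
        }
    }
    overlap <- NULL
    if (length(sets) >= 2L) {
        if (level != "unique_link")
            sets <- lapply(sets, groupToUniqueLinks)
        overlap <- computeOverlap(sets, library)
        p <- file.path(outDir, "overlap_regions.csv")
        reg <- data.frame(
            region = names(regionMembers(overlap)),
            n_links = regionCounts(overlap),
            validated_fdr = regionFdr(overlap))
        utils::write.csv(reg, p, row.names = FALSE)
        paths <- c(paths, p)
        if (length(sets) <= 3L) {
            fig <- file.path(outDir, "overlap_venn.png")
            plotVenn(overlap, file = fig)
            paths <- c(paths, fig)
        }
        for (r in names(regionMembers(overlap)))
            logLines <- c(logLines, sprintf(
                "overlap %s: %d links, FDR %s", r,
                regionCounts(overlap)[[r]],
                if (is.na(regionFdr(overlap)[[r]])) "n/a"
                else formatFdrPercent(regionFdr(overlap)[[r]])))
    }
    logPath <- file.path(outDir, "run_log.txt")
    writeLines(logLines, logPath)
    paths <- c(paths, logPath)
    invisible(list(validations = validations, cutoffs = cutoffs,
                   overlap = overlap, paths = paths, log = logLines))
}
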