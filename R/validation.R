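## Experimentally validated FDR: the real error rate of a crosslink
## result set, measurable because the grouped library design makes every
## cross-group or non-library link a known false positive.

#' Format an FDR fraction as a display percentage
#'
#' Percentages are rounded half-up to one decimal for display (0.0047
#' prints as "0.5 %"); all stored values remain unrounded fractions.
#'
#' @param fdr Fraction in \[0, 1\] (vectorized).
#' @return Character, e.g. \code{"0.5 %"}.
#' @export
#' @examples
#' formatFdrPercent(2 / 425)
formatFdrPercent <- function(fdr) {
    pct <- floor(fdr * 100 * 10 + 0.5) / 10   # round half-up, 1 decimal
    paste0(formatC(pct, format = "f", digits = 1), " %")
}

## Link class of each record: from library provenance when both peptides
## are library members, from the record's own protein fields otherwise.
.recordLinkClass <- function(rec, cls) {
    ifelse(!is.na(cls$link_class), cls$link_class,
    ifelse(rec$seq_a == rec$seq_b, "homeotypic",
    ifelse(!is.na(rec$protein_a) & !is.na(rec$protein_b) &
               rec$protein_a == rec$protein_b,
           "intraprotein", "interprotein")))
}

#' Experimentally validated FDR against the library ground truth
#'
#' Labels every target crosslink record via [classifyPair()] and computes
#' the experimentally validated false discovery rate: the fraction of
#' reported target crosslinks joining peptides not crosslinked within one
#' group —
#' \deqn{FDR = (n_{cross\mbox{-}group} + n_{non\mbox{-}library}) / n_{total}.}
#' At CSM level every spectrum match counts once; at unique-link level
#' every residue pair counts once. Both false categories are reported
#' separately (a cross-group link joins two real library peptides from
#' different reaction vials; a non-library link involves a peptide that
#' was never synthesized), and the same counts are stratified by link
#' class (homeotypic / intraprotein / interprotein).
#'
#' @param x A [CrosslinkSet()] already passed through [filterTargets()].
#' @param library A [PeptideLibrary()].
#' @param level Expected record level; defaults to the set's own level and
#'   errors on mismatch.
#' @return A \linkS4class{ValidationResult}. An empty input yields
#'   \code{nTotal = 0}, \code{fdr = 0} with a warning.
#' @export
#' @examples
#' cfg <- simulationConfig(nPeptides = 30, nTrue = 99, nCrossGroup = 1,
#'                         seed = 7)
#' lib <- generateLibrary(cfg)
#' sim <- generateResults(lib, cfg)
#' links <- groupToUniqueLinks(filterTargets(sim$records))
#' validatedFdr(links, lib)   # 1 false of 100: FDR 1.0 %
validatedFdr <- function(x, library, level = recordLevel(x)) {
    stopifnot(is(x, "CrosslinkSet"), is(library, "PeptideLibrary"))
    if (!identical(level, recordLevel(x)))
        stop("records are at '", recordLevel(x),
             "' level but level = '", level, "' was requested", call. = FALSE)
    rec <- records(x)
    if (nrow(rec) == 0L) {
        warning("no target crosslinks to validate; FDR reported as 0",
                call. = FALSE)
        return(new("ValidationResult", level = level, nTotal = 0L,
                   nCrossGroup = 0L, nNonLibrary = 0L, fdr = 0,
                   perClass = .emptyPerClass(), annotated = rec))
    }
    cls <- classifyPair(rec$seq_a, rec$seq_b, library)
    rec$truth <- cls$truth
    rec$link_class <- .recordLinkClass(rec, cls)
    nCross <- sum(rec$truth == "cross_group_false")
    nNonLib <- sum(rec$truth == "non_library_false")
    perClass <- do.call(rbind, lapply(.LINK_CLASSES, function(cl) {
        sub <- rec[rec$link_class == cl, , drop = FALSE]
        nc <- sum(sub$truth == "cross_group_false")
        nn <- sum(sub$truth == "non_library_false")
        data.frame(link_class = cl, n_total = nrow(sub),
                   n_cross_group = nc, n_non_library = nn,
                   fdr = if (nrow(sub)) (nc + nn) / nrow(sub) else 0,
                   stringsAsFactors = FALSE)
    }))
    new("ValidationResult", level = level, nTotal = nrow(rec),
        nCrossGroup = as.integer(nCross), nNonLibrary = as.integer(nNonLib),
        fdr = (nCross + nNonLib) / nrow(rec),
        perClass = perClass, annotated = rec)
}

.emptyPerClass <- function() {
    data.frame(link_class = .LINK_CLASSES, n_total = 0L,
               n_cross_group = 0L, n_non_library = 0L, fdr = 0,
               stringsAsFactors = FALSE)
}

#' Score threshold vs validated FDR curve
#'
#' Evaluates the experimentally validated FDR and the number of retained
#' records at every distinct score value, from strictest (highest
#' threshold) to least strict. The retained set at threshold t is
#' \{score >= t\}, so retained counts are non-decreasing along the curve.
#' This is the basis both of the diagnostic score-vs-FDR plot and of
#' [applyScoreCutoff()].
#'
#' @inheritParams validatedFdr
#' @return \code{data.frame} with columns \code{threshold},
#'   \code{n_retained}, \code{fdr}, thresholds descending.
#' @export
fdrScoreCurve <- function(x, library) {
    stopifnot(is(x, "CrosslinkSet"))
    rec <- records(x)
    if (nrow(rec) == 0L)
        return(data.frame(threshold = numeric(), n_retained = integer(),
                          fdr = numeric()))
    cls <- classifyPair(rec$seq_a, rec$seq_b, library)
    isFalse <- cls$truth != "within_group_true"
    ord <- order(rec$score, decreasing = TRUE)
    score <- rec$score[ord]
    cumFalse <- cumsum(isFalse[ord])
    n <- seq_along(score)
    ## keep the last (= complete) entry per distinct score
    last <- !duplicated(score, fromLast = TRUE)
    data.frame(threshold = score[last], n_retained = n[last],
               fdr = cumFalse[last] / n[last])
}

#' Post-score cutoff to a target validated FDR
#'
#' Search engines' internal target-decoy FDR estimates are often
#' optimistic; an empirical score cutoff can correct the result list to a
#' chosen real FDR. The threshold returned is the least strict score
#' value (ties retained, inclusive \eqn{\ge} on the normalized
#' higher-is-better scale) whose retained set has experimentally
#' validated FDR at or below \code{targetFdr}, i.e. the qualifying
#' threshold maximizing the number of retained records. When no threshold
#' qualifies the retained set is empty and \code{threshold} is
#' \code{Inf}.
#'
#' @inheritParams validatedFdr
#' @param targetFdr Target FDR fraction in (0, 1].
#' @return A \linkS4class{CutoffResult}.
#' @export
#' @examples
#' lib <- PeptideLibrary(data.frame(
#'     sequence = c("MAKTIK", "VAVIKAVR"), group_id = c("g1", "g2"),
#'     protein_id = c("P1", "P2"), start_pos = 1L, site_pos = c(3L, 5L),
#'     chemistry = "lysine"))
#' rec <- data.frame(seq_a = c(rep("MAKTIK", 3), "MAKTIK"),
#'                   seq_b = c(rep("MAKTIK", 3), "VAVIKAVR"),
#'                   site_a = 3L, site_b = c(3L, 3L, 3L, 5L),
#'                   protein_a = "P1", protein_b = c("P1", "P1", "P1", "P2"),
#'                   pos_a = 1L, pos_b = c(1L, 1L, 1L, 1L),
#'                   score = c(10, 9, 8, 7), is_decoy = FALSE,
#'                   link_type = "crosslink", engine = "demo",
#'                   replicate = "r1", spectrum_ref = NA, n_csms = 1L)
#' applyScoreCutoff(CrosslinkSet(rec, "unique_link"), lib, 0.01)
applyScoreCutoff <- function(x, library, targetFdr) {
    stopifnot(is(x, "CrosslinkSet"),
              is.numeric(targetFdr), targetFdr > 0, targetFdr <= 1)
    curve <- fdrScoreCurve(x, library)
    ok <- which(curve$fdr <= targetFdr)
    if (length(ok) == 0L) {
        empty <- records(x)[0, , drop = FALSE]
        return(new("CutoffResult", threshold = Inf, nRetained = 0L,
                   achievedFdr = NA_real_, targetFdr = targetFdr,
                   curve = curve,
                   retained = CrosslinkSet(empty, level = recordLevel(x))))
    }
    best <- max(ok)   # thresholds descend: last qualifying = most retained
    thr <- curve$threshold[best]
    rec <- records(x)
    keep <- rec$score >= thr
    new("CutoffResult", threshold = thr,
        nRetained = as.integer(curve$n_retained[best]),
        achievedFdr = curve$fdr[best], targetFdr = targetFdr,
        curve = curve,
        retained = CrosslinkSet(rec[keep, , drop = FALSE],
                                level = recordLevel(x)))
}

#' Plot the score vs validated FDR diagnostic
#'
#' Two-panel base-graphics plot of the threshold curve: validated FDR and
#' number of retained identifications against the score cutoff.
#'
#' @param curve Curve as returned by [fdrScoreCurve()] or stored in a
#'   \linkS4class{CutoffResult}.
#' @param file Optional PNG path; when \code{NULL} the current device is
#'   used.
#' @param targetFdr Optional target to draw as a horizontal reference.
#' @return Invisibly, \code{file}.
#' @export
plotFdrCurve <- function(curve, file = NULL, targetFdr = NULL) {
    if (is(curve, "CutoffResult")) {
        if (is.null(targetFdr)) targetFdr <- curve@targetFdr
        curve <- fdrCurve(curve)
    }
    if (!is.null(file)) {
        grDevices::png(file, width = 1400, height = 600, res = 120)
        on.exit(grDevices::dev.off())
    }
    op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
    on.exit(graphics::par(op), add = TRUE)
    graphics::plot(curve$threshold, 100 * curve$fdr, type = "s",
                   xlab = "score cutoff", ylab = "validated FDR [%]",
                   main = "FDR vs score cutoff", xlim = rev(range(curve$threshold)))
    if (!is.null(targetFdr))
        graphics::abline(h = 100 * targetFdr, lty = 2, col = "red")
    graphics::plot(curve$threshold, curve$n_retained, type = "s",
                   xlab = "score cutoff", ylab = "retained IDs",
                   main = "IDs vs score cutoff", xlim = rev(range(curve$threshold)))
    invisible(file)
}
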