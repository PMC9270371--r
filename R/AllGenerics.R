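## Accessor generics and show() methods for the core classes.

#' Accessors for xlfdr objects
#'
#' Small accessor layer over the S4 classes: \code{peptides()} returns the
#' peptide table of a [PeptideLibrary()], \code{records()} the record table
#' of a [CrosslinkSet()], \code{recordLevel()} its level, \code{crosslinks()}
#' the pair table of a \linkS4class{TheoreticalSpace}, \code{classCounts()}
#' its per-link-class totals, \code{fdrValue()} the validated FDR of a
#' \linkS4class{ValidationResult}, \code{annotated()} its truth-labeled
#' records, \code{fdrCurve()} the threshold curve of a
#' \linkS4class{CutoffResult}, \code{retained()} its retained records,
#' \code{regionCounts()} and \code{regionFdr()} the per-region summaries of
#' an \linkS4class{OverlapResult}, and \code{probs()} / \code{support()}
#' the matrix and per-column support of a
#' \linkS4class{PositionProbabilityMatrix}.
#'
#' @param x An xlfdr S4 object of the matching class.
#' @return The slot content described above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("peptides", function(x) standardGeneric("peptides"))
#' @rdname accessors
#' @export
setMethod("peptides", "PeptideLibrary", function(x) x@peptides)

#' @rdname accessors
#' @export
setGeneric("libraryId", function(x) standardGeneric("libraryId"))
#' @rdname accessors
#' @export
setMethod("libraryId", "PeptideLibrary", function(x) x@libraryId)

#' @rdname accessors
#' @export
setGeneric("records", function(x) standardGeneric("records"))
#' @rdname accessors
#' @export
setMethod("records", "CrosslinkSet", function(x) x@records)

#' @rdname accessors
#' @export
setGeneric("recordLevel", function(x) standardGeneric("recordLevel"))
#' @rdname accessors
#' @export
setMethod("recordLevel", "CrosslinkSet", function(x) x@level)

#' @rdname accessors
#' @export
setGeneric("crosslinks", function(x) standardGeneric("crosslinks"))
#' @rdname accessors
#' @export
setMethod("crosslinks", "TheoreticalSpace", function(x) x@crosslinks)

#' @rdname accessors
#' @export
setGeneric("classCounts", function(x) standardGeneric("classCounts"))
#' @rdname accessors
#' @export
setMethod("classCounts", "TheoreticalSpace", function(x) x@counts)

#' @rdname accessors
#' @export
setGeneric("spaceMode", function(x) standardGeneric("spaceMode"))
#' @rdname accessors
#' @export
setMethod("spaceMode", "TheoreticalSpace", function(x) x@mode)

#' @rdname accessors
#' @export
setGeneric("fdrValue", function(x) standardGeneric("fdrValue"))
#' @rdname accessors
#' @export
setMethod("fdrValue", "ValidationResult", function(x) x@fdr)
#' @rdname accessors
#' @export
setMethod("fdrValue", "CutoffResult", function(x) x@achievedFdr)

#' @rdname accessors
#' @export
setGeneric("annotated", function(x) standardGeneric("annotated"))
#' @rdname accessors
#' @export
setMethod("annotated", "ValidationResult", function(x) x@annotated)

#' @rdname accessors
#' @export
setGeneric("perClass", function(x) standardGeneric("perClass"))
#' @rdname accessors
#' @export
setMethod("perClass", "ValidationResult", function(x) x@perClass)

#' @rdname accessors
#' @export
setGeneric("fdrCurve", function(x) standardGeneric("fdrCurve"))
#' @rdname accessors
#' @export
setMethod("fdrCurve", "CutoffResult", function(x) x@curve)

#' @rdname accessors
#' @export
setGeneric("retained", function(x) standardGeneric("retained"))
#' @rdname accessors
#' @export
setMethod("retained", "CutoffResult", function(x) x@retained)

#' @rdname accessors
#' @export
setGeneric("regionCounts", function(x) standardGeneric("regionCounts"))
#' @rdname accessors
#' @export
setMethod("regionCounts", "OverlapResult", function(x) x@counts)

#' @rdname accessors
#' @export
setGeneric("regionFdr", function(x) standardGeneric("regionFdr"))
#' @rdname accessors
#' @export
setMethod("regionFdr", "OverlapResult", function(x) x@regionFdr)

#' @rdname accessors
#' @export
setGeneric("regionMembers", function(x) standardGeneric("regionMembers"))
#' @rdname accessors
#' @export
setMethod("regionMembers", "OverlapResult", function(x) x@regions)

#' @rdname accessors
#' @export
setGeneric("probs", function(x) standardGeneric("probs"))
#' @rdname accessors
#' @export
setMethod("probs", "PositionProbabilityMatrix", function(x) x@probs)

#' @rdname accessors
#' @export
setGeneric("support", function(x) standardGeneric("support"))
#' @rdname accessors
#' @export
setMethod("support", "PositionProbabilityMatrix", function(x) x@support)

#' @rdname accessors
#' @export
setGeneric("comparisonTable", function(x) standardGeneric("comparisonTable"))
#' @rdname accessors
#' @export
setMethod("comparisonTable", "DistributionComparison", function(x) x@table)

setMethod("show", "PeptideLibrary", function(object) {
    pep <- object@peptides
    cat(sprintf("PeptideLibrary '%s': %d peptides in %d groups\n",
                object@libraryId, nrow(pep),
                length(unique(pep$group_id))))
    if (nrow(pep)) {
        cat(sprintf("  chemistry: %s; peptide lengths %d-%d\n",
                    paste(unique(pep$chemistry), collapse = "/"),
                    min(nchar(pep$sequence)), max(nchar(pep$sequence))))
    }
})

setMethod("show", "CrosslinkSet", function(object) {
    rec <- object@records
    cat(sprintf("CrosslinkSet (%s level): %d records\n",
                object@level, nrow(rec)))
    if (nrow(rec)) {
        tt <- table(rec$link_type)
        cat("  link types:",
            paste(sprintf("%s=%d", names(tt), tt), collapse = ", "), "\n")
        cat(sprintf("  decoys: %d; engines: %s\n", sum(rec$is_decoy),
                    paste(unique(rec$engine), collapse = ", ")))
    }
})

setMethod("show", "TheoreticalSpace", function(object) {
    cat(sprintf("TheoreticalSpace (%s mode): %d crosslink combinations\n",
                object@mode, nrow(object@crosslinks)))
    cc <- object@counts
    cat("  ", paste(sprintf("%s=%d", names(cc), cc), collapse = ", "),
        "\n", sep = "")
})

setMethod("show", "ValidationResult", function(object) {
    cat(sprintf("ValidationResult (%s level)\n", object@level))
    cat(sprintf("  %d target crosslinks: %d cross-group, %d non-library false\n",
                object@nTotal, object@nCrossGroup, object@nNonLibrary))
    cat(sprintf("  experimentally validated FDR: %s (%.6g)\n",
                formatFdrPercent(object@fdr), object@fdr))
})

setMethod("show", "CutoffResult", function(object) {
    if (object@nRetained == 0L) {
        cat(sprintf("CutoffResult: target FDR %.4g infeasible, nothing retained\n",
                    object@targetFdr))
    } else {
        cat(sprintf("CutoffResult: score >= %.6g retains %d records\n",
                    object@threshold, object@nRetained))
        cat(sprintf("  achieved FDR %s at target %s\n",
                    formatFdrPercent(object@achievedFdr),
                    formatFdrPercent(object@targetFdr)))
    }
})

setMethod("show", "OverlapResult", function(object) {
    cat(sprintf("OverlapResult over %d sets (%s)\n",
                length(object@setLabels),
                paste(object@setLabels, collapse = ", ")))
    for (r in names(object@regions)) {
        f <- object@regionFdr[[r]]
        cat(sprintf("  %-12s %6d links, validated FDR %s\n", r,
                    object@counts[[r]],
                    if (is.na(f)) "n/a" else formatFdrPercent(f)))
    }
})

setMethod("show", "PositionProbabilityMatrix", function(object) {
    cat(sprintf("PositionProbabilityMatrix: offsets %s (site %s)\n",
                paste(range(as.integer(colnames(object@probs))),
                      collapse = ".."),
                if (object@includeSite) "included" else "excluded"))
    cat("  support per position:",
        paste(object@support, collapse = " "), "\n")
})

setMethod("show", "DistributionComparison", function(object) {
    cat(sprintf("DistributionComparison (%s level, %s theoretical mode)\n",
                object@level, object@mode))
    tab <- object@table
    extreme <- tab[order(abs(log(pmax(tab$ratio, 1e-6)))), , drop = FALSE]
    extreme <- utils::tail(extreme, 3L)
    cat("  largest deviations:",
        paste(sprintf("%s (ratio %.2f)", extreme$aa, extreme$ratio),
              collapse = ", "), "\n")
})
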