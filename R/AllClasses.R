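#' @import methods
NULL

## Required columns of the peptide table inside a PeptideLibrary.
.LIBRARY_COLS <- c("sequence", "group_id", "protein_id", "start_pos",
                   "site_pos", "chemistry")

## Required columns of the record table inside a CrosslinkSet.
.RECORD_COLS <- c("seq_a", "seq_b", "site_a", "site_b",
                  "protein_a", "protein_b", "pos_a", "pos_b",
                  "score", "is_decoy", "link_type", "engine",
                  "replicate", "spectrum_ref")

## Returns TRUE (internal, non-terminal) reactive-residue positions for a
## chemistry. The C-terminal residue is never a candidate: in lysine
## chemistry the terminal K carries the azide protection during the
## crosslink reaction, and in acidic chemistry the terminal K/R is only
## produced by tryptic release.
.reactiveSites <- function(sequence, chemistry) {
    residues <- strsplit(sequence, "")[[1]]
    targets <- if (chemistry == "lysine") "K" else c("D", "E")
    hits <- which(residues %in% targets)
    hits[hits < length(residues)]
}

#' @rdname PeptideLibrary
#' @export
setClass("PeptideLibrary",
    representation(libraryId = "character", peptides = "data.frame"))

setValidity("PeptideLibrary", function(object) {
    pep <- object@peptides
    missing <- setdiff(.LIBRARY_COLS, names(pep))
    if (length(missing))
        return(paste("peptide table lacks column(s):",
                     paste(missing, collapse = ", ")))
    if (nrow(pep) == 0L)
        return(TRUE)
    if (!all(grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", pep$sequence)))
        return("sequences must use the 20 standard uppercase residues")
    if (anyDuplicated(pep$sequence))
        return("each sequence must appear in exactly one group; duplicated sequences found")
    if (!all(pep$chemistry %in% c("lysine", "acidic")))
        return("chemistry must be 'lysine' or 'acidic'")
    for (i in seq_len(nrow(pep))) {
        sites <- .reactiveSites(pep$sequence[i], pep$chemistry[i])
        if (length(sites) != 1L)
            return(sprintf(
                "peptide %s must contain exactly one non-terminal reactive residue (found %d)",
                pep$sequence[i], length(sites)))
        if (sites != pep$site_pos[i])
            return(sprintf("peptide %s: site_pos %d does not match reactive residue at %d",
                           pep$sequence[i], pep$site_pos[i], sites))
    }
    if (any(pep$start_pos < 1L) || any(pep$site_pos < 1L))
        return("start_pos and site_pos are 1-based and must be >= 1")
    TRUE
})

#' Synthetic peptide library with crosslink-group ground truth
#'
#' A \code{PeptideLibrary} holds the final tryptic peptides of a synthetic
#' crosslink benchmarking library, each with its crosslink group, source
#' protein accession, 1-based start position in that protein, the 1-based
#' position of its single reactive residue, and its reactive chemistry
#' (\code{"lysine"} for amine-reactive linkers, \code{"acidic"} for
#' carboxyl-reactive linkers). Peptides are crosslinked groupwise, so only
#' links between peptides of the same group can be true; the group
#' partition is the ground truth against which search results are
#' validated.
#'
#' The C-terminal residue is never the reactive site: terminal lysines are
#' azide-protected during the reaction and terminal K/R of acidic-chemistry
#' peptides arise from tryptic release of the protection tag.
#'
#' @param peptides \code{data.frame} with columns \code{sequence},
#'   \code{group_id}, \code{protein_id}, \code{start_pos}, \code{site_pos},
#'   \code{chemistry}.
#' @param libraryId Character name of the library (e.g. \code{"main"},
#'   \code{"acidic"}).
#' @return A validated \code{PeptideLibrary}.
#' @seealso [loadLibrary()] to read the support-file format,
#'   [enumerateTheoretical()], [classifyPair()], [generateLibrary()].
#' @export
#' @examples
#' lib <- PeptideLibrary(data.frame(
#'     sequence = c("MAKTIK", "VAVIKAVR"),
#'     group_id = c("g1", "g1"),
#'     protein_id = c("P1", "P2"),
#'     start_pos = c(1L, 10L),
#'     site_pos = c(3L, 5L),
#'     chemistry = "lysine"))
#' lib
PeptideLibrary <- function(peptides, libraryId = "user-defined") {
    peptides <- as.data.frame(peptides, stringsAsFactors = FALSE)
    peptides$start_pos <- as.integer(peptides$start_pos)
    peptides$site_pos <- as.integer(peptides$site_pos)
    rownames(peptides) <- NULL
    new("PeptideLibrary", libraryId = libraryId, peptides = peptides)
}

#' @rdname CrosslinkSet
#' @export
setClass("CrosslinkSet",
    representation(records = "data.frame", level = "character"))

setValidity("CrosslinkSet", function(object) {
    if (!object@level %in% c("csm", "unique_link"))
        return("level must be 'csm' or 'unique_link'")
    missing <- setdiff(.RECORD_COLS, names(object@records))
    if (length(missing))
        return(paste("record table lacks column(s):",
                     paste(missing, collapse = ", ")))
    rec <- object@records
    if (nrow(rec) && !all(rec$link_type %in% .LINK_TYPES))
        return(paste("link_type must be one of:",
                     paste(.LINK_TYPES, collapse = ", ")))
    if (object@level == "unique_link" && !"n_csms" %in% names(rec))
        return("unique_link level requires an n_csms column")
    TRUE
})

#' Normalized crosslink identifications
#'
#' A \code{CrosslinkSet} is the canonical record model shared by all
#' analysis steps: one row per crosslink-spectrum match (CSM,
#' \code{level = "csm"}) or per unique residue pair
#' (\code{level = "unique_link"}). Scores are always on a higher-is-better
#' scale; engines reporting e-value-like scores are negated on import (the
#' original value is kept in \code{raw_score}). The two peptide sides carry
#' unordered-pair semantics: a record is the same identification as its
#' (a, b) swap.
#'
#' @param records \code{data.frame} with columns \code{seq_a}, \code{seq_b},
#'   \code{site_a}, \code{site_b}, \code{protein_a}, \code{protein_b},
#'   \code{pos_a}, \code{pos_b}, \code{score}, \code{is_decoy},
#'   \code{link_type}, \code{engine}, \code{replicate},
#'   \code{spectrum_ref}; unique-link level additionally \code{n_csms}.
#' @param level \code{"csm"} or \code{"unique_link"}.
#' @return A validated \code{CrosslinkSet}.
#' @seealso [readResults()], [filterTargets()], [groupToUniqueLinks()],
#'   [validatedFdr()].
#' @export
CrosslinkSet <- function(records, level = "csm") {
    records <- as.data.frame(records, stringsAsFactors = FALSE)
    rownames(records) <- NULL
    new("CrosslinkSet", records = records, level = level)
}

#' @rdname TheoreticalSpace
#' @export
setClass("TheoreticalSpace",
    representation(mode = "character", crosslinks = "data.frame",
                   counts = "integer"))

setValidity("TheoreticalSpace", function(object) {
    if (!object@mode %in% c("grouped", "pooled"))
        return("mode must be 'grouped' or 'pooled'")
    needed <- c("seq_a", "seq_b", "link_class", "same_group")
    missing <- setdiff(needed, names(object@crosslinks))
    if (length(missing))
        return(paste("crosslink table lacks column(s):",
                     paste(missing, collapse = ", ")))
    if (!identical(sort(names(object@counts)), sort(.LINK_CLASSES)))
        return("counts must be named by the three link classes")
    if (sum(object@counts) != nrow(object@crosslinks))
        return("per-class counts must sum to the number of crosslinks")
    TRUE
})

#' In-silico crosslink combination space of a peptide library
#'
#' All theoretically possible crosslink combinations of a library:
#' unordered peptide pairs including homeotypic self-pairs. In
#' \code{"pooled"} mode every pair of the n library peptides is reachable,
#' giving n(n+1)/2 combinations; in \code{"grouped"} mode only within-group
#' pairs form, giving the sum of n_g(n_g+1)/2 over groups. Each combination
#' is classified as homeotypic (identical sequences), intraprotein
#' (homomeric: same source protein) or interprotein (heteromeric).
#'
#' Objects are created by [enumerateTheoretical()].
#'
#' @seealso [enumerateTheoretical()], [distributionComparison()].
#' @name TheoreticalSpace
NULL

#' @rdname ValidationResult
#' @export
setClass("ValidationResult",
    representation(level = "character", nTotal = "integer",
                   nCrossGroup = "integer", nNonLibrary = "integer",
                   fdr = "numeric", perClass = "data.frame",
                   annotated = "data.frame"))

#' Experimentally validated FDR of a crosslink result set
#'
#' Counts of target crosslink records split by ground-truth label, and the
#' experimentally validated false discovery rate
#' \deqn{FDR = \frac{\#\,cross\mbox{-}group + \#\,non\mbox{-}library}
#'                  {\#\,target\ crosslinks\ total}}
#' i.e. the fraction of reported target crosslinks joining peptides that
#' were never crosslinked together — either peptides allocated to
#' different reaction groups, or peptides absent from the library
#' altogether. \code{perClass} splits the same counts by link class, and
#' \code{annotated} carries the input records with their truth labels.
#'
#' Objects are created by [validatedFdr()].
#'
#' @seealso [validatedFdr()], [applyScoreCutoff()].
#' @name ValidationResult
NULL

#' @rdname CutoffResult
#' @export
setClass("CutoffResult",
    representation(threshold = "numeric", nRetained = "integer",
                   achievedFdr = "numeric", targetFdr = "numeric",
                   curve = "data.frame", retained = "CrosslinkSet"))

#' Post-score cutoff achieving a target validated FDR
#'
#' The least strict score threshold (on the normalized higher-is-better
#' scale, ties retained inclusively) whose retained record set has
#' experimentally validated FDR at or below the target, together with the
#' retained records and the full threshold/count/FDR curve. An infeasible
#' target yields an empty retained set with \code{threshold = Inf}.
#'
#' Objects are created by [applyScoreCutoff()].
#'
#' @seealso [applyScoreCutoff()], [fdrScoreCurve()].
#' @name CutoffResult
NULL

#' @rdname OverlapResult
#' @export
setClass("OverlapResult",
    representation(setLabels = "character", regions = "list",
                   counts = "integer", regionFdr = "numeric"))

#' Overlap of crosslink sets across engines or replicates
#'
#' Exact partition of the union of 2 or more unique-link sets into
#' membership regions (e.g. \code{"A&B"}, \code{"A"}, \code{"B"} for two
#' sets), with the number of link keys and the experimentally validated
#' FDR computed per region. Commonly found links are expected to be the
#' most reliable; exclusive regions concentrate the false positives.
#'
#' Objects are created by [computeOverlap()].
#'
#' @seealso [computeOverlap()], [makeLinkKey()], [plotVenn()].
#' @name OverlapResult
NULL

#' @rdname PositionProbabilityMatrix
#' @export
setClass("PositionProbabilityMatrix",
    representation(probs = "matrix", support = "integer",
                   includeSite = "logical"))

setValidity("PositionProbabilityMatrix", function(object) {
    if (!identical(rownames(object@probs), aminoAcids()))
        return("rows must be the 20 standard amino acids")
    if (length(object@support) != ncol(object@probs))
        return("one support count per position required")
    ok <- object@support > 0L
    sums <- colSums(object@probs)[ok]
    if (length(sums) && any(abs(sums - 1) > 1e-9))
        return("supported columns must sum to 1")
    TRUE
})

#' Amino-acid probabilities around the crosslink site
#'
#' Per-position amino-acid probability matrix over offsets -3..+3 relative
#' to the linked residue, aggregated over both peptides of every record.
#' Offsets falling outside a peptide contribute nothing; columns are
#' normalized over their observed support, and zero-support columns are
#' left at zero (flagged by \code{support() == 0}) rather than normalized.
#'
#' Objects are created by [ppmAroundSite()].
#'
#' @seealso [ppmAroundSite()].
#' @name PositionProbabilityMatrix
NULL

#' @rdname DistributionComparison
#' @export
setClass("DistributionComparison",
    representation(table = "data.frame", level = "character",
                   mode = "character"))

#' Observed vs expected amino-acid distribution
#'
#' Comparison of the amino-acid frequency observed in identified
#' crosslinks against the distribution expected from the theoretical
#' crosslink space under the assumption that every theoretical combination
#' yields exactly one CSM. The table holds, per amino acid, the observed
#' frequency, expected frequency, their ratio and their difference; both
#' frequency vectors sum to 1.
#'
#' Objects are created by [distributionComparison()].
#'
#' @seealso [distributionComparison()], [enumerateTheoretical()].
#' @name DistributionComparison
NULL
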