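## Engine-dialect layer: crosslink search engines export incompatible
## table layouts, score conventions and decoy encodings. A dialect is a
## small, user-auditable description that maps one export format onto the
## canonical CrosslinkSet record model.

.CANONICAL_FIELDS <- c("sequence_a", "sequence_b", "protein_a", "protein_b",
                       "position_a", "position_b", "score", "decoy",
                       "link_type")
.OPTIONAL_FIELDS <- c("site_a", "site_b", "replicate", "spectrum_ref")

#' @rdname engineDialect
#' @export
setClass("EngineDialect",
    representation(engineName = "character", columnMap = "character",
                   scoreDirection = "character", decoyValues = "character",
                   linkTypeVocabulary = "list", positionBase = "integer"))

setValidity("EngineDialect", function(object) {
    missing <- setdiff(.CANONICAL_FIELDS, names(object@columnMap))
    if (length(missing))
        return(paste("column_map must cover:",
                     paste(missing, collapse = ", ")))
    if (!object@scoreDirection %in% c("higher_better", "lower_better"))
        return("score_direction must be 'higher_better' or 'lower_better'")
    if (!all(names(object@linkTypeVocabulary) %in% .LINK_TYPES))
        return(paste("link_type_vocabulary keys must be among:",
                     paste(.LINK_TYPES, collapse = ", ")))
    if (!object@positionBase %in% c(0L, 1L))
        return("position_base must be 0 or 1")
    TRUE
})

#' Describe a search engine's export format
#'
#' An \code{EngineDialect} tells [readResults()] how to interpret one
#' engine's result export: which source column holds each canonical field,
#' whether larger or smaller scores mean more confidence, which values of
#' the decoy column mark decoy hits, which source terms denote crosslinks,
#' dead-ends (mono-links), loop-links and linear peptides, and whether the
#' engine reports peptide positions 0- or 1-based. Dialects are plain data
#' and are typically stored as YAML files next to the exports (see
#' [readDialect()]); two examples ship under
#' \code{system.file("extdata/dialects", package = "xlfdr")}.
#'
#' @param engineName Label for the engine.
#' @param columnMap Named character vector mapping canonical field names
#'   (\code{sequence_a}, \code{sequence_b}, \code{protein_a},
#'   \code{protein_b}, \code{position_a}, \code{position_b}, \code{score},
#'   \code{decoy}, \code{link_type}; optionally \code{site_a},
#'   \code{site_b}, \code{replicate}, \code{spectrum_ref}) to source
#'   column names.
#' @param scoreDirection \code{"higher_better"} (default) or
#'   \code{"lower_better"} for e-value-like scores.
#' @param decoyValues Values of the decoy column marking a decoy row
#'   (case-insensitive; default \code{c("TRUE", "1", "decoy")}).
#' @param linkTypeVocabulary Named list mapping the canonical types
#'   \code{crosslink}, \code{deadend}, \code{looplink}, \code{linear} to
#'   the source terms used for them.
#' @param positionBase 0 or 1: base of the engine's peptide-position
#'   convention; positions are normalized to 1-based on import.
#' @return An \code{EngineDialect}.
#' @seealso [readResults()], [readDialect()], [canonicalDialect()].
#' @export
engineDialect <- function(engineName, columnMap,
                          scoreDirection = "higher_better",
                          decoyValues = c("TRUE", "1", "decoy"),
                          linkTypeVocabulary = list(
                              crosslink = "crosslink",
                              deadend = "deadend",
                              looplink = "looplink",
                              linear = "linear"),
                          positionBase = 1L) {
    new("EngineDialect", engineName = engineName,
        columnMap = columnMap, scoreDirection = scoreDirection,
        decoyValues = as.character(decoyValues),
        linkTypeVocabulary = linkTypeVocabulary,
        positionBase = as.integer(positionBase))
}

#' The canonical dialect
#'
#' Dialect describing the package's own canonical CSV schema: canonical
#' column names, higher-is-better scores, logical decoy column, canonical
#' link-type terms, 1-based positions. Files written by [writeRecords()]
#' and [generateResults()] use this layout.
#'
#' @return An [engineDialect()].
#' @export
canonicalDialect <- function() {
    fields <- c(.CANONICAL_FIELDS, .OPTIONAL_FIELDS)
    engineDialect("canonical",
                  columnMap = stats::setNames(fields, fields))
}

#' @rdname readDialect
#' @param dialect An [engineDialect()].
#' @param file Path of the YAML file to write / read.
#' @export
writeDialect <- function(dialect, file) {
    stopifnot(is(dialect, "EngineDialect"))
    yaml::write_yaml(list(
        engine_name = dialect@engineName,
        column_map = as.list(dialect@columnMap),
        score_direction = dialect@scoreDirection,
        decoy_values = dialect@decoyValues,
        link_type_vocabulary = dialect@linkTypeVocabulary,
        position_base = dialect@positionBase), file)
    invisible(file)
}

#' Read or write an engine dialect as YAML
#'
#' Dialects are shipped and edited as YAML files so that the mapping from
#' a vendor export to the canonical schema stays auditable by the user
#' rather than being hard-coded; vendor layouts change between versions.
#'
#' @return \code{readDialect} returns an [engineDialect()];
#'   \code{writeDialect} invisibly returns \code{file}.
#' @export
readDialect <- function(file) {
    y <- yaml::read_yaml(file)
    engineDialect(
        engineName = y$engine_name,
        columnMap = unlist(y$column_map),
        scoreDirection = y$score_direction,
        decoyValues = as.character(y$decoy_values),
        linkTypeVocabulary = y$link_type_vocabulary,
        positionBase = y$position_base)
}

#' Read a search-engine result export
#'
#' Parses a delimited CSM-level export through an [engineDialect()] into
#' the canonical record model. Scores are normalized so that larger
#' always means more confident — \code{lower_better} engines are negated
#' (order-preserving and invertible), with the original value kept in
#' \code{raw_score}. Peptide positions are normalized to 1-based; decoy
#' flags and link-type terms are mapped through the dialect's vocabulary.
#'
#' @param file Path to a CSV or TSV export.
#' @param dialect An [engineDialect()] or path to a dialect YAML.
#' @param replicate Replicate label stored on every record when the export
#'   has no replicate column.
#' @return A CSM-level [CrosslinkSet()]. An empty table yields an empty
#'   set, not an error.
#' @export
readResults <- function(file, dialect = canonicalDialect(),
                        replicate = "r1") {
    if (is.character(dialect))
        dialect <- readDialect(dialect)
    stopifnot(is(dialect, "EngineDialect"))
    validObject(dialect)
    tab <- .readDelimited(file)
    map <- dialect@columnMap
    required <- map[.CANONICAL_FIELDS]
    missing <- required[!required %in% names(tab)]
    if (length(missing))
        stop("result file lacks column(s) required by dialect '",
             dialect@engineName, "': ",
             paste(missing, collapse = ", "), call. = FALSE)
    getOpt <- function(field, default) {
        if (field %in% names(map) && map[[field]] %in% names(tab))
            tab[[map[[field]]]]
        else default
    }
    n <- nrow(tab)
    rawScore <- as.numeric(tab[[map[["score"]]]])
    score <- if (dialect@scoreDirection == "lower_better") -rawScore
             else rawScore
    linkTypeSrc <- tolower(trimws(as.character(tab[[map[["link_type"]]]])))
    vocab <- dialect@linkTypeVocabulary
    lookup <- stats::setNames(
        rep(names(vocab), lengths(vocab)),
        tolower(unlist(vocab, use.names = FALSE)))
    linkType <- unname(lookup[linkTypeSrc])
    if (n && anyNA(linkType))
        stop("unknown link-type term(s) for dialect '",
             dialect@engineName, "': ",
             paste(unique(linkTypeSrc[is.na(linkType)]), collapse = ", "),
             call. = FALSE)
    offset <- 1L - dialect@positionBase
    rec <- data.frame(
        seq_a = toupper(as.character(tab[[map[["sequence_a"]]]])),
        seq_b = toupper(as.character(tab[[map[["sequence_b"]]]])),
        site_a = as.integer(getOpt("site_a", rep(NA_integer_, n))),
        site_b = as.integer(getOpt("site_b", rep(NA_integer_, n))),
        protein_a = as.character(tab[[map[["protein_a"]]]]),
        protein_b = as.character(tab[[map[["protein_b"]]]]),
        pos_a = as.integer(tab[[map[["position_a"]]]]) + offset,
        pos_b = as.integer(tab[[map[["position_b"]]]]) + offset,
        score = score,
        raw_score = rawScore,
        is_decoy = tolower(trimws(as.character(tab[[map[["decoy"]]]]))) %in%
            tolower(dialect@decoyValues),
        link_type = if (n) linkType else character(),
        engine = rep(dialect@engineName, n),
        replicate = as.character(getOpt("replicate", rep(replicate, n))),
        spectrum_ref = as.character(getOpt("spectrum_ref",
                                           rep(NA_character_, n))),
        stringsAsFactors = FALSE)
    CrosslinkSet(rec, level = "csm")
}

#' Write records in the canonical CSV schema
#'
#' @param x A [CrosslinkSet()].
#' @param file Output CSV path.
#' @return Invisibly, \code{file}.
#' @export
writeRecords <- function(x, file) {
    stopifnot(is(x, "CrosslinkSet"))
    rec <- records(x)
    out <- data.frame(
        sequence_a = rec$seq_a, sequence_b = rec$seq_b,
        protein_a = rec$protein_a, protein_b = rec$protein_b,
        position_a = rec$pos_a, position_b = rec$pos_b,
        score = rec$score, decoy = rec$is_decoy,
        link_type = rec$link_type,
        site_a = rec$site_a, site_b = rec$site_b,
        replicate = rec$replicate, spectrum_ref = rec$spectrum_ref,
        stringsAsFactors = FALSE)
    if ("n_csms" %in% names(rec)) out$n_csms <- rec$n_csms
    if ("truth" %in% names(rec)) out$truth <- rec$truth
    utils::write.csv(out, file, row.names = FALSE, quote = FALSE)
    invisible(file)
}

#' Filter to target inter/intra-protein crosslinks
#'
#' Keeps only the records the validated-FDR formula is defined on: decoy
#' hits are removed, and so are all identifications that are not
#' inter-peptide residue pairs — dead-end (mono-)links, loop-links and
#' linear peptides. Optionally, pairs whose shorter peptide falls below a
#' minimum length are removed as well: very short peptides carry little
#' fragment evidence and are a known source of false positives. The
#' operation is idempotent.
#'
#' @param x A [CrosslinkSet()].
#' @param minShortPeptideLen Minimum length of the shorter peptide of each
#'   pair (default 1: no length filtering).
#' @return A [CrosslinkSet()] at the same level.
#' @export
filterTargets <- function(x, minShortPeptideLen = 1L) {
    stopifnot(is(x, "CrosslinkSet"), minShortPeptideLen >= 1L)
    rec <- records(x)
    keep <- !rec$is_decoy & rec$link_type == "crosslink" &
        pmin(nchar(rec$seq_a), nchar(rec$seq_b)) >= minShortPeptideLen
    CrosslinkSet(rec[keep, , drop = FALSE], level = recordLevel(x))
}

#' Group CSMs to unique residue pairs
#'
#' Several spectra can match the same crosslink; for link-level analysis
#' CSMs are collapsed onto unique residue pairs by their canonical link
#' key (see [makeLinkKey()]). Each unique link carries the best (maximum
#' normalized) score among its member CSMs and the member count
#' \code{n_csms}, so that score-cutoff filtering at link level is
#' consistent with CSM-level filtering.
#'
#' @param x A CSM-level [CrosslinkSet()].
#' @param strict Include link-site positions in the identity key (see
#'   [makeLinkKey()]).
#' @return A [CrosslinkSet()] at \code{unique_link} level.
#' @export
groupToUniqueLinks <- function(x, strict = FALSE) {
    stopifnot(is(x, "CrosslinkSet"))
    if (recordLevel(x) == "unique_link")
        return(x)
    rec <- records(x)
    if (nrow(rec) == 0L) {
        rec$n_csms <- integer()
        return(CrosslinkSet(rec, level = "unique_link"))
    }
    key <- makeLinkKey(x, strict = strict)
    ord <- order(key, -rec$score)
    rec <- rec[ord, , drop = FALSE]
    key <- key[ord]
    first <- !duplicated(key)
    out <- rec[first, , drop = FALSE]
    out$n_csms <- as.integer(table(key)[key[first]])
    out$spectrum_ref <- NA_character_
    CrosslinkSet(out, level = "unique_link")
}
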