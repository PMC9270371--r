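## Library ground-truth model: synthesis constructs, tryptic release,
## theoretical crosslink space, and truth classification of peptide pairs.

#' @rdname digestConstruct
#' @export
setClass("SynthesisConstruct",
    representation(nTag = "character", core = "character",
                   cTag = "character", azideK = "logical"))

setValidity("SynthesisConstruct", function(object) {
    if (!nzchar(object@core))
        return("core peptide must be non-empty")
    if (nzchar(object@nTag)) {
        tag <- .stripTagDecoration(object@nTag)
        if (!grepl("[KR]$", tag))
            return("N-terminal tag must end in K or R (tryptic release point)")
        if (!grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", tag))
            return("N-terminal tag contains non-standard residues")
    }
    if (!grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", object@core))
        return("core contains non-standard residues")
    TRUE
})

## Tags are written with their chemical protection spelled out,
## e.g. "acetyl-WGGGGR" or "GGGG-amide"; strip the decoration to get
## the residue letters.
.stripTagDecoration <- function(tag) {
    tag <- sub("^(acetyl|ac)-", "", tag, ignore.case = TRUE)
    tag <- sub("-?(amide|am)$", "", tag, ignore.case = TRUE)
    toupper(tag)
}

#' @rdname digestConstruct
#' @param core Final peptide part of the construct.
#' @param nTag Optional protected N-terminal tag, e.g. \code{"acetyl-WGGGGR"};
#'   must end in K or R so trypsin releases the core.
#' @param cTag Optional protected C-terminal tag, e.g. \code{"GGGG-amide"}.
#' @param azideK \code{TRUE} if the C-terminal lysine of the core carries an
#'   azide instead of an amine.
#' @export
SynthesisConstruct <- function(core, nTag = "", cTag = "", azideK = FALSE) {
    new("SynthesisConstruct", nTag = nTag, core = toupper(core),
        cTag = cTag, azideK = azideK)
}

#' Tryptic release of a protected synthesis construct
#'
#' Synthetic library peptides are synthesized with protection groups that
#' block unwanted crosslink reactions: an acetylated N-terminal tag ending
#' in arginine (removed by tryptic digestion), an optional amide-protected
#' C-terminal tag, and an azide on C-terminal lysines (reduced back to an
#' amine after the reaction). \code{digestConstruct} models the sample
#' processing that turns the protected construct into the ordinary tryptic
#' peptide the mass spectrometer sees: both tags are stripped and the
#' azide-lysine becomes a plain K, so the result is exactly the
#' \code{sequence} field of a library peptide.
#'
#' @param construct A \code{SynthesisConstruct}.
#' @return Character scalar: the final tryptic peptide sequence.
#' @export
#' @examples
#' digestConstruct(SynthesisConstruct("MAKTIK", nTag = "acetyl-WGGGGR",
#'                                    azideK = TRUE))
#' digestConstruct(SynthesisConstruct("APDLK", nTag = "acetyl-WGGGGR",
#'                                    cTag = "GGGG-amide"))
digestConstruct <- function(construct) {
    stopifnot(is(construct, "SynthesisConstruct"))
    validObject(construct)
    ## tags fall away; the azide-K is reduced to an ordinary lysine, which
    ## is already how the core is written in one-letter code
    construct@core
}

#' Read a library support file
#'
#' Reads the delimited group-allocation support file that defines the
#' ground truth: one row per synthetic tryptic peptide with its crosslink
#' group, source protein, 1-based start position, and reactive-site
#' position. Exact duplicates of (sequence, group) are collapsed; a
#' sequence allocated to two different groups is a consistency error, as is
#' a peptide violating the single-reactive-residue design.
#'
#' @param file Path to a CSV (default) or TSV support file with header.
#' @param dialect Optional named character vector mapping the canonical
#'   column names \code{sequence}, \code{group}, \code{protein},
#'   \code{start}, \code{site}, \code{chemistry} to the file's column
#'   names. Defaults to the identity mapping.
#' @param fasta Optional path to a FASTA of the source proteins; when
#'   given, each peptide is checked to occur at its stated start position
#'   and mismatches raise a warning.
#' @param libraryId Name for the library; defaults to the file name.
#' @return A [PeptideLibrary()].
#' @export
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' write.csv(data.frame(sequence = c("MAKTIK", "VAVIKAVR", "GGDLLR"),
#'                      group = c("g1", "g1", "g2"),
#'                      protein = c("P1", "P2", "P3"),
#'                      start = c(1, 10, 4),
#'                      site = c(3, 5, 3),
#'                      chemistry = c("lysine", "lysine", "acidic")),
#'           tf, row.names = FALSE)
#' loadLibrary(tf)
loadLibrary <- function(file, dialect = NULL, fasta = NULL,
                        libraryId = basename(file)) {
    if (!file.exists(file))
        stop("support file not found: ", file, call. = FALSE)
    tab <- .readDelimited(file)
    canonical <- c("sequence", "group", "protein", "start", "site")
    map <- stats::setNames(canonical, canonical)
    map["chemistry"] <- "chemistry"
    if (!is.null(dialect))
        map[names(dialect)] <- dialect
    missing <- map[canonical][!map[canonical] %in% names(tab)]
    if (length(missing))
        stop("support file lacks required column(s): ",
             paste(missing, collapse = ", "), call. = FALSE)
    pep <- data.frame(
        sequence = toupper(trimws(as.character(tab[[map[["sequence"]]]]))),
        group_id = as.character(tab[[map[["group"]]]]),
        protein_id = as.character(tab[[map[["protein"]]]]),
        start_pos = as.integer(tab[[map[["start"]]]]),
        site_pos = as.integer(tab[[map[["site"]]]]),
        stringsAsFactors = FALSE)
    if (map[["chemistry"]] %in% names(tab)) {
        pep$chemistry <- tolower(as.character(tab[[map[["chemistry"]]]]))
    } else {
        ## infer: a non-terminal K means lysine chemistry
        pep$chemistry <- ifelse(
            vapply(pep$sequence,
                   function(s) length(.reactiveSites(s, "lysine")) > 0,
                   logical(1)),
            "lysine", "acidic")
    }
    pep <- unique(pep)
    dup <- pep$sequence[duplicated(pep$sequence)]
    if (length(dup))
        stop("sequence allocated to more than one group: ",
             paste(unique(dup), collapse = ", "), call. = FALSE)
    lib <- PeptideLibrary(pep, libraryId = libraryId)
    if (!is.null(fasta))
        .checkAgainstFasta(lib, fasta)
    lib
}

.readDelimited <- function(file) {
    sep <- if (grepl("\\.tsv$|\\.txt$", file, ignore.case = TRUE)) "\t" else ","
    ## read everything as character: numeric fields are converted
    ## explicitly by the callers, and type guessing must not turn decoy
    ## flags like "T" into logicals
    utils::read.table(file, header = TRUE, sep = sep, quote = "\"",
                      colClasses = "character", comment.char = "",
                      check.names = FALSE, fileEncoding = "UTF-8")
}

.checkAgainstFasta <- function(library, fasta) {
    prot <- Biostrings::readAAStringSet(fasta)
    names(prot) <- sub("\\s.*$", "", names(prot))
    pep <- peptides(library)
    for (i in seq_len(nrow(pep))) {
        acc <- pep$protein_id[i]
        if (!acc %in% names(prot)) next
        seq <- as.character(prot[[acc]])
        at <- pep$start_pos[i]
        found <- substr(seq, at, at + nchar(pep$sequence[i]) - 1L)
        if (!identical(found, pep$sequence[i]))
            warning(sprintf(
                "peptide %s not found at position %d of %s (found '%s')",
                pep$sequence[i], at, acc, found), call. = FALSE)
    }
    invisible(library)
}

#' Enumerate the theoretical crosslink space
#'
#' Builds every crosslink combination that can form in silico: all
#' unordered peptide pairs including homeotypic self-pairs. In
#' \code{"pooled"} mode all n peptides react in one vessel, giving
#' n(n+1)/2 combinations (946 for the 43-peptide acidic library); in
#' \code{"grouped"} mode only peptides of the same crosslink group can
#' meet, giving the sum of n_g(n_g+1)/2 over groups. Each combination is
#' labeled homeotypic, intraprotein (homomeric) or interprotein
#' (heteromeric), and flagged for group co-membership.
#'
#' @param library A [PeptideLibrary()].
#' @param mode \code{"grouped"} or \code{"pooled"}.
#' @return A \linkS4class{TheoreticalSpace}.
#' @export
#' @examples
#' lib <- generateLibrary(simulationConfig(nPeptides = 12,
#'                                         groupSizes = c(6, 6), seed = 1))
#' enumerateTheoretical(lib, "grouped")
#' enumerateTheoretical(lib, "pooled")
enumerateTheoretical <- function(library, mode = c("grouped", "pooled")) {
    mode <- match.arg(mode)
    pep <- peptides(library)
    if (nrow(pep) == 0L)
        stop("library is empty", call. = FALSE)
    pairIdx <- function(idx) {
        n <- length(idx)
        i <- rep.int(idx, times = rev(seq_len(n)))
        j <- unlist(lapply(seq_len(n), function(k) idx[k:n]), use.names = FALSE)
        cbind(i, j)
    }
    ij <- if (mode == "pooled") {
        pairIdx(seq_len(nrow(pep)))
    } else {
        do.call(rbind, lapply(split(seq_len(nrow(pep)), pep$group_id),
                              pairIdx))
    }
    xl <- data.frame(
        seq_a = pep$sequence[ij[, 1]],
        seq_b = pep$sequence[ij[, 2]],
        protein_a = pep$protein_id[ij[, 1]],
        protein_b = pep$protein_id[ij[, 2]],
        group_a = pep$group_id[ij[, 1]],
        group_b = pep$group_id[ij[, 2]],
        stringsAsFactors = FALSE)
    xl$link_class <- ifelse(xl$seq_a == xl$seq_b, "homeotypic",
                     ifelse(xl$protein_a == xl$protein_b,
                            "intraprotein", "interprotein"))
    xl$same_group <- xl$group_a == xl$group_b
    rownames(xl) <- NULL
    counts <- vapply(.LINK_CLASSES,
                     function(cl) sum(xl$link_class == cl), integer(1))
    new("TheoreticalSpace", mode = mode, crosslinks = xl, counts = counts)
}

#' Classify a peptide pair against the library ground truth
#'
#' The group design makes truth decidable for any reported pair: a
#' crosslink is only possibly correct if both peptides were synthesized
#' and allocated to the same reaction group. Sequence identity is literal
#' uppercase string equality with I and L distinct — an isobaric
#' permutation of a library peptide (e.g. MAKLTK vs the library's MAKTIK)
#' is a non-library false positive, exactly the error mode the library is
#' built to expose.
#'
#' @param seqA,seqB Uppercase amino-acid sequences of the two sides
#'   (vectorized; recycled to common length).
#' @param library A [PeptideLibrary()].
#' @return \code{data.frame} with columns \code{truth}
#'   (\code{within_group_true}, \code{cross_group_false} or
#'   \code{non_library_false}) and \code{link_class} (\code{homeotypic} /
#'   \code{intraprotein} / \code{interprotein}, \code{NA} when a side is
#'   not a library peptide). Symmetric in the two arguments.
#' @export
#' @examples
#' lib <- PeptideLibrary(data.frame(
#'     sequence = c("MAKTIK", "VAVIKAVR"), group_id = c("g1", "g2"),
#'     protein_id = c("P1", "P2"), start_pos = 1L, site_pos = c(3L, 5L),
#'     chemistry = "lysine"))
#' classifyPair("MAKLTK", "MAKLTK", lib)    # isobaric decoy: non-library
#' classifyPair("MAKTIK", "VAVIKAVR", lib)  # different groups: false
#' classifyPair("MAKTIK", "MAKTIK", lib)    # self pair: true homeotypic
classifyPair <- function(seqA, seqB, library) {
    pep <- peptides(library)
    n <- max(length(seqA), length(seqB))
    seqA <- rep_len(as.character(seqA), n)
    seqB <- rep_len(as.character(seqB), n)
    ia <- match(seqA, pep$sequence)
    ib <- match(seqB, pep$sequence)
    truth <- ifelse(is.na(ia) | is.na(ib), "non_library_false",
             ifelse(pep$group_id[ia] != pep$group_id[ib],
                    "cross_group_false", "within_group_true"))
    linkClass <- ifelse(is.na(ia) | is.na(ib), NA_character_,
                 ifelse(seqA == seqB, "homeotypic",
                 ifelse(pep$protein_id[ia] == pep$protein_id[ib],
                        "intraprotein", "interprotein")))
    data.frame(truth = truth, link_class = linkClass,
               stringsAsFactors = FALSE)
}

#' Flag near-isobaric peptide pairs in a library
#'
#' Diagnostic for the identity convention: distinct library sequences
#' whose monoisotopic masses differ by at most \code{tolerance} Da (for
#' example permutations of the same residues) can generate
#' mass-indistinguishable spectra and are worth knowing about when
#' interpreting non-library false positives.
#'
#' @param library A [PeptideLibrary()].
#' @param tolerance Mass tolerance in Da (default 0.01).
#' @return \code{data.frame} with columns \code{seq_a}, \code{seq_b},
#'   \code{delta_mass}.
#' @export
nearIsobaricPairs <- function(library, tolerance = 0.01) {
    seqs <- peptides(library)$sequence
    mass <- vapply(seqs, peptideMass, numeric(1))
    out <- list()
    if (length(seqs) > 1L) {
        for (i in seq_len(length(seqs) - 1L)) {
            for (j in seq((i + 1L), length(seqs))) {
                d <- abs(mass[i] - mass[j])
                if (d <= tolerance)
                    out[[length(out) + 1L]] <- data.frame(
                        seq_a = seqs[i], seq_b = seqs[j], delta_mass = d,
                        stringsAsFactors = FALSE)
            }
        }
    }
    if (length(out)) do.call(rbind, out)
    else data.frame(seq_a = character(), seq_b = character(),
                    delta_mass = numeric())
}
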