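## Physicochemical properties of crosslinks. Crosslinked peptide pairs are
## represented in a linearized form (canonical concatenation of the two
## sequences) so that standard protein-parameter math applies; the mass
## model still accounts for both peptide chains.

#' @rdname linearizePair
#' @export
setClass("LinearizedCrosslink",
    representation(sequence = "character", massExtra = "numeric",
                   nPeptides = "integer"))

#' Linearize a crosslinked peptide pair
#'
#' Concatenates the two peptide sequences in canonical (lexicographic)
#' order into one linear sequence. The properties computed downstream
#' (GRAVY, aromaticity, residue frequencies, mass) are order-invariant, so
#' the canonical order only fixes the display form. The residue multiset
#' of the result is exactly the union of both peptides' residues; the
#' number of chains is retained for the mass model (one water per
#' peptide).
#'
#' @param seqA,seqB Uppercase peptide sequences.
#' @param massExtra Crosslinker mass addition in Da remaining on the
#'   linked pair (reagent-dependent; default 0).
#' @return A \code{LinearizedCrosslink}.
#' @export
#' @examples
#' linearizePair("KA", "GR")    # "GRKA"
#' linearizePair("PK", "PK")    # homeotypic: "PKPK"
linearizePair <- function(seqA, seqB, massExtra = 0) {
    seqA <- toupper(seqA); seqB <- toupper(seqB)
    .checkSequence(c(seqA, seqB))
    combined <- if (seqA <= seqB) paste0(seqA, seqB) else paste0(seqB, seqA)
    new("LinearizedCrosslink", sequence = combined,
        massExtra = massExtra, nPeptides = 2L)
}

#' @rdname accessors
#' @export
setMethod("show", "LinearizedCrosslink", function(object) {
    cat(sprintf("LinearizedCrosslink: %s (%d chains, +%.4f Da)\n",
                object@sequence, object@nPeptides, object@massExtra))
})

#' Monoisotopic mass of a linear peptide
#'
#' Sum of monoisotopic residue masses plus one water.
#'
#' @param sequence Uppercase peptide sequence.
#' @return Mass in Da.
#' @export
#' @examples
#' peptideMass("G")   # 75.0320
peptideMass <- function(sequence) {
    .checkSequence(sequence)
    sum(.MONO_MASS[strsplit(sequence, "")[[1]]]) + .MASS_WATER
}

#' Isoelectric point by net-charge bisection
#'
#' Henderson-Hasselbalch net charge of the sequence as a function of pH,
#' using the EMBOSS pKa set (N-terminus 8.6, C-terminus 3.6; side chains
#' K 10.8, R 12.5, H 6.5, D 3.9, E 4.1, C 8.5, Y 10.1), with the pI found
#' by bisection on pH in \[0, 14\] to a tolerance of 0.01 pH units. The
#' linearized crosslink is treated as a single chain with one pair of
#' termini, consistent with its linear representation.
#'
#' @param sequence Uppercase peptide sequence.
#' @param tol Bisection tolerance in pH units.
#' @return pI in pH units.
#' @export
isoelectricPoint <- function(sequence, tol = 0.01) {
    .checkSequence(sequence)
    residues <- strsplit(sequence, "")[[1]]
    nPos <- table(factor(residues, levels = names(.PKA$positive)))
    nNeg <- table(factor(residues, levels = names(.PKA$negative)))
    charge <- function(pH) {
        pos <- 1 / (1 + 10^(pH - .PKA$nterm)) +
            sum(nPos / (1 + 10^(pH - .PKA$positive)))
        neg <- 1 / (1 + 10^(.PKA$cterm - pH)) +
            sum(nNeg / (1 + 10^(.PKA$negative - pH)))
        pos - neg
    }
    lo <- 0; hi <- 14
    while (hi - lo > tol) {
        mid <- (lo + hi) / 2
        if (charge(mid) > 0) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
}

#' Physicochemical properties of a linearized crosslink
#'
#' Computes, on the linearized sequence: the GRAVY value (mean
#' Kyte-Doolittle hydropathy), the aromaticity (fraction of F, W, Y),
#' the monoisotopic molecular mass (residue masses plus one water per
#' peptide chain plus the crosslinker mass addition), the isoelectric
#' point ([isoelectricPoint()]), and the per-residue frequency vector.
#'
#' @param xl A \code{LinearizedCrosslink} (or plain sequence, treated as a
#'   single chain).
#' @return List with elements \code{isoelectric_point}, \code{aromaticity},
#'   \code{molecular_mass}, \code{gravy}, \code{aa_frequencies}.
#' @export
#' @examples
#' computeProperties("AA")$gravy          # 1.8
#' computeProperties("WGGG")$aromaticity  # 0.25
computeProperties <- function(xl) {
    if (is.character(xl))
        xl <- new("LinearizedCrosslink", sequence = toupper(xl),
                  massExtra = 0, nPeptides = 1L)
    stopifnot(is(xl, "LinearizedCrosslink"))
    .checkSequence(xl@sequence)
    residues <- strsplit(xl@sequence, "")[[1]]
    freq <- table(factor(residues, levels = aminoAcids())) / length(residues)
    list(
        isoelectric_point = isoelectricPoint(xl@sequence),
        aromaticity = mean(residues %in% .AROMATIC),
        molecular_mass = sum(.MONO_MASS[residues]) +
            xl@nPeptides * .MASS_WATER + xl@massExtra,
        gravy = mean(.KD_SCALE[residues]),
        aa_frequencies = stats::setNames(as.numeric(freq), aminoAcids()))
}

#' Property table for every crosslink in a set
#'
#' Applies [linearizePair()] and [computeProperties()] to each record;
#' records containing non-standard residues are skipped with a message.
#'
#' @param x A [CrosslinkSet()].
#' @param massExtra Crosslinker mass addition in Da (per link).
#' @return \code{data.frame} with one row per successfully processed
#'   record: the linearized sequence and the four scalar properties.
#' @export
crosslinkProperties <- function(x, massExtra = 0) {
    stopifnot(is(x, "CrosslinkSet"))
    rec <- records(x)
    rows <- lapply(seq_len(nrow(rec)), function(i) {
        p <- tryCatch({
            xl <- linearizePair(rec$seq_a[i], rec$seq_b[i], massExtra)
            c(list(linearized = xl@sequence),
              computeProperties(xl)[c("isoelectric_point", "aromaticity",
                                      "molecular_mass", "gravy")])
        }, error = function(e) {
            message("record ", i, " skipped: ", conditionMessage(e))
            NULL
        })
        if (is.null(p)) NULL else as.data.frame(p, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
        out <- data.frame(linearized = character(),
                          isoelectric_point = numeric(),
                          aromaticity = numeric(),
                          molecular_mass = numeric(), gravy = numeric())
    out
}

.aaCounts <- function(sequences) {
    residues <- unlist(strsplit(sequences, ""), use.names = FALSE)
    table(factor(residues, levels = aminoAcids()))
}

#' Observed vs theoretically expected amino-acid distribution
#'
#' Compares the amino-acid frequency observed in identified crosslinks to
#' the distribution expected from the library's theoretical crosslink
#' space under the assumption that every theoretical combination yields
#' exactly one CSM. The observed side counts residues over the linearized
#' sequences of the input records (CSM or unique-link level, as given —
#' both are meaningful and the level is recorded); the expected side
#' counts each theoretical crosslink of the chosen enumeration mode once.
#'
#' @param x A [CrosslinkSet()] (must be non-empty).
#' @param library A [PeptideLibrary()].
#' @param mode Enumeration mode of the expected space (\code{"grouped"} or
#'   \code{"pooled"}); use the mode the experiment was actually run in.
#' @return A \linkS4class{DistributionComparison}. Ratios where the
#'   expected frequency is 0 are \code{NA}.
#' @export
distributionComparison <- function(x, library,
                                   mode = c("grouped", "pooled")) {
    mode <- match.arg(mode)
    stopifnot(is(x, "CrosslinkSet"))
    rec <- records(x)
    if (nrow(rec) == 0L)
        stop("no records: nothing to compare", call. = FALSE)
    obsCnt <- .aaCounts(paste0(rec$seq_a, rec$seq_b))
    space <- enumerateTheoretical(library, mode)
    xl <- crosslinks(space)
    expCnt <- .aaCounts(paste0(xl$seq_a, xl$seq_b))
    observed <- as.numeric(obsCnt) / sum(obsCnt)
    expected <- as.numeric(expCnt) / sum(expCnt)
    tab <- data.frame(
        aa = aminoAcids(), observed = observed, expected = expected,
        ratio = ifelse(expected > 0, observed / expected, NA_real_),
        difference = observed - expected, stringsAsFactors = FALSE)
    new("DistributionComparison", table = tab,
        level = recordLevel(x), mode = mode)
}

#' Position probability matrix around the link site
#'
#' Counts the residues at offsets -window..+window around the linked
#' residue, over both peptides of every record that carries link-site
#' information, and normalizes each offset column over its observed
#' support. Offsets reaching beyond a peptide's termini contribute
#' nothing, so terminal-proximal sites have smaller support; zero-support
#' columns are left unnormalized at zero. The site column (offset 0) is
#' included by default and its inclusion is recorded on the object.
#'
#' @param x A [CrosslinkSet()] with \code{site_a}/\code{site_b} set.
#' @param window Number of neighboring positions on each side (default 3).
#' @param includeSite Keep the offset-0 column (the linked residue
#'   itself).
#' @return A \linkS4class{PositionProbabilityMatrix}.
#' @export
ppmAroundSite <- function(x, window = 3L, includeSite = TRUE) {
    stopifnot(is(x, "CrosslinkSet"), window >= 1L)
    rec <- records(x)
    hasSite <- !is.na(rec$site_a) | !is.na(rec$site_b)
    if (!any(hasSite))
        stop("no records carry link-site information", call. = FALSE)
    offsets <- seq(-window, window)
    if (!includeSite) offsets <- offsets[offsets != 0L]
    counts <- matrix(0L, nrow = 20L, ncol = length(offsets),
                     dimnames = list(aminoAcids(), as.character(offsets)))
    addSide <- function(seq, site) {
        if (is.na(site)) return()
        residues <- strsplit(seq, "")[[1]]
        for (k in seq_along(offsets)) {
            p <- site + offsets[k]
            if (p >= 1L && p <= length(residues))
                counts[residues[p], k] <<- counts[residues[p], k] + 1L
        }
    }
    for (i in which(hasSite)) {
        addSide(rec$seq_a[i], rec$site_a[i])
        addSide(rec$seq_b[i], rec$site_b[i])
    }
    supp <- colSums(counts)
    storage.mode(supp) <- "integer"
    probs <- counts
    ok <- supp > 0L
    probs[, ok] <- sweep(counts[, ok, drop = FALSE], 2L, supp[ok], "/")
    new("PositionProbabilityMatrix", probs = probs, support = supp,
        includeSite = includeSite)
}

#' Sequence-motif profile plot of a position probability matrix
#'
#' Stacked-letter-free profile: per offset, the residues are drawn as
#' text scaled by their probability, a plain base-graphics stand-in for a
#' sequence logo.
#'
#' @param ppm A \linkS4class{PositionProbabilityMatrix}.
#' @param file Optional PNG path.
#' @param minProb Residues below this probability are not drawn.
#' @return Invisibly, \code{file}.
#' @export
plotPpm <- function(ppm, file = NULL, minProb = 0.02) {
    stopifnot(is(ppm, "PositionProbabilityMatrix"))
    p <- probs(ppm)
    if (!is.null(file)) {
        grDevices::png(file, width = 900, height = 600, res = 120)
        on.exit(grDevices::dev.off())
    }
    graphics::plot.new()
    graphics::plot.window(c(0.5, ncol(p) + 0.5), c(0, 1))
    graphics::axis(1, at = seq_len(ncol(p)), labels = colnames(p))
    graphics::axis(2)
    graphics::title(xlab = "offset from link site", ylab = "probability")
    for (j in seq_len(ncol(p))) {
        col <- sort(p[p[, j] >= minProb, j], decreasing = TRUE)
        y <- 0
        for (aa in names(col)) {
            h <- col[[aa]]
            graphics::text(j, y + h / 2, aa, cex = 0.6 + 2.5 * h)
            y <- y + h
        }
    }
    invisible(file)
}
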