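## Amino-acid scales and mass tables used throughout the package.
## All tables cover the 20 standard residues, one-letter uppercase codes.

#' The 20 standard amino-acid one-letter codes
#'
#' Alphabetically ordered vector of the standard residue letters; the
#' ordering defines row order of position probability matrices and
#' amino-acid frequency vectors.
#'
#' @return Character vector of length 20.
#' @export
#' @examples
#' aminoAcids()
aminoAcids <- function() {
    c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
      "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

## Kyte-Doolittle hydropathy scale (J Mol Biol 1982, 157:105-132).
.KD_SCALE <- c(
    A =  1.8, C =  2.5, D = -3.5, E = -3.5, F =  2.8,
    G = -0.4, H = -3.2, I =  4.5, K = -3.9, L =  3.8,
    M =  1.9, N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
    S = -0.8, T = -0.7, V =  4.2, W = -0.9, Y = -1.3)

## Monoisotopic residue masses in Da (residue = amino acid minus water).
.MONO_MASS <- c(
    A =  71.03711, C = 103.00919, D = 115.02694, E = 129.04259,
    F = 147.06841, G =  57.02146, H = 137.05891, I = 113.08406,
    K = 128.09496, L = 113.08406, M = 131.04049, N = 114.04293,
    P =  97.05276, Q = 128.05858, R = 156.10111, S =  87.03203,
    T = 101.04768, V =  99.06841, W = 186.07931, Y = 163.06333)

.MASS_WATER <- 18.010565

## EMBOSS pKa set used for the net-charge model behind isoelectric points.
## N-terminal amine, C-terminal carboxyl, and the ionizable side chains.
.PKA <- list(
    nterm = 8.6, cterm = 3.6,
    positive = c(K = 10.8, R = 12.5, H = 6.5),
    negative = c(D = 3.9, E = 4.1, C = 8.5, Y = 10.1))

## Aromatic residues used for the aromaticity fraction.
.AROMATIC <- c("F", "W", "Y")

## Canonical link-type vocabulary.
.LINK_TYPES <- c("crosslink", "deadend", "looplink", "linear")

## Truth labels assigned by classifyPair().
.TRUTH_LABELS <- c("within_group_true", "cross_group_false",
                   "non_library_false")

## Link classes of a theoretical or observed crosslink.
.LINK_CLASSES <- c("homeotypic", "intraprotein", "interprotein")

.checkSequence <- function(x, what = "sequence") {
    bad <- !grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", x)
    if (any(bad))
        stop(what, " contains non-standard residues: ",
             paste(unique(x[bad]), collapse = ", "), call. = FALSE)
    invisible(x)
}
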