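## Simulator: synthetic peptide libraries and search-engine result files
## with planted ground truth, so the whole validation pipeline can be
## exercised end-to-end without any experimental data.

#' Configuration of the library / result simulator
#'
#' Collects every knob of [generateLibrary()] and [generateResults()].
#' Defaults emulate the structure of the physical benchmarking libraries:
#' peptides of 6-20 residues with exactly one internal reactive residue
#' and a tryptic C-terminal K/R, grouped into crosslink groups of 6-10
#' peptides, with peptide-to-protein allocation at roughly 141 peptides
#' per 38 proteins. Scores are drawn from two normal distributions on the
#' normalized higher-is-better scale — well-separated correct vs
#' incorrect populations, as real engines show for their true and false
#' identifications.
#'
#' @param nPeptides Number of library peptides.
#' @param groupSizes Integer vector of crosslink-group sizes summing to
#'   \code{nPeptides}; by default near-equal groups of 6-10.
#' @param chemistry \code{"lysine"} or \code{"acidic"}.
#' @param nTrue,nCrossGroup,nNonLibrary Planted counts of within-group
#'   (true), cross-group (false) and non-library (false) links.
#' @param nDecoys Number of decoy rows to emit.
#' @param scoreModel List with normal location/scale for each population:
#'   \code{list(correct = c(mean, sd), incorrect = c(mean, sd))}.
#' @param csmsPerLink CSMs emitted per planted link (constant integer).
#' @param seed Integer seed; all simulator randomness flows from it.
#' @param dialect [engineDialect()] used when writing result files.
#' @return A \code{SimulationConfig} (named list).
#' @export
simulationConfig <- function(nPeptides = 100L, groupSizes = NULL,
                             chemistry = c("lysine", "acidic"),
                             nTrue = 100L, nCrossGroup = 0L,
                             nNonLibrary = 0L, nDecoys = 0L,
                             scoreModel = list(
                                 correct = c(mean = 200, sd = 30),
                                 incorrect = c(mean = 60, sd = 20)),
                             csmsPerLink = 1L, seed = 1L,
                             dialect = canonicalDialect()) {
    chemistry <- match.arg(chemistry)
    if (is.null(groupSizes)) {
        g <- max(1L, round(nPeptides / 8))
        groupSizes <- rep(nPeptides %/% g, g)
        extra <- nPeptides %% g
        if (extra) groupSizes[seq_len(extra)] <- groupSizes[seq_len(extra)] + 1L
    }
    if (sum(groupSizes) != nPeptides)
        stop("groupSizes must sum to nPeptides", call. = FALSE)
    if (any(c(nTrue, nCrossGroup, nNonLibrary, nDecoys) < 0))
        stop("planted counts must be >= 0", call. = FALSE)
    structure(list(
        nPeptides = as.integer(nPeptides),
        groupSizes = as.integer(groupSizes), chemistry = chemistry,
        nTrue = as.integer(nTrue), nCrossGroup = as.integer(nCrossGroup),
        nNonLibrary = as.integer(nNonLibrary), nDecoys = as.integer(nDecoys),
        scoreModel = scoreModel, csmsPerLink = as.integer(csmsPerLink),
        seed = as.integer(seed), dialect = dialect),
        class = "SimulationConfig")
}

## One random library-style peptide: internal body free of cleavage
## sites, exactly one internal reactive residue, tryptic C-terminus.
.randomPeptide <- function(chemistry, minLen = 6L, maxLen = 20L) {
    len <- sample(minLen:maxLen, 1L)
    reactive <- if (chemistry == "lysine") "K" else sample(c("D", "E"), 1L)
    body <- setdiff(aminoAcids(), c("K", "R", "D", "E"))
    residues <- sample(body, len - 1L, replace = TRUE)
    site <- sample(seq_len(len - 1L), 1L)
    residues[site] <- reactive
    residues[len] <- sample(c("K", "R"), 1L)
    list(sequence = paste(residues, collapse = ""), site = site)
}

#' Generate a synthetic peptide library
#'
#' Draws \code{nPeptides} random tryptic peptides (6-20 residues, exactly
#' one internal reactive residue of the configured chemistry, C-terminal
#' K or R), allocates them to crosslink groups of the configured sizes
#' and to source proteins, and optionally writes the support file in the
#' canonical schema. Deterministic under the config seed: the same seed
#' reproduces the library byte-for-byte.
#'
#' @param config A [simulationConfig()].
#' @param supportFile Optional CSV path to write the group-allocation
#'   support file to.
#' @return A [PeptideLibrary()].
#' @export
#' @examples
#' lib <- generateLibrary(simulationConfig(nPeptides = 43, seed = 3))
#' classCounts(enumerateTheoretical(lib, "pooled"))
generateLibrary <- function(config, supportFile = NULL) {
    stopifnot(inherits(config, "SimulationConfig"))
    set.seed(config$seed)
    seqs <- character(0)
    sites <- integer(0)
    while (length(seqs) < config$nPeptides) {
        p <- .randomPeptide(config$chemistry)
        if (p$sequence %in% seqs) next
        seqs <- c(seqs, p$sequence)
        sites <- c(sites, p$site)
    }
    nProteins <- max(1L, round(config$nPeptides * 38 / 141))
    pep <- data.frame(
        sequence = seqs,
        group_id = paste0("g", rep(seq_along(config$groupSizes),
                                   times = config$groupSizes)),
        protein_id = paste0("P", sample.int(nProteins, config$nPeptides,
                                            replace = TRUE)),
        start_pos = sample.int(300L, config$nPeptides, replace = TRUE),
        site_pos = sites,
        chemistry = config$chemistry,
        stringsAsFactors = FALSE)
    lib <- PeptideLibrary(pep, libraryId = sprintf("sim-seed%d", config$seed))
    if (!is.null(supportFile))
        writeSupportFile(lib, supportFile)
    lib
}

#' Write a library as a canonical support file
#'
#' @param library A [PeptideLibrary()].
#' @param file Output CSV path.
#' @return Invisibly, \code{file}.
#' @export
writeSupportFile <- function(library, file) {
    pep <- peptides(library)
    out <- data.frame(sequence = pep$sequence, group = pep$group_id,
                      protein = pep$protein_id, start = pep$start_pos,
                      site = pep$site_pos, chemistry = pep$chemistry,
                      stringsAsFactors = FALSE)
    utils::write.csv(out, file, row.names = FALSE, quote = FALSE)
    invisible(file)
}

## Build a CSM row block for a set of planted pairs.
.pairRows <- function(pep, ia, ib, truth) {
    data.frame(
        seq_a = pep$sequence[ia], seq_b = pep$sequence[ib],
        site_a = pep$site_pos[ia], site_b = pep$site_pos[ib],
        protein_a = pep$protein_id[ia], protein_b = pep$protein_id[ib],
        pos_a = pep$start_pos[ia], pos_b = pep$start_pos[ib],
        truth = rep_len(truth, length(ia)), stringsAsFactors = FALSE)
}

#' Simulate a search-engine result file with planted ground truth
#'
#' Emits CSMs for a planted composition: \code{nTrue} distinct
#' within-group pairs (correct), \code{nCrossGroup} distinct cross-group
#' pairs and \code{nNonLibrary} pairs involving an invented sequence
#' absent from the library (both incorrect), plus \code{nDecoys} decoy
#' rows. Scores are drawn from the configured correct/incorrect normal
#' distributions according to each link's truth status;
#' \code{csmsPerLink} spectra are emitted per link, each with its own
#' score draw. With one CSM per link, the validated FDR of the emitted
#' target links is exactly
#' \code{(nCrossGroup + nNonLibrary) / (nTrue + nCrossGroup + nNonLibrary)}.
#'
#' Deterministic under the config seed (offset from the library draw so
#' the two stages use independent streams).
#'
#' @param library A [PeptideLibrary()], typically from [generateLibrary()].
#' @param config A [simulationConfig()].
#' @param resultFile Optional path: writes the CSM table in the config's
#'   dialect (lower-is-better dialects get back-transformed scores, to
#'   exercise normalization on read).
#' @param truthFile Optional path: writes the planted ground-truth table.
#' @return List with \code{records} (a CSM-level [CrosslinkSet()]),
#'   \code{truth} (\code{data.frame} of planted link labels) and
#'   \code{files} (paths written).
#' @export
generateResults <- function(library, config, resultFile = NULL,
                            truthFile = NULL) {
    stopifnot(is(library, "PeptideLibrary"),
              inherits(config, "SimulationConfig"))
    set.seed(config$seed + 1L)
    pep <- peptides(library)
    n <- nrow(pep)
    grp <- pep$group_id
    ## candidate index pairs (i <= j), split by group co-membership
    i <- rep.int(seq_len(n), times = rev(seq_len(n)))
    j <- unlist(lapply(seq_len(n), function(k) k:n), use.names = FALSE)
    within <- grp[i] == grp[j]
    pick <- function(idx, k, what) {
        if (length(idx) < k)
            stop("requested ", k, " ", what, " links but only ",
                 length(idx), " pairs are available", call. = FALSE)
        idx[sample.int(length(idx), k)]
    }
    sel <- list(
        within = pick(which(within), config$nTrue, "within-group"),
        cross = pick(which(!within), config$nCrossGroup, "cross-group"))
    links <- rbind(
        .pairRows(pep, i[sel$within], j[sel$within], "within_group_true"),
        .pairRows(pep, i[sel$cross], j[sel$cross], "cross_group_false"))
    ## non-library links: one invented sequence per link, checked absent
    if (config$nNonLibrary > 0L) {
        fake <- character(0)
        while (length(fake) < config$nNonLibrary) {
            p <- .randomPeptide(config$chemistry)
            if (p$sequence %in% pep$sequence || p$sequence %in% fake) next
            fake <- c(fake, p$sequence)
        }
        partner <- sample.int(n, config$nNonLibrary, replace = TRUE)
        fakeSite <- vapply(fake, function(s)
            .reactiveSites(s, config$chemistry)[1], integer(1))
        links <- rbind(links, data.frame(
            seq_a = fake, seq_b = pep$sequence[partner],
            site_a = unname(fakeSite), site_b = pep$site_pos[partner],
            protein_a = paste0("NONLIB_", seq_len(config$nNonLibrary)),
            protein_b = pep$protein_id[partner],
            pos_a = sample.int(300L, config$nNonLibrary, replace = TRUE),
            pos_b = pep$start_pos[partner],
            truth = "non_library_false", stringsAsFactors = FALSE))
    }
    ## expand links to CSMs and draw scores by truth status
    csm <- links[rep(seq_len(nrow(links)), each = config$csmsPerLink), ,
                 drop = FALSE]
    correct <- csm$truth == "within_group_true"
    m <- config$scoreModel
    csm$score <- ifelse(correct,
        stats::rnorm(nrow(csm), m$correct[["mean"]], m$correct[["sd"]]),
        stats::rnorm(nrow(csm), m$incorrect[["mean"]], m$incorrect[["sd"]]))
    csm$is_decoy <- FALSE
    csm$link_type <- "crosslink"
    ## decoy rows: random pairs, incorrect-population scores
    if (config$nDecoys > 0L) {
        d <- sample(length(i), config$nDecoys, replace = TRUE)
        dec <- .pairRows(pep, i[d], j[d], "decoy")
        dec$score <- stats::rnorm(config$nDecoys, m$incorrect[["mean"]],
                                  m$incorrect[["sd"]])
        dec$is_decoy <- TRUE
        dec$link_type <- "crosslink"
        csm <- rbind(csm, dec)
    }
    csm$raw_score <- if (config$dialect@scoreDirection == "lower_better")
        -csm$score else csm$score
    csm$engine <- config$dialect@engineName
    csm$replicate <- "r1"
    csm$spectrum_ref <- sprintf("sim.raw:%d", seq_len(nrow(csm)))
    rownames(csm) <- NULL
    truth <- csm[, c("seq_a", "seq_b", "truth")]
    rec <- csm[, c(.RECORD_COLS, "raw_score")]
    out <- CrosslinkSet(rec, level = "csm")
    files <- character(0)
    if (!is.null(resultFile)) {
        .writeInDialect(csm, resultFile, config$dialect)
        files <- c(files, result = resultFile)
    }
    if (!is.null(truthFile)) {
        utils::write.csv(truth, truthFile, row.names = FALSE, quote = FALSE)
        files <- c(files, truth = truthFile)
    }
    list(records = out, truth = truth, files = files)
}

## Write a CSM table under a dialect's source column names; scores are
## written on the engine's own scale (back-negated for lower_better).
.writeInDialect <- function(csm, file, dialect) {
    map <- dialect@columnMap
    canonical <- data.frame(
        sequence_a = csm$seq_a, sequence_b = csm$seq_b,
        protein_a = csm$protein_a, protein_b = csm$protein_b,
        position_a = csm$pos_a + (dialect@positionBase - 1L),
        position_b = csm$pos_b + (dialect@positionBase - 1L),
        score = csm$raw_score,
        decoy = ifelse(csm$is_decoy, dialect@decoyValues[1], "target"),
        link_type = vapply(csm$link_type, function(t)
            dialect@linkTypeVocabulary[[t]][1], character(1)),
        site_a = csm$site_a, site_b = csm$site_b,
        replicate = csm$replicate, spectrum_ref = csm$spectrum_ref,
        stringsAsFactors = FALSE)
    present <- intersect(names(map), names(canonical))
    out <- canonical[, present, drop = FALSE]
    names(out) <- unname(map[present])
    utils::write.csv(out, file, row.names = FALSE, quote = FALSE)
    invisible(file)
}
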