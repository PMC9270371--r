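## Fixture builders and independent brute-force oracles. The oracles are
## deliberately naive (double loops, exhaustive sweeps) and share no code
## with the package implementation.

## -- fixtures ---------------------------------------------------------

tinyLib <- function() {
    PeptideLibrary(data.frame(
        sequence = c("MAKTIK", "VAVIKAVR", "LSYDTEASIAKAK", "GGAKLR",
                     "PPWKTR", "AAKGGR"),
        group_id = c("g1", "g2", "g4", "g1", "g3", "g3"),
        protein_id = c("P1", "P2", "P2", "P1", "P3", "P4"),
        start_pos = c(1L, 10L, 25L, 40L, 7L, 90L),
        site_pos = c(3L, 5L, 11L, 4L, 4L, 3L),
        chemistry = "lysine"), libraryId = "tiny")
}

## A bare canonical record row; override any field via ...
recRow <- function(seq_a, seq_b, score = 100, ...) {
    row <- list(seq_a = seq_a, seq_b = seq_b, site_a = 1L, site_b = 1L,
                protein_a = "P1", protein_b = "P1", pos_a = 1L, pos_b = 1L,
                score = score, is_decoy = FALSE, link_type = "crosslink",
                engine = "test", replicate = "r1",
                spectrum_ref = NA_character_)
    extra <- list(...)
    row[names(extra)] <- extra
    as.data.frame(row, stringsAsFactors = FALSE)
}

recSet <- function(..., level = "csm") {
    CrosslinkSet(do.call(rbind, list(...)), level = level)
}

## Random record set over a library: true, cross-group, non-library and
## homeotypic pairs in random proportions, library-derived sites and
## positions. Relies on the caller's RNG state.
randomRecords <- function(lib, n, level = "unique_link") {
    pep <- peptides(lib)
    rows <- lapply(seq_len(n), function(k) {
        if (stats::runif(1) < 0.15) {   # non-library side
            fake <- paste(sample(c("A", "G", "S", "T", "V"), 7,
                                 replace = TRUE), collapse = "")
            i <- sample.int(nrow(pep), 1)
            recRow(fake, pep$sequence[i], score = stats::rnorm(1, 80, 30),
                   site_a = 2L, site_b = pep$site_pos[i],
                   protein_a = "FAKE", protein_b = pep$protein_id[i],
                   pos_a = 1L, pos_b = pep$start_pos[i])
        } else {
            ij <- sample.int(nrow(pep), 2, replace = TRUE)
            recRow(pep$sequence[ij[1]], pep$sequence[ij[2]],
                   score = stats::rnorm(1, 120, 40),
                   site_a = pep$site_pos[ij[1]], site_b = pep$site_pos[ij[2]],
                   protein_a = pep$protein_id[ij[1]],
                   protein_b = pep$protein_id[ij[2]],
                   pos_a = pep$start_pos[ij[1]], pos_b = pep$start_pos[ij[2]])
        }
    })
    out <- do.call(rbind, rows)
    if (level == "unique_link") out$n_csms <- 1L
    CrosslinkSet(out, level = level)
}

## -- oracles ----------------------------------------------------------

## truth of one pair, by direct lookup
bfTruth <- function(sa, sb, pep) {
    ga <- pep$group_id[pep$sequence == sa]
    gb <- pep$group_id[pep$sequence == sb]
    if (length(ga) == 0 || length(gb) == 0) "non_library_false"
    else if (ga != gb) "cross_group_false"
    else "within_group_true"
}

bfFdr <- function(rec, pep) {
    if (nrow(rec) == 0) return(0)
    bad <- 0
    for (r in seq_len(nrow(rec)))
        if (bfTruth(rec$seq_a[r], rec$seq_b[r], pep) != "within_group_true")
            bad <- bad + 1
    bad / nrow(rec)
}

bfCurve <- function(rec, pep) {
    thr <- sort(unique(rec$score), decreasing = TRUE)
    out <- data.frame(threshold = thr, n_retained = NA_integer_,
                      fdr = NA_real_)
    for (k in seq_along(thr)) {
        keep <- rec[rec$score >= thr[k], , drop = FALSE]
        out$n_retained[k] <- nrow(keep)
        out$fdr[k] <- bfFdr(keep, pep)
    }
    out
}

bfCutoff <- function(rec, pep, target) {
    cur <- bfCurve(rec, pep)
    ok <- cur[cur$fdr <= target, , drop = FALSE]
    if (nrow(ok) == 0) return(NULL)
    ok[which.max(ok$n_retained), ]
}

## unordered identity key built independently of makeLinkKey
bfKey <- function(rec) {
    vapply(seq_len(nrow(rec)), function(r) {
        a <- paste(rec$seq_a[r], rec$protein_a[r], rec$pos_a[r], sep = "/")
        b <- paste(rec$seq_b[r], rec$protein_b[r], rec$pos_b[r], sep = "/")
        paste(sort(c(a, b)), collapse = "+")
    }, character(1))
}

bfRegions <- function(keyList) {
    un <- unique(unlist(keyList))
    lab <- names(keyList)
    region <- character(length(un))
    for (k in seq_along(un))
        region[k] <- paste(lab[vapply(keyList, function(ks) un[k] %in% ks,
                                      logical(1))], collapse = "&")
    table(region)
}

bfPpm <- function(seqs, sites, window = 3, includeSite = TRUE) {
    offs <- seq(-window, window)
    if (!includeSite) offs <- offs[offs != 0]
    m <- matrix(0, 20, length(offs),
                dimnames = list(aminoAcids(), as.character(offs)))
    for (r in seq_along(seqs)) {
        if (is.na(sites[r])) next
        res <- strsplit(seqs[r], "")[[1]]
        for (k in seq_along(offs)) {
            p <- sites[r] + offs[k]
            if (p >= 1 && p <= length(res))
                m[res[p], k] <- m[res[p], k] + 1
        }
    }
    supp <- colSums(m)
    for (k in seq_along(supp))
        if (supp[k] > 0) m[, k] <- m[, k] / supp[k]
    storage.mode(supp) <- "integer"
    list(probs = m, support = supp)
}

## Henderson-Hasselbalch net charge, written independently for checking
## the pI bisection (EMBOSS pKa set).
bfNetCharge <- function(sequence, pH) {
    res <- strsplit(sequence, "")[[1]]
    pos <- 1 / (1 + 10^(pH - 8.6)) +
        sum(res == "K") / (1 + 10^(pH - 10.8)) +
        sum(res == "R") / (1 + 10^(pH - 12.5)) +
        sum(res == "H") / (1 + 10^(pH - 6.5))
    neg <- 1 / (1 + 10^(3.6 - pH)) +
        sum(res == "D") / (1 + 10^(3.9 - pH)) +
        sum(res == "E") / (1 + 10^(4.1 - pH)) +
        sum(res == "C") / (1 + 10^(8.5 - pH)) +
        sum(res == "Y") / (1 + 10^(10.1 - pH))
    pos - neg
}
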