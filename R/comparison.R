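## Cross-engine / cross-replicate comparison: a canonical link identity
## shared by all engines, exact overlap regions, and per-region validated
## FDR. Commonly found links concentrate the true positives.

#' Canonical identity key of a crosslink
#'
#' Builds, for every record, a key invariant to the order of the two
#' sides, to the reporting engine, to the score and to modification
#' annotations: each side is \code{sequence|protein|position} (peptide
#' start in the protein, 1-based), the two sides are sorted
#' lexicographically and joined. Engines disagree on residue-site
#' assignment within a peptide, so link-site positions are excluded from
#' the default key; \code{strict = TRUE} appends them for site-resolved
#' comparisons. Records missing protein or position degrade to a
#' sequence-only key with a warning.
#'
#' @param x A [CrosslinkSet()].
#' @param strict Include the within-peptide link sites in the key.
#' @return Character vector of keys, one per record.
#' @export
#' @examples
#' rec <- data.frame(seq_a = "VAVIKAVR", seq_b = "MAKTIK",
#'                   site_a = 5L, site_b = 3L,
#'                   protein_a = "P2", protein_b = "P1",
#'                   pos_a = 10L, pos_b = 1L, score = 100,
#'                   is_decoy = FALSE, link_type = "crosslink",
#'                   engine = "demo", replicate = "r1", spectrum_ref = NA)
#' makeLinkKey(CrosslinkSet(rec))   # same key as the (a, b)-swapped record
makeLinkKey <- function(x, strict = FALSE) {
    stopifnot(is(x, "CrosslinkSet"))
    rec <- records(x)
    if (nrow(rec) == 0L)
        return(character())
    degraded <- is.na(rec$protein_a) | is.na(rec$protein_b) |
        rec$protein_a == "" | rec$protein_b == "" |
        is.na(rec$pos_a) | is.na(rec$pos_b)
    if (any(degraded))
        warning(sum(degraded),
                " record(s) lack protein/position; their keys degrade",
                " to sequence-only", call. = FALSE)
    side <- function(seq, prot, pos, site) {
        s <- paste(seq, prot, pos, sep = "|")
        if (strict) s <- paste(s, site, sep = "|")
        ifelse(degraded, seq, s)
    }
    a <- side(rec$seq_a, rec$protein_a, rec$pos_a, rec$site_a)
    b <- side(rec$seq_b, rec$protein_b, rec$pos_b, rec$site_b)
    ifelse(a <= b, paste(a, b, sep = "--"), paste(b, a, sep = "--"))
}

#' Overlap of crosslink sets with per-region validated FDR
#'
#' Partitions the union of two or more unique-link sets (engines or
#' replicates) into exact membership regions and computes the
#' experimentally validated FDR separately on each region's links.
#' Region labels join member set labels with \code{"&"}
#' (e.g. \code{"annika&merox"} for the intersection of two sets). Links
#' whose sequences and positions match between sets while their protein
#' accessions disagree indicate an ambiguous protein mapping; these are
#' reported with a warning rather than silently merged.
#'
#' @param sets Named list of 2 or more [CrosslinkSet()]s at
#'   \code{unique_link} level.
#' @param library A [PeptideLibrary()].
#' @param strict Passed to [makeLinkKey()].
#' @return An \linkS4class{OverlapResult}.
#' @export
computeOverlap <- function(sets, library, strict = FALSE) {
    stopifnot(is.list(sets), length(sets) >= 2L)
    if (is.null(names(sets)) || any(!nzchar(names(sets))))
        names(sets) <- paste0("set", seq_along(sets))
    labels <- names(sets)
    for (s in sets) {
        stopifnot(is(s, "CrosslinkSet"))
        if (recordLevel(s) != "unique_link")
            stop("overlap requires unique_link level sets; run ",
                 "groupToUniqueLinks() first", call. = FALSE)
    }
    keys <- lapply(sets, makeLinkKey, strict = strict)
    allKeys <- unique(unlist(keys, use.names = FALSE))
    membership <- vapply(keys, function(k) allKeys %in% k,
                         logical(length(allKeys)))
    if (length(allKeys) == 1L)
        membership <- matrix(membership, nrow = 1,
                             dimnames = list(NULL, labels))
    regionOf <- apply(membership, 1L, function(m)
        paste(labels[m], collapse = "&"))
    ## every non-empty label combination is a region, even when empty
    combos <- unlist(lapply(seq_along(labels), function(k)
        utils::combn(labels, k, paste, collapse = "&", simplify = FALSE)))
    regions <- lapply(combos, function(r) allKeys[regionOf == r])
    names(regions) <- combos
    ## one representative record per key, for per-region FDR
    recAll <- do.call(rbind, lapply(sets, records))
    keyAll <- unlist(keys, use.names = FALSE)
    rep1 <- recAll[!duplicated(keyAll), , drop = FALSE]
    key1 <- keyAll[!duplicated(keyAll)]
    .warnProteinConflicts(rep1)
    regionFdr <- vapply(regions, function(k) {
        if (length(k) == 0L) return(NA_real_)
        sub <- rep1[key1 %in% k, , drop = FALSE]
        suppressWarnings(
            fdrValue(validatedFdr(CrosslinkSet(sub, "unique_link"), library)))
    }, numeric(1))
    new("OverlapResult", setLabels = labels, regions = regions,
        counts = vapply(regions, length, integer(1)),
        regionFdr = regionFdr)
}

## Same unordered sequence+position pair reported with different protein
## accessions: ambiguous mapping, worth surfacing.
.warnProteinConflicts <- function(rec) {
    if (nrow(rec) < 2L) return(invisible())
    sideSeqPos <- function(seq, pos) paste(seq, pos, sep = "|")
    a <- sideSeqPos(rec$seq_a, rec$pos_a)
    b <- sideSeqPos(rec$seq_b, rec$pos_b)
    loose <- ifelse(a <= b, paste(a, b, sep = "--"), paste(b, a, sep = "--"))
    prot <- ifelse(rec$protein_a <= rec$protein_b,
                   paste(rec$protein_a, rec$protein_b, sep = "--"),
                   paste(rec$protein_b, rec$protein_a, sep = "--"))
    byKey <- split(prot, loose)
    conflict <- names(byKey)[vapply(byKey, function(p)
        length(unique(p)) > 1L, logical(1))]
    if (length(conflict))
        warning("protein accession conflict for ", length(conflict),
                " link(s) with matching sequence/position; not merged",
                call. = FALSE)
    invisible()
}

#' Venn diagram of 2-3 crosslink sets
#'
#' Proportional placement is not attempted; circles are drawn in a fixed
#' layout with region counts printed at the standard positions.
#'
#' @param overlap An \linkS4class{OverlapResult} over 2 or 3 sets.
#' @param file Optional PNG path.
#' @param main Plot title.
#' @return Invisibly, \code{file}.
#' @export
plotVenn <- function(overlap, file = NULL, main = "Crosslink overlap") {
    stopifnot(is(overlap, "OverlapResult"))
    labels <- overlap@setLabels
    k <- length(labels)
    if (k > 3L)
        stop("Venn rendering supports at most 3 sets; use regionCounts() ",
             "for more", call. = FALSE)
    if (!is.null(file)) {
        grDevices::png(file, width = 800, height = 800, res = 120)
        on.exit(grDevices::dev.off())
    }
    graphics::plot.new()
    graphics::plot.window(c(0, 10), c(0, 10), asp = 1)
    graphics::title(main)
    circ <- function(cx, cy, r, col) graphics::symbols(
        cx, cy, circles = r, add = TRUE, inches = FALSE,
        fg = col, bg = grDevices::adjustcolor(col, 0.25))
    cols <- c("#1b9e77", "#d95f02", "#7570b3")
    cnt <- overlap@counts
    fdrTxt <- function(r) {
        f <- overlap@regionFdr[[r]]
        if (is.na(f)) "" else paste0("\n", formatFdrPercent(f))
    }
    lab <- function(x, y, r) graphics::text(
        x, y, paste0(cnt[[r]], fdrTxt(r)), cex = 0.9)
    if (k == 2L) {
        circ(4, 5, 2.5, cols[1]); circ(6, 5, 2.5, cols[2])
        graphics::text(c(4, 6), 8, labels)
        lab(2.8, 5, labels[1]); lab(7.2, 5, labels[2])
        lab(5, 5, paste(labels, collapse = "&"))
    } else {
        circ(4, 6, 2.3, cols[1]); circ(6, 6, 2.3, cols[2])
        circ(5, 4.2, 2.3, cols[3])
        graphics::text(c(3, 7, 5), c(8.7, 8.7, 1.5), labels)
        lab(3, 6.6, labels[1]); lab(7, 6.6, labels[2]); lab(5, 3, labels[3])
        lab(5, 7, paste(labels[1:2], collapse = "&"))
        lab(3.8, 4.8, paste(labels[c(1, 3)], collapse = "&"))
        lab(6.2, 4.8, paste(labels[2:3], collapse = "&"))
        lab(5, 5.4, paste(labels, collapse = "&"))
    }
    invisible(file)
}
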