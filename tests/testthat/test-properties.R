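test_that("linearization concatenates in canonical order and preserves residues", {
    expect_equal(linearizePair("KA", "GR")@sequence, "GRKA")
    expect_equal(linearizePair("PK", "PK")@sequence, "PKPK")
    set.seed(15)
    for (trial in 1:20) {
        a <- paste(sample(aminoAcids(), sample(3:12, 1), replace = TRUE),
                   collapse = "")
        b <- paste(sample(aminoAcids(), sample(3:12, 1), replace = TRUE),
                   collapse = "")
        xl <- linearizePair(a, b)
        expect_equal(sort(strsplit(xl@sequence, "")[[1]]),
                     sort(strsplit(paste0(a, b), "")[[1]]))
        expect_identical(xl@sequence, linearizePair(b, a)@sequence)
    }
})

test_that("scalar property math matches the published scales", {
    expect_equal(computeProperties("AA")$gravy, 1.8)
    expect_equal(computeProperties("WGGG")$aromaticity, 0.25)
    expect_equal(peptideMass("G"), 75.0320, tolerance = 1e-4)
    p <- computeProperties("ACDEFGHIKLMNPQRSTVWY")
    expect_equal(sum(p$aa_frequencies), 1)
    expect_true(all(p$aa_frequencies == 0.05))
    expect_error(computeProperties("AXB"), "non-standard")
})

test_that("mass is additive under linearization", {
    set.seed(16)
    for (trial in 1:10) {
        a <- paste(sample(aminoAcids(), 8, replace = TRUE), collapse = "")
        b <- paste(sample(aminoAcids(), 5, replace = TRUE), collapse = "")
        extra <- stats::runif(1, 0, 200)
        xl <- linearizePair(a, b, massExtra = extra)
        expect_equal(computeProperties(xl)$molecular_mass,
                     peptideMass(a) + peptideMass(b) + extra,
                     tolerance = 1e-9)
    }
})

test_that("the isoelectric point zeroes the independent net-charge model", {
    for (s in c("GGKGG", "DDEE", "ACDEFGHIKLMNPQRSTVWY", "KKRRHH")) {
        pI <- isoelectricPoint(s)
        expect_lt(abs(bfNetCharge(s, pI)), 0.05)
        ## charge is positive just below and negative just above the pI
        expect_gt(bfNetCharge(s, pI - 0.2), bfNetCharge(s, pI + 0.2))
    }
    expect_gt(isoelectricPoint("GGKGG"), isoelectricPoint("GGDGG"))
})

test_that("observed equals expected when every theoretical crosslink is seen once", {
    lib <- PeptideLibrary(data.frame(
        sequence = c("DG", "DA"), group_id = "g1", protein_id = "P1",
        start_pos = c(1L, 10L), site_pos = 1L, chemistry = "acidic"))
    ## all 3 theoretical pairs (DG-DG, DG-DA, DA-DA), one CSM each
    x <- recSet(recRow("DG", "DG"), recRow("DG", "DA"), recRow("DA", "DA"))
    dc <- distributionComparison(x, lib, mode = "pooled")
    tab <- comparisonTable(dc)
    expect_equal(sum(tab$observed), 1)
    expect_equal(sum(tab$expected), 1)
    expect_equal(tab$observed, tab$expected)
    expect_true(all(tab$ratio[tab$expected > 0] == 1))
    ## the same holds for any simulated library (one CSM per pair)
    lib2 <- generateLibrary(simulationConfig(nPeptides = 12,
                                             groupSizes = c(6, 6),
                                             seed = 6))
    xl <- crosslinks(enumerateTheoretical(lib2, "grouped"))
    rows <- do.call(rbind, lapply(seq_len(nrow(xl)), function(i)
        recRow(xl$seq_a[i], xl$seq_b[i])))
    dc2 <- distributionComparison(CrosslinkSet(rows), lib2, "grouped")
    tab2 <- comparisonTable(dc2)
    expect_equal(tab2$observed, tab2$expected)
})

test_that("a planted depletion shows as a ratio below one and order does not matter", {
    lib <- generateLibrary(simulationConfig(nPeptides = 20, seed = 17))
    xl <- crosslinks(enumerateTheoretical(lib, "grouped"))
    hasH <- grepl("H", paste0(xl$seq_a, xl$seq_b))
    expect_true(any(hasH) && !all(hasH))
    kept <- xl[!hasH, , drop = FALSE]
    rows <- do.call(rbind, lapply(seq_len(nrow(kept)), function(i)
        recRow(kept$seq_a[i], kept$seq_b[i])))
    dc <- distributionComparison(CrosslinkSet(rows), lib, "grouped")
    tab <- comparisonTable(dc)
    expect_equal(tab$ratio[tab$aa == "H"], 0)
    shuffled <- rows[sample.int(nrow(rows)), , drop = FALSE]
    dcs <- distributionComparison(CrosslinkSet(shuffled), lib, "grouped")
    expect_equal(comparisonTable(dcs), tab)
    expect_error(
        distributionComparison(CrosslinkSet(rows[0, , drop = FALSE]),
                               lib, "grouped"),
        "nothing to compare")
})

test_that("PPM columns are one-hot for a single peptide and average over records", {
    ## single peptide GAKWR, site 3: every in-range offset is one-hot
    x <- recSet(recRow("GAKWR", "GAKWR", site_a = 3L, site_b = NA))
    ppm <- ppmAroundSite(x)
    p <- probs(ppm)
    expect_equal(p["G", "-2"], 1)
    expect_equal(p["A", "-1"], 1)
    expect_equal(p["K", "0"], 1)
    expect_equal(p["W", "1"], 1)
    expect_equal(p["R", "2"], 1)
    expect_equal(support(ppm)[["-3"]], 0L)   # beyond the N-terminus
    expect_equal(support(ppm)[["3"]], 0L)
    ## two equal-support sequences differing only at +1
    y <- recSet(recRow("GAKWR", "GAKWR", site_a = 3L, site_b = NA),
                recRow("GAKYR", "GAKYR", site_a = 3L, site_b = NA))
    p2 <- probs(ppmAroundSite(y))
    expect_equal(p2["W", "1"], 0.5)
    expect_equal(p2["Y", "1"], 0.5)
})

test_that("PPMs match brute-force positional counting on random sets", {
    lib <- generateLibrary(simulationConfig(nPeptides = 25, seed = 18))
    set.seed(19)
    for (trial in 1:20) {
        x <- randomRecords(lib, sample(3:40, 1))
        ppm <- ppmAroundSite(x)
        rec <- records(x)
        bf <- bfPpm(c(rec$seq_a, rec$seq_b), c(rec$site_a, rec$site_b))
        expect_equal(probs(ppm), bf$probs)
        expect_equal(support(ppm), bf$support)
        supported <- support(ppm) > 0
        expect_equal(unname(colSums(probs(ppm))[supported]),
                     rep(1, sum(supported)))
        expect_true(all(support(ppm) <= 2 * nrow(rec)))
    }
    noSite <- recSet(recRow("GAKWR", "GAKWR", site_a = NA, site_b = NA))
    expect_error(ppmAroundSite(noSite), "site")
})
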