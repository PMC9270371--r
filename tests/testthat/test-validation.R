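test_that("the 425-link replicate example gives 0.47 % displayed as 0.5 %", {
    cfg <- simulationConfig(nPeptides = 100, nTrue = 423, nCrossGroup = 2,
                            seed = 11)
    lib <- generateLibrary(cfg)
    sim <- generateResults(lib, cfg)
    links <- groupToUniqueLinks(filterTargets(sim$records))
    v <- validatedFdr(links, lib)
    expect_equal(v@nTotal, 425L)
    expect_equal(v@nCrossGroup, 2L)
    expect_equal(fdrValue(v), 2 / 425)
    expect_equal(round(100 * fdrValue(v), 2), 0.47)
    expect_equal(formatFdrPercent(fdrValue(v)), "0.5 %")
})

test_that("all-within-group sets have FDR 0 and empty sets warn", {
    lib <- tinyLib()
    x <- recSet(recRow("MAKTIK", "GGAKLR"), recRow("MAKTIK", "MAKTIK"),
                level = "csm")
    expect_equal(fdrValue(validatedFdr(x, lib)), 0)
    empty <- CrosslinkSet(records(x)[0, , drop = FALSE])
    expect_warning(v <- validatedFdr(empty, lib), "no target")
    expect_equal(fdrValue(v), 0)
    expect_equal(v@nTotal, 0L)
})

test_that("per-class counts sum to the totals and respect protein provenance", {
    lib <- tinyLib()
    x <- recSet(
        recRow("MAKTIK", "MAKTIK"),                       # homeotypic
        recRow("MAKTIK", "GGAKLR"),                       # same protein P1
        recRow("PPWKTR", "AAKGGR", protein_a = "P3",
               protein_b = "P4"),                          # interprotein
        recRow("MAKTIK", "VAVIKAVR", protein_b = "P2"))    # cross-group
    v <- validatedFdr(x, lib)
    pc <- perClass(v)
    expect_equal(sum(pc$n_total), v@nTotal)
    expect_equal(sum(pc$n_cross_group), v@nCrossGroup)
    expect_equal(pc$n_total[pc$link_class == "homeotypic"], 1L)
    expect_equal(pc$n_total[pc$link_class == "intraprotein"], 1L)
    expect_equal(pc$n_total[pc$link_class == "interprotein"], 2L)
})

test_that("validated FDR equals a brute-force recount on random sets", {
    lib <- generateLibrary(simulationConfig(nPeptides = 30, seed = 21))
    set.seed(77)
    for (trial in 1:200) {
        x <- randomRecords(lib, sample(2:80, 1))
        v <- validatedFdr(x, lib)
        expect_equal(fdrValue(v), bfFdr(records(x), peptides(lib)))
        expect_gte(fdrValue(v), 0)
        expect_lte(fdrValue(v), 1)
    }
})

test_that("adding a false record raises the FDR and a true one lowers it", {
    lib <- tinyLib()
    base <- recSet(recRow("MAKTIK", "GGAKLR"),
                   recRow("MAKTIK", "VAVIKAVR", protein_b = "P2"))
    f0 <- fdrValue(validatedFdr(base, lib))
    withCross <- CrosslinkSet(rbind(records(base),
                                    recRow("PPWKTR", "VAVIKAVR",
                                           protein_a = "P3",
                                           protein_b = "P2")))
    expect_gt(fdrValue(validatedFdr(withCross, lib)), f0)
    withTrue <- CrosslinkSet(rbind(records(base),
                                   recRow("GGAKLR", "GGAKLR")))
    expect_lt(fdrValue(validatedFdr(withTrue, lib)), f0)
})

test_that("the score-FDR curve matches a brute-force threshold sweep", {
    lib <- generateLibrary(simulationConfig(nPeptides = 30, seed = 22))
    set.seed(123)
    for (trial in 1:30) {
        x <- randomRecords(lib, sample(2:60, 1))
        cur <- fdrScoreCurve(x, lib)
        bf <- bfCurve(records(x), peptides(lib))
        expect_equal(cur$threshold, bf$threshold)
        expect_equal(cur$n_retained, bf$n_retained)
        expect_equal(cur$fdr, bf$fdr)
        expect_true(all(diff(cur$n_retained) >= 0))
        expect_true(all(diff(cur$threshold) < 0))
    }
    ## degenerate shapes
    one <- recSet(recRow("MAKTIK", "GGAKLR", score = 5))
    cur <- fdrScoreCurve(one, lib <- tinyLib())
    expect_equal(nrow(cur), 1L)
    expect_equal(cur$n_retained, 1L)
    allTrue <- recSet(recRow("MAKTIK", "GGAKLR", score = 3),
                      recRow("MAKTIK", "MAKTIK", score = 2),
                      recRow("GGAKLR", "GGAKLR", score = 1))
    expect_true(all(fdrScoreCurve(allTrue, lib)$fdr == 0))
})

test_that("the cutoff picks the least strict qualifying threshold", {
    lib <- tinyLib()
    x <- recSet(recRow("MAKTIK", "GGAKLR", score = 10),
                recRow("MAKTIK", "MAKTIK", score = 9),
                recRow("GGAKLR", "GGAKLR", score = 8),
                recRow("MAKTIK", "VAVIKAVR", score = 7, protein_b = "P2"))
    co <- applyScoreCutoff(x, lib, 0.01)
    expect_equal(co@threshold, 8)
    expect_equal(co@nRetained, 3L)
    expect_equal(co@achievedFdr, 0)
    ## a set already at the target keeps everything at the minimum score
    ok <- recSet(recRow("MAKTIK", "GGAKLR", score = 4),
                 recRow("MAKTIK", "MAKTIK", score = 2))
    co2 <- applyScoreCutoff(ok, lib, 0.05)
    expect_equal(co2@threshold, 2)
    expect_equal(co2@nRetained, 2L)
    ## all-false input is infeasible: empty retained set
    bad <- recSet(recRow("XXXXXX", "MAKTIK", score = 5))
    co3 <- applyScoreCutoff(bad, lib, 0.5)
    expect_equal(co3@nRetained, 0L)
    expect_equal(nrow(records(retained(co3))), 0L)
})

test_that("cutoffs are optimal under exhaustive sweep and monotone in the target", {
    lib <- generateLibrary(simulationConfig(nPeptides = 30, seed = 23))
    set.seed(321)
    for (trial in 1:40) {
        x <- randomRecords(lib, sample(3:70, 1))
        target <- stats::runif(1, 0.01, 0.6)
        co <- applyScoreCutoff(x, lib, target)
        bf <- bfCutoff(records(x), peptides(lib), target)
        if (is.null(bf)) {
            expect_equal(co@nRetained, 0L)
        } else {
            expect_equal(co@threshold, bf$threshold)
            expect_equal(co@nRetained, bf$n_retained)
            expect_lte(co@achievedFdr, target)
        }
        ## retained counts shrink as the target tightens
        targets <- sort(stats::runif(4, 0.005, 0.8), decreasing = TRUE)
        ns <- vapply(targets, function(t)
            applyScoreCutoff(x, lib, t)@nRetained, integer(1))
        expect_true(all(diff(ns) <= 0))
    }
})

test_that("CSM and link level FDR agree when every link has one CSM", {
    lib <- generateLibrary(simulationConfig(nPeptides = 30, seed = 24))
    set.seed(11)
    x <- randomRecords(lib, 50, level = "csm")
    rec <- records(x)[!duplicated(bfKey(records(x))), , drop = FALSE]
    csm <- CrosslinkSet(rec, "csm")
    link <- groupToUniqueLinks(csm)
    expect_equal(fdrValue(validatedFdr(csm, lib)),
                 fdrValue(validatedFdr(link, lib)))
})
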