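test_that("tryptic digestion strips protection tags and reduces azide-K", {
    expect_identical(
        digestConstruct(SynthesisConstruct("MAKTIK",
                                           nTag = "acetyl-WGGGGR",
                                           azideK = TRUE)),
        "MAKTIK")
    expect_identical(
        digestConstruct(SynthesisConstruct("VAVIKAVR")), "VAVIKAVR")
    expect_identical(
        digestConstruct(SynthesisConstruct("APDLK",
                                           nTag = "acetyl-WGGGGR",
                                           cTag = "GGGG-amide")),
        "APDLK")
    expect_error(SynthesisConstruct("APDLK", nTag = "acetyl-WGGGG"),
                 "K or R")
})

test_that("support files parse into validated libraries", {
    tf <- withr::local_tempfile(fileext = ".csv")
    write.csv(data.frame(sequence = c("MAKTIK", "VAVIKAVR", "GGDLLR"),
                         group = c("g1", "g1", "g2"),
                         protein = c("P1", "P2", "P3"),
                         start = c(1, 10, 4), site = c(3, 5, 3),
                         chemistry = c("lysine", "lysine", "acidic")),
              tf, row.names = FALSE)
    lib <- loadLibrary(tf)
    expect_s4_class(lib, "PeptideLibrary")
    expect_equal(nrow(peptides(lib)), 3L)
    expect_equal(length(unique(peptides(lib)$group_id)), 2L)
})

test_that("schema and consistency violations are reported by name", {
    tf <- withr::local_tempfile(fileext = ".csv")
    write.csv(data.frame(sequence = "MAKTIK", group = "g1",
                         protein = "P1", start = 1),
              tf, row.names = FALSE)
    expect_error(loadLibrary(tf), "site")
    ## two internal lysines violate the single-reactive-residue design
    write.csv(data.frame(sequence = "MAKKTIR", group = "g1",
                         protein = "P1", start = 1, site = 3,
                         chemistry = "lysine"),
              tf, row.names = FALSE)
    expect_error(loadLibrary(tf), "exactly one")
    ## one sequence in two groups breaks the partition
    write.csv(data.frame(sequence = c("MAKTIK", "MAKTIK"),
                         group = c("g1", "g2"), protein = "P1",
                         start = 1, site = 3, chemistry = "lysine"),
              tf, row.names = FALSE)
    expect_error(loadLibrary(tf), "more than one group")
    ## exact duplicates collapse silently
    write.csv(data.frame(sequence = c("MAKTIK", "MAKTIK"),
                         group = "g1", protein = "P1",
                         start = 1, site = 3, chemistry = "lysine"),
              tf, row.names = FALSE)
    expect_equal(nrow(peptides(loadLibrary(tf))), 1L)
})

test_that("generated support files round-trip through loadLibrary", {
    tf <- withr::local_tempfile(fileext = ".csv")
    cfg <- simulationConfig(nPeptides = 100L, seed = 42L)
    lib <- generateLibrary(cfg, supportFile = tf)
    back <- loadLibrary(tf)
    expect_equal(nrow(peptides(back)), 100L)
    expect_identical(
        peptides(back)[order(peptides(back)$sequence), ],
        `rownames<-`(peptides(lib)[order(peptides(lib)$sequence), ],
                     NULL),
        ignore_attr = TRUE)
})

test_that("pooled and grouped enumeration match the closed forms and a brute-force double loop", {
    set.seed(5)
    for (trial in 1:6) {
        n <- sample(1:50, 1)
        cfg <- simulationConfig(nPeptides = n,
                                groupSizes = NULL, seed = trial)
        lib <- generateLibrary(cfg)
        pooled <- enumerateTheoretical(lib, "pooled")
        expect_equal(nrow(crosslinks(pooled)), n * (n + 1) / 2)
        grouped <- enumerateTheoretical(lib, "grouped")
        sizes <- table(peptides(lib)$group_id)
        expect_equal(nrow(crosslinks(grouped)),
                     sum(sizes * (sizes + 1) / 2))
        ## brute-force double loop over all peptide pairs
        pep <- peptides(lib)
        cntPooled <- 0L; cntGrouped <- 0L
        for (i in seq_len(n)) for (j in i:n) {
            cntPooled <- cntPooled + 1L
            if (pep$group_id[i] == pep$group_id[j])
                cntGrouped <- cntGrouped + 1L
        }
        expect_equal(nrow(crosslinks(pooled)), cntPooled)
        expect_equal(nrow(crosslinks(grouped)), cntGrouped)
    }
})

test_that("a single peptide yields exactly its homeotypic self-pair", {
    lib <- PeptideLibrary(data.frame(
        sequence = "MAKTIK", group_id = "g1", protein_id = "P1",
        start_pos = 1L, site_pos = 3L, chemistry = "lysine"))
    sp <- enumerateTheoretical(lib, "pooled")
    expect_equal(nrow(crosslinks(sp)), 1L)
    expect_equal(unname(classCounts(sp)["homeotypic"]), 1L)
})

test_that("grouped enumeration of group sizes {2, 3} gives 3 + 6 pairs", {
    lib <- PeptideLibrary(data.frame(
        sequence = c("MAKTIK", "GGAKLR", "VAVIKAVR", "PPWKTR", "AAKGGR"),
        group_id = c("a", "a", "b", "b", "b"),
        protein_id = paste0("P", 1:5),
        start_pos = 1L, site_pos = c(3L, 4L, 5L, 4L, 3L),
        chemistry = "lysine"))
    expect_equal(nrow(crosslinks(enumerateTheoretical(lib, "grouped"))), 9L)
})

test_that("link classes partition every theoretical space", {
    lib <- generateLibrary(simulationConfig(nPeptides = 40, seed = 9))
    for (mode in c("grouped", "pooled")) {
        sp <- enumerateTheoretical(lib, mode)
        expect_equal(sum(classCounts(sp)), nrow(crosslinks(sp)))
        expect_setequal(unique(crosslinks(sp)$link_class),
                        names(classCounts(sp))[classCounts(sp) > 0])
    }
})

test_that("grouped-mode crosslinks are all same-group and within-group-true", {
    lib <- generateLibrary(simulationConfig(nPeptides = 30, seed = 2))
    xl <- crosslinks(enumerateTheoretical(lib, "grouped"))
    expect_true(all(xl$same_group))
    cls <- classifyPair(xl$seq_a, xl$seq_b, lib)
    expect_true(all(cls$truth == "within_group_true"))
})

test_that("pair classification matches the library worked cases and is symmetric", {
    lib <- tinyLib()
    ## homeotypic link of a sequence absent from the library (isobaric
    ## permutation of a library peptide) is a non-library false positive
    expect_equal(classifyPair("MAKLTK", "MAKLTK", lib)$truth,
                 "non_library_false")
    expect_equal(classifyPair("LSYDTEASIAKAK", "VAVIKAVR", lib)$truth,
                 "cross_group_false")   # both synthesized, groups differ
    expect_equal(classifyPair("MAKTIK", "VAVIKAVR", lib)$truth,
                 "cross_group_false")
    for (p in peptides(lib)$sequence) {
        cls <- classifyPair(p, p, lib)
        expect_equal(cls$truth, "within_group_true")
        expect_equal(cls$link_class, "homeotypic")
    }
    ## symmetry over random argument pairs
    set.seed(31)
    pool <- c(peptides(lib)$sequence, "AAAAAA", "MAKLTK")
    for (k in 1:25) {
        ab <- sample(pool, 2, replace = TRUE)
        expect_identical(classifyPair(ab[1], ab[2], lib),
                         classifyPair(ab[2], ab[1], lib))
    }
})

test_that("near-isobaric diagnostics flag permuted sequences", {
    lib <- PeptideLibrary(data.frame(
        sequence = c("MAKTIK", "MAKITK", "GGAKLR"),
        group_id = c("g1", "g2", "g3"),
        protein_id = c("P1", "P2", "P3"),
        start_pos = 1L, site_pos = c(3L, 3L, 4L), chemistry = "lysine"))
    hits <- nearIsobaricPairs(lib)
    expect_equal(nrow(hits), 1L)
    expect_setequal(c(hits$seq_a, hits$seq_b), c("MAKTIK", "MAKITK"))
})
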