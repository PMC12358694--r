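test_that("relative abundances normalize counts and keep zero taxa", {
    expect_equal(relativeAbundances(c(2, 2)), c(0.5, 0.5))
    expect_equal(relativeAbundances(c(8, 2, 0)), c(0.8, 0.2, 0.0))
    expect_error(relativeAbundances(c(0, 0)), "empty community")
    expect_error(relativeAbundances(c(-1, 2)), "non-negative")
})

test_that("Hill numbers match hand values and reject bad orders", {
    expect_equal(hillNumber(rep(0.25, 4), q = 2), 4.0)
    expect_equal(hillNumber(c(0.5, 0.5), q = 1), 2.0)
    # (0.8, 0.2) at q = 2: 1 / (0.64 + 0.04)
    expect_equal(hillNumber(c(0.8, 0.2), q = 2), 1 / 0.68,
                 tolerance = 1e-12)
    expect_error(hillNumber(c(0.5, 0.5), q = -1), "non-negative")
    expect_error(hillNumber(c(0.6, 0.6), q = 0), "sum to 1")
})

test_that("Hill closed forms agree with independent formulas and vegan", {
    skip_if_not_installed("vegan")
    set.seed(42)
    for (i in 1:200) {
        p <- randomSimplex(sample(3:40, 1))
        expect_equal(hillNumber(p, 0), sum(p > 0))
        expect_equal(hillNumber(p, 1), exp(-sum(p * log(p))),
                     tolerance = 1e-12)
        expect_equal(hillNumber(p, 2), 1 / sum(p^2), tolerance = 1e-12)
        # independent package oracle
        expect_equal(hillNumber(p, 1),
                     exp(vegan::diversity(p, "shannon")),
                     tolerance = 1e-10)
        expect_equal(hillNumber(p, 2),
                     vegan::diversity(p, "invsimpson"),
                     tolerance = 1e-10)
    }
})

test_that("Hill number is non-increasing in q and invariant to zeros and
           taxon order", {
    set.seed(7)
    qGrid <- seq(0, 3, by = 0.25)
    for (i in 1:50) {
        p <- randomSimplex(sample(3:25, 1))
        d <- vapply(qGrid, function(q) hillNumber(p, q), numeric(1))
        expect_true(all(diff(d) <= 1e-10))
        perm <- sample(length(p))
        padded <- c(p, rep(0, 5))
        for (q in c(0, 1, 2.5)) {
            expect_equal(hillNumber(p[perm], q), hillNumber(p, q))
            expect_equal(hillNumber(padded, q), hillNumber(p, q))
        }
    }
})

test_that("pooled diversity sums raw counts before normalizing", {
    m <- matrix(c(1L, 0L, 0L, 1L), nrow = 2, byrow = TRUE,
                dimnames = list(c("s1", "s2"), c("a", "b")))
    ct <- CommunityTable(m)
    expect_equal(pooledDiversity(ct, 1:2, q = 0), 2)

    ident <- identicalTable(2, c(3L, 1L))
    expect_equal(pooledDiversity(ident, 1:2, q = 0), 2)

    m2 <- matrix(c(3L, 1L, 1L, 3L), nrow = 2, byrow = TRUE,
                 dimnames = list(c("s1", "s2"), c("a", "b")))
    ct2 <- CommunityTable(m2)
    expect_equal(pooledDiversity(ct2, 1:2, q = 2), 2.0)  # pooled (4, 4)
    expect_error(pooledDiversity(ct2, integer(), q = 0), "non-empty")
})

test_that("accumulation curves pool prefixes of the ordering", {
    one <- CommunityTable(matrix(c(1L, 1L, 1L), nrow = 1,
                                 dimnames = list("s1", c("a", "b", "c"))))
    cv <- accumulationCurve(one, 1, q = 0)
    expect_equal(cv@diversities, 3)

    m <- matrix(0L, 2, 5, dimnames = list(c("s1", "s2"), letters[1:5]))
    m[1, 1:3] <- 1L; m[2, 4:5] <- 1L
    cv2 <- accumulationCurve(CommunityTable(m), 1:2, q = 0)
    expect_equal(cv2@diversities, c(3, 5))

    ident <- identicalTable(5)
    for (q in c(0, 1, 2)) {
        cvq <- accumulationCurve(ident, 1:5, q)
        expect_equal(cvq@diversities, rep(cvq@diversities[1], 5))
    }
    expect_error(accumulationCurve(ident, c(1, 1, 2), q = 0),
                 "permutation")
})

test_that("richness accumulation is monotone and the endpoint order-free", {
    cfg <- syntheticConfig(nSamples = 10, poolSize = 100,
                           readsPerSample = 300)
    ct <- generateCohort(cfg, seed = 11)
    set.seed(3)
    ends <- vapply(1:5, function(i) {
        cv <- accumulationCurve(ct, sample(10), q = 0)
        expect_true(all(diff(cv@diversities) >= 0))
        cv@diversities[10]
    }, numeric(1))
    expect_equal(ends, rep(ends[1], 5))
    # endpoint holds at q > 0 too: pooled community is order-free
    e1 <- accumulationCurve(ct, 1:10, q = 2)@diversities[10]
    e2 <- accumulationCurve(ct, 10:1, q = 2)@diversities[10]
    expect_equal(e1, e2, tolerance = 1e-12)
})

test_that("CommunityTable validates counts and drops empty samples", {
    m <- matrix(c(1L, 2L, 0L, 0L, 3L, 1L), nrow = 3, byrow = TRUE,
                dimnames = list(paste0("s", 1:3), c("a", "b")))
    expect_warning(ct <- CommunityTable(m), "zero-read")
    expect_equal(sampleIDs(ct), c("s1", "s3"))

    dup <- m[c(1, 1, 3), ]
    expect_error(CommunityTable(dup), "duplicated sample")
    expect_error(CommunityTable(matrix(-1, 1, 1)), "non-negative")
    expect_error(CommunityTable(matrix(1.5, 1, 1)), "whole numbers")
})

test_that("TSV count tables and metadata round-trip", {
    ct <- generateCohort(syntheticConfig(nSamples = 6, poolSize = 30,
                                         readsPerSample = 200), seed = 2)
    sampleGroups(ct) <- rep(c("NT", "PT"), 3)
    tsv <- tempfile(fileext = ".tsv")
    meta <- tempfile(fileext = ".tsv")
    writeCountTable(ct, tsv)
    writeSampleMetadata(ct, meta)
    back <- readCountTable(tsv, metadata = meta)
    expect_equal(counts(back), counts(ct))
    expect_equal(sampleGroups(back), sampleGroups(ct))

    # transposed orientation is explicit, never guessed
    m <- t(counts(ct))  # samples x taxa
    tf <- tempfile(fileext = ".tsv")
    utils::write.table(
        data.frame(taxon_id = colnames(m), t(m), check.names = FALSE),
        tf, sep = "\t", quote = FALSE, row.names = FALSE)
    back2 <- readCountTable(tf, transpose = TRUE)
    expect_equal(unname(counts(back2)), unname(counts(ct)))
})

test_that("BIOM tables read through biomformat", {
    skip_if_not_installed("biomformat")
    ct <- generateCohort(syntheticConfig(nSamples = 4, poolSize = 12,
                                         readsPerSample = 100), seed = 3)
    bf <- tempfile(fileext = ".biom")
    biomformat::write_biom(biomformat::make_biom(counts(ct)), bf)
    back <- readBiomTable(bf)
    expect_equal(unname(counts(back)), unname(counts(ct)))
})

test_that("merging tables unions taxa and keeps annotations", {
    a <- CommunityTable(matrix(c(1L, 2L), 1,
                               dimnames = list("a1", c("t1", "t2"))),
                        groups = "A")
    b <- CommunityTable(matrix(c(3L, 4L), 1,
                               dimnames = list("b1", c("t2", "t3"))),
                        groups = "B")
    m <- mergeCommunityTables(a, b)
    expect_setequal(taxonIDs(m), c("t1", "t2", "t3"))
    expect_equal(unname(counts(m)["t2", ]), c(2, 3))
    expect_equal(unname(sampleGroups(m)), c("A", "B"))
    expect_error(mergeCommunityTables(a, a), "collide")
})
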