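test_that("pairwise diversity overlap has the analytic endpoints", {
    expect_identical(pdoFromZ(1), 0)
    expect_identical(pdoFromZ(0), 1)
    expect_equal(pdoFromZ(0.463), 2 - 2^0.463, tolerance = 1e-12)
    expect_warning(pdoFromZ(1.4), "outside")
})

test_that("overlap is strictly decreasing in z and maps [0,1] onto
           [0,1]", {
    z <- seq(0, 1, by = 0.01)
    g <- pdoFromZ(z)
    expect_true(all(diff(g) < 0))
    expect_true(all(g >= 0 & g <= 1))
})

test_that("A_max is -z/d and requires a negative taper-off", {
    expect_equal(aMax(0.5, -0.001), 500)
    expect_equal(aMax(0.45, -0.003), 150)
    expect_error(aMax(0.5, 0), "no interior maximum")
    expect_error(aMax(-0.1, -0.01), "positive")
})

test_that("D_max matches the numeric maximum of the PLEC curve", {
    expect_equal(dMax(c = 5, z = 0, d = -0.2), 5)
    # grid oracle for the hand example
    A <- seq(0.01, 5000, by = 0.01)
    gridMax <- max(10 * A^0.5 * exp(-0.001 * A))
    expect_equal(dMax(10, 0.5, -0.001), gridMax, tolerance = 1e-5)
    expect_equal(dMax(10, 0.5, -0.001), 135.62, tolerance = 0.01)
    expect_error(dMax(10, 0.5, 0.001), "negative")

    set.seed(12)
    for (i in 1:20) {
        cc <- runif(1, 0.5, 50)
        z <- runif(1, 0.05, 1)
        d <- -runif(1, 1e-4, 0.05)
        opt <- stats::optimize(function(a) cc * a^z * exp(d * a),
                               c(1e-6, 10 * (-z / d)), maximum = TRUE)
        expect_equal(dMax(cc, z, d), opt$objective, tolerance = 1e-6)
        # evaluating the curve at A_max reproduces D_max analytically
        am <- aMax(z, d)
        expect_equal(cc * am^z * exp(d * am), dMax(cc, z, d),
                     tolerance = 1e-9)
    }
})

test_that("LGD is the local-to-global percentage", {
    expect_equal(lgd(10, 100), 10)
    expect_equal(lgd(55, 55), 100)
    expect_equal(lgd(37.864, 606), 100 * 37.864 / 606)
    expect_error(lgd(10, 0), "positive")
})

test_that("profiles over a disjoint cohort show no overlap at q = 0", {
    tab <- disjointTable(10, 4)
    ps <- buildProfiles(tab, qGrid = 0, nPermutations = 20, seed = 3)
    tab0 <- profileTable(ps)
    expect_equal(tab0$pl_z, 1, tolerance = 1e-9)
    expect_equal(tab0$g, 0, tolerance = 1e-9)
    expect_equal(tab0$pl_N, 20L)
})

test_that("identical-sample cohorts leave profile cells missing", {
    ident <- identicalTable(8)
    ps <- suppressWarnings(buildProfiles(ident, qGrid = 0,
                                         nPermutations = 5, seed = 1))
    tab <- profileTable(ps)
    expect_true(is.na(tab$g))
    expect_true(is.na(tab$D_max))
    expect_equal(tab$pl_N, 0L)
})

test_that("profile construction is deterministic under a seed", {
    ct <- generateCohort(syntheticConfig(nSamples = 12, poolSize = 200,
                                         readsPerSample = 800), seed = 6)
    p1 <- buildProfiles(ct, qGrid = c(0, 2), nPermutations = 15, seed = 9)
    p2 <- buildProfiles(ct, qGrid = c(0, 2), nPermutations = 15, seed = 9)
    expect_identical(profileTable(p1), profileTable(p2))
    expect_error(buildProfiles(ct, qGrid = numeric()), "non-empty")
})

test_that("the scaling exponent declines with diversity order on
           synthetic cohorts (seed-averaged trend)", {
    zByQ <- sapply(1:4, function(s) {
        ct <- generateCohort(syntheticConfig(nSamples = 15,
                                             poolSize = 300,
                                             readsPerSample = 1000),
                             seed = 20 + s)
        vapply(c(0, 1, 2), function(q)
            permutedFit(ct, q = q, model = "PL", nPermutations = 20,
                        seed = 50 + s)@meanZ, numeric(1))
    })
    avg <- rowMeans(zByQ)
    expect_true(all(diff(avg) < 0))
})
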