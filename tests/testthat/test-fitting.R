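test_that("exact power-law curves are recovered to machine precision", {
    fit <- fitPL(generateExactPowerCurve(c = 3, z = 0.5, nAreas = 20))
    expect_equal(fit@z, 0.5, tolerance = 1e-9)
    expect_equal(fit@c, 3, tolerance = 1e-9)
    expect_equal(fit@R, 1, tolerance = 1e-9)
    expect_false(isDegenerate(fit))

    fit2 <- fitPLEC(generateExactPowerCurve(c = 2, z = 0.6, nAreas = 30,
                                            d = -0.01))
    expect_equal(unname(coef(fit2)), c(0.6, 2, -0.01), tolerance = 1e-9)
    expect_equal(fit2@R, 1, tolerance = 1e-9)
})

test_that("PLEC nests PL: d vanishes on a pure power law", {
    cv <- generateExactPowerCurve(c = 3, z = 0.5, nAreas = 20)
    plec <- fitPLEC(cv)
    pl <- fitPL(cv)
    expect_equal(plec@d, 0, tolerance = 1e-9)
    expect_equal(plec@z, pl@z, tolerance = 1e-9)
    expect_equal(plec@c, pl@c, tolerance = 1e-9)
})

test_that("PLEC residual sum of squares never exceeds PL's", {
    set.seed(9)
    for (i in 1:20) {
        A <- seq_len(sample(8:30, 1))
        D <- runif(1, 1, 5) * A^runif(1, 0.1, 0.9) *
            exp(rnorm(length(A), sd = 0.1))
        cv <- new("AccumulationCurve", q = NA_real_,
                  areas = A, diversities = D, ordering = A)
        expect_lte(fitRSS(fitPLEC(cv), cv), fitRSS(fitPL(cv), cv) + 1e-10)
    }
})

test_that("flat curves yield a degenerate flag, not an error", {
    cv <- new("AccumulationCurve", q = 0, areas = 1:10,
              diversities = rep(7, 10), ordering = 1:10)
    fit <- fitPL(cv)
    expect_true(isDegenerate(fit))
    expect_equal(fit@z, 0)
    expect_true(is.na(fit@R))
    expect_true(isDegenerate(fitPLEC(cv)))
})

test_that("too few points is an error", {
    short <- new("AccumulationCurve", q = 0, areas = 1:2,
                 diversities = c(1, 2), ordering = 1:2)
    expect_error(fitPL(short), "at least 3")
    three <- new("AccumulationCurve", q = 0, areas = 1:3,
                 diversities = c(1, 2, 3), ordering = 1:3)
    expect_error(fitPLEC(three), "at least 4")
})

test_that("coefficients match an independent normal-equations oracle", {
    A <- 1:20
    eps <- 0.02 * sin(A)  # fixed perturbation sequence
    D <- 3 * A^0.5 * (1 + eps)
    cv <- new("AccumulationCurve", q = NA_real_, areas = A,
              diversities = D, ordering = A)

    beta <- normalEquationsFit(A, D, plec = FALSE)
    fit <- fitPL(cv)
    expect_equal(fit@z, beta[2], tolerance = 1e-8)
    expect_equal(fit@c, exp(beta[1]), tolerance = 1e-8)

    D2 <- 2 * A^0.6 * exp(-0.02 * A) * (1 + eps)
    cv2 <- new("AccumulationCurve", q = NA_real_, areas = A,
               diversities = D2, ordering = A)
    beta2 <- normalEquationsFit(A, D2, plec = TRUE)
    fit2 <- fitPLEC(cv2)
    expect_equal(fit2@z, beta2[2], tolerance = 1e-8)
    expect_equal(fit2@c, exp(beta2[1]), tolerance = 1e-8)
    expect_equal(fit2@d, beta2[3], tolerance = 1e-8)
})

test_that("permuted fitting counts identical-sample cohorts as failures", {
    ident <- identicalTable(10)
    expect_warning(s <- permutedFit(ident, q = 0, model = "PL",
                                    nPermutations = 10, seed = 1),
                   "no successful")
    expect_equal(s@N, 0L)
    expect_true(is.na(s@meanZ))
})

test_that("disjoint equal-richness cohorts give z = 1, c = k for every
           ordering", {
    k <- 4L
    tab <- disjointTable(10, k)
    s <- permutedFit(tab, q = 0, model = "PL", nPermutations = 25,
                     seed = 5)
    expect_equal(s@N, 25L)
    expect_equal(s@meanZ, 1, tolerance = 1e-9)
    expect_equal(s@meanC, k, tolerance = 1e-9)
    # permutation-symmetric table: zero variance across orderings
    expect_lt(stats::sd(permutationFits(s)$z), 1e-12)
})

test_that("permuted fitting is reproducible under a seed and leaves the
           caller's RNG untouched", {
    ct <- generateCohort(syntheticConfig(nSamples = 12, poolSize = 150,
                                         readsPerSample = 500), seed = 4)
    set.seed(123)
    before <- rnorm(1)
    set.seed(123)
    s1 <- permutedFit(ct, q = 1, model = "PLEC", nPermutations = 15,
                      seed = 42)
    after <- rnorm(1)
    s2 <- permutedFit(ct, q = 1, model = "PLEC", nPermutations = 15,
                      seed = 42)
    expect_identical(permutationFits(s1), permutationFits(s2))
    expect_identical(s1@meanZ, s2@meanZ)
    expect_identical(before, after)
})

test_that("more permutations shrink the spread of the averaged exponent", {
    ct <- generateCohort(syntheticConfig(nSamples = 15, poolSize = 300,
                                         readsPerSample = 1000), seed = 8)
    zAt <- function(np, seed) {
        permutedFit(ct, q = 0, model = "PL", nPermutations = np,
                    seed = seed)@meanZ
    }
    z10 <- vapply(1:15, function(s) zAt(10, s), numeric(1))
    z100 <- vapply(1:15, function(s) zAt(100, 100 + s), numeric(1))
    expect_lt(stats::sd(z100), stats::sd(z10))
})

test_that("fewer than four samples is an error", {
    tab <- disjointTable(3, 2)
    expect_error(permutedFit(tab, q = 0, model = "PL"), "at least 4")
})
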