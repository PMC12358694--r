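# Small deterministic community fixtures built in code.

# n samples with pairwise-disjoint supports of k taxa each; richness
# accumulates exactly linearly, so the q = 0 curve is D(A) = k * A.
disjointTable <- function(n, k, count = 1L) {
    m <- matrix(0L, nrow = n, ncol = n * k,
                dimnames = list(paste0("s", seq_len(n)),
                                paste0("t", seq_len(n * k))))
    for (i in seq_len(n))
        m[i, (i - 1L) * k + seq_len(k)] <- count
    CommunityTable(m)
}

# n copies of the same count vector; every accumulation curve is constant.
identicalTable <- function(n, counts = c(5L, 3L, 2L)) {
    m <- matrix(rep(counts, each = n), nrow = n,
                dimnames = list(paste0("s", seq_len(n)),
                                paste0("t", seq_along(counts))))
    CommunityTable(m)
}

# Random point on the simplex (relative-abundance vector).
randomSimplex <- function(s) {
    x <- stats::rexp(s)
    x / sum(x)
}

# Independent normal-equations OLS oracle: beta = (X'X)^-1 X'y.
normalEquationsFit <- function(areas, diversities, plec = FALSE) {
    y <- log(diversities)
    X <- if (plec) cbind(1, log(areas), areas) else cbind(1, log(areas))
    unname(drop(solve(t(X) %*% X, t(X) %*% y)))
}

# Residual sum of squares of a DarFit on its own curve, from the fitted
# coefficients (not the fitting internals).
fitRSS <- function(fit, curve) {
    A <- curve@areas
    pred <- log(fit@c) + fit@z * log(A) +
        (if (fit@model == "PLEC") fit@d * A else 0)
    sum((log(curve@diversities) - pred)^2)
}
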