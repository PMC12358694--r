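#' @include diversity.R
NULL

# Core log-linear least squares for both DAR models.
# PL:   ln D = ln c + z ln A
# PLEC: ln D = ln c + z ln A + d A
# Returns a DarFit; degenerate (flat response or rank-deficient design)
# fits are flagged rather than raised, so permutation loops can count them
# as failures.
.fitLogLinear <- function(areas, diversities, q, plec) {
    minPts <- if (plec) 4L else 3L
    n <- length(areas)
    if (n < minPts)
        stop("need at least ", minPts, " curve points")
    if (any(diversities <= 0))
        stop("diversities must be positive for the log transform")
    y <- log(diversities)
    X <- if (plec) cbind(1, log(areas), areas) else cbind(1, log(areas))
    model <- if (plec) "PLEC" else "PL"

    degenerate <- function() {
        new("DarFit", model = model, q = q, z = 0,
            c = exp(mean(y)), d = if (plec) 0 else NA_real_,
            R = NA_real_, pValue = NA_real_, nPoints = n,
            degenerate = TRUE)
    }

    sst <- sum((y - mean(y))^2)
    if (sst < 1e-20) return(degenerate())
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) return(degenerate())
    beta <- qr.coef(qrX, y)
    resid <- y - drop(X %*% beta)
    ssr <- sum(resid^2)
    r2 <- max(0, min(1, 1 - ssr / sst))
    k <- ncol(X) - 1L
    df2 <- n - k - 1L
    f <- (r2 / k) / ((1 - r2) / df2)  # Inf on an exact fit
    pval <- stats::pf(f, k, df2, lower.tail = FALSE)
    new("DarFit", model = model, q = q,
        z = unname(beta[2L]), c = exp(unname(beta[1L])),
        d = if (plec) unname(beta[3L]) else NA_real_,
        R = sqrt(r2), pValue = pval, nPoints = n, degenerate = FALSE)
}

#' @describeIn fitPL Fit the power-law model D = c A^z by ordinary least
#'   squares on ln D = ln c + z ln A. R is the correlation between observed
#'   and fitted ln D; the p-value is the overall regression F-test. A flat
#'   curve yields a degenerate fit (flagged, not an error). Requires at
#'   least 3 points.
#' @param curve an \linkS4class{AccumulationCurve}.
#' @return A \linkS4class{DarFit}.
#' @examples
#' cv <- generateExactPowerCurve(c = 3, z = 0.5, nAreas = 20)
#' fitPL(cv)
#' @export
setMethod("fitPL", "AccumulationCurve", function(curve) {
    .fitLogLinear(curve@areas, curve@diversities, curve@q, plec = FALSE)
})

#' @describeIn fitPLEC Fit the power law with exponential cutoff
#'   D = c A^z exp(d A) via ln D = ln c + z ln A + d A. Requires at least
#'   4 points; R is the multiple-correlation analogue of the PL case.
#' @param curve an \linkS4class{AccumulationCurve}.
#' @return A \linkS4class{DarFit}.
#' @export
setMethod("fitPLEC", "AccumulationCurve", function(curve) {
    .fitLogLinear(curve@areas, curve@diversities, curve@q, plec = TRUE)
})

setMethod("show", "DarFit", function(object) {
    if (object@degenerate) {
        cat("DarFit (", object@model, ", q = ", object@q,
            "): degenerate\n", sep = "")
        return(invisible(NULL))
    }
    cat("DarFit (", object@model, ", q = ", object@q, "): z = ",
        signif(object@z, 4), ", c = ", signif(object@c, 4), sep = "")
    if (object@model == "PLEC")
        cat(", d = ", signif(object@d, 4), sep = "")
    cat(", R = ", signif(object@R, 4), ", p = ",
        format.pval(object@pValue, digits = 3), " (n = ", object@nPoints,
        ")\n", sep = "")
})

#' Coefficients of a DAR fit
#'
#' @param object a \linkS4class{DarFit}.
#' @param ... ignored.
#' @return Named numeric vector (z, c and, for PLEC, d).
#' @export
coef.DarFit <- function(object, ...) {
    out <- c(z = object@z, c = object@c)
    if (object@model == "PLEC") out <- c(out, d = object@d)
    out
}

#' Was the fit degenerate?
#'
#' @param fit a \linkS4class{DarFit}.
#' @return Logical scalar.
#' @export
isDegenerate <- function(fit) {
    stopifnot(is(fit, "DarFit"))
    fit@degenerate
}

# A fit counts toward N when non-degenerate, significant at 0.05 and (for
# PLEC) tapering off: d >= 0 would put the diversity maximum at a negative
# area, so such fits are treated as failures.
.fitSuccess <- function(fit) {
    !fit@degenerate && !is.na(fit@pValue) && fit@pValue < 0.05 &&
        (fit@model == "PL" || fit@d < 0)
}

#' @describeIn permutedFit Fit one DAR model to accumulation curves built
#'   from random orderings of the samples and average the parameters over
#'   the successful fits. Because the pooling order affects the parameter
#'   c, the fit is repeated over `nPermutations` uniformly random orderings
#'   and z, c, d, R and the p-value are averaged (on their natural scale)
#'   across the successes; N counts the successes. A fit succeeds when it
#'   is non-degenerate, has p < 0.05, and — for PLEC — a negative taper-off
#'   d.
#' @param x a \linkS4class{CommunityTable}.
#' @param q diversity order.
#' @param model "PL" or "PLEC".
#' @param nPermutations number of random orderings (default 100).
#' @param seed optional integer seed; the caller's RNG state is restored.
#' @param samples optional sample IDs or indices restricting the cohort.
#' @return A \linkS4class{PermutedFitSummary}.
#' @examples
#' cfg <- syntheticConfig(nSamples = 12, poolSize = 80,
#'                        readsPerSample = 500)
#' ct <- generateCohort(cfg, seed = 1)
#' permutedFit(ct, q = 0, model = "PL", nPermutations = 20, seed = 2)
#' @export
setMethod("permutedFit", "CommunityTable",
    function(x, q, model = c("PL", "PLEC"), nPermutations = 100L,
             seed = NULL, samples = NULL) {
    model <- match.arg(model)
    m <- .sampleMatrix(x)
    if (!is.null(samples)) {
        if (is.character(samples))
            samples <- match(samples, sampleIDs(x))
        if (any(is.na(samples)))
            stop("unknown sample identifiers in `samples`")
        m <- m[samples, , drop = FALSE]
    }
    n <- nrow(m)
    if (n < 4L)
        stop("need at least 4 samples to fit DAR models")
    nPermutations <- as.integer(nPermutations)
    if (nPermutations < 1L)
        stop("nPermutations must be >= 1")
    plec <- model == "PLEC"

    fits <- withSeed(seed, lapply(seq_len(nPermutations), function(i) {
        ord <- sample.int(n)
        d <- .accumDiversities(m, ord, q)
        .fitLogLinear(seq_len(n), d, q, plec)
    }))

    df <- data.frame(
        z = vapply(fits, slot, numeric(1), "z"),
        c = vapply(fits, slot, numeric(1), "c"),
        d = vapply(fits, slot, numeric(1), "d"),
        R = vapply(fits, slot, numeric(1), "R"),
        pValue = vapply(fits, slot, numeric(1), "pValue"),
        degenerate = vapply(fits, slot, logical(1), "degenerate"))
    df$success <- vapply(fits, .fitSuccess, logical(1))

    ok <- df$success
    N <- sum(ok)
    if (N == 0L)
        warning("no successful ", model, " fits at q = ", q,
                " across ", nPermutations, " permutations")
    mn <- function(v) if (N >= 1L) mean(v[ok]) else NA_real_
    new("PermutedFitSummary", model = model, q = as.numeric(q),
        meanZ = mn(df$z), meanC = mn(df$c),
        meanD = if (plec) mn(df$d) else NA_real_,
        meanR = mn(df$R), meanP = mn(df$pValue),
        N = as.integer(N), nPermutations = nPermutations,
        seed = if (is.null(seed)) NA_real_ else as.numeric(seed),
        fits = df)
})

setMethod("show", "PermutedFitSummary", function(object) {
    cat("PermutedFitSummary (", object@model, ", q = ", object@q, "): N = ",
        object@N, "/", object@nPermutations, sep = "")
    if (object@N >= 1L) {
        cat("; mean z = ", signif(object@meanZ, 4), ", c = ",
            signif(object@meanC, 4), sep = "")
        if (object@model == "PLEC")
            cat(", d = ", signif(object@meanD, 4), sep = "")
        cat(", R = ", signif(object@meanR, 4), sep = "")
    }
    cat("\n")
})

#' @describeIn permutedFit per-permutation fit results (one row each) for
#'   diagnostics.
#' @export
setMethod("permutationFits", "PermutedFitSummary", function(x) x@fits)
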