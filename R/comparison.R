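#' @include profiles.R
NULL

# Permutation-averaged value of one DAR parameter for a sample subset.
# Returns NA when the underlying fits had no successes, so callers can
# skip the iteration.
.darParameter <- function(x, samples, parameter, q, model,
                          nPermutations, seed) {
    needBoth <- parameter == "LGD"
    plecPars <- c("d", "A_max", "D_max")
    useModel <- if (parameter %in% plecPars) "PLEC"
                else if (parameter == "g") "PL"
                else model
    seeds <- if (needBoth) deriveSeeds(seed, 2L) else list(seed)
    fit <- permutedFit(x, q = q,
                       model = if (needBoth) "PLEC" else useModel,
                       nPermutations = nPermutations, seed = seeds[[1L]],
                       samples = samples)
    if (fit@N == 0L) return(NA_real_)
    switch(parameter,
        z = fit@meanZ,
        c = fit@meanC,
        R = fit@meanR,
        d = fit@meanD,
        g = pdoFromZ(fit@meanZ),
        A_max = if (fit@meanZ > 0 && fit@meanD < 0)
                    aMax(fit@meanZ, fit@meanD) else NA_real_,
        D_max = if (fit@meanZ > 0 && fit@meanD < 0)
                    dMax(fit@meanC, fit@meanZ, fit@meanD) else NA_real_,
        LGD = {
            if (fit@meanZ <= 0 || fit@meanD >= 0) return(NA_real_)
            dm <- dMax(fit@meanC, fit@meanZ, fit@meanD)
            pl <- permutedFit(x, q = q, model = "PL",
                              nPermutations = nPermutations,
                              seed = seeds[[2L]], samples = samples)
            if (pl@N == 0L) NA_real_ else lgd(pl@meanC, dm)
        },
        stop("unknown parameter '", parameter, "'"))
}

#' @describeIn compareGroups Randomization test for a difference in a DAR
#'   parameter between two sample groups. The observed statistic is the
#'   difference of the permutation-averaged parameter (group A minus group
#'   B); the null distribution is built by permuting the group labels over
#'   the pooled samples (preserving the group sizes) and recomputing the
#'   difference, and the two-sided p-value uses the add-one correction
#'   p = (1 + #\{|null| >= |observed|\}) / (1 + iterations used).
#'   Iterations in which the parameter is undefined (no successful fits)
#'   are skipped and counted in `nSkipped`. The test is symmetric: swapping
#'   `groupA` and `groupB` under the same seed gives the same p-value.
#'
#' @param x a \linkS4class{CommunityTable} with group labels.
#' @param groupA,groupB the two group labels to compare (each needs >= 4
#'   samples).
#' @param parameter one of `"z"`, `"c"`, `"R"`, `"d"`, `"g"`, `"A_max"`,
#'   `"D_max"`, `"LGD"`.
#' @param q diversity order.
#' @param model model supplying `z`/`c`/`R` (forced to PLEC for `d`,
#'   `A_max`, `D_max`; to PL for `g`).
#' @param nIterations label permutations (default 100).
#' @param innerPermutations sample orderings per fit inside each iteration
#'   (default 10) — a speed/accuracy knob; raise it for final runs.
#' @param seed optional master seed.
#' @return A \linkS4class{ComparisonResult}.
#' @export
setMethod("compareGroups", "CommunityTable",
    function(x, groupA, groupB, parameter = "z", q = 0,
             model = c("PL", "PLEC"), nIterations = 100L,
             innerPermutations = 10L, seed = NULL) {
    model <- match.arg(model)
    parameter <- match.arg(parameter,
        c("z", "c", "R", "d", "g", "A_max", "D_max", "LGD"))
    nIterations <- as.integer(nIterations)
    if (nIterations < 1L)
        stop("nIterations must be >= 1")
    if (identical(groupA, groupB))
        stop("groupA and groupB must differ")
    idsA <- samplesInGroup(x, groupA)
    idsB <- samplesInGroup(x, groupB)
    if (length(idsA) < 4L || length(idsB) < 4L)
        stop("both groups need at least 4 samples (",
             groupA, ": ", length(idsA), ", ",
             groupB, ": ", length(idsB), ")")

    # Canonical ordering of both the pooled samples (table order) and the
    # groups (sorted labels) makes the computation independent of the
    # argument order, so p is invariant under swapping A and B.
    canon <- sort(c(groupA, groupB))
    g <- sampleGroups(x)
    sel <- !is.na(g) & g %in% c(groupA, groupB)
    pool <- sampleIDs(x)[sel]
    labels <- unname(g[sel])

    master <- deriveSeeds(seed, 2L)
    shuffles <- withSeed(master[[1L]],
        lapply(seq_len(nIterations), function(i) sample(labels)))
    paramSeeds <- deriveSeeds(master[[2L]], 2L * (nIterations + 1L))

    valuePair <- function(lab, at) {
        vapply(seq_along(canon), function(j) {
            .darParameter(x, pool[lab == canon[j]], parameter, q, model,
                          innerPermutations,
                          paramSeeds[[2L * at + j]])
        }, numeric(1))
    }
    diffOf <- function(v) {
        v[match(groupA, canon)] - v[match(groupB, canon)]
    }

    observed <- diffOf(valuePair(labels, 0L))
    if (is.na(observed))
        stop("parameter '", parameter,
             "' is undefined for the observed groups (no successful fits)")
    nullDiff <- vapply(seq_len(nIterations), function(i) {
        diffOf(valuePair(shuffles[[i]], i))
    }, numeric(1))
    skipped <- sum(is.na(nullDiff))
    if (skipped > 0L)
        message(skipped, " of ", nIterations,
                " iterations skipped (parameter undefined)")
    nullDiff <- nullDiff[!is.na(nullDiff)]
    p <- (1 + sum(abs(nullDiff) >= abs(observed))) /
         (1 + length(nullDiff))

    new("ComparisonResult", parameter = parameter, q = as.numeric(q),
        model = model, groups = c(groupA, groupB),
        observed = observed, nullDiff = nullDiff, pValue = p,
        nIterations = nIterations, nSkipped = as.integer(skipped),
        seed = if (is.null(seed)) NA_real_ else as.numeric(seed))
})

setMethod("show", "ComparisonResult", function(object) {
    cat("ComparisonResult: ", object@parameter, " (", object@model,
        ", q = ", object@q, "), ", object@groups[1L], " vs ",
        object@groups[2L], "\n", sep = "")
    cat("  observed difference ", signif(object@observed, 4),
        ", p = ", signif(object@pValue, 4), " (",
        length(object@nullDiff), " null iterations",
        if (object@nSkipped > 0L)
            paste0(", ", object@nSkipped, " skipped"),
        ")\n", sep = "")
})

#' p-value of a randomization comparison
#'
#' @param result a \linkS4class{ComparisonResult}.
#' @return The two-sided add-one permutation p-value.
#' @export
pValue <- function(result) {
    stopifnot(is(result, "ComparisonResult"))
    result@pValue
}
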