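#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
NULL

#' CommunityTable: a cohort of per-sample taxon counts
#'
#' An extension of \linkS4class{SummarizedExperiment} holding a single
#' `counts` assay with taxa as rows and samples as columns, plus an optional
#' `group` column (e.g. NT/PT/LUAD/LUSC tissue labels) and an optional
#' `dataset` column in `colData`. One sample is one unit of "area" for the
#' diversity-area analysis.
#'
#' Validity requires non-negative whole-number counts, unique sample and
#' taxon identifiers, and a positive read total in every sample; the
#' \code{\link{CommunityTable}} constructor drops zero-read samples with a
#' warning before validity is checked.
#'
#' @seealso \code{\link{CommunityTable}}, \code{\link{readCountTable}}
#' @name CommunityTable-class
#' @aliases CommunityTable-class
#' @exportClass CommunityTable
setClass("CommunityTable", contains = "SummarizedExperiment")

setValidity("CommunityTable", function(object) {
    msgs <- character()
    if (!("counts" %in% SummarizedExperiment::assayNames(object)))
        return("assay 'counts' is missing")
    m <- SummarizedExperiment::assay(object, "counts")
    if (!is.numeric(m))
        msgs <- c(msgs, "counts must be numeric")
    else {
        if (any(!is.finite(m)) || any(m < 0))
            msgs <- c(msgs, "counts must be finite and non-negative")
        if (!isWholeNumber(m))
            msgs <- c(msgs, "counts must be whole numbers")
        if (ncol(m) > 0L && any(colSums(m) <= 0))
            msgs <- c(msgs, "every sample must have a positive read total")
    }
    if (anyDuplicated(colnames(object)))
        msgs <- c(msgs, "duplicated sample identifiers")
    if (anyDuplicated(rownames(object)))
        msgs <- c(msgs, "duplicated taxon identifiers")
    if (length(msgs)) msgs else TRUE
})

#' AccumulationCurve: diversity along one sample ordering
#'
#' Ordered pairs (A, D(A)) where A = 1..n is the number of pooled samples and
#' D(A) the Hill diversity of the pooled community over the first A samples
#' of one ordering, at one diversity order q. Curves produced directly from
#' an analytic law (see \code{\link{generateExactPowerCurve}}) carry
#' `q = NA` and an identity ordering.
#'
#' @slot q numeric(1), the diversity order (may be `NA` for analytic curves).
#' @slot areas integer vector 1..n.
#' @slot diversities positive numeric vector, same length as `areas`.
#' @slot ordering integer vector of the sample indices pooled, in order.
#' @exportClass AccumulationCurve
setClass("AccumulationCurve",
    representation(q = "numeric", areas = "integer",
                   diversities = "numeric", ordering = "integer"))

setValidity("AccumulationCurve", function(object) {
    msgs <- character()
    if (length(object@q) != 1L)
        msgs <- c(msgs, "q must be a single value")
    if (length(object@areas) != length(object@diversities))
        msgs <- c(msgs, "areas and diversities differ in length")
    if (length(object@areas) &&
        !identical(object@areas, seq_along(object@areas)))
        msgs <- c(msgs, "areas must be 1..n")
    if (any(!is.finite(object@diversities)) || any(object@diversities <= 0))
        msgs <- c(msgs, "diversities must be positive and finite")
    if (length(msgs)) msgs else TRUE
})

#' DarFit: one fitted diversity-area model
#'
#' Result of ordinary least squares on the log-linear transform of the
#' power-law model ln D = ln c + z ln A (PL) or
#' ln D = ln c + z ln A + d A (PLEC), for one accumulation curve.
#'
#' @slot model "PL" or "PLEC".
#' @slot q diversity order of the curve (may be `NA`).
#' @slot z scaling exponent (slope on ln A).
#' @slot c diversity of the first area unit, `exp(intercept)`.
#' @slot d taper-off parameter (PLEC only; `NA` for PL).
#' @slot R correlation between observed and fitted ln D (`NA` if degenerate).
#' @slot pValue overall regression F-test p-value.
#' @slot nPoints number of curve points used.
#' @slot degenerate `TRUE` when the response or design had no usable
#'   variation; such fits are never counted as successes.
#' @exportClass DarFit
setClass("DarFit",
    representation(model = "character", q = "numeric", z = "numeric",
                   c = "numeric", d = "numeric", R = "numeric",
                   pValue = "numeric", nPoints = "integer",
                   degenerate = "logical"))

setValidity("DarFit", function(object) {
    msgs <- character()
    if (!object@model %in% c("PL", "PLEC"))
        msgs <- c(msgs, "model must be 'PL' or 'PLEC'")
    if (object@model == "PL" && !is.na(object@d))
        msgs <- c(msgs, "PL fits carry no d parameter")
    if (!object@degenerate && (!is.finite(object@c) || object@c <= 0))
        msgs <- c(msgs, "c must be positive")
    if (!is.na(object@pValue) &&
        (object@pValue < 0 || object@pValue > 1))
        msgs <- c(msgs, "pValue must lie in [0, 1]")
    if (length(msgs)) msgs else TRUE
})

#' PermutedFitSummary: model parameters averaged over random orderings
#'
#' Aggregates DAR fits over random permutations of the sample order. A fit
#' is a success when it is non-degenerate, its regression p-value is below
#' 0.05 and, for PLEC, its taper-off parameter d is negative. Parameter
#' means are taken over successes only; `N` counts them.
#'
#' @slot model,q as in \linkS4class{DarFit}.
#' @slot meanZ,meanC,meanD,meanR,meanP success-averaged parameters (`NA`
#'   when `N == 0`; `meanD` is `NA` for PL).
#' @slot N integer count of successful fits.
#' @slot nPermutations number of orderings attempted.
#' @slot seed the seed used (`NA` if unseeded).
#' @slot fits data.frame with one row per permutation (z, c, d, R, pValue,
#'   degenerate, success) for diagnostics.
#' @exportClass PermutedFitSummary
setClass("PermutedFitSummary",
    representation(model = "character", q = "numeric", meanZ = "numeric",
                   meanC = "numeric", meanD = "numeric", meanR = "numeric",
                   meanP = "numeric", N = "integer",
                   nPermutations = "integer", seed = "numeric",
                   fits = "data.frame"))

setValidity("PermutedFitSummary", function(object) {
    msgs <- character()
    if (object@N < 0L || object@N > object@nPermutations)
        msgs <- c(msgs, "N must lie in [0, nPermutations]")
    if (object@N == 0L && !is.na(object@meanZ))
        msgs <- c(msgs, "means must be NA when N == 0")
    if (length(msgs)) msgs else TRUE
})

#' DarProfileSet: the four DAR-based profiles across diversity orders
#'
#' One row per diversity order q holding the permutation-averaged PL and
#' PLEC parameters together with the derived quantities: pairwise diversity
#' overlap g = 2 - 2^z (from the PL exponent), the area of maximal accrued
#' diversity A_max = -z/d and its value D_max = c (-z/d)^z exp(-z) (from the
#' PLEC parameters), and the local-to-global ratio LGD% = 100 c_PL / D_max.
#'
#' @slot profiles a \linkS4class{DataFrame}, one row per q.
#' @slot qGrid the diversity orders profiled.
#' @slot nPermutations orderings per fit.
#' @slot seed master seed (`NA` if unseeded).
#' @exportClass DarProfileSet
setClass("DarProfileSet",
    representation(profiles = "DataFrame", qGrid = "numeric",
                   nPermutations = "integer", seed = "numeric"))

#' ComparisonResult: randomization test for a DAR parameter between groups
#'
#' @slot parameter one of z, c, d, g, A_max, D_max, LGD.
#' @slot q diversity order.
#' @slot model model supplying the parameter ("PL" or "PLEC").
#' @slot groups character(2), the labels compared (A, B).
#' @slot observed observed difference A - B.
#' @slot nullDiff null differences from label permutations (skipped
#'   iterations omitted).
#' @slot pValue two-sided add-one permutation p-value.
#' @slot nIterations iterations requested.
#' @slot nSkipped iterations dropped because the parameter was undefined.
#' @slot seed seed used (`NA` if unseeded).
#' @exportClass ComparisonResult
setClass("ComparisonResult",
    representation(parameter = "character", q = "numeric",
                   model = "character", groups = "character",
                   observed = "numeric", nullDiff = "numeric",
                   pValue = "numeric", nIterations = "integer",
                   nSkipped = "integer", seed = "numeric"))

setValidity("ComparisonResult", function(object) {
    if (object@pValue <= 0 || object@pValue > 1)
        "pValue must lie in (0, 1]" else TRUE
})

#' SyntheticConfig: parameters of the synthetic cohort generator
#'
#' Describes a cohort drawn from a global species pool: per-species pool
#' abundances are lognormal(meanlog, sdlog); a fixed core fraction of the
#' pool is present in every sample; each remaining (satellite) species gets
#' an occupancy probability from a Beta law and per-sample presence by
#' Bernoulli draws; reads are then drawn multinomially per sample. The
#' `disjoint` switch instead partitions the pool evenly across samples with
#' no sharing (the no-overlap limit, fitted z -> 1).
#'
#' @slot nSamples number of samples (areas).
#' @slot poolSize global species pool size.
#' @slot coreFraction fraction of the pool present in every sample, in
#'   \[0, 1\].
#' @slot occupancyShape numeric(2), Beta(a, b) shapes for satellite
#'   occupancy probabilities.
#' @slot abundanceMeanlog,abundanceSdlog lognormal pool-abundance
#'   parameters; `abundanceSdlog = 0` gives a uniform (even) pool.
#' @slot readsPerSample reads drawn per sample (length 1 or nSamples).
#' @slot disjoint partition the pool with no sharing instead of the
#'   core/satellite model.
#' @slot seed default seed for \code{\link{generateCohort}} (`NA` = none).
#' @exportClass SyntheticConfig
setClass("SyntheticConfig",
    representation(nSamples = "integer", poolSize = "integer",
                   coreFraction = "numeric", occupancyShape = "numeric",
                   abundanceMeanlog = "numeric", abundanceSdlog = "numeric",
                   readsPerSample = "numeric", disjoint = "logical",
                   seed = "numeric"))

setValidity("SyntheticConfig", function(object) {
    msgs <- character()
    if (object@nSamples < 1L) msgs <- c(msgs, "nSamples must be >= 1")
    if (object@poolSize < 1L) msgs <- c(msgs, "poolSize must be >= 1")
    if (object@coreFraction < 0 || object@coreFraction > 1)
        msgs <- c(msgs, "coreFraction must lie in [0, 1]")
    if (length(object@occupancyShape) != 2L ||
        any(object@occupancyShape <= 0))
        msgs <- c(msgs, "occupancyShape must be two positive values")
    if (any(object@readsPerSample < 1))
        msgs <- c(msgs, "readsPerSample must be >= 1")
    if (!length(object@readsPerSample) %in% c(1L, object@nSamples))
        msgs <- c(msgs, "readsPerSample must have length 1 or nSamples")
    if (object@abundanceSdlog < 0)
        msgs <- c(msgs, "abundanceSdlog must be >= 0")
    if (length(msgs)) msgs else TRUE
})
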