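#' @include AllClasses.R
NULL

#' @export
setGeneric("sampleIDs", function(x) standardGeneric("sampleIDs"))

#' @export
setGeneric("taxonIDs", function(x) standardGeneric("taxonIDs"))

#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' @export
setGeneric("sampleGroups<-",
    function(x, value) standardGeneric("sampleGroups<-"))

#' @export
setGeneric("pooledDiversity",
    function(x, samples, q) standardGeneric("pooledDiversity"))

#' @export
setGeneric("accumulationCurve",
    function(x, ordering, q) standardGeneric("accumulationCurve"))

#' @export
setGeneric("fitPL", function(curve) standardGeneric("fitPL"))

#' @export
setGeneric("fitPLEC", function(curve) standardGeneric("fitPLEC"))

#' @export
setGeneric("permutedFit",
    function(x, q, model = c("PL", "PLEC"), nPermutations = 100L,
             seed = NULL, samples = NULL)
        standardGeneric("permutedFit"))

#' @export
setGeneric("permutationFits", function(x) standardGeneric("permutationFits"))

#' @export
setGeneric("buildProfiles",
    function(x, qGrid = c(0, 1, 2, 3), nPermutations = 100L, seed = NULL,
             samples = NULL)
        standardGeneric("buildProfiles"))

#' @export
setGeneric("profileTable", function(x) standardGeneric("profileTable"))

#' @export
setGeneric("compareGroups",
    function(x, groupA, groupB, parameter = "z", q = 0,
             model = c("PL", "PLEC"), nIterations = 100L,
             innerPermutations = 10L, seed = NULL)
        standardGeneric("compareGroups"))

#' @export
setGeneric("generateCohort",
    function(config, seed = NULL) standardGeneric("generateCohort"))
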