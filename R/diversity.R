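#' @include community-table.R
NULL

#' Relative abundances from a count vector
#'
#' Normalizes a vector of non-negative counts to relative abundances.
#' Zero-count taxa are retained with abundance 0; they contribute nothing
#' to any Hill number.
#'
#' @param counts non-negative numeric vector with a positive sum.
#' @return Numeric vector summing to 1.
#' @examples
#' relativeAbundances(c(8, 2, 0))
#' @export
relativeAbundances <- function(counts) {
    if (!is.numeric(counts) || any(!is.finite(counts)) || any(counts < 0))
        stop("counts must be finite and non-negative")
    s <- sum(counts)
    if (s <= 0) stop("empty community: all counts are zero")
    counts / s
}

.checkAbundances <- function(p, tol = 1e-9) {
    if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0))
        stop("abundances must be finite and non-negative")
    if (abs(sum(p) - 1) > tol)
        stop("abundances must sum to 1 (got ", format(sum(p)), ")")
    invisible(p)
}

#' Hill number of a relative-abundance vector
#'
#' The Hill number of order q is `(sum_i p_i^q)^(1/(1-q))` over taxa with
#' positive abundance; at q = 1 the analytic limit `exp(-sum_i p_i ln p_i)`
#' is used (taken whenever |q - 1| < 1e-9). q = 0 counts present taxa,
#' q = 1 is the exponential of Shannon entropy, q = 2 the inverse Simpson
#' concentration; larger q weights abundant taxa more heavily. Absent taxa
#' (p_i = 0) are excluded from the sum at every order.
#'
#' @param p relative abundances (must sum to 1 within 1e-9).
#' @param q diversity order, a single non-negative finite number.
#' @return The effective number of taxa, a positive scalar.
#' @examples
#' hillNumber(c(0.25, 0.25, 0.25, 0.25), q = 2)  # 4: even community
#' hillNumber(c(0.8, 0.2), q = 2)                # 1 / (0.64 + 0.04)
#' @export
hillNumber <- function(p, q) {
    .checkAbundances(p)
    if (!is.numeric(q) || length(q) != 1L || !is.finite(q) || q < 0)
        stop("q must be a single finite non-negative number")
    p <- p[p > 0]
    if (q == 0) return(length(p))
    if (abs(q - 1) < 1e-9) return(exp(-sum(p * log(p))))
    sum(p^q)^(1 / (1 - q))
}

#' @describeIn pooledDiversity Hill diversity of the pooled community
#'   formed by summing raw counts over a subset of samples.
#' @param x a \linkS4class{CommunityTable}.
#' @param samples non-empty vector of sample IDs or indices.
#' @param q diversity order.
#' @return Positive scalar diversity.
#' @export
setMethod("pooledDiversity", "CommunityTable", function(x, samples, q) {
    if (missing(samples) || length(samples) == 0L)
        stop("sample subset must be non-empty")
    m <- .sampleMatrix(x)[samples, , drop = FALSE]
    hillNumber(relativeAbundances(colSums(m)), q)
})

# Diversity of the pooled community over each prefix of `ordering`,
# vectorized over prefixes: cumulative counts by taxon, then the Hill
# transform row-wise.
.accumDiversities <- function(m, ordering, q) {
    cs <- apply(m[ordering, , drop = FALSE], 2L, cumsum)
    if (length(ordering) == 1L)
        cs <- matrix(cs, nrow = 1L)
    if (q == 0) return(rowSums(cs > 0))
    p <- cs / rowSums(cs)
    if (abs(q - 1) < 1e-9) {
        plp <- p * log(p)
        plp[p == 0] <- 0
        exp(-rowSums(plp))
    } else {
        rowSums(p^q)^(1 / (1 - q))
    }
}

#' @describeIn accumulationCurve Diversity accumulation along one sample
#'   ordering: point A is the pooled diversity of the first A samples.
#' @param x a \linkS4class{CommunityTable}.
#' @param ordering a vector of distinct sample IDs or indices giving the
#'   pooling order (a permutation of the selected samples).
#' @param q diversity order.
#' @return An \linkS4class{AccumulationCurve}.
#' @examples
#' ct <- CommunityTable(matrix(c(1, 0, 0, 1), 2, 2,
#'     dimnames = list(c("s1", "s2"), c("a", "b"))))
#' accumulationCurve(ct, 1:2, q = 0)
#' @export
setMethod("accumulationCurve", "CommunityTable", function(x, ordering, q) {
    if (is.character(ordering))
        ordering <- match(ordering, sampleIDs(x))
    if (any(is.na(ordering)) || anyDuplicated(ordering) ||
        any(ordering < 1L) || any(ordering > ncol(x)))
        stop("ordering must be a permutation of distinct sample indices")
    ordering <- as.integer(ordering)
    if (!is.numeric(q) || length(q) != 1L || !is.finite(q) || q < 0)
        stop("q must be a single finite non-negative number")
    d <- .accumDiversities(.sampleMatrix(x), ordering, q)
    new("AccumulationCurve", q = as.numeric(q),
        areas = seq_along(ordering), diversities = as.numeric(d),
        ordering = ordering)
})

setMethod("show", "AccumulationCurve", function(object) {
    cat("AccumulationCurve: q =", object@q, "over",
        length(object@areas), "areas; D(1) =",
        signif(object@diversities[1L], 4), "-> D(n) =",
        signif(object@diversities[length(object@diversities)], 4), "\n")
})

#' Areas and diversities of an accumulation curve as a data.frame
#'
#' @param x an \linkS4class{AccumulationCurve}.
#' @param ... ignored.
#' @return data.frame with columns `area` and `diversity`.
#' @export
as.data.frame.AccumulationCurve <- function(x, ...) {
    data.frame(area = x@areas, diversity = x@diversities)
}
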