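#' @include fitting.R
NULL

#' Pairwise diversity overlap from the scaling exponent
#'
#' For the power-law model, the expected proportion of diversity shared by
#' two adjacent equal-size areas is g = 2(D_A - (D_2A - D_A))/D_A = 2 - 2^z.
#' z = 1 gives g = 0 (no overlap: diversity doubles with area); z = 0 gives
#' g = 1 (complete overlap). Values of z outside [0, 1] are accepted with a
#' warning since fitted exponents can stray outside the interpretable range.
#'
#' @param z scaling exponent(s) from the PL model.
#' @return g, same length as `z`.
#' @examples
#' pdoFromZ(c(0, 0.463, 1))
#' @export
pdoFromZ <- function(z) {
    if (!is.numeric(z) || any(!is.finite(z)))
        stop("z must be finite")
    if (any(z < -1e-8 | z > 1 + 1e-8))
        warning("z outside [0, 1]; overlap g leaves [0, 1]")
    2 - 2^z
}

#' Area of maximal accrued diversity under the PLEC model
#'
#' The PLEC curve c A^z exp(d A) with z > 0 and d < 0 peaks at
#' A_max = -z/d areas.
#'
#' @param z positive scaling exponent.
#' @param d negative taper-off parameter.
#' @return A_max, a positive scalar.
#' @export
aMax <- function(z, d) {
    if (!is.numeric(z) || !is.numeric(d) || !is.finite(z) || !is.finite(d))
        stop("z and d must be finite")
    if (d >= 0)
        stop("no interior maximum: taper-off d must be negative")
    if (z <= 0)
        stop("z must be positive")
    -z / d
}

#' Maximal accrued diversity under the PLEC model
#'
#' The maximum of c A^z exp(d A) over A > 0, attained at A_max = -z/d:
#' D_max = c (-z/d)^z exp(-z). Interpreted as the potential total diversity
#' of the cohort.
#'
#' @param c positive first-area diversity parameter.
#' @param z positive scaling exponent.
#' @param d negative taper-off parameter.
#' @return D_max, a positive scalar.
#' @examples
#' dMax(c = 10, z = 0.5, d = -0.001)
#' @export
dMax <- function(c, z, d) {
    if (!is.numeric(c) || !is.finite(c) || c <= 0)
        stop("c must be positive and finite")
    if (!is.numeric(z) || !is.finite(z) || z < 0)
        stop("z must be non-negative and finite")
    if (!is.numeric(d) || !is.finite(d) || d >= 0)
        stop("taper-off d must be negative")
    if (z == 0) return(c)
    c * (-z / d)^z * exp(-z)
}

#' Local-to-global diversity ratio (percent)
#'
#' Ratio of the local diversity (the PL parameter c, diversity of one area
#' unit) to the maximal accrued diversity D_max, expressed in percent:
#' LGD% = 100 c / D_max.
#'
#' @param cPL positive PL-model c parameter.
#' @param dMaxValue positive maximal accrued diversity.
#' @return Percentage.
#' @export
lgd <- function(cPL, dMaxValue) {
    if (!is.numeric(cPL) || !is.finite(cPL) || cPL <= 0)
        stop("cPL must be positive and finite")
    if (!is.numeric(dMaxValue) || !is.finite(dMaxValue) || dMaxValue <= 0)
        stop("dMaxValue must be positive")
    100 * cPL / dMaxValue
}

#' @describeIn buildProfiles Build the DAR, PDO, MAD and LGD profiles for a
#'   cohort: at each diversity order q in `qGrid`, run `permutedFit` for
#'   both the PL and the PLEC model, then derive g = 2 - 2^z from the
#'   averaged PL exponent, A_max and D_max from the averaged PLEC
#'   parameters, and LGD% = 100 c_PL / D_max. Orders at which a model has
#'   no successful fits get `NA` in the dependent cells, with a warning.
#' @param x a \linkS4class{CommunityTable}.
#' @param qGrid diversity orders to profile (default 0:3).
#' @param nPermutations orderings per fit (default 100).
#' @param seed optional master seed; per-(q, model) child seeds are derived
#'   from it so results are reproducible.
#' @param samples optional sample subset.
#' @return A \linkS4class{DarProfileSet}.
#' @export
setMethod("buildProfiles", "CommunityTable",
    function(x, qGrid = c(0, 1, 2, 3), nPermutations = 100L, seed = NULL,
             samples = NULL) {
    if (length(qGrid) == 0L)
        stop("qGrid must be non-empty")
    if (any(!is.finite(qGrid)) || any(qGrid < 0))
        stop("qGrid must be finite and non-negative")
    seeds <- deriveSeeds(seed, 2L * length(qGrid))
    rows <- lapply(seq_along(qGrid), function(i) {
        q <- qGrid[i]
        pl <- permutedFit(x, q = q, model = "PL",
                          nPermutations = nPermutations,
                          seed = seeds[[2L * i - 1L]], samples = samples)
        plec <- permutedFit(x, q = q, model = "PLEC",
                            nPermutations = nPermutations,
                            seed = seeds[[2L * i]], samples = samples)
        g <- if (pl@N >= 1L) pdoFromZ(pl@meanZ) else NA_real_
        am <- dm <- lg <- NA_real_
        if (plec@N >= 1L && plec@meanZ > 0 && plec@meanD < 0) {
            am <- aMax(plec@meanZ, plec@meanD)
            dm <- dMax(plec@meanC, plec@meanZ, plec@meanD)
            if (pl@N >= 1L) lg <- lgd(pl@meanC, dm)
        } else if (plec@N >= 1L) {
            warning("PLEC means at q = ", q,
                    " admit no interior maximum; MAD/LGD cells set to NA")
        }
        S4Vectors::DataFrame(
            q = q,
            pl_z = pl@meanZ, pl_c = pl@meanC, pl_R = pl@meanR,
            g = g, pl_p = pl@meanP, pl_N = pl@N,
            plec_z = plec@meanZ, plec_d = plec@meanD, plec_c = plec@meanC,
            plec_R = plec@meanR, plec_p = plec@meanP, plec_N = plec@N,
            A_max = am, D_max = dm, lgd_percent = lg)
    })
    new("DarProfileSet", profiles = do.call(rbind, rows),
        qGrid = as.numeric(qGrid),
        nPermutations = as.integer(nPermutations),
        seed = if (is.null(seed)) NA_real_ else as.numeric(seed))
})

#' @describeIn buildProfiles the profile table as a plain data.frame (one
#'   row per q; PL columns, PLEC columns, and the derived g, A_max, D_max
#'   and LGD% cells).
#' @export
setMethod("profileTable", "DarProfileSet", function(x) {
    as.data.frame(x@profiles)
})

setMethod("show", "DarProfileSet", function(object) {
    cat("DarProfileSet over q = {",
        paste(object@qGrid, collapse = ", "), "}, ",
        object@nPermutations, " permutations per fit\n", sep = "")
    print(profileTable(object), digits = 4, row.names = FALSE)
})
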