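#' @include community-table.R
NULL

#' Configure the synthetic cohort generator
#'
#' Builds a \linkS4class{SyntheticConfig} describing a cohort of taxon
#' count vectors drawn from one global species pool. The generator follows
#' a core/satellite occupancy model: a `coreFraction` of the pool is
#' present in every sample; each remaining (satellite) species receives an
#' occupancy probability from a Beta(`occupancyShape`) law and is present
#' in a sample by an independent Bernoulli draw. Species pool abundances
#' are lognormal; per sample, reads are drawn multinomially from the
#' renormalized abundances of the species present, emulating finite
#' sequencing depth. `coreFraction` is the knob that moves
#' inter-individual overlap and hence the fitted diversity-area scaling
#' exponent z.
#'
#' @param nSamples samples (area units) to generate. Default 50, the
#'   smallest cohort size in the kind of multi-study lung-tissue data this
#'   mirrors.
#' @param poolSize global species pool size. Default 600, echoing
#'   cohort-level species totals in the hundreds.
#' @param coreFraction fraction of the pool present in all samples
#'   (default 0.1).
#' @param occupancyShape Beta(a, b) shapes for satellite occupancy
#'   probabilities. The default `c(0.5, 1.5)` (mean 0.25, mass near 0)
#'   gives many sporadic and few near-core satellites.
#' @param abundanceMeanlog,abundanceSdlog lognormal species-abundance
#'   parameters (defaults 0 and 1.5, a typical heavy-tailed microbial
#'   abundance distribution). `abundanceSdlog = 0` yields a perfectly even
#'   pool.
#' @param readsPerSample reads drawn per sample, length 1 or `nSamples`
#'   (default 2000).
#' @param disjoint if `TRUE`, ignore the core/satellite model and
#'   partition the pool evenly across samples with no sharing — the
#'   no-overlap limit in which richness accumulates linearly (z -> 1).
#' @param seed default seed used by \code{\link{generateCohort}} when none
#'   is passed there.
#' @return A \linkS4class{SyntheticConfig}.
#' @examples
#' cfg <- syntheticConfig(nSamples = 10, poolSize = 100)
#' ct <- generateCohort(cfg, seed = 1)
#' ct
#' @export
syntheticConfig <- function(nSamples = 50L, poolSize = 600L,
                            coreFraction = 0.1,
                            occupancyShape = c(0.5, 1.5),
                            abundanceMeanlog = 0, abundanceSdlog = 1.5,
                            readsPerSample = 2000L, disjoint = FALSE,
                            seed = NULL) {
    new("SyntheticConfig",
        nSamples = as.integer(nSamples), poolSize = as.integer(poolSize),
        coreFraction = as.numeric(coreFraction),
        occupancyShape = as.numeric(occupancyShape),
        abundanceMeanlog = as.numeric(abundanceMeanlog),
        abundanceSdlog = as.numeric(abundanceSdlog),
        readsPerSample = as.numeric(readsPerSample),
        disjoint = isTRUE(disjoint),
        seed = if (is.null(seed)) NA_real_ else as.numeric(seed))
}

setMethod("show", "SyntheticConfig", function(object) {
    cat("SyntheticConfig:", object@nSamples, "samples, pool",
        object@poolSize, "\n")
    if (object@disjoint) {
        cat("  disjoint pool partition (no sharing)\n")
    } else {
        cat("  core fraction ", object@coreFraction,
            ", satellite occupancy Beta(",
            object@occupancyShape[1L], ", ", object@occupancyShape[2L],
            ")\n", sep = "")
    }
    cat("  abundances lognormal(", object@abundanceMeanlog, ", ",
        object@abundanceSdlog, "), reads/sample ",
        paste(unique(object@readsPerSample), collapse = "/"), "\n",
        sep = "")
})

#' @describeIn syntheticConfig Draw a cohort from a configuration. The
#'   draw is fully determined by the seed (argument, falling back to the
#'   config's own seed). A sample that ends up with no species present has
#'   its satellite presences redrawn once; a second failure is an error.
#' @param config a \linkS4class{SyntheticConfig}.
#' @param seed integer seed; overrides `config`'s seed slot.
#' @return A \linkS4class{CommunityTable}.
#' @export
setMethod("generateCohort", "SyntheticConfig", function(config,
                                                        seed = NULL) {
    validObject(config)
    if (is.null(seed) && !is.na(config@seed))
        seed <- config@seed
    n <- config@nSamples
    P <- config@poolSize
    reads <- rep_len(config@readsPerSample, n)

    withSeed(seed, {
        lambda <- stats::rlnorm(P, config@abundanceMeanlog,
                                config@abundanceSdlog)
        presence <- matrix(FALSE, n, P)
        if (config@disjoint) {
            block <- rep_len(seq_len(n), P)  # even partition of the pool
            for (i in seq_len(n)) presence[i, block == i] <- TRUE
        } else {
            nCore <- ceiling(config@coreFraction * P)
            core <- if (nCore > 0L) sample.int(P, nCore) else integer()
            sat <- setdiff(seq_len(P), core)
            presence[, core] <- TRUE
            if (length(sat)) {
                occ <- stats::rbeta(length(sat), config@occupancyShape[1L],
                                    config@occupancyShape[2L])
                presence[, sat] <- matrix(
                    stats::rbinom(n * length(sat), 1L,
                                  rep(occ, each = n)) == 1L,
                    n, length(sat))
            }
            redraw <- function(i) {
                if (length(sat))
                    presence[i, sat] <<- stats::rbinom(
                        length(sat), 1L, occ) == 1L
            }
            for (i in seq_len(n)) {
                if (!any(presence[i, ])) {
                    redraw(i)
                    if (!any(presence[i, ]))
                        stop("sample ", i,
                             " has no species present after one redraw")
                }
            }
        }
        m <- matrix(0L, n, P,
                    dimnames = list(sprintf("sample%03d", seq_len(n)),
                                    sprintf("sp%04d", seq_len(P))))
        for (i in seq_len(n)) {
            pres <- presence[i, ]
            m[i, pres] <- stats::rmultinom(1L, reads[i], lambda[pres])[, 1L]
        }
        CommunityTable(m)
    })
})

#' Noiseless power-law accumulation curves
#'
#' Builds the analytic curve D(A) = c A^z exp(d A) for A = 1..nAreas,
#' bypassing count tables; intended as an exact fixture for fit-recovery
#' checks. With the default `d = 0` it is a pure power law.
#'
#' @param c positive scale parameter.
#' @param z scaling exponent.
#' @param nAreas number of areas (>= 4).
#' @param d taper-off parameter (default 0).
#' @return An \linkS4class{AccumulationCurve}; its `q` slot is `NA` since
#'   the curve comes from a law, not a community.
#' @examples
#' fitPL(generateExactPowerCurve(3, 0.5, 20))
#' @export
generateExactPowerCurve <- function(c, z, nAreas, d = 0) {
    stopifnot(is.numeric(c), c > 0, is.numeric(z),
              is.numeric(nAreas), nAreas >= 4, is.numeric(d))
    A <- seq_len(as.integer(nAreas))
    new("AccumulationCurve", q = NA_real_, areas = A,
        diversities = c * A^z * exp(d * A), ordering = A)
}
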