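#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed`, restoring the previous
#' RNG state afterwards so library code does not clobber the caller's stream.
#' A `NULL` seed evaluates `expr` against the current stream unchanged.
#'
#' @param seed integer scalar or `NULL`.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
withSeed <- function(seed, expr) {
    if (is.null(seed)) {
        return(eval.parent(substitute(expr)))
    }
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (had) {
            assign(".Random.seed", old, envir = globalenv())
        } else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE)) {
            rm(".Random.seed", envir = globalenv())
        }
    })
    set.seed(as.integer(seed))
    eval.parent(substitute(expr))
}

# Derive n child seeds from a master seed, each usable with set.seed().
# NULL propagates NULL so unseeded runs stay unseeded.
deriveSeeds <- function(seed, n) {
    if (is.null(seed)) {
        return(vector("list", n))
    }
    as.list(withSeed(seed, sample.int(.Machine$integer.max - 1L, n)))
}

# Whole-number check tolerant of numeric storage.
isWholeNumber <- function(x, tol = 1e-8) {
    is.numeric(x) && all(is.finite(x)) && all(abs(x - round(x)) < tol)
}
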