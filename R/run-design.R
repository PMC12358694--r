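#' @include comparison.R io.R
NULL

#' Assemble and validate a full-analysis configuration
#'
#' Bundles everything \code{\link{runDesign}} needs: the cohort (a
#' \linkS4class{CommunityTable} or a TSV path plus metadata path), the
#' diversity orders, the permutation budgets, and the output directory.
#'
#' @param table a \linkS4class{CommunityTable}, or a path to a TSV count
#'   table.
#' @param metadata optional sample-metadata TSV path (required when
#'   `table` is a path and group comparisons are wanted).
#' @param qGrid non-empty vector of diversity orders (default 0:3).
#' @param nPermutations sample orderings per model fit (default 100).
#' @param nIterations label permutations per group comparison (default
#'   100).
#' @param innerPermutations orderings per fit inside comparison iterations
#'   (default 10).
#' @param compareParameters DAR parameters to test between groups
#'   (default `"z"`).
#' @param seed master seed; every downstream random draw is derived from
#'   it.
#' @param outdir output directory (created if absent).
#' @param compare run pairwise group comparisons (default `TRUE`).
#' @return A validated configuration list of class `darRunConfig`.
#' @export
darRunConfig <- function(table, metadata = NULL, qGrid = c(0, 1, 2, 3),
                         nPermutations = 100L, nIterations = 100L,
                         innerPermutations = 10L,
                         compareParameters = "z", seed = 1L,
                         outdir = "dar-results", compare = TRUE) {
    if (is.character(table)) {
        if (!file.exists(table))
            stop("count table not found: ", table)
        if (!is.null(metadata) && !file.exists(metadata))
            stop("metadata file not found: ", metadata)
        table <- readCountTable(table, metadata = metadata)
    }
    if (!is(table, "CommunityTable"))
        stop("table must be a CommunityTable or a TSV path")
    if (length(qGrid) == 0L)
        stop("qGrid must be non-empty")
    if (any(!is.finite(qGrid)) || any(qGrid < 0))
        stop("qGrid must be finite and non-negative")
    structure(list(table = table, qGrid = as.numeric(qGrid),
                   nPermutations = as.integer(nPermutations),
                   nIterations = as.integer(nIterations),
                   innerPermutations = as.integer(innerPermutations),
                   compareParameters = compareParameters,
                   seed = as.integer(seed), outdir = outdir,
                   compare = isTRUE(compare)),
              class = "darRunConfig")
}

#' Run the three-tier DAR analysis design
#'
#' Executes the full design over a cohort: (1) per-dataset fits, for each
#' dataset label present; (2) per-group fits, for each group label
#' (unioning datasets); (3) one pooled fit over all samples. Each tier
#' unit gets a full DAR/PDO/MAD/LGD profile via
#' \code{\link{buildProfiles}}; pairwise randomization comparisons between
#' groups are run for the configured parameters and diversity orders.
#' Tidy TSV tables, a JSON report carrying the derived seeds, and a run
#' log are written to the output directory; reruns with the same
#' configuration reproduce the outputs byte for byte.
#'
#' @param config a \code{\link{darRunConfig}}.
#' @return Invisibly, a list with elements `profiles` (data.frame, one row
#'   per tier unit and q) and `comparisons` (data.frame or `NULL`).
#' @export
runDesign <- function(config) {
    stopifnot(inherits(config, "darRunConfig"))
    x <- config$table
    groups <- sampleGroups(x)
    cd <- SummarizedExperiment::colData(x)
    datasets <- if ("dataset" %in% colnames(cd))
        stats::setNames(cd$dataset, sampleIDs(x)) else NULL

    units <- list(list(tier = "pooled", label = "all",
                       samples = sampleIDs(x)))
    if (!all(is.na(groups))) {
        for (gl in sort(unique(stats::na.omit(groups))))
            units <- c(units, list(list(tier = "group", label = gl,
                                        samples = names(groups)[
                                            !is.na(groups) &
                                            groups == gl])))
    }
    if (!is.null(datasets) && !all(is.na(datasets))) {
        for (dl in sort(unique(stats::na.omit(datasets))))
            units <- c(units, list(list(tier = "dataset", label = dl,
                                        samples = names(datasets)[
                                            !is.na(datasets) &
                                            datasets == dl])))
    }

    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    logPath <- file.path(config$outdir, "run.log")
    logLines <- c(paste("darscaling runDesign, master seed",
                        config$seed),
                  paste("tiers:", length(units), "profile units"))

    unitSeeds <- deriveSeeds(config$seed, length(units) + 1L)
    profRows <- list()
    for (i in seq_along(units)) {
        u <- units[[i]]
        logLines <- c(logLines, paste0("profiles: tier=", u$tier,
            " unit=", u$label, " n=", length(u$samples),
            " seed=", unitSeeds[[i]]))
        ps <- withCallingHandlers(
            buildProfiles(x, qGrid = config$qGrid,
                          nPermutations = config$nPermutations,
                          seed = unitSeeds[[i]], samples = u$samples),
            warning = function(w) {
                logLines <<- c(logLines, paste("warning:",
                                               conditionMessage(w)))
                invokeRestart("muffleWarning")
            })
        tab <- profileTable(ps)
        profRows[[i]] <- cbind(
            data.frame(tier = u$tier, unit = u$label,
                       n_samples = length(u$samples),
                       seed = unitSeeds[[i]]),
            tab)
    }
    profiles <- do.call(rbind, profRows)

    comparisons <- NULL
    glabs <- sort(unique(stats::na.omit(groups)))
    eligible <- glabs[vapply(glabs, function(gl)
        sum(!is.na(groups) & groups == gl) >= 4L, logical(1))]
    if (config$compare && length(eligible) >= 2L) {
        pairs <- utils::combn(eligible, 2L, simplify = FALSE)
        grid <- expand.grid(pair = seq_along(pairs),
                            parameter = config$compareParameters,
                            q = config$qGrid,
                            stringsAsFactors = FALSE)
        cmpSeeds <- deriveSeeds(unitSeeds[[length(units) + 1L]],
                                nrow(grid))
        rows <- lapply(seq_len(nrow(grid)), function(k) {
            pr <- pairs[[grid$pair[k]]]
            res <- compareGroups(x, pr[1L], pr[2L],
                parameter = grid$parameter[k], q = grid$q[k],
                nIterations = config$nIterations,
                innerPermutations = config$innerPermutations,
                seed = cmpSeeds[[k]])
            data.frame(group_a = pr[1L], group_b = pr[2L],
                       parameter = grid$parameter[k], q = grid$q[k],
                       observed_difference = res@observed,
                       p_value = res@pValue,
                       n_iterations = length(res@nullDiff),
                       n_skipped = res@nSkipped,
                       seed = cmpSeeds[[k]])
        })
        comparisons <- do.call(rbind, rows)
    }

    utils::write.table(profiles,
        file.path(config$outdir, "profiles.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(comparisons))
        utils::write.table(comparisons,
            file.path(config$outdir, "comparisons.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
        list(seed = config$seed, qGrid = config$qGrid,
             nPermutations = config$nPermutations,
             nIterations = config$nIterations,
             profiles = profiles, comparisons = comparisons),
        file.path(config$outdir, "report.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(logLines, logPath)

    invisible(list(profiles = profiles, comparisons = comparisons))
}
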