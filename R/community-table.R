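#' @include AllGenerics.R
NULL

#' Construct a CommunityTable from a samples-by-taxa count matrix
#'
#' The input matrix is oriented the way tabular OTU exports usually are:
#' one row per sample, one column per taxon. Internally the object stores
#' taxa as rows and samples as columns, following the
#' \linkS4class{SummarizedExperiment} convention.
#'
#' Samples whose row sum is zero carry no information for diversity
#' accumulation and are dropped with a warning; public OTU tables commonly
#' contain such rows.
#'
#' @param counts numeric matrix of non-negative whole numbers, samples as
#'   rows, with rownames (sample IDs) and colnames (taxon IDs). Missing
#'   dimnames are filled with `sample1..n` / `taxon1..m`.
#' @param groups optional group labels: either an unnamed vector aligned
#'   with the rows of `counts`, or a named vector / list mapping sample ID
#'   to label.
#' @param datasets optional dataset-of-origin labels, same conventions as
#'   `groups`.
#' @return A \linkS4class{CommunityTable}.
#' @examples
#' m <- matrix(rpois(30, 5), nrow = 3,
#'             dimnames = list(paste0("s", 1:3), paste0("t", 1:10)))
#' ct <- CommunityTable(m, groups = c("NT", "NT", "PT"))
#' sampleGroups(ct)
#' @export
CommunityTable <- function(counts, groups = NULL, datasets = NULL) {
    counts <- as.matrix(counts)
    if (!is.numeric(counts))
        stop("counts must be a numeric matrix")
    if (is.null(rownames(counts)))
        rownames(counts) <- paste0("sample", seq_len(nrow(counts)))
    if (is.null(colnames(counts)))
        colnames(counts) <- paste0("taxon", seq_len(ncol(counts)))
    if (anyDuplicated(rownames(counts)))
        stop("duplicated sample identifiers")
    if (anyDuplicated(colnames(counts)))
        stop("duplicated taxon identifiers")
    if (any(!is.finite(counts)) || any(counts < 0))
        stop("counts must be finite and non-negative")
    if (!isWholeNumber(counts))
        stop("counts must be whole numbers")

    groups <- .alignSampleAnnotation(groups, rownames(counts), "groups")
    datasets <- .alignSampleAnnotation(datasets, rownames(counts),
                                       "datasets")

    keep <- rowSums(counts) > 0
    if (!all(keep)) {
        warning(sum(!keep), " zero-read sample(s) dropped: ",
                paste(rownames(counts)[!keep], collapse = ", "))
        counts <- counts[keep, , drop = FALSE]
        groups <- groups[keep]
        datasets <- datasets[keep]
    }
    if (nrow(counts) == 0L)
        stop("no samples with positive read totals")

    cd <- S4Vectors::DataFrame(row.names = rownames(counts))
    if (!all(is.na(groups))) cd$group <- groups
    if (!all(is.na(datasets))) cd$dataset <- datasets
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = S4Vectors::SimpleList(counts = t(counts)),
        colData = cd)
    new("CommunityTable", se)
}

.alignSampleAnnotation <- function(ann, ids, what) {
    if (is.null(ann)) return(rep(NA_character_, length(ids)))
    ann <- unlist(ann)
    if (!is.null(names(ann))) {
        missing <- setdiff(ids, names(ann))
        out <- rep(NA_character_, length(ids))
        out[match(intersect(ids, names(ann)), ids)] <-
            as.character(ann[intersect(ids, names(ann))])
        if (length(missing))
            warning("no ", what, " annotation for sample(s): ",
                    paste(missing, collapse = ", "))
        return(out)
    }
    if (length(ann) != length(ids))
        stop(what, " must be named or match the number of samples")
    as.character(ann)
}

# samples-by-taxa numeric matrix view (the orientation the accumulation
# machinery works in)
.sampleMatrix <- function(x) {
    t(SummarizedExperiment::assay(x, "counts"))
}

#' @describeIn CommunityTable-class sample identifiers (one per area unit).
#' @param x a `CommunityTable`.
#' @export
setMethod("sampleIDs", "CommunityTable", function(x) colnames(x))

#' @describeIn CommunityTable-class taxon identifiers.
#' @export
setMethod("taxonIDs", "CommunityTable", function(x) rownames(x))

#' @describeIn CommunityTable-class group label per sample (`NA` where
#'   unannotated).
#' @export
setMethod("sampleGroups", "CommunityTable", function(x) {
    cd <- SummarizedExperiment::colData(x)
    if ("group" %in% colnames(cd)) {
        stats::setNames(cd$group, rownames(cd))
    } else {
        stats::setNames(rep(NA_character_, ncol(x)), colnames(x))
    }
})

#' @describeIn CommunityTable-class replace the group labels.
#' @param value replacement labels (unnamed, aligned with samples, or named
#'   by sample ID).
#' @export
setMethod("sampleGroups<-", "CommunityTable", function(x, value) {
    SummarizedExperiment::colData(x)$group <-
        .alignSampleAnnotation(value, colnames(x), "groups")
    validObject(x)
    x
})

#' @describeIn CommunityTable-class the taxa-by-samples count matrix.
#' @param object a `CommunityTable`.
#' @importMethodsFrom BiocGenerics counts
#' @export
setMethod("counts", "CommunityTable", function(object) {
    SummarizedExperiment::assay(object, "counts")
})

setMethod("show", "CommunityTable", function(object) {
    cat("CommunityTable with", ncol(object), "samples and",
        nrow(object), "taxa\n")
    g <- sampleGroups(object)
    if (!all(is.na(g))) {
        tab <- table(g, useNA = "no")
        cat("groups:", paste(names(tab), tab, sep = "=", collapse = " "),
            "\n")
    }
    cat("reads per sample: median",
        stats::median(colSums(counts(object))), "\n")
})

#' Merge community tables over the union of their taxa
#'
#' Samples are concatenated; counts for taxa absent from a table are zero.
#' Sample identifiers must be unique across the inputs. Group and dataset
#' annotations are carried along where present.
#'
#' @param ... two or more \linkS4class{CommunityTable} objects.
#' @return A \linkS4class{CommunityTable}.
#' @export
mergeCommunityTables <- function(...) {
    tabs <- list(...)
    if (length(tabs) == 1L && is.list(tabs[[1L]])) tabs <- tabs[[1L]]
    if (length(tabs) < 2L) stop("need at least two tables")
    if (!all(vapply(tabs, is, logical(1), "CommunityTable")))
        stop("all inputs must be CommunityTable objects")
    ids <- unlist(lapply(tabs, sampleIDs))
    if (anyDuplicated(ids))
        stop("sample identifiers collide across tables")
    taxa <- Reduce(union, lapply(tabs, taxonIDs))
    m <- matrix(0, nrow = length(ids), ncol = length(taxa),
                dimnames = list(ids, taxa))
    groups <- datasets <- rep(NA_character_, length(ids))
    at <- 0L
    for (tb in tabs) {
        sm <- .sampleMatrix(tb)
        idx <- at + seq_len(nrow(sm))
        m[idx, colnames(sm)] <- sm
        groups[idx] <- sampleGroups(tb)
        cd <- SummarizedExperiment::colData(tb)
        if ("dataset" %in% colnames(cd)) datasets[idx] <- cd$dataset
        at <- at + nrow(sm)
    }
    CommunityTable(m,
        groups = if (all(is.na(groups))) NULL else groups,
        datasets = if (all(is.na(datasets))) NULL else datasets)
}

#' Sample identifiers belonging to a group
#'
#' @param x a \linkS4class{CommunityTable}.
#' @param group a group label.
#' @return Character vector of sample IDs.
#' @export
samplesInGroup <- function(x, group) {
    g <- sampleGroups(x)
    names(g)[!is.na(g) & g == group]
}
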