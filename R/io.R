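#' @include community-table.R
NULL

#' Read a TSV count table
#'
#' Expects a tab-separated file whose first column holds sample IDs and
#' whose header row holds taxon IDs, with whole-number cells. If the file
#' is oriented the other way (taxa as rows), set `transpose = TRUE`; the
#' orientation is never guessed.
#'
#' @param path path to the TSV file.
#' @param transpose `TRUE` when rows are taxa and columns are samples.
#' @param metadata optional path to a sample-metadata TSV (see
#'   \code{\link{readSampleMetadata}}); its `group`/`dataset` columns are
#'   attached.
#' @return A \linkS4class{CommunityTable}.
#' @export
readCountTable <- function(path, transpose = FALSE, metadata = NULL) {
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- as.character(df[[1L]])
    storage.mode(m) <- "numeric"
    if (transpose) m <- t(m)
    groups <- datasets <- NULL
    if (!is.null(metadata)) {
        md <- readSampleMetadata(metadata)
        groups <- stats::setNames(md$group, md$sample_id)
        if ("dataset" %in% names(md))
            datasets <- stats::setNames(md$dataset, md$sample_id)
    }
    CommunityTable(m, groups = groups, datasets = datasets)
}

#' Write a CommunityTable as a TSV count table
#'
#' Writes samples as rows (first column `sample_id`, taxon IDs in the
#' header), the orientation \code{\link{readCountTable}} reads back by
#' default.
#'
#' @param x a \linkS4class{CommunityTable}.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCountTable <- function(x, path) {
    m <- .sampleMatrix(x)
    df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read a sample-metadata TSV
#'
#' A tab-separated file with columns `sample_id` and `group`, and
#' optionally `dataset` (study of origin).
#'
#' @param path path to the TSV file.
#' @return data.frame with character columns.
#' @export
readSampleMetadata <- function(path) {
    md <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = "character")
    need <- c("sample_id", "group")
    if (!all(need %in% names(md)))
        stop("metadata must contain columns: ",
             paste(need, collapse = ", "))
    if (anyDuplicated(md$sample_id))
        stop("duplicated sample_id in metadata")
    md
}

#' Write sample metadata for a CommunityTable
#'
#' @param x a \linkS4class{CommunityTable}.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSampleMetadata <- function(x, path) {
    cd <- SummarizedExperiment::colData(x)
    df <- data.frame(sample_id = sampleIDs(x),
                     group = if ("group" %in% colnames(cd)) cd$group
                             else NA_character_)
    if ("dataset" %in% colnames(cd)) df$dataset <- cd$dataset
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read a BIOM-format OTU table
#'
#' Delegates parsing to the biomformat package (JSON and HDF5 BIOM).
#'
#' @param path path to a BIOM file.
#' @param metadata optional sample-metadata TSV path.
#' @return A \linkS4class{CommunityTable}.
#' @export
readBiomTable <- function(path, metadata = NULL) {
    if (!requireNamespace("biomformat", quietly = TRUE))
        stop("reading BIOM files requires the 'biomformat' package")
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")  # taxa x samples
    groups <- datasets <- NULL
    if (!is.null(metadata)) {
        md <- readSampleMetadata(metadata)
        groups <- stats::setNames(md$group, md$sample_id)
        if ("dataset" %in% names(md))
            datasets <- stats::setNames(md$dataset, md$sample_id)
    }
    CommunityTable(t(m), groups = groups, datasets = datasets)
}
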