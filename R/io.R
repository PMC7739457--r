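#' Read an expression matrix
#'
#' Reads a genes x cells expression matrix from dense CSV/TSV (first column
#' gene identifiers, header row cell identifiers) or Matrix Market `.mtx`
#' with `genes.tsv` and `cells.tsv` sidecars (one identifier per line,
#' matching the matrix rows and columns in order; Matrix Market coordinates
#' are 1-based per the standard).
#'
#' @param path Matrix file path.
#' @param format `"auto"` (by extension), `"csv"`, `"tsv"` or `"mtx"`.
#' @param genesPath,cellsPath Sidecar paths for `.mtx` input (default:
#'   `genes.tsv` / `cells.tsv` next to the matrix).
#' @return A `SingleCellExperiment` with assay `counts` and the gene/cell
#'   identifiers as dimnames.
#' @seealso [writeExpressionMatrix()], [readCellLabels()]
#' @export
readExpressionMatrix <- function(path, format = c("auto", "csv", "tsv",
                                                  "mtx"),
                                 genesPath = NULL, cellsPath = NULL) {
    format <- match.arg(format)
    if (!file.exists(path))
        stop("file not found: ", path, call. = FALSE)
    if (format == "auto") {
        ext <- tolower(tools::file_ext(path))
        format <- switch(ext, csv = "csv", tsv = "tsv", txt = "tsv",
                         mtx = "mtx",
                         stop("cannot infer format from extension '.", ext,
                              "' of ", path, call. = FALSE))
    }
    if (format == "mtx") {
        if (is.null(genesPath)) genesPath <- file.path(dirname(path),
                                                       "genes.tsv")
        if (is.null(cellsPath)) cellsPath <- file.path(dirname(path),
                                                       "cells.tsv")
        for (p in c(genesPath, cellsPath))
            if (!file.exists(p))
                stop("missing sidecar for ", path, ": ", p, call. = FALSE)
        m <- as.matrix(Matrix::readMM(path))
        genes <- readLines(genesPath)
        cells <- readLines(cellsPath)
        if (length(genes) != nrow(m))
            stop(genesPath, " lists ", length(genes), " genes but ", path,
                 " has ", nrow(m), " rows", call. = FALSE)
        if (length(cells) != ncol(m))
            stop(cellsPath, " lists ", length(cells), " cells but ", path,
                 " has ", ncol(m), " columns", call. = FALSE)
        dimnames(m) <- list(genes, cells)
    } else {
        sep <- if (format == "csv") "," else "\t"
        df <- utils::read.table(path, header = TRUE, sep = sep,
                                row.names = 1L, check.names = FALSE,
                                stringsAsFactors = FALSE)
        bad <- which(!vapply(df, is.numeric, logical(1)))
        if (length(bad))
            stop("non-numeric expression column(s) in ", path, ": ",
                 paste(colnames(df)[bad], collapse = ", "), call. = FALSE)
        m <- as.matrix(df)
    }
    if (anyDuplicated(rownames(m)))
        stop("duplicate gene identifiers in ", path, call. = FALSE)
    if (anyDuplicated(colnames(m)))
        stop("duplicate cell identifiers in ", path, call. = FALSE)
    SingleCellExperiment::SingleCellExperiment(assays = list(counts = m))
}

#' Write an expression matrix
#'
#' Inverse of [readExpressionMatrix()]: dense CSV/TSV (gene identifiers in
#' the first column) or Matrix Market `.mtx` plus `genes.tsv` / `cells.tsv`
#' sidecars in the same directory.
#'
#' @param x A genes x cells matrix or `SummarizedExperiment`.
#' @param path Output matrix path.
#' @param format `"auto"` (by extension), `"csv"`, `"tsv"` or `"mtx"`.
#' @return `path`, invisibly.
#' @export
writeExpressionMatrix <- function(x, path, format = c("auto", "csv", "tsv",
                                                      "mtx")) {
    format <- match.arg(format)
    if (format == "auto")
        format <- switch(tolower(tools::file_ext(path)),
                         csv = "csv", tsv = "tsv", mtx = "mtx",
                         stop("cannot infer format from extension of ", path,
                              call. = FALSE))
    if (methods::is(x, "SummarizedExperiment"))
        x <- SummarizedExperiment::assay(x, 1L)
    x <- as.matrix(x)
    if (is.null(rownames(x))) rownames(x) <- paste0("gene_", seq_len(nrow(x)))
    if (is.null(colnames(x))) colnames(x) <- paste0("cell_", seq_len(ncol(x)))
    if (format == "mtx") {
        Matrix::writeMM(methods::as(Matrix::Matrix(x, sparse = TRUE),
                                    "generalMatrix"), path)
        writeLines(rownames(x), file.path(dirname(path), "genes.tsv"))
        writeLines(colnames(x), file.path(dirname(path), "cells.tsv"))
    } else {
        sep <- if (format == "csv") "," else "\t"
        df <- data.frame(gene_id = rownames(x), x, check.names = FALSE,
                         stringsAsFactors = FALSE)
        utils::write.table(df, path, sep = sep, quote = FALSE,
                           row.names = FALSE)
    }
    invisible(path)
}

#' Read per-cell labels
#'
#' Reads a TSV with header columns `cell_id`, `group` and optionally
#' `batch`. When a dataset is supplied the labels are joined to it by
#' `cell_id` (row order in the file is irrelevant); any dataset cell
#' without a label, or label without a dataset cell, is an error naming
#' the offenders.
#'
#' @param path Label TSV path.
#' @param x Optional `SingleCellExperiment` to annotate.
#' @return Without `x`, a data.frame of the label table; with `x`, the
#'   dataset with `group` (and `batch`) added to its `colData`.
#' @export
readCellLabels <- function(path, x = NULL) {
    if (!file.exists(path))
        stop("file not found: ", path, call. = FALSE)
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, check.names = FALSE)
    if (!all(c("cell_id", "group") %in% colnames(df)))
        stop(path, " must have header columns 'cell_id' and 'group'",
             call. = FALSE)
    dup <- df$cell_id[duplicated(df$cell_id)]
    if (length(dup))
        stop("duplicate cell_id in ", path, ": ",
             paste(unique(dup), collapse = ", "), call. = FALSE)
    if (is.null(x)) return(df)
    ids <- colnames(x)
    missing <- setdiff(ids, df$cell_id)
    if (length(missing))
        stop("no label for cell(s): ",
             paste(utils::head(missing, 5), collapse = ", "),
             if (length(missing) > 5) " ..." else "", call. = FALSE)
    extra <- setdiff(df$cell_id, ids)
    if (length(extra))
        stop("label file names unknown cell(s): ",
             paste(utils::head(extra, 5), collapse = ", "),
             if (length(extra) > 5) " ..." else "", call. = FALSE)
    ord <- match(ids, df$cell_id)
    SummarizedExperiment::colData(x)$group <- df$group[ord]
    if ("batch" %in% colnames(df))
        SummarizedExperiment::colData(x)$batch <- df$batch[ord]
    x
}

#' Write per-cell labels
#'
#' @param x A `SingleCellExperiment` with colData `group` (and optionally
#'   `batch`).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
writeCellLabels <- function(x, path) {
    cd <- SummarizedExperiment::colData(x)
    if (!"group" %in% colnames(cd))
        stop("dataset has no 'group' annotation", call. = FALSE)
    df <- data.frame(cell_id = colnames(x), group = cd$group,
                     stringsAsFactors = FALSE)
    if ("batch" %in% colnames(cd)) df$batch <- cd$batch
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
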