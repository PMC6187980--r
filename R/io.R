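#' @include AllClasses.R
NULL

#' Read an expression matrix into a PatchSeqExperiment
#'
#' TSV input has genes as rows and cells as columns, a header row of cell
#' identifiers and gene symbols in the first column. MatrixMarket input is a
#' triplet `.mtx` file with `genes.tsv` and `cells.tsv` sidecar files (one
#' identifier per line) next to it, in the 10x tradition. Duplicate gene
#' symbols are collapsed by summation (transcript-to-gene aggregation) with
#' a warning; negative values are rejected.
#'
#' @param path file path to the TSV or MTX file.
#' @param format `"tsv"` or `"mtx"`.
#' @param normalization normalization tag recorded on the object.
#' @param genesFile,cellsFile sidecar paths for `format = "mtx"`; default
#'   `genes.tsv` / `cells.tsv` in the directory of `path`.
#' @return A [PatchSeqExperiment-class].
#' @export
readExpression <- function(path, format = c("tsv", "mtx"),
                           normalization = c("TPM", "CPM_UMI", "FPKM", "RAW"),
                           genesFile = NULL, cellsFile = NULL) {
    format <- match.arg(format)
    normalization <- match.arg(normalization)
    if (!file.exists(path)) stop(sprintf("file not found: %s", path))
    if (format == "tsv") {
        tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                                 stringsAsFactors = FALSE)
        genes <- as.character(tab[[1L]])
        m <- as.matrix(tab[, -1L, drop = FALSE])
        storage.mode(m) <- "double"
        rownames(m) <- genes
    } else {
        dir <- dirname(path)
        if (is.null(genesFile)) genesFile <- file.path(dir, "genes.tsv")
        if (is.null(cellsFile)) cellsFile <- file.path(dir, "cells.tsv")
        m <- as.matrix(Matrix::readMM(path))
        genes <- readLines(genesFile)
        cells <- readLines(cellsFile)
        if (nrow(m) != length(genes) || ncol(m) != length(cells))
            stop(sprintf(
                "dimension mismatch: matrix is %d x %d but sidecars list %d genes, %d cells",
                nrow(m), ncol(m), length(genes), length(cells)))
        dimnames(m) <- list(genes, cells)
    }
    if (anyNA(m)) stop("expression matrix contains missing values")
    if (any(m < 0)) stop("negative expression values in ", path)
    if (anyDuplicated(rownames(m))) {
        ndup <- sum(duplicated(rownames(m)))
        warning(sprintf("%d duplicate gene symbols collapsed by summation", ndup))
        m <- rowsum(m, group = rownames(m), reorder = FALSE)
    }
    PatchSeqExperiment(m, normalization)
}

#' Read per-cell annotations
#'
#' Expects a headered TSV with required columns `cell_id` and `cell_type`;
#' optional `dataset` and `is_gabaergic_subtype` columns are interpreted,
#' any other columns are carried along untouched.
#'
#' @param path TSV file path.
#' @return A `DataFrame` with one row per cell, row names = `cell_id`.
#' @export
readAnnotations <- function(path) {
    tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
    for (col in c("cell_id", "cell_type"))
        if (!col %in% colnames(tab))
            stop(sprintf("missing required column '%s'", col))
    if (anyDuplicated(tab$cell_id))
        stop("duplicate cell id: ",
             paste(unique(tab$cell_id[duplicated(tab$cell_id)]), collapse = ", "))
    if (any(is.na(tab$cell_type) | !nzchar(tab$cell_type)))
        stop("empty cell_type field")
    if (!"is_gabaergic_subtype" %in% colnames(tab))
        tab$is_gabaergic_subtype <- FALSE
    tab$is_gabaergic_subtype <- as.logical(tab$is_gabaergic_subtype)
    ann <- as(tab, "DataFrame")
    rownames(ann) <- tab$cell_id
    ann
}

#' Attach cell annotations to a PatchSeqExperiment
#'
#' Every annotated `cell_id` must exist in the matrix; cells without
#' annotation keep `NA` fields.
#'
#' @param x a [PatchSeqExperiment-class].
#' @param ann annotations from [readAnnotations()] (or any data frame with
#'   `cell_id` and `cell_type`).
#' @return `x` with `colData` filled in.
#' @export
annotateCells <- function(x, ann) {
    ann <- as(ann, "DataFrame")
    if (is.null(rownames(ann)) && "cell_id" %in% colnames(ann))
        rownames(ann) <- ann$cell_id
    missing <- setdiff(rownames(ann), colnames(x))
    if (length(missing))
        stop("annotated cells absent from matrix: ",
             paste(utils::head(missing, 5L), collapse = ", "))
    idx <- match(colnames(x), rownames(ann))
    for (col in setdiff(colnames(ann), "cell_id"))
        colData(x)[[col]] <- ann[[col]][idx]
    validObject(x)
    x
}

#' Read per-cell read-accounting tables
#'
#' Required columns: `cell_id`, `library_size` (total sequenced reads),
#' `ercc_reads`, `mapped_reads`. An optional `detected_genes` column is kept
#' if present. Enforces `ercc_reads + mapped_reads <= library_size`.
#'
#' @param path TSV file path.
#' @return A `data.frame`.
#' @export
readReadAccounting <- function(path) {
    tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
    need <- c("cell_id", "library_size", "ercc_reads", "mapped_reads")
    for (col in need)
        if (!col %in% colnames(tab))
            stop(sprintf("missing required column '%s'", col))
    if (anyDuplicated(tab$cell_id)) stop("duplicate cell id")
    num <- c("library_size", "ercc_reads", "mapped_reads")
    if (any(tab[num] < 0)) stop("read counts must be nonnegative")
    bad <- tab$ercc_reads + tab$mapped_reads > tab$library_size
    if (any(bad))
        stop("ercc_reads + mapped_reads exceed library_size for: ",
             paste(utils::head(tab$cell_id[bad], 5L), collapse = ", "))
    tab
}

#' The electrophysiological feature vocabulary
#'
#' Input resistance (Rin, MOhm), resting membrane potential (Vrest, mV),
#' action potential threshold/amplitude/half-width (APthr, APamp in mV,
#' APhw in ms), membrane time constant (Tau, ms), after-hyperpolarization
#' amplitude (AHPamp, mV), rheobase (Rheo, pA), maximum firing rate
#' (FRmax, Hz) and capacitance (Cm, pF).
#'
#' @return Character vector of feature names.
#' @export
ephysFeatureVocabulary <- function() {
    c("Rin", "Vrest", "APthr", "APamp", "APhw", "Tau", "AHPamp", "Rheo",
      "FRmax", "Cm")
}

#' Read a per-cell electrophysiology feature table
#'
#' Headered TSV with a `cell_id` (or `type_id`) column followed by feature
#' columns drawn from [ephysFeatureVocabulary()] (missing values written as
#' `NA`). Each row must carry at least one non-missing feature.
#'
#' @param path TSV file path.
#' @param vocabulary allowed feature names.
#' @return A `data.frame` with the identifier column first.
#' @export
readEphys <- function(path, vocabulary = ephysFeatureVocabulary()) {
    tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
    idcol <- intersect(c("cell_id", "type_id"), colnames(tab))
    if (!length(idcol)) stop("missing required column 'cell_id' (or 'type_id')")
    idcol <- idcol[1L]
    feats <- setdiff(colnames(tab), idcol)
    unknown <- setdiff(feats, vocabulary)
    if (length(unknown))
        stop("unknown electrophysiology features: ",
             paste(unknown, collapse = ", "))
    if (!length(feats)) stop("no feature columns present")
    allNA <- apply(is.na(tab[feats]), 1L, all)
    if (any(allNA))
        stop("rows with no non-missing feature: ",
             paste(utils::head(tab[[idcol]][allNA], 5L), collapse = ", "))
    tab
}

#' Write and re-read per-cell score tables
#'
#' `writeScores` serializes [ContaminationProfiles-class] to a TSV with one
#' row per cell (`cell_id`, `cell_type`, one `CS_<type>` column per
#' off-target type, `contam_index`, `quality_score`,
#' `own_markers_detected`, `contaminated`); values round-trip through
#' `readScores` losslessly to well beyond 6 significant digits.
#'
#' @param profiles a [ContaminationProfiles-class] object.
#' @param path output TSV path.
#' @return `writeScores` returns `path` invisibly; `readScores` the parsed
#'   `data.frame`.
#' @export
writeScores <- function(profiles, path) {
    if (!is(profiles, "ContaminationProfiles"))
        stop("profiles must be a ContaminationProfiles object")
    if (length(profiles@cellId) == 0L) stop("no profiles")
    df <- scoreTable(profiles)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeScores
#' @export
readScores <- function(path) {
    utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
}

#' Serialize marker sets as JSON
#'
#' Schema: `{"markers": {type: [genes]}, "broad_types": [...],
#' "comparison_exclusions": {type: [types]}, "unusable_types": [...],
#' "thresholds": {...}}`.
#'
#' @param x a [MarkerSet-class].
#' @param path JSON file path.
#' @return `writeMarkerSet` returns `path` invisibly; `readMarkerSet` a
#'   [MarkerSet-class].
#' @export
writeMarkerSet <- function(x, path) {
    stopifnot(is(x, "MarkerSet"))
    obj <- list(markers = x@markers,
                broad_types = x@broadTypes,
                comparison_exclusions = x@comparisonExclusions,
                unusable_types = x@unusableTypes,
                thresholds = x@thresholds)
    jsonlite::write_json(obj, path, auto_unbox = FALSE, pretty = TRUE,
                         digits = NA)
    invisible(path)
}

#' @rdname writeMarkerSet
#' @export
readMarkerSet <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    asCharList <- function(x) lapply(as.list(x), as.character)
    MarkerSet(markers = asCharList(obj$markers),
              broadTypes = as.character(obj$broad_types),
              comparisonExclusions = asCharList(obj$comparison_exclusions),
              unusableTypes = as.character(obj$unusable_types),
              thresholds = as.list(obj$thresholds))
}

#' Counts-per-million normalization
#'
#' Scales each cell's counts to sum to one million. Cells with zero total
#' counts are left at zero with a warning.
#'
#' @param counts nonnegative genes x cells matrix.
#' @return Matrix of the same shape.
#' @export
cpmNormalize <- function(counts) {
    counts <- as.matrix(counts)
    tot <- colSums(counts)
    if (any(tot == 0)) {
        warning(sum(tot == 0), " cells with zero total counts left at zero")
        tot[tot == 0] <- 1
    }
    t(t(counts) / tot) * 1e6
}
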