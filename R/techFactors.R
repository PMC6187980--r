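#' @include AllClasses.R AllGenerics.R
NULL

#' Spike-in read ratio
#'
#' Reads mapping to the synthetic ERCC spike-in reference divided by the
#' library size (total sequenced reads). Because the same spike-in quantity
#' is added to each sample, this ratio inversely indexes how much cellular
#' mRNA was extracted.
#'
#' @param erccReads,librarySize nonnegative read counts (vectorized).
#' @return Fractions in `[0, 1]`.
#' @export
spikeInRatio <- function(erccReads, librarySize) {
    if (any(librarySize == 0)) stop("library size must be positive")
    if (any(erccReads > librarySize))
        stop("ercc reads exceed library size")
    if (any(erccReads < 0 | librarySize < 0)) stop("read counts must be nonnegative")
    erccReads / librarySize
}

#' Unmapped read ratio
#'
#' Reads mapping to neither the transcriptome nor the spike-in reference,
#' divided by the library size minus the spike-in count — the fraction of
#' the cellular-side reads that were too low quality to map.
#'
#' @param librarySize,mappedReads,erccReads nonnegative read counts
#'   (vectorized).
#' @return Fractions in `[0, 1]`.
#' @export
unmappedRatio <- function(librarySize, mappedReads, erccReads) {
    if (any(mappedReads + erccReads > librarySize))
        stop("mapped + ercc reads exceed library size")
    denom <- librarySize - erccReads
    if (any(denom <= 0)) stop("library size minus ercc count must be positive")
    (librarySize - mappedReads - erccReads) / denom
}

#' Number of genes detected in a cell
#'
#' Genes with expression strictly above `threshold`, optionally restricted
#' to a protein-coding universe.
#'
#' @param x expression vector, genes x cells matrix, or
#'   [PatchSeqExperiment-class].
#' @param proteinCoding optional gene universe to restrict to.
#' @param threshold detection threshold (default 0).
#' @return Integer count, or a named vector of counts per cell.
#' @export
detectedGeneCount <- function(x, proteinCoding = NULL, threshold = 0) {
    if (is(x, "PatchSeqExperiment")) x <- exprValues(x)
    if (!is.matrix(x)) {
        if (!is.null(proteinCoding))
            x <- x[names(x) %in% proteinCoding]
        return(sum(x > threshold))
    }
    if (!is.null(proteinCoding))
        x <- x[rownames(x) %in% proteinCoding, , drop = FALSE]
    colSums(x > threshold)
}

#' Assemble the per-cell technical-factor table
#'
#' Joins a read-accounting table with contamination indices into the record
#' layout used by [fitFactorModel()]. `detected_genes` is taken from the
#' accounting table when present, otherwise computed from `expr`.
#'
#' @param accounting `data.frame` from [readReadAccounting()].
#' @param profiles [ContaminationProfiles-class] for the same cells.
#' @param expr optional [PatchSeqExperiment-class] for detected-gene counts.
#' @param proteinCoding optional gene universe for the detected-gene count.
#' @return `data.frame` with columns `cell_id`, `library_size`,
#'   `spike_in_ratio`, `unmapped_ratio`, `contam_index`, `detected_genes`.
#' @export
techFactorTable <- function(accounting, profiles, expr = NULL,
                            proteinCoding = NULL) {
    idx <- match(accounting$cell_id, profiles@cellId)
    if (anyNA(idx))
        stop("cells missing contamination profiles: ",
             paste(utils::head(accounting$cell_id[is.na(idx)], 5L), collapse = ", "))
    dg <- accounting$detected_genes
    if (is.null(dg)) {
        if (is.null(expr)) stop("need detected_genes column or an expression matrix")
        dg <- detectedGeneCount(expr, proteinCoding)[accounting$cell_id]
    }
    data.frame(cell_id = accounting$cell_id,
               library_size = accounting$library_size,
               spike_in_ratio = spikeInRatio(accounting$ercc_reads,
                                             accounting$library_size),
               unmapped_ratio = unmappedRatio(accounting$library_size,
                                              accounting$mapped_reads,
                                              accounting$ercc_reads),
               contam_index = profiles@contamIndex[idx],
               detected_genes = as.numeric(dg),
               stringsAsFactors = FALSE)
}

.zscore <- function(x) (x - mean(x)) / stats::sd(x)

#' Fit the standardized detected-genes model
#'
#' Ordinary least squares of the detected-gene count on technical factors
#' (library size, spike-in ratio, unmapped ratio, contamination index),
#' with every term — response included — first scaled to z-scores (sample
#' standard deviation, n-1), yielding standardized beta coefficients
#' directly comparable across factors. Cells without spike-ins carry no
#' information about mRNA content and are excluded when
#' `requireSpikeIns = TRUE`.
#'
#' @param records `data.frame` from [techFactorTable()] (columns
#'   `detected_genes` plus the requested factors).
#' @param factors subset of `library_size`, `spike_in_ratio`,
#'   `unmapped_ratio`, `contam_index`.
#' @param requireSpikeIns drop cells with zero or missing spike-in reads.
#' @return A [RegressionResult-class]; standardized betas, their standard
#'   errors, and the fraction of variance explained.
#' @export
fitFactorModel <- function(records,
                           factors = c("library_size", "spike_in_ratio",
                                       "unmapped_ratio", "contam_index"),
                           requireSpikeIns = TRUE) {
    factors <- match.arg(factors, several.ok = TRUE)
    missingCols <- setdiff(c("detected_genes", factors), colnames(records))
    if (length(missingCols))
        stop("missing columns: ", paste(missingCols, collapse = ", "))
    if (requireSpikeIns && "spike_in_ratio" %in% colnames(records)) {
        keep <- !is.na(records$spike_in_ratio) & records$spike_in_ratio > 0
        records <- records[keep, , drop = FALSE]
    }
    records <- records[stats::complete.cases(records[c("detected_genes", factors)]), ,
                       drop = FALSE]
    if (nrow(records) < 10L)
        stop("need at least 10 cells with complete technical factors")
    dropped <- factors[vapply(records[factors], stats::sd, 0) == 0]
    if (length(dropped)) {
        warning("zero-variance factors dropped: ",
                paste(dropped, collapse = ", "))
        factors <- setdiff(factors, dropped)
    }
    if (!length(factors)) stop("no factors with nonzero variance")
    z <- as.data.frame(lapply(records[c("detected_genes", factors)], .zscore))
    fit <- stats::lm(detected_genes ~ ., data = z)
    coefs <- stats::coef(fit)
    if (anyNA(coefs)) stop("rank-deficient design: ",
                           paste(names(coefs)[is.na(coefs)], collapse = ", "))
    sm <- summary(fit)
    betas <- coefs[factors]
    new("RegressionResult",
        coefficients = betas,
        stdErrors = setNames(sm$coefficients[factors, "Std. Error"], factors),
        rSquared = sm$r.squared,
        nCells = nrow(records),
        dropped = dropped)
}

#' @describeIn fitFactorModel variance explained, as the percentage
#'   reported alongside the standardized coefficients.
#' @param fit a [RegressionResult-class].
#' @export
percentVarianceExplained <- function(fit) {
    stopifnot(is(fit, "RegressionResult"))
    100 * fit@rSquared
}

#' Serialize a fitted factor model
#'
#' One row per factor (`factor`, `beta`, `std_error`) plus a summary row
#' carrying `r_squared` and `n_cells`.
#'
#' @param fit a [RegressionResult-class].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeFactorModel <- function(fit, path) {
    df <- data.frame(factor = names(fit@coefficients),
                     beta = unname(fit@coefficients),
                     std_error = unname(fit@stdErrors),
                     r_squared = NA_real_, n_cells = NA_integer_)
    df <- rbind(df, data.frame(factor = "(model)", beta = NA_real_,
                               std_error = NA_real_,
                               r_squared = fit@rSquared,
                               n_cells = fit@nCells))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
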