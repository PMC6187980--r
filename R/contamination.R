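#' @include AllClasses.R AllGenerics.R
NULL

#' Summed log-scale marker expression
#'
#' For each cell, the sum over a marker list of `log2(expression + 1)`; the
#' pseudocount of 1 keeps the logarithm defined at zero. Markers absent
#' from the matrix are dropped with a warning; an entirely absent list is
#' an error.
#'
#' @param x normalized expression: a named numeric vector (one cell), a
#'   genes x cells matrix, or a [PatchSeqExperiment-class].
#' @param markers character vector of marker genes.
#' @param sourceType optional label used in messages.
#' @return Named numeric vector, one marker sum per cell.
#' @examples
#' markerSum(c(g1 = 3, g2 = 7), c("g1", "g2"))  # log2(4) + log2(8) = 5
#' @export
markerSum <- function(x, markers, sourceType = NULL) {
    if (is(x, "PatchSeqExperiment")) x <- exprValues(x)
    if (!is.matrix(x)) x <- matrix(x, ncol = 1L,
                                   dimnames = list(names(x), "cell"))
    present <- intersect(markers, rownames(x))
    label <- if (is.null(sourceType)) "" else sprintf(" for type '%s'", sourceType)
    if (!length(present))
        stop(sprintf("none of the %d markers%s are present in the matrix",
                     length(markers), label))
    if (length(present) < length(unique(markers)))
        warning(sprintf("%d markers%s absent from matrix and dropped",
                        length(unique(markers)) - length(present), label))
    colSums(log2(x[present, , drop = FALSE] + 1))
}

#' Compute dissociated-cell marker baselines
#'
#' For every pair (cell type `A`, marker source type `B`), the median over
#' reference cells of type `A` of the summed log2 expression of `B`'s
#' markers ([markerSum()]). Pairs where the source type's own baseline does
#' not exceed the assessed type's (`d[B, B] <= d[A, B]`) are flagged
#' degenerate: those markers cannot discriminate contamination.
#'
#' @param ref annotated reference [PatchSeqExperiment-class].
#' @param markerSet a [MarkerSet-class]; baselines are computed for every
#'   type carrying a marker list.
#' @param assessedTypes cell types to compute baselines for; defaults to
#'   every annotated type in `ref`.
#' @return A [ReferenceBaseline-class].
#' @export
computeBaselines <- function(ref, markerSet, assessedTypes = NULL) {
    types <- cellTypes(ref)
    if (is.null(assessedTypes)) assessedTypes <- sort(unique(types))
    counts <- table(types)[assessedTypes]
    if (any(is.na(counts) | counts < 2L))
        stop("every assessed type needs >= 2 reference cells: ",
             paste(assessedTypes[is.na(counts) | counts < 2L], collapse = ", "))
    sources <- names(markerGenes(markerSet))
    expr <- exprValues(ref)
    d <- matrix(NA_real_, length(assessedTypes), length(sources),
                dimnames = list(assessedTypes, sources))
    for (B in sources) {
        ms <- markerSum(expr, markerGenes(markerSet, B), sourceType = B)
        d[, B] <- vapply(assessedTypes,
                         function(A) stats::median(ms[types == A]), 0)
    }
    degenerate <- matrix(FALSE, nrow(d), ncol(d), dimnames = dimnames(d))
    for (B in intersect(sources, assessedTypes))
        degenerate[, B] <- d[, B] >= d[B, B] & rownames(d) != B
    new("ReferenceBaseline", d = d, degenerate = degenerate)
}

#' Contamination score of one off-target type in one cell
#'
#' The excess of the cell's summed off-target marker expression over the
#' dissociated-cell baseline for its own type, scaled by the off-target
#' type's own marker level: `(M - d_AB) / (d_BB - d_AB)`. Negative values
#' (no detected contamination) are floored at 0; with `cap = TRUE` (the
#' default, matching the 0-1 interpretation of the score) values above 1
#' are capped. When the markers do not discriminate (`d_BB <= d_AB`) the
#' score is missing.
#'
#' @param M summed log2 off-target marker expression of the cell
#'   ([markerSum()]); may be a vector over cells.
#' @param dAB baseline of the off-target markers in the cell's own type.
#' @param dBB baseline of the off-target markers in the off-target type.
#' @param cap cap scores at 1 (default `TRUE`).
#' @return Numeric vector of scores in `[0, 1]` (or unbounded above when
#'   `cap = FALSE`); `NA` for degenerate baselines.
#' @examples
#' contaminationScore(5, 1, 9)    # 0.5
#' contaminationScore(0.5, 1, 9)  # floored at 0
#' @export
contaminationScore <- function(M, dAB, dBB, cap = TRUE) {
    if (!is.finite(dAB) || !is.finite(dBB) || dBB <= dAB) {
        warning("non-discriminative markers (d_BB <= d_AB); score set to missing")
        return(rep(NA_real_, length(M)))
    }
    cs <- pmax(0, (M - dAB) / (dBB - dAB))
    if (cap) cs <- pmin(1, cs)
    cs
}

#' Contamination index of a cell
#'
#' The sum of the cell's non-missing contamination scores across off-target
#' broad types. GABAergic marker sources are excluded when the cell itself
#' is a GABAergic subtype (inhibitory-to-inhibitory contamination is not
#' assessed).
#'
#' @param cs named numeric vector of contamination scores by source type
#'   (missing values are skipped).
#' @param isGabaergic is the cell a GABAergic subtype?
#' @param gabaergicSources source types that are GABAergic.
#' @return Nonnegative scalar.
#' @examples
#' contaminationIndex(c(Pyramidal = 0.5, Microglia = 0.25, Astrocyte = 0))
#' @export
contaminationIndex <- function(cs, isGabaergic = FALSE,
                               gabaergicSources = character()) {
    if (isGabaergic && length(gabaergicSources))
        cs <- cs[setdiff(names(cs), gabaergicSources)]
    nMissing <- sum(is.na(cs))
    if (nMissing)
        message(nMissing, " missing contamination scores skipped")
    sum(cs, na.rm = TRUE)
}

#' Marker-correlation quality score of a cell
#'
#' Spearman rank correlation (ties get average ranks) between the cell's
#' expression over the combined on/off marker panel and the mean
#' dissociated-cell profile of its own type, floored at `floor`. Low values
#' flag both visible off-target contamination and cells whose endogenous
#' markers are weakly expressed. Expression enters as `log2(x + 1)`
#' (rank correlation is unaffected by the monotone transform; the scale
#' matches the marker sums).
#'
#' @param cellExpr named expression vector of the cell (or vector aligned
#'   with `refMeanProfile`).
#' @param refMeanProfile mean reference expression over the marker panel
#'   for the cell's type.
#' @param floor minimum returned score (default 0.1).
#' @return Scalar in `[floor, 1]`.
#' @export
qualityScore <- function(cellExpr, refMeanProfile, floor = 0.1) {
    if (!is.null(names(cellExpr)) && !is.null(names(refMeanProfile))) {
        shared <- intersect(names(refMeanProfile), names(cellExpr))
        cellExpr <- cellExpr[shared]
        refMeanProfile <- refMeanProfile[shared]
    }
    if (length(cellExpr) < 5L)
        stop("marker panel must share at least 5 genes between cell and reference")
    x <- log2(cellExpr + 1)
    y <- log2(refMeanProfile + 1)
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
        warning("zero-variance marker panel; quality score floored")
        return(floor)
    }
    max(floor, stats::cor(x, y, method = "spearman"))
}

#' Score every patch-seq cell for contamination and quality
#'
#' For each cell: marker sums for every marker-source type, contamination
#' scores for every applicable broad off-target type (skipping the cell's
#' own type, the types excluded from its comparisons — e.g. GABAergic
#' sources for GABAergic cells — and degenerate baseline pairs), their sum
#' (contamination index), the marker-panel quality score against the mean
#' dissociated-cell profile of the cell's type, and a contamination call
#' (any score above `csThreshold`).
#'
#' @param patchseq annotated patch-seq [PatchSeqExperiment-class].
#' @param markerSet a [MarkerSet-class].
#' @param baselines matching [ReferenceBaseline-class] from
#'   [computeBaselines()].
#' @param ref the reference [PatchSeqExperiment-class] (for the mean marker
#'   profiles behind the quality score).
#' @param typeMap optional named character vector translating patch-seq
#'   cell type labels to reference type labels.
#' @param csThreshold contamination calling threshold on single scores
#'   (default 0.5).
#' @param cap cap contamination scores at 1.
#' @param qualityFloor floor for the quality score.
#' @param minOwnMarkers,dropLowMarkerCells cells expressing fewer than
#'   `minOwnMarkers` of their own type's markers are dropped when
#'   `dropLowMarkerCells = TRUE` (otherwise only counted in the output).
#' @return A [ContaminationProfiles-class].
#' @export
scoreCells <- function(patchseq, markerSet, baselines, ref, typeMap = NULL,
                       csThreshold = 0.5, cap = TRUE, qualityFloor = 0.1,
                       minOwnMarkers = 3L, dropLowMarkerCells = FALSE) {
    if (!identical(normalizationTag(patchseq), normalizationTag(ref)))
        warning(sprintf(
            "normalization mismatch: patch-seq is %s but reference is %s",
            normalizationTag(patchseq), normalizationTag(ref)))
    types <- cellTypes(patchseq)
    refTypes <- if (is.null(typeMap)) types else {
        mapped <- unname(typeMap[types])
        ifelse(is.na(mapped), types, mapped)
    }
    d <- baselineMatrix(baselines)
    known <- rownames(d)[rownames(d) %in% names(markerGenes(markerSet))]
    bad <- !(refTypes %in% known)
    if (any(bad))
        stop("cells with unmapped cell types: ",
             paste(utils::head(colnames(patchseq)[bad], 5L), collapse = ", "),
             " (types: ", paste(unique(refTypes[bad]), collapse = ", "), ")")

    expr <- exprValues(patchseq)
    sources <- names(markerGenes(markerSet))
    Ms <- vapply(sources, function(B)
        markerSum(expr, markerGenes(markerSet, B), sourceType = B),
        numeric(ncol(expr)))
    if (!is.matrix(Ms)) Ms <- matrix(Ms, nrow = 1L, dimnames = list(colnames(expr), sources))

    offTypes <- setdiff(broadCellTypes(markerSet), markerSet@unusableTypes)
    cs <- matrix(NA_real_, ncol(expr), length(offTypes),
                 dimnames = list(colnames(expr), offTypes))
    excl <- markerSet@comparisonExclusions
    nDegenerate <- 0L
    for (i in seq_len(ncol(expr))) {
        A <- refTypes[i]
        skip <- c(A, excl[[A]] %||% character())
        for (B in setdiff(offTypes, skip)) {
            if (baselines@degenerate[A, B]) { nDegenerate <- nDegenerate + 1L; next }
            cs[i, B] <- suppressWarnings(
                contaminationScore(Ms[i, B], d[A, B], d[B, B], cap = cap))
        }
    }
    if (nDegenerate)
        warning(nDegenerate,
                " cell/type pairs skipped for non-discriminative markers")
    ci <- rowSums(cs, na.rm = TRUE)

    # quality: cell vs mean dissociated profile of its type over the full panel
    panel <- unique(unlist(markerGenes(markerSet), use.names = FALSE))
    panel <- intersect(panel, intersect(rownames(expr), rownames(ref)))
    refExpr <- exprValues(ref)[panel, , drop = FALSE]
    refTypeLabels <- cellTypes(ref)
    refMeans <- vapply(unique(refTypes), function(A)
        rowMeans(refExpr[, refTypeLabels == A, drop = FALSE]),
        numeric(length(panel)))
    qs <- vapply(seq_len(ncol(expr)), function(i)
        qualityScore(expr[panel, i], setNames(refMeans[, refTypes[i]], panel),
                     floor = qualityFloor), 0)

    own <- vapply(seq_len(ncol(expr)), function(i) {
        mk <- intersect(markerGenes(markerSet, refTypes[i]), rownames(expr))
        sum(expr[mk, i] > 0)
    }, 0L)

    keep <- rep(TRUE, ncol(expr))
    if (dropLowMarkerCells) {
        keep <- own >= minOwnMarkers
        if (any(!keep))
            message(sum(!keep), " cells dropped for expressing fewer than ",
                    minOwnMarkers, " of their own type's markers")
    }
    new("ContaminationProfiles",
        cellId = colnames(expr)[keep], cellType = unname(refTypes[keep]),
        markerSums = Ms[keep, , drop = FALSE], cs = cs[keep, , drop = FALSE],
        contamIndex = unname(ci[keep]), qualityScore = qs[keep],
        ownMarkersDetected = as.integer(own[keep]),
        contaminated = unname(apply(cs[keep, , drop = FALSE] > csThreshold,
                                    1L, any, na.rm = TRUE)),
        threshold = csThreshold)
}
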