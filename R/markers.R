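#' @include AllClasses.R AllGenerics.R
NULL

.typeMeans <- function(expr, types) {
    grp <- split(seq_along(types), types)
    out <- vapply(grp, function(ix) rowMeans(expr[, ix, drop = FALSE]),
                  numeric(nrow(expr)))
    if (!is.matrix(out))
        out <- matrix(out, nrow = nrow(expr),
                      dimnames = list(rownames(expr), names(grp)))
    out
}

.detectionFrac <- function(expr, cells, cutoff) {
    rowMeans(expr[, cells, drop = FALSE] > cutoff)
}

#' Select "on" marker genes for a cell type
#'
#' "On" markers are highly and ubiquitously expressed in the type of
#' interest with enriched expression relative to other types. A gene passes
#' when (i) its mean expression in `targetType` exceeds
#' `foldChange` times its mean in every other non-excluded type
#' (`compare = "each"`, the default strict reading) or in the pooled mean of
#' all other cells (`compare = "pooled"`); (ii) its mean in the target type
#' exceeds `minMean`; and (iii) it is expressed above `prevalenceExpr` in
#' strictly more than `prevalenceFrac` of the target type's cells. A zero
#' mean in a comparison type counts as passing (infinite enrichment). For
#' GABAergic subtypes, pass the other GABAergic types via `exclusions` so
#' they are skipped in the comparison.
#'
#' @param ref reference [PatchSeqExperiment-class] with `cell_type`
#'   annotation, or a list of them (markers must then survive in every
#'   dataset; the result keeps the first dataset's ordering).
#' @param targetType the cell type to find markers for.
#' @param thresholds a [MarkerThresholds-class] (or a list of them parallel
#'   to `ref` when `ref` is a list, e.g. [umiThresholds()] for a `CPM_UMI`
#'   dataset).
#' @param exclusions cell types excluded from the enrichment comparison.
#' @param compare `"each"` or `"pooled"` (see above).
#' @return Character vector of gene symbols, sorted by descending fold
#'   change; empty (with a warning) when no gene passes.
#' @export
selectOnMarkers <- function(ref, targetType, thresholds = markerThresholds(),
                            exclusions = character(),
                            compare = c("each", "pooled")) {
    compare <- match.arg(compare)
    if (is.list(ref) && !is(ref, "PatchSeqExperiment")) {
        if (!is.list(thresholds)) thresholds <- rep(list(thresholds), length(ref))
        lists <- mapply(function(r, th)
            selectOnMarkers(r, targetType, th, exclusions, compare),
            ref, thresholds, SIMPLIFY = FALSE)
        keep <- Reduce(intersect, lists[-1L], lists[[1L]])
        return(lists[[1L]][lists[[1L]] %in% keep])
    }
    th <- thresholds
    types <- cellTypes(ref)
    keepCells <- !(types %in% setdiff(exclusions, targetType))
    expr <- exprValues(ref)[, keepCells, drop = FALSE]
    types <- types[keepCells]
    if (!targetType %in% types)
        stop(sprintf("target type '%s' not present in reference", targetType))
    if (length(unique(types)) < 2L)
        stop("need at least 2 cell types after exclusions")
    tm <- .typeMeans(expr, types)
    target <- tm[, targetType]
    others <- tm[, setdiff(colnames(tm), targetType), drop = FALSE]

    if (compare == "each") {
        # zero mean in the other type counts as infinitely enriched
        each <- vapply(seq_len(ncol(others)), function(j) {
            o <- others[, j]
            o == 0 | target > th@foldChange * o
        }, logical(length(target)))
        if (!is.matrix(each)) each <- matrix(each, nrow = length(target))
        enriched <- rowSums(!each) == 0L
        worst <- apply(others, 1L, max)
    } else {
        pooled <- rowMeans(expr[, types != targetType, drop = FALSE])
        enriched <- pooled == 0 | target > th@foldChange * pooled
        worst <- pooled
    }
    prev <- .detectionFrac(expr, types == targetType, th@prevalenceExpr)
    pass <- enriched & target > th@minMean & prev > th@prevalenceFrac
    genes <- rownames(expr)[pass]
    if (!length(genes)) {
        warning(sprintf("no genes pass the on-marker thresholds for '%s'",
                        targetType))
        return(character())
    }
    fc <- ifelse(worst[pass] == 0, Inf, target[pass] / worst[pass])
    genes[order(-fc, genes)]
}

#' Filter candidate "off" marker genes against reference data
#'
#' "Off" markers for a broad contamination-source type are genes specific to
#' that type whose presence in a patch-seq cell of another type signals
#' contamination. Starting from a candidate list (for example a published
#' cell type marker list, or [selectOnMarkers()] output for the source
#' type), genes are retained when they are (i) expressed above
#' `offLowExpr` in strictly more than `offLowFrac` of the source type's
#' reference cells (drops lowly expressed candidates) and (ii) expressed
#' above `offTargetExpr` in at most `offTargetFrac` of the cells of every
#' protected patch-seq target type (drops genes moderately expressed in the
#' types being assessed).
#'
#' @param initial nonempty character vector of candidate genes.
#' @param ref reference [PatchSeqExperiment-class] (or list, intersected as
#'   in [selectOnMarkers()]).
#' @param sourceType the contamination-source type the markers belong to.
#' @param protectedTypes patch-seq target types the markers must not be
#'   moderately expressed in.
#' @param thresholds a [MarkerThresholds-class] (or parallel list).
#' @return The retained genes, in `initial` order. Candidates absent from
#'   the reference are dropped with a warning.
#' @export
filterOffMarkers <- function(initial, ref, sourceType, protectedTypes,
                             thresholds = markerThresholds()) {
    if (!length(initial)) stop("empty initial marker list")
    if (is.list(ref) && !is(ref, "PatchSeqExperiment")) {
        if (!is.list(thresholds)) thresholds <- rep(list(thresholds), length(ref))
        lists <- mapply(function(r, th)
            filterOffMarkers(initial, r, sourceType, protectedTypes, th),
            ref, thresholds, SIMPLIFY = FALSE)
        return(initial[initial %in% Reduce(intersect, lists)])
    }
    th <- thresholds
    expr <- exprValues(ref)
    types <- cellTypes(ref)
    absent <- setdiff(initial, rownames(expr))
    if (length(absent))
        warning(sprintf("%d candidate markers absent from reference: %s",
                        length(absent),
                        paste(utils::head(absent, 5L), collapse = ", ")))
    genes <- intersect(initial, rownames(expr))
    if (!sourceType %in% types)
        stop(sprintf("source type '%s' not present in reference", sourceType))
    srcFrac <- .detectionFrac(expr[genes, , drop = FALSE],
                              types == sourceType, th@offLowExpr)
    keep <- srcFrac > th@offLowFrac
    for (pt in protectedTypes) {
        if (!pt %in% types)
            stop(sprintf("protected type '%s' not present in reference", pt))
        ptFrac <- .detectionFrac(expr[genes, , drop = FALSE],
                                 types == pt, th@offTargetExpr)
        keep <- keep & ptFrac <= th@offTargetFrac
    }
    genes[keep]
}

#' Build a full marker set from reference data
#'
#' Composes [selectOnMarkers()] and [filterOffMarkers()] into the per-type
#' marker lists used for contamination scoring. Target (patch-seq) types get
#' "on" marker lists; broad contamination-source types get "off" lists —
#' their own on-markers (or user-supplied candidate lists via
#' `offCandidates`, standing in for published marker collections) passed
#' through the off-marker filters with the target types protected.
#' GABAergic subtypes are not compared with each other; a gene qualifying
#' for more than one broad type is removed from all of them; a broad type
#' ending with fewer than `minMarkers` genes is flagged unusable with a
#' warning.
#'
#' @param ref reference [PatchSeqExperiment-class] or list of them.
#' @param targetTypes patch-seq target cell types.
#' @param broadTypes broad contamination-source types.
#' @param gabaergicTypes which of the types are GABAergic subtypes
#'   (mutually excluded from each other's comparisons).
#' @param thresholds [MarkerThresholds-class] or parallel list.
#' @param offCandidates optional named list of candidate off-marker vectors
#'   per broad type.
#' @param compare fold-change comparison mode, see [selectOnMarkers()].
#' @param minMarkers minimum usable list size for a broad type.
#' @return A [MarkerSet-class].
#' @export
buildMarkerSet <- function(ref, targetTypes, broadTypes,
                           gabaergicTypes = character(),
                           thresholds = markerThresholds(),
                           offCandidates = NULL,
                           compare = c("each", "pooled"),
                           minMarkers = 3L) {
    compare <- match.arg(compare)
    exclusions <- list()
    for (t in intersect(gabaergicTypes, c(targetTypes, broadTypes)))
        exclusions[[t]] <- setdiff(gabaergicTypes, t)

    allTypes <- union(targetTypes, broadTypes)
    onLists <- lapply(setNames(allTypes, allTypes), function(t)
        selectOnMarkers(ref, t, thresholds,
                        exclusions = exclusions[[t]] %||% character(),
                        compare = compare))

    markers <- onLists[targetTypes]
    for (b in broadTypes) {
        cand <- offCandidates[[b]] %||% onLists[[b]]
        markers[[b]] <- if (length(cand))
            filterOffMarkers(cand, ref, b, protectedTypes = targetTypes,
                             thresholds = thresholds)
        else character()
    }

    # uniqueness rule: a gene passing for several broad types discriminates
    # none of them
    broadGenes <- unlist(markers[broadTypes], use.names = FALSE)
    shared <- unique(broadGenes[duplicated(broadGenes)])
    if (length(shared)) {
        warning(sprintf("%d genes qualified for multiple broad types and were removed: %s",
                        length(shared),
                        paste(utils::head(shared, 5L), collapse = ", ")))
        for (b in broadTypes) markers[[b]] <- setdiff(markers[[b]], shared)
    }

    unusable <- union(intersect(broadTypes,
                                names(markers)[lengths(markers) < minMarkers]),
                      names(markers)[lengths(markers) == 0L])
    if (length(unusable))
        warning("types flagged unusable (fewer than ", minMarkers,
                " markers): ", paste(unusable, collapse = ", "))

    thList <- if (is.list(thresholds)) lapply(thresholds, .thresholdsAsList)
              else .thresholdsAsList(thresholds)
    MarkerSet(markers = markers, broadTypes = broadTypes,
              comparisonExclusions = exclusions, unusableTypes = unusable,
              thresholds = thList)
}

.thresholdsAsList <- function(th) {
    list(fold_change = th@foldChange, min_mean = th@minMean,
         prevalence_expr = th@prevalenceExpr, prevalence_frac = th@prevalenceFrac,
         off_low_expr = th@offLowExpr, off_low_frac = th@offLowFrac,
         off_target_expr = th@offTargetExpr, off_target_frac = th@offTargetFrac)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
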