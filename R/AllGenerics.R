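#' @include AllClasses.R
NULL

#' Accessors for scPatchQC classes
#'
#' `normalizationTag` returns the normalization of a
#' [PatchSeqExperiment-class]; `cellTypes` gets/sets the broad cell type
#' annotation; `exprValues` returns the normalized expression matrix;
#' `markerGenes` extracts marker lists from a [MarkerSet-class];
#' `broadCellTypes` the contamination-source types; `baselineMatrix` the
#' `d[A, B]` matrix of a [ReferenceBaseline-class]; `scoreTable` a
#' `data.frame` view of [ContaminationProfiles-class].
#'
#' @param x an object of the documented class.
#' @param ... further arguments (unused).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("normalizationTag", function(x) standardGeneric("normalizationTag"))

#' @rdname accessors
#' @export
setGeneric("cellTypes", function(x) standardGeneric("cellTypes"))

#' @rdname accessors
#' @param value replacement value.
#' @export
setGeneric("cellTypes<-", function(x, value) standardGeneric("cellTypes<-"))

#' @rdname accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname accessors
#' @param type optional cell type; when given, the single marker vector.
#' @export
setGeneric("markerGenes", function(x, type = NULL) standardGeneric("markerGenes"))

#' @rdname accessors
#' @export
setGeneric("broadCellTypes", function(x) standardGeneric("broadCellTypes"))

#' @rdname accessors
#' @export
setGeneric("baselineMatrix", function(x) standardGeneric("baselineMatrix"))

#' @rdname accessors
#' @export
setGeneric("scoreTable", function(x, ...) standardGeneric("scoreTable"))

setMethod("normalizationTag", "PatchSeqExperiment",
          function(x) x@normalization)

setMethod("cellTypes", "PatchSeqExperiment", function(x) {
    ct <- colData(x)$cell_type
    if (is.null(ct)) stop("no 'cell_type' annotation attached; see annotateCells()")
    setNames(as.character(ct), colnames(x))
})

setMethod("cellTypes<-", "PatchSeqExperiment", function(x, value) {
    colData(x)$cell_type <- as.character(value)
    validObject(x)
    x
})

setMethod("exprValues", "PatchSeqExperiment", function(x) assay(x, "expr"))

setMethod("markerGenes", "MarkerSet", function(x, type = NULL) {
    if (is.null(type)) return(x@markers)
    if (!type %in% names(x@markers))
        stop(sprintf("no markers for type '%s'", type))
    x@markers[[type]]
})

setMethod("broadCellTypes", "MarkerSet", function(x) x@broadTypes)

setMethod("baselineMatrix", "ReferenceBaseline", function(x) x@d)

setMethod("scoreTable", "ContaminationProfiles", function(x, ...) {
    df <- data.frame(cell_id = x@cellId, cell_type = x@cellType,
                     stringsAsFactors = FALSE)
    cs <- x@cs
    colnames(cs) <- paste0("CS_", colnames(cs))
    df <- cbind(df, as.data.frame(cs))
    df$contam_index <- x@contamIndex
    df$quality_score <- x@qualityScore
    df$own_markers_detected <- x@ownMarkersDetected
    df$contaminated <- x@contaminated
    rownames(df) <- NULL
    df
})

#' @export
#' @describeIn ContaminationProfiles-class coerce to `data.frame`
#'   (one row per cell, one `CS_<type>` column per off-target type).
#' @param x a `ContaminationProfiles` object.
#' @param ... unused.
as.data.frame.ContaminationProfiles <- function(x, ...) scoreTable(x)

setMethod("show", "PatchSeqExperiment", function(object) {
    callNextMethod()
    cat("normalization:", object@normalization, "\n")
})

setMethod("show", "MarkerSet", function(object) {
    cat(sprintf("MarkerSet with %d cell types (%d broad contamination sources)\n",
                length(object@markers), length(object@broadTypes)))
    for (t in names(object@markers)) {
        flag <- if (t %in% object@unusableTypes) " [unusable]" else ""
        role <- if (t %in% object@broadTypes) "off" else "on"
        cat(sprintf("  %s (%s): %d markers%s\n", t, role,
                    length(object@markers[[t]]), flag))
    }
    if (length(object@comparisonExclusions))
        cat("comparison exclusions:",
            paste(names(object@comparisonExclusions), collapse = ", "), "\n")
})

setMethod("show", "ReferenceBaseline", function(object) {
    cat(sprintf("ReferenceBaseline: %d cell types x %d marker sources\n",
                nrow(object@d), ncol(object@d)))
    print(round(object@d, 2))
    if (any(object@degenerate))
        cat(sum(object@degenerate), "degenerate (non-discriminative) pairs\n")
})

setMethod("show", "ContaminationProfiles", function(object) {
    cat(sprintf("ContaminationProfiles for %d cells\n", length(object@cellId)))
    cat(sprintf("  contaminated (any CS > %.2f): %d\n", object@threshold,
                sum(object@contaminated)))
    cat(sprintf("  contamination index: median %.3f, max %.3f\n",
                stats::median(object@contamIndex), max(object@contamIndex)))
    cat(sprintf("  quality score: median %.3f\n",
                stats::median(object@qualityScore)))
})

setMethod("show", "RegressionResult", function(object) {
    cat(sprintf("Standardized technical-factor model (n = %d cells)\n",
                object@nCells))
    tab <- data.frame(beta = round(object@coefficients, 4),
                      std_error = round(object@stdErrors, 4))
    print(tab)
    cat(sprintf("variance explained: %.1f%%\n", 100 * object@rSquared))
    if (length(object@dropped))
        cat("dropped (zero variance):", paste(object@dropped, collapse = ", "), "\n")
})

setMethod("show", "SimulationConfig", function(object) {
    cat(sprintf(paste0("SimulationConfig: %d types x %d cells, %d markers/type, ",
                       "%d background genes\n"),
                object@nTypes, object@cellsPerType, object@nMarkersPerType,
                object@nBackgroundGenes))
    cat(sprintf("  alpha grid: %s\n", paste(object@alphaGrid, collapse = ", ")))
    cat(sprintf("  library ~%g reads, spike-in pool %g, content %g-%g, seed %d\n",
                object@librarySize, object@spikeInPool,
                object@mrnaContentRange[1], object@mrnaContentRange[2],
                object@seed))
})
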