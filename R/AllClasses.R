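#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#'   colData<- rowData assayNames
NULL

.NORMALIZATIONS <- c("TPM", "CPM_UMI", "FPKM", "RAW")

#' Container for a normalized genes-by-cells expression matrix
#'
#' `PatchSeqExperiment` extends
#' [SummarizedExperiment::SummarizedExperiment] with a normalization tag
#' (`TPM`, `CPM_UMI`, `FPKM` or `RAW`). The first assay, named `"expr"`,
#' holds nonnegative normalized expression with unique gene symbols as row
#' names and unique cell identifiers as column names. Cell-level annotation
#' (broad `cell_type`, `dataset`, `is_gabaergic_subtype`) lives in
#' `colData`.
#'
#' @slot normalization single string, one of `TPM`, `CPM_UMI`, `FPKM`, `RAW`.
#' @export
setClass("PatchSeqExperiment",
    contains = "SummarizedExperiment",
    representation(normalization = "character"))

setValidity("PatchSeqExperiment", function(object) {
    msg <- character()
    if (length(object@normalization) != 1L ||
        !object@normalization %in% .NORMALIZATIONS)
        msg <- c(msg, sprintf("normalization must be one of %s",
                              paste(.NORMALIZATIONS, collapse = ", ")))
    if (!"expr" %in% assayNames(object))
        msg <- c(msg, "first assay must be named 'expr'")
    else {
        x <- assay(object, "expr")
        if (any(x < 0, na.rm = TRUE))
            msg <- c(msg, "negative expression values are not allowed")
    }
    gn <- rownames(object)
    cn <- colnames(object)
    if (is.null(gn) || anyDuplicated(gn))
        msg <- c(msg, "gene ids must be present and unique")
    if (is.null(cn) || anyDuplicated(cn))
        msg <- c(msg, "cell ids must be present and unique")
    if (length(msg)) msg else TRUE
})

#' Construct a PatchSeqExperiment
#'
#' @param values nonnegative numeric matrix, genes in rows (row names are
#'   gene symbols), cells in columns (column names are cell identifiers).
#' @param normalization normalization tag; one of `"TPM"`, `"CPM_UMI"`,
#'   `"FPKM"`, `"RAW"`.
#' @param cellData optional `DataFrame`/`data.frame` of per-cell annotation,
#'   one row per column of `values`. A `cell_type` column declares the broad
#'   type used for contamination scoring.
#' @param counts optional matrix of raw counts with the same dimensions,
#'   stored as a second assay.
#' @return A [PatchSeqExperiment-class] object.
#' @examples
#' m <- matrix(c(1, 0, 2, 5, 0, 3), nrow = 3, byrow = TRUE,
#'             dimnames = list(c("Ndnf", "Slc17a7", "C1qa"), c("c1", "c2")))
#' pse <- PatchSeqExperiment(m, "TPM")
#' normalizationTag(pse)
#' @export
PatchSeqExperiment <- function(values, normalization = c("TPM", "CPM_UMI",
                                                         "FPKM", "RAW"),
                               cellData = NULL, counts = NULL) {
    normalization <- match.arg(normalization)
    values <- as.matrix(values)
    storage.mode(values) <- "double"
    assays <- list(expr = values)
    if (!is.null(counts)) assays$counts <- as.matrix(counts)
    if (is.null(cellData)) {
        cellData <- DataFrame(row.names = colnames(values))
    } else {
        cellData <- as(cellData, "DataFrame")
        if (is.null(rownames(cellData)) && "cell_id" %in% colnames(cellData))
            rownames(cellData) <- cellData$cell_id
    }
    se <- SummarizedExperiment(assays = assays, colData = cellData)
    new("PatchSeqExperiment", se, normalization = normalization)
}

#' Thresholds controlling marker-gene selection
#'
#' Defaults follow the enrichment and prevalence rules used for
#' dissociated-cell reference atlases on the TPM scale: an "on" marker must
#' be enriched more than `foldChange`-fold over every other (non-excluded)
#' cell type, have mean expression above `minMean`, and be expressed above
#' `prevalenceExpr` in more than `prevalenceFrac` of the cells of its type.
#' "Off" markers must be expressed above `offLowExpr` in more than
#' `offLowFrac` of the source-type cells and above `offTargetExpr` in at
#' most `offTargetFrac` of the cells of every protected (patch-seq target)
#' type.
#'
#' @export
setClass("MarkerThresholds",
    representation(foldChange = "numeric", minMean = "numeric",
                   prevalenceExpr = "numeric", prevalenceFrac = "numeric",
                   offLowExpr = "numeric", offLowFrac = "numeric",
                   offTargetExpr = "numeric", offTargetFrac = "numeric"),
    prototype(foldChange = 10, minMean = 100,
              prevalenceExpr = 10, prevalenceFrac = 0.75,
              offLowExpr = 10, offLowFrac = 0.5,
              offTargetExpr = 10, offTargetFrac = 1 / 3))

setValidity("MarkerThresholds", function(object) {
    vals <- c(object@foldChange, object@minMean, object@prevalenceExpr,
              object@offLowExpr, object@offTargetExpr)
    fracs <- c(object@prevalenceFrac, object@offLowFrac, object@offTargetFrac)
    if (any(vals < 0)) return("thresholds must be nonnegative")
    if (any(fracs < 0 | fracs > 1)) return("fractions must lie in [0, 1]")
    TRUE
})

#' @param foldChange,minMean,prevalenceExpr,prevalenceFrac enrichment and
#'   prevalence rules for "on" markers (see class description).
#' @param offLowExpr,offLowFrac,offTargetExpr,offTargetFrac filters applied
#'   to "off" marker candidates.
#' @return A `MarkerThresholds` object.
#' @rdname MarkerThresholds-class
#' @export
markerThresholds <- function(foldChange = 10, minMean = 100,
                             prevalenceExpr = 10, prevalenceFrac = 0.75,
                             offLowExpr = 10, offLowFrac = 0.5,
                             offTargetExpr = 10, offTargetFrac = 1 / 3) {
    new("MarkerThresholds", foldChange = foldChange, minMean = minMean,
        prevalenceExpr = prevalenceExpr, prevalenceFrac = prevalenceFrac,
        offLowExpr = offLowExpr, offLowFrac = offLowFrac,
        offTargetExpr = offTargetExpr, offTargetFrac = offTargetFrac)
}

#' Preset thresholds for UMI counts-per-million references
#'
#' UMI-based atlases are shallower per cell than read-based TPM data, so the
#' prevalence rules drop to >1 unit in >50% of cells for "on" markers and
#' >2 units in more than a third of protected-type cells for "off" markers.
#'
#' @return A `MarkerThresholds` object tuned for `CPM_UMI` references.
#' @export
umiThresholds <- function() {
    markerThresholds(prevalenceExpr = 1, prevalenceFrac = 0.5,
                     offLowExpr = 1, offLowFrac = 0.5,
                     offTargetExpr = 2, offTargetFrac = 1 / 3)
}

#' Cell type marker sets
#'
#' Per cell type lists of marker genes, together with the designation of
#' broad contamination-source ("off") types and, for GABAergic subtypes, the
#' cell types excluded from their enrichment comparisons. Within the broad
#' types no gene may belong to two different lists.
#'
#' @slot markers named list of character vectors, one per cell type.
#' @slot broadTypes character, names of types usable as contamination
#'   sources.
#' @slot comparisonExclusions named list: for a target type, the types its
#'   enrichment comparisons (and its contamination assessment) skip.
#' @slot unusableTypes character, types whose lists fell below the minimum
#'   marker count and are flagged unusable.
#' @slot thresholds list of threshold settings used to build the set.
#' @export
setClass("MarkerSet",
    representation(markers = "list", broadTypes = "character",
                   comparisonExclusions = "list",
                   unusableTypes = "character", thresholds = "list"),
    prototype(markers = list(), broadTypes = character(),
              comparisonExclusions = list(), unusableTypes = character(),
              thresholds = list()))

setValidity("MarkerSet", function(object) {
    msg <- character()
    if (length(object@markers) &&
        (is.null(names(object@markers)) || anyDuplicated(names(object@markers))))
        msg <- c(msg, "markers must be a uniquely named list")
    broad <- intersect(object@broadTypes, names(object@markers))
    bg <- unlist(object@markers[broad], use.names = FALSE)
    if (anyDuplicated(bg))
        msg <- c(msg, "a gene may not appear in two broad types' marker lists")
    empty <- names(object@markers)[lengths(object@markers) == 0L]
    bad <- setdiff(empty, object@unusableTypes)
    if (length(bad))
        msg <- c(msg, sprintf("types with empty marker lists must be flagged unusable: %s",
                              paste(bad, collapse = ", ")))
    if (length(msg)) msg else TRUE
})

#' @param markers named list of marker gene vectors.
#' @param broadTypes types usable as contamination sources.
#' @param comparisonExclusions named list of excluded comparison types.
#' @param unusableTypes types flagged unusable.
#' @param thresholds list of thresholds used (for provenance).
#' @rdname MarkerSet-class
#' @export
MarkerSet <- function(markers, broadTypes = character(),
                      comparisonExclusions = list(),
                      unusableTypes = character(), thresholds = list()) {
    new("MarkerSet", markers = markers, broadTypes = broadTypes,
        comparisonExclusions = comparisonExclusions,
        unusableTypes = unusableTypes, thresholds = thresholds)
}

#' Dissociated-cell marker-expression baselines
#'
#' The entry `d[A, B]` is the median, over reference (dissociated) cells of
#' type `A`, of the summed log2 expression of type `B`'s markers — how much
#' of `B`'s marker signal a clean cell of type `A` is expected to carry. A
#' pair is degenerate when `d[B, B] <= d[A, B]`, i.e. the markers do not
#' discriminate `B` from `A`; degenerate pairs yield missing contamination
#' scores downstream.
#'
#' @slot d numeric matrix, rows = cell types assessed (A), columns = marker
#'   source types (B).
#' @slot degenerate logical matrix of the same shape.
#' @export
setClass("ReferenceBaseline",
    representation(d = "matrix", degenerate = "matrix"))

setValidity("ReferenceBaseline", function(object) {
    if (!identical(dim(object@d), dim(object@degenerate)))
        return("d and degenerate must have identical dimensions")
    if (any(object@d < 0, na.rm = TRUE))
        return("baselines must be nonnegative with a pseudocount of 1")
    TRUE
})

#' Per-cell contamination and quality scores
#'
#' One row per patch-seq cell: summed marker expression for every marker
#' source type, contamination scores for the applicable broad off-target
#' types (in `[0, 1]`, `NA` where not assessed), their sum (the
#' contamination index), the marker-correlation quality score, and the
#' contamination call at `threshold`.
#'
#' @slot cellId,cellType character vectors.
#' @slot markerSums cells x marker-source-types matrix of summed log2
#'   marker expression.
#' @slot cs cells x broad-types matrix of contamination scores.
#' @slot contamIndex numeric, sum of non-missing contamination scores.
#' @slot qualityScore numeric in `[floor, 1]`.
#' @slot ownMarkersDetected integer, how many of the cell's own type's
#'   markers are expressed above zero.
#' @slot contaminated logical, any contamination score above `threshold`.
#' @slot threshold numeric, the calling threshold used.
#' @export
setClass("ContaminationProfiles",
    representation(cellId = "character", cellType = "character",
                   markerSums = "matrix", cs = "matrix",
                   contamIndex = "numeric", qualityScore = "numeric",
                   ownMarkersDetected = "integer", contaminated = "logical",
                   threshold = "numeric"))

setValidity("ContaminationProfiles", function(object) {
    n <- length(object@cellId)
    if (length(object@cellType) != n || nrow(object@cs) != n ||
        nrow(object@markerSums) != n || length(object@contamIndex) != n ||
        length(object@qualityScore) != n || length(object@contaminated) != n)
        return("per-cell slots must have one entry per cell")
    cs <- object@cs
    if (any(cs < 0 | cs > 1, na.rm = TRUE))
        return("contamination scores must lie in [0, 1] (after floor and cap)")
    if (any(object@contamIndex < 0))
        return("contamination index must be nonnegative")
    TRUE
})

#' Standardized technical-factor regression fit
#'
#' Ordinary least squares of the z-scored detected-gene count on z-scored
#' technical factors. Coefficients are standardized betas, in units of
#' standard deviations of the response per standard deviation of the factor.
#'
#' @slot coefficients,stdErrors named numeric vectors (intercept excluded).
#' @slot rSquared fraction of variance explained, in `[0, 1]`.
#' @slot nCells number of cells entering the fit.
#' @slot dropped factors dropped for zero variance.
#' @export
setClass("RegressionResult",
    representation(coefficients = "numeric", stdErrors = "numeric",
                   rSquared = "numeric", nCells = "integer",
                   dropped = "character"))

setValidity("RegressionResult", function(object) {
    if (object@rSquared < 0 || object@rSquared > 1)
        return("rSquared must lie in [0, 1]")
    if (!identical(names(object@coefficients), names(object@stdErrors)))
        return("coefficients and stdErrors must be parallel")
    TRUE
})

#' Settings for the synthetic patch-seq study generator
#'
#' Defines the planted truth every simulation draws from: the cell type
#' panel and marker structure of the dissociated-cell reference, the
#' contamination mixture grid for patch-seq cells, the spike-in pool and
#' mRNA-content range governing read accounting, and the
#' gene-electrophysiology couplings. See [simulationConfig()] for defaults
#' and units.
#'
#' @export
setClass("SimulationConfig",
    representation(nTypes = "integer", nMarkersPerType = "integer",
                   nBackgroundGenes = "integer", cellsPerType = "integer",
                   markerMean = "numeric", backgroundMean = "numeric",
                   dispersion = "numeric", alphaGrid = "numeric",
                   spikeInPool = "numeric", mrnaContentRange = "numeric",
                   unmappedRange = "numeric", librarySize = "numeric",
                   ephysCouplings = "data.frame", seed = "integer"))

setValidity("SimulationConfig", function(object) {
    msg <- character()
    if (any(c(object@nTypes, object@nMarkersPerType, object@nBackgroundGenes,
              object@cellsPerType, object@librarySize) <= 0))
        msg <- c(msg, "counts must be positive")
    if (object@nTypes > 8L)
        msg <- c(msg, "at most 8 cell types are supported")
    if (any(object@alphaGrid < 0 | object@alphaGrid > 1))
        msg <- c(msg, "alphaGrid values must lie in [0, 1]")
    if (object@dispersion <= 0)
        msg <- c(msg, "dispersion must be positive")
    for (rng in list(object@mrnaContentRange, object@unmappedRange))
        if (length(rng) != 2L || rng[1] > rng[2] || any(rng < 0))
            msg <- c(msg, "ranges must be (low, high) with 0 <= low <= high")
    need <- c("gene", "feature", "slope", "noise_sd")
    if (!all(need %in% colnames(object@ephysCouplings)))
        msg <- c(msg, "ephysCouplings needs columns gene, feature, slope, noise_sd")
    if (length(msg)) msg else TRUE
})
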