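#' @include AllClasses.R AllGenerics.R
NULL

#' Drop lowly expressed genes before correlation analysis
#'
#' Retains genes whose mean expression across cells strictly exceeds the
#' given percentile of all genes' means. The percentile uses the
#' linear-interpolation convention (R's default quantile type 7), so with
#' gene means 1..10 and a 0.30 cutoff the threshold is 3.7.
#'
#' @param x [PatchSeqExperiment-class] or genes x cells matrix with at
#'   least 10 genes.
#' @param percentileCutoff fraction in `[0, 1)` (default 0.30).
#' @return The filtered object of the same class.
#' @export
filterGenes <- function(x, percentileCutoff = 0.30) {
    stopifnot(percentileCutoff >= 0, percentileCutoff < 1)
    m <- if (is(x, "PatchSeqExperiment")) exprValues(x) else x
    if (nrow(m) < 10L) stop("need at least 10 genes")
    means <- rowMeans(m)
    cutoff <- stats::quantile(means, percentileCutoff, names = FALSE, type = 7)
    keep <- means > cutoff
    if (!any(keep))
        warning("no genes above the percentile cutoff (constant means?)")
    x[keep, ]
}

#' Weighted Pearson correlation with a t-based p-value
#'
#' The correlation of `x` and `y` under nonnegative observation weights:
#' weighted covariance over the product of weighted standard deviations,
#' with the weights rescaled to sum to the number of observations. The
#' two-sided p-value comes from the t statistic with `n - 2` degrees of
#' freedom applied to the weighted correlation, the convention of the
#' survey-weights toolboxes. Uniform weights reduce exactly to the ordinary
#' Pearson correlation test.
#'
#' @param x,y numeric vectors; pairs with missing values are dropped.
#' @param w nonnegative weights (default uniform), not all zero.
#' @return `list(r, p, n)`; `r` and `p` are `NA` (with a warning) when
#'   either variable has zero weighted variance.
#' @export
weightedPearson <- function(x, y, w = NULL) {
    if (is.null(w)) w <- rep(1, length(x))
    if (length(x) != length(y) || length(x) != length(w))
        stop("x, y and w must have equal length")
    ok <- stats::complete.cases(x, y, w)
    x <- x[ok]; y <- y[ok]; w <- w[ok]
    n <- length(x)
    if (n < 3L) stop("need at least 3 complete observations")
    if (any(w < 0)) stop("weights must be nonnegative")
    if (all(w == 0)) stop("weights must not all be zero")
    w <- w / sum(w) * n
    mx <- sum(w * x) / n
    my <- sum(w * y) / n
    vx <- sum(w * (x - mx)^2) / n
    vy <- sum(w * (y - my)^2) / n
    if (vx == 0 || vy == 0) {
        warning("zero variance; weighted correlation undefined")
        return(list(r = NA_real_, p = NA_real_, n = n))
    }
    r <- sum(w * (x - mx) * (y - my)) / n / sqrt(vx * vy)
    r <- max(-1, min(1, r))
    p <- if (abs(r) == 1) 0 else {
        tstat <- r * sqrt((n - 2) / (1 - r^2))
        2 * stats::pt(-abs(tstat), df = n - 2)
    }
    list(r = r, p = p, n = n)
}

# weighted correlation of every column of X against y; same moments as
# weightedPearson, vectorized over genes
.weightedPearsonMat <- function(X, y, w) {
    n <- length(y)
    w <- w / sum(w) * n
    mX <- colSums(w * X) / n
    my <- sum(w * y) / n
    Xc <- sweep(X, 2L, mX)
    yc <- y - my
    vX <- colSums(w * Xc^2) / n
    vy <- sum(w * yc^2) / n
    r <- (colSums(w * Xc * yc) / n) / sqrt(vX * vy)
    r[vX == 0 | vy == 0] <- NA_real_
    r <- pmax(-1, pmin(1, r))
    tstat <- r * sqrt((n - 2) / pmax(1e-300, 1 - r^2))
    p <- ifelse(abs(r) == 1, 0, 2 * stats::pt(-abs(tstat), df = n - 2))
    list(r = r, p = p)
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up adjusted p-values: monotone, capped at 1. Inputs outside
#' `(0, 1]` are rejected.
#'
#' @param p numeric vector of raw p-values in `(0, 1]`.
#' @return Adjusted values, same length and order.
#' @export
bhFDR <- function(p) {
    if (!length(p)) return(numeric())
    if (anyNA(p) || any(p <= 0 | p > 1))
        stop("p-values must lie in (0, 1]")
    stats::p.adjust(p, method = "BH")
}

#' Correlate every gene with every electrophysiological feature
#'
#' For each (gene, feature) pair, Pearson correlation and p-value both
#' unweighted and weighted by per-cell quality scores, on
#' pairwise-complete observations. P-values are adjusted by
#' Benjamini-Hochberg within each feature across genes (the default
#' family; `family = "global"` adjusts across all pairs at once).
#'
#' @param expr [PatchSeqExperiment-class] or genes x cells matrix (apply
#'   [filterGenes()] first if desired).
#' @param ephys `data.frame` with a `cell_id` (or `type_id`) column and
#'   feature columns; missing values allowed.
#' @param weights named per-cell weights (e.g. quality scores from
#'   [scoreCells()]); `NULL` for the unweighted analysis only (the
#'   weighted columns then duplicate the unweighted ones).
#' @param fdrCutoff significance cutoff applied in the summary columns.
#' @param family `"per_feature"` or `"global"` multiple-testing family.
#' @return `data.frame` with one row per (gene, feature): `r_unweighted`,
#'   `p_unweighted`, `fdr_unweighted`, `r_weighted`, `p_weighted`,
#'   `fdr_weighted`, `n`, and logical `sig_unweighted` / `sig_weighted`
#'   at `fdrCutoff`.
#' @export
correlateAll <- function(expr, ephys, weights = NULL, fdrCutoff = 0.1,
                         family = c("per_feature", "global")) {
    family <- match.arg(family)
    m <- if (is(expr, "PatchSeqExperiment")) exprValues(expr) else expr
    idcol <- intersect(c("cell_id", "type_id"), colnames(ephys))[1L]
    if (is.na(idcol)) stop("ephys table needs a cell_id or type_id column")
    shared <- intersect(colnames(m), ephys[[idcol]])
    if (!length(shared)) stop("no shared cells between expression and ephys tables")
    if (length(shared) < 5L)
        stop("need at least 5 shared cells, got ", length(shared))
    m <- m[, shared, drop = FALSE]
    ephys <- ephys[match(shared, ephys[[idcol]]), , drop = FALSE]
    w <- if (is.null(weights)) rep(1, length(shared)) else {
        if (is.null(names(weights))) stop("weights must be named by cell id")
        if (any(is.na(weights[shared]))) stop("weights missing for some cells")
        unname(weights[shared])
    }
    features <- setdiff(colnames(ephys), idcol)
    X <- t(log2(m + 1))  # cells x genes, log scale for expression

    out <- lapply(features, function(f) {
        y <- ephys[[f]]
        ok <- !is.na(y) & !is.na(w)
        if (sum(ok) < 3L) return(NULL)
        un <- .weightedPearsonMat(X[ok, , drop = FALSE], y[ok], rep(1, sum(ok)))
        wt <- .weightedPearsonMat(X[ok, , drop = FALSE], y[ok], w[ok])
        data.frame(gene = colnames(X), feature = f,
                   r_unweighted = un$r, p_unweighted = un$p,
                   r_weighted = wt$r, p_weighted = wt$p,
                   n = sum(ok), stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    adjustWithin <- function(p, grp) {
        fdr <- rep(NA_real_, length(p))
        for (g in unique(grp)) {
            ix <- grp == g & !is.na(p)
            fdr[ix] <- bhFDR(p[ix])
        }
        fdr
    }
    grp <- if (family == "per_feature") res$feature else rep("all", nrow(res))
    res$fdr_unweighted <- adjustWithin(res$p_unweighted, grp)
    res$fdr_weighted <- adjustWithin(res$p_weighted, grp)
    res$sig_unweighted <- !is.na(res$fdr_unweighted) & res$fdr_unweighted < fdrCutoff
    res$sig_weighted <- !is.na(res$fdr_weighted) & res$fdr_weighted < fdrCutoff
    res
}

#' Count significant genes per feature
#'
#' @param res result of [correlateAll()].
#' @return `data.frame` with per-feature counts of significant genes in the
#'   weighted and unweighted analyses.
#' @export
discoveryCounts <- function(res) {
    agg <- stats::aggregate(cbind(unweighted = res$sig_unweighted,
                           weighted = res$sig_weighted),
                     by = list(feature = res$feature), FUN = sum)
    agg
}

#' Harmonic-mean cell-count weight
#'
#' Weight for a pooled cell type represented by `nE` electrophysiology
#' cells and `nG` expression cells: `2 * nE * nG / (nE + nG)`.
#'
#' @param nE,nG cell counts (vectorized).
#' @return Numeric weights.
#' @examples
#' harmonicMeanWeight(89, 14)  # ~24.19
#' @export
harmonicMeanWeight <- function(nE, nG) {
    stopifnot(all(nE >= 0), all(nG >= 0))
    ifelse(nE + nG == 0, 0, 2 * nE * nG / (nE + nG))
}

#' Pool expression and electrophysiology to the cell-type level
#'
#' When expression and electrophysiology were measured in different cells
#' of the same types (e.g. dissociated scRNA-seq merged with patch-clamp
#' recordings by transgenic line), each type contributes its mean
#' expression profile and mean feature values, weighted by the harmonic
#' mean of the two cell counts so types represented by few cells in either
#' modality count less.
#'
#' @param exprGroups named list (by type) of genes x cells matrices or
#'   [PatchSeqExperiment-class] objects.
#' @param ephysGroups named list (by type) of `data.frame`s of feature
#'   values, one row per cell.
#' @return List with `expr` (genes x types mean matrix), `ephys`
#'   (`data.frame`, one row per type with a `type_id` column), `weights`
#'   (named harmonic-mean weights), and `nE`/`nG` counts. Types missing a
#'   modality are skipped with a warning; fewer than 3 complete types is
#'   an error.
#' @export
poolCellTypes <- function(exprGroups, ephysGroups) {
    common <- intersect(names(exprGroups), names(ephysGroups))
    common <- common[vapply(common, function(t) {
        e <- exprGroups[[t]]
        ncol(if (is(e, "PatchSeqExperiment")) exprValues(e) else e) > 0 &&
            nrow(ephysGroups[[t]]) > 0
    }, TRUE)]
    skipped <- setdiff(union(names(exprGroups), names(ephysGroups)), common)
    if (length(skipped))
        warning("types missing a modality skipped: ",
                paste(skipped, collapse = ", "))
    if (length(common) < 3L)
        stop("need at least 3 cell types with both modalities")
    mats <- lapply(exprGroups[common], function(e)
        if (is(e, "PatchSeqExperiment")) exprValues(e) else as.matrix(e))
    meanExpr <- vapply(mats, rowMeans, numeric(nrow(mats[[1L]])))
    featureCols <- Reduce(intersect, lapply(ephysGroups[common], function(d)
        colnames(d)[vapply(d, is.numeric, TRUE)]))
    meanEphys <- t(vapply(ephysGroups[common], function(d)
        colMeans(d[featureCols], na.rm = TRUE), numeric(length(featureCols))))
    nG <- vapply(mats, ncol, 0L)
    nE <- vapply(ephysGroups[common], nrow, 0L)
    w <- harmonicMeanWeight(nE, nG)
    ephys <- data.frame(type_id = common, meanEphys, stringsAsFactors = FALSE,
                        row.names = NULL)
    list(expr = meanExpr, ephys = ephys, weights = setNames(w, common),
         nE = nE, nG = nG)
}
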