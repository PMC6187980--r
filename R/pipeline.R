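#' @include AllClasses.R AllGenerics.R
NULL

.stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
        stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
             call. = FALSE))
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the [runPipeline()] configuration list; relative input paths
#' are resolved against the YAML file's directory.
#'
#' @param path YAML file.
#' @return Named list.
#' @export
readPipelineConfig <- function(path) {
    cfg <- yaml::read_yaml(path)
    base <- dirname(normalizePath(path))
    pathKeys <- c("reference", "referenceAnnotations", "patchseq",
                  "annotations", "accounting", "ephys", "markers")
    for (k in intersect(pathKeys, names(cfg))) {
        if (!is.null(cfg[[k]]) && !file.exists(cfg[[k]]))
            cfg[[k]] <- file.path(base, cfg[[k]])
    }
    cfg
}

#' Run the patch-seq quality-control workflow end to end
#'
#' Executes marker selection, contamination/quality scoring, the
#' technical-factor regression and the quality-weighted ephys correlation,
#' as available inputs permit, and writes a plain-text report plus one TSV
#' per stage into `config$outDir`. Stages with missing optional inputs
#' (read accounting, ephys) are skipped with a notice; any stage error
#' aborts with the stage named.
#'
#' @param config named list (or path to a YAML file, see
#'   [readPipelineConfig()]) with entries: `reference`,
#'   `referenceAnnotations`, `patchseq`, `annotations` (paths or objects);
#'   optional `accounting`, `ephys`, `markers` (precomputed marker JSON);
#'   `targetTypes`, `broadTypes`, `gabaergicTypes`; optional `normalization`
#'   (default `"TPM"`), `thresholds` (passed to [markerThresholds()]),
#'   `csThreshold` (0.5), `fdrCutoff` (0.1), `qualityFloor` (0.1); and
#'   `outDir`.
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with the marker set, profiles, factor model,
#'   correlation table and output paths.
#' @export
runPipeline <- function(config, quiet = FALSE) {
    if (is.character(config)) config <- readPipelineConfig(config)
    stopifnot(is.list(config), !is.null(config$outDir))
    say <- function(...) if (!quiet) message(...)
    outDir <- config$outDir
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    norm <- config$normalization %||% "TPM"

    loadExpr <- function(x, annPath = NULL) {
        if (is(x, "PatchSeqExperiment")) return(x)
        pse <- readExpression(x, format = "tsv", normalization = norm)
        if (!is.null(annPath))
            pse <- annotateCells(pse, if (is.character(annPath))
                readAnnotations(annPath) else annPath)
        pse
    }

    say("stage 1/4: marker selection")
    ref <- .stage("select-markers",
                  loadExpr(config$reference, config$referenceAnnotations))
    markerSet <- .stage("select-markers", {
        if (!is.null(config$markers)) {
            if (is.character(config$markers)) readMarkerSet(config$markers)
            else config$markers
        } else {
            th <- do.call(markerThresholds, config$thresholds %||% list())
            buildMarkerSet(ref, targetTypes = config$targetTypes,
                           broadTypes = config$broadTypes,
                           gabaergicTypes = config$gabaergicTypes %||% character(),
                           thresholds = th)
        }
    })
    markersPath <- file.path(outDir, "markers.json")
    writeMarkerSet(markerSet, markersPath)

    say("stage 2/4: contamination and quality scoring")
    patchseq <- .stage("score", loadExpr(config$patchseq, config$annotations))
    profiles <- .stage("score", {
        baselines <- computeBaselines(ref, markerSet)
        scoreCells(patchseq, markerSet, baselines, ref,
                   csThreshold = config$csThreshold %||% 0.5,
                   qualityFloor = config$qualityFloor %||% 0.1)
    })
    scoresPath <- file.path(outDir, "scores.tsv")
    writeScores(profiles, scoresPath)

    fit <- NULL
    if (!is.null(config$accounting)) {
        say("stage 3/4: technical-factor model")
        fit <- .stage("tech-factors", {
            acc <- if (is.character(config$accounting))
                readReadAccounting(config$accounting) else config$accounting
            fitFactorModel(techFactorTable(acc, profiles, expr = patchseq))
        })
        writeFactorModel(fit, file.path(outDir, "tech_factors.tsv"))
    } else say("stage 3/4: tech-factors skipped (no read-accounting input)")

    corr <- NULL
    if (!is.null(config$ephys)) {
        say("stage 4/4: quality-weighted ephys correlation")
        corr <- .stage("ephys-corr", {
            ephys <- if (is.character(config$ephys)) readEphys(config$ephys)
                     else config$ephys
            expr <- filterGenes(patchseq,
                                config$genePercentileCutoff %||% 0.30)
            w <- setNames(profiles@qualityScore, profiles@cellId)
            correlateAll(expr, ephys, weights = w,
                         fdrCutoff = config$fdrCutoff %||% 0.1)
        })
        utils::write.table(corr, file.path(outDir, "correlations.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    } else say("stage 4/4: ephys-corr skipped (no electrophysiology input)")

    reportPath <- file.path(outDir, "report.txt")
    writeLines(.pipelineReport(markerSet, profiles, fit, corr), reportPath)
    say("report written to ", reportPath)
    invisible(list(markerSet = markerSet, profiles = profiles, fit = fit,
                   correlations = corr,
                   paths = c(markers = markersPath, scores = scoresPath,
                             report = reportPath)))
}

.pipelineReport <- function(markerSet, profiles, fit, corr) {
    lines <- c("patch-seq quality control report",
               "================================", "")
    lines <- c(lines, "marker sets:",
               vapply(names(markerGenes(markerSet)), function(t)
                   sprintf("  %s: %d markers%s", t,
                           length(markerGenes(markerSet, t)),
                           if (t %in% markerSet@unusableTypes) " [unusable]" else ""),
                   ""), "")
    tab <- table(profiles@cellType, profiles@contaminated)
    lines <- c(lines, sprintf("contaminated cells (any CS > %.2f):",
                              profiles@threshold))
    for (t in rownames(tab)) {
        nc <- if ("TRUE" %in% colnames(tab)) tab[t, "TRUE"] else 0L
        lines <- c(lines, sprintf("  %s: %d / %d", t, nc, sum(tab[t, ])))
    }
    lines <- c(lines, sprintf("median contamination index: %.3f",
                              stats::median(profiles@contamIndex)),
               sprintf("median quality score: %.3f",
                       stats::median(profiles@qualityScore)), "")
    if (!is.null(fit)) {
        lines <- c(lines, "technical-factor model (standardized betas):",
                   sprintf("  %s: %+.3f (se %.3f)", names(fit@coefficients),
                           fit@coefficients, fit@stdErrors),
                   sprintf("  variance explained: %.1f%% (n = %d cells)",
                           100 * fit@rSquared, fit@nCells), "")
    } else lines <- c(lines, "technical-factor model: skipped", "")
    if (!is.null(corr)) {
        dc <- discoveryCounts(corr)
        lines <- c(lines, "genes significantly correlated with ephys features:",
                   sprintf("  %s: %d unweighted, %d quality-weighted",
                           dc$feature, dc$unweighted, dc$weighted))
    } else lines <- c(lines, "ephys correlation: skipped")
    lines
}
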