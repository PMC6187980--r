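#' @include AllClasses.R AllGenerics.R
NULL

.TYPE_PANEL <- c("Ndnf", "Pyramidal", "Astrocyte", "Microglia", "Pvalb",
                 "Oligodendrocyte", "Endothelial", "Sncg")
.GABA_TYPES <- c("Ndnf", "Pvalb", "Sncg")

#' Configure the synthetic patch-seq study
#'
#' The generator emulates a miniature cortical cell-type atlas and a
#' patch-seq experiment run against it, with full ground truth. Defaults
#' describe the study conditions the rest of the package is exercised
#' under:
#' \itemize{
#'   \item 4 cell types — a GABAergic Ndnf-like target plus Pyramidal,
#'     Astrocyte and Microglia broad contamination sources (up to 8 types
#'     from a fixed panel; Pvalb and Sncg are treated as GABAergic).
#'   \item 30 planted marker genes per type (expected 30 molecules in the
#'     own type, 0.15 elsewhere — ~200-fold enrichment, comfortably above
#'     the 10x selection rule) over 2000 background genes at 0.15
#'     molecules, gamma-Poisson (negative-binomial-like) counts with a
#'     single shared dispersion (size 2, scRNA-seq-like overdispersion).
#'   \item patch-seq cells mixed with one off-target type per cell at the
#'     expected-count level over `alphaGrid` (0 to 1 by 0.1, 50 cells
#'     per level), mRNA content drawn in `mrnaContentRange` against a
#'     fixed spike-in pool, ~50k sequenced reads per cell split between
#'     spike-ins, mapped and unmapped reads.
#'   \item electrophysiological features coupled linearly to the log2 of
#'     chosen genes' uncontaminated expression.
#' }
#' All randomness derives from `seed`; identical configurations give
#' byte-identical outputs.
#'
#' @param nTypes number of cell types (first is the patch-seq target).
#' @param nMarkersPerType planted markers per type.
#' @param nBackgroundGenes background genes shared by all types.
#' @param cellsPerType reference cells per type, and patch-seq cells per
#'   alpha level.
#' @param markerMean,backgroundMean expected molecule counts.
#' @param dispersion gamma-Poisson size parameter (larger = closer to
#'   Poisson).
#' @param alphaGrid contamination mixture fractions.
#' @param spikeInPool expected spike-in molecules per sample (fixed pool).
#' @param mrnaContentRange (low, high) relative mRNA content per cell.
#' @param unmappedRange (low, high) fraction of cellular-side reads that
#'   fail to map.
#' @param librarySize expected sequenced reads per patch-seq cell.
#' @param ephysCouplings `data.frame` with columns `gene`, `feature`,
#'   `slope`, `noise_sd`.
#' @param seed integer seed.
#' @return A [SimulationConfig-class].
#' @export
simulationConfig <- function(nTypes = 4, nMarkersPerType = 30,
                             nBackgroundGenes = 2000, cellsPerType = 50,
                             markerMean = 30, backgroundMean = 0.15,
                             dispersion = 2, alphaGrid = seq(0, 1, by = 0.1),
                             spikeInPool = 80, mrnaContentRange = c(0.25, 1),
                             unmappedRange = c(0.05, 0.35),
                             librarySize = 5e4,
                             ephysCouplings = defaultEphysCouplings(),
                             seed = 1L) {
    new("SimulationConfig", nTypes = as.integer(nTypes),
        nMarkersPerType = as.integer(nMarkersPerType),
        nBackgroundGenes = as.integer(nBackgroundGenes),
        cellsPerType = as.integer(cellsPerType),
        markerMean = markerMean, backgroundMean = backgroundMean,
        dispersion = dispersion, alphaGrid = alphaGrid,
        spikeInPool = spikeInPool, mrnaContentRange = mrnaContentRange,
        unmappedRange = unmappedRange, librarySize = librarySize,
        ephysCouplings = ephysCouplings, seed = as.integer(seed))
}

#' @rdname simulationConfig
#' @export
defaultEphysCouplings <- function() {
    data.frame(gene = paste0("MK_Ndnf_", 1:4),
               feature = c("APhw", "Rin", "Vrest", "Tau"),
               slope = c(-0.5, 0.5, -0.4, 0.4),
               noise_sd = 0.6, stringsAsFactors = FALSE)
}

.simTypeNames <- function(config) .TYPE_PANEL[seq_len(config@nTypes)]

.simGeneNames <- function(config) {
    types <- .simTypeNames(config)
    c(unlist(lapply(types, function(t)
        paste0("MK_", t, "_", seq_len(config@nMarkersPerType)))),
      paste0("BG_", seq_len(config@nBackgroundGenes)))
}

# expected molecule counts per gene for each type (genes x types)
.simProfiles <- function(config) {
    types <- .simTypeNames(config)
    genes <- .simGeneNames(config)
    markerOf <- c(rep(types, each = config@nMarkersPerType),
                  rep(NA_character_, config@nBackgroundGenes))
    prof <- vapply(types, function(t)
        ifelse(!is.na(markerOf) & markerOf == t,
               config@markerMean, config@backgroundMean),
        numeric(length(genes)))
    rownames(prof) <- genes
    list(profiles = prof, markerOf = setNames(markerOf, genes))
}

#' Simulate a dissociated-cell reference atlas
#'
#' Draws `cellsPerType` cells per type with gamma-Poisson counts around
#' the planted expected profiles and normalizes each cell to counts per
#' million. Marker genes have expected expression `markerMean` in their
#' own type and `backgroundMean` everywhere else.
#'
#' @param config a [SimulationConfig-class].
#' @return List with `ref` (annotated [PatchSeqExperiment-class], assays
#'   `expr` = CPM and `counts`) and `truth` (marker assignment per gene,
#'   type roles, expected profiles).
#' @export
simulateReference <- function(config) {
    stopifnot(is(config, "SimulationConfig"))
    set.seed(config@seed)
    pr <- .simProfiles(config)
    types <- .simTypeNames(config)
    nGenes <- nrow(pr$profiles)
    counts <- do.call(cbind, lapply(types, function(t)
        matrix(stats::rnbinom(nGenes * config@cellsPerType,
                              mu = pr$profiles[, t], size = config@dispersion),
               nrow = nGenes)))
    rownames(counts) <- rownames(pr$profiles)
    colnames(counts) <- paste0(rep(types, each = config@cellsPerType), "_ref_",
                               sequence(rep(config@cellsPerType, length(types))))
    typeLabels <- rep(types, each = config@cellsPerType)
    cellData <- DataFrame(cell_id = colnames(counts), cell_type = typeLabels,
                          dataset = "synthetic_reference",
                          is_gabaergic_subtype = typeLabels %in% .GABA_TYPES,
                          row.names = colnames(counts))
    ref <- PatchSeqExperiment(cpmNormalize(counts), "CPM_UMI",
                              cellData = cellData, counts = counts)
    gaba <- intersect(.GABA_TYPES, types)
    truth <- list(markerOf = pr$markerOf, profiles = pr$profiles,
                  markerLists = split(names(pr$markerOf)[!is.na(pr$markerOf)],
                                      pr$markerOf[!is.na(pr$markerOf)]),
                  typeNames = types,
                  gabaergicTypes = gaba,
                  targetTypes = if (length(gaba)) gaba else types[1L],
                  broadTypes = setdiff(types, gaba))
    list(ref = ref, truth = truth)
}

#' Simulate a contaminated patch-seq experiment
#'
#' Each patch-seq cell is a target-type cell whose expected expression is a
#' convex mixture `(1 - alpha) * own profile + alpha * off-target profile`
#' at the expected-count level (one off-target broad type per cell, drawn
#' uniformly), scaled by a drawn relative mRNA content. Sequenced reads are
#' then allocated between the fixed spike-in pool, mapped cellular reads
#' and unmapped reads, so the spike-in ratio falls and the detected-gene
#' count rises with mRNA content.
#'
#' @param config a [SimulationConfig-class].
#' @param refTruth the `truth` element of [simulateReference()].
#' @return List with `ps` (annotated [PatchSeqExperiment-class], CPM),
#'   `accounting` (per-cell read accounting `data.frame`), `truth`
#'   (per-cell `data.frame`: `cell_id`, `true_type`, `true_alpha`,
#'   `true_off_target`, `true_content`), and `trueExpr` (CPM-scale
#'   uncontaminated expression, the coupling substrate for
#'   [simulateEphys()]).
#' @export
simulatePatchseq <- function(config, refTruth) {
    stopifnot(is(config, "SimulationConfig"))
    set.seed(config@seed + 1L)
    target <- refTruth$targetTypes[1L]
    offTypes <- refTruth$broadTypes
    if (!length(offTypes)) stop("no broad off-target types in the reference truth")
    prof <- refTruth$profiles
    nGenes <- nrow(prof)
    alphas <- rep(config@alphaGrid, each = config@cellsPerType)
    n <- length(alphas)
    offs <- sample(offTypes, n, replace = TRUE)
    ids <- sprintf("%s_ps_%03d", target, seq_len(n))

    counts <- matrix(0L, nGenes, n, dimnames = list(rownames(prof), ids))
    trueExpr <- matrix(0, nGenes, n, dimnames = list(rownames(prof), ids))
    lib <- integer(n); ercc <- integer(n); mapped <- integer(n)
    content <- stats::runif(n, config@mrnaContentRange[1L],
                            config@mrnaContentRange[2L])
    unmapped <- stats::runif(n, config@unmappedRange[1L],
                             config@unmappedRange[2L])
    for (i in seq_len(n)) {
        gam <- stats::rgamma(nGenes, shape = config@dispersion,
                             rate = config@dispersion)
        own <- prof[, target] * gam
        mix <- (1 - alphas[i]) * own + alphas[i] * prof[, offs[i]] * gam
        mols <- stats::rpois(nGenes, content[i] * mix)
        eMols <- stats::rpois(1L, config@spikeInPool)
        L <- round(stats::rlnorm(1L, log(config@librarySize), 0.35))
        pe <- eMols / (eMols + sum(mols) / (1 - unmapped[i]))
        ercc[i] <- stats::rbinom(1L, L, pe)
        mapped[i] <- stats::rbinom(1L, L - ercc[i], 1 - unmapped[i])
        lib[i] <- L
        if (sum(mols) > 0 && mapped[i] > 0)
            counts[, i] <- stats::rmultinom(1L, mapped[i], mols)
        trueExpr[, i] <- own / sum(own) * 1e6
    }
    cellData <- DataFrame(cell_id = ids, cell_type = target,
                          dataset = "synthetic_patchseq",
                          is_gabaergic_subtype = target %in% .GABA_TYPES,
                          row.names = ids)
    ps <- PatchSeqExperiment(cpmNormalize(counts), "CPM_UMI",
                             cellData = cellData, counts = counts)
    accounting <- data.frame(cell_id = ids, library_size = lib,
                             ercc_reads = ercc, mapped_reads = mapped,
                             detected_genes = colSums(counts > 0),
                             stringsAsFactors = FALSE)
    truth <- data.frame(cell_id = ids, true_type = target,
                        true_alpha = alphas, true_off_target = offs,
                        true_content = content, stringsAsFactors = FALSE)
    list(ps = ps, accounting = accounting, truth = truth, trueExpr = trueExpr)
}

#' Simulate electrophysiological features coupled to gene expression
#'
#' Each configured coupling contributes
#' `slope * log2(true uncontaminated expression + 1)` plus Gaussian noise
#' to its feature (couplings sharing a feature add up). Because the
#' coupling uses the uncontaminated expression while the observed matrix is
#' contaminated, quality-weighted correlation recovers the couplings better
#' than unweighted correlation.
#'
#' @param config a [SimulationConfig-class].
#' @param psTruth result of [simulatePatchseq()] (uses `trueExpr`).
#' @return `data.frame` with `cell_id` and one column per coupled feature.
#' @export
simulateEphys <- function(config, psTruth) {
    stopifnot(is(config, "SimulationConfig"))
    set.seed(config@seed + 2L)
    cp <- config@ephysCouplings
    missing <- setdiff(cp$gene, rownames(psTruth$trueExpr))
    if (length(missing))
        stop("coupled genes absent from simulation: ",
             paste(missing, collapse = ", "))
    ids <- colnames(psTruth$trueExpr)
    n <- length(ids)
    offsets <- c(Rin = 150, Vrest = -65, APthr = -40, APamp = 75, APhw = 1,
                 Tau = 15, AHPamp = 10, Rheo = 80, FRmax = 40, Cm = 90)
    feats <- unique(cp$feature)
    out <- data.frame(cell_id = ids, stringsAsFactors = FALSE)
    for (f in feats) {
        rows <- which(cp$feature == f)
        val <- rep(unname(offsets[f]) %||% 0, n)
        for (j in rows) {
            val <- val + cp$slope[j] *
                log2(psTruth$trueExpr[cp$gene[j], ] + 1) +
                stats::rnorm(n, 0, cp$noise_sd[j])
        }
        out[[f]] <- val
    }
    out
}

#' Simulate technical-factor records with planted standardized betas
#'
#' Draws independent standard-normal technical factors and a response whose
#' true standardized regression coefficients equal `betas` exactly: the raw
#' response is `X %*% (c * betas) + noise` with `c` chosen so that the
#' response variance is consistent with the planted coefficients and the
#' residual standard deviation `noiseSd`. Everything is then shifted to
#' natural units (reads, ratios, counts) by affine maps, which leave
#' standardized betas untouched. Requires `sum(betas^2) < 1`.
#'
#' @param n number of cells.
#' @param betas named standardized coefficients for `library_size`,
#'   `spike_in_ratio`, `unmapped_ratio`, `contam_index`.
#' @param noiseSd residual standard deviation on the raw response scale.
#' @param seed integer seed.
#' @return `data.frame` in the [fitFactorModel()] record layout.
#' @export
simulateTechFactors <- function(n = 200,
                                betas = c(library_size = 0.5,
                                          spike_in_ratio = -0.5,
                                          unmapped_ratio = -0.3,
                                          contam_index = 0.3),
                                noiseSd = 0.3, seed = 1L) {
    stopifnot(sum(betas^2) < 1)
    set.seed(seed)
    p <- length(betas)
    X <- matrix(stats::rnorm(n * p), n, p, dimnames = list(NULL, names(betas)))
    scale <- sqrt(noiseSd^2 / (1 - sum(betas^2)))
    y <- as.vector(X %*% (scale * betas)) + stats::rnorm(n, 0, noiseSd)
    df <- data.frame(cell_id = sprintf("cell_%03d", seq_len(n)))
    units <- list(library_size = c(8e5, 2e5), spike_in_ratio = c(0.12, 0.025),
                  unmapped_ratio = c(0.3, 0.06), contam_index = c(1, 0.25))
    for (f in names(betas)) {
        u <- units[[f]] %||% c(0, 1)
        df[[f]] <- u[1L] + u[2L] * X[, f]
    }
    df$detected_genes <- 6000 + 1500 * y
    df
}

#' Write a full simulated dataset to disk
#'
#' Emits the reference matrix and annotations, the patch-seq matrix,
#' annotations and read accounting, the electrophysiology table and the
#' per-cell ground truth as TSV files in `dir`.
#'
#' @param config a [SimulationConfig-class].
#' @param dir output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
writeSimulation <- function(config, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    refSim <- simulateReference(config)
    psSim <- simulatePatchseq(config, refSim$truth)
    ephys <- simulateEphys(config, psSim)
    writeTSVMatrix <- function(m, path) {
        df <- data.frame(gene = rownames(m), m, check.names = FALSE,
                         stringsAsFactors = FALSE)
        utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    }
    paths <- c(reference = file.path(dir, "reference.tsv"),
               reference_annotations = file.path(dir, "reference_annotations.tsv"),
               patchseq = file.path(dir, "patchseq.tsv"),
               annotations = file.path(dir, "annotations.tsv"),
               accounting = file.path(dir, "accounting.tsv"),
               ephys = file.path(dir, "ephys.tsv"),
               truth = file.path(dir, "truth.tsv"))
    writeTSVMatrix(exprValues(refSim$ref), paths["reference"])
    utils::write.table(as.data.frame(colData(refSim$ref)), paths["reference_annotations"],
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeTSVMatrix(exprValues(psSim$ps), paths["patchseq"])
    utils::write.table(as.data.frame(colData(psSim$ps)), paths["annotations"],
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(psSim$accounting, paths["accounting"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(ephys, paths["ephys"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(psSim$truth, paths["truth"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(paths)
}
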