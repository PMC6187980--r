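# shared fixtures, built in code; the default simulation is cached because
# several files exercise the same study conditions

makePSE <- function(values, types, normalization = "TPM", gaba = character()) {
    cd <- S4Vectors::DataFrame(
        cell_id = colnames(values), cell_type = types,
        is_gabaergic_subtype = types %in% gaba,
        row.names = colnames(values))
    PatchSeqExperiment(values, normalization, cellData = cd)
}

# a tiny deterministic reference: 3 types x 10 cells, genes with known
# selection outcomes
makeTinyReference <- function() {
    nc <- 10
    types <- rep(c("A", "B", "C"), each = nc)
    genes <- c("g_good", "g_fc5", "g_lowprev", "g_lowmean", "g_bmark", "g_flat")
    m <- matrix(0, length(genes), length(types),
                dimnames = list(genes, paste0("c", seq_along(types))))
    m["g_good", ] <- c(rep(1000, 9), 500, rep(5, nc), rep(5, nc))
    m["g_fc5", ] <- c(rep(1000, nc), rep(200, nc), rep(5, nc))
    m["g_lowprev", ] <- c(rep(c(2000, 0), nc / 2), rep(5, nc), rep(5, nc))
    m["g_lowmean", ] <- c(rep(50, nc), rep(1, nc), rep(1, nc))
    m["g_bmark", ] <- c(rep(2, nc), rep(800, nc), rep(2, nc))
    m["g_flat", ] <- 300
    makePSE(m, types)
}

defaultSim <- local({
    cache <- NULL
    function() {
        if (is.null(cache)) {
            cfg <- simulationConfig(seed = 1)
            refSim <- simulateReference(cfg)
            ms <- buildMarkerSet(refSim$ref,
                                 targetTypes = refSim$truth$targetTypes,
                                 broadTypes = refSim$truth$broadTypes,
                                 gabaergicTypes = refSim$truth$gabaergicTypes)
            bl <- computeBaselines(refSim$ref, ms)
            psSim <- simulatePatchseq(cfg, refSim$truth)
            prof <- scoreCells(psSim$ps, ms, bl, refSim$ref)
            cache <<- list(cfg = cfg, ref = refSim$ref, truth = refSim$truth,
                           ms = ms, bl = bl, ps = psSim$ps,
                           accounting = psSim$accounting,
                           psTruth = psSim$truth, trueExpr = psSim$trueExpr,
                           prof = prof)
        }
        cache
    }
})

# per-cell contamination score at each cell's true off-target type
trueOffTargetCS <- function(sim) {
    vapply(seq_along(sim$prof@cellId), function(i)
        sim$prof@cs[i, sim$psTruth$true_off_target[i]], 0)
}

# independent brute-force weighted Pearson (loops, no shared code)
bruteWeightedPearson <- function(x, y, w) {
    n <- length(x)
    w <- w * n / sum(w)
    mx <- 0; my <- 0
    for (i in 1:n) { mx <- mx + w[i] * x[i] / n; my <- my + w[i] * y[i] / n }
    sxx <- 0; syy <- 0; sxy <- 0
    for (i in 1:n) {
        sxx <- sxx + w[i] * (x[i] - mx)^2
        syy <- syy + w[i] * (y[i] - my)^2
        sxy <- sxy + w[i] * (x[i] - mx) * (y[i] - my)
    }
    r <- sxy / sqrt(sxx * syy)
    tt <- r * sqrt((n - 2) / (1 - r^2))
    list(r = r, p = 2 * stats::pt(-abs(tt), n - 2))
}

# independent brute-force Benjamini-Hochberg step-up
bruteBH <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- numeric(m)
    prev <- 1
    for (k in m:1) {
        val <- min(prev, m * p[o[k]] / k)
        adj[o[k]] <- val
        prev <- val
    }
    adj
}
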