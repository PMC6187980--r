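test_that("on-marker selection applies enrichment and prevalence rules", {
    ref <- makeTinyReference()
    got <- selectOnMarkers(ref, "A")
    # 190-fold enriched, mean 950, expressed everywhere -> in
    expect_true("g_good" %in% got)
    # 5-fold enrichment over B fails the 10x rule
    expect_false("g_fc5" %in% got)
    # high mean but expressed in only 50% of A cells
    expect_false("g_lowprev" %in% got)
    # enriched but mean below 100
    expect_false("g_lowmean" %in% got)
    # flat gene never qualifies
    expect_false("g_flat" %in% got)
    expect_true("g_bmark" %in% selectOnMarkers(ref, "B"))
    expect_error(selectOnMarkers(ref, "Z"), "not present")
})

test_that("pooled comparison mode is more permissive than per-type", {
    ref <- makeTinyReference()
    # g_fc5: mean 1000 in A vs pooled (200*10 + 5*10)/20 = 102.5 -> ~9.8x, still out;
    # with foldChange 9 it passes pooled but not per-type (vs B alone: 5x)
    th <- markerThresholds(foldChange = 9)
    expect_true("g_fc5" %in% selectOnMarkers(ref, "A", th, compare = "pooled"))
    expect_false("g_fc5" %in% selectOnMarkers(ref, "A", th, compare = "each"))
})

test_that("comparison exclusions allow shared GABAergic-subtype markers", {
    nc <- 6
    types <- rep(c("Ndnf", "Sst", "Pyramidal"), each = nc)
    m <- rbind(g_shared = c(rep(500, 2 * nc), rep(2, nc)),
               g_other = rep(100, 3 * nc))
    colnames(m) <- paste0("c", seq_along(types))
    ref <- makePSE(m, types, gaba = c("Ndnf", "Sst"))
    # shared by Ndnf and Sst: fails when Sst is compared ...
    expect_warning(none <- selectOnMarkers(ref, "Ndnf"), "no genes pass")
    expect_length(none, 0)
    # ... but qualifies once other GABAergic subtypes are excluded
    expect_identical(selectOnMarkers(ref, "Ndnf", exclusions = "Sst"),
                     "g_shared")
})

test_that("zero mean in a comparison type counts as infinite enrichment", {
    types <- rep(c("A", "B"), each = 5)
    m <- rbind(g1 = c(rep(200, 5), rep(0, 5)))
    colnames(m) <- paste0("c", 1:10)
    ref <- makePSE(m, types)
    expect_identical(selectOnMarkers(ref, "A"), "g1")
})

test_that("off-marker filtering keeps specific, well-expressed genes", {
    nc <- 10
    types <- rep(c("Microglia", "Ndnf"), each = nc)
    m <- rbind(
        # expressed >10 in 80% of microglia, <10 in all Ndnf -> retained
        g_keep = c(rep(c(50, 50, 50, 50, 2), 2), rep(1, nc)),
        # expressed >10 in 40% of Ndnf cells -> moderately expressed in a
        # protected type, removed
        g_modNdnf = c(rep(50, nc), rep(c(20, 20, 0, 0, 0), 2)),
        # expressed >10 in only 30% of microglia -> lowly expressed in source
        g_lowSrc = c(rep(c(50, 0, 0, 0, 50, 50, 0, 0, 0, 0), 1), rep(1, nc)))
    colnames(m) <- paste0("c", seq_along(types))
    ref <- makePSE(m, types)
    kept <- filterOffMarkers(c("g_keep", "g_modNdnf", "g_lowSrc"), ref,
                             sourceType = "Microglia", protectedTypes = "Ndnf")
    expect_identical(kept, "g_keep")
    expect_error(filterOffMarkers(character(), ref, "Microglia", "Ndnf"),
                 "empty initial")
    expect_warning(
        filterOffMarkers(c("g_keep", "g_absent"), ref, "Microglia", "Ndnf"),
        "absent from reference")
})

test_that("marker sets recover planted markers on synthetic reference data", {
    sim <- defaultSim()
    for (t in names(markerGenes(sim$ms))) {
        planted <- sim$truth$markerLists[[t]]
        got <- markerGenes(sim$ms, t)
        expect_setequal(got, planted)
    }
    expect_length(sim$ms@unusableTypes, 0)
})

test_that("genes qualifying for two broad types are removed from both", {
    nc <- 8
    types <- rep(c("T", "B1", "B2"), each = nc)
    m <- rbind(g_t = c(rep(500, nc), rep(1, 2 * nc)),
               g_b1 = c(rep(1, nc), rep(500, nc), rep(1, nc)),
               g_b2 = c(rep(1, 2 * nc), rep(500, nc)),
               # planted in both broad types at high level
               g_both = c(rep(1, nc), rep(500, nc), rep(500, nc)),
               g_b1b = c(rep(1, nc), rep(400, nc), rep(1, nc)),
               g_b2b = c(rep(1, 2 * nc), rep(400, nc)),
               g_b1c = c(rep(1, nc), rep(300, nc), rep(1, nc)),
               g_b2c = c(rep(1, 2 * nc), rep(300, nc)))
    colnames(m) <- paste0("c", seq_along(types))
    ref <- makePSE(m, types)
    # g_both arrives on both candidate lists (as with published marker
    # collections); specific to neither, it must be dropped from both
    expect_warning(
        ms <- buildMarkerSet(ref, targetTypes = "T", broadTypes = c("B1", "B2"),
                             offCandidates = list(
                                 B1 = c("g_b1", "g_b1b", "g_b1c", "g_both"),
                                 B2 = c("g_b2", "g_b2b", "g_b2c", "g_both"))),
        "multiple broad types")
    expect_false("g_both" %in% unlist(markerGenes(ms)))
    expect_setequal(markerGenes(ms, "B1"), c("g_b1", "g_b1b", "g_b1c"))
})

test_that("broad types falling below three markers are flagged unusable", {
    nc <- 8
    types <- rep(c("T", "B1"), each = nc)
    m <- rbind(g_t = c(rep(500, nc), rep(1, nc)),
               g_b1 = c(rep(1, nc), rep(500, nc)),
               # second B1 marker fails source prevalence (on in half of B1)
               g_b1weak = c(rep(1, nc), rep(c(500, 0), nc / 2)))
    colnames(m) <- paste0("c", seq_along(types))
    ref <- makePSE(m, types)
    expect_warning(
        ms <- buildMarkerSet(ref, targetTypes = "T", broadTypes = "B1"),
        "unusable")
    expect_identical(ms@unusableTypes, "B1")
})

test_that("selection is deterministic and monotone in the fold-change threshold", {
    sim <- defaultSim()
    a <- selectOnMarkers(sim$ref, "Pyramidal")
    b <- selectOnMarkers(sim$ref, "Pyramidal")
    expect_identical(a, b)
    for (fc in c(5, 10, 50, 100)) {
        lo <- suppressWarnings(
            selectOnMarkers(sim$ref, "Pyramidal", markerThresholds(foldChange = fc)))
        hi <- suppressWarnings(
            selectOnMarkers(sim$ref, "Pyramidal",
                            markerThresholds(foldChange = fc * 2)))
        expect_true(all(hi %in% lo))  # raising fold change never adds a marker
    }
})

test_that("multi-dataset selection intersects per-dataset survivors", {
    ref1 <- makeTinyReference()
    # second dataset where g_good is not enriched
    m2 <- exprValues(ref1)
    m2["g_good", ] <- 300
    ref2 <- makePSE(m2, cellTypes(ref1))
    both <- suppressWarnings(selectOnMarkers(list(ref1, ref2), "A"))
    expect_false("g_good" %in% both)
    expect_true("g_good" %in% suppressWarnings(selectOnMarkers(list(ref1, ref1), "A")))
})
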