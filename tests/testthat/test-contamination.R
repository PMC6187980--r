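test_that("marker sums follow the summed-log2 closed form", {
    expect_equal(unname(markerSum(c(g1 = 3, g2 = 7), c("g1", "g2"))), 5)
    zeros <- setNames(rep(0, 4), paste0("g", 1:4))
    expect_equal(unname(markerSum(zeros, names(zeros))), 0)
    ones <- setNames(rep(1, 10), paste0("g", 1:10))
    expect_equal(unname(markerSum(ones, names(ones))), 10)
    # matrix input gives one sum per cell
    m <- matrix(c(3, 7, 0, 0), 2, dimnames = list(c("g1", "g2"), c("c1", "c2")))
    expect_equal(markerSum(m, c("g1", "g2")), c(c1 = 5, c2 = 0))
    expect_warning(s <- markerSum(c(g1 = 3), c("g1", "gX")), "absent")
    expect_equal(unname(s), 2)
    expect_error(markerSum(c(g1 = 3), c("gX", "gY"), sourceType = "Microglia"),
                 "Microglia")
})

test_that("baselines are per-type medians of marker sums", {
    # 3 type-A cells whose B-marker sums are 1, 2, 9 -> d[A, B] = 2
    vals <- 2^c(1, 2, 9) - 1
    m <- rbind(mb = c(vals, rep(2^9 - 1, 2)),
               ma = c(rep(1000, 3), rep(1, 2)))
    colnames(m) <- paste0("c", 1:5)
    ref <- makePSE(m, c("A", "A", "A", "B", "B"))
    ms <- MarkerSet(markers = list(A = "ma", B = "mb"), broadTypes = "B")
    bl <- computeBaselines(ref, ms)
    expect_equal(baselineMatrix(bl)["A", "B"], 2)
    expect_equal(baselineMatrix(bl)["B", "B"], 9)
    expect_false(bl@degenerate["A", "B"])
    # identical cells: the median is the common value
    expect_equal(baselineMatrix(bl)["B", "B"],
                 unname(markerSum(m[, 4], "mb")))
    expect_error(computeBaselines(ref, ms, assessedTypes = c("A", "Z")),
                 ">= 2 reference cells")
})

test_that("baselines separate own type from others on synthetic data", {
    sim <- defaultSim()
    d <- baselineMatrix(sim$bl)
    for (B in colnames(d))
        expect_true(all(d[B, B] > d[rownames(d) != B, B]))
    expect_false(any(sim$bl@degenerate))
})

test_that("the contamination score is baseline-subtracted, floored and capped", {
    expect_equal(contaminationScore(5, 1, 9), 0.5)
    expect_equal(contaminationScore(0.5, 1, 9), 0)   # negative floored
    expect_equal(contaminationScore(9, 1, 9), 1)     # matches off-target median
    expect_equal(contaminationScore(17, 1, 9, cap = FALSE), 2)
    expect_equal(contaminationScore(17, 1, 9, cap = TRUE), 1)
    expect_warning(na <- contaminationScore(5, 3, 2), "non-discriminative")
    expect_true(is.na(na))
    # monotone non-decreasing in the off-target marker sum
    M <- seq(0, 12, by = 0.5)
    cs <- contaminationScore(M, 1, 9)
    expect_true(all(diff(cs) >= 0))
})

test_that("the contamination index sums applicable scores", {
    expect_equal(contaminationIndex(c(Pyr = 0.5, Micro = 0.25, Astro = 0)), 0.75)
    expect_equal(contaminationIndex(c(Pyr = 0, Micro = 0)), 0)
    # GABAergic cells are not assessed with GABAergic marker sources
    expect_equal(contaminationIndex(c(Pvalb = 0.9, Micro = 0.25),
                                    isGabaergic = TRUE,
                                    gabaergicSources = "Pvalb"), 0.25)
    expect_message(ci <- contaminationIndex(c(a = 0.5, b = NA_real_)), "skipped")
    expect_equal(ci, 0.5)
})

test_that("quality scores are rank correlations floored at 0.1", {
    prof <- setNames(2^(1:20), paste0("g", 1:20))
    expect_equal(qualityScore(prof, prof), 1)             # self-correlation
    expect_equal(qualityScore(rev(unname(prof)), unname(prof)), 0.1)  # reversed
    set.seed(42)
    panel <- setNames(runif(100, 0, 1000), paste0("g", 1:100))
    r <- qualityScore(sample(unname(panel)), unname(panel))
    expect_lt(r, 0.35)  # random permutation: near zero, floored if negative
    expect_gte(r, 0.1)
    expect_warning(f <- qualityScore(rep(1, 10), unname(prof)[1:10]),
                   "zero-variance")
    expect_equal(f, 0.1)
    expect_error(qualityScore(c(a = 1, b = 2), c(a = 2, b = 1)),
                 "at least 5 genes")
})

test_that("scored cells behave like the planted truth", {
    sim <- defaultSim()
    alpha <- sim$psTruth$true_alpha
    cs <- trueOffTargetCS(sim)
    # pure cells show essentially no contamination
    expect_lt(mean(cs[alpha == 0]), 0.1)
    # fully swapped cells score like the off-target type itself
    expect_gt(mean(cs[alpha == 1]), 0.85)
    # calling rule: any score above 0.5
    expect_identical(unname(sim$prof@contaminated),
                     unname(apply(sim$prof@cs > 0.5, 1, any, na.rm = TRUE)))
    # quality and contamination are negatively associated
    expect_lt(cor(sim$prof@qualityScore, sim$prof@contamIndex), -0.5)
    # CI equals the sum of non-missing scores
    expect_equal(sim$prof@contamIndex, unname(rowSums(sim$prof@cs, na.rm = TRUE)))
})

test_that("per-cell scores match a brute-force reimplementation", {
    sim <- defaultSim()
    d <- baselineMatrix(sim$bl)
    expr <- exprValues(sim$ps)
    idx <- seq(1, ncol(expr), by = 37)  # spot-check a spread of cells
    for (i in idx) {
        A <- cellTypes(sim$ps)[i]
        for (B in broadCellTypes(sim$ms)) {
            if (B == A) next
            mk <- markerGenes(sim$ms, B)
            M <- sum(log2(expr[mk, i] + 1))
            want <- min(1, max(0, (M - d[A, B]) / (d[B, B] - d[A, B])))
            expect_equal(unname(sim$prof@cs[i, B]), want, tolerance = 1e-12)
        }
    }
})

test_that("the mid-mixture score matches its closed-form prediction", {
    # the score is a log-scale excess measure: at alpha = 0.5 it sits well
    # above 0.5, at the level predicted from the generator's expected profiles
    sim <- defaultSim()
    alpha <- sim$psTruth$true_alpha
    cs <- trueOffTargetCS(sim)
    got <- mean(cs[alpha == 0.5])
    d <- baselineMatrix(sim$bl)
    preds <- vapply(unique(sim$psTruth$true_off_target), function(B) {
        mk <- markerGenes(sim$ms, B)
        # expected CPM of B's markers in a 50:50 mixture cell
        profs <- sim$truth$profiles
        mix <- 0.5 * profs[, sim$psTruth$true_type[1]] + 0.5 * profs[, B]
        cpm <- mix / sum(mix) * 1e6
        M <- sum(log2(cpm[mk] + 1))
        A <- sim$psTruth$true_type[1]
        min(1, max(0, (M - d[A, B]) / (d[B, B] - d[A, B])))
    }, 0)
    expect_equal(got, mean(preds), tolerance = 0.1)
    expect_gt(got, 0.7)  # log-scale compression, not ~0.5
})

test_that("contamination scores rise monotonically with off-target expression", {
    sim <- defaultSim()
    d <- baselineMatrix(sim$bl)
    mk <- markerGenes(sim$ms, "Pyramidal")
    base <- exprValues(sim$ps)[, 1]
    prev <- -Inf
    for (scale in c(0, 0.5, 1, 2, 5, 10)) {
        x <- base
        x[mk] <- x[mk] * scale + scale
        cs <- contaminationScore(unname(markerSum(x, mk)),
                                 d["Ndnf", "Pyramidal"],
                                 d["Pyramidal", "Pyramidal"])
        expect_gte(cs, prev)
        prev <- cs
    }
})

test_that("GABAergic sources are skipped for GABAergic cells", {
    nc <- 6
    types <- rep(c("Ndnf", "Pvalb", "Pyramidal"), each = nc)
    m <- rbind(mk_n1 = c(rep(900, nc), rep(1, 2 * nc)),
               mk_n2 = c(rep(700, nc), rep(2, 2 * nc)),
               mk_v1 = c(rep(1, nc), rep(900, nc), rep(1, nc)),
               mk_v2 = c(rep(2, nc), rep(700, nc), rep(2, nc)),
               mk_p1 = c(rep(1, 2 * nc), rep(900, nc)),
               mk_p2 = c(rep(2, 2 * nc), rep(700, nc)))
    colnames(m) <- paste0("c", seq_along(types))
    ref <- makePSE(m, types, gaba = c("Ndnf", "Pvalb"))
    ms <- MarkerSet(markers = list(Ndnf = c("mk_n1", "mk_n2"),
                                   Pvalb = c("mk_v1", "mk_v2"),
                                   Pyramidal = c("mk_p1", "mk_p2")),
                    broadTypes = c("Pvalb", "Pyramidal"),
                    comparisonExclusions = list(Ndnf = "Pvalb", Pvalb = "Ndnf"))
    bl <- computeBaselines(ref, ms)
    prof <- scoreCells(ref[, types == "Ndnf"], ms, bl, ref, qualityFloor = 0.1)
    expect_true(all(is.na(prof@cs[, "Pvalb"])))
    expect_false(anyNA(prof@cs[, "Pyramidal"]))
})

test_that("cells with unmapped types are rejected and low-marker cells droppable", {
    sim <- defaultSim()
    odd <- makePSE(exprValues(sim$ps)[, 1:5], rep("Mystery", 5),
                   normalization = "CPM_UMI")
    expect_error(scoreCells(odd, sim$ms, sim$bl, sim$ref), "unmapped")
    # typeMap translates labels
    prof <- scoreCells(odd, sim$ms, sim$bl, sim$ref,
                       typeMap = c(Mystery = "Ndnf"))
    expect_identical(unique(prof@cellType), "Ndnf")
    # dropLowMarkerCells removes cells expressing almost none of their own markers
    m <- exprValues(sim$ps)[, 1:5]
    mk <- markerGenes(sim$ms, "Ndnf")
    m[mk, 1] <- 0
    dark <- makePSE(m, rep("Ndnf", 5), normalization = "CPM_UMI",
                    gaba = "Ndnf")
    prof2 <- suppressMessages(
        scoreCells(dark, sim$ms, sim$bl, sim$ref, dropLowMarkerCells = TRUE))
    expect_identical(length(prof2@cellId), 4L)
})
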