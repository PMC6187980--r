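test_that("gene filtering uses the interpolated percentile of gene means", {
    m <- matrix(rep(1:10, each = 4), nrow = 10, byrow = TRUE,
                dimnames = list(paste0("g", 1:10), paste0("c", 1:4)))
    kept <- filterGenes(m, 0.30)
    # quantile(1:10, .3) = 3.7 -> genes with mean > 3.7
    expect_identical(rownames(kept), paste0("g", 4:10))
    kept0 <- filterGenes(m, 0)
    expect_identical(rownames(kept0), paste0("g", 2:10))
    flat <- matrix(5, 10, 4, dimnames = list(paste0("g", 1:10), paste0("c", 1:4)))
    expect_warning(none <- filterGenes(flat), "no genes above")
    expect_identical(nrow(none), 0L)
    expect_error(filterGenes(m[1:3, ]), "at least 10 genes")
})

test_that("uniform weights reduce to the ordinary Pearson test", {
    set.seed(21)
    x <- rnorm(40); y <- 0.5 * x + rnorm(40)
    res <- weightedPearson(x, y)
    ct <- cor.test(x, y)
    expect_equal(res$r, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(res$p, ct$p.value, tolerance = 1e-12)
    # rescaling all weights by a constant changes nothing
    res2 <- weightedPearson(x, y, rep(7, 40))
    expect_equal(res2$r, res$r, tolerance = 1e-14)
})

test_that("weight concentration and degenerate inputs behave as specified", {
    # all weight on two points: correlation is +/-1
    expect_equal(abs(weightedPearson(c(1, 2, 5, 9), c(3, -2, 0, 1),
                                     c(1, 1, 0, 0))$r), 1)
    expect_warning(res <- weightedPearson(rep(1, 5), rnorm(5)), "zero variance")
    expect_true(is.na(res$r))
    expect_error(weightedPearson(1:2, 1:2), "at least 3")
    expect_error(weightedPearson(1:4, 4:1, rep(0, 4)), "not all be zero")
    expect_error(weightedPearson(1:4, 4:1, c(-1, 1, 1, 1)), "nonnegative")
    # missing pairs are dropped
    expect_equal(weightedPearson(c(1, 2, 3, NA), c(1, 2, 3, 9))$n, 3)
})

test_that("weighted moments match an independent brute-force oracle", {
    got <- weightedPearson(c(1, 2, 3, 4), c(1, 2, 3, 10), c(1, 1, 1, 0.1))
    want <- bruteWeightedPearson(c(1, 2, 3, 4), c(1, 2, 3, 10), c(1, 1, 1, 0.1))
    expect_equal(got$r, want$r, tolerance = 1e-12)
    expect_equal(got$p, want$p, tolerance = 1e-12)
})

test_that("BH adjustment is the step-up procedure", {
    expect_equal(bhFDR(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_equal(bhFDR(0.37), 0.37)
    expect_equal(bhFDR(rep(1, 5)), rep(1, 5))
    expect_error(bhFDR(c(0.5, 0)), "0, 1")
    expect_error(bhFDR(c(0.5, 1.2)), "0, 1")
    # adjusted values dominate raw ones within the family
    set.seed(3)
    p <- runif(30)
    expect_true(all(bhFDR(p) >= p))
})

test_that("correlateAll matches per-pair computation and respects weights", {
    set.seed(5)
    n <- 30
    m <- matrix(2^rnorm(5 * n, 6), 5, n,
                dimnames = list(paste0("g", 1:5), paste0("c", 1:n)))
    ephys <- data.frame(cell_id = colnames(m),
                        Rin = log2(m["g1", ] + 1) + rnorm(n, 0, 0.3),
                        APhw = rnorm(n))
    ephys$APhw[3] <- NA
    w <- setNames(runif(n, 0.1, 1), colnames(m))

    res <- correlateAll(m, ephys, weights = w)
    expect_identical(nrow(res), 10L)
    # equal weights: weighted equals unweighted
    resU <- correlateAll(m, ephys, weights = NULL)
    expect_equal(resU$r_weighted, resU$r_unweighted, tolerance = 1e-12)
    expect_equal(resU$p_weighted, resU$p_unweighted, tolerance = 1e-12)
    # spot-check one weighted pair against the scalar implementation
    ok <- !is.na(ephys$APhw)
    ref <- weightedPearson(log2(m["g2", ok] + 1), ephys$APhw[ok], w[ok])
    row <- res[res$gene == "g2" & res$feature == "APhw", ]
    expect_equal(row$r_weighted, ref$r, tolerance = 1e-12)
    expect_equal(row$p_weighted, ref$p, tolerance = 1e-12)
    expect_identical(row$n, sum(ok))
    # FDR within each feature family dominates the raw p-values
    expect_true(all(res$fdr_weighted >= res$p_weighted - 1e-15))
    expect_error(correlateAll(m[, 1:4], ephys[1:4, ]), "at least 5")
    expect_error(correlateAll(m, data.frame(cell_id = "zz", Rin = 1)),
                 "no shared cells")
})

test_that("permuted features yield essentially no discoveries", {
    set.seed(17)
    n <- 40
    m <- matrix(2^rnorm(500 * n, 5), 500, n,
                dimnames = list(paste0("g", 1:500), paste0("c", 1:n)))
    ephys <- data.frame(cell_id = colnames(m), Rin = sample(rnorm(n)))
    res <- correlateAll(m, ephys)
    expect_lte(sum(res$sig_unweighted), 1)
})

test_that("pooled cell types carry harmonic-mean weights", {
    expect_equal(harmonicMeanWeight(89, 14), 2 * 89 * 14 / 103)
    expect_equal(harmonicMeanWeight(89, 14), 24.1942, tolerance = 1e-4)
    expect_equal(harmonicMeanWeight(7, 7), 7)   # symmetry
    expect_true(all(harmonicMeanWeight(1:10, 3) <= 2 * pmin(1:10, 3)))

    set.seed(2)
    mkMat <- function(n) matrix(2^rnorm(20 * n, 5), 20, n,
                                dimnames = list(paste0("g", 1:20), NULL))
    exprGroups <- list(t1 = mkMat(4), t2 = mkMat(6), t3 = mkMat(3),
                       t4 = mkMat(5), t5 = mkMat(7))
    ephysGroups <- lapply(list(t1 = 3, t2 = 8, t3 = 2, t4 = 5, t5 = 4),
                          function(k) data.frame(Rin = rnorm(k), APhw = rnorm(k)))
    pooled <- poolCellTypes(exprGroups, ephysGroups)
    expect_identical(colnames(pooled$expr), c("t1", "t2", "t3", "t4", "t5"))
    expect_equal(unname(pooled$weights["t2"]), harmonicMeanWeight(8, 6))
    expect_equal(pooled$expr["g1", "t1"], mean(exprGroups$t1["g1", ]))
    expect_equal(pooled$ephys$Rin[pooled$ephys$type_id == "t3"],
                 mean(ephysGroups$t3$Rin))
    # a type missing a modality is skipped with a warning
    expect_warning(p2 <- poolCellTypes(exprGroups[1:4], ephysGroups), "skipped")
    expect_identical(names(p2$weights), c("t1", "t2", "t3", "t4"))
    expect_error(suppressWarnings(poolCellTypes(exprGroups[1:2], ephysGroups)),
                 "at least 3")
    # pooled correlation plumbs through correlateAll
    res <- correlateAll(pooled$expr,
                        cbind(pooled$ephys),
                        weights = pooled$weights, fdrCutoff = 0.1)
    expect_identical(sort(unique(res$feature)), c("APhw", "Rin"))
})
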