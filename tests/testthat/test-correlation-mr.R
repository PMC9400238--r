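test_that("Pearson correlations match the formula on the toy and random matrices", {
    cc <- as.matrix(computePcc(toyExpr()))
    expect_equal(cc["g1", "g2"], 1)
    expect_equal(cc["g1", "g3"], -1)
    expect_equal(cc["g1", "g4"], 0.8)
    expect_equal(cc, t(cc), tolerance = 1e-12)

    ## brute-force double-loop oracle on random matrices
    for (seed in c(1, 2, 3)) {
        m <- randExpr(10, 6, seed = seed)
        expect_equal(as.matrix(computePcc(m)), oraclePccMatrix(m),
                     tolerance = 1e-10)
    }

    ## zero-variance gene is flagged undefined, not NaN-propagated silently
    m <- toyExpr()
    m <- rbind(m, flat = rep(2, 5))
    expect_warning(c5 <- computePcc(m), "zero-variance")
    expect_true(c5@undefined["flat"])
    expect_true(all(is.na(as.matrix(c5)["flat", ])))
    expect_equal(as.matrix(c5)["g1", "g4"], 0.8)

    expect_error(computePcc(toyExpr()[, 1:2]), "3 samples")
})

test_that("quantile thresholds follow the linear-interpolation convention with additive offset", {
    ## correlation matrix whose off-diagonal set is exactly
    ## {-0.9, -0.5, 0, 0.5, 0.9} (plus one duplicated 0 to fill 4x4)
    vals <- c(-0.9, -0.5, 0, 0.5, 0.9, 0)
    cc <- diag(4)
    cc[upper.tri(cc)] <- vals
    cc <- cc + t(cc) - diag(4) + diag(4) * 0
    diag(cc) <- 1
    dimnames(cc) <- list(paste0("g", 1:4), paste0("g", 1:4))
    co <- asCorr(cc)
    t0 <- pccQuantileThresholds(co, topQ = 0.2, bottomQ = 0.2)
    expect_equal(t0@posCut,
                 unname(quantile(c(vals), 0.8, type = 7)))
    ## additivity of the offset before clamping
    t1 <- pccQuantileThresholds(co, topQ = 0.2, bottomQ = 0.2, offset = 0.1)
    expect_equal(t1@posCut, t0@posCut + 0.1)
    expect_equal(t1@negCut, t0@negCut - 0.1)
    ## one-sided tightening leaves the negative cut alone
    t1p <- pccQuantileThresholds(co, topQ = 0.2, bottomQ = 0.2, offset = 0.1,
                                 symmetric = FALSE)
    expect_equal(t1p@negCut, t0@negCut)
    ## clamping at the ends of [-1, 1] warns
    expect_warning(tc <- pccQuantileThresholds(co, topQ = 0.2, bottomQ = 0.2,
                                               offset = 0.6,
                                               symmetric = FALSE), "clamp")
    expect_equal(tc@posCut, 1)
    tb <- suppressWarnings(pccQuantileThresholds(co, topQ = 0.2,
                                                 bottomQ = 0.2, offset = 0.6))
    expect_equal(tb@posCut, 1)
    expect_equal(tb@negCut, -1)
})

test_that("directional ranks sort partners by correlation with lexicographic ties", {
    co <- computePcc(toyExpr())
    r <- as.matrix(computeRanks(co))
    ## row g1: partners g2 (1.0) > g4 (0.8) > g3 (-1)
    expect_equal(r["g1", c("g2", "g4", "g3")], c(g2 = 1, g4 = 2, g3 = 3))
    expect_equal(r, oracleRanks(as.matrix(co)))

    ## identical correlations: the lexicographically smaller id ranks first
    cc <- diag(3)
    cc[upper.tri(cc)] <- c(0.5, 0.5, 0.1)  # (a,b)=.5 (a,c)=.5 (b,c)=.1
    cc <- cc + t(cc); diag(cc) <- 1
    dimnames(cc) <- list(c("a", "b", "c"), c("a", "b", "c"))
    rt <- as.matrix(computeRanks(asCorr(cc)))
    expect_equal(rt["a", "b"], 1)
    expect_equal(rt["a", "c"], 2)

    ## two genes: mutual rank 1 both ways
    cc2 <- matrix(c(1, 0.3, 0.3, 1), 2, 2,
                  dimnames = list(c("x", "y"), c("x", "y")))
    r2 <- as.matrix(computeRanks(asCorr(cc2)))
    expect_equal(unname(r2["x", "y"]), 1)
    expect_equal(unname(r2["y", "x"]), 1)

    ## every row is a permutation over partners (randomized)
    for (seed in c(5, 6)) {
        m <- randExpr(12, 8, seed = seed)
        rr <- as.matrix(computeRanks(computePcc(m)))
        expect_equal(rr, oracleRanks(oraclePccMatrix(m)))
        for (i in seq_len(nrow(rr)))
            expect_setequal(rr[i, -i], 1:(nrow(rr) - 1))
    }
})

test_that("mutual ranks are the geometric mean of the directional ranks", {
    ## analytically forced: Rank(A->B)=4, Rank(B->A)=9 -> MR = 6
    rk <- matrix(NA_real_, 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
    rk["A", "B"] <- 4; rk["B", "A"] <- 9
    mr <- as.matrix(computeMr(new("RankMatrix", values = rk)))
    expect_equal(unname(mr["A", "B"]), 6)
    expect_equal(unname(mr["B", "A"]), 6)

    ## toy: g1 and g2 rank each other first -> MR 1
    co <- computePcc(toyExpr())
    mrt <- as.matrix(computeMr(computeRanks(co)))
    expect_equal(unname(mrt["g1", "g2"]), 1)

    ## symmetry and invariance under monotone transforms of the correlations
    m <- randExpr(15, 7, seed = 9)
    co <- computePcc(m)
    mr1 <- as.matrix(computeMr(computeRanks(co)))
    expect_identical(mr1, t(mr1))
    expect_true(all(mr1[upper.tri(mr1)] >= 1))
    warped <- asCorr(sign(as.matrix(co)) * abs(as.matrix(co))^(1 / 3))
    mr2 <- as.matrix(computeMr(computeRanks(warped)))
    expect_equal(mr1, mr2)
})

test_that("MR edge filter applies strict cuts and the any/all combination rule", {
    ## 3 genes with controlled ranks via a constructed rank matrix
    mkCase <- function(mrVal, minRank) {
        rk <- matrix(NA_real_, 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
        rk["A", "B"] <- minRank
        rk["B", "A"] <- mrVal^2 / minRank
        cc <- matrix(c(1, 0.9, 0.9, 1), 2, 2, dimnames = dimnames(rk))
        list(mr = computeMr(new("RankMatrix", values = rk)),
             r = new("RankMatrix", values = rk), c = asCorr(cc))
    }
    ## MR=29.9 passes the bidirectional rule alone
    cs <- mkCase(29.9, 10)
    expect_equal(nEdges(mrEdgeFilter(cs$mr, cs$r, cs$c)), 1)
    ## MR=50 with min rank 2: kept by any, dropped by all
    cs <- mkCase(50, 2)
    expect_equal(nEdges(mrEdgeFilter(cs$mr, cs$r, cs$c, combine = "any")), 1)
    expect_equal(nEdges(mrEdgeFilter(cs$mr, cs$r, cs$c, combine = "all")), 0)
    ## boundary: MR exactly 30 (and min rank 3) is dropped - strict cuts
    cs <- mkCase(30, 3)
    expect_equal(nEdges(mrEdgeFilter(cs$mr, cs$r, cs$c)), 0)

    ## retained edges carry both directional ranks, mr, pcc, sign
    cs <- mkCase(6, 4)  # ranks 4 and 9
    e <- edges(mrEdgeFilter(cs$mr, cs$r, cs$c))
    expect_equal(e$rank_ab, 4)
    expect_equal(e$rank_ba, 9)
    expect_equal(e$mr, 6)
    expect_equal(e$pcc, 0.9)
    expect_identical(e$sign, "+")
    expect_identical(e$methods, "mr")

    ## monotonicity: relaxing either cut never removes a kept edge
    m <- randExpr(12, 6, seed = 13)
    co <- computePcc(m); r <- computeRanks(co); mr <- computeMr(r)
    key <- function(e) paste(edges(e)$gene_a, edges(e)$gene_b)
    base <- key(mrEdgeFilter(mr, r, co, mrCut = 4, uniCut = 2))
    expect_true(all(base %in% key(mrEdgeFilter(mr, r, co, mrCut = 8, uniCut = 2))))
    expect_true(all(base %in% key(mrEdgeFilter(mr, r, co, mrCut = 4, uniCut = 5))))

    ## inconsistent gene universes are rejected
    other <- computePcc(randExpr(12, 6, seed = 14)[sample(12), ])
    expect_error(mrEdgeFilter(mr, r, other), "universe")
})

test_that("hard correlation filter keeps closed intervals at the cuts", {
    cc <- diag(3)
    cc[upper.tri(cc)] <- c(0.58, 0.99, 0)
    cc <- cc + t(cc); diag(cc) <- 1
    dimnames(cc) <- list(paste0("g", 1:3), paste0("g", 1:3))
    co <- asCorr(cc)
    t <- new("PccThresholds", posCut = 0.58, negCut = -0.45, topQ = 0.05,
             bottomQ = 0.05, offset = 0)
    e <- edges(pccEdgeFilter(co, t))
    ## pcc exactly at the positive cut is kept (closed interval), 0 dropped
    expect_equal(nrow(e), 2)
    expect_true(all(e$pcc >= 0.58))
    expect_identical(unique(e$sign), "+")
    expect_identical(unique(e$methods), "pcc")

    ## negative side: pcc <= negCut kept with negative sign
    cc2 <- diag(2); cc2[1, 2] <- cc2[2, 1] <- -0.5
    diag(cc2) <- 1
    dimnames(cc2) <- list(c("a", "b"), c("a", "b"))
    en <- edges(pccEdgeFilter(asCorr(cc2), t))
    expect_identical(en$sign, "-")

    ## extreme cuts: nothing survives / everything survives
    m <- randExpr(10, 6, seed = 21)
    co <- computePcc(m)
    hi <- new("PccThresholds", posCut = 1, negCut = -1, topQ = 0, bottomQ = 0,
              offset = 0)
    expect_equal(nEdges(pccEdgeFilter(co, hi)), 0)  # no perfect correlations
    lo <- new("PccThresholds", posCut = -1 + 1e-12, negCut = -1, topQ = 0,
              bottomQ = 0, offset = 0)
    expect_equal(nEdges(pccEdgeFilter(co, lo)), choose(10, 2))
})
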