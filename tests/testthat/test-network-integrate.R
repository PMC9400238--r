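test_that("edge-set integration obeys union/intersection set algebra", {
    A <- edgeTable(gene_a = c("a", "b"), gene_b = c("b", "c"),
                   pcc = c(0.9, 0.8), mr = c(2, 3), methods = "mr")
    B <- edgeTable(gene_a = c("b", "c"), gene_b = c("c", "d"),
                   tom = c(0.4, 0.2), methods = "tom")
    u <- integrateEdges(A, B, "union")
    eu <- edges(u)
    expect_equal(nEdges(u), 3)
    expect_setequal(paste(eu$gene_a, eu$gene_b), c("a b", "b c", "c d"))
    ## shared pair carries both provenances and both score columns
    bc <- eu[eu$gene_a == "b", ]
    expect_identical(bc$methods, "mr,tom")
    expect_equal(bc$pcc, 0.8)
    expect_equal(bc$tom, 0.4)
    ## union gene set is the union of the inputs
    expect_setequal(geneIds(u), union(geneIds(A), geneIds(B)))

    i <- integrateEdges(A, B, "intersection")
    expect_equal(nEdges(i), 1)
    expect_identical(edges(i)$gene_a, "b")

    ## empty table is the identity element of union
    E <- edgeTable()
    expect_equal(edges(integrateEdges(A, E, "union")), edges(A))

    ## conflicting shared numeric column: second table's value kept qualified
    B2 <- edgeTable(gene_a = "b", gene_b = "c", pcc = 0.1, methods = "tom")
    expect_warning(u2 <- integrateEdges(A, B2, "union"), "pcc_tom")
    expect_equal(edges(u2)$pcc[edges(u2)$gene_a == "b"], 0.8)
    expect_equal(edges(u2)$pcc_tom[edges(u2)$gene_a == "b"], 0.1)

    ## randomized invariants
    set.seed(55)
    for (rep in 1:5) {
        g <- sprintf("g%02d", 1:12)
        pr <- t(combn(g, 2))
        X <- quickEdges(pr[sample(nrow(pr), 20), ],
                        pcc = runif(20, -1, 1), methods = "pcc")
        Y <- quickEdges(pr[sample(nrow(pr), 20), ],
                        tom = runif(20), methods = "tom")
        un <- integrateEdges(X, Y, "union")
        it <- integrateEdges(X, Y, "intersection")
        expect_lte(nEdges(un), nEdges(X) + nEdges(Y))
        key <- function(e) paste(edges(e)$gene_a, edges(e)$gene_b)
        expect_true(all(key(it) %in% key(X)) && all(key(it) %in% key(Y)))
        expect_setequal(key(un), union(key(X), key(Y)))
    }
})

test_that("network statistics reproduce coverage and connectivity arithmetic", {
    tri <- edgeTable(gene_a = c("a", "a", "b"), gene_b = c("b", "c", "c"),
                     pcc = c(0.9, 0.8, 0.7), methods = "pcc")
    s <- networkStats(tri, sprintf("g%02d", 1:7) |> c("a", "b", "c"))
    expect_equal(s@nGenes, 3L)
    expect_equal(s@nEdges, 3L)
    expect_equal(s@geneCoveragePct, 30)
    expect_equal(s@meanConnectivity, 2)
    expect_equal(s@pctNegativeEdges, 0)   # all edges positive

    ## 91 edges of which 19 negative -> 20.88% negative
    n <- 91; neg <- 19
    ga <- sprintf("a%03d", seq_len(n)); gb <- sprintf("b%03d", seq_len(n))
    e91 <- edgeTable(gene_a = ga, gene_b = gb,
                     pcc = c(rep(-0.9, neg), rep(0.9, n - neg)),
                     methods = "pcc")
    s91 <- networkStats(e91, c(ga, gb))
    expect_equal(s91@pctNegativeEdges, 100 * 19 / 91)
    expect_equal(round(s91@pctNegativeEdges, 2), 20.88)

    expect_error(networkStats(tri, c("a", "b")), "absent")
})

test_that("family subnetworks report both per-gene pair conventions", {
    ## 136 cross-family edges between 24 and 8 genes -> 4.25 pairs per gene
    lhcb <- sprintf("B%02d", 1:24); lhca <- sprintf("A%02d", 1:8)
    all_pairs <- expand.grid(a = lhcb, b = lhca, stringsAsFactors = FALSE)
    set.seed(8)
    pick <- all_pairs[sample(nrow(all_pairs), 136), ]
    net <- edgeTable(gene_a = pick$a, gene_b = pick$b, pcc = 0.9,
                     methods = "pcc")
    sub <- familySubnetwork(net, lhcb, lhca)
    expect_equal(nEdges(sub$edges), 136)
    expect_equal(nrow(sub$degrees), 32)
    expect_equal(sub$pairsPerGene, 136 / 32)   # = 4.25, edges per gene
    expect_equal(sub$pairsPerGene, 4.25)
    expect_equal(sub$meanDegree, 2 * 136 / 32) # = 8.5, average degree
    ## mean connectivity of the subnetwork equals the degree-table mean
    ss <- networkStats(sub$edges, c(lhca, lhcb))
    expect_equal(ss@meanConnectivity, mean(sub$degrees$degree))

    ## disjoint families without cross edges: empty subnetwork
    none <- familySubnetwork(net, c("X1", "X2"), c("Y1", "Y2"))
    expect_equal(nEdges(none$edges), 0)
    expect_equal(none$pairsPerGene, 0)

    ## a single edge between two genes: 0.5 pairs per gene
    one <- edgeTable(gene_a = "u", gene_b = "v", pcc = 0.9, methods = "pcc")
    expect_equal(familySubnetwork(one, c("u"), c("v"))$pairsPerGene, 0.5)

    expect_error(familySubnetwork(net, character()), "non-empty")
})

test_that("top-k neighborhoods follow the rank ordering", {
    co <- computePcc(toyExpr())
    expect_identical(topNeighborhood(co, "g1", 2), c("g2", "g4"))
    expect_identical(topNeighborhood(co, "g1", 0), character())
    expect_warning(all3 <- topNeighborhood(co, "g1", 10), "partners")
    expect_identical(all3, c("g2", "g4", "g3"))
    expect_error(topNeighborhood(co, "nope", 2), "not in")

    ## full neighborhood ordering equals the rank-matrix row
    m <- randExpr(12, 8, seed = 77)
    co <- computePcc(m)
    r <- as.matrix(computeRanks(co))
    nb <- suppressWarnings(topNeighborhood(co, "g05", 11))
    expect_identical(nb, names(sort(r["g05", -5])))
})

test_that("homolog overlap counts map hits between neighborhoods", {
    map <- data.frame(a = c("a1", "a2"), b = c("b1", "b1"))
    expect_equal(homologOverlap(c("a1", "a2"), "b1", map[1, ])$n, 1)
    expect_equal(homologOverlap(c("a1", "a2"), "b1", map)$n, 2)
    expect_equal(homologOverlap(c("a1"), "b9", map)$n, 0)
    empty <- data.frame(a = character(), b = character())
    expect_equal(homologOverlap(c("a1"), c("b1"), empty)$n, 0)
})

test_that("term enrichment matches exact hypergeometric enumeration with BH", {
    universe <- sprintf("g%02d", 1:10)
    ann <- data.frame(gene = universe[1:5], term = "T1")
    res <- enrichTerms(universe[1:4], ann, universe)
    ## N=10, K=5, n=4, k=4 -> p = C(5,4) C(5,0) / C(10,4) = 5/210
    expect_equal(res$p, 5 / 210)
    expect_equal(res[, c("k", "K", "n", "N")],
                 data.frame(k = 4L, K = 5L, n = 4L, N = 10L),
                 ignore_attr = TRUE)
    ## single term: q = p
    expect_equal(res$q, res$p)

    ## k = 0: upper tail includes the observed zero -> p = 1
    res0 <- enrichTerms(universe[6:9], ann, universe)
    expect_equal(res0$p, 1)

    ## brute-force pmf enumeration across random small configurations
    set.seed(123)
    for (i in 1:20) {
        N <- sample(8:25, 1)
        uni <- sprintf("u%02d", seq_len(N))
        K <- sample(2:(N - 1), 1)
        n <- sample(2:(N - 1), 1)
        ann2 <- data.frame(gene = sample(uni, K), term = "X")
        set <- sample(uni, n)
        r <- enrichTerms(set, ann2, uni)
        expect_equal(r$p, oracleHyperP(sum(set %in% ann2$gene), K, n, N),
                     tolerance = 1e-12)
    }
    ## BH across several terms agrees with p.adjust
    ann3 <- data.frame(gene = rep(universe, 2),
                       term = rep(c("A", "B"), each = 10)[1:20])
    ann3 <- rbind(ann3, data.frame(gene = universe[1:3], term = "C"))
    r3 <- enrichTerms(universe[1:4], ann3, universe)
    expect_equal(r3$q, p.adjust(r3$p, "BH"))
    expect_error(enrichTerms(c("zz"), ann, universe), "contained")
})

test_that("hub ranking orders candidates by degree with lexicographic ties", {
    star <- edgeTable(gene_a = rep("hub", 4),
                      gene_b = c("l1", "l2", "l3", "l4"),
                      pcc = 0.9, methods = "pcc")
    h <- hubRank(star, c("hub", "l1", "iso"))
    expect_identical(h$gene, c("hub", "l1", "iso"))
    expect_equal(h$degree, c(4L, 1L, 0L))  # isolated candidate ranks last
    ## equal degree: lexicographic order
    h2 <- hubRank(star, c("l2", "l1"))
    expect_identical(h2$gene, c("l1", "l2"))
})

test_that("edge tables survive a TSV round trip", {
    e <- edgeTable(gene_a = c("a", "b"), gene_b = c("b", "c"),
                   pcc = c(-0.9, 0.5), mr = c(1.5, NA), tom = c(NA, 0.3),
                   rank_ab = c(1, NA), rank_ba = c(2, NA),
                   methods = c("mr", "tom"))
    f <- tempfile(fileext = ".tsv")
    writeEdgeTable(e, f)
    back <- readEdgeTable(f)
    expect_equal(edges(back)$pcc, edges(e)$pcc)
    expect_equal(edges(back)$mr, edges(e)$mr)
    expect_identical(edges(back)$sign, edges(e)$sign)
    expect_identical(edges(back)$methods, edges(e)$methods)
})
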