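## Independent brute-force oracles and shared fixtures. The oracles evaluate
## the defining formulas directly (double/triple loops, exhaustive
## enumeration) and never call the package functions they check.

oraclePcc <- function(x, y) {
    n <- length(x)
    sum((x - mean(x)) * (y - mean(y))) /
        sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

oraclePccMatrix <- function(m) {
    g <- nrow(m)
    out <- matrix(NA_real_, g, g, dimnames = list(rownames(m), rownames(m)))
    for (i in seq_len(g)) for (j in seq_len(g))
        out[i, j] <- oraclePcc(m[i, ], m[j, ])
    out
}

## directional ranks by explicit sort, ties by gene id
oracleRanks <- function(cc) {
    g <- rownames(cc)
    out <- matrix(NA_real_, nrow(cc), ncol(cc), dimnames = dimnames(cc))
    for (a in g) {
        partners <- setdiff(g, a)
        ord <- partners[order(-cc[a, partners], partners, method = "radix")]
        out[a, ord] <- seq_along(ord)
    }
    out
}

## unsigned TOM by triple loop over the formula
oracleTom <- function(a) {
    g <- nrow(a)
    out <- matrix(0, g, g, dimnames = dimnames(a))
    k <- numeric(g)
    for (i in seq_len(g)) k[i] <- sum(a[i, -i])
    for (i in seq_len(g)) for (j in seq_len(g)) {
        if (i == j) { out[i, j] <- 1; next }
        L <- 0
        for (u in seq_len(g)) if (u != i && u != j) L <- L + a[i, u] * a[u, j]
        out[i, j] <- (L + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
    }
    out
}

## AUC as the mean over all positive-negative comparisons, half credit ties
oracleAuc <- function(pos, neg) {
    cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
    mean(cmp)
}

## hypergeometric upper tail by exhaustive pmf summation
oracleHyperP <- function(k, K, n, N) {
    i <- max(k, max(0, n - (N - K))):min(K, n)
    sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

## wrap a numeric correlation matrix (diag 1, symmetric) as the S4 class
asCorr <- function(cc, undefined = NULL) {
    if (is.null(undefined)) {
        undefined <- rep(FALSE, nrow(cc))
        names(undefined) <- rownames(cc)
    }
    new("CorrelationMatrix", values = cc, undefined = undefined)
}

asAdj <- function(a, beta = 1L) {
    diag(a) <- 1
    new("AdjacencyMatrix", values = a, beta = as.integer(beta))
}

## the 4-gene toy used across modules
toyExpr <- function() {
    m <- rbind(g1 = c(1, 2, 3, 4, 5), g2 = c(2, 4, 6, 8, 10),
               g3 = c(5, 4, 3, 2, 1), g4 = c(1, 3, 2, 5, 4))
    colnames(m) <- paste0("s", 1:5)
    m
}

## random positive expression matrix with gene/sample names
randExpr <- function(nGenes, nSamples, seed) {
    set.seed(seed)
    m <- matrix(exp(rnorm(nGenes * nSamples)), nGenes, nSamples,
                dimnames = list(sprintf("g%02d", seq_len(nGenes)),
                                sprintf("s%02d", seq_len(nSamples))))
    m
}

## random symmetric adjacency in [0,1] with unit diagonal
randAdj <- function(nGenes, seed) {
    set.seed(seed)
    a <- matrix(runif(nGenes^2), nGenes, nGenes)
    a <- (a + t(a)) / 2
    diag(a) <- 1
    dimnames(a) <- list(sprintf("g%02d", seq_len(nGenes)),
                        sprintf("g%02d", seq_len(nGenes)))
    a
}

## quick edge table over given pairs with one score column
quickEdges <- function(pairs, pcc = NA_real_, mr = NA_real_, tom = NA_real_,
                       methods = "pcc") {
    edgeTable(gene_a = pairs[, 1L], gene_b = pairs[, 2L], pcc = pcc,
              mr = mr, tom = tom, methods = methods)
}

## gold standard directly from labelled pairs
asGold <- function(gene_a, gene_b, label) {
    p <- data.frame(gene_a = pmin(gene_a, gene_b),
                    gene_b = pmax(gene_a, gene_b), label = label,
                    stringsAsFactors = FALSE)
    new("GoldStandard", pairs = p, source = "test", seed = 0L)
}
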