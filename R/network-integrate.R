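## Edge-set integration with provenance, network statistics, family
## subnetworks, neighborhoods, homolog overlap, and term enrichment.

.methodOrder <- c("pcc", "mr", "tom")

.canonMethods <- function(m) {
    parts <- sort(unique(unlist(strsplit(m, ","))))
    paste(parts[order(match(parts, .methodOrder))], collapse = ",")
}

.primaryMethod <- function(e) {
    m <- unlist(strsplit(e@edges$methods, ","))
    if (!length(m)) "none" else m[which.min(match(m, .methodOrder))]
}

#' Integrate two edge tables
#'
#' `union` merges pair-wise: a pair present in both contributes one row whose
#' `methods` is the union of the two provenance sets and whose score columns
#' are coalesced (taken from whichever table defines them). When both tables
#' define the same numeric column with materially different values, the first
#' table's value is kept in the plain column and the second's is preserved in
#' a method-qualified column (e.g. `pcc_tom`), with a warning.
#' `intersection` keeps only pairs present in both tables.
#'
#' @param a,b [EdgeTable-class] objects.
#' @param mode `"union"` (default) or `"intersection"`.
#' @param tol numeric tolerance for declaring a shared score column
#'   conflicting.
#' @return an [EdgeTable-class].
#' @export
integrateEdges <- function(a, b, mode = c("union", "intersection"),
                           tol = 1e-8) {
    stopifnot(methods::is(a, "EdgeTable"), methods::is(b, "EdgeTable"))
    mode <- match.arg(mode)
    ea <- a@edges
    eb <- b@edges
    keyA <- .pairKey(ea$gene_a, ea$gene_b)
    keyB <- .pairKey(eb$gene_a, eb$gene_b)
    numCols <- c("pcc", "rank_ab", "rank_ba", "mr", "tom")
    if (mode == "intersection") {
        keep <- keyA %in% keyB
        ea <- ea[keep, , drop = FALSE]
        keyA <- keyA[keep]
    }
    m <- match(keyA, keyB)
    out <- ea
    for (col in numCols) {
        other <- eb[[col]][m]
        fill <- is.na(out[[col]]) & !is.na(other)
        out[[col]][fill] <- other[fill]
        clash <- !is.na(out[[col]]) & !is.na(other) &
            abs(out[[col]] - other) > tol
        if (any(clash)) {
            qcol <- paste(col, .primaryMethod(b), sep = "_")
            warning("conflicting values in shared column '", col,
                    "'; second table's values kept as '", qcol, "'")
            out[[qcol]] <- ifelse(clash, other, NA_real_)
        }
    }
    shared <- !is.na(m)
    out$methods[shared] <- vapply(
        paste(out$methods[shared], eb$methods[m[shared]], sep = ","),
        .canonMethods, character(1L))
    if (mode == "union") {
        only_b <- eb[!(keyB %in% keyA), , drop = FALSE]
        out <- .rbindEdges(out, only_b)
    }
    out$sign <- ifelse(is.na(out$pcc), out$sign,
                       ifelse(out$pcc < 0, "-", "+"))
    out <- out[order(out$gene_a, out$gene_b, method = "radix"), ,
               drop = FALSE]
    rownames(out) <- NULL
    methods::new("EdgeTable", edges = out)
}

## rbind two edge data.frames whose columns may differ (qualified columns)
.rbindEdges <- function(x, y) {
    allCols <- union(colnames(x), colnames(y))
    for (col in setdiff(allCols, colnames(x)))
        x[[col]] <- rep(NA_real_, nrow(x))
    for (col in setdiff(allCols, colnames(y)))
        y[[col]] <- rep(NA_real_, nrow(y))
    rbind(x[, allCols, drop = FALSE], y[, allCols, drop = FALSE])
}

#' Whole-network summary statistics
#'
#' @param e an [EdgeTable-class].
#' @param universe character gene universe the coverage percentage refers to;
#'   must contain every gene touched by an edge.
#' @return a [NetworkStats-class] with gene count, edge count,
#'   `coverage = 100 * V / |universe|`, `mean connectivity = 2 E / V`, and
#'   the percentage of sign-carrying edges that are negative.
#' @export
networkStats <- function(e, universe) {
    stopifnot(methods::is(e, "EdgeTable"))
    universe <- unique(as.character(universe))
    g <- geneIds(e)
    missing <- setdiff(g, universe)
    if (length(missing))
        stop("edge gene(s) absent from the universe: ",
             paste(utils::head(missing, 5L), collapse = ", "))
    nV <- length(g)
    nE <- nEdges(e)
    signed <- e@edges$sign[!is.na(e@edges$sign)]
    methods::new("NetworkStats", nGenes = nV, nEdges = as.integer(nE),
        geneCoveragePct = if (length(universe)) 100 * nV / length(universe)
                          else 0,
        meanConnectivity = if (nV) 2 * nE / nV else 0,
        pctNegativeEdges = if (length(signed))
            100 * sum(signed == "-") / length(signed) else 0)
}

#' Subnetwork between (or within) gene families
#'
#' Extracts edges with one endpoint in `familyA` and the other in `familyB`
#' (within-family edges when the two lists coincide). Two per-gene averages
#' are reported because both conventions appear in the co-expression
#' literature: `pairsPerGene = E / V` (edges per distinct subnetwork gene)
#' and `meanDegree = 2 E / V` (average degree).
#'
#' @param e an [EdgeTable-class].
#' @param familyA,familyB character gene lists (`familyB` defaults to
#'   `familyA`).
#' @return list with `edges` (an [EdgeTable-class]), `degrees` (data.frame
#'   gene, degree over subnetwork genes), `pairsPerGene`, and `meanDegree`.
#' @export
familySubnetwork <- function(e, familyA, familyB = familyA) {
    stopifnot(methods::is(e, "EdgeTable"))
    familyA <- unique(as.character(familyA))
    familyB <- unique(as.character(familyB))
    if (!length(familyA) || !length(familyB))
        stop("family lists must be non-empty")
    d <- e@edges
    keep <- (d$gene_a %in% familyA & d$gene_b %in% familyB) |
            (d$gene_a %in% familyB & d$gene_b %in% familyA)
    sub <- d[keep, , drop = FALSE]
    rownames(sub) <- NULL
    subE <- methods::new("EdgeTable", edges = sub)
    genes <- sort(unique(c(sub$gene_a, sub$gene_b)), method = "radix")
    deg <- vapply(genes, function(g)
        sum(sub$gene_a == g) + sum(sub$gene_b == g), integer(1L))
    nV <- length(genes)
    nE <- nrow(sub)
    list(edges = subE,
         degrees = data.frame(gene = genes, degree = as.integer(deg),
                              row.names = NULL, stringsAsFactors = FALSE),
         pairsPerGene = if (nV) nE / nV else 0,
         meanDegree = if (nV) 2 * nE / nV else 0)
}

#' Top-k correlation neighborhood of a gene
#'
#' The k partners with the highest signed correlation to `gene`, in rank
#' order (ties broken by gene id in byte order). Requesting more partners
#' than exist returns all partners with a warning.
#'
#' @param c a [CorrelationMatrix-class].
#' @param gene gene id present in `c`.
#' @param k neighborhood size (default 300).
#' @return character vector of partner gene ids.
#' @export
topNeighborhood <- function(c, gene, k = 300) {
    stopifnot(methods::is(c, "CorrelationMatrix"))
    g <- geneIds(c)
    if (!(gene %in% g)) stop("gene '", gene, "' not in the matrix")
    if (k <= 0) return(character())
    p <- c@values[gene, ]
    partners <- setdiff(g[!is.na(p)], gene)
    ord <- partners[order(-p[partners], partners, method = "radix")]
    if (k > length(ord)) {
        warning("k exceeds the number of partners; returning all ",
                length(ord))
        k <- length(ord)
    }
    ord[seq_len(k)]
}

#' Overlap of two cross-species neighborhoods through a homolog map
#'
#' Counts homolog pairs `(x, y)` with `x` in the first neighborhood and `y`
#' in the second.
#'
#' @param neighA,neighB character gene lists (e.g. top-300 neighborhoods in
#'   two species).
#' @param homologPairs two-column data.frame of cross-species homolog pairs
#'   (first column in the species of `neighA`).
#' @return list with `n` (count) and `pairs` (the matching rows).
#' @export
homologOverlap <- function(neighA, neighB, homologPairs) {
    stopifnot(is.data.frame(homologPairs), ncol(homologPairs) >= 2L)
    hp <- unique(data.frame(a = as.character(homologPairs[[1L]]),
                            b = as.character(homologPairs[[2L]]),
                            stringsAsFactors = FALSE))
    hit <- hp[hp$a %in% neighA & hp$b %in% neighB, , drop = FALSE]
    rownames(hit) <- NULL
    list(n = nrow(hit), pairs = hit)
}

#' Hypergeometric term enrichment of a gene set
#'
#' For every term annotated in the universe: `k` = set genes carrying the
#' term, `K` = universe genes carrying it, `n` = set size, `N` = universe
#' size; the p-value is the hypergeometric upper tail `P(X >= k)` and `q` is
#' the Benjamini-Hochberg adjustment across all tested terms.
#'
#' @param geneSet character gene list (must be contained in `universe`).
#' @param annotation two-column data.frame (gene, term).
#' @param universe character gene universe.
#' @return data.frame (term, k, K, n, N, p, q) ordered by p.
#' @export
enrichTerms <- function(geneSet, annotation, universe) {
    geneSet <- unique(as.character(geneSet))
    universe <- unique(as.character(universe))
    if (!length(geneSet) || !length(universe))
        stop("gene set and universe must be non-empty")
    if (length(setdiff(geneSet, universe)))
        stop("gene set must be contained in the universe")
    ann <- annotation[annotation[[1L]] %in% universe, 1:2]
    names(ann) <- c("gene", "term")
    ann <- unique(ann)
    if (!nrow(ann)) stop("no annotation for the universe")
    N <- length(universe)
    n <- length(geneSet)
    byTerm <- split(ann$gene, ann$term)
    rows <- lapply(sort(names(byTerm), method = "radix"), function(tm) {
        K <- length(byTerm[[tm]])
        k <- sum(byTerm[[tm]] %in% geneSet)
        p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
        data.frame(term = tm, k = k, K = K, n = n, N = N, p = p,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$q <- stats::p.adjust(out$p, method = "BH")
    out <- out[order(out$p, out$term, method = "radix"), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Rank candidate hub genes by degree
#'
#' @param e an [EdgeTable-class].
#' @param candidates character gene list; genes without edges get degree 0.
#' @return data.frame (gene, degree) ordered by decreasing degree, ties by
#'   gene id.
#' @export
hubRank <- function(e, candidates) {
    stopifnot(methods::is(e, "EdgeTable"))
    candidates <- unique(as.character(candidates))
    d <- e@edges
    deg <- vapply(candidates, function(g)
        sum(d$gene_a == g) + sum(d$gene_b == g), integer(1L))
    out <- data.frame(gene = candidates, degree = as.integer(deg),
                      stringsAsFactors = FALSE)
    out <- out[order(-out$degree, out$gene, method = "radix"), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Read / write edge tables as TSV
#'
#' Columns gene_a, gene_b, pcc, rank_ab, rank_ba, mr, tom, sign, methods
#' (plus any method-qualified columns from integration); one row per
#' undirected pair with `gene_a < gene_b`. Empty cells encode `NA`.
#'
#' @param e an [EdgeTable-class].
#' @param path TSV path.
#' @export
writeEdgeTable <- function(e, path) {
    stopifnot(methods::is(e, "EdgeTable"))
    d <- e@edges
    num <- vapply(d, is.numeric, logical(1L))
    d[num] <- lapply(d[num], function(x)
        ifelse(is.na(x), "", format(x, digits = 15, trim = TRUE,
                                    scientific = FALSE)))
    utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "", fileEncoding = "UTF-8")
    invisible(path)
}

#' @rdname writeEdgeTable
#' @export
readEdgeTable <- function(path) {
    d <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           na.strings = "", colClasses = "character",
                           fileEncoding = "UTF-8")
    for (col in setdiff(colnames(d), c("gene_a", "gene_b", "sign", "methods")))
        d[[col]] <- as.numeric(d[[col]])
    if (!nrow(d)) {
        d$sign <- character()
        d$methods <- character()
    }
    methods::new("EdgeTable", edges = d)
}
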