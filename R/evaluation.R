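## Gold-standard construction, ROC/AUC scoring of edge sets, and the
## AUC-maximizing correlation-threshold grid search.

## run expr with a private RNG state seeded by `seed`
.withSeed <- function(seed, expr) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    expr
}

.pairKey <- function(a, b) paste(a, b, sep = "\r")

## all unordered pairs of a character vector, gene_a < gene_b (byte order)
.allPairs <- function(genes) {
    genes <- sort(genes, method = "radix")
    n <- length(genes)
    if (n < 2L) return(data.frame(gene_a = character(), gene_b = character()))
    i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
    j <- unlist(lapply(seq_len(n - 1L), function(k) (k + 1L):n))
    data.frame(gene_a = genes[i], gene_b = genes[j], stringsAsFactors = FALSE)
}

#' Build a gold standard from a gene-to-term annotation map
#'
#' Positive pairs are all unordered pairs of universe genes sharing at least
#' one annotation term. Negative pairs are a seeded uniform sample, without
#' replacement, of universe pairs sharing no term (pairs involving
#' unannotated genes qualify), of size `round(negRatio * n_pos)`, capped at
#' availability with a warning.
#'
#' @param annotation two-column data.frame (gene, term); a gene may carry
#'   several terms over several rows.
#' @param genes gene universe (character).
#' @param negRatio negatives per positive (default 1).
#' @param seed integer seed for the negative sample.
#' @return a [GoldStandard-class].
#' @export
buildGoldStandard <- function(annotation, genes, negRatio = 1, seed = 1L) {
    stopifnot(is.data.frame(annotation), ncol(annotation) >= 2L)
    genes <- sort(unique(as.character(genes)), method = "radix")
    ann <- annotation[annotation[[1L]] %in% genes, 1:2]
    names(ann) <- c("gene", "term")
    if (length(unique(ann$gene)) < 2L)
        stop("need at least 2 annotated genes in the universe")
    terms <- split(as.character(ann$term), as.character(ann$gene))
    pairs <- .allPairs(genes)
    share <- mapply(function(a, b) {
        ta <- terms[[a]]; tb <- terms[[b]]
        !is.null(ta) && !is.null(tb) && length(intersect(ta, tb)) > 0L
    }, pairs$gene_a, pairs$gene_b, USE.NAMES = FALSE)
    nPos <- sum(share)
    if (!nPos) stop("no pair of universe genes shares a term")
    negPool <- which(!share)
    if (!length(negPool)) stop("no term-disjoint pair available for negatives")
    want <- round(negRatio * nPos)
    if (want > length(negPool)) {
        warning("only ", length(negPool), " negative pairs available; capped")
        want <- length(negPool)
    }
    negIdx <- .withSeed(seed, sort(sample(negPool, want)))
    p <- rbind(cbind(pairs[share, , drop = FALSE], label = "positive"),
               cbind(pairs[negIdx, , drop = FALSE], label = "negative"))
    rownames(p) <- NULL
    methods::new("GoldStandard", pairs = p,
                 source = "annotation-sharing pairs", seed = as.integer(seed))
}

#' Score the edges of an edge table for ROC ranking
#'
#' Converts one of the stored score columns into a "higher is more
#' co-expressed" score: `pcc_abs` gives `|pcc|`, `pcc` the signed
#' correlation, `neg_mr` the reciprocal mutual rank `1 / mr`, `tom` the
#' topological overlap. `integrated` min-max-normalises each available score
#' column across the table and takes the per-edge maximum, which makes the
#' heterogeneous columns of an integrated network comparable. Gene pairs
#' absent from the edge table are treated as "not co-expressed" and receive
#' score 0 when evaluated against a gold standard.
#'
#' @param e an [EdgeTable-class].
#' @param method one of `"pcc_abs"`, `"pcc"`, `"neg_mr"`, `"tom"`,
#'   `"integrated"`.
#' @return data.frame (gene_a, gene_b, score).
#' @export
scoreEdges <- function(e, method = c("pcc_abs", "pcc", "neg_mr", "tom",
                                     "integrated")) {
    stopifnot(methods::is(e, "EdgeTable"))
    method <- match.arg(method)
    d <- e@edges
    need <- switch(method, pcc_abs = "pcc", pcc = "pcc", neg_mr = "mr",
                   tom = "tom", integrated = NULL)
    if (!is.null(need) && (nrow(d) > 0L) && all(is.na(d[[need]])))
        stop("score column '", need, "' absent from this edge table")
    s <- switch(method,
        pcc_abs = abs(d$pcc),
        pcc = d$pcc,
        neg_mr = 1 / d$mr,
        tom = d$tom,
        integrated = {
            mm <- function(x) {
                if (all(is.na(x))) return(rep(NA_real_, length(x)))
                rng <- range(x, na.rm = TRUE)
                if (diff(rng) == 0) return(ifelse(is.na(x), NA_real_, 1))
                (x - rng[1L]) / diff(rng)
            }
            cand <- cbind(mm(abs(d$pcc)), mm(1 / d$mr), mm(d$tom))
            if (nrow(d)) apply(cand, 1L, function(r)
                if (all(is.na(r))) NA_real_ else max(r, na.rm = TRUE))
            else numeric()
        })
    data.frame(gene_a = d$gene_a, gene_b = d$gene_b, score = s,
               stringsAsFactors = FALSE)
}

#' ROC curve and AUC of scored pairs against a gold standard
#'
#' Gold-standard pairs missing from the score list receive score 0 (absence
#' from an edge set means "not called co-expressed"). The AUC is computed
#' from the rank statistic with the half-credit tie convention, so it equals
#' the Mann-Whitney U statistic divided by `n_pos * n_neg`; the curve is a
#' threshold sweep over the distinct scores (trapezoidal geometry).
#'
#' @param gs a [GoldStandard-class].
#' @param scores data.frame (gene_a, gene_b, score) as from [scoreEdges()].
#' @return a [RocResult-class].
#' @export
rocAuc <- function(gs, scores) {
    stopifnot(methods::is(gs, "GoldStandard"))
    p <- gs@pairs
    s <- rep(0, nrow(p))
    if (nrow(scores)) {
        key <- .pairKey(pmin(scores$gene_a, scores$gene_b),
                        pmax(scores$gene_a, scores$gene_b))
        hit <- match(.pairKey(p$gene_a, p$gene_b), key)
        s[!is.na(hit)] <- scores$score[hit[!is.na(hit)]]
    }
    if (anyNA(s)) stop("scores must not be NA")
    pos <- p$label == "positive"
    nPos <- sum(pos)
    nNeg <- sum(!pos)
    if (!nPos || !nNeg) stop("need both labels to compute an ROC")
    rk <- rank(s)  # average ranks: half credit for ties
    aucVal <- (sum(rk[pos]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
    thr <- sort(unique(s), decreasing = TRUE)
    tprs <- vapply(thr, function(t) sum(s[pos] >= t) / nPos, numeric(1L))
    fprs <- vapply(thr, function(t) sum(s[!pos] >= t) / nNeg, numeric(1L))
    curve <- data.frame(fpr = c(0, fprs), tpr = c(0, tprs))
    if (curve$fpr[nrow(curve)] < 1 || curve$tpr[nrow(curve)] < 1)
        curve <- rbind(curve, data.frame(fpr = 1, tpr = 1))
    methods::new("RocResult", auc = unname(aucVal), nPos = as.integer(nPos),
                 nNeg = as.integer(nNeg), curve = curve)
}

#' Grid search for the AUC-maximizing correlation-threshold offset
#'
#' Starting from the top/bottom quantile cuts, the offset delta is swept over
#' `0, step, 2 * step, ..., maxOffset`. For each delta the hard-threshold
#' edge set is built, scored by `|pcc|`, and its AUC against the gold
#' standard computed. The best offset is the argmax of the AUC column (ties
#' resolved toward the smallest delta); offsets yielding an empty edge set
#' are recorded with `NA` AUC and skipped with a warning.
#'
#' @param c a [CorrelationMatrix-class].
#' @param gs a [GoldStandard-class].
#' @param step grid step (default 0.1, must be positive).
#' @param maxOffset largest offset tried (default 0.4).
#' @param topQ,bottomQ base quantile fractions (defaults 0.05).
#' @param symmetric tighten the negative cut too (default TRUE).
#' @return list with `bestOffset` (numeric) and `table` (data.frame with
#'   columns offset, pos_cut, neg_cut, n_edges, auc).
#' @export
optimizePccOffset <- function(c, gs, step = 0.1, maxOffset = 0.4,
                              topQ = 0.05, bottomQ = 0.05, symmetric = TRUE) {
    stopifnot(methods::is(c, "CorrelationMatrix"),
              methods::is(gs, "GoldStandard"))
    if (step <= 0) stop("step must be positive")
    offsets <- seq(0, maxOffset, by = step)
    rows <- lapply(offsets, function(d) {
        t <- suppressWarnings(
            pccQuantileThresholds(c, topQ, bottomQ, offset = d,
                                  symmetric = symmetric))
        e <- pccEdgeFilter(c, t)
        aucVal <- NA_real_
        if (nEdges(e) > 0L)
            aucVal <- auc(rocAuc(gs, scoreEdges(e, "pcc_abs")))
        data.frame(offset = d, pos_cut = t@posCut, neg_cut = t@negCut,
                   n_edges = nEdges(e), auc = aucVal)
    })
    tab <- do.call(rbind, rows)
    if (any(is.na(tab$auc)))
        warning("offset(s) with an empty edge set skipped for the argmax: ",
                paste(tab$offset[is.na(tab$auc)], collapse = ", "))
    if (all(is.na(tab$auc))) stop("every offset produced an empty edge set")
    best <- tab$offset[which.max(tab$auc)]  # first max = smallest offset
    list(bestOffset = best, table = tab)
}

#' Write an offset-optimization AUC table to TSV
#' @param opt result of [optimizePccOffset()].
#' @param path output path.
#' @export
writeAucTable <- function(opt, path) {
    utils::write.table(opt$table, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    invisible(path)
}

#' Read / write gold-standard pair tables
#' @param gs a [GoldStandard-class].
#' @param path TSV path (columns gene_a, gene_b, label).
#' @export
writeGoldStandard <- function(gs, path) {
    utils::write.table(gs@pairs, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    invisible(path)
}

#' @rdname writeGoldStandard
#' @export
readGoldStandard <- function(path) {
    p <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character", quote = "",
                           fileEncoding = "UTF-8")
    methods::new("GoldStandard", pairs = p, source = paste0("file:", path),
                 seed = NA_integer_)
}
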