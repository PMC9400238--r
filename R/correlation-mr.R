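## Pearson correlations, directional ranks, mutual ranks, and the two hard
## edge filters (quantile PCC cuts; MR/unidirectional-rank cuts).

#' Pairwise Pearson correlation between genes
#'
#' Correlates every pair of gene expression vectors across samples,
#' \deqn{r = \frac{\sum_i (x_i - \bar x)(y_i - \bar y)}
#'                {\sqrt{\sum_i (x_i - \bar x)^2 \sum_i (y_i - \bar y)^2}},}
#' where the sums run over samples. Genes with zero variance have no defined
#' correlation; they are flagged in the result's `undefined` slot and their
#' rows/columns are `NA` rather than silently propagated.
#'
#' @param x a [TpmExperiment-class] with at least 3 samples, or a numeric
#'   genes-by-samples matrix with gene rownames.
#' @return a [CorrelationMatrix-class].
#' @examples
#' m <- rbind(g1 = c(1, 2, 3, 4, 5), g2 = c(2, 4, 6, 8, 10),
#'            g3 = c(5, 4, 3, 2, 1), g4 = c(1, 3, 2, 5, 4))
#' colnames(m) <- paste0("s", 1:5)
#' as.matrix(computePcc(m))["g1", "g4"]  # 0.8
#' @export
computePcc <- function(x) {
    v <- if (methods::is(x, "TpmExperiment")) tpm(x) else as.matrix(x)
    if (is.null(rownames(v))) stop("gene rownames are required")
    if (nrow(v) < 2L) stop("need at least 2 genes")
    if (ncol(v) < 3L) stop("need at least 3 samples for correlation")
    sds <- apply(v, 1L, stats::sd)
    undef <- sds == 0
    names(undef) <- rownames(v)
    cc <- suppressWarnings(stats::cor(t(v)))
    cc[undef, ] <- NA_real_
    cc[, undef] <- NA_real_
    diag(cc)[!undef] <- 1
    cc <- (cc + t(cc)) / 2  # guard symmetry against rounding
    if (any(undef))
        warning(sum(undef), " zero-variance gene(s) have undefined correlations")
    methods::new("CorrelationMatrix", values = cc, undefined = undef)
}

#' Quantile-based hard correlation thresholds
#'
#' The positive cut is the `1 - topQ` quantile of all defined off-diagonal
#' correlations plus `offset`; the negative cut is the `bottomQ` quantile
#' minus `offset` (symmetric tightening; set `symmetric = FALSE` to tighten
#' only the positive side). Quantiles use the linear-interpolation convention
#' (`stats::quantile` type 7). Cuts exceeding \eqn{[-1, 1]} are clamped with a
#' warning.
#'
#' @param c a [CorrelationMatrix-class].
#' @param topQ,bottomQ quantile fractions (defaults 0.05 each).
#' @param offset additive tightening term (default 0).
#' @param symmetric apply `offset` to the negative cut as well (default TRUE).
#' @return a [PccThresholds-class].
#' @export
pccQuantileThresholds <- function(c, topQ = 0.05, bottomQ = 0.05, offset = 0,
                                  symmetric = TRUE) {
    stopifnot(methods::is(c, "CorrelationMatrix"))
    v <- c@values[upper.tri(c@values)]
    v <- v[!is.na(v)]
    if (!length(v)) stop("no defined off-diagonal correlations")
    pos <- unname(stats::quantile(v, 1 - topQ, type = 7)) + offset
    neg <- unname(stats::quantile(v, bottomQ, type = 7)) -
        if (symmetric) offset else 0
    if (pos > 1) {
        warning("positive cut exceeded 1; clamped")
        pos <- 1
    }
    if (neg < -1) {
        warning("negative cut fell below -1; clamped")
        neg <- -1
    }
    methods::new("PccThresholds", posCut = pos, negCut = neg, topQ = topQ,
                 bottomQ = bottomQ, offset = offset)
}

#' Directional correlation ranks
#'
#' For each gene A, partners are sorted by signed correlation descending
#' (self excluded) and `Rank(A -> B)` is B's position in that order. Ties are
#' broken by gene id in byte (C-locale) order so ranks are deterministic.
#' Globally undefined (zero-variance) genes are excluded from every ranking;
#' their rows and columns are `NA`.
#'
#' @param c a [CorrelationMatrix-class].
#' @param rank_on `"signed"` (default; mutual-rank convention of the
#'   co-expression databases this pipeline follows) or `"abs"` to rank on
#'   `|pcc|`.
#' @return a [RankMatrix-class].
#' @export
computeRanks <- function(c, rank_on = c("signed", "abs")) {
    stopifnot(methods::is(c, "CorrelationMatrix"))
    rank_on <- match.arg(rank_on)
    v <- c@values
    if (rank_on == "abs") v <- abs(v)
    g <- rownames(v)
    def <- !c@undefined
    if (!any(def)) stop("all genes have undefined correlations")
    r <- matrix(NA_real_, nrow(v), ncol(v), dimnames = dimnames(v))
    defIdx <- which(def)
    for (i in defIdx) {
        j <- setdiff(defIdx, i)
        ord <- j[order(-v[i, j], g[j], method = "radix")]
        r[i, ord] <- seq_along(ord)
    }
    methods::new("RankMatrix", values = r)
}

#' Mutual ranks: geometric mean of the two directional ranks
#'
#' `MR(A, B) = sqrt(Rank(A -> B) * Rank(B -> A))`; symmetric by construction,
#' with `MR >= 1`. Low MR means the two genes rank each other among their top
#' correlation partners.
#'
#' @param r a [RankMatrix-class].
#' @return a [MutualRankMatrix-class].
#' @examples
#' # Rank(A->B) = 4 and Rank(B->A) = 9 give MR = 6
#' sqrt(4 * 9)
#' @export
computeMr <- function(r) {
    stopifnot(methods::is(r, "RankMatrix"))
    v <- r@values
    mr <- sqrt(v * t(v))
    diag(mr) <- NA_real_
    methods::new("MutualRankMatrix", values = mr)
}

#' Mutual-rank edge filter
#'
#' Retains gene pairs by two rules: a bidirectional rule `MR < mrCut` and a
#' unidirectional rule `min(Rank(A->B), Rank(B->A)) < uniCut`, both strict.
#' `combine = "any"` keeps a pair satisfying either rule (the union of the
#' two rule outputs); `combine = "all"` requires both.
#'
#' @param mrm a [MutualRankMatrix-class].
#' @param r the [RankMatrix-class] the mutual ranks came from.
#' @param c the [CorrelationMatrix-class], used to attach `pcc` and sign to
#'   each retained edge.
#' @param mrCut mutual-rank cutoff (default 30).
#' @param uniCut unidirectional rank cutoff (default 3).
#' @param combine `"any"` (default) or `"all"`.
#' @return an [EdgeTable-class] with `methods = "mr"`.
#' @export
mrEdgeFilter <- function(mrm, r, c, mrCut = 30, uniCut = 3,
                         combine = c("any", "all")) {
    stopifnot(methods::is(mrm, "MutualRankMatrix"),
              methods::is(r, "RankMatrix"),
              methods::is(c, "CorrelationMatrix"))
    combine <- match.arg(combine)
    g <- geneIds(mrm)
    if (!identical(g, geneIds(r)) || !identical(g, geneIds(c)))
        stop("inconsistent gene universes")
    mr <- mrm@values
    rk <- r@values
    ut <- upper.tri(mr)
    minRank <- pmin(rk, t(rk))
    bid <- mr < mrCut
    uni <- minRank < uniCut
    keep <- if (combine == "any") (bid | uni) else (bid & uni)
    keep[is.na(keep)] <- FALSE
    idx <- which(keep & ut, arr.ind = TRUE)
    edgeTable(gene_a = g[idx[, 1L]], gene_b = g[idx[, 2L]],
              pcc = c@values[idx], rank_ab = rk[idx],
              rank_ba = rk[idx[, c(2L, 1L), drop = FALSE]],
              mr = mr[idx], methods = "mr")
}

#' Hard-threshold correlation edge filter
#'
#' Keeps a pair when `pcc >= posCut` or `pcc <= negCut` (closed intervals:
#' a correlation exactly at a cut is retained). Edge sign follows the sign of
#' the correlation.
#'
#' @param c a [CorrelationMatrix-class].
#' @param t a [PccThresholds-class].
#' @return an [EdgeTable-class] with `methods = "pcc"`.
#' @export
pccEdgeFilter <- function(c, t) {
    stopifnot(methods::is(c, "CorrelationMatrix"),
              methods::is(t, "PccThresholds"))
    v <- c@values
    g <- rownames(v)
    keep <- (v >= t@posCut | v <= t@negCut)
    keep[is.na(keep)] <- FALSE
    idx <- which(keep & upper.tri(v), arr.ind = TRUE)
    edgeTable(gene_a = g[idx[, 1L]], gene_b = g[idx[, 2L]],
              pcc = v[idx], methods = "pcc")
}
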