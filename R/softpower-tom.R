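## Scale-free soft-threshold selection, unsigned adjacency, topological
## overlap, and TOM-based candidate edge extraction.

#' Scale-free topology fit over candidate soft powers
#'
#' For each candidate power beta the unsigned adjacency `a_ij = |pcc_ij|^beta`
#' is formed and each gene's connectivity `k_i = sum_{j != i} a_ij` computed.
#' Connectivities are binned into `nBins` equal-width bins; the log-log
#' regression `log10(p(k)) ~ log10(mean k)` over non-empty bins yields the
#' fit, reported as a signed R-squared (negated when the slope is positive,
#' since scale-free degree distributions require a decreasing fit). The
#' selected power is the smallest beta whose signed R-squared reaches
#' `r2Target`.
#'
#' @param c a [CorrelationMatrix-class] over at least 10 genes.
#' @param betas integer candidate powers (default `1:20`).
#' @param nBins number of connectivity histogram bins (default 10).
#' @param r2Target signed R-squared target (default 0.90).
#' @return a [SoftPowerReport-class]; `selectedBeta(r)` is `NA` when no
#'   candidate reaches the target.
#' @export
fitScaleFree <- function(c, betas = 1:20, nBins = 10, r2Target = 0.90) {
    stopifnot(methods::is(c, "CorrelationMatrix"))
    a0 <- abs(c@values)
    a0[is.na(a0)] <- 0
    diag(a0) <- 0
    G <- nrow(a0)
    if (G < 10L) stop("scale-free fit needs at least 10 genes")
    if (all(a0 == 0)) stop("all correlations are zero; nothing to fit")
    betas <- sort(unique(as.integer(betas)))
    rows <- lapply(betas, function(b) {
        a <- a0^b
        k <- rowSums(a)
        out <- data.frame(beta = b, r2 = NA_real_, slope = NA_real_,
                          mean_k = mean(k))
        if (max(k) - min(k) < .Machine$double.eps^0.5) return(out)
        breaks <- seq(min(k), max(k), length.out = nBins + 1L)
        bin <- cut(k, breaks = breaks, include.lowest = TRUE)
        cnt <- tabulate(bin, nbins = nBins)
        dk <- tapply(k, bin, mean)[cnt > 0L]
        p <- cnt[cnt > 0L] / G
        ok <- dk > 0
        if (sum(ok) < 3L) return(out)
        fit <- stats::lm(log10(p[ok]) ~ log10(dk[ok]))
        sl <- unname(stats::coef(fit)[2L])
        r2 <- summary(fit)$r.squared
        out$slope <- sl
        out$r2 <- if (is.na(sl)) NA_real_ else if (sl < 0) r2 else -r2
        out
    })
    tab <- do.call(rbind, rows)
    if (all(is.na(tab$r2)))
        stop("degenerate connectivity distribution at every candidate power")
    hit <- which(!is.na(tab$r2) & tab$r2 >= r2Target)
    sel <- if (length(hit)) as.integer(tab$beta[hit[1L]]) else NA_integer_
    tab$selected <- as.integer(!is.na(sel) & tab$beta == sel)
    methods::new("SoftPowerReport", table = tab, selectedBeta = sel,
                 r2Target = r2Target)
}

#' Fallback soft power from the sample count
#'
#' When no candidate power reaches the scale-free fit target (common for
#' strongly modular expression designs, whose degree distributions are not
#' scale-free), the conventional recourse for unsigned networks is a default
#' power keyed to the number of samples: 9 below 20 samples, 8 for 20-29,
#' 7 for 30-39, 6 for 40 and more.
#'
#' @param nSamples number of samples the correlations were computed from.
#' @return integer power.
#' @export
defaultSoftPower <- function(nSamples) {
    if (nSamples < 20) 9L else if (nSamples < 30) 8L
    else if (nSamples < 40) 7L else 6L
}

#' Unsigned soft-threshold adjacency
#'
#' `a_ij = |pcc_ij|^beta`, diagonal 1. Pairs with undefined correlations get
#' adjacency 0 with a warning.
#'
#' @param c a [CorrelationMatrix-class].
#' @param beta integer power `>= 1`.
#' @return an [AdjacencyMatrix-class].
#' @export
computeAdjacency <- function(c, beta) {
    stopifnot(methods::is(c, "CorrelationMatrix"))
    beta <- as.integer(beta)
    if (is.na(beta) || beta < 1L) stop("beta must be an integer >= 1")
    a <- abs(c@values)^beta
    if (anyNA(a)) {
        warning("undefined correlations set to adjacency 0")
        a[is.na(a)] <- 0
    }
    diag(a) <- 1
    methods::new("AdjacencyMatrix", values = a, beta = beta)
}

#' Topological overlap matrix
#'
#' Unsigned TOM combining direct adjacency with shared-neighbour
#' ("indirect") adjacency:
#' \deqn{TOM_{ij} = \frac{L_{ij} + a_{ij}}{\min(k_i, k_j) + 1 - a_{ij}},}
#' with \eqn{L_{ij} = \sum_{u \ne i,j} a_{iu} a_{uj}} and
#' \eqn{k_i = \sum_{u \ne i} a_{iu}}. The diagonal is set to 1. For unsigned
#' adjacencies the denominator is at least 1, so the formula is defined
#' everywhere, including fully isolated genes (TOM 0).
#'
#' @param a an [AdjacencyMatrix-class].
#' @return a [TomMatrix-class].
#' @examples
#' # 3 genes with a12 = 0.8, a13 = 0.6, a23 = 0.5:
#' # TOM12 = (0.6 * 0.5 + 0.8) / (min(1.4, 1.3) + 1 - 0.8) = 1.1 / 1.5
#' @export
computeTom <- function(a) {
    stopifnot(methods::is(a, "AdjacencyMatrix"))
    A <- a@values
    diag(A) <- 0
    L <- A %*% A          # zero diagonal of A excludes u = i and u = j
    k <- rowSums(A)
    denom <- outer(k, k, pmin) + 1 - A
    tom <- (L + A) / denom
    diag(tom) <- 1
    tom[tom > 1] <- 1     # guard against rounding at the perfect-overlap limit
    tom <- (tom + t(tom)) / 2
    methods::new("TomMatrix", values = tom)
}

#' TOM candidate edge filter
#'
#' Keeps gene pairs with `tom > tomCut` (strict). When the correlation matrix
#' is supplied, each retained edge also carries the underlying correlation
#' and its sign.
#'
#' @param t a [TomMatrix-class].
#' @param tomCut cutoff (default 0.1).
#' @param c optional [CorrelationMatrix-class] on the same genes.
#' @return an [EdgeTable-class] with `methods = "tom"`.
#' @export
tomEdgeFilter <- function(t, tomCut = 0.1, c = NULL) {
    stopifnot(methods::is(t, "TomMatrix"))
    v <- t@values
    g <- rownames(v)
    keep <- v > tomCut
    keep[is.na(keep)] <- FALSE
    idx <- which(keep & upper.tri(v), arr.ind = TRUE)
    pcc <- rep(NA_real_, nrow(idx))
    if (!is.null(c)) {
        stopifnot(methods::is(c, "CorrelationMatrix"))
        if (!identical(g, geneIds(c))) stop("inconsistent gene universes")
        pcc <- c@values[idx]
    }
    edgeTable(gene_a = g[idx[, 1L]], gene_b = g[idx[, 2L]],
              pcc = pcc, tom = v[idx], methods = "tom")
}
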